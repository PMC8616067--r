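#' End-to-end experiment workflow: simulate, analyze, report
#'
#' File-based drivers tying the pipeline together: a simulated experiment
#' mirroring the study protocol (resistance levels 2-5, 3 trials each),
#' a full analysis pass (preprocess, segment, normalize, decompose,
#' metrics, statistics) and figure/summary reporting.
#'
#' @name interface
NULL

#' Pipeline configuration
#'
#' @param highpass_hz,lowpass_hz envelope filter cutoffs (Hz).
#' @param filter_order Butterworth order per pass.
#' @param t_norm normalized cycle length (samples).
#' @param n_phases fixed decomposition order (3 pedaling phases).
#' @param vaf_threshold VAF threshold used when reporting/selecting order.
#' @param n_max largest order tried by order selection.
#' @param restarts,per_cycle_restarts NMF restarts for condition-level and
#'   per-cycle fits.
#' @param max_iter,tol NMF iteration cap and convergence tolerance.
#' @param min_period_s,prominence_frac segmentation settings (`NULL` means
#'   infer the period from the composite autocorrelation).
#' @param onset_frac anchor threshold fraction.
#' @param stability_mode `"nmf"` or `"project"`, see [per_cycle_models()].
#' @param stats_method,p_adjust,alpha comparison settings, see
#'   [pairwise_tests()].
#' @param seed root seed for all pipeline randomness.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(highpass_hz = 10, lowpass_hz = 10,
                            filter_order = 4, t_norm = 200L, n_phases = 3L,
                            vaf_threshold = 0.95, n_max = 4L,
                            restarts = 10L, per_cycle_restarts = 5L,
                            max_iter = 1000L, tol = 1e-6,
                            min_period_s = NULL, prominence_frac = 0.2,
                            onset_frac = 0.2,
                            stability_mode = c("nmf", "project"),
                            stats_method = c("mann_whitney", "signed_rank"),
                            p_adjust = "none", alpha = 0.05, seed = 1L) {
  cfg <- list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
              filter_order = filter_order, t_norm = as.integer(t_norm),
              n_phases = as.integer(n_phases),
              vaf_threshold = vaf_threshold, n_max = as.integer(n_max),
              restarts = as.integer(restarts),
              per_cycle_restarts = as.integer(per_cycle_restarts),
              max_iter = as.integer(max_iter), tol = tol,
              min_period_s = min_period_s, prominence_frac = prominence_frac,
              onset_frac = onset_frac,
              stability_mode = match.arg(stability_mode),
              stats_method = match.arg(stats_method),
              p_adjust = p_adjust, alpha = alpha, seed = as.integer(seed))
  stopifnot(cfg$highpass_hz > 0, cfg$lowpass_hz > 0, cfg$t_norm >= 10L,
            cfg$n_phases >= 1L, cfg$vaf_threshold <= 1,
            cfg$restarts >= 1L, cfg$alpha > 0, cfg$alpha < 1)
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(cfg, f)
  unname(tools::md5sum(f))
}

#' Write / read a trial as delimited text
#'
#' Trials are stored as CSV with one header row of muscle labels and one
#' column per muscle (samples in rows, microvolts); acquisition metadata
#' travels in a YAML sidecar.
#'
#' @param session an [emg_session()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(session, path) {
  dt <- data.table::as.data.table(t(session$samples))
  data.table::setnames(dt, session$muscle_labels)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_trial_csv
#' @param fs_hz,condition_label,trial_id,participant_id metadata for the
#'   session object (overridden by a `<path>.meta.yaml` sidecar if present).
#' @export
read_trial_csv <- function(path, fs_hz = 1500, condition_label = NA_integer_,
                           trial_id = 1L, participant_id = "P01") {
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    fs_hz <- meta$fs_hz %||% fs_hz
    condition_label <- meta$condition_label %||% condition_label
    trial_id <- meta$trial_id %||% trial_id
    participant_id <- meta$participant_id %||% participant_id
  }
  dt <- data.table::fread(path)
  emg_session(t(as.matrix(dt)), fs_hz, names(dt), condition_label,
              trial_id, participant_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full experiment to disk
#'
#' Writes one simulated participant: resistance levels 2-5, 3 trials per
#' level (the study protocol), as trial CSVs with YAML metadata and
#' ground-truth sidecars, plus a manifest with MD5 checksums. Byte-identical
#' across reruns with the same seed.
#'
#' @param out_dir output directory (created if needed).
#' @param seed root seed.
#' @param config base [synth_config()]; per-level effects are applied via
#'   [apply_resistance_effect()].
#' @param levels resistance levels to simulate.
#' @param trials_per_level trials per level.
#' @param participant_id participant label.
#' @return invisible data.frame manifest (file, md5).
#' @export
simulate_experiment <- function(out_dir, seed = 1L, config = synth_config(),
                                levels = 2:5, trials_per_level = 3L,
                                participant_id = "P01") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  trial_no <- 0L
  for (level in levels) {
    cfg <- apply_resistance_effect(config, level)
    cfg$seed <- as.integer(seed)
    for (t in seq_len(trials_per_level)) {
      trial_no <- trial_no + 1L
      gen <- generate_trial(cfg, trial_id = trial_no,
                            participant_id = participant_id)
      stem <- file.path(out_dir, sprintf("level%d_trial%d", level, t))
      write_trial_csv(gen$session, paste0(stem, ".csv"))
      yaml::write_yaml(list(fs_hz = cfg$fs_hz, condition_label = level,
                            trial_id = trial_no,
                            participant_id = participant_id),
                       paste0(stem, ".csv.meta.yaml"))
      tr <- gen$truth
      yaml::write_yaml(list(
        condition_label = level, trial_id = trial_no,
        true_boundaries = as.integer(tr$true_boundaries),
        cycle_len = tr$cycle_len,
        true_W = apply(tr$true_W, 1, as.list),
        centers = apply(tr$centers, 1, as.list),
        timing_jitter_sd = cfg$timing_jitter_sd,
        amplitude_jitter_sd = cfg$amplitude_jitter_sd
      ), paste0(stem, ".truth.yaml"))
      files <- c(files, paste0(stem, c(".csv", ".csv.meta.yaml",
                                       ".truth.yaml")))
    }
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  yaml::write_yaml(lapply(seq_len(nrow(manifest)), function(i) {
    list(file = manifest$file[i], md5 = manifest$md5[i])
  }), file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

# In-memory analysis of one session: a list of emg_session trials ->
# all pipeline tables. The file-based analyze_experiment() wraps this.
analyze_session <- function(sessions, config = pipeline_config()) {
  envs <- preprocess_session(sessions, config$highpass_hz, config$lowpass_hz,
                             config$filter_order)
  norm_by_trial <- lapply(envs, function(env) {
    comp <- composite_envelope(env)
    b <- detect_boundaries(comp, env$fs_hz, config$min_period_s,
                           config$prominence_frac)
    cs <- segment_cycles(env, b)
    normalize_cycles(cs, config$t_norm, config$onset_frac)
  })
  conds <- sort(unique(vapply(envs, function(e) as.integer(e$condition_label),
                              integer(1))))
  reference <- NULL
  models <- list()
  vaf_rows <- list()
  contrib_rows <- list()
  stab_rows <- list()
  for (lv in conds) {
    idx <- which(vapply(envs, function(e) identical(as.integer(e$condition_label), lv),
                        logical(1)))
    ncs <- bind_normalized_cycles(norm_by_trial[idx])
    M <- concat_cycles(ncs)
    fit <- nmf(M, config$n_phases, seed = derive_seed(config$seed, lv),
               restarts = config$restarts, max_iter = config$max_iter,
               tol = config$tol)
    fit <- normalize_model(fit)
    if (is.null(reference)) {
      # order the reference phases by the peak position of the cycle-folded
      # mean temporal pattern, so phase 1 is the earliest (traction) burst
      nc_cond <- ncol(fit$H) %/% config$t_norm
      peaks <- vapply(seq_len(nrow(fit$H)), function(p) {
        which.max(rowMeans(matrix(fit$H[p, ], config$t_norm, nc_cond)))
      }, integer(1))
      ord <- order(peaks)
      fit$W <- fit$W[, ord, drop = FALSE]
      fit$H <- fit$H[ord, , drop = FALSE]
      reference <- fit
    } else {
      fit <- match_phases(fit, reference)
    }
    models[[as.character(lv)]] <- fit
    vaf_rows[[length(vaf_rows) + 1L]] <-
      data.frame(condition = lv, order = config$n_phases, vaf = fit$vaf,
                 vaf_threshold = config$vaf_threshold,
                 reached = fit$vaf >= config$vaf_threshold)

    # per-cycle metrics
    pcm <- per_cycle_models(ncs, fit, mode = config$stability_mode,
                            seed = derive_seed(config$seed, 100L + lv),
                            restarts = config$per_cycle_restarts,
                            max_iter = config$max_iter, tol = config$tol)
    for (k in seq_along(pcm$models)) {
      ci <- relative_contribution(pcm$models[[k]])
      contrib_rows[[length(contrib_rows) + 1L]] <-
        data.frame(condition = lv,
                   trial = ncs$trial_of_cycle[pcm$cycle_index[k]],
                   cycle = pcm$cycle_index[k],
                   phase = seq_along(ci), value = unname(ci))
    }
    # condition-level stability plus per-trial stability for statistics
    st <- stability_indices(pcm)
    st$condition <- lv
    st$trial <- NA_integer_
    stab_rows[[length(stab_rows) + 1L]] <- st
    for (tr in unique(ncs$trial_of_cycle)) {
      sel <- which(ncs$trial_of_cycle[pcm$cycle_index] == tr)
      if (length(sel) < 2L) next
      sub <- list(models = pcm$models[sel], n_cycles = length(sel))
      st_t <- stability_indices(sub)
      st_t$condition <- lv
      st_t$trial <- tr
      stab_rows[[length(stab_rows) + 1L]] <- st_t
    }
  }

  contrib <- do.call(rbind, contrib_rows)
  stab <- do.call(rbind, stab_rows)

  comp_rows <- list()
  for (p in seq_len(config$n_phases)) {
    sub <- contrib[contrib$phase == p, ]
    comp_rows[[length(comp_rows) + 1L]] <- cbind(
      phase = p,
      pairwise_tests(sub, metric_name = "contribution",
                     method = config$stats_method, alpha = config$alpha,
                     p_adjust = config$p_adjust))
    for (metric in c("temporal", "spatial")) {
      sub_s <- stab[stab$phase == p & !is.na(stab$trial), ]
      sub_s$value <- sub_s[[metric]]
      comp_rows[[length(comp_rows) + 1L]] <- cbind(
        phase = p,
        pairwise_tests(sub_s, metric_name = paste0(metric, "_stability"),
                       method = config$stats_method, alpha = config$alpha,
                       p_adjust = config$p_adjust))
    }
  }

  list(models = models, reference = reference,
       vaf_table = do.call(rbind, vaf_rows),
       contribution = contrib, stability = stab,
       comparisons = do.call(rbind, comp_rows),
       normalized = norm_by_trial)
}

#' Analyze a directory of trial CSVs end to end
#'
#' Reads every `*_trial*.csv` under `in_dir` (with its metadata sidecar),
#' runs preprocessing, segmentation, normalization, per-condition NMF at the
#' configured order, contribution and stability metrics, and pairwise
#' Mann-Whitney comparisons, then writes tidy CSV tables (`synergy_W.csv`,
#' `synergy_H.csv`, `vaf.csv`, `contribution.csv`, `stability.csv`,
#' `comparisons.csv`) and a `run_log.yaml` with all resolved parameters.
#' Every table carries the configuration hash.
#'
#' @param in_dir directory of trial CSVs (as written by
#'   [simulate_experiment()] or matching its layout).
#' @param out_dir output directory for tables.
#' @param config a [pipeline_config()].
#' @return invisible list of the computed tables and models.
#' @export
analyze_experiment <- function(in_dir, out_dir, config = pipeline_config()) {
  paths <- sort(list.files(in_dir, pattern = "_trial[0-9]+\\.csv$",
                           full.names = TRUE))
  if (length(paths) == 0) stop("no trial CSVs found in in_dir")
  sessions <- lapply(paths, read_trial_csv)
  res <- analyze_session(sessions, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)

  w_rows <- list(); h_rows <- list()
  for (lv in names(res$models)) {
    m <- res$models[[lv]]
    for (p in seq_len(m$n_phases)) {
      w_rows[[length(w_rows) + 1L]] <-
        data.frame(condition = as.integer(lv), phase = p,
                   muscle = rownames(m$W), weight = m$W[, p])
      h_rows[[length(h_rows) + 1L]] <-
        data.frame(condition = as.integer(lv), phase = p,
                   time = seq_len(ncol(m$H)), activation = m$H[p, ])
    }
  }
  tables <- list(
    synergy_W = do.call(rbind, w_rows),
    synergy_H = do.call(rbind, h_rows),
    vaf = res$vaf_table,
    contribution = res$contribution,
    stability = res$stability,
    comparisons = res$comparisons
  )
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    tab$config_hash <- hash
    data.table::fwrite(tab, file.path(out_dir, paste0(nm, ".csv")))
  }
  yaml::write_yaml(list(config = unclass(config), config_hash = hash,
                        n_trials = length(paths),
                        trials = basename(paths)),
                   file.path(out_dir, "run_log.yaml"))
  invisible(c(res, list(config_hash = hash, out_dir = out_dir)))
}

#' Summarize an analysis into figures and summary tables
#'
#' Produces one figure per condition (max-normalized temporal activations
#' next to muscle weight bars) and three summary CSVs: phase contribution,
#' temporal stability and spatial stability summaries.
#'
#' @param out_dir directory holding [analyze_experiment()] outputs.
#' @param fig_dir where to put figures and summaries; defaults to
#'   `file.path(out_dir, "report")`.
#' @return invisible character vector of written files.
#' @export
report_experiment <- function(out_dir, fig_dir = file.path(out_dir, "report")) {
  need <- file.path(out_dir, c("synergy_W.csv", "synergy_H.csv",
                               "contribution.csv", "stability.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("missing analysis tables: ", paste(basename(missing), collapse = ", "))
  }
  W <- data.table::fread(need[1])
  H <- data.table::fread(need[2])
  contrib <- data.table::fread(need[3])
  stab <- data.table::fread(need[4])
  dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)

  for (lv in sort(unique(W$condition))) {
    f <- file.path(fig_dir, sprintf("condition_level%d.png", lv))
    grDevices::png(f, width = 1200, height = 800, res = 120)
    phases <- sort(unique(W$phase[W$condition == lv]))
    graphics::par(mfrow = c(length(phases), 2),
                  mar = c(3.5, 3.5, 2, 1), mgp = c(2.2, 0.7, 0))
    for (p in phases) {
      h <- H[H$condition == lv & H$phase == p, ]
      graphics::plot(h$time, h$activation / max(h$activation), type = "l",
                     lwd = 2, xlab = "normalized cycle time",
                     ylab = "activation",
                     main = sprintf("level %d, phase %d", lv, p))
      w <- W[W$condition == lv & W$phase == p, ]
      graphics::barplot(w$weight, names.arg = w$muscle, ylab = "weight",
                        col = "grey70")
    }
    grDevices::dev.off()
    written <- c(written, f)
  }

  summarize <- function(df, value_col) {
    do.call(rbind, lapply(split(df, list(df$condition, df$phase),
                                drop = TRUE), function(g) {
      v <- g[[value_col]]
      data.frame(condition = g$condition[1], phase = g$phase[1],
                 n = length(v), mean = mean(v), median = median(v),
                 q25 = unname(quantile(v, 0.25)),
                 q75 = unname(quantile(v, 0.75)))
    }))
  }
  sum_files <- c(contribution_summary = "contribution_summary.csv",
                 temporal_stability_summary = "temporal_stability_summary.csv",
                 spatial_stability_summary = "spatial_stability_summary.csv")
  stab_trials <- stab[!is.na(stab$trial), ]
  sums <- list(summarize(contrib, "value"),
               summarize(stab_trials, "temporal"),
               summarize(stab_trials, "spatial"))
  for (i in seq_along(sums)) {
    f <- file.path(fig_dir, sum_files[i])
    data.table::fwrite(sums[[i]], f)
    written <- c(written, f)
  }
  invisible(written)
}
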