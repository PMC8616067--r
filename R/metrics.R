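#' Phase contribution and inter-cycle stability metrics
#'
#' Two summary statistics of a phase decomposition: the relative
#' contribution of each phase to the total reconstructed signal amplitude,
#' and per-phase temporal/spatial stability indices measuring how
#' reproducible the temporal patterns (H rows) and muscle weightings
#' (W columns) are across motion cycles.
#'
#' @name phase_metrics
NULL

#' Relative contribution of each phase to the total activation
#'
#' `C_i = (sum_m W[m,i]) * (sum_t H[i,t]) / sum_j (sum_m W[m,j]) * (sum_t H[j,t])`,
#' i.e. each phase's share of the total reconstructed amplitude, with the
#' temporal pattern entering through its time-sum. The fractions are
#' nonnegative and sum to one; jointly rescaling `W` and `H` leaves them
#' unchanged.
#'
#' @param W nonnegative muscle x phase matrix (or a [synergy_model()], in
#'   which case `H` is taken from it).
#' @param H nonnegative phase x time matrix.
#' @return numeric vector of phase fractions summing to 1.
#' @export
relative_contribution <- function(W, H = NULL) {
  if (inherits(W, "synergy_model")) {
    H <- W$H
    W <- W$W
  }
  if (any(W < 0) || any(H < 0)) stop("W and H must be nonnegative")
  if (ncol(W) != nrow(H)) stop("inconsistent phase counts")
  num <- colSums(W) * rowSums(H)
  denom <- sum(num)
  if (denom <= 0) stop_degenerate("all-zero model has no defined contribution")
  num / denom
}

# Mean zero-lag correlation over all unordered pairs of rows; constant rows
# make a pair undefined and it is skipped.
mean_pairwise_cor <- function(X) {
  nr <- nrow(X)
  if (nr < 2L) stop("need >= 2 rows")
  vals <- numeric(0)
  for (i in seq_len(nr - 1L)) {
    for (j in (i + 1L):nr) {
      if (sd(X[i, ]) == 0 || sd(X[j, ]) == 0) next
      vals <- c(vals, cor(X[i, ], X[j, ]))
    }
  }
  if (length(vals) == 0) {
    stop_degenerate("all cycle pairs degenerate (zero variance)")
  }
  mean(vals)
}

#' Temporal stability index for one phase
#'
#' Mean zero-lag linear correlation over all unordered cycle pairs of the
#' time-normalized temporal patterns of one phase. Bounded in `[-1, 1]`;
#' equals 1 for identical traces.
#'
#' @param H_set cycle x time matrix: one phase's `H` row per cycle.
#' @return scalar index.
#' @export
temporal_stability <- function(H_set) {
  mean_pairwise_cor(as.matrix(H_set))
}

#' Spatial stability index for one phase
#'
#' Mean pairwise linear correlation of the per-cycle muscle weight vectors
#' (W columns) of one phase; requires at least 3 muscles.
#'
#' @param W_set cycle x muscle matrix: one phase's `W` column per cycle.
#' @return scalar index.
#' @export
spatial_stability <- function(W_set) {
  W_set <- as.matrix(W_set)
  if (ncol(W_set) < 3L) stop("need >= 3 muscles for spatial stability")
  mean_pairwise_cor(W_set)
}

#' Fit and match a synergy model to every motion cycle
#'
#' Each cycle of a [normalize_cycles()] set is decomposed independently at
#' the reference model's order and phase-matched to the reference (mode
#' `"nmf"`), or its temporal patterns are obtained by nonnegative projection
#' onto the reference's fixed `W` (mode `"project"`). Cycles whose
#' decomposition fails (all-zero data) are dropped with a warning.
#'
#' @param ncs a [normalize_cycles()] result.
#' @param reference a [synergy_model()] fixing order and phase ordering.
#' @param mode `"nmf"` (independent per-cycle factorization, default) or
#'   `"project"` (fixed-W nonnegative projection).
#' @param seed,restarts,max_iter,tol per-cycle NMF settings (restarts
#'   default 5; cycles are small).
#' @return list: `models` (matched per-cycle [synergy_model()]s),
#'   `cycle_index` (surviving cycle numbers), `n_cycles`.
#' @export
per_cycle_models <- function(ncs, reference, mode = c("nmf", "project"),
                             seed = 1L, restarts = 5L, max_iter = 500L,
                             tol = 1e-6) {
  mode <- match.arg(mode)
  nc <- dim(ncs$tensor)[1]
  n <- reference$n_phases
  models <- list()
  kept <- integer(0)
  for (k in seq_len(nc)) {
    M <- ncs$tensor[k, , , drop = TRUE]
    fit <- tryCatch({
      if (mode == "nmf") {
        mod <- nmf(M, n, seed = derive_seed(seed, k), restarts = restarts,
                   max_iter = max_iter, tol = tol)
        match_phases(normalize_model(mod), reference)
      } else {
        H0 <- matrix(mean(M) / max(mean(reference$W), 1e-12), n, ncol(M))
        pr <- nmf_project_cpp(M, reference$W, H0, as.integer(max_iter), tol)
        synergy_model(reference$W, pr$H, vaf = vaf(M, reference$W, pr$H),
                      converged = pr$converged, n_iter = pr$n_iter)
      }
    }, error = function(e) NULL)
    if (is.null(fit)) {
      warning(sprintf("cycle %d dropped: decomposition failed", k))
      next
    }
    models[[length(models) + 1L]] <- fit
    kept <- c(kept, k)
  }
  if (length(models) < 2L) {
    stop_degenerate("fewer than 2 cycles survived per-cycle decomposition")
  }
  list(models = models, cycle_index = kept, n_cycles = length(models))
}

#' Inter-cycle stability indices from per-cycle models
#'
#' @param pcm a [per_cycle_models()] result.
#' @return data.frame with one row per phase: `phase`, `temporal`,
#'   `spatial`, `n_cycles`.
#' @export
stability_indices <- function(pcm) {
  n <- pcm$models[[1]]$n_phases
  out <- lapply(seq_len(n), function(p) {
    H_set <- do.call(rbind, lapply(pcm$models, function(m) m$H[p, ]))
    W_set <- do.call(rbind, lapply(pcm$models, function(m) m$W[, p]))
    data.frame(phase = p,
               temporal = temporal_stability(H_set),
               spatial = spatial_stability(W_set),
               n_cycles = pcm$n_cycles)
  })
  do.call(rbind, out)
}
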