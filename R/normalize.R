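#' Cycle time-normalization, activation anchors and anchor-aligned averaging
#'
#' Cycles of variable native length are resampled to a common normalized
#' length; per-muscle activation anchors (onset, peak, offset) then drive a
#' monotone piecewise-linear warp so that temporal and spatial variation are
#' integrated before pointwise averaging.
#'
#' @name cycle_averaging
NULL

#' Resample one cycle to a fixed normalized length
#'
#' Linear-interpolation resampling of each muscle trace to `t_norm` points;
#' endpoints are preserved exactly.
#'
#' @param cycle muscle x time matrix (>= 4 samples).
#' @param t_norm target length, default 200.
#' @return muscle x `t_norm` matrix.
#' @export
time_normalize <- function(cycle, t_norm = 200L) {
  if (!is.matrix(cycle) || ncol(cycle) < 4L) {
    stop_degenerate("cycle too short to time-normalize (need >= 4 samples)")
  }
  xout <- seq(1, ncol(cycle), length.out = t_norm)
  out <- t(apply(cycle, 1, function(x) {
    approx(seq_along(x), x, xout = xout, method = "linear")$y
  }))
  rownames(out) <- rownames(cycle)
  out
}

#' Detect per-muscle activation anchors in a normalized cycle
#'
#' For each muscle: onset is the first sample exceeding
#' `onset_frac * max`, offset the last, and peak the argmax. A muscle whose
#' trace never exceeds the threshold (all-zero trace) yields `NA` anchors.
#'
#' @param cycle nonnegative muscle x t_norm matrix.
#' @param onset_frac activation threshold as a fraction of the per-muscle
#'   maximum, default 0.2.
#' @return data.frame with columns `muscle`, `onset`, `peak`, `offset`
#'   (1-based sample positions within the normalized cycle, or `NA`).
#' @export
detect_anchors <- function(cycle, onset_frac = 0.2) {
  if (any(cycle < 0)) stop("cycle must be nonnegative")
  rows <- lapply(seq_len(nrow(cycle)), function(m) {
    x <- cycle[m, ]
    mx <- max(x)
    if (mx <= 0) {
      return(data.frame(muscle = m, onset = NA_integer_, peak = NA_integer_,
                        offset = NA_integer_))
    }
    above <- which(x > onset_frac * mx)
    data.frame(muscle = m, onset = min(above), peak = which.max(x),
               offset = max(above))
  })
  out <- do.call(rbind, rows)
  if (!is.null(rownames(cycle))) out$muscle <- rownames(cycle)[out$muscle]
  out
}

#' Build a normalized cycle set with anchor table
#'
#' @param cycle_set a [segment_cycles()] result.
#' @param t_norm normalized cycle length.
#' @param onset_frac anchor threshold, see [detect_anchors()].
#' @return object of class `normalized_cycles`: `tensor` (cycle x muscle x
#'   t_norm array), `anchors` (per cycle per muscle data.frame), `t_norm`,
#'   labels and metadata.
#' @export
normalize_cycles <- function(cycle_set, t_norm = 200L, onset_frac = 0.2) {
  mats <- lapply(cycle_set$cycles, time_normalize, t_norm = t_norm)
  nc <- length(mats)
  nm <- length(cycle_set$muscle_labels)
  tensor <- array(0, dim = c(nc, nm, t_norm),
                  dimnames = list(NULL, cycle_set$muscle_labels, NULL))
  anchors <- vector("list", nc)
  for (k in seq_len(nc)) {
    tensor[k, , ] <- mats[[k]]
    a <- detect_anchors(mats[[k]], onset_frac)
    a$cycle <- k
    anchors[[k]] <- a
  }
  structure(list(tensor = tensor, anchors = do.call(rbind, anchors),
                 t_norm = as.integer(t_norm),
                 muscle_labels = cycle_set$muscle_labels,
                 fs_hz = cycle_set$fs_hz,
                 condition_label = cycle_set$condition_label,
                 trial_id = cycle_set$trial_id,
                 participant_id = cycle_set$participant_id),
            class = "normalized_cycles")
}

#' @export
print.normalized_cycles <- function(x, ...) {
  cat(sprintf("<normalized_cycles> %d cycles x %d muscles x %d samples\n",
              dim(x$tensor)[1], dim(x$tensor)[2], dim(x$tensor)[3]))
  invisible(x)
}

# Monotone piecewise-linear warp of one trace: anchors src (positions in the
# trace) are mapped onto dst (target positions); out-of-order anchor pairs
# are dropped so the warp never reorders time.
warp_trace <- function(x, src, dst) {
  t_norm <- length(x)
  keep <- !is.na(src) & !is.na(dst)
  src <- c(1, src[keep], t_norm)
  dst <- c(1, dst[keep], t_norm)
  ord <- order(dst)
  src <- src[ord]; dst <- dst[ord]
  ok <- rep(TRUE, length(src))
  last_s <- src[1]; last_d <- dst[1]
  for (i in seq_along(src)[-1]) {
    if (src[i] <= last_s || dst[i] <= last_d) {
      ok[i] <- FALSE
    } else {
      last_s <- src[i]; last_d <- dst[i]
    }
  }
  src <- src[ok]; dst <- dst[ok]
  # sample positions in the source trace for each target position
  pos <- approx(dst, src, xout = seq_len(t_norm), rule = 2)$y
  approx(seq_len(t_norm), x, xout = pos, rule = 2)$y
}

#' Anchor-aligned average cycle
#'
#' Each cycle is piecewise-linearly warped so that its per-muscle anchors
#' (onset, peak, offset) align with the median anchor positions across
#' cycles, then the pointwise mean is taken. Muscles with `NA` anchors in a
#' cycle are averaged without warping. The warp is monotone by construction.
#'
#' @param ncs a [normalize_cycles()] result with >= 2 cycles.
#' @return object of class `average_cycle`: `matrix` (muscle x t_norm) and
#'   `n_cycles_used`.
#' @export
average_cycles <- function(ncs) {
  nc <- dim(ncs$tensor)[1]
  if (nc < 2L) stop("need >= 2 cycles to average")
  nm <- dim(ncs$tensor)[2]
  t_norm <- dim(ncs$tensor)[3]
  a <- ncs$anchors
  avg <- matrix(0, nm, t_norm, dimnames = list(ncs$muscle_labels, NULL))
  for (m in seq_len(nm)) {
    am <- a[a$muscle == ncs$muscle_labels[m], ]
    am <- am[order(am$cycle), ]
    med <- c(onset = median(am$onset, na.rm = TRUE),
             peak = median(am$peak, na.rm = TRUE),
             offset = median(am$offset, na.rm = TRUE))
    acc <- matrix(0, nc, t_norm)
    for (k in seq_len(nc)) {
      x <- ncs$tensor[k, m, ]
      src <- c(am$onset[k], am$peak[k], am$offset[k])
      if (anyNA(src) || anyNA(med)) {
        acc[k, ] <- x
      } else {
        acc[k, ] <- warp_trace(x, src, med)
      }
    }
    avg[m, ] <- colMeans(acc)
  }
  structure(list(matrix = pmax(avg, 0), n_cycles_used = nc,
                 muscle_labels = ncs$muscle_labels),
            class = "average_cycle")
}

# Concatenate normalized cycles along time into one muscle x (n*t_norm)
# matrix -- the NMF input for condition-level decompositions.
concat_cycles <- function(ncs) {
  nc <- dim(ncs$tensor)[1]
  do.call(cbind, lapply(seq_len(nc), function(k) ncs$tensor[k, , , drop = TRUE]))
}

# Stack several normalized_cycles objects (e.g. the trials of one
# condition) into one; native metadata comes from the first.
bind_normalized_cycles <- function(ncs_list) {
  stopifnot(length(ncs_list) >= 1)
  t_norm <- ncs_list[[1]]$t_norm
  nm <- dim(ncs_list[[1]]$tensor)[2]
  ncs_total <- sum(vapply(ncs_list, function(x) dim(x$tensor)[1], integer(1)))
  tensor <- array(0, dim = c(ncs_total, nm, t_norm),
                  dimnames = list(NULL, ncs_list[[1]]$muscle_labels, NULL))
  anchors <- list()
  trial_of_cycle <- integer(0)
  at <- 0L
  for (x in ncs_list) {
    nk <- dim(x$tensor)[1]
    tensor[(at + 1L):(at + nk), , ] <- x$tensor
    a <- x$anchors
    a$cycle <- a$cycle + at
    anchors[[length(anchors) + 1L]] <- a
    trial_of_cycle <- c(trial_of_cycle, rep(x$trial_id, nk))
    at <- at + nk
  }
  out <- ncs_list[[1]]
  out$tensor <- tensor
  out$anchors <- do.call(rbind, anchors)
  out$trial_of_cycle <- trial_of_cycle
  out
}
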