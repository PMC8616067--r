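#' Non-negative matrix factorization into pedaling phases
#'
#' The envelope matrix `M` (muscle x time) is approximated as `W %*% H` with
#' nonnegative `W` (muscle contributions, m x n) and `H` (temporal phase
#' activations, n x t), fitted by Lee-Seung multiplicative updates for the
#' Frobenius loss. Decomposition quality is measured by the uncentered
#' global variance accounted for (VAF) and the order is the smallest n whose
#' VAF clears a threshold (95% by default).
#'
#' @name synergy_decomposition
NULL

#' Construct a synergy model
#'
#' @param W nonnegative muscle x phase matrix.
#' @param H nonnegative phase x time matrix.
#' @param vaf variance accounted for of the fit.
#' @param converged,n_iter fit diagnostics.
#' @param loss_trace optional per-iteration loss values.
#' @return object of class `synergy_model`.
#' @export
synergy_model <- function(W, H, vaf = NA_real_, converged = NA, n_iter = NA_integer_,
                          loss_trace = NULL) {
  if (any(W < 0) || any(H < 0)) stop("W and H must be nonnegative")
  if (ncol(W) != nrow(H)) stop("W and H have inconsistent phase counts")
  structure(list(W = W, H = H, n_phases = ncol(W), vaf = vaf,
                 converged = converged, n_iter = n_iter,
                 loss_trace = loss_trace),
            class = "synergy_model")
}

#' @export
print.synergy_model <- function(x, ...) {
  cat(sprintf("<synergy_model> %d muscles x %d phases, VAF %.4f (%s, %d iter)\n",
              nrow(x$W), x$n_phases, x$vaf,
              if (isTRUE(x$converged)) "converged" else "max_iter", x$n_iter))
  invisible(x)
}

#' Variance accounted for by a factorization
#'
#' Uncentered global VAF: `1 - ||M - WH||_F^2 / ||M||_F^2`.
#'
#' @param M nonnegative data matrix.
#' @param W,H factor matrices of consistent shape.
#' @return fraction in `(-Inf, 1]`.
#' @export
vaf <- function(M, W, H) {
  denom <- sum(M^2)
  if (denom == 0) stop_degenerate("all-zero matrix has undefined VAF")
  1 - sum((M - W %*% H)^2) / denom
}

#' Fit an NMF model by multiplicative updates
#'
#' Best of `restarts` seeded random initializations (uniform in (0,1],
#' scaled to the data mean); each restart runs Lee-Seung updates until the
#' relative loss change drops below `tol` or `max_iter` is reached. The loss
#' is non-increasing across iterations and the fit is deterministic given
#' `seed`.
#'
#' @param M nonnegative finite matrix (muscle x time).
#' @param n factorization order, `1 <= n <= min(dim(M))`.
#' @param seed integer seed for the restart initializations.
#' @param restarts number of random restarts, default 10.
#' @param max_iter iteration cap per restart, default 1000.
#' @param tol relative loss-change convergence tolerance, default 1e-6.
#' @return a [synergy_model()] with `vaf`, `loss_trace` (best restart) set.
#' @export
nmf <- function(M, n, seed = 1L, restarts = 10L, max_iter = 1000L, tol = 1e-6) {
  if (!is.matrix(M) || !all(is.finite(M)) || any(M < 0)) {
    stop("M must be a finite nonnegative matrix")
  }
  if (sum(M) == 0) stop_degenerate("all-zero matrix cannot be factorized")
  m <- nrow(M); t_len <- ncol(M)
  if (n < 1L || n > min(m, t_len)) stop("order n out of range")
  scale0 <- sqrt(mean(M) / n)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- with_local_seed(derive_seed(seed, r), function() {
      list(W = matrix(runif(m * n), m, n) * scale0,
           H = matrix(runif(n * t_len), n, t_len) * scale0)
    })
    fit <- nmf_mu_cpp(M, init$W, init$H, as.integer(max_iter), tol)
    if (is.null(best) || fit$loss[length(fit$loss)] <
          best$loss[length(best$loss)]) {
      best <- fit
    }
  }
  model <- synergy_model(best$W, best$H, vaf = vaf(M, best$W, best$H),
                         converged = best$converged, n_iter = best$n_iter,
                         loss_trace = best$loss)
  rownames(model$W) <- rownames(M)
  model
}

#' Smallest order whose VAF clears the threshold
#'
#' Fits NMF models for `n = 1..n_max` and returns the smallest order whose
#' best-of-restarts VAF reaches `vaf_threshold`. If no order reaches it, the
#' best-VAF order is returned with `reached = FALSE` and a warning.
#'
#' @param M nonnegative matrix.
#' @param vaf_threshold VAF threshold, default 0.95.
#' @param n_max largest order to try, default `min(dim(M))`.
#' @inheritParams nmf
#' @return list: `order` (integer), `vaf_by_order` (numeric vector),
#'   `reached` (logical), `models` (fitted models by order).
#' @export
select_order <- function(M, vaf_threshold = 0.95, n_max = min(dim(M)),
                         seed = 1L, restarts = 10L, max_iter = 1000L,
                         tol = 1e-6) {
  vafs <- numeric(0)
  models <- list()
  for (n in seq_len(n_max)) {
    fit <- nmf(M, n, seed = seed, restarts = restarts, max_iter = max_iter,
               tol = tol)
    vafs[n] <- fit$vaf
    models[[n]] <- fit
    if (fit$vaf >= vaf_threshold) {
      return(list(order = n, vaf_by_order = vafs, reached = TRUE,
                  models = models))
    }
  }
  warning(sprintf("no order up to %d reached VAF %.3f; best is n=%d (VAF %.3f)",
                  n_max, vaf_threshold, which.max(vafs), max(vafs)))
  list(order = which.max(vafs), vaf_by_order = vafs, reached = FALSE,
       models = models)
}

#' Normalize temporal patterns to unit maximum
#'
#' Each `H` row is divided by its maximum and the maximum is transferred to
#' the matching `W` column, leaving the reconstruction `W %*% H` unchanged.
#'
#' @param model a [synergy_model()]; every `H` row must have positive max.
#' @return normalized model.
#' @export
normalize_model <- function(model) {
  mx <- apply(model$H, 1, max)
  if (any(mx <= 0)) stop_degenerate("all-zero H row cannot be normalized")
  model$H <- model$H / mx
  model$W <- model$W * rep(mx, each = nrow(model$W))
  model
}

#' Match a model's phases to a reference ordering
#'
#' Greedy one-to-one assignment maximizing the correlation between `H`
#' rows; ties are broken by `W`-column correlation, then lower index. The
#' returned model has its phases permuted to the reference order.
#'
#' @param model,reference [synergy_model()] objects with equal muscle and
#'   phase counts (and equal `H` length).
#' @return `model` with phases reordered; attribute `"permutation"` maps
#'   reference phase -> original phase index.
#' @export
match_phases <- function(model, reference) {
  if (nrow(model$W) != nrow(reference$W) ||
      model$n_phases != reference$n_phases) {
    stop("model and reference dimensions differ")
  }
  n <- model$n_phases
  safe_cor <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) return(0)
    cor(x, y)
  }
  # H rows are only comparable at equal lengths (e.g. both time-normalized);
  # otherwise matching falls through to the W-column correlations.
  use_h <- ncol(model$H) == ncol(reference$H)
  ch <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    if (!use_h) return(0)
    safe_cor(reference$H[i, ], model$H[j, ])
  }))
  cw <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    safe_cor(reference$W[, i], model$W[, j])
  }))
  perm <- integer(n)
  used_r <- rep(FALSE, n); used_m <- rep(FALSE, n)
  for (step in seq_len(n)) {
    best <- c(-Inf, -Inf, NA, NA)
    for (i in which(!used_r)) {
      for (j in which(!used_m)) {
        cand <- c(ch[i, j], cw[i, j], i, j)
        if (cand[1] > best[1] ||
            (cand[1] == best[1] && cand[2] > best[2]) ||
            (cand[1] == best[1] && cand[2] == best[2] &&
             (is.na(best[3]) || cand[3] < best[3] ||
              (cand[3] == best[3] && cand[4] < best[4])))) {
          best <- cand
        }
      }
    }
    perm[best[3]] <- best[4]
    used_r[best[3]] <- TRUE; used_m[best[4]] <- TRUE
  }
  model$W <- model$W[, perm, drop = FALSE]
  model$H <- model$H[perm, , drop = FALSE]
  attr(model, "permutation") <- perm
  model
}
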