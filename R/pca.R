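#' Principal component analysis by singular value decomposition
#'
#' Columns are centred and the SVD of the centred matrix taken; scores are
#' `U %*% diag(d)`, loadings are the right singular vectors, and the
#' explained fraction of component i is `d_i^2 / sum(d^2)`. For determinism
#' across runs and linear-algebra backends, each loading vector is signed so
#' that its largest-magnitude element is positive.
#'
#' @param sm a [spectrum_matrix()] or numeric matrix.
#' @param k number of components to retain; defaults to the number needed to
#'   reach 90% cumulative explained variance. Must satisfy
#'   `k <= min(n - 1, p)`.
#' @return a `pca_model`: list with `loadings` (p x k, orthonormal), `scores`
#'   (n x k), `explained_fraction` (length k), `explained_all` (full
#'   spectrum of fractions), `center`, `k`, `n`, `k90` (components needed
#'   for 90%).
#' @export
fit_pca <- function(sm, k = NULL) {
  X <- sm_values(sm)
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  d2 <- sv$d^2
  expl <- d2 / sum(d2)
  kmax <- min(n - 1L, p)
  k90 <- which(cumsum(expl) >= 0.9)[1]
  if (is.null(k)) k <- min(k90, kmax)
  if (k > kmax) stopf("k = %d exceeds min(n - 1, p) = %d", k, kmax)
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  scores <- U * rep(sv$d[seq_len(k)], each = n)
  for (j in seq_len(k)) {            # deterministic sign convention
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) { V[, j] <- -V[, j]; scores[, j] <- -scores[, j] }
  }
  rownames(scores) <- rownames(X)
  structure(list(loadings = V, scores = scores,
                 explained_fraction = expl[seq_len(k)],
                 explained_all = expl, center = mu, k = k, n = n, k90 = k90),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d samples, k = %d (%.1f%% var; %d PCs for 90%%)\n",
              x$n, x$k, 100 * sum(x$explained_fraction), x$k90))
  invisible(x)
}

#' Hotelling T-squared outlier screen
#'
#' Flags samples whose first `n_pcs` PC scores lie outside the
#' `1 - alpha` confidence ellipse:
#' `T2_i = sum_c t_ic^2 / lambda_c` with `lambda_c` the score variance, and
#' limit `n_pcs (n - 1) / (n - n_pcs) * F(1 - alpha; n_pcs, n - n_pcs)`.
#' Flagged samples are candidates for manual inspection, not automatic
#' removal.
#'
#' @param model a [fit_pca()] result.
#' @param n_pcs number of leading components to use (default 2).
#' @param alpha significance level (default 0.05).
#' @return data.frame with `sample`, `t2`, `flagged`; the limit is attached
#'   as attribute `limit`.
#' @export
hotelling_outliers <- function(model, n_pcs = 2, alpha = 0.05) {
  stopifnot(inherits(model, "pca_model"))
  if (n_pcs > model$k) stopf("n_pcs exceeds fitted components")
  n <- model$n
  if (n <= n_pcs) stopf("need n > n_pcs")
  S <- model$scores[, seq_len(n_pcs), drop = FALSE]
  lambda <- apply(S, 2, stats::var)
  t2 <- rowSums(sweep(S^2, 2, lambda, "/"))
  limit <- n_pcs * (n - 1) / (n - n_pcs) *
    stats::qf(1 - alpha, n_pcs, n - n_pcs)
  out <- data.frame(sample = rownames(S) %||% seq_len(n), t2 = t2,
                    flagged = t2 > limit, row.names = NULL)
  attr(out, "limit") <- limit
  out
}

#' Between-model PC score correlations
#'
#' For each of the first `n_pcs` components, computes the matrix of absolute
#' Pearson correlations between the scores of every pair of PCA models
#' (e.g. uncorrected spectra vs spectra corrected for each fixed-effect set).
#' Low correlation means the corrected dataset differs strongly from the
#' uncorrected one, i.e. the removed effect mattered. Absolute values are
#' used because PC signs are arbitrary.
#'
#' @param models named list of [fit_pca()] results sharing sample count and
#'   order.
#' @param n_pcs number of components to compare (default 3).
#' @return named list of correlation matrices, one per component; undefined
#'   entries (zero-variance scores) are `NA`.
#' @export
score_correlations <- function(models, n_pcs = 3) {
  stopifnot(is.list(models), length(models) >= 2)
  ns <- vapply(models, function(m) m$n, 0)
  if (length(unique(ns)) != 1) stopf("models differ in sample count")
  if (any(vapply(models, function(m) m$k, 0) < n_pcs))
    stopf("every model needs >= n_pcs components")
  nm <- names(models) %||% paste0("model", seq_along(models))
  out <- vector("list", n_pcs)
  names(out) <- paste0("PC", seq_len(n_pcs))
  for (pc in seq_len(n_pcs)) {
    M <- diag(1, length(models))
    dimnames(M) <- list(nm, nm)
    for (a in seq_along(models)) for (b in seq_along(models)) {
      if (a == b) next
      x <- models[[a]]$scores[, pc]; y <- models[[b]]$scores[, pc]
      M[a, b] <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
        abs(stats::cor(x, y))
    }
    out[[pc]] <- M
  }
  out
}
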