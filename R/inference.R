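#' Conditional Wald F tests on a response
#'
#' Fits the full fixed-effect model (e.g. PC score ~ weeks-in-milk + parity +
#' herd) by OLS and, for every factor, the reduced model dropping that
#' factor. The conditional F statistic tests each term as if fitted last,
#' i.e. given all remaining predictors:
#' `F = ((RSS_reduced - RSS_full) / q) / (RSS_full / df_res)`, with `q` the
#' number of columns the factor contributes and `df_res = n - rank(full)`.
#' For a single-factor model this is the ordinary one-way ANOVA F.
#'
#' @param score numeric response (typically a PC score vector).
#' @param metadata data.frame with the factor columns.
#' @param factors character vector of factor names (default wim, parity,
#'   herd).
#' @return data.frame with one row per factor: `factor`, `f`, `df1`, `df2`,
#'   `p`.
#' @export
conditional_wald_f <- function(score, metadata,
                               factors = c("wim", "parity", "herd")) {
  score <- as.numeric(score)
  full <- encode_design(metadata, factors)
  if (length(score) != nrow(full$X)) stopf("score length != sample count")
  rss_full <- sum(qr.resid(full$qr, score)^2)
  df_res <- full$df_residual
  if (df_res <= 0) stopf("no residual degrees of freedom")
  out <- lapply(full$factors, function(f) {
    keep <- full$term != f
    Xr <- full$X[, keep, drop = FALSE]
    qr_r <- qr(Xr)
    if (qr_r$rank < ncol(Xr))
      stopf("rank deficiency when dropping factor '%s'", f)
    rss_red <- sum(qr.resid(qr_r, score)^2)
    q <- sum(!keep)
    fstat <- max(0, (rss_red - rss_full) / q / (rss_full / df_res))
    data.frame(factor = f, f = fstat, df1 = q, df2 = df_res,
               p = stats::pf(fstat, q, df_res, lower.tail = FALSE))
  })
  do.call(rbind, out)
}

#' ANOVA-simultaneous component analysis decomposition
#'
#' Partitions the column-centred data matrix into main-effect matrices (one
#' per design factor) plus a residual. Each factor's effect matrix assigns to
#' every sample the level mean of the centred matrix, and its magnitude is
#' reported as a percentage of the centred total sum of squares. A small
#' component model (SVD of the size-weighted level means) of each effect
#' matrix is retained for inspection. For unbalanced designs the per-factor
#' effect matrices are not mutually orthogonal and the percentages need not
#' sum to 100 with the residual; this simplest published variant is used
#' deliberately.
#'
#' @param sm a [spectrum_matrix()] or matrix.
#' @param metadata data.frame with the factor columns.
#' @param factors character vector of factor names.
#' @return an `asca_result`: list with `magnitudes` (% of centred SSQ per
#'   factor), `effects` (per-factor effect matrices), `level_means`,
#'   `residuals`, `total_ssq`, `components` (per-factor SVD of weighted
#'   level means), `factors`, and (after [asca_permute()]) `p_values`,
#'   `n_perm`, `seed`.
#' @export
asca_decompose <- function(sm, metadata, factors) {
  X <- sm_values(sm)
  stopifnot(is.data.frame(metadata), nrow(metadata) == nrow(X))
  Xc <- sweep(X, 2, colMeans(X))
  tot <- sum(Xc^2)
  effects <- list(); lmeans <- list(); comps <- list()
  mags <- numeric(0)
  E <- Xc
  for (f in factors) {
    fv <- factor(as.character(metadata[[f]]))
    if (any(table(fv) == 0) || nlevels(fv) < 2)
      stopf("factor '%s' needs >= 2 non-empty levels", f)
    cnt <- as.vector(table(fv))
    lm_ <- rowsum(Xc, fv) / cnt
    Xf <- lm_[as.integer(fv), , drop = FALSE]
    rownames(Xf) <- rownames(X)
    effects[[f]] <- Xf
    lmeans[[f]] <- lm_
    mags[f] <- 100 * sum(Xf^2) / tot
    sv <- svd(lm_ * sqrt(cnt), nu = 0)
    ncomp <- min(3L, nlevels(fv) - 1L)
    comps[[f]] <- list(loadings = sv$v[, seq_len(ncomp), drop = FALSE],
                       singular_values = sv$d[seq_len(ncomp)])
    E <- E - Xf
  }
  structure(list(magnitudes = mags, effects = effects, level_means = lmeans,
                 residuals = E, total_ssq = tot, components = comps,
                 factors = factors),
            class = "asca_result")
}

#' @export
print.asca_result <- function(x, ...) {
  cat("<asca_result> effect magnitudes (% of centred total SSQ):\n")
  for (f in x$factors) {
    pv <- if (!is.null(x$p_values)) sprintf(", p = %.3g", x$p_values[f])
    else ""
    cat(sprintf("  %-8s %8.4f%s\n", f, x$magnitudes[f], pv))
  }
  invisible(x)
}

# Effect magnitude of one factor for a centred matrix (permutation kernel).
asca_magnitude <- function(Xc, fv, tot) {
  cnt <- as.vector(table(fv))
  lm_ <- rowsum(Xc, fv) / cnt
  100 * sum(lm_^2 * cnt) / tot
}

#' ASCA with permutation testing
#'
#' Runs [asca_decompose()] and attaches a permutation p-value per factor:
#' that factor's labels are permuted across samples (all other factors stay
#' attached to their samples) `n_perm` times and
#' `p = (1 + #\{perm magnitude >= observed\}) / (1 + n_perm)`, so the
#' smallest attainable p with 50 permutations is 1/51 (~0.02).
#'
#' @param sm a [spectrum_matrix()] or matrix.
#' @param metadata data.frame with the factor columns.
#' @param factors character vector of factor names.
#' @param n_perm number of permutations (>= 1; default 50).
#' @param seed integer seed.
#' @return an `asca_result` with `p_values`, `n_perm`, `seed`.
#' @export
asca_permute <- function(sm, metadata, factors, n_perm = 50, seed = 1) {
  if (!is_count(n_perm) || n_perm < 1) stopf("n_perm must be >= 1")
  res <- asca_decompose(sm, metadata, factors)
  X <- sm_values(sm)
  Xc <- sweep(X, 2, colMeans(X))
  n <- nrow(Xc)
  pv <- with_seed(seed, {
    vapply(factors, function(f) {
      fv <- factor(as.character(metadata[[f]]))
      obs <- res$magnitudes[f]
      ge <- 0L
      for (b in seq_len(n_perm)) {
        mg <- asca_magnitude(Xc, fv[sample.int(n)], res$total_ssq)
        if (mg >= obs - 1e-12) ge <- ge + 1L
      }
      (1 + ge) / (1 + n_perm)
    }, 0)
  })
  res$p_values <- pv
  res$n_perm <- n_perm
  res$seed <- seed
  res
}
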