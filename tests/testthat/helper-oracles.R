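# Independent oracles and small fixtures used across the suite.
# Oracles deliberately take the naive route (per-column lm(), explicit
# enumeration, textbook NIPALS) so they share no code with the package
# implementations they check.

# Per-column OLS residuals and R2 via stats::lm, one column at a time.
naive_ols <- function(Y, X) {
  E <- matrix(0, nrow(Y), ncol(Y))
  r2 <- numeric(ncol(Y))
  for (j in seq_len(ncol(Y))) {
    fit <- stats::lm(Y[, j] ~ X - 1)   # X already carries an intercept
    E[, j] <- stats::residuals(fit)
    tss <- sum((Y[, j] - mean(Y[, j]))^2)
    r2[j] <- if (tss > 0) 1 - sum(E[, j]^2) / tss else 0
  }
  list(residuals = E, r2 = r2)
}

# Textbook NIPALS PLS1 fitted values for a given component count.
pls1_fitted <- function(X, y, ncomp) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  fitted <- rep(ym, length(y))
  for (a in seq_len(ncomp)) {
    w <- as.numeric(crossprod(Xc, yc))
    w <- w / sqrt(sum(w^2))
    t_ <- as.numeric(Xc %*% w)
    p_ <- as.numeric(crossprod(Xc, t_)) / sum(t_^2)
    q_ <- sum(yc * t_) / sum(t_^2)
    fitted <- fitted + t_ * q_
    Xc <- Xc - tcrossprod(t_, p_)
    yc <- yc - t_ * q_
  }
  fitted
}

# Exhaustive COW path search mirroring the package's segment definition:
# shared-endpoint segments from cow_boundaries(), windows interpolated with
# approx(), Pearson correlation per segment (0 for zero-variance segments).
brute_cow_score <- function(x, ref, boundaries, slack) {
  nseg <- length(boundaries) - 1L
  seg_score <- function(tb) {
    total <- 0
    for (i in seq_len(nseg)) {
      rseg <- ref[boundaries[i]:boundaries[i + 1]]
      L <- length(rseg)
      xs <- seq(tb[i], tb[i + 1], length.out = L)
      wseg <- stats::approx(seq_along(x), x, xout = xs)$y
      total <- total +
        (if (stats::sd(rseg) == 0 || stats::sd(wseg) == 0) 0
         else stats::cor(wseg, rseg))
    }
    total
  }
  offs <- (-slack):slack
  grid <- do.call(expand.grid, rep(list(offs), nseg - 1L))
  best <- -Inf
  for (r in seq_len(nrow(grid))) {
    tb <- boundaries
    tb[2:nseg] <- boundaries[2:nseg] + as.integer(grid[r, ])
    sc <- seg_score(tb)
    if (sc > best) best <- sc
  }
  best
}

# Small multi-herd cohort for module tests (fast: 2048-point grid).
tiny_cohort <- function(seed = 7, n_herds = 4, sizes = c(20, 15, 25, 18),
                        grid = 2048, ...) {
  cfg <- cohort_config(n_herds = n_herds, herd_sizes = sizes, seed = seed,
                       grid_size = grid, ...)
  generate_cohort(cfg)
}

# Deterministic toy metadata with the full 4 x 4 x k factor structure.
toy_metadata <- function(n, n_herds = 3, seed = 1) {
  set.seed(seed)
  md <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    herd = sample(sprintf("H%02d", seq_len(n_herds)), n, replace = TRUE),
    parity = sample(c("1", "2", "3", "4+"), n, replace = TRUE),
    dim = sample(1:30, n, replace = TRUE),
    stringsAsFactors = FALSE)
  md$wim <- wim_from_dim(md$dim)
  md$bhba <- abs(rnorm(n, 0.6, 0.2))
  md
}

# A clean one-sample synthetic_truth for direct render_spectra tests.
manual_truth <- function(conc_row, metabolites, config) {
  conc <- matrix(conc_row, nrow = 1, dimnames = list(NULL, metabolites))
  structure(list(concentrations = conc,
                 effect_fractions = NULL,
                 bhba_true = if ("bhba" %in% metabolites)
                   conc[, "bhba"] else numeric(1),
                 metadata = data.frame(sample_id = "S0001"),
                 config = config),
            class = "synthetic_truth")
}
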