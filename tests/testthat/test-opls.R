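test_that("OPLS reduces to PLS1 and matches the multi-component equivalence", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 30; p <- 20
    X <- matrix(rnorm(n * p), n, p)
    b <- c(rep(2, 3), rep(0, p - 3))
    y <- as.numeric(X %*% b) + rnorm(n, 0, 0.3)
    # n_ortho = 0 is exactly single-component PLS1
    m0 <- fit_opls(X, y, n_ortho = 0)
    expect_equal(m0$fitted, pls1_fitted(X, y, 1), tolerance = 1e-10)
    # OPLS with k orthogonal components explains the same y-variance as
    # PLS1 with k + 1 components
    for (k in 1:3) {
      mk <- fit_opls(X, y, n_ortho = k)
      sse_opls <- sum((y - mk$fitted)^2)
      sse_pls <- sum((y - pls1_fitted(X, y, k + 1))^2)
      expect_equal(sse_opls, sse_pls, tolerance = 1e-6)
    }
  }
})

test_that("OPLS model structure invariants hold", {
  set.seed(21)
  X <- matrix(rnorm(40 * 15), 40, 15)
  y <- X[, 4] + rnorm(40, 0, 0.1)
  m <- fit_opls(X, y, n_ortho = 2)
  expect_equal(sum(m$w^2), 1, tolerance = 1e-12)
  # orthogonal scores are orthogonal to the final predictive score
  expect_lt(max(abs(crossprod(m$T_o, m$t))), 1e-8)
  expect_equal(mean(m$vip^2), 1, tolerance = 1e-8)
  # y equal to one X column: R2 = 1 with n_ortho = 0 once the column is
  # identifiable by a single component (orthonormal predictors)
  Xo <- qr.Q(qr(scale(X, scale = FALSE)))
  m1 <- fit_opls(Xo, Xo[, 4], n_ortho = 0)
  expect_equal(m1$r2, 1, tolerance = 1e-10)
  # degenerate y rejected
  expect_error(fit_opls(X, rep(0, 40), 0), "uncorrelated")
})

test_that("prediction reproduces training, duplicates rows, nulls P_o", {
  set.seed(22)
  X <- matrix(rnorm(35 * 12), 35, 12)
  y <- as.numeric(X %*% c(1, -1, rep(0, 10))) + rnorm(35, 0, 0.2)
  m <- fit_opls(X, y, n_ortho = 2)
  expect_equal(predict_opls(m, X), m$fitted, tolerance = 1e-10)
  # duplicated row duplicates the prediction
  expect_equal(predict_opls(m, X[c(3, 3), ]),
               rep(predict_opls(m, X[3, , drop = FALSE]), 2),
               tolerance = 1e-12)
  # adding a stored orthogonal loading direction changes nothing
  x_pert <- X[5, ] + 4 * m$P_o[, 1]
  expect_equal(predict_opls(m, rbind(x_pert)),
               predict_opls(m, X[5, , drop = FALSE]), tolerance = 1e-8)
  expect_error(predict_opls(m, X[, 1:5]), "columns")
})

test_that("VIP identities and significance mask", {
  set.seed(23)
  X <- matrix(rnorm(30 * 8), 30, 8)
  # orthonormal predictors with y = row sums give exactly uniform weights,
  # hence all VIP = 1
  Xo <- qr.Q(qr(scale(X, scale = FALSE)))
  mu_ <- fit_opls(Xo, rowSums(Xo), n_ortho = 0)
  expect_equal(unname(mu_$vip), rep(1, 8), tolerance = 1e-6)
  m <- fit_opls(X, X[, 2] + rnorm(30, 0, 0.05), n_ortho = 1)
  v <- vip(m)
  expect_equal(mean(v^2), 1, tolerance = 1e-8)
  expect_true(attr(v, "significant")[2])
})

test_that("venetian-blinds CV strides the sample order", {
  set.seed(24)
  n <- 20
  # noiseless single-latent-variable world: CV R2 ~ 1
  t0 <- rnorm(n)
  pvec <- rnorm(6)
  X <- outer(t0, pvec) + matrix(rnorm(n * 6, 0, 0.001), n, 6)
  y1 <- 2 * t0
  cv <- venetian_cv(X, y1, n_splits = 10, n_ortho = 0)
  expect_gt(cv$r2_cv, 0.99)
  # fold arithmetic: n = 20, 10 splits, stride 10, 2 samples per fold
  expect_equal(seq(3, n, by = 10), c(3, 13))
  # permuted y: CV R2 near or below zero across seeds
  worse <- 0
  for (s in 1:5) {
    set.seed(30 + s)
    cvp <- venetian_cv(X, sample(y1), n_splits = 10, n_ortho = 0)
    if (cvp$r2_cv < 0.2) worse <- worse + 1
  }
  expect_gte(worse, 4)
  expect_error(venetian_cv(X[1:5, ], y1[1:5], n_splits = 10), "n_splits")
})

test_that("calibration RMSE does not beat cross-validation on average", {
  set.seed(25)
  diffs <- replicate(20, {
    X <- matrix(rnorm(40 * 10), 40, 10)
    y <- as.numeric(X %*% rnorm(10)) + rnorm(40, 0, 0.5)
    cv <- venetian_cv(X, y, n_splits = 10, n_ortho = 1)
    cv$rmse_cv - cv$rmse_cal
  })
  expect_gt(mean(diffs), 0)
})

test_that("leave-one-group-out reports every group and flags deviance", {
  set.seed(26)
  n <- 60
  g <- rep(c("f1", "f2", "f3"), each = 20)
  X <- matrix(rnorm(n * 10), n, 10)
  y <- as.numeric(X %*% c(1.5, rep(0, 9))) + rnorm(n, 0, 0.05)
  rep_ <- leave_one_group_out(X, y, g, n_ortho = 1)
  expect_identical(nrow(rep_), 4L)            # (all) + 3 groups
  expect_identical(rep_$group, c("(all)", "f1", "f2", "f3"))
  expect_true(all(rep_$n_train[-1] + rep_$n_test[-1] == n))
  # exchangeable groups: external RMSE close to calibration RMSE
  expect_lt(max(rep_$rmse_ext[-1]), 4 * rep_$rmse_cal[1] + 0.05)
  # constant withheld y: external R2 undefined
  y2 <- y; y2[g == "f2"] <- 1
  rep2 <- leave_one_group_out(X, y2, g, n_ortho = 1)
  expect_true(is.na(rep2$r2_ext[rep2$group == "f2"]))
  expect_error(leave_one_group_out(X, y, rep("a", n)), "groups")
})

test_that("permutation significance has the rank floor and honest null", {
  set.seed(27)
  n <- 40
  X <- matrix(rnorm(n * 10), n, 10)
  y <- as.numeric(X %*% c(3, rep(0, 9))) + rnorm(n, 0, 0.1)
  ps <- permutation_significance(X, y, n_perm = 50, n_ortho = 0, seed = 5)
  expect_equal(ps$p, 1 / 51, tolerance = 1e-12)
  expect_lt(ps$p_wilcoxon, 0.05)
  expect_error(permutation_significance(X, y, n_perm = 0), "n_perm")

  # y independent of X: p > 0.05 in >= 80% of seeded repeats
  ok <- 0
  for (s in 1:10) {
    set.seed(40 + s)
    yn <- rnorm(n)
    pn <- permutation_significance(X, yn, n_perm = 19, n_ortho = 0,
                                   seed = 50 + s)
    if (pn$p > 0.05) ok <- ok + 1
  }
  expect_gte(ok, 8)
})

test_that("component selection is parsimonious and deterministic", {
  set.seed(28)
  n <- 50
  # pure single-direction signal: selects 0 or 1 orthogonal components
  t0 <- rnorm(n)
  X <- outer(t0, rnorm(12)) + matrix(rnorm(n * 12, 0, 0.05), n, 12)
  y <- 2 * t0 + rnorm(n, 0, 0.05)
  k <- select_components(X, y, max_ortho = 4)
  expect_lte(as.integer(k), 1L)
  tab <- attr(k, "cv_table")
  expect_identical(nrow(tab), 5L)
  # within one SE of the minimum by construction
  best <- which.min(tab$rmse_cv)
  expect_lte(tab$rmse_cv[as.integer(k) + 1],
             tab$rmse_cv[best] + tab$se[best] + 1e-12)
  # deterministic
  expect_identical(as.integer(select_components(X, y, max_ortho = 4)),
                   as.integer(k))
})
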