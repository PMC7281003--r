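#' Fit a single-response OPLS regression model
#'
#' Orthogonal projections to latent structures: the predictive weight vector
#' is `w = X'y / ||X'y||`; each orthogonal component is extracted from the
#' current X loading `p = X't/(t't)` as `w_o = p - (w'p) w` (normalised),
#' with score `t_o = X w_o` and deflation `X <- X - t_o p_o'`. After
#' `n_ortho` deflations the predictive score is `t = X w` and y is regressed
#' on it (`q = y't / (t't)`). X and y are centred internally and the centres
#' stored. With `n_ortho = 0` the model is exactly single-component PLS1,
#' and with `n_ortho` orthogonal components it explains the same y-variance
#' as PLS1 with `n_ortho + 1` components.
#'
#' @param X predictor matrix (samples x variables) or [spectrum_matrix()].
#' @param y numeric response (e.g. serum BHBA, mmol/L).
#' @param n_ortho number of orthogonal components (>= 0).
#' @return an `opls_model`: list with `w` (unit predictive weights), `t`,
#'   `p_load`, `q`, `W_o`, `T_o`, `P_o`, `n_ortho`, `x_center`, `y_center`,
#'   `vip`, `fitted`, `r2`, `rmse`, `coefficients` (back-projected
#'   predictive coefficient vector).
#' @export
fit_opls <- function(X, y, n_ortho = 0) {
  X <- sm_values(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stopf("length(y) != nrow(X)")
  if (!is_count(n_ortho)) stopf("n_ortho must be a count >= 0")
  if (n <= n_ortho + 1) stopf("need n > n_ortho + 1")
  x_center <- colMeans(X)
  y_center <- mean(y)
  Xc <- sweep(X, 2, x_center)
  yc <- y - y_center
  w <- as.numeric(crossprod(Xc, yc))
  nw <- sqrt(sum(w^2))
  if (nw <= 1e-12 * max(sqrt(sum(yc^2)), 1e-300))
    stopf("y uncorrelated with X: degenerate predictive weight")
  w <- w / nw
  W_o <- matrix(0, p, 0); P_o <- matrix(0, p, 0); T_o <- matrix(0, n, 0)
  k <- 0L
  for (i in seq_len(n_ortho)) {
    t_ <- as.numeric(Xc %*% w)
    pl <- as.numeric(crossprod(Xc, t_)) / sum(t_^2)
    w_o <- pl - sum(w * pl) * w
    nwo <- sqrt(sum(w_o^2))
    if (nwo <= 1e-10 * sqrt(sum(pl^2))) break   # no orthogonal variation left
    w_o <- w_o / nwo
    t_o <- as.numeric(Xc %*% w_o)
    p_o <- as.numeric(crossprod(Xc, t_o)) / sum(t_o^2)
    Xc <- Xc - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
    k <- k + 1L
  }
  t_ <- as.numeric(Xc %*% w)
  q <- sum(yc * t_) / sum(t_^2)
  p_load <- as.numeric(crossprod(Xc, t_)) / sum(t_^2)
  fitted <- t_ * q + y_center
  sse <- sum((y - fitted)^2)
  sst <- sum(yc^2)
  vip <- sqrt(p * w^2)     # predictive component only; mean(vip^2) = 1
  structure(list(w = w, t = t_, p_load = p_load, q = q,
                 W_o = W_o, T_o = T_o, P_o = P_o, n_ortho = k,
                 x_center = x_center, y_center = y_center, vip = vip,
                 fitted = fitted, r2 = 1 - sse / sst,
                 rmse = sqrt(sse / n), coefficients = w * q),
            class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "<opls_model> %d variables, 1 predictive + %d orthogonal; R2 = %.3f\n",
    length(x$w), x$n_ortho, x$r2))
  invisible(x)
}

#' Predict from an OPLS model
#'
#' New samples are centred with the training centres, filtered through the
#' stored orthogonal components (`t_o = X w_o`, `X <- X - t_o p_o'`), then
#' scored on the predictive component.
#'
#' @param model an [fit_opls()] model.
#' @param X_new matrix (or [spectrum_matrix()]) with the training column
#'   count.
#' @return numeric vector of predictions.
#' @export
predict_opls <- function(model, X_new) {
  stopifnot(inherits(model, "opls_model"))
  X_new <- sm_values(X_new)
  if (is.null(dim(X_new))) X_new <- matrix(X_new, nrow = 1)
  if (ncol(X_new) != length(model$w))
    stopf("X_new has %d columns; model expects %d", ncol(X_new),
          length(model$w))
  Xc <- sweep(X_new, 2, model$x_center)
  for (i in seq_len(model$n_ortho)) {
    t_o <- as.numeric(Xc %*% model$W_o[, i])
    Xc <- Xc - tcrossprod(t_o, model$P_o[, i])
  }
  as.numeric(Xc %*% model$w) * model$q + model$y_center
}

#' Variable importance in projection
#'
#' VIP of variable j on the predictive component:
#' `VIP_j = sqrt(p * (w_j / ||w||)^2)`; the mean of squared VIPs is exactly 1
#' and variables with VIP > 1 are conventionally called influential.
#'
#' @param model an [fit_opls()] model.
#' @return numeric VIP vector with attribute `significant` (`vip > 1`).
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "opls_model"))
  v <- model$vip
  attr(v, "significant") <- v > 1
  v
}

# R2/RMSE helpers; R2 uses the given reference values' own mean.
pred_stats <- function(y, yhat) {
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  c(r2 = if (sst > 0) 1 - sse / sst else NA_real_,
    rmse = sqrt(sse / length(y)))
}

#' Venetian-blinds cross-validation
#'
#' Fold `f` contains the samples at positions `f, f + n_splits,
#' f + 2 n_splits, ...` in the given sample order (the common chemometrics
#' toolbox convention). Each fold is predicted by a model refitted on the
#' remaining samples; pooled predictions give the cross-validated R2 and
#' RMSE, alongside the calibration statistics of the full fit.
#'
#' @param X predictor matrix or [spectrum_matrix()].
#' @param y numeric response.
#' @param n_splits number of folds (default 10); requires `n >= n_splits`.
#' @param n_ortho orthogonal components per refit.
#' @return list with `n`, `n_ortho`, `r2_cal`, `rmse_cal`, `r2_cv`,
#'   `rmse_cv`, `predictions` (pooled CV predictions) and `residuals`
#'   (CV residuals `y - yhat`).
#' @export
venetian_cv <- function(X, y, n_splits = 10, n_ortho = 0) {
  X <- sm_values(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < n_splits) stopf("need n >= n_splits (fold with < 1 sample)")
  full <- fit_opls(X, y, n_ortho)
  yhat <- numeric(n)
  for (f in seq_len(n_splits)) {
    idx <- seq(f, n, by = n_splits)
    fit <- fit_opls(X[-idx, , drop = FALSE], y[-idx], n_ortho)
    yhat[idx] <- predict_opls(fit, X[idx, , drop = FALSE])
  }
  cv <- pred_stats(y, yhat)
  list(n = n, n_ortho = n_ortho,
       r2_cal = full$r2, rmse_cal = full$rmse,
       r2_cv = unname(cv["r2"]), rmse_cv = unname(cv["rmse"]),
       predictions = yhat, residuals = y - yhat)
}

#' Select the number of orthogonal components by cross-validation
#'
#' Computes the venetian-blinds RMSE_CV for 0..`max_ortho` orthogonal
#' components and applies a one-standard-error parsimony rule: the smallest
#' count whose RMSE_CV is within one standard error of the minimum. The
#' standard error of an RMSE is estimated from the spread of the per-sample
#' squared errors. Deterministic for fixed input.
#'
#' @param X predictor matrix or [spectrum_matrix()].
#' @param y numeric response.
#' @param max_ortho maximal orthogonal component count (default 6).
#' @param n_splits venetian-blinds folds.
#' @return selected `n_ortho` (integer) with attribute `cv_table`.
#' @export
select_components <- function(X, y, max_ortho = 6, n_splits = 10) {
  X <- sm_values(X)
  if (max_ortho < 0) stopf("max_ortho must be >= 0")
  max_ortho <- min(max_ortho, nrow(X) - 2L)
  rmse <- se <- numeric(max_ortho + 1)
  for (k in 0:max_ortho) {
    cv <- venetian_cv(X, y, n_splits, k)
    rmse[k + 1] <- cv$rmse_cv
    sq <- cv$residuals^2
    se[k + 1] <- stats::sd(sq) / (2 * cv$rmse_cv * sqrt(length(sq)))
  }
  best <- which.min(rmse)
  sel <- which(rmse <= rmse[best] + se[best])[1] - 1L
  structure(as.integer(sel),
            cv_table = data.frame(n_ortho = 0:max_ortho, rmse_cv = rmse,
                                  se = se))
}

#' Leave-one-group-out external validation
#'
#' Iteratively withholds every group (e.g. farm), trains on the remaining
#' groups (reporting calibration and internal venetian-blinds CV statistics)
#' and predicts the withheld group. External R2 uses the validation set's
#' own mean in its total sum of squares and is `NA` when the withheld y is
#' constant. A leading `(all)` row reports the model trained on the full
#' data with no external set.
#'
#' @param X predictor matrix or [spectrum_matrix()].
#' @param y numeric response.
#' @param groups group label per sample (>= 2 groups).
#' @param n_ortho orthogonal components; `NULL` (default) selects per
#'   training set via [select_components()].
#' @param max_ortho cap for per-fold selection.
#' @param n_splits internal venetian-blinds folds.
#' @return a `validation_report` data.frame: `group`, `lv` (1 predictive +
#'   n_ortho), `n_train`, `r2_cal`, `rmse_cal`, `r2_cv`, `rmse_cv`,
#'   `n_test`, `r2_ext`, `rmse_ext`.
#' @export
leave_one_group_out <- function(X, y, groups, n_ortho = NULL, max_ortho = 4,
                                n_splits = 10) {
  X <- sm_values(X)
  y <- as.numeric(y)
  g <- factor(as.character(groups))
  if (nlevels(g) < 2) stopf("need >= 2 groups")
  pick <- function(Xt, yt) if (is.null(n_ortho))
    as.integer(select_components(Xt, yt, max_ortho, n_splits)) else n_ortho
  k_all <- pick(X, y)
  cv_all <- venetian_cv(X, y, n_splits, k_all)
  rows <- list(data.frame(
    group = "(all)", lv = k_all + 1L, n_train = length(y),
    r2_cal = cv_all$r2_cal, rmse_cal = cv_all$rmse_cal,
    r2_cv = cv_all$r2_cv, rmse_cv = cv_all$rmse_cv,
    n_test = 0L, r2_ext = NA_real_, rmse_ext = NA_real_))
  for (lv in levels(g)) {
    test <- g == lv
    Xt <- X[!test, , drop = FALSE]; yt <- y[!test]
    k <- pick(Xt, yt)
    cv <- venetian_cv(Xt, yt, n_splits, k)
    fit <- fit_opls(Xt, yt, k)
    yhat <- predict_opls(fit, X[test, , drop = FALSE])
    st <- pred_stats(y[test], yhat)
    rows[[length(rows) + 1]] <- data.frame(
      group = lv, lv = k + 1L, n_train = sum(!test),
      r2_cal = cv$r2_cal, rmse_cal = cv$rmse_cal,
      r2_cv = cv$r2_cv, rmse_cv = cv$rmse_cv,
      n_test = sum(test), r2_ext = unname(st["r2"]),
      rmse_ext = unname(st["rmse"]))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("validation_report", class(out))
  out
}

#' Permutation significance of an OPLS model
#'
#' Refits the model under `n_perm` random permutations of y, each evaluated
#' by venetian-blinds cross-validation. The primary p-value is rank-based:
#' `p = (1 + #\{permuted RMSE_CV <= true RMSE_CV\}) / (1 + n_perm)`, with
#' floor `1 / (n_perm + 1)`. A secondary Wilcoxon signed-rank p compares the
#' absolute CV residuals of the true model against each permuted model
#' (alternative: true residuals smaller); the median over permutations is
#' reported.
#'
#' @param X predictor matrix or [spectrum_matrix()].
#' @param y numeric response.
#' @param n_perm number of permutations (>= 1; default 50).
#' @param n_splits venetian-blinds folds.
#' @param n_ortho orthogonal components.
#' @param seed integer seed.
#' @return list with `p` (rank-based, primary), `p_wilcoxon`, `rmse_cv`
#'   (true model) and `rmse_perm` (permuted RMSE_CV values).
#' @export
permutation_significance <- function(X, y, n_perm = 50, n_splits = 10,
                                     n_ortho = 0, seed = 1) {
  if (!is_count(n_perm) || n_perm < 1) stopf("n_perm must be >= 1")
  X <- sm_values(X)
  y <- as.numeric(y)
  true_cv <- venetian_cv(X, y, n_splits, n_ortho)
  res_true <- abs(true_cv$residuals)
  with_seed(seed, {
    rmse_perm <- numeric(n_perm)
    wil <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      yp <- sample(y)
      cv <- venetian_cv(X, yp, n_splits, n_ortho)
      rmse_perm[b] <- cv$rmse_cv
      wil[b] <- suppressWarnings(
        stats::wilcox.test(res_true, abs(cv$residuals), paired = TRUE,
                           alternative = "less")$p.value)
    }
    list(p = (1 + sum(rmse_perm <= true_cv$rmse_cv)) / (1 + n_perm),
         p_wilcoxon = stats::median(wil),
         rmse_cv = true_cv$rmse_cv, rmse_perm = rmse_perm)
  })
}
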