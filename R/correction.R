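#' Encode a fixed-effect design matrix
#'
#' Builds an intercept-plus-dummy (treatment coded) design from the cohort
#' metadata for any subset of the weeks-in-milk, parity and herd factors.
#' Levels are sorted, the first level of each factor is the (dropped)
#' reference, and factors with fewer than two observed levels are dropped
#' with a warning.
#'
#' @param metadata data.frame with the requested factor columns.
#' @param factors character subset of `c("wim", "parity", "herd")` (any
#'   categorical metadata columns are accepted).
#' @return a `fixed_effect_design`: list with `X` (n x q design matrix),
#'   `factors` (retained factors), `term` (column-to-factor map),
#'   `df_residual`, `qr` (QR of X) and `levels` (per-factor level sets).
#' @export
encode_design <- function(metadata, factors = c("wim", "parity", "herd")) {
  stopifnot(is.data.frame(metadata), length(factors) >= 1)
  miss <- setdiff(factors, names(metadata))
  if (length(miss)) stopf("metadata lacks factor column(s): %s",
                          paste(miss, collapse = ", "))
  n <- nrow(metadata)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  term <- "(Intercept)"
  kept <- character(0)
  levs <- list()
  for (f in factors) {
    fv <- factor(as.character(metadata[[f]]),
                 levels = sort(unique(as.character(metadata[[f]]))))
    if (nlevels(fv) < 2) {
      warnf("factor '%s' has a single observed level and was dropped", f)
      next
    }
    kept <- c(kept, f)
    levs[[f]] <- levels(fv)
    for (lv in levels(fv)[-1]) {
      X <- cbind(X, as.numeric(fv == lv))
      colnames(X)[ncol(X)] <- paste0(f, lv)
      term <- c(term, f)
    }
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stopf("rank-deficient design; aliased column(s): %s",
          paste(aliased, collapse = ", "))
  }
  structure(list(X = X, factors = kept, term = term,
                 df_residual = n - ncol(X), qr = qrx, levels = levs),
            class = "fixed_effect_design")
}

#' Residualise a spectrum matrix on a fixed-effect design
#'
#' Fits a separate ordinary least squares model to the signal intensity at
#' every chemical shift, with the design's fixed effects as predictors. The
#' matrix of residuals is the "corrected" spectrum set: the intensity
#' variation left after removing the modelled systematic effects. Per-shift
#' coefficients of determination `r2 = 1 - RSS/TSS` (TSS about the column
#' mean) quantify how much variation each effect set explains at each shift.
#' All columns share one orthogonal projection (via the design's QR), which
#' is numerically identical to column-by-column fits.
#'
#' @param sm a [spectrum_matrix()] (or plain matrix).
#' @param design a [encode_design()] result.
#' @return a `correction_result`: list with `residuals` (corrected
#'   [spectrum_matrix()] or matrix), `fitted`, `r2` (per-shift vector),
#'   `model` (factor tag) and `design`.
#' @export
correct_matrix <- function(sm, design) {
  stopifnot(inherits(design, "fixed_effect_design"))
  Y <- sm_values(sm)
  if (nrow(Y) != nrow(design$X))
    stopf("sample count (%d) != design rows (%d)", nrow(Y), nrow(design$X))
  if (nrow(Y) <= ncol(design$X))
    stopf("need more samples than design columns")
  fitted <- qr.fitted(design$qr, Y)
  E <- Y - fitted
  mu <- colMeans(Y)
  tss <- colSums(sweep(Y, 2, mu)^2)
  rss <- colSums(E^2)
  r2 <- ifelse(tss > 0, pmin(pmax(1 - rss / tss, 0), 1), 0)
  zv <- tss == 0
  if (any(zv)) {       # constant columns: define residual 0, r2 0
    E[, zv] <- 0
    fitted[, zv] <- Y[, zv]
  }
  res <- if (inherits(sm, "spectrum_matrix")) sm_replace(sm, E) else E
  structure(list(residuals = res, fitted = fitted, r2 = unname(r2),
                 model = paste(design$factors, collapse = "+"),
                 design = design),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("<correction_result> model: %s; %d x %d; mean R2 = %.3f\n",
              x$model, nrow(x$fitted), ncol(x$fitted), mean(x$r2)))
  invisible(x)
}

#' Class centering
#'
#' Subtracts from every spectrum the mean spectrum of its class. For a single
#' categorical factor this is exactly the residual of the per-column OLS fit
#' on that factor (see [correct_matrix()]); with one class it reduces to
#' global mean centering.
#'
#' @param sm a [spectrum_matrix()] or matrix.
#' @param factor_values class label per sample.
#' @return object of the same type as `sm`, class-centred.
#' @export
class_center <- function(sm, factor_values) {
  X <- sm_values(sm)
  f <- factor(as.character(factor_values))
  if (length(f) != nrow(X)) stopf("factor length != sample count")
  means <- rowsum(X, f) / as.vector(table(f))
  out <- X - means[as.integer(f), , drop = FALSE]
  if (inherits(sm, "spectrum_matrix")) sm_replace(sm, out) else out
}

#' Residualise a phenotype on a fixed-effect design
#'
#' The corrected phenotype (e.g. corrected BHBA) is the OLS residual of the
#' reference values on the same fixed effects used for spectral correction.
#' Residuals have mean ~0 and may be negative; they are relative rankings,
#' not absolute concentrations.
#'
#' @param y numeric phenotype vector (e.g. BHBA, mmol/L).
#' @param design a [encode_design()] result.
#' @return numeric vector of residuals.
#' @export
correct_phenotype <- function(y, design) {
  stopifnot(inherits(design, "fixed_effect_design"))
  y <- as.numeric(y)
  if (length(y) != nrow(design$X)) stopf("length(y) != design rows")
  as.numeric(qr.resid(design$qr, y))
}

#' Per-shift R-squared overlay table
#'
#' Tabulates the per-chemical-shift variance fraction explained by the
#' corrected model together with the mean spectrum, ready for plotting as a
#' colour-coded overlay ("percentage of variation explained at each shift").
#'
#' @param result a [correct_matrix()] result.
#' @param ppm optional ppm axis; defaults to the axis stored in the result.
#' @return data.frame with columns `ppm`, `r2`, `mean_intensity`.
#' @export
r2_overlay <- function(result, ppm = NULL) {
  stopifnot(inherits(result, "correction_result"))
  if (is.null(ppm)) {
    if (!inherits(result$residuals, "spectrum_matrix"))
      stopf("ppm must be supplied when the result holds a plain matrix")
    ppm <- result$residuals$ppm
  }
  if (length(ppm) != length(result$r2)) stopf("ppm length != r2 length")
  data.frame(ppm = ppm, r2 = result$r2,
             mean_intensity = colMeans(result$fitted))
}

#' Plot an R-squared overlay
#'
#' Draws the mean spectrum coloured by the per-shift explained-variance
#' fraction (as a percentage).
#'
#' @param overlay a [r2_overlay()] table.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the overlay.
#' @export
plot_r2_overlay <- function(overlay, ...) {
  pal <- grDevices::hcl.colors(101, "viridis")
  col <- pal[1 + round(100 * overlay$r2)]
  graphics::plot(overlay$ppm, overlay$mean_intensity, type = "n",
                 xlim = rev(range(overlay$ppm)), xlab = "ppm",
                 ylab = "mean intensity", ...)
  graphics::segments(overlay$ppm[-1], overlay$mean_intensity[-1],
                     overlay$ppm[-nrow(overlay)],
                     overlay$mean_intensity[-nrow(overlay)], col = col)
  invisible(overlay)
}
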