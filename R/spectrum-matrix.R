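#' Spectrum matrix container
#'
#' A `spectrum_matrix` bundles a samples-by-chemical-shifts intensity matrix
#' with its ppm axis and sample identifiers. The ppm axis is stored strictly
#' monotone decreasing (downfield first), the layout in which 1D 1H NMR
#' spectra are conventionally displayed and processed.
#'
#' @param intensities numeric matrix, samples in rows, chemical shifts in
#'   columns. No missing values are allowed.
#' @param ppm numeric vector of chemical shifts (ppm), strictly decreasing,
#'   one per column of `intensities`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `rownames(intensities)`.
#' @return an object of class `spectrum_matrix` with fields `intensities`,
#'   `ppm` and `sample_ids`.
#' @export
spectrum_matrix <- function(intensities, ppm,
                            sample_ids = rownames(intensities)) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (anyNA(intensities)) stopf("intensity matrix contains missing values")
  if (length(ppm) != ncol(intensities))
    stopf("ppm axis length (%d) != column count (%d)",
          length(ppm), ncol(intensities))
  if (length(ppm) >= 2 && any(diff(ppm) >= 0))
    stopf("ppm axis must be strictly decreasing")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(intensities)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(intensities))
    stopf("sample_ids length != row count")
  if (anyDuplicated(sample_ids))
    stopf("duplicate sample ids: %s",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  rownames(intensities) <- sample_ids
  structure(list(intensities = intensities, ppm = as.numeric(ppm),
                 sample_ids = sample_ids),
            class = "spectrum_matrix")
}

#' @export
dim.spectrum_matrix <- function(x) dim(x$intensities)

#' @export
as.matrix.spectrum_matrix <- function(x, ...) x$intensities

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat(sprintf("<spectrum_matrix> %d samples x %d shifts, ppm %.3f .. %.3f\n",
              nrow(x$intensities), ncol(x$intensities),
              max(x$ppm), min(x$ppm)))
  invisible(x)
}

# Replace the intensity matrix, keeping axis/ids consistent.
sm_replace <- function(sm, intensities) {
  sm$intensities <- intensities
  rownames(sm$intensities) <- sm$sample_ids
  sm
}

# Coerce a spectrum_matrix or plain matrix to a numeric matrix.
sm_values <- function(x) {
  if (inherits(x, "spectrum_matrix")) x$intensities else as.matrix(x)
}

#' Locate peak-top columns around nominal resonance positions
#'
#' For each nominal centre, searches a small window of the mean spectrum and
#' returns the columns whose mean intensity reaches at least `frac` of the
#' window maximum — the near-top columns of that peak, robust to small
#' alignment offsets.
#'
#' @param sm a [spectrum_matrix()].
#' @param centers nominal peak positions (ppm).
#' @param halfwin half-width of the search window (ppm).
#' @param frac fraction of the window maximum defining "near-top".
#' @return integer vector of column indices (unique, sorted).
#' @export
peak_columns <- function(sm, centers, halfwin = 0.015, frac = 0.75) {
  stopifnot(inherits(sm, "spectrum_matrix"))
  ms <- colMeans(sm$intensities)
  idx <- integer(0)
  for (ctr in centers) {
    win <- which(abs(sm$ppm - ctr) <= halfwin)
    if (!length(win)) stopf("no columns within %.3f ppm of %.3f", halfwin,
                            ctr)
    idx <- c(idx, win[ms[win] >= frac * max(ms[win])])
  }
  sort(unique(idx))
}
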