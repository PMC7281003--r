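#' Remove chemical-shift regions from a spectrum matrix
#'
#' Columns whose ppm falls inside any of the given intervals (closed on both
#' ends) are removed; the order of the remaining columns is preserved. Used
#' for the residual-water (4.68-5.00 ppm), methanol (3.32-3.36 ppm), upfield
#' reference (-0.60-0.40 ppm) and non-informative downfield (> 9.00 ppm)
#' excisions.
#'
#' @param sm a [spectrum_matrix()].
#' @param intervals list of numeric length-2 vectors `c(lo, hi)` in ppm;
#'   `Inf` is allowed as an upper bound. An empty list is the identity.
#' @return the excised [spectrum_matrix()], with attributes `n_retained` and
#'   `excised_intervals`.
#' @export
excise_regions <- function(sm, intervals) {
  stopifnot(inherits(sm, "spectrum_matrix"))
  if (length(intervals) == 0) {
    attr(sm, "n_retained") <- ncol(sm$intensities)
    attr(sm, "excised_intervals") <- list()
    return(sm)
  }
  keep <- rep(TRUE, length(sm$ppm))
  for (iv in intervals) {
    iv <- sort(as.numeric(iv))
    if (length(iv) != 2 || anyNA(iv)) stopf("each interval must be c(lo, hi)")
    if (iv[2] < min(sm$ppm) || iv[1] > max(sm$ppm))
      stopf("interval [%g, %g] lies outside the ppm range", iv[1], iv[2])
    keep <- keep & !(sm$ppm >= iv[1] & sm$ppm <= iv[2])
  }
  if (!any(keep)) stopf("excision would remove every column")
  out <- spectrum_matrix(sm$intensities[, keep, drop = FALSE], sm$ppm[keep],
                         sm$sample_ids)
  attr(out, "n_retained") <- sum(keep)
  attr(out, "excised_intervals") <- intervals
  out
}

# Segment boundaries for COW: near-equal splits of 1..p, shared endpoints.
cow_boundaries <- function(p, segment_len) {
  nseg <- max(2L, round((p - 1) / segment_len))
  unique(round(seq(1, p, length.out = nseg + 1)))
}

# Correlations of all samples' interpolated target windows against one
# reference segment. X: n x p; ref_seg: centred reference values; window
# [a, b] (real positions) interpolated to length(ref_seg) points.
cow_segment_cor <- function(X, rc, sr, a, b) {
  L <- length(rc)
  xs <- seq(a, b, length.out = L)
  lo <- pmax(1L, pmin(ncol(X) - 1L, floor(xs)))
  fr <- xs - lo
  W <- X[, lo, drop = FALSE] * rep(1 - fr, each = nrow(X)) +
    X[, lo + 1L, drop = FALSE] * rep(fr, each = nrow(X))
  Wc <- W - rowMeans(W)
  den <- sqrt(rowSums(Wc^2)) * sr
  num <- as.vector(Wc %*% rc)
  out <- ifelse(den > 0, num / den, 0)
  out
}

#' Correlation optimised warping alignment
#'
#' Aligns every spectrum to a reference by segment-wise linear stretching and
#' compression. Interior segment boundaries may shift by up to `slack` points;
#' the boundary offsets are chosen by dynamic programming to maximise the sum
#' of per-segment Pearson correlations with the reference. The identity path
#' is always feasible, and any sample whose whole-spectrum correlation with
#' the reference would decrease is left unwarped, so alignment never reduces
#' the correlation to the reference.
#'
#' @param sm a [spectrum_matrix()].
#' @param reference sample index, sample id, or `"median"` (default): the
#'   sample with maximal mean correlation to all others.
#' @param segment_len nominal segment length in points; must exceed
#'   `2 * slack`.
#' @param slack maximal boundary shift in points (>= 1).
#' @return list with `spectra` (aligned [spectrum_matrix()]) and `paths`
#'   (per-sample warp paths: reference and target boundary indices plus
#'   per-segment correlation before and after warping), and `reference`
#'   (the reference sample index).
#' @export
cow_align <- function(sm, reference = "median", segment_len = 50, slack = 5) {
  stopifnot(inherits(sm, "spectrum_matrix"))
  X <- sm$intensities
  n <- nrow(X); p <- ncol(X)
  if (!(segment_len > 2 * slack) || slack < 1)
    stopf("need segment_len > 2 * slack and slack >= 1")
  if (p < 2 * segment_len) stopf("spectrum too short for segment_len")

  ref_idx <- if (identical(reference, "median")) {
    cc <- suppressWarnings(stats::cor(t(X)))
    cc[!is.finite(cc)] <- 0
    which.max(colMeans(cc))
  } else if (is.character(reference)) {
    match(reference, sm$sample_ids)
  } else as.integer(reference)
  if (is.na(ref_idx) || ref_idx < 1 || ref_idx > n)
    stopf("invalid reference sample")
  ref <- X[ref_idx, ]

  b <- cow_boundaries(p, segment_len)
  nseg <- length(b) - 1L
  if (any(diff(b) <= 2 * slack))
    stopf("segments shorter than 2 * slack; decrease slack or segment_len")
  offs <- (-slack):slack
  no <- length(offs)

  # Reference segments (centred) and their scale.
  rcs <- vector("list", nseg); srs <- numeric(nseg)
  zero_var <- FALSE
  for (i in seq_len(nseg)) {
    r <- ref[b[i]:b[i + 1]]
    rc <- r - mean(r)
    sr <- sqrt(sum(rc^2))
    if (sr == 0) zero_var <- TRUE
    rcs[[i]] <- rc; srs[i] <- sr
  }
  if (zero_var)
    warnf("constant reference segment: its correlation contribution is 0")

  # Per-segment correlation tables C[[i]][oL, oR, sample]; end offsets fixed.
  C <- vector("list", nseg)
  for (i in seq_len(nseg)) {
    oL <- if (i == 1L) 0L else offs
    oR <- if (i == nseg) 0L else offs
    arr <- array(0, c(length(oL), length(oR), n))
    for (a_i in seq_along(oL)) for (b_i in seq_along(oR)) {
      arr[a_i, b_i, ] <- cow_segment_cor(X, rcs[[i]], srs[i],
                                         b[i] + oL[a_i], b[i + 1] + oR[b_i])
    }
    C[[i]] <- arr
  }

  # DP over interior boundary offsets, vectorised across samples.
  # D: no x n cumulative score at boundary i; ptr[[i]]: argmax back-pointers.
  ptr <- vector("list", nseg)
  D <- matrix(C[[1]][1, , ], nrow = no, ncol = n)   # boundary 1 offsets
  if (nseg > 2L) {
    for (i in 2L:(nseg - 1L)) {
      Dn <- matrix(-Inf, no, n)
      pt <- matrix(1L, no, n)
      for (oR in seq_len(no)) {
        cand <- D + matrix(C[[i]][, oR, ], nrow = no, ncol = n)
        best <- max.col(t(cand), ties.method = "first")
        pt[oR, ] <- best
        Dn[oR, ] <- cand[cbind(best, seq_len(n))]
      }
      ptr[[i]] <- pt
      D <- Dn
    }
  }
  final <- D + matrix(C[[nseg]][, 1, ], nrow = no, ncol = n)
  last <- max.col(t(final), ties.method = "first")

  # Backtrack per sample to interior boundary offsets.
  path_off <- matrix(0L, n, nseg - 1L)
  for (s in seq_len(n)) {
    o <- last[s]
    path_off[s, nseg - 1L] <- o
    if (nseg > 2L) for (i in (nseg - 1L):2L) {
      o <- ptr[[i]][o, s]
      path_off[s, i - 1L] <- o
    }
  }

  warp_one <- function(x, off_idx) {
    tb <- b
    if (nseg > 1L) tb[2:nseg] <- b[2:nseg] + offs[off_idx]
    out <- numeric(p)
    for (i in seq_len(nseg)) {
      L <- b[i + 1] - b[i] + 1L
      xs <- seq(tb[i], tb[i + 1], length.out = L)
      lo <- pmax(1L, pmin(p - 1L, floor(xs)))
      fr <- xs - lo
      out[b[i]:b[i + 1]] <- x[lo] * (1 - fr) + x[lo + 1L] * fr
    }
    out
  }

  aligned <- X
  paths <- vector("list", n)
  n_fallback <- 0L
  for (s in seq_len(n)) {
    w <- warp_one(X[s, ], path_off[s, ])
    c_before <- safe_cor(X[s, ], ref)
    c_after <- safe_cor(w, ref)
    if (c_after >= c_before) {
      aligned[s, ] <- w
      used <- path_off[s, ]
    } else {  # identity fallback keeps the no-degradation guarantee
      used <- rep(which(offs == 0L), nseg - 1L)
      c_after <- c_before
      n_fallback <- n_fallback + 1L
    }
    seg_before <- seg_after <- numeric(nseg)
    for (i in seq_len(nseg)) {
      idx <- b[i]:b[i + 1]
      seg_before[i] <- safe_cor(X[s, idx], ref[idx])
      seg_after[i] <- safe_cor(aligned[s, idx], ref[idx])
    }
    tb <- b
    if (nseg > 1L) tb[2:nseg] <- b[2:nseg] + offs[used]
    paths[[s]] <- structure(list(ref_boundaries = b, target_boundaries = tb,
                                 cor_before = seg_before,
                                 cor_after = seg_after,
                                 total_before = c_before,
                                 total_after = c_after),
                            class = "warp_path")
  }
  if (n_fallback > 0)
    message(sprintf("cow_align: identity fallback for %d/%d samples",
                    n_fallback, n))
  list(spectra = sm_replace(sm, aligned), paths = paths, reference = ref_idx)
}

#' Total-area normalisation
#'
#' Scales each spectrum so its summed intensity equals `target`, removing
#' inherent concentration/dilution differences between samples.
#'
#' @param sm a [spectrum_matrix()].
#' @param target row sum after scaling (default 1, i.e. relative areas).
#' @return normalised [spectrum_matrix()].
#' @export
normalize_total_area <- function(sm, target = 1) {
  stopifnot(inherits(sm, "spectrum_matrix"))
  s <- rowSums(sm$intensities)
  bad <- which(s <= 0)
  if (length(bad))
    stopf("non-positive total area for sample(s): %s",
          paste(sm$sample_ids[bad], collapse = ", "))
  sm_replace(sm, sm$intensities * (target / s))
}

#' Baseline removal by asymmetric weighted least squares
#'
#' Estimates a smooth baseline per spectrum by iteratively reweighted
#' penalised least squares: the baseline minimises
#' `sum(w * (y - z)^2) + lambda * sum(diff(z, d = 2)^2)` with weight `asym_p`
#' for points above the current baseline and `1 - asym_p` below, so the
#' baseline hugs the signal-free floor. Iterates until the weight assignment
#' is stable or `max_iter`.
#'
#' @param sm a [spectrum_matrix()].
#' @param smooth_lambda positive smoothness penalty on the squared second
#'   difference (default 1e7).
#' @param asym_p asymmetry weight in (0, 0.5) for points above the baseline
#'   (default 0.001).
#' @param max_iter maximal reweighting iterations (default 20).
#' @return baseline-corrected [spectrum_matrix()] with attributes `baseline`
#'   (the removed baselines) and `n_not_converged`.
#' @export
baseline_awls <- function(sm, smooth_lambda = 1e7, asym_p = 0.001,
                          max_iter = 20) {
  stopifnot(inherits(sm, "spectrum_matrix"))
  if (smooth_lambda <= 0) stopf("smooth_lambda must be > 0")
  if (asym_p <= 0 || asym_p >= 0.5) stopf("asym_p must be in (0, 0.5)")
  X <- sm$intensities
  p <- ncol(X)
  D <- Matrix::bandSparse(p - 2, p, k = 0:2,
                          diagonals = list(rep(1, p - 2), rep(-2, p - 2),
                                           rep(1, p - 2)))
  P <- smooth_lambda * Matrix::crossprod(D)
  B <- matrix(0, nrow(X), p)
  n_nc <- 0L
  for (s in seq_len(nrow(X))) {
    y <- X[s, ]
    w <- rep(1, p)
    z <- y
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      Wm <- Matrix::Diagonal(p, w)
      z <- as.numeric(Matrix::solve(Wm + P, w * y))
      w_new <- ifelse(y > z, asym_p, 1 - asym_p)
      if (identical(w_new, w) && it > 1) { converged <- TRUE; break }
      w <- w_new
    }
    if (!converged) n_nc <- n_nc + 1L
    B[s, ] <- z
  }
  if (n_nc > 0)
    message(sprintf("baseline_awls: %d spectra hit max_iter", n_nc))
  out <- sm_replace(sm, X - B)
  attr(out, "baseline") <- B
  attr(out, "n_not_converged") <- n_nc
  out
}

#' Column mean centering
#'
#' @param sm a [spectrum_matrix()] with at least 2 samples.
#' @return list with `spectra` (centred [spectrum_matrix()]) and `means`
#'   (removed column means, for back-transformation).
#' @export
mean_center <- function(sm) {
  stopifnot(inherits(sm, "spectrum_matrix"))
  if (nrow(sm$intensities) < 2) stopf("mean centering needs >= 2 samples")
  mu <- colMeans(sm$intensities)
  list(spectra = sm_replace(sm, sweep(sm$intensities, 2, mu)), means = mu)
}

#' Preprocessing configuration
#'
#' Stage toggles and parameters of [preprocess_pipeline()], in processing
#' order: residual-water excision, alignment, total-area normalisation,
#' post-normalisation excisions (methanol, upfield reference region,
#' downfield tail), baseline removal, mean centering.
#'
#' @param excise_water logical; remove the water interval before alignment.
#' @param water_interval ppm interval of the residual water peak.
#' @param align logical; run [cow_align()].
#' @param reference,segment_len,slack alignment parameters.
#' @param normalize logical; run [normalize_total_area()].
#' @param area_target row sum after normalisation.
#' @param excise_post logical; apply `post_intervals` after normalisation.
#' @param post_intervals list of ppm intervals removed after normalisation:
#'   methanol, the upfield reference region read as \[-0.60, 0.40\], and the
#'   downfield tail above (not including) 9.00 ppm.
#' @param baseline logical; run [baseline_awls()].
#' @param smooth_lambda,asym_p,max_iter baseline parameters.
#' @param center logical; run [mean_center()].
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(excise_water = TRUE,
                              water_interval = c(4.68, 5.00),
                              align = TRUE, reference = "median",
                              segment_len = 50, slack = 5,
                              normalize = TRUE, area_target = 1,
                              excise_post = TRUE,
                              post_intervals = list(c(3.32, 3.36),
                                                    c(-0.60, 0.40),
                                                    c(9.00 + 1e-9, Inf)),
                              baseline = TRUE, smooth_lambda = 1e7,
                              asym_p = 0.001, max_iter = 20,
                              center = TRUE) {
  structure(as.list(environment()), class = "preprocess_config")
}

#' Full spectral preprocessing chain
#'
#' Applies, in order: water-region excision, correlation optimised warping,
#' total-area normalisation, methanol/reference/downfield excisions, baseline
#' removal, and mean centering. Each stage can be disabled via the
#' configuration; with every stage disabled the pipeline is the identity.
#'
#' @param sm a [spectrum_matrix()].
#' @param config a [preprocess_config()].
#' @return the processed [spectrum_matrix()] with attribute `provenance`
#'   (a list: retained ppm columns, stage parameters, column means if
#'   centred, warp reference).
#' @export
preprocess_pipeline <- function(sm, config = preprocess_config()) {
  stopifnot(inherits(sm, "spectrum_matrix"),
            inherits(config, "preprocess_config"))
  prov <- list(config = unclass(config), n_input = ncol(sm$intensities))
  if (config$excise_water)
    sm <- excise_regions(sm, list(config$water_interval))
  if (config$align) {
    al <- cow_align(sm, config$reference, config$segment_len, config$slack)
    sm <- al$spectra
    prov$warp_reference <- al$reference
  }
  if (config$normalize) sm <- normalize_total_area(sm, config$area_target)
  if (config$excise_post) sm <- excise_regions(sm, config$post_intervals)
  if (config$baseline)
    sm <- baseline_awls(sm, config$smooth_lambda, config$asym_p,
                        config$max_iter)
  if (config$center) {
    mc <- mean_center(sm)
    sm <- mc$spectra
    prov$column_means <- mc$means
  }
  prov$retained_ppm <- sm$ppm
  prov$n_retained <- ncol(sm$intensities)
  attr(sm, "provenance") <- prov
  sm
}
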