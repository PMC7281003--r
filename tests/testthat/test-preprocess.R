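make_sm <- function(n = 6, p = 200, seed = 1) {
  set.seed(seed)
  ppm <- seq(10, -0.6, length.out = p)
  spectrum_matrix(matrix(abs(rnorm(n * p)), n, p), ppm)
}

test_that("region excision removes exactly the closed-interval columns", {
  sm <- make_sm(p = 400)
  win <- sm$ppm >= 4.68 & sm$ppm <= 5.00
  out <- excise_regions(sm, list(c(4.68, 5.00)))
  expect_identical(ncol(out$intensities), ncol(sm$intensities) - sum(win))
  expect_false(any(out$ppm >= 4.68 & out$ppm <= 5.00))
  expect_identical(out$ppm, sm$ppm[!win])        # order preserved

  # empty interval list is the identity
  idp <- excise_regions(sm, list())
  expect_identical(idp$intensities, sm$intensities)

  # the study's four excisions: retained count equals independent
  # closed-interval arithmetic on the same grid
  ivs <- list(c(4.68, 5.00), c(3.32, 3.36), c(-0.60, 0.40),
              c(9.00 + 1e-9, Inf))
  out4 <- excise_regions(sm, ivs)
  keep <- rep(TRUE, length(sm$ppm))
  for (iv in ivs) keep <- keep & !(sm$ppm >= iv[1] & sm$ppm <= iv[2])
  expect_identical(attr(out4, "n_retained"), sum(keep))
  expect_error(excise_regions(sm, list(c(-10, -5))), "outside")
  expect_error(excise_regions(sm, list(c(-1, 11))), "every column")
})

test_that("total-area normalisation is exact and scale invariant", {
  sm <- make_sm()
  out <- normalize_total_area(sm, target = 1)
  expect_true(all(abs(rowSums(out$intensities) - 1) < 1e-9))
  # already-normalised input is unchanged; doubling a raw spectrum is too
  expect_equal(normalize_total_area(out)$intensities, out$intensities,
               tolerance = 1e-12)
  doubled <- spectrum_matrix(sm$intensities * 2, sm$ppm, sm$sample_ids)
  expect_equal(normalize_total_area(doubled)$intensities, out$intensities,
               tolerance = 1e-12)
  zero <- spectrum_matrix(matrix(0, 2, 5), seq(5, 1), c("a", "b"))
  expect_error(normalize_total_area(zero), "a")
})

test_that("asymmetric weighted least squares recovers smooth baselines", {
  p <- 1024
  ppm <- seq(10, -0.6, length.out = p)
  x <- seq_along(ppm)
  # flat spectrum: baseline ~ c, corrected ~ 0
  flat <- spectrum_matrix(matrix(5, 2, p), ppm, c("a", "b"))
  out <- baseline_awls(flat, smooth_lambda = 1e5)
  expect_lt(max(abs(out$intensities)), 1e-6)
  expect_equal(mean(attr(out, "baseline")), 5, tolerance = 1e-6)

  # peaks on a zero baseline: correction leaves them nearly untouched
  set.seed(2)
  peaks <- 3 * exp(-((x - 300) / 6)^2) + 2 * exp(-((x - 700) / 8)^2)
  noisy <- peaks + rnorm(p, 0, 0.01)
  smp <- spectrum_matrix(rbind(noisy), ppm, "s1")
  outp <- baseline_awls(smp, smooth_lambda = 1e6)
  expect_lt(sqrt(mean((outp$intensities[1, ] - noisy)^2)), 0.05)

  # known slow sinusoidal drift recovered within 10% RMS; the smoothness
  # penalty is matched to the drift period (the 1e7 default targets the
  # much longer periods of full-width spectra)
  drift <- 0.5 * (1.3 + sin(2 * pi * x / 800))
  smd <- spectrum_matrix(rbind(peaks + drift), ppm, "s1")
  outd <- baseline_awls(smd, smooth_lambda = 1e4)
  est <- attr(outd, "baseline")[1, ]
  expect_lt(sqrt(mean((est - drift)^2)), 0.1 * sqrt(mean(drift^2)))
  expect_error(baseline_awls(flat, smooth_lambda = -1), "smooth_lambda")
  expect_error(baseline_awls(flat, asym_p = 0.7), "asym_p")
})

test_that("mean centering is exact, idempotent and reversible", {
  sm <- make_sm()
  mc <- mean_center(sm)
  expect_lt(max(abs(colMeans(mc$spectra$intensities))), 1e-10)
  mc2 <- mean_center(mc$spectra)
  expect_equal(mc2$spectra$intensities, mc$spectra$intensities,
               tolerance = 1e-12)
  # adding a constant to one column shifts only its stored mean
  shifted <- sm
  shifted$intensities[, 3] <- shifted$intensities[, 3] + 7
  mcs <- mean_center(shifted)
  expect_equal(mcs$means[3], mc$means[3] + 7, ignore_attr = TRUE)
  expect_equal(mcs$means[-3], mc$means[-3], tolerance = 1e-12)
  expect_equal(mcs$spectra$intensities, mc$spectra$intensities,
               tolerance = 1e-12)
})

test_that("COW aligns rigid shifts and never degrades reference correlation", {
  set.seed(3)
  p <- 512
  x <- seq_len(p)
  ref <- exp(-((x - 100) / 5)^2) + 0.7 * exp(-((x - 260) / 7)^2) +
    0.5 * exp(-((x - 400) / 4)^2) + 0.02 * rnorm(p)
  shift3 <- c(ref[4:p], ref[p - (2:0)])          # rigid 3-point shift
  set.seed(4)
  jig <- ref + 0.05 * rnorm(p)
  sm <- spectrum_matrix(rbind(ref, shift3, jig),
                        seq(10, -0.6, length.out = p),
                        c("ref", "shift", "jig"))
  al <- cow_align(sm, reference = 1, segment_len = 64, slack = 5)
  # reference aligned to itself: identity path, correlation 1
  expect_identical(al$paths[[1]]$target_boundaries,
                   al$paths[[1]]$ref_boundaries)
  expect_equal(al$paths[[1]]$total_after, 1, tolerance = 1e-12)
  # every sample: correlation after >= before
  for (pth in al$paths) expect_gte(pth$total_after, pth$total_before)
  # a rigid shift within slack is substantially corrected
  expect_gt(al$paths[[2]]$total_after, 0.99)
  expect_gt(al$paths[[2]]$total_after, al$paths[[2]]$total_before + 0.01)
  expect_error(cow_align(sm, segment_len = 8, slack = 5), "slack")
})

test_that("COW dynamic programme matches exhaustive path enumeration", {
  for (seed in 1:4) {
    set.seed(seed)
    p <- 64
    x <- seq_len(p)
    ref <- exp(-((x - 18) / 3)^2) + 0.8 * exp(-((x - 45) / 4)^2) +
      0.05 * rnorm(p)
    tgt <- exp(-((x - 20) / 3)^2) + 0.8 * exp(-((x - 43) / 4)^2) +
      0.05 * rnorm(p)
    sm <- spectrum_matrix(rbind(ref, tgt), seq(5, 1, length.out = p),
                          c("r", "t"))
    al <- cow_align(sm, reference = 1, segment_len = 16, slack = 2)
    b <- al$paths[[2]]$ref_boundaries
    dp_score <- sum(al$paths[[2]]$cor_after)
    brute <- brute_cow_score(tgt, ref, b, slack = 2)
    expect_equal(dp_score, brute, tolerance = 1e-10)
  }
})

test_that("COW treats constant segments as zero-correlation with a warning", {
  p <- 256
  ref <- c(rep(0, 64), exp(-((65:p - 150) / 10)^2))
  tgt <- c(rep(0, 64), exp(-((65:p - 153) / 10)^2))
  sm <- spectrum_matrix(rbind(ref, tgt) + 1e-9,
                        seq(5, 1, length.out = p), c("r", "t"))
  sm$intensities[, 1:64] <- 3   # exactly constant block
  expect_warning(cow_align(sm, reference = 1, segment_len = 32, slack = 2),
                 "constant reference segment")
})

test_that("pipeline applies stages in order and can be disabled entirely", {
  coh <- tiny_cohort(seed = 31, sizes = c(8, 7, 6, 7))
  pp <- suppressMessages(preprocess_pipeline(coh$spectra))
  expect_lt(ncol(pp$intensities), ncol(coh$spectra$intensities))
  expect_false(any(pp$ppm >= 4.68 & pp$ppm <= 5.00))
  expect_false(any(pp$ppm >= 3.32 & pp$ppm <= 3.36))
  expect_false(any(pp$ppm <= 0.40))
  expect_false(any(pp$ppm > 9.00))
  expect_lt(max(abs(colMeans(pp$intensities))), 1e-10)
  prov <- attr(pp, "provenance")
  expect_identical(prov$n_retained, ncol(pp$intensities))
  expect_identical(prov$retained_ppm, pp$ppm)

  off <- preprocess_config(excise_water = FALSE, align = FALSE,
                           normalize = FALSE, excise_post = FALSE,
                           baseline = FALSE, center = FALSE)
  idp <- preprocess_pipeline(coh$spectra, off)
  expect_identical(idp$intensities, coh$spectra$intensities)

  # deterministic: same input and config give identical output
  pp2 <- suppressMessages(preprocess_pipeline(coh$spectra))
  expect_identical(pp$intensities, pp2$intensities)

  # corrected downstream without shape errors
  cr <- correct_matrix(pp, encode_design(coh$metadata, c("wim", "parity",
                                                         "herd")))
  expect_identical(dim(cr$residuals$intensities), dim(pp$intensities))
})
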