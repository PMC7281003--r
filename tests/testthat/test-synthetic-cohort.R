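test_that("spectral library covers the required serum metabolites", {
  lib <- build_spectral_library(c(-0.6, 10))
  expect_gte(length(lib), 10)
  need <- c("lactate", "bhba", "acetate", "glucose", "glycine", "creatine",
            "betaine", "pyruvate", "hippurate", "unknown_aromatic")
  expect_true(all(need %in% names(lib)))
  # hippurate carries aromatic multiplets in 7.5-7.9 ppm
  hip <- vapply(lib$hippurate$multiplets, function(m) m$center, 0)
  expect_true(any(hip >= 7.5 & hip <= 7.9))
  # every multiplet centre (and component) lies inside the range
  for (tm in lib) for (mp in tm$multiplets) {
    span <- mp$spacing * (length(mp$heights) - 1) / 2
    expect_true(mp$center - span >= -0.6 && mp$center + span <= 10)
    expect_true(all(mp$heights > 0))
    expect_gt(tm$linewidth, 0)
  }
  expect_error(build_spectral_library(c(0, 10)), "must cover")
})

test_that("rendered acetate-only spectrum peaks at the grid point nearest 1.92 ppm", {
  cfg <- cohort_config(n_herds = 1, herd_sizes = 1, jitter_sd = 0,
                       noise_sd = 0, baseline_amp = 0, water_amp = 0,
                       methanol_amp = 0, seed = 3, grid_size = 2048)
  lib <- build_spectral_library(cfg$ppm_range, cfg$linewidth)
  conc <- setNames(numeric(length(lib)), names(lib))
  conc["acetate"] <- 1
  tr <- manual_truth(conc, names(lib), cfg)
  sm <- render_spectra(tr, lib, config = cfg)
  expect_equal(which.max(sm$intensities[1, ]),
               which.min(abs(sm$ppm - 1.92)))
  # generative identity: spectrum equals the scaled template profile
  expect_equal(as.numeric(sm$intensities[1, ]),
               render_template(lib$acetate, sm$ppm), tolerance = 1e-12)
})

test_that("rendering is linear in concentration and injects a water surrogate", {
  cfg <- cohort_config(n_herds = 1, herd_sizes = 2, jitter_sd = 0,
                       noise_sd = 0, baseline_amp = 0, water_amp = 0,
                       methanol_amp = 0, seed = 3, grid_size = 2048)
  lib <- build_spectral_library(cfg$ppm_range, cfg$linewidth)
  conc1 <- setNames(rep(0.5, length(lib)), names(lib))
  conc2 <- conc1; conc2["bhba"] <- 2 * conc1["bhba"]
  tr <- manual_truth(conc1, names(lib), cfg)
  tr$concentrations <- rbind(conc1, conc2)
  tr$metadata <- data.frame(sample_id = c("S1", "S2"))
  sm <- render_spectra(tr, lib, config = cfg)
  j <- which.min(abs(sm$ppm - 1.20))
  bh <- render_template(lib$bhba, sm$ppm)[j]
  # doubling BHBA doubles the BHBA contribution at its 1.20 doublet
  expect_equal(as.numeric(sm$intensities[2, j] - sm$intensities[1, j]),
               0.5 * bh, tolerance = 1e-10)

  # default artifacts: every sample has a dominant peak inside 4.68-5.00
  coh <- tiny_cohort(seed = 5, sizes = c(6, 5, 4, 5))
  win <- which(coh$spectra$ppm >= 4.68 & coh$spectra$ppm <= 5.00)
  for (s in seq_len(nrow(coh$spectra$intensities))) {
    expect_gt(max(coh$spectra$intensities[s, win]),
              5 * stats::median(coh$spectra$intensities[s, ]))
  }
  # grid resolution guard
  expect_error(generate_cohort(cohort_config(n_herds = 1, herd_sizes = 2,
                                             linewidth = 1e-4, seed = 1)),
               "too coarse")
  expect_error(render_spectra(tr, lib, grid_size = 1024, config = cfg),
               ">= 2048")
})

test_that("concentration simulation honours nulls, targets and determinism", {
  lib <- build_spectral_library()
  # null world: no herd/parity/wim effects anywhere
  cfg0 <- cohort_config(herd_frac = numeric(0), parity_effects = list(),
                        wim_effects = list(), energy_corr = numeric(0),
                        deviant_herd = 0, seed = 9)
  tr0 <- simulate_concentrations(cfg0, lib)
  n <- sum(cfg0$herd_sizes)
  expect_true(all(tr0$effect_fractions["herd", ] <
                    3 * (cfg0$n_herds - 1) / (n - 1)))
  expect_true(all(tr0$effect_fractions >= 0 & tr0$effect_fractions <= 1))
  expect_true(all(tr0$concentrations > 0))

  # default world: hippurate herd share hits its 0.8 target
  tr <- simulate_concentrations(cohort_config(seed = 11), lib)
  expect_equal(unname(tr$effect_fractions["herd", "hippurate"]), 0.8,
               tolerance = 0.05)

  # determinism: same seed bit-identical, different seed differs
  tr2 <- simulate_concentrations(cohort_config(seed = 11), lib)
  expect_identical(tr$concentrations, tr2$concentrations)
  tr3 <- simulate_concentrations(cohort_config(seed = 12), lib)
  expect_false(identical(tr$concentrations, tr3$concentrations))

  expect_error(cohort_config(noise_sd = -1), ">= 0")
  expect_error(cohort_config(herd_sizes = c(10, 10)), "n_herds")
})

test_that("generated cohort has the Table-1-like structure", {
  coh <- tiny_cohort(seed = 21)
  md <- coh$metadata
  expect_identical(md$sample_id, coh$spectra$sample_ids)
  expect_identical(nrow(coh$truth$concentrations), nrow(md))
  expect_true(all(md$dim >= 1 & md$dim <= 30))
  expect_true(all(md$parity %in% c("1", "2", "3", "4+")))
  expect_identical(md$wim, wim_from_dim(md$dim))
  # days 29-30 fold into week class 4
  expect_identical(wim_from_dim(c(1, 7, 8, 14, 15, 21, 22, 28, 29, 30)),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 4L, 4L))
  # default config: 707 cows across 13 herds
  cfg <- cohort_config()
  expect_identical(sum(cfg$herd_sizes), 707L)
  expect_identical(length(cfg$herd_sizes), 13L)

  # assay noise: sd of (reference - true) matches assay_sd at large n
  coh2 <- tiny_cohort(seed = 22, sizes = c(180, 180, 170, 177),
                      assay_sd = 0.03)
  expect_lt(abs(stats::sd(coh2$metadata$bhba - coh2$truth$bhba_true) -
                  0.03), 0.005)

  # single herd: herd correction degenerates to global mean centering
  coh1 <- tiny_cohort(seed = 23, n_herds = 1, sizes = 40)
  expect_warning(des <- encode_design(coh1$metadata, "herd"),
                 "single observed level")
  cr <- correct_matrix(coh1$spectra, des)
  expect_equal(cr$residuals$intensities,
               scale(coh1$spectra$intensities, scale = FALSE),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("cohort summary weights per-herd means by herd size", {
  ref <- utils::read.csv(system.file("extdata",
                                     "herd_summary_reference.csv",
                                     package = "herdnmr"))
  tab <- cohort_summary(ref)
  all_row <- tab[tab$herd == "ALL", ]
  expect_equal(all_row$n, 707)
  expect_equal(round(all_row$bhba_mean, 2), 0.63)
  expect_equal(round(all_row$dim_mean, 1), 17.4)
  expect_equal(round(all_row$parity_mean, 1), 2.5)

  # one herd only: overall row equals that herd's row
  one <- ref[3, ]
  tab1 <- cohort_summary(one)
  expect_equal(tab1$bhba_mean[2], one$bhba_mean)
  expect_equal(tab1$dim_mean[2], one$dim_mean)

  # raw-metadata path agrees with direct computation
  md <- tiny_cohort(seed = 4)$metadata
  tab2 <- cohort_summary(md)
  expect_equal(tab2$bhba_mean[tab2$herd == "ALL"], mean(md$bhba))
  expect_equal(tab2$n[tab2$herd == "H03"], sum(md$herd == "H03"))
  expect_error(cohort_summary(transform(ref, n = 0)), "N = 0")
})
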