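#' Study configuration
#'
#' Bundles every stage's parameters for [run_study()]. The single global
#' `seed` fans out to per-stage seeds by fixed offsets, so stages are
#' reproducible in isolation.
#'
#' @param cohort a [cohort_config()] (its seed is overridden by `seed`).
#' @param preprocess a [preprocess_config()].
#' @param factors fixed-effect factors (weeks-in-milk, parity, herd).
#' @param correct logical; fit the per-shift correction models. With
#'   `FALSE`, downstream analyses of corrected data (including the corrected
#'   OPLS comparison) are skipped with a warning.
#' @param n_pcs PC scores compared/tested (default 3).
#' @param asca_n_perm ASCA permutations (0 skips permutation p-values).
#' @param opls_n_perm OPLS permutations (0 skips permutation p-values).
#' @param n_splits venetian-blinds folds.
#' @param max_ortho cap for orthogonal-component selection.
#' @param logo_n_ortho orthogonal components for leave-one-farm-out;
#'   `NULL` selects per training set.
#' @param reference_farm herd id used for the single-farm control OPLS
#'   comparison.
#' @param write_matrices logical; write the full corrected spectra matrices.
#' @param seed global seed.
#' @return a `study_config` list.
#' @export
study_config <- function(cohort = cohort_config(),
                         preprocess = preprocess_config(),
                         factors = c("wim", "parity", "herd"),
                         correct = TRUE,
                         n_pcs = 3,
                         asca_n_perm = 50,
                         opls_n_perm = 50,
                         n_splits = 10,
                         max_ortho = 4,
                         logo_n_ortho = NULL,
                         reference_farm = "H01",
                         write_matrices = FALSE,
                         seed = 1) {
  structure(as.list(environment()), class = "study_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(config), f, version = 2)
  unname(tools::md5sum(f))
}

write_table_prov <- function(df, path, provenance) {
  write_provenance(path, provenance)
  tc <- file(path, "a")
  on.exit(close(tc))
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = NA),
                     tc, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full multi-herd correction study
#'
#' Orchestrates the end-to-end analysis on a synthetic cohort (or ingested
#' files): simulation, preprocessing, the four per-shift correction models
#' (weeks-in-milk; parity; herd; all three), five PCAs (uncorrected plus the
#' four corrected datasets) with between-model score correlations and a
#' Hotelling outlier screen, conditional Wald F tests on the leading PC
#' scores, ASCA with permutation testing on all five datasets, OPLS
#' comparisons (single reference farm; all farms uncorrected; all farms
#' corrected, with the phenotype corrected identically), and a
#' leave-one-farm-out external validation. All tables are written as
#' delimited text with provenance headers, plus a machine-readable JSON
#' summary; a seeded run is byte-identical when repeated.
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created if absent).
#' @param spectra,metadata optional pre-made [spectrum_matrix()] and
#'   metadata data.frame; when supplied, simulation is skipped.
#' @return invisibly, a list with every stage result and `out_dir`.
#' @export
run_study <- function(config = study_config(), out_dir,
                      spectra = NULL, metadata = NULL) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  prov <- list(package = paste0("herdnmr ",
                                as.character(utils::packageVersion("herdnmr"))),
               seed = config$seed, config_md5 = hash)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed (seed %d, config %s): %s", name, config$seed,
            hash, conditionMessage(e)))
  }

  # -- cohort ---------------------------------------------------------------
  truth <- NULL
  if (is.null(spectra)) {
    cc <- config$cohort
    cc$seed <- config$seed
    cohort <- stage("simulate", generate_cohort(cc))
    spectra <- cohort$spectra
    metadata <- cohort$metadata
    truth <- cohort$truth
  }
  stage("ingest", check_cohort(spectra, metadata))
  summary_tab <- stage("cohort_summary", cohort_summary(metadata))
  write_table_prov(summary_tab, file.path(out_dir, "cohort_summary.tsv"),
                   prov)

  # -- preprocessing --------------------------------------------------------
  pp <- stage("preprocess", preprocess_pipeline(spectra, config$preprocess))

  # -- correction models 1-4 ------------------------------------------------
  model_sets <- c(as.list(config$factors), list(config$factors))
  names(model_sets) <- c(config$factors, "all")
  corrections <- NULL
  corrected_bhba <- NULL
  if (config$correct) {
    corrections <- stage("correct", lapply(model_sets, function(fs)
      correct_matrix(pp, encode_design(metadata, fs))))
    r2_tab <- data.frame(ppm = pp$ppm)
    for (nm in names(corrections)) r2_tab[[nm]] <- corrections[[nm]]$r2
    write_table_prov(r2_tab, file.path(out_dir, "r2_by_shift.tsv"), prov)
    corrected_bhba <- correct_phenotype(
      metadata$bhba, encode_design(metadata, config$factors))
    write_table_prov(
      data.frame(sample_id = metadata$sample_id, bhba = metadata$bhba,
                 bhba_corrected = corrected_bhba),
      file.path(out_dir, "corrected_bhba.tsv"), prov)
    if (config$write_matrices)
      for (nm in names(corrections))
        write_spectra(corrections[[nm]]$residuals,
                      file.path(out_dir, paste0("corrected_", nm, ".tsv")),
                      prov)
  } else {
    warnf("correction disabled: corrected analyses are skipped")
  }

  # -- PCA ------------------------------------------------------------------
  datasets <- c(list(uncorrected = pp),
                lapply(corrections %||% list(), function(cr) cr$residuals))
  pcas <- stage("pca", lapply(datasets, function(d)
    fit_pca(d, k = max(config$n_pcs, 3))))
  expl <- data.frame(dataset = names(pcas),
                     t(vapply(pcas, function(m)
                       m$explained_fraction[seq_len(config$n_pcs)],
                       numeric(config$n_pcs))),
                     pcs_for_90pct = vapply(pcas, function(m) m$k90, 0L))
  names(expl)[2:(1 + config$n_pcs)] <- paste0("PC", seq_len(config$n_pcs))
  write_table_prov(expl, file.path(out_dir, "pca_explained.tsv"), prov)
  outliers <- hotelling_outliers(pcas$uncorrected, n_pcs = 2)
  write_table_prov(outliers, file.path(out_dir, "hotelling_outliers.tsv"),
                   prov)

  score_cors <- NULL
  if (length(pcas) >= 2) {
    score_cors <- stage("score_correlations",
                        score_correlations(pcas, config$n_pcs))
    for (pc in names(score_cors))
      write_table_prov(
        data.frame(dataset = rownames(score_cors[[pc]]),
                   score_cors[[pc]], check.names = FALSE),
        file.path(out_dir, paste0("score_correlations_", pc, ".tsv")), prov)
  }

  # -- conditional Wald F on leading PCs ------------------------------------
  wald <- stage("waldf", do.call(rbind, lapply(seq_len(config$n_pcs),
    function(pc) cbind(pc = pc,
                       conditional_wald_f(pcas$uncorrected$scores[, pc],
                                          metadata, config$factors)))))
  write_table_prov(wald, file.path(out_dir, "wald_f.tsv"), prov)

  # -- ASCA on all datasets -------------------------------------------------
  asca_tab <- stage("asca", do.call(rbind, lapply(names(datasets),
    function(nm) {
      a <- if (config$asca_n_perm > 0)
        asca_permute(datasets[[nm]], metadata, config$factors,
                     config$asca_n_perm, seed = config$seed + 11L)
      else asca_decompose(datasets[[nm]], metadata, config$factors)
      data.frame(dataset = nm, factor = config$factors,
                 magnitude_pct = unname(a$magnitudes[config$factors]),
                 p = if (!is.null(a$p_values))
                   unname(a$p_values[config$factors]) else NA_real_,
                 row.names = NULL)
    })))
  write_table_prov(asca_tab, file.path(out_dir, "asca.tsv"), prov)

  # -- OPLS comparisons -----------------------------------------------------
  ref_idx <- metadata$herd == config$reference_farm
  if (!any(ref_idx)) stopf("reference farm '%s' absent", config$reference_farm)
  comp_sets <- list(
    reference_farm = list(X = pp$intensities[ref_idx, , drop = FALSE],
                          y = metadata$bhba[ref_idx]),
    all_uncorrected = list(X = pp$intensities, y = metadata$bhba))
  if (config$correct)
    comp_sets$all_corrected <- list(
      X = corrections$all$residuals$intensities, y = corrected_bhba)
  opls_rows <- list(); vip_tab <- data.frame(ppm = pp$ppm)
  opls_models <- list()
  for (nm in names(comp_sets)) {
    cs <- comp_sets[[nm]]
    k <- stage(paste0("opls_", nm),
               as.integer(select_components(cs$X, cs$y, config$max_ortho,
                                            config$n_splits)))
    cv <- venetian_cv(cs$X, cs$y, config$n_splits, k)
    fit <- fit_opls(cs$X, cs$y, k)
    opls_models[[nm]] <- fit
    pval <- if (config$opls_n_perm > 0)
      permutation_significance(cs$X, cs$y, config$opls_n_perm,
                               config$n_splits, k,
                               seed = config$seed + 12L)$p else NA_real_
    opls_rows[[nm]] <- data.frame(
      dataset = nm, n = cv$n, lv = k + 1L, p_perm = pval,
      r2_cal = cv$r2_cal, rmse_cal = cv$rmse_cal,
      r2_cv = cv$r2_cv, rmse_cv = cv$rmse_cv)
    vip_tab[[nm]] <- fit$vip
  }
  opls_tab <- do.call(rbind, c(opls_rows, list(make.row.names = FALSE)))
  write_table_prov(opls_tab, file.path(out_dir, "opls_comparisons.tsv"),
                   prov)
  write_table_prov(vip_tab, file.path(out_dir, "opls_vip.tsv"), prov)

  # -- leave-one-farm-out ---------------------------------------------------
  logo <- stage("logo", leave_one_group_out(
    pp$intensities, metadata$bhba, metadata$herd,
    n_ortho = config$logo_n_ortho, max_ortho = config$max_ortho,
    n_splits = config$n_splits))
  write_table_prov(logo, file.path(out_dir, "logo_validation.tsv"), prov)

  # -- machine-readable summary --------------------------------------------
  summary <- list(
    seed = config$seed, config_md5 = hash,
    n_samples = nrow(spectra$intensities),
    n_herds = length(unique(metadata$herd)),
    n_shifts_input = length(spectra$ppm),
    n_shifts_retained = length(pp$ppm),
    cohort_all_row = as.list(summary_tab[summary_tab$herd == "ALL", ]),
    n_outliers_flagged = sum(outliers$flagged),
    pca_explained = expl,
    mean_r2 = if (config$correct)
      lapply(corrections, function(cr) mean(cr$r2)) else NULL,
    score_correlations = lapply(score_cors %||% list(), function(m)
      as.data.frame(m)),
    wald_f = wald, asca = asca_tab, opls = opls_tab,
    logo = logo)
  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = 10,
                           dataframe = "rows", na = "null", pretty = TRUE)
  writeLines(json, file.path(out_dir, "summary.json"))

  invisible(list(spectra = spectra, metadata = metadata, truth = truth,
                 preprocessed = pp, corrections = corrections,
                 corrected_bhba = corrected_bhba, pcas = pcas,
                 score_correlations = score_cors, wald = wald,
                 asca = asca_tab, opls = opls_tab, opls_models = opls_models,
                 logo = logo, summary = summary, out_dir = out_dir))
}
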