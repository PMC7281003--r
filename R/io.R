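# Delimited-text I/O for spectra and metadata, with provenance headers.
# Formats: spectra are tab-delimited with the ppm axis as the first row
# (column names) and sample ids as the first column; metadata is a
# tab-delimited table with columns sample_id, herd, parity, dim, wim, bhba.
# Lines starting with '#' are provenance comments and are skipped on read.

count_header_lines <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  k <- 0L
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0 || !startsWith(ln, "#")) break
    k <- k + 1L
  }
  k
}

write_provenance <- function(path, provenance) {
  lines <- character(0)
  if (length(provenance))
    lines <- paste0("# ", names(provenance), ": ",
                    vapply(provenance, function(x)
                      paste(format(x), collapse = " "), ""))
  writeLines(lines, path)
  lines
}

#' Write a spectrum matrix as delimited text
#'
#' @param sm a [spectrum_matrix()].
#' @param path output file.
#' @param provenance optional named list written as leading `#` comment
#'   lines.
#' @return invisibly, `path`.
#' @export
write_spectra <- function(sm, path, provenance = NULL) {
  stopifnot(inherits(sm, "spectrum_matrix"))
  write_provenance(path, provenance)
  df <- data.table::as.data.table(sm$intensities)
  data.table::setnames(df, sprintf("%.15g", sm$ppm))
  df <- cbind(data.table::data.table(sample_id = sm$sample_ids), df)
  data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a spectrum matrix from delimited text
#'
#' Rejects ragged rows, duplicate sample ids and non-numeric cells, naming
#' the offending file lines.
#'
#' @param path file written by [write_spectra()].
#' @return a [spectrum_matrix()].
#' @export
read_spectra <- function(path) {
  skip <- count_header_lines(path)
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", skip = skip, header = TRUE,
                      fill = FALSE, check.names = FALSE),
    error = function(e) stopf("malformed spectra file '%s': %s", path,
                              conditionMessage(e)))
  if (names(dt)[1] != "sample_id")
    stopf("first column must be 'sample_id'")
  ids <- as.character(dt[[1]])
  ppm <- suppressWarnings(as.numeric(names(dt)[-1]))
  if (anyNA(ppm)) stopf("non-numeric ppm axis in header row")
  vals <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(apply(vals, 1, function(r)
      anyNA(suppressWarnings(as.numeric(r)))))
    stopf("non-numeric intensities at data line(s): %s",
          paste(bad + skip + 1L, collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    bad <- which(duplicated(ids))
    stopf("duplicate sample id(s) at data line(s): %s",
          paste(bad + skip + 1L, collapse = ", "))
  }
  spectrum_matrix(vals, ppm, ids)
}

#' Write cohort metadata as delimited text
#'
#' @param metadata data.frame with columns sample_id, herd, parity, dim,
#'   wim, bhba.
#' @param path output file.
#' @param provenance optional named list written as `#` comment lines.
#' @return invisibly, `path`.
#' @export
write_metadata <- function(metadata, path, provenance = NULL) {
  need <- c("sample_id", "herd", "parity", "dim", "wim", "bhba")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stopf("metadata lacks column(s): %s",
                          paste(miss, collapse = ", "))
  write_provenance(path, provenance)
  data.table::fwrite(metadata[, need], path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' Read cohort metadata from delimited text
#'
#' Parity labels are folded onto the declared level set `1, 2, 3, 4+`:
#' numeric parities of 4 or more become `"4+"` (with a warning for values
#' above 4). Unknown non-numeric labels are rejected.
#'
#' @param path file written by [write_metadata()].
#' @return metadata data.frame.
#' @export
read_metadata <- function(path) {
  skip <- count_header_lines(path)
  md <- as.data.frame(data.table::fread(path, sep = "\t", skip = skip,
                                        header = TRUE, fill = FALSE,
                                        colClasses = list(
                                          character = c("sample_id", "herd",
                                                        "parity"))))
  need <- c("sample_id", "herd", "parity", "dim", "wim", "bhba")
  miss <- setdiff(need, names(md))
  if (length(miss)) stopf("metadata lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stopf("duplicate sample ids in metadata")
  pr <- as.character(md$parity)
  num <- suppressWarnings(as.numeric(pr))
  fold <- !is.na(num) & num >= 4 & pr != "4+"
  if (any(fold)) {
    if (any(num[fold] > 4))
      warnf("parity level(s) %s folded into '4+'",
            paste(unique(pr[fold & num > 4]), collapse = ", "))
    pr[fold] <- "4+"
  }
  unknown <- !(pr %in% c("1", "2", "3", "4+"))
  if (any(unknown))
    stopf("unknown parity level(s): %s",
          paste(unique(pr[unknown]), collapse = ", "))
  md$parity <- pr
  md
}

#' Check that spectra and metadata describe the same samples
#'
#' @param sm a [spectrum_matrix()].
#' @param metadata metadata data.frame.
#' @return invisibly `TRUE`; errors listing offending sample ids otherwise.
#' @export
check_cohort <- function(sm, metadata) {
  a <- sm$sample_ids; b <- metadata$sample_id
  extra_s <- setdiff(a, b); extra_m <- setdiff(b, a)
  if (length(extra_s) || length(extra_m))
    stopf("sample sets differ; only in spectra: [%s]; only in metadata: [%s]",
          paste(extra_s, collapse = ", "), paste(extra_m, collapse = ", "))
  if (!identical(a, b))
    stopf("sample order differs between spectra and metadata")
  invisible(TRUE)
}
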