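#' Read and write spectrum sets as plain text
#'
#' Spectra are stored as a TSV whose first column is the ppm axis
#' (descending) and remaining columns one sample each, plus a metadata CSV
#' (`sample_id`, `sex`, `temperature_C`, `replicate`) and an optional JSON
#' sidecar echoing seeds and parameters.
#'
#' @param set A `spectrum_set`.
#' @param path Base path without extension; writes `<path>.tsv`,
#'   `<path>_meta.csv` and (if `sidecar` is given) `<path>.json`.
#' @param sidecar Optional named list of parameters/seeds to echo.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path, sidecar = NULL) {
  tsv <- tibble::tibble(ppm = set$ppm)
  for (i in seq_len(n_spectra(set)))
    tsv[[set$meta$sample_id[i]]] <- set$intensities[i, ]
  readr::write_tsv(tsv, paste0(path, ".tsv"))
  meta <- set$meta
  names(meta)[names(meta) == "temperature"] <- "temperature_C"
  readr::write_csv(meta, paste0(path, "_meta.csv"))
  if (!is.null(sidecar))
    jsonlite::write_json(c(sidecar, list(processing_log = set$log)),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  tsv <- readr::read_tsv(paste0(path, ".tsv"),
                         col_types = readr::cols(.default = readr::col_double()))
  meta <- readr::read_csv(paste0(path, "_meta.csv"),
                          col_types = readr::cols())
  names(meta)[names(meta) == "temperature_C"] <- "temperature"
  log <- character()
  jf <- paste0(path, ".json")
  if (file.exists(jf)) {
    side <- jsonlite::read_json(jf, simplifyVector = TRUE)
    log <- side$processing_log %||% character()
  }
  vals <- t(as.matrix(tsv[, -1, drop = FALSE]))
  new_spectrum_set(tsv$ppm, vals, meta[match(rownames(vals), meta$sample_id), ],
                   log = log)
}
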