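#' Spectrum and spectrum-set containers
#'
#' A `spectrum` holds one processed 1D 1H spectrum: a strictly monotone ppm
#' axis (stored descending, NMR convention), non-negative intensities and
#' sample metadata. A `spectrum_set` holds many spectra on one common grid
#' as a samples x points matrix together with a metadata tibble and an
#' append-only processing log.
#'
#' @param ppm Numeric ppm axis, strictly monotone.
#' @param intensity Numeric intensities, same length as `ppm`.
#' @param meta Named list or one-row tibble with at least `sample_id`.
#' @return A `spectrum` object.
#' @export
new_spectrum <- function(ppm, intensity, meta = list(sample_id = "s1")) {
  if (length(ppm) != length(intensity))
    abort("`ppm` and `intensity` must have equal length")
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) abort("`ppm` must be strictly monotone")
  if (anyNA(intensity)) abort("`intensity` must not contain missing values")
  if (all(d > 0)) { ppm <- rev(ppm); intensity <- rev(intensity) }
  structure(list(ppm = as.numeric(ppm), intensity = as.numeric(intensity),
                 meta = tibble::as_tibble(meta)),
            class = "spectrum")
}

#' @param intensities Numeric matrix, one row per sample, columns matching
#'   `ppm`.
#' @param log Character vector of processing steps already applied.
#' @rdname new_spectrum
#' @export
new_spectrum_set <- function(ppm, intensities, meta, log = character()) {
  if (!is.matrix(intensities)) intensities <- rbind(intensities)
  if (ncol(intensities) != length(ppm))
    abort("`intensities` columns must match the ppm axis")
  meta <- tibble::as_tibble(meta)
  if (nrow(meta) != nrow(intensities))
    abort("`meta` must have one row per spectrum")
  if (anyDuplicated(meta$sample_id))
    abort("duplicate sample_id in `meta`")
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) abort("`ppm` must be strictly monotone")
  if (all(d > 0)) {
    ppm <- rev(ppm)
    intensities <- intensities[, rev(seq_along(ppm)), drop = FALSE]
  }
  rownames(intensities) <- meta$sample_id
  structure(list(ppm = as.numeric(ppm), intensities = intensities,
                 meta = meta, log = log),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set> ", nrow(x$intensities), " spectra x ",
      length(x$ppm), " points, ppm ", max(x$ppm), " to ", min(x$ppm), "\n",
      sep = "")
  cat("  processing log:",
      if (length(x$log)) paste(x$log, collapse = " -> ") else "(raw)", "\n")
  invisible(x)
}

n_spectra <- function(set) nrow(set$intensities)

log_step <- function(set, step) {
  set$log <- c(set$log, step)
  set
}

step_applied <- function(set, step) any(startsWith(set$log, step))

require_step_absent <- function(set, step) {
  if (step_applied(set, step))
    abort(paste0("step '", step, "' has already been applied; ",
                 "re-running a pipeline step is not allowed"))
}

# Extract one spectrum from a set.
get_spectrum <- function(set, i) {
  new_spectrum(set$ppm, set$intensities[i, ], set$meta[i, ])
}

#' @export
as_tibble.spectrum_set <- function(x, ...) {
  long <- tidyr::expand_grid(sample_id = x$meta$sample_id, ppm = x$ppm)
  long$intensity <- as.vector(t(x$intensities))
  dplyr::left_join(long, x$meta, by = "sample_id")
}

#' Feature matrix with preprocessing provenance
#'
#' The samples x ppm-bin matrix consumed by the multivariate analyses,
#' carrying its metadata, whether rows were total-intensity normalized, and
#' which scaling (`"none"`, `"pareto_centered"`, `"pareto_uncentered"`) has
#' been applied.
#'
#' @param values Numeric matrix, samples x bins.
#' @param ppm Numeric bin labels (ppm, descending).
#' @param meta Metadata tibble, one row per sample.
#' @param normalized Logical flag: rows of the pre-scaling matrix sum to 1.
#' @param scaling Scaling descriptor.
#' @param log Processing log inherited from the spectrum set.
#' @return A `feature_matrix` object.
#' @export
new_feature_matrix <- function(values, ppm, meta, normalized = FALSE,
                               scaling = "none", log = character()) {
  if (!is.matrix(values)) abort("`values` must be a matrix")
  if (ncol(values) != length(ppm)) abort("bin labels must match columns")
  meta <- tibble::as_tibble(meta)
  if (nrow(meta) != nrow(values)) abort("one metadata row per sample required")
  if (anyDuplicated(meta$sample_id)) abort("duplicate sample ids")
  if (anyDuplicated(ppm)) abort("duplicate bin labels")
  rownames(values) <- meta$sample_id
  colnames(values) <- format(ppm, trim = TRUE)
  structure(list(values = values, ppm = as.numeric(ppm), meta = meta,
                 normalized = isTRUE(normalized), scaling = scaling,
                 log = log),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " samples x ", ncol(x$values),
      " bins; normalized = ", x$normalized, ", scaling = ", x$scaling, "\n",
      sep = "")
  invisible(x)
}

#' @export
as_tibble.feature_matrix <- function(x, ...) {
  dplyr::bind_cols(x$meta, tibble::as_tibble(x$values, .name_repair = "minimal"))
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
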