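#' Integrate metabolite signals from spectra
#'
#' Quantifies each defined metabolite in every sample as the summed
#' intensity over the grid points whose ppm lies in the closed integration
#' range. Works on a normalized `spectrum_set` or on a `feature_matrix`
#' at full resolution (e.g. the sex-difference matrix).
#'
#' @param x A `spectrum_set` (aligned and normalized) or `feature_matrix`.
#' @param defs Metabolite definitions ([load_metabolite_definitions()]).
#' @return A tibble: the sample metadata columns followed by one column of
#'   integrated intensity per metabolite.
#' @export
integrate_metabolites <- function(x, defs) {
  if (inherits(x, "spectrum_set")) {
    ppm <- x$ppm; vals <- x$intensities; meta <- x$meta
  } else if (inherits(x, "feature_matrix")) {
    ppm <- x$ppm; vals <- x$values; meta <- x$meta
  } else abort("`x` must be a spectrum_set or feature_matrix")
  out <- meta
  for (j in seq_len(nrow(defs))) {
    idx <- which(ppm >= defs$range_low[j] & ppm <= defs$range_high[j])
    if (length(idx) == 0)
      abort(paste0("integration range of '", defs$name[j],
                   "' lies entirely outside the retained ppm window"))
    out[[defs$name[j]]] <- rowSums(vals[, idx, drop = FALSE])
  }
  out
}

# Summed intensity in a +/- half_width window around one chemical shift;
# used to verify correlations at a metabolite's other characteristic
# shifts. Returns NULL when the window has no retained grid points.
shift_window_intensity <- function(x, shift, half_width = 0.005) {
  ppm <- if (inherits(x, "spectrum_set")) x$ppm else x$ppm
  vals <- if (inherits(x, "spectrum_set")) x$intensities else x$values
  idx <- which(ppm >= shift - half_width & ppm <= shift + half_width)
  if (length(idx) == 0) return(NULL)
  rowSums(vals[, idx, drop = FALSE])
}
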