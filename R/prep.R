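# Spectral preprocessing: TSP referencing, alignment, trimming,
# total-intensity normalization, binning and Pareto scaling — in the fixed
# pipeline order reference -> align -> trim -> normalize -> (scale).

#' Reference a spectrum to the TSP line
#'
#' Shifts the spectrum by an integer number of grid points so that the
#' maximum within the TSP search window sits at the grid point nearest the
#' target shift (-0.017 ppm by default). Vacated points are filled with the
#' edge value.
#'
#' @param s A `spectrum`.
#' @param tsp_target Target ppm of the TSP line.
#' @param window ppm window searched for the TSP maximum.
#' @param prominence Minimum excess of the window maximum over the window
#'   median required to accept a peak.
#' @return The referenced `spectrum`.
#' @export
reference_to_tsp <- function(s, tsp_target = -0.017,
                             window = c(-0.25, 0.25), prominence = 0) {
  idx <- which(s$ppm >= min(window) & s$ppm <= max(window))
  if (length(idx) == 0) abort("spectrum does not cover the TSP window")
  w <- s$intensity[idx]
  if (max(w) - stats::median(w) <= prominence)
    abort("no TSP peak above the prominence threshold in the search window")
  at <- idx[which.max(w)]
  target <- which.min(abs(s$ppm - tsp_target))
  s$intensity <- shift_fill(s$intensity, target - at)
  s
}

#' @rdname reference_to_tsp
#' @param set A `spectrum_set`.
#' @export
reference_set <- function(set, tsp_target = -0.017,
                          window = c(-0.25, 0.25), prominence = 0) {
  require_step_absent(set, "reference")
  for (i in seq_len(n_spectra(set))) {
    s <- reference_to_tsp(get_spectrum(set, i), tsp_target, window, prominence)
    set$intensities[i, ] <- s$intensity
  }
  log_step(set, sprintf("reference(tsp=%g)", tsp_target))
}

# Best integer lag (|lag| <= max_lag) maximizing the cross-correlation of
# x against ref; ties broken toward the smallest |lag|.
best_lag <- function(x, ref, max_lag) {
  lags <- seq.int(-max_lag, max_lag)
  cc <- vapply(lags, function(l) sum(ref * shift_fill(x, l)), numeric(1))
  lags[order(-cc, abs(lags))][1]
}

#' Align a spectrum set by segment-wise cross-correlation
#'
#' Interval-based correlation-optimized shifting: within each ppm segment,
#' every spectrum is shifted by the integer number of grid points (capped
#' at `max_shift`) that maximizes its cross-correlation with the set's
#' pointwise median spectrum; vacated points take the segment-edge value.
#' By default the procedure runs twice, recomputing the median reference
#' after the first pass.
#'
#' @param set A `spectrum_set` (referenced).
#' @param segments List of ppm intervals `c(low, high)`; default one
#'   whole-axis segment.
#' @param max_shift Maximum allowed shift in ppm.
#' @param passes Number of align-to-median passes.
#' @return The aligned `spectrum_set`.
#' @export
align_set <- function(set, segments = NULL, max_shift = 0.01, passes = 2) {
  require_step_absent(set, "align")
  step <- stats::median(abs(diff(set$ppm)))
  max_lag <- max(1L, round(max_shift / step))
  if (is.null(segments)) segments <- list(range(set$ppm))
  seg_idx <- lapply(segments, function(sg) {
    idx <- which(set$ppm >= min(sg) & set$ppm <= max(sg))
    if (length(idx) < 2 * max_lag)
      abort("segment narrower than twice the maximum shift")
    idx
  })
  capped <- FALSE
  for (pass in seq_len(passes)) {
    ref <- apply(set$intensities, 2, stats::median)
    for (idx in seg_idx) {
      for (i in seq_len(n_spectra(set))) {
        x <- set$intensities[i, idx]
        lag <- best_lag(x, ref[idx], max_lag)
        if (abs(lag) == max_lag && max_lag > 0) capped <- TRUE
        set$intensities[i, idx] <- shift_fill(x, lag)
      }
    }
  }
  if (capped)
    warn("alignment shift(s) hit the max_shift cap; residual misalignment may remain")
  log_step(set, sprintf("align(max_shift=%g, segments=%d, passes=%d)",
                        max_shift, length(seg_idx), passes))
}

#' Trim the water region and spectral edges
#'
#' Removes grid points whose ppm lies in the closed water interval
#' (4.67-4.85 ppm by default) and points outside the closed analysis
#' window (0.5-9.5 ppm by default), preserving axis order.
#'
#' @param s A `spectrum`.
#' @param water Closed ppm interval removed around the residual water line.
#' @param keep Closed ppm window retained.
#' @return The trimmed `spectrum`.
#' @export
trim_spectrum <- function(s, water = c(4.67, 4.85), keep = c(0.5, 9.5)) {
  keep_idx <- trim_index(s$ppm, water, keep)
  s$ppm <- s$ppm[keep_idx]
  s$intensity <- s$intensity[keep_idx]
  s
}

trim_index <- function(ppm, water, keep) {
  idx <- which(!(ppm >= min(water) & ppm <= max(water)) &
                 ppm >= min(keep) & ppm <= max(keep))
  if (length(idx) == 0) abort("trimming removed every grid point")
  idx
}

#' @rdname trim_spectrum
#' @param set A `spectrum_set`.
#' @export
trim_set <- function(set, water = c(4.67, 4.85), keep = c(0.5, 9.5)) {
  require_step_absent(set, "trim")
  idx <- trim_index(set$ppm, water, keep)
  set$ppm <- set$ppm[idx]
  set$intensities <- set$intensities[, idx, drop = FALSE]
  log_step(set, sprintf("trim(water=[%g,%g], keep=[%g,%g])",
                        min(water), max(water), min(keep), max(keep)))
}

#' Normalize each spectrum to unit total intensity
#'
#' Divides every spectrum by its own summed intensity so each row sums to
#' one, suppressing separation driven by the amount of sample.
#'
#' @param set A `spectrum_set` with positive totals.
#' @return The normalized `spectrum_set`.
#' @export
normalize_total <- function(set) {
  require_step_absent(set, "normalize")
  totals <- rowSums(set$intensities)
  if (any(totals <= 0)) abort("non-positive total intensity; cannot normalize")
  set$intensities <- set$intensities / totals
  log_step(set, "normalize(total)")
}

#' Convert a spectrum set to a feature matrix
#'
#' Columns are the grid points themselves (`bin_width = NULL`) or means
#' over half-open ppm bins; a bin covers `(high - w, high]` so a boundary
#' point belongs to the higher-ppm bin only. Sample metadata is carried
#' onto the rows.
#'
#' @param set An aligned, trimmed `spectrum_set`.
#' @param bin_width Bin width in ppm, or `NULL` for full resolution.
#' @return A [new_feature_matrix()] object.
#' @export
to_feature_matrix <- function(set, bin_width = NULL) {
  normalized <- step_applied(set, "normalize")
  if (is.null(bin_width)) {
    return(new_feature_matrix(set$intensities, set$ppm, set$meta,
                              normalized = normalized, log = set$log))
  }
  step <- stats::median(abs(diff(set$ppm)))
  if (bin_width < step) abort("`bin_width` smaller than the grid step")
  hi <- max(set$ppm)
  # bin index 1 covers (hi - w, hi]; boundary points go to the higher bin
  bin <- ceiling(round((hi - set$ppm) / bin_width, 9))
  bin[bin == 0] <- 1L
  centers <- hi - (unique(sort(bin)) - 0.5) * bin_width
  groups <- split(seq_along(set$ppm), bin)
  vals <- vapply(groups, function(ix)
    rowMeans(set$intensities[, ix, drop = FALSE]),
    numeric(n_spectra(set)))
  if (n_spectra(set) == 1L) vals <- rbind(vals)
  new_feature_matrix(vals, centers, set$meta, normalized = normalized,
                     log = c(set$log, sprintf("bin(width=%g)", bin_width)))
}

#' Pareto scale a feature matrix
#'
#' Divides each column by the square root of its sample standard deviation
#' (n - 1 denominator), after subtracting the column mean when `centered`.
#' Zero-variance columns become all zeros (centered) or are left unscaled
#' with a warning (uncentered).
#'
#' @param m A `feature_matrix` with at least two rows.
#' @param centered Subtract column means first?
#' @return The scaled `feature_matrix` with its `scaling` flag updated.
#' @export
pareto_scale <- function(m, centered = TRUE) {
  if (!inherits(m, "feature_matrix")) abort("`m` must be a feature_matrix")
  if (m$scaling != "none") abort("matrix is already scaled")
  if (nrow(m$values) < 2) abort("Pareto scaling needs >= 2 rows")
  x <- m$values
  mu <- colMeans(x)
  sds <- col_sds(x)
  zero <- sds == 0 | !is.finite(sds)
  if (centered) {
    x <- sweep(x, 2, mu)
    div <- sqrt(sds)
    div[zero] <- 1  # centered zero-SD columns are already all zero
    x <- sweep(x, 2, div, "/")
  } else {
    if (any(zero))
      warn(sprintf("%d zero-variance column(s) left unscaled", sum(zero)))
    div <- sqrt(sds)
    div[zero] <- 1
    x <- sweep(x, 2, div, "/")
  }
  m$values <- x
  m$scaling <- if (centered) "pareto_centered" else "pareto_uncentered"
  m$log <- c(m$log, sprintf("pareto_scale(centered=%s)", centered))
  m
}

# Pareto-scaling parameters estimated on a training matrix and applied to
# another matrix (used inside cross-validation folds to avoid leakage).
pareto_params <- function(x, centered = TRUE) {
  sds <- col_sds(x)
  div <- sqrt(sds)
  div[sds == 0 | !is.finite(div) | div == 0] <- 1
  list(center = if (centered) colMeans(x) else rep(0, ncol(x)), div = div)
}

pareto_apply <- function(x, p) sweep(sweep(x, 2, p$center), 2, p$div, "/")
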