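#' Simulation design for the developmental-temperature experiment
#'
#' A `simulation_design` records the experimental layout that the synthetic
#' data generator emulates: the developmental temperatures, the two sexes,
#' the number of pooled-fly NMR replicates per sex-by-temperature cell, the
#' vial layout for the viability/developmental-time assays, and the ppm grid
#' on which spectra are simulated.
#'
#' @param temperatures Strictly increasing developmental temperatures in
#'   degrees C, all within \[12, 32\].
#' @param sexes Character vector of sex labels (default `"female"`, `"male"`).
#' @param replicates_per_cell Pooled-sample spectra per sex x temperature
#'   cell (>= 2).
#' @param vials_per_temperature Egg vials set up at each temperature.
#' @param eggs_per_vial Eggs deposited per vial (>= 1).
#' @param flies_assayed_per_cell Individuals per sex per temperature scored
#'   in each thermal-limit assay.
#' @param ppm_grid Named numeric `c(min, max, step)`; must cover
#'   \[-0.1, 9.6\] ppm so both the TSP reference region and the analysis
#'   window exist.
#'
#' @return A `simulation_design` object (a named list).
#' @export
simulation_design <- function(temperatures,
                              sexes = c("female", "male"),
                              replicates_per_cell = 5L,
                              vials_per_temperature = 20L,
                              eggs_per_vial = 40L,
                              flies_assayed_per_cell = 20L,
                              ppm_grid = c(min = -0.1, max = 9.6, step = 0.001)) {
  if (length(temperatures) < 1L || any(diff(temperatures) <= 0))
    abort("`temperatures` must be strictly increasing")
  if (any(temperatures < 12 | temperatures > 32))
    abort("`temperatures` must lie within [12, 32] degrees C")
  if (replicates_per_cell < 2L) abort("`replicates_per_cell` must be >= 2")
  if (eggs_per_vial < 1L) abort("`eggs_per_vial` must be >= 1")
  ppm_grid <- c(min = unname(ppm_grid[["min"]]), max = unname(ppm_grid[["max"]]),
                step = unname(ppm_grid[["step"]]))
  if (ppm_grid[["min"]] > -0.1 || ppm_grid[["max"]] < 9.6)
    abort("`ppm_grid` must cover [-0.1, 9.6] ppm")
  if (ppm_grid[["step"]] <= 0) abort("`ppm_grid` step must be positive")
  structure(
    list(temperatures = as.numeric(temperatures),
         sexes = as.character(sexes),
         replicates_per_cell = as.integer(replicates_per_cell),
         vials_per_temperature = as.integer(vials_per_temperature),
         eggs_per_vial = as.integer(eggs_per_vial),
         flies_assayed_per_cell = as.integer(flies_assayed_per_cell),
         ppm_grid = ppm_grid),
    class = "simulation_design")
}

#' Default study design
#'
#' The layout of the original experiment: ten developmental temperatures
#' (12, 15.5, 18, 20, 22, 25, 27, 29.5, 31, 32 degrees C), two sexes, five
#' replicate pools of 40 flies per cell (100 spectra), 20 vials of exactly
#' 40 eggs per temperature, and 20 flies per sex per temperature in each
#' thermal-tolerance assay.
#'
#' @return A [simulation_design()] object.
#' @export
#' @examples
#' d <- default_design()
#' d$temperatures
default_design <- function() {
  simulation_design(
    temperatures = c(12, 15.5, 18, 20, 22, 25, 27, 29.5, 31, 32))
}

# Descending ppm axis (NMR convention) for a design's grid.
design_ppm <- function(design) {
  g <- design$ppm_grid
  rev(seq(g[["min"]], g[["max"]], by = g[["step"]]))
}

#' @export
print.simulation_design <- function(x, ...) {
  cat("<simulation_design>\n")
  cat("  temperatures:", paste(x$temperatures, collapse = ", "), "degC\n")
  cat("  sexes:", paste(x$sexes, collapse = ", "), "\n")
  cat("  replicates per cell:", x$replicates_per_cell,
      "-> spectra:", length(x$temperatures) * length(x$sexes) *
        x$replicates_per_cell, "\n")
  cat("  vials per temperature:", x$vials_per_temperature,
      "x", x$eggs_per_vial, "eggs\n")
  cat("  ppm grid:", x$ppm_grid[["min"]], "to", x$ppm_grid[["max"]],
      "step", x$ppm_grid[["step"]], "\n")
  invisible(x)
}

# The two-state temperature encoding used by the U-shape prior: the two
# lowest (12, 15.5 degC) and two highest (31, 32 degC) rearing temperatures
# are "extreme" (1), 18-29.5 degC is "intermediate" (0).

#' Binary extreme/intermediate encoding of developmental temperature
#'
#' Encodes each temperature as 1 for the extremes of the design
#' (12, 15.5, 31 and 32 degrees C) and 0 for the intermediate range
#' (18 to 29.5 degrees C). Temperatures outside the design's ten values
#' raise an error; the encoding is categorical, never interpolated.
#'
#' @param temperatures Numeric vector of developmental temperatures.
#' @return Integer vector of 0/1 codes.
#' @export
#' @examples
#' ushape_prior_encoding(c(12, 20, 32))
ushape_prior_encoding <- function(temperatures) {
  extreme <- c(12, 15.5, 31, 32)
  intermediate <- c(18, 20, 22, 25, 27, 29.5)
  bad <- setdiff(unique(temperatures), c(extreme, intermediate))
  if (length(bad) > 0)
    abort(paste0("temperature(s) not in the design: ",
                 paste(bad, collapse = ", ")))
  as.integer(temperatures %in% extreme)
}
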