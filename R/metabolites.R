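#' Load metabolite definitions (characteristic shifts and integration ranges)
#'
#' Reads the bundled assignment table of 30 Drosophila metabolites — each
#' with its characteristic 1H chemical shifts and the narrow ppm range whose
#' summed intensity quantifies it — or a user CSV in the same dialect
#' (columns `name`, `shifts` semicolon-separated, `range_high`, `range_low`).
#'
#' @param source Path to a CSV, or `NULL` for the bundled table.
#' @return A tibble with columns `name`, `shifts` (list column of numeric
#'   vectors), `range_high`, `range_low`.
#' @export
#' @examples
#' defs <- load_metabolite_definitions()
#' defs[defs$name == "Glucose", ]
load_metabolite_definitions <- function(source = NULL) {
  bundled <- is.null(source)
  if (bundled)
    source <- system.file("extdata", "metabolite_definitions.csv",
                          package = "thermometab", mustWork = TRUE)
  raw <- readr::read_csv(source, col_types = readr::cols(
    name = readr::col_character(), shifts = readr::col_character(),
    range_high = readr::col_double(), range_low = readr::col_double()))
  if (anyDuplicated(raw$name))
    abort("duplicate metabolite name in definitions")
  bad <- raw$range_high <= raw$range_low
  if (any(bad))
    abort(paste0("inverted integration range for: ",
                 paste(raw$name[bad], collapse = ", ")))
  defs <- tibble::tibble(
    name = raw$name,
    shifts = lapply(strsplit(raw$shifts, ";", fixed = TRUE), as.numeric),
    range_high = raw$range_high,
    range_low = raw$range_low)
  no_overlap <- !mapply(function(sh, hi, lo)
    any(sh >= lo - 0.05 & sh <= hi + 0.05), defs$shifts,
    defs$range_high, defs$range_low)
  # the bundled table knowingly carries one such row (beta-alanine is
  # integrated at its 2.54 ppm signal, which its shift list omits)
  if (any(no_overlap) && !bundled)
    warn(paste0("integration range far from every listed shift for: ",
                paste(defs$name[no_overlap], collapse = ", ")))
  defs
}

norm_classes <- c("linear_up", "linear_down", "ushape_up", "ushape_down",
                  "sex_dimorphic", "null")

#' Planted reaction-norm truths for the default simulation
#'
#' Assigns each of the 30 assigned metabolites a reaction-norm class and
#' effect parameters used as simulation ground truth: 10 linear (5 rising,
#' 5 falling with temperature), 5 inverted-U (depressed at the extreme
#' temperatures), 5 sex-dimorphic (constant female-male offset) and 10 null.
#' The linear classes are balanced up/down so the assigned metabolite pool
#' is approximately conserved; the remaining imbalance is absorbed by the
#' unassigned spectral background during simulation (see
#' [simulate_spectra()]).
#'
#' @param defs Metabolite definitions, as from
#'   [load_metabolite_definitions()].
#' @param effect_size Absolute fractional effect over the temperature range
#'   (linear) or at the extremes (U-shape).
#' @param sex_delta Fractional female-minus-male offset for the dimorphic
#'   class.
#' @return Tibble of metabolite truths: definitions plus `norm_class`,
#'   `baseline`, `effect_size` (signed), `sex_effect` (list column) and
#'   `peak_width` (FWHM, ppm).
#' @export
default_metabolite_truths <- function(defs = load_metabolite_definitions(),
                                      effect_size = 0.6,
                                      sex_delta = 0.5) {
  # class assignment respects spectral adjacency: metabolites whose
  # integration windows receive Lorentzian tail leakage from a neighbour
  # (the leucine/isoleucine/valine cluster, leucine's 1.73 line inside the
  # arginine window, maltose beside glucose) share that neighbour's
  # temperature class or a temperature-neutral one, so planted "null"
  # labels stay null on the observed scale
  class_map <- c(
    "Proline" = "linear_down", "Leucine" = "linear_down",
    "Isoleucine" = "linear_down", "Valine" = "linear_down",
    "Arginine" = "linear_down",
    "Phosphocholine" = "linear_up", "Acetate" = "linear_up",
    "Maltose" = "linear_up", "Glucose" = "linear_up",
    "Glutamine" = "linear_up",
    "NAD+" = "ushape_down", "NADP+" = "ushape_down", "AMP" = "ushape_down",
    "Mannose" = "ushape_down", "beta-Alanine" = "ushape_down",
    "Galactoside" = "sex_dimorphic", "Alanine" = "sex_dimorphic",
    "Lactate" = "sex_dimorphic", "Glutamate" = "sex_dimorphic",
    "Aspartate" = "sex_dimorphic")
  cls <- unname(class_map[defs$name])
  cls[is.na(cls)] <- "null"
  eff <- dplyr::case_when(
    cls == "linear_up" ~ effect_size,
    cls == "linear_down" ~ -effect_size,
    cls == "ushape_up" ~ effect_size,
    cls == "ushape_down" ~ -effect_size,
    TRUE ~ 0)
  sexfx <- lapply(cls, function(cl) {
    if (cl == "sex_dimorphic") list(type = "constant", delta = sex_delta)
    else list(type = "none", delta = 0)
  })
  out <- defs
  # every simulated metabolite must resonate inside its own integration
  # range; where the printed shift list does not cover the range (the
  # beta-alanine row), a line at the range midpoint is added for simulation
  out$shifts <- purrr::pmap(out[c("shifts", "range_high", "range_low")],
                            function(shifts, range_high, range_low) {
                              if (!any(shifts >= range_low - 0.005 &
                                         shifts <= range_high + 0.005))
                                shifts <- c(shifts, (range_high + range_low) / 2)
                              shifts
                            })
  out$norm_class <- cls
  out$baseline <- 1
  out$effect_size <- eff
  out$sex_effect <- sexfx
  out$peak_width <- 0.002
  validate_truths(out)
  out
}

validate_truths <- function(truths) {
  if (nrow(truths) == 0) abort("`truths` must be non-empty")
  if (anyDuplicated(truths$name))
    abort("overlapping definition of the same metabolite name")
  if (!all(truths$norm_class %in% norm_classes))
    abort(paste0("unknown norm_class: ",
                 paste(setdiff(truths$norm_class, norm_classes),
                       collapse = ", ")))
  if (any(truths$baseline <= 0)) abort("baselines must be > 0")
  if (any(!is.finite(truths$effect_size))) abort("effect sizes must be finite")
  down <- truths$norm_class %in% c("linear_down", "ushape_down")
  up <- truths$norm_class %in% c("linear_up", "ushape_up")
  if (any(truths$effect_size[down] > 0) || any(truths$effect_size[up] < 0))
    abort("effect_size sign must match the *_up / *_down class")
  invisible(truths)
}

#' Expected correlation signs for planted metabolites
#'
#' The recovery-test oracle: for each simulated metabolite, the sign its
#' integrated intensity is expected to show against the linear and U-shape
#' temperature targets (components oriented to increase with temperature
#' and with the extreme encoding, respectively), and against the
#' female-minus-male sex-difference score.
#'
#' @param truths Metabolite truths, as from [default_metabolite_truths()].
#' @return Tibble with columns `name`, `norm_class`, `expected_linear`,
#'   `expected_ushape`, `expected_sexdiff`, each in `"-"`, `"0"`, `"+"`.
#' @export
truth_table <- function(truths) {
  validate_truths(truths)
  sgn <- function(x) c("-", "0", "+")[sign(x) + 2]
  lin <- ifelse(startsWith(truths$norm_class, "linear"),
                sgn(truths$effect_size), "0")
  ush <- ifelse(startsWith(truths$norm_class, "ushape"),
                sgn(truths$effect_size), "0")
  sx <- vapply(truths$sex_effect, function(s)
    if (s$type == "none" || s$delta == 0) "0" else sgn(s$delta), character(1))
  tibble::tibble(name = truths$name, norm_class = truths$norm_class,
                 expected_linear = lin, expected_ushape = ush,
                 expected_sexdiff = sx)
}
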