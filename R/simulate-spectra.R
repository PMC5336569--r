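#' Nuisance (noise) settings for spectrum simulation
#'
#' Describes the non-biological variation planted in raw spectra: additive
#' baseline noise, a per-sample dilution factor (removed later by
#' total-intensity normalization) and a per-sample global chemical-shift
#' jitter (removed later by TSP referencing and alignment).
#'
#' @param baseline_noise_sd SD of additive Gaussian noise per grid point,
#'   in intensity units (a unit-area peak of default width has height
#'   ~318, so the default gives strong lines a point SNR of ~160). The
#'   default noise floor is set above the Lorentzian tail leakage between
#'   neighbouring assignment windows, so planted null metabolites stay
#'   null on the observed scale.
#' @param dilution_sdlog sdlog of the log-normal per-sample dilution factor
#'   (median 1).
#' @param jitter_ppm Half-width of the uniform per-sample global ppm jitter.
#' @return A `nuisance_control` list.
#' @export
nuisance_control <- function(baseline_noise_sd = 2,
                             dilution_sdlog = 0.15,
                             jitter_ppm = 0.005) {
  if (baseline_noise_sd < 0 || dilution_sdlog < 0 || jitter_ppm < 0)
    abort("nuisance magnitudes must be non-negative")
  structure(list(baseline_noise_sd = baseline_noise_sd,
                 dilution_sdlog = dilution_sdlog,
                 jitter_ppm = jitter_ppm),
            class = "nuisance_control")
}

#' @rdname nuisance_control
#' @export
nuisance_off <- function() nuisance_control(0, 0, 0)

# Add a Lorentzian line of given integrated area to an intensity vector,
# evaluated only within +/- 0.25 ppm of the center (the truncated tail is
# < 0.3% of the area at the default linewidth).
add_lorentzian <- function(y, ppm, center, area, fwhm) {
  gamma <- fwhm / 2
  idx <- which(abs(ppm - center) <= 0.25)
  if (length(idx) == 0) return(y)
  y[idx] <- y[idx] + (area / pi) * gamma / ((ppm[idx] - center)^2 + gamma^2)
  y
}

# Class- and condition-dependent multiplier of a metabolite's baseline
# area. Linear: 1 + e * (T - mean(T_design)) / range(T_design). U-shape:
# 1 + e * 1[T extreme]. Sex effects multiply on top: constant offsets split
# +/- delta/2 between females and males; "hump" offsets are weighted by a
# Gaussian in temperature peaking at `peak` (default 22 degC).
class_modifier <- function(truth_row, temperature, sex, design) {
  cl <- truth_row$norm_class
  e <- truth_row$effect_size
  temps <- design$temperatures
  m <- 1
  if (cl %in% c("linear_up", "linear_down")) {
    m <- 1 + e * (temperature - mean(temps)) / diff(range(temps))
  } else if (cl %in% c("ushape_up", "ushape_down")) {
    m <- 1 + e * ushape_prior_encoding(temperature)
  }
  sfx <- truth_row$sex_effect[[1]]
  if (sfx$type != "none" && sfx$delta != 0) {
    w <- if (identical(sfx$type, "hump")) {
      peak <- sfx$peak %||% 22
      width <- sfx$width %||% 5
      exp(-((temperature - peak)^2) / (2 * width^2))
    } else 1
    sgn <- if (identical(sex, "female")) 1 else -1
    m <- m * (1 + sgn * sfx$delta * w / 2)
  }
  m
}

# Fixed positions for the unassigned spectral background: a regular comb
# over the analysis window, dropping any tooth within 0.03 ppm of a listed
# characteristic shift or integration range (so background never leaks
# into a quantified or verification window) or of the water region (so
# trimming never removes a tooth carrying part of the conserved pool).
background_positions <- function(truths, n = 60, water = c(4.67, 4.85)) {
  cand <- seq(0.55, 9.45, length.out = n * 2)
  keep <- vapply(cand, function(p) {
    near_shift <- any(abs(unlist(truths$shifts) - p) < 0.03)
    near_range <- any(p > truths$range_low - 0.03 &
                        p < truths$range_high + 0.03)
    in_water <- p > min(water) - 0.03 && p < max(water) + 0.03
    !near_shift && !near_range && !in_water
  }, logical(1))
  pos <- cand[keep]
  if (length(pos) > n) pos <- pos[round(seq(1, length(pos), length.out = n))]
  pos
}

#' Simulate a raw spectrum set
#'
#' Generates one unaligned, unnormalized spectrum per design cell and
#' replicate. Each metabolite contributes a Lorentzian line at each of its
#' characteristic shifts with integrated area `baseline` times a
#' class-dependent temperature/sex modifier; a TSP reference line is placed
#' at -0.017 ppm plus the sample's global jitter; an unassigned background
#' comb (outside every integration range) carries the remainder of the
#' metabolite pool so the pre-dilution total is conserved across
#' conditions. Dilution scales the whole spectrum, then additive baseline
#' noise is applied and intensities are clipped at zero.
#'
#' @param design A [simulation_design()].
#' @param truths Metabolite truths ([default_metabolite_truths()]).
#' @param nuisance A [nuisance_control()].
#' @param seed Integer seed; one sub-seed per sample is split off a single
#'   parent stream, so identical inputs give bitwise-identical output.
#' @param tsp_area Integrated area of the TSP reference line.
#' @param background_total Total baseline area of the unassigned
#'   background; defaults to twice the assigned pool.
#' @return A `spectrum_set` of raw spectra with sample metadata
#'   (`sample_id`, `sex`, `temperature`, `replicate`).
#' @export
#' @examples
#' d <- simulation_design(c(12, 22, 32), replicates_per_cell = 2)
#' s <- simulate_spectra(d, default_metabolite_truths(),
#'                       nuisance_off(), seed = 1)
#' s
simulate_spectra <- function(design, truths,
                             nuisance = nuisance_control(), seed,
                             tsp_area = 3,
                             background_total = 2 * sum(truths$baseline)) {
  validate_truths(truths)
  ppm <- design_ppm(design)
  step <- design$ppm_grid[["step"]]
  if (nuisance$jitter_ppm > 0.25)
    abort("jitter exceeds the supported grid range")
  meta <- tidyr::expand_grid(
    sex = design$sexes, temperature = design$temperatures,
    replicate = seq_len(design$replicates_per_cell))
  meta$sample_id <- sprintf("%s%g_r%d", toupper(substr(meta$sex, 1, 1)),
                            meta$temperature, meta$replicate)
  meta <- meta[, c("sample_id", "sex", "temperature", "replicate")]
  n <- nrow(meta)
  seeds <- sub_seeds(seed, n)
  bg_pos <- background_positions(truths)
  # a metabolite deposits its area at every characteristic shift, so the
  # conserved pool is counted in spectral-area units (area x line count)
  n_lines <- lengths(truths$shifts)
  pool <- sum(truths$baseline * n_lines)
  intens <- matrix(0, n, length(ppm))
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    # global calibration jitter, quantized to whole grid steps: the
    # generator models exactly the rigid misalignment that referencing
    # and alignment invert (sub-grid lineshape interpolation is out of
    # scope, like all FID-level effects)
    jit <- if (nuisance$jitter_ppm > 0)
      round(runif(1, -nuisance$jitter_ppm, nuisance$jitter_ppm) / step) * step
    else 0
    dil <- if (nuisance$dilution_sdlog > 0)
      exp(rnorm(1, 0, nuisance$dilution_sdlog)) else 1
    y <- numeric(length(ppm))
    areas <- numeric(nrow(truths))
    for (j in seq_len(nrow(truths))) {
      areas[j] <- truths$baseline[j] *
        class_modifier(truths[j, ], meta$temperature[i], meta$sex[i], design)
      for (sh in truths$shifts[[j]])
        y <- add_lorentzian(y, ppm, sh + jit, areas[j], truths$peak_width[j])
    }
    bg_total_i <- background_total + (pool - sum(areas * n_lines))
    if (bg_total_i <= 0)
      abort("background pool exhausted; increase `background_total`")
    for (p in bg_pos)
      y <- add_lorentzian(y, ppm, p + jit, bg_total_i / length(bg_pos), 0.002)
    y <- add_lorentzian(y, ppm, -0.017 + jit, tsp_area, 0.002)
    y <- y * dil
    if (nuisance$baseline_noise_sd > 0)
      y <- y + rnorm(length(y), 0, nuisance$baseline_noise_sd)
    intens[i, ] <- pmax(y, 0)
  }
  new_spectrum_set(ppm, intens, meta,
                   log = paste0("simulate(seed=", seed, ")"))
}
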