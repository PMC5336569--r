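# Shared fixtures, built in code.

small_design <- function(temperatures = c(12, 22, 32), reps = 3,
                         vials = 6, step = 0.005) {
  simulation_design(temperatures, replicates_per_cell = reps,
                    vials_per_temperature = vials,
                    flies_assayed_per_cell = 10,
                    ppm_grid = c(min = -0.1, max = 9.6, step = step))
}

# A one-row truths tibble for a synthetic metabolite.
one_truth <- function(name = "TestMet", shifts = list(c(3.0, 7.0)),
                      range = c(3.01, 2.99), norm_class = "null",
                      effect_size = 0, baseline = 1,
                      sex_effect = list(list(type = "none", delta = 0))) {
  tibble::tibble(name = name, shifts = shifts,
                 range_high = range[1], range_low = range[2],
                 norm_class = norm_class, baseline = baseline,
                 effect_size = effect_size, sex_effect = sex_effect,
                 peak_width = 0.002)
}

default_truths_quiet <- function(...)
  suppressWarnings(default_metabolite_truths(...))

# Reference integer shift with edge fill (independent of the package's
# internal helper).
shift_fill_test <- function(x, s) {
  n <- length(x)
  if (s == 0L) return(x)
  if (s > 0) c(rep(x[1], s), x[seq_len(n - s)])
  else c(x[seq.int(-s + 1L, n)], rep(x[n], -s))
}

# Hand-built spectrum set on an arbitrary grid.
toy_set <- function(intensities, ppm = NULL, meta = NULL, log = character()) {
  if (is.null(ppm)) ppm <- rev(seq_len(ncol(intensities)))
  if (is.null(meta))
    meta <- tibble::tibble(
      sample_id = paste0("s", seq_len(nrow(intensities))),
      sex = rep_len(c("female", "male"), nrow(intensities)),
      temperature = 20, replicate = seq_len(nrow(intensities)))
  new_spectrum_set(ppm, intensities, meta, log = log)
}

# Preprocessed default-design data shared by the heavier chemometric
# tests; computed once per test run.
default_prepped <- local({
  cache <- NULL
  function(seed = 1) {
    if (!is.null(cache)) return(cache)
    tr <- default_truths_quiet()
    set <- simulate_spectra(default_design(), tr, nuisance_control(),
                            seed = seed) |>
      reference_set() |>
      align_set() |>
      trim_set(keep = c(0.5, 9.6)) |>
      normalize_total()
    cache <<- list(set = set, truths = tr, fm = to_feature_matrix(set))
    cache
  }
})
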