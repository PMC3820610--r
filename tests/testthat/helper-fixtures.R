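# Shared fixtures, built once per test run.

TEST_DB <- build_lipid_database()

# A scaled-down study: 4 samples (two tissues, one sample without internal
# standards, one blank), one technical replicate, 3 repeat scans.
small_design <- function(seed = 1, noise_cv = 0.05, noise_floor = 25, ...) {
  samples <- tibble::tibble(
    sample_name = c("cortex_a", "cortex_b", "cortex_nois", "blank1"),
    tissue = c("cerebellum", "hippocampus", "cerebellum", "blank"),
    genotype = c("wt", "wt", "ko", NA),
    is_blank = c(FALSE, FALSE, FALSE, TRUE),
    has_is = c(TRUE, TRUE, FALSE, TRUE))
  study_design(samples = samples, replicates = 1, n_scans = 3,
               noise_cv = noise_cv, noise_floor = noise_floor,
               seed = seed, db = TEST_DB, ...)
}

# target list for one range of a design
design_targets <- function(design, range) {
  pol <- if (startsWith(range$id, "+")) "positive" else "negative"
  generate_target_list(
    design$db, scan_range = range,
    classes = default_range_classes()[[range$id]],
    standards = tibble::tibble(species_name = design$standards$species_name,
                               label = design$standards$label),
    locks = design$locks[design$locks$polarity == pol, ])
}

# independent brute-force isotope envelope: multiply the polynomial one atom
# at a time (no per-element exponentiation)
oracle_envelope <- function(formula, n_peaks) {
  tab <- atomic_mass_table()
  comp <- parse_formula(formula)
  poly <- 1
  for (el in names(comp)) {
    heavy <- tab$isotope_shifts[[el]]
    atom <- numeric(if (length(heavy)) max(as.integer(names(heavy))) + 1 else 1)
    atom[1] <- 1 - sum(heavy)
    if (length(heavy)) atom[as.integer(names(heavy)) + 1] <- heavy
    for (k in seq_len(comp[[el]])) {
      new <- numeric(length(poly) + length(atom) - 1)
      for (i in seq_along(poly)) {
        new[i:(i + length(atom) - 1)] <- new[i:(i + length(atom) - 1)] +
          poly[i] * atom
      }
      poly <- new
    }
  }
  out <- numeric(n_peaks)
  take <- seq_len(min(n_peaks, length(poly)))
  out[take] <- poly[take]
  out
}

# build a Gaussian profile spectrum on a regular grid
gaussian_spectrum <- function(centres, apexes, low, high, step = 0.0005,
                              sigma = NULL, acquisition_id = "acq",
                              scan_range_id = "+FTMS 500-1200") {
  mz <- seq(low, high, by = step)
  intensity <- numeric(length(mz))
  for (i in seq_along(centres)) {
    s <- if (is.null(sigma)) centres[i] / (1e5 * 2.3548) else sigma
    intensity <- intensity + apexes[i] * exp(-((mz - centres[i])^2) / (2 * s^2))
  }
  profile_spectrum(mz, intensity, acquisition_id, scan_range_id)
}
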