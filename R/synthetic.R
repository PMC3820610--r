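#' Default sample set of the synthetic study design
#'
#' Mirrors a comparative tissue study: three tissues from two wild-type and
#' two knockout mice (12 samples), plus two spiked blank extraction
#' controls — 14 samples in total. One sample (cerebellum, knockout mouse 2)
#' is generated without internal standards so that its two technical
#' replicates land at injections 07 and 08 and surface in lock-mass QC.
#'
#' @return Tibble with `sample_name`, `tissue`, `genotype`, `is_blank`,
#'   `has_is`.
#' @export
default_samples <- function() {
  tissues <- c("cerebellum", "hippocampus", "s1bf")
  rows <- list()
  for (tis in tissues) {
    for (gt in c("wt", "ko")) {
      for (mouse in 1:2) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          sample_name = paste0(tis, "_", gt, mouse),
          tissue = tis, genotype = gt, is_blank = FALSE, has_is = TRUE)
      }
    }
  }
  smp <- dplyr::bind_rows(rows)
  smp$has_is[smp$sample_name == "cerebellum_ko2"] <- FALSE
  dplyr::bind_rows(smp, tibble::tibble(
    sample_name = c("blank1", "blank2"), tissue = "blank",
    genotype = NA_character_, is_blank = TRUE, has_is = TRUE))
}

#' Default panel of planted endogenous species
#'
#' Sum-composition species spanning all four scan ranges with base molar
#' amounts (pmol per sample) typical of tissue extracts at the 10 ug protein
#' scale. Per-sample amounts are the base amount times a tissue factor.
#'
#' @return Tibble with `species_name`, `base_pmol`.
#' @export
default_planted_species <- function() {
  tibble::tribble(
    ~species_name,   ~base_pmol,
    "LPC 16:0",      40,
    "LPC 18:1",      25,
    "LPE 18:1",      15,
    "PC 32:0",       120,
    "PC 34:1",       200,
    "PE 38:4",       90,
    "PE O-36:2",     20,
    "PC O-34:1",     25,
    "SM 36:1;2",     60,
    "Cer 34:1;2",    12,
    "DAG 36:2",      8,
    "TAG 52:2",      30,
    "LPS 18:0",      6,
    "LPS 22:6",      4,
    "LPI 18:0",      5,
    "LPA 18:1",      3,
    "PS 36:1",       45,
    "PS 40:6",       30,
    "PI 38:4",       55,
    "PG 34:1",       12,
    "PA 34:1",       9,
    "SHexCer 36:1;2", 15
  )
}

#' Default internal-standard set
#'
#' One standard per directly spiked class, referenced in the database by its
#' sum-composition name and displayed under its chain-level spike label.
#' Spike amounts are pmol per sample.
#'
#' @return Tibble with `class`, `species_name`, `label`, `spike_pmol`.
#' @export
default_internal_standards <- function() {
  tibble::tribble(
    ~class,     ~species_name,    ~label,                    ~spike_pmol,
    "CE",       "CE 19:0",        "CE 19:0 (IS)",            54,
    "TAG",      "TAG 51:3",       "TAG 17:1/17:1/17:1",      35,
    "DAG",      "DAG 38:0",       "DAG 19:0/19:0",           35,
    "PA",       "PA 31:1",        "PA 17:0/14:1",            35,
    "LPS",      "LPS 17:1",       "LPS 17:1 (IS)",           25,
    "PS",       "PS 37:4",        "PS 17:0/20:4",            13,
    "PE O-",    "PE O-40:0",      "PE O-20:0/O-20:0",        50,
    "PC",       "PC 36:6",        "PC 18:3/18:3",            137,
    "PI",       "PI 37:4",        "PI 17:0/20:4",            35,
    "PG",       "PG 34:0",        "PG 17:0/17:0",            30,
    "Cer",      "Cer 35:1;2",     "Cer 18:1;2/17:0;0",       55,
    "SM",       "SM 35:1;2",      "SM 18:1;2/17:0;0",        69,
    "HexCer",   "HexCer 30:1;2",  "HexCer 18:1;2/12:0;0",    49,
    "SHexCer",  "SHexCer 30:1;2", "SHexCer 18:1;2/12:0;0",   28
  )
}

#' Default class-to-standard spike mapping for quantification
#'
#' Extends [default_internal_standards()] with explicit duplicate mappings
#' for classes quantified against a related class's standard (lyso classes
#' and diacyl PE against the PE O- standard).
#'
#' @return Tibble with `class`, `standard_species` (display label),
#'   `spike_pmol`.
#' @export
default_is_spikes <- function() {
  std <- default_internal_standards()
  direct <- tibble::tibble(class = std$class, standard_species = std$label,
                           spike_pmol = std$spike_pmol)
  borrow <- function(cls, from) {
    i <- match(from, std$class)
    tibble::tibble(class = cls, standard_species = std$label[i],
                   spike_pmol = std$spike_pmol[i])
  }
  dplyr::bind_rows(direct,
                   borrow("LPC", "PC"), borrow("LPE", "PE O-"),
                   borrow("PE", "PE O-"), borrow("PC O-", "PC"),
                   borrow("LPA", "PA"), borrow("LPI", "PI"))
}

#' Default lock-mass configuration
#'
#' Positive mode uses the ubiquitous chemical background ion
#' tris(ditert-butylphenyl) phosphate (C42H63O4P, [M+NH4]+) and the TAG
#' internal standard; the low positive range uses the phthalate plasticizer
#' background ion. Negative mode uses internal standards as locks. Entries
#' carry a formula so range membership can always be decided.
#'
#' @return Tibble with `name`, `species_name`, `formula`, `adduct`,
#'   `polarity`.
#' @export
default_locks <- function() {
  tibble::tribble(
    ~name,                                 ~species_name,           ~formula,       ~adduct, ~polarity,
    "tris(ditert-butylphenyl) phosphate",  NA_character_,           "C42H63O4P",    "+NH4",  "positive",
    "diisooctyl phthalate",                NA_character_,           "C24H38O4",     "+H",    "positive",
    "TAG 17:1/17:1/17:1",                  "TAG 17:1/17:1/17:1",    "C54H98O6",     "+NH4",  "positive",
    "LPS 17:1 (IS)",                       "LPS 17:1 (IS)",         "C23H44NO9P",   "-H",    "negative",
    "PI 17:0/20:4",                        "PI 17:0/20:4",          "C46H81O13P",   "-H",    "negative"
  )
}

#' Default chemical background ions planted in every acquisition
#'
#' Fixed-intensity ions present in samples and blanks alike: the two
#' positive-mode lock ions and a low-abundance negative-mode contaminant
#' that is falsely identifiable as PI 40:3 (exercising blank-based
#' false-identification screening).
#'
#' @return Tibble with `name`, `formula`, `adduct`, `polarity`, `intensity`.
#' @export
default_backgrounds <- function() {
  tibble::tribble(
    ~name,                                ~formula,      ~adduct, ~polarity,  ~intensity,
    "tris(ditert-butylphenyl) phosphate", "C42H63O4P",   "+NH4",  "positive", 5e5,
    "diisooctyl phthalate",               "C24H38O4",    "+H",    "positive", 4e5,
    "background at PI 40:3",              "C49H89O13P",  "-H",    "negative", 3e3
  )
}

#' Synthetic multiplexed shotgun-lipidomics study design
#'
#' Deterministic generator configuration standing in for the instrument and
#' the study layout: 14 samples (12 tissues + 2 blanks) analysed twice per
#' polarity (56 acquisitions), each polarity multiplexing a low and a high
#' m/z scan range (112 peak lists). Profile peaks are Gaussians on a fixed
#' m/z grid with sigma following a resolving power of 100,000 (fwhm), a
#' per-acquisition calibration offset, multiplicative peak noise and an
#' additive intensity floor.
#'
#' @param samples Sample tibble ([default_samples()]).
#' @param replicates Technical replicates per sample and polarity.
#' @param species Planted species panel ([default_planted_species()]).
#' @param standards Internal standards ([default_internal_standards()]).
#' @param spikes Class-to-standard map ([default_is_spikes()]).
#' @param locks Lock configuration ([default_locks()]).
#' @param backgrounds Background ions ([default_backgrounds()]).
#' @param tissue_factors Named multipliers applied to base amounts per
#'   tissue (blanks are zero).
#' @param offset_from,offset_to Calibration offset (Da) of the first and
#'   last injection of each polarity series; intermediate injections drift
#'   linearly.
#' @param grid_step m/z grid step in Da.
#' @param resolution Mass resolving power (fwhm) defining the Gaussian
#'   sigma, `sigma = mz / (resolution * 2.3548)`.
#' @param n_scans Repeat profile scans recorded per scan range.
#' @param response_factor Apex intensity counts per pmol.
#' @param noise_cv Multiplicative (lognormal) peak amplitude CV per scan.
#' @param noise_floor Additive intensity floor (standard deviation of the
#'   half-normal baseline added to each materialised grid point).
#' @param seed Integer seed driving all randomness.
#' @param db Lipid database (built once by default).
#' @return List of class `study_design`.
#' @export
study_design <- function(samples = default_samples(),
                         replicates = 2,
                         species = default_planted_species(),
                         standards = default_internal_standards(),
                         spikes = default_is_spikes(),
                         locks = default_locks(),
                         backgrounds = default_backgrounds(),
                         tissue_factors = c(cerebellum = 1, hippocampus = 1.3,
                                            s1bf = 0.75, blank = 0),
                         offset_from = -0.0015, offset_to = 0.0015,
                         grid_step = 0.0005, resolution = 1e5,
                         n_scans = 25, response_factor = 2e4,
                         noise_cv = 0.05, noise_floor = 25,
                         seed = 1,
                         db = build_lipid_database()) {
  stopifnot(grid_step > 0, n_scans >= 1, replicates >= 1)
  ranges <- list(
    positive = list(
      list(id = "+FTMS 280-580", low = 280, high = 580),
      list(id = "+FTMS 500-1200", low = 500, high = 1200)),
    negative = list(
      list(id = "-FTMS 370-660", low = 370, high = 660),
      list(id = "-FTMS 550-1700", low = 550, high = 1700))
  )
  structure(
    list(samples = samples, replicates = replicates, species = species,
         standards = standards, spikes = spikes, locks = locks,
         backgrounds = backgrounds, tissue_factors = tissue_factors,
         ranges = ranges, offset_from = offset_from, offset_to = offset_to,
         grid_step = grid_step, resolution = resolution, n_scans = n_scans,
         response_factor = response_factor, noise_cv = noise_cv,
         noise_floor = noise_floor, seed = as.integer(seed), db = db),
    class = "study_design")
}

#' Acquisition plan of a study design
#'
#' One row per injection (sample x replicate x polarity), in injection
#' order per polarity series, with the true calibration offset of each
#' injection and a derived per-acquisition RNG seed.
#'
#' @param design A [study_design()].
#' @return Tibble with `acquisition_id`, `sample_name`, `replicate`,
#'   `polarity`, `injection`, `is_blank`, `has_is`, `delta`, `acq_seed`.
#' @export
acquisition_plan <- function(design) {
  rows <- list()
  for (pol in names(design$ranges)) {
    inj <- 0L
    n_inj <- nrow(design$samples) * design$replicates
    for (s in seq_len(nrow(design$samples))) {
      for (r in seq_len(design$replicates)) {
        inj <- inj + 1L
        frac <- if (n_inj > 1) (inj - 1) / (n_inj - 1) else 0
        rows[[length(rows) + 1]] <- tibble::tibble(
          acquisition_id = sprintf("%s_%02d_%s_r%d",
                                   substr(pol, 1, 3), inj,
                                   design$samples$sample_name[s], r),
          sample_name = design$samples$sample_name[s],
          replicate = r, polarity = pol, injection = inj,
          is_blank = design$samples$is_blank[s],
          has_is = design$samples$has_is[s],
          delta = design$offset_from + frac * (design$offset_to - design$offset_from))
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      acquisition_id = character(), sample_name = character(),
      replicate = integer(), polarity = character(), injection = integer(),
      is_blank = logical(), has_is = logical(), delta = numeric(),
      acq_seed = integer()))
  }
  plan <- dplyr::bind_rows(rows)
  plan$acq_seed <- as.integer((as.numeric(design$seed) * 7919 +
                                 seq_len(nrow(plan)) * 101) %% 2147483647)
  plan
}

#' Ground-truth molar amounts of the planted species
#'
#' @param design A [study_design()].
#' @return Tibble with `sample_name`, `species_name`, `class`, `pmol`.
#' @export
truth_amounts <- function(design) {
  grid <- tidyr::expand_grid(sample_name = design$samples$sample_name,
                             species_name = design$species$species_name)
  si <- match(grid$sample_name, design$samples$sample_name)
  pi <- match(grid$species_name, design$species$species_name)
  tis <- design$samples$tissue[si]
  fac <- unname(design$tissue_factors[tis])
  fac[is.na(fac)] <- 1
  grid$class <- vapply(grid$species_name,
                       function(s) parse_annotation(s)$class, character(1))
  grid$pmol <- design$species$base_pmol[pi] * fac
  grid
}

# planted peak table for one acquisition x scan range:
# columns mz (true centre incl. offset), apex (expected apex intensity)
.planted_peaks <- function(design, plan_row, range) {
  pol <- plan_row$polarity
  adducts <- default_adducts()
  peaks <- list()
  add_peak <- function(mz, apex) {
    if (mz >= range$low && mz <= range$high && apex > 0) {
      peaks[[length(peaks) + 1]] <<- c(mz = mz, apex = apex)
    }
  }
  # endogenous species at tissue-scaled amounts
  truth <- truth_amounts(design)
  truth <- truth[truth$sample_name == plan_row$sample_name, ]
  for (i in seq_len(nrow(truth))) {
    row <- db_species(design$db, truth$species_name[i])
    adduct <- trimws(strsplit(row$adducts, ",", fixed = TRUE)[[1]][1])
    if (lookup_adduct(adduct, adducts)$polarity != pol) next
    m0 <- isotope_envelope(row$formula, 1)[1]
    add_peak(ion_mz(row$formula, adduct, adducts),
             truth$pmol[i] * design$response_factor * m0)
  }
  # internal standards (when spiked)
  if (isTRUE(plan_row$has_is)) {
    for (i in seq_len(nrow(design$standards))) {
      row <- db_species(design$db, design$standards$species_name[i])
      adduct <- trimws(strsplit(row$adducts, ",", fixed = TRUE)[[1]][1])
      if (lookup_adduct(adduct, adducts)$polarity != pol) next
      m0 <- isotope_envelope(row$formula, 1)[1]
      add_peak(ion_mz(row$formula, adduct, adducts),
               design$standards$spike_pmol[i] * design$response_factor * m0)
    }
  }
  # chemical background ions, present in every acquisition
  bg <- design$backgrounds[design$backgrounds$polarity == pol, ]
  for (i in seq_len(nrow(bg))) {
    add_peak(ion_mz(bg$formula[i], bg$adduct[i], adducts), bg$intensity[i])
  }
  if (length(peaks) == 0) {
    return(tibble::tibble(mz = numeric(), apex = numeric()))
  }
  m <- do.call(rbind, peaks)
  tibble::tibble(mz = m[, "mz"] + plan_row$delta, apex = m[, "apex"])
}

#' Simulate the repeat profile scans of one acquisition and scan range
#'
#' Each planted species contributes a Gaussian profile centred at its ion
#' m/z plus the acquisition's true calibration offset, with apex intensity
#' proportional to its molar amount scaled by its monoisotopic isotopologue
#' fraction. Only grid points within 4.5 sigma of a peak are materialised
#' (the baseline between peaks carries no information for targeted
#' extraction). Reproducible for a fixed seed.
#'
#' @param design A [study_design()].
#' @param plan_row One row of [acquisition_plan()].
#' @param range One scan-range spec (list with `id`, `low`, `high`).
#' @param seed Integer seed (defaults to the plan row's derived seed).
#' @return List of `n_scans` [profile_spectrum()] objects.
#' @export
simulate_scans <- function(design, plan_row, range, seed = plan_row$acq_seed) {
  set.seed(seed)
  peaks <- .planted_peaks(design, plan_row, range)
  step <- design$grid_step
  sigma <- peaks$mz / (design$resolution * 2.3548)
  # materialised grid: union of per-peak windows, as integer grid indices
  idx_list <- lapply(seq_len(nrow(peaks)), function(i) {
    w <- ceiling(4.5 * sigma[i] / step)
    centre <- round((peaks$mz[i] - range$low) / step)
    (centre - w):(centre + w)
  })
  all_idx <- sort(unique(unlist(idx_list)))
  all_idx <- all_idx[all_idx >= 0]
  grid_mz <- range$low + all_idx * step
  pos_list <- lapply(idx_list, function(ix) match(ix[ix >= 0], all_idx))
  gauss_list <- lapply(seq_len(nrow(peaks)), function(i) {
    ix <- idx_list[[i]]
    mzv <- range$low + ix[ix >= 0] * step
    exp(-((mzv - peaks$mz[i])^2) / (2 * sigma[i]^2))
  })
  scans <- vector("list", design$n_scans)
  for (s in seq_len(design$n_scans)) {
    intensity <- numeric(length(all_idx))
    for (i in seq_len(nrow(peaks))) {
      amp <- peaks$apex[i]
      if (design$noise_cv > 0) amp <- amp * exp(rnorm(1, 0, design$noise_cv))
      intensity[pos_list[[i]]] <- intensity[pos_list[[i]]] + amp * gauss_list[[i]]
    }
    if (design$noise_floor > 0) {
      intensity <- intensity + abs(rnorm(length(intensity), 0, design$noise_floor))
    }
    scans[[s]] <- profile_spectrum(grid_mz, intensity,
                                   acquisition_id = plan_row$acquisition_id,
                                   scan_range_id = range$id)
  }
  scans
}

#' Simulate a full study and write it as a converter-style folder tree
#'
#' Generates every acquisition of the design, averages its repeat scans and
#' organises the averaged peak lists into per-scan-range folders. Ground
#' truth (sample information, planted amounts, true offsets) is written
#' alongside as tab-separated text.
#'
#' @param design A [study_design()].
#' @param out_dir Output directory (created).
#' @return List with `manifest` (file tree manifest), `sample_info`,
#'   `truth_amounts`, `truth_offsets`, `peaklist_dir`.
#' @export
simulate_study <- function(design, out_dir) {
  plan <- acquisition_plan(design)
  peaklist_dir <- file.path(out_dir, "peaklists")
  dir.create(peaklist_dir, recursive = TRUE, showWarnings = FALSE)
  manifests <- list()
  for (k in seq_len(nrow(plan))) {
    plan_row <- plan[k, ]
    ranges <- design$ranges[[plan_row$polarity]]
    scans <- list()
    for (j in seq_along(ranges)) {
      scans[[ranges[[j]]$id]] <- simulate_scans(
        design, plan_row, ranges[[j]],
        seed = (plan_row$acq_seed + j) %% 2147483647L)
    }
    aset <- list(list(acquisition_id = plan_row$acquisition_id, scans = scans))
    manifests[[k]] <- organize_acquisitions(aset, peaklist_dir)
  }
  manifest <- dplyr::bind_rows(manifests)

  si <- match(plan$sample_name, design$samples$sample_name)
  sample_info <- tibble::tibble(
    acquisition_id = plan$acquisition_id,
    sample_name = plan$sample_name,
    tissue = design$samples$tissue[si],
    genotype = design$samples$genotype[si],
    replicate = plan$replicate,
    polarity = plan$polarity,
    injection = plan$injection,
    is_blank = plan$is_blank,
    has_is = plan$has_is)
  truth_off <- tibble::tibble(acquisition_id = plan$acquisition_id,
                              delta = plan$delta)
  truth_amt <- truth_amounts(design)

  write.table(as.data.frame(sample_info), file.path(out_dir, "sample_info.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(truth_amt), file.path(out_dir, "truth_amounts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(truth_off), file.path(out_dir, "truth_offsets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  spikes_df <- design$spikes
  names(spikes_df) <- c("class", "standard_species", "spike_pmol")
  write.table(as.data.frame(spikes_df), file.path(out_dir, "is_spikes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  list(manifest = manifest, sample_info = sample_info,
       truth_amounts = truth_amt, truth_offsets = truth_off,
       peaklist_dir = peaklist_dir)
}
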