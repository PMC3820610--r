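#' Default mapping of scan ranges to monitored lipid classes
#'
#' The low positive range monitors lyso-PC and lyso-PE species; the high
#' positive range the neutral-loss-rich classes SM, Cer, DAG, PC, PC O-,
#' PE, PE O- and TAG; the low negative range the lyso anionic classes; the
#' high negative range the diacyl anionic classes and sulfatides.
#'
#' @return Named list mapping scan_range_id to a character vector of
#'   classes.
#' @export
default_range_classes <- function() {
  list(
    "+FTMS 280-580"  = c("LPC", "LPE"),
    "+FTMS 500-1200" = c("SM", "Cer", "DAG", "PC", "PC O-", "PE", "PE O-", "TAG"),
    "-FTMS 370-660"  = c("LPA", "LPS", "LPI"),
    "-FTMS 550-1700" = c("PA", "PS", "PI", "PG", "SHexCer")
  )
}

#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir Output directory.
#' @param seed Integer seed for the synthetic study.
#' @param design A [study_design()]; built from `seed` when NULL.
#' @param tolerance Identification tolerance (Da).
#' @param offset_mode `"automatic"`, `"constant"` or `"none"`.
#' @param offset Constant offset (Da) when `offset_mode = "constant"`.
#' @param intensity_threshold Intensity filter threshold.
#' @param isotope_mode `"type2"` or `"none"`.
#' @param range_classes Scan-range to class mapping.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, design = NULL,
                       tolerance = 0.0020,
                       offset_mode = c("automatic", "constant", "none"),
                       offset = 0,
                       intensity_threshold = 500,
                       isotope_mode = c("type2", "none"),
                       range_classes = default_range_classes()) {
  offset_mode <- match.arg(offset_mode)
  isotope_mode <- match.arg(isotope_mode)
  if (is.null(design)) design <- study_design(seed = seed)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), design = design,
         tolerance = tolerance, offset_mode = offset_mode, offset = offset,
         intensity_threshold = intensity_threshold,
         isotope_mode = isotope_mode, range_classes = range_classes),
    class = "run_config")
}

#' Run the full pipeline: simulate, convert, target, extract, unify, QC,
#' quantify
#'
#' Executes every stage on the configured synthetic study and writes the
#' documented text outputs plus a machine-readable JSON run manifest with
#' the parameters and per-stage row counts. Stage errors propagate with the
#' stage name attached.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the unified table, QC table, quantified
#'   table, target lists and the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  design <- config$design
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    say("[%s] done in %.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    out
  }

  sim <- stage("simulate", simulate_study(design, config$out_dir))

  # target lists, one per scan range
  std_for_targets <- tibble::tibble(
    species_name = design$standards$species_name,
    label = design$standards$label)
  all_ranges <- c(design$ranges$positive, design$ranges$negative)
  targets <- stage("targets", {
    tl <- lapply(all_ranges, function(rg) {
      pol <- if (startsWith(rg$id, "+")) "positive" else "negative"
      locks <- design$locks[design$locks$polarity == pol, ]
      generate_target_list(
        design$db, scan_range = rg,
        classes = config$range_classes[[rg$id]],
        standards = std_for_targets, locks = locks)
    })
    names(tl) <- vapply(all_ranges, function(rg) rg$id, character(1))
    tdir <- file.path(config$out_dir, "target_lists")
    dir.create(tdir, showWarnings = FALSE)
    for (rid in names(tl)) {
      write_target_list(tl[[rid]], file.path(tdir, paste0(
        scan_range_folder(rid), ".tsv")))
    }
    tl
  })

  extracted <- stage("extract", {
    spectra <- read_acquisition_tree(sim$peaklist_dir)
    per_range <- list()
    estimates <- list()
    for (sp in spectra) {
      tgt <- targets[[sp$scan_range_id]]
      if (is.null(tgt)) next
      res <- extract_targets(sp, tgt, tolerance = config$tolerance,
                             offset_mode = config$offset_mode,
                             offset = config$offset)
      per_range[[length(per_range) + 1]] <- res$rows
      if (!is.null(res$offset_estimate)) {
        estimates[[length(estimates) + 1]] <- res$offset_estimate
      }
    }
    list(tables = per_range, estimates = estimates)
  })

  unified <- stage("unify", unify_ranges(extracted$tables))
  utils::write.csv(as.data.frame(unified),
                   file.path(config$out_dir, "unified.csv"), row.names = FALSE)

  qc <- stage("qc", {
    inj <- setNames(sim$sample_info$injection, sim$sample_info$acquisition_id)
    qc_lockmass(extracted$estimates, injection_order = inj)
  })
  utils::write.csv(as.data.frame(qc),
                   file.path(config$out_dir, "lockmass_qc.csv"),
                   row.names = FALSE)

  quant <- stage("quant", {
    spikes <- design$spikes
    names(spikes) <- c("class", "standard_species", "spike_pmol")
    tbl <- join_sample_info(unified, sim$sample_info)
    tbl <- filter_intensity(tbl, config$intensity_threshold)
    tbl <- subtract_blank(tbl)
    tbl <- isotope_correct(tbl, mode = config$isotope_mode)
    tbl <- compute_amounts(tbl, spikes)
    # blanks are excluded from the mol% universe (their amounts are zero by
    # construction after background subtraction)
    mol_percent(tbl, universe = function(t) {
      !t$is_blank & !t$is_internal_standard & !is.na(t$amount_fmol)
    })
  })
  utils::write.csv(as.data.frame(quant),
                   file.path(config$out_dir, "quantified.csv"),
                   row.names = FALSE)

  manifest <- list(
    parameters = list(
      seed = design$seed, tolerance = config$tolerance,
      offset_mode = config$offset_mode,
      intensity_threshold = config$intensity_threshold,
      isotope_mode = config$isotope_mode,
      n_scans = design$n_scans, grid_step = design$grid_step,
      noise_cv = design$noise_cv, noise_floor = design$noise_floor),
    counts = list(
      acquisitions = length(unique(sim$sample_info$acquisition_id)),
      peaklist_files = nrow(sim$manifest),
      scan_ranges = length(targets),
      targets_per_range = lapply(targets, nrow),
      unified_rows = nrow(unified),
      qc_rows = nrow(qc),
      quant_rows = nrow(quant)),
    outputs = c("unified.csv", "lockmass_qc.csv", "quantified.csv"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(unified = unified, qc = qc, quant = quant,
                 targets = targets, manifest = manifest, sim = sim))
}
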