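#' Compile a target list for one FT MS scan range
#'
#' Selects database species by class, adduct and index predicates, keeps
#' those whose adduct ion m/z falls inside the scan-range bounds, attaches
#' accessory lipid features and the M+0..M+2 isotopologue fractions, and
#' appends internal-standard entries (referenced by display label) and lock
#' masses (database species or explicit non-lipid compositions).
#'
#' @param db Lipid database.
#' @param scan_range List with `id`, `low`, `high` (m/z bounds, `low < high`).
#' @param classes Character vector of classes to include (default: all).
#' @param adduct_names Restrict to these adducts (default: each class's
#'   allowed adducts).
#' @param c_range,db_range,oh_range Optional integer vectors restricting the
#'   indices.
#' @param species Explicit species names to include regardless of the index
#'   predicates (still bounded by the scan range); unknown names are errors.
#' @param standards Optional tibble (`species_name`, `label`) of internal
#'   standards; entries are emitted under their display label with
#'   `is_internal_standard = TRUE`.
#' @param locks Optional tibble of lock masses with columns `name` and either
#'   `species_name` (database lock, e.g. an internal standard) or `formula`
#'   (non-lipid background ion), plus `adduct`.
#' @param adducts Adduct catalog.
#' @return Tibble of class `target_list` with attributes `scan_range_id`,
#'   `mz_low`, `mz_high`.
#' @export
generate_target_list <- function(db, scan_range,
                                 classes = NULL, adduct_names = NULL,
                                 c_range = NULL, db_range = NULL, oh_range = NULL,
                                 species = NULL, standards = NULL, locks = NULL,
                                 adducts = default_adducts()) {
  stopifnot(is.list(scan_range), scan_range$low < scan_range$high)
  if (!is.null(classes)) {
    unknown <- setdiff(classes, unique(db$class))
    if (length(unknown) > 0) {
      stop("filter references unknown class(es): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  sel <- db
  if (!is.null(classes)) sel <- sel[sel$class %in% classes, ]
  if (!is.null(c_range)) sel <- sel[sel$c_index %in% c_range, ]
  if (!is.null(db_range)) sel <- sel[sel$db_index %in% db_range, ]
  if (!is.null(oh_range)) sel <- sel[sel$oh_index %in% oh_range, ]
  if (!is.null(species)) {
    unknown <- setdiff(species, db$species_name)
    if (length(unknown) > 0) {
      stop("explicit species absent from database: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    extra <- db[db$species_name %in% species, ]
    sel <- dplyr::distinct(dplyr::bind_rows(sel, extra))
  }
  ions <- db_ion_table(sel, adducts)
  if (!is.null(adduct_names)) ions <- ions[ions$adduct %in% adduct_names, ]
  ions <- ions[ions$theoretical_mz >= scan_range$low &
                 ions$theoretical_mz <= scan_range$high, ]
  feat <- sel[match(ions$species_name, sel$species_name),
              c("class", "category", "c_index", "db_index", "oh_index",
                "mono_mass")]
  entries <- tibble::tibble(
    species_name = ions$species_name,
    adduct = ions$adduct,
    theoretical_mz = ions$theoretical_mz,
    is_internal_standard = FALSE,
    is_lock_mass = FALSE,
    formula = ions$formula
  )
  entries <- dplyr::bind_cols(entries, feat)

  if (!is.null(standards) && nrow(standards) > 0) {
    std_rows <- lapply(seq_len(nrow(standards)), function(i) {
      row <- db_species(db, standards$species_name[i])
      adduct <- trimws(strsplit(row$adducts, ",", fixed = TRUE)[[1]][1])
      mz <- ion_mz(row$formula, adduct, adducts)
      if (mz < scan_range$low || mz > scan_range$high) return(NULL)
      tibble::tibble(
        species_name = standards$label[i], adduct = adduct,
        theoretical_mz = mz, is_internal_standard = TRUE, is_lock_mass = FALSE,
        formula = row$formula, class = row$class, category = row$category,
        c_index = row$c_index, db_index = row$db_index, oh_index = row$oh_index,
        mono_mass = row$mono_mass)
    })
    entries <- dplyr::bind_rows(entries, std_rows)
  }

  if (!is.null(locks) && nrow(locks) > 0) {
    lock_rows <- lapply(seq_len(nrow(locks)), function(i) {
      lk <- locks[i, ]
      has_species <- !is.null(lk$species_name) && !is.na(lk$species_name) &&
        nzchar(lk$species_name)
      if (has_species) {
        # lock ion that is itself a (standard) species already on the list
        hit <- which(entries$species_name == lk$species_name &
                       entries$adduct == lk$adduct)
        if (length(hit) > 0) {
          entries$is_lock_mass[hit] <<- TRUE
          return(NULL)
        }
      }
      if (has_species && lk$species_name %in% db$species_name) {
        row <- db_species(db, lk$species_name)
        formula <- row$formula
        cls <- row$class; cat <- row$category
        ci <- row$c_index; dbi <- row$db_index; ohi <- row$oh_index
      } else if (!is.null(lk$formula) && !is.na(lk$formula) &&
                 nzchar(lk$formula)) {
        formula <- lk$formula
        cls <- NA_character_; cat <- NA_character_
        ci <- NA_integer_; dbi <- NA_integer_; ohi <- NA_integer_
      } else {
        stop("lock mass '", lk$name, "' has neither a known species nor a formula",
             call. = FALSE)
      }
      mz <- ion_mz(formula, lk$adduct, adducts)
      if (mz < scan_range$low || mz > scan_range$high) return(NULL)
      tibble::tibble(
        species_name = lk$name, adduct = lk$adduct, theoretical_mz = mz,
        is_internal_standard = FALSE, is_lock_mass = TRUE, formula = formula,
        class = cls, category = cat, c_index = ci, db_index = dbi,
        oh_index = ohi, mono_mass = monoisotopic_mass(formula))
    })
    entries <- dplyr::bind_rows(entries, lock_rows)
  }

  dup <- duplicated(entries[, c("species_name", "adduct")])
  if (any(dup)) entries <- entries[!dup, ]
  env <- t(vapply(entries$formula, function(f) isotope_envelope(f, 3),
                  numeric(3)))
  entries$isotope_m0 <- env[, 1]
  entries$isotope_m1 <- env[, 2]
  entries$isotope_m2 <- env[, 3]
  entries <- entries[order(entries$theoretical_mz), ]
  attr(entries, "scan_range_id") <- scan_range$id
  attr(entries, "mz_low") <- scan_range$low
  attr(entries, "mz_high") <- scan_range$high
  class(entries) <- c("target_list", class(entries))
  entries
}

#' Write a target list as tab-separated text
#'
#' The scan-range identity is stored in comment header lines so the file is
#' self-describing and can be audited or hand-edited.
#'
#' @param targets A `target_list`.
#' @param path Output path.
#' @export
write_target_list <- function(targets, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scan_range_id\t%s", attr(targets, "scan_range_id")), con)
  writeLines(sprintf("# mz_low\t%.6f", attr(targets, "mz_low")), con)
  writeLines(sprintf("# mz_high\t%.6f", attr(targets, "mz_high")), con)
  df <- as.data.frame(targets)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read a target list written by [write_target_list()]
#' @param path File path.
#' @return A `target_list` tibble.
#' @export
read_target_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- do.call(rbind, strsplit(sub("^# ?", "", hdr), "\t"))
  df <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  out <- tibble::as_tibble(df)
  meta_val <- setNames(meta[, 2], meta[, 1])
  attr(out, "scan_range_id") <- unname(meta_val["scan_range_id"])
  attr(out, "mz_low") <- as.numeric(meta_val["mz_low"])
  attr(out, "mz_high") <- as.numeric(meta_val["mz_high"])
  class(out) <- c("target_list", class(out))
  out
}
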