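#' Read a sample-information table
#'
#' One row per acquisition with at least `acquisition_id`, `sample_name` and
#' `is_blank`; any further columns (tissue, genotype, replicate, injection
#' order, ...) are carried along as free sample attributes.
#'
#' @param path Tab- or comma-separated text file with a header.
#' @param sep Field separator (default tab).
#' @return Tibble.
#' @export
read_sample_info <- function(path, sep = "\t") {
  df <- tibble::as_tibble(read.table(path, header = TRUE, sep = sep,
                                     stringsAsFactors = FALSE))
  validate_sample_info(df)
}

validate_sample_info <- function(sample_info) {
  req <- c("acquisition_id", "sample_name", "is_blank")
  missing_cols <- setdiff(req, names(sample_info))
  if (length(missing_cols) > 0) {
    stop("sample info missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_info$acquisition_id)) {
    stop("duplicate acquisition_id in sample info", call. = FALSE)
  }
  sample_info$is_blank <- as.logical(sample_info$is_blank)
  sample_info
}

#' Read an internal-standard spike table
#'
#' Maps each quantified lipid class to exactly one internal standard
#' (referenced by its display label on the target list) and the molar amount
#' spiked per sample. Classes sharing a standard appear as duplicate
#' explicit rows.
#'
#' @param path Text file with header columns `class`, `standard_species`,
#'   `spike_pmol`.
#' @param sep Field separator (default tab).
#' @return Tibble.
#' @export
read_is_spikes <- function(path, sep = "\t") {
  df <- tibble::as_tibble(read.table(path, header = TRUE, sep = sep,
                                     stringsAsFactors = FALSE))
  validate_is_spikes(df)
}

validate_is_spikes <- function(spikes) {
  req <- c("class", "standard_species", "spike_pmol")
  missing_cols <- setdiff(req, names(spikes))
  if (length(missing_cols) > 0) {
    stop("IS spike table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(spikes$spike_pmol <= 0)) {
    stop("spike amounts must be positive", call. = FALSE)
  }
  if (anyDuplicated(spikes$class)) {
    stop("each class must map to exactly one internal standard", call. = FALSE)
  }
  spikes
}

#' Join sample information onto a unified result table
#'
#' Row count is preserved; sample attribute columns are appended. Every
#' acquisition in the table must be described in the sample info.
#'
#' @param table Unified result table.
#' @param sample_info Tibble from [read_sample_info()].
#' @return The table with sample columns appended.
#' @export
join_sample_info <- function(table, sample_info) {
  sample_info <- validate_sample_info(sample_info)
  unmatched <- setdiff(unique(table$acquisition_id), sample_info$acquisition_id)
  if (length(unmatched) > 0) {
    stop("acquisition(s) missing from sample info: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  dplyr::left_join(table, sample_info, by = "acquisition_id")
}

#' Remove rows below an intensity threshold
#'
#' Rows with `intensity < threshold` are dropped (strict inequality, so a
#' threshold of zero removes nothing).
#'
#' @param table Result table.
#' @param threshold Non-negative intensity threshold.
#' @export
filter_intensity <- function(table, threshold) {
  stopifnot(threshold >= 0)
  table[table$intensity >= threshold, , drop = FALSE]
}

#' Background subtraction against blank samples
#'
#' Per (species, adduct, rangeID), the mean intensity over blank acquisitions
#' is subtracted from every row's intensity, floored at zero, and stored in
#' `corrected_intensity`. Internal-standard and lock-mass rows are exempt
#' (blanks are spiked with internal standards, so subtracting blanks there
#' would destroy the quantification denominators). Blank rows are retained
#' and flagged in `blank_consumed`.
#'
#' @param table Result table joined with sample info (needs `is_blank`).
#' @return Table with `corrected_intensity` and `blank_consumed` columns.
#' @export
subtract_blank <- function(table) {
  if (!"is_blank" %in% names(table)) {
    stop("subtract_blank requires sample info (is_blank column)", call. = FALSE)
  }
  if (!any(table$is_blank)) {
    warning("no blank acquisitions present; corrected intensity equals raw")
    table$corrected_intensity <- table$intensity
    table$blank_consumed <- FALSE
    return(table)
  }
  key <- paste(table$species_name, table$adduct,
               if ("rangeID" %in% names(table)) table$rangeID else table$scan_range_id,
               sep = "\r")
  blank <- table$is_blank
  blank_mean <- tapply(table$intensity[blank], key[blank], mean)
  bm <- blank_mean[key]
  bm[is.na(bm)] <- 0
  corrected <- pmax(0, table$intensity - bm)
  exempt <- table$is_internal_standard | table$is_lock_mass
  corrected[exempt] <- table$intensity[exempt]
  table$corrected_intensity <- unname(corrected)
  table$blank_consumed <- blank
  table
}

#' Isotope correction of intensities
#'
#' `mode = "type2"` divides each intensity by the species' monoisotopic
#' (M+0) isotopologue fraction, restoring the intensity carried by heavier
#' isotopologues that fall outside the monoisotopic tolerance window.
#' `mode = "none"` is the identity.
#'
#' @param table Result table with `isotope_m0` and a `corrected_intensity`
#'   column (falls back to `intensity` if absent).
#' @param mode `"none"` or `"type2"`.
#' @export
isotope_correct <- function(table, mode = c("none", "type2")) {
  mode <- match.arg(mode)
  if (!"corrected_intensity" %in% names(table)) {
    table$corrected_intensity <- table$intensity
  }
  if (mode == "none") return(table)
  if (!"isotope_m0" %in% names(table)) {
    stop("isotope correction requires isotope_m0 fractions", call. = FALSE)
  }
  if (any(table$isotope_m0 <= 0)) {
    stop("non-positive M+0 fraction", call. = FALSE)
  }
  table$corrected_intensity <- table$corrected_intensity / table$isotope_m0
  table
}

#' Compute molar amounts from internal-standard intensities
#'
#' Implements the internal-standard quantification equation: for each row,
#' `amount_fmol = corrected_intensity / IS_corrected_intensity *
#' spike_pmol * 1000`, where the IS intensity is that of the class's
#' internal standard within the same acquisition. Amounts are missing (not
#' zero) for acquisitions whose IS was not detected. Spikes are given in
#' pmol; amounts are reported in fmol.
#'
#' @param table Result table with `corrected_intensity` (lock-mass rows are
#'   dropped from the output; IS rows are retained and flagged).
#' @param spikes IS spike tibble (`class`, `standard_species`, `spike_pmol`).
#' @return Table with `spike_pmol`, `is_intensity` and `amount_fmol` columns.
#' @export
compute_amounts <- function(table, spikes) {
  spikes <- validate_is_spikes(spikes)
  if (!"corrected_intensity" %in% names(table)) {
    table$corrected_intensity <- table$intensity
  }
  quant <- table[!table$is_lock_mass | table$is_internal_standard, , drop = FALSE]
  classes <- unique(quant$class[!quant$is_internal_standard & !is.na(quant$class)])
  unmapped <- setdiff(classes, spikes$class)
  if (length(unmapped) > 0) {
    stop("no internal standard mapping for class(es): ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  si <- match(quant$class, spikes$class)
  quant$spike_pmol <- spikes$spike_pmol[si]
  std_label <- spikes$standard_species[si]
  # IS intensity per (acquisition, standard label)
  is_rows <- quant[quant$is_internal_standard, , drop = FALSE]
  is_key <- paste(is_rows$acquisition_id, is_rows$species_name, sep = "\r")
  is_int <- setNames(is_rows$corrected_intensity, is_key)
  quant$is_intensity <- unname(is_int[paste(quant$acquisition_id, std_label,
                                            sep = "\r")])
  ok <- !is.na(quant$is_intensity) & quant$is_intensity > 0
  quant$amount_fmol <- ifelse(
    ok, quant$corrected_intensity / quant$is_intensity * quant$spike_pmol * 1000,
    NA_real_)
  quant
}

#' mol% of molar amounts within grouping cells
#'
#' Within each grouping cell (e.g. per acquisition), each row matching the
#' universe predicate gets
#' `mol_percent = amount_fmol / sum(amount_fmol in cell & universe) * 100`;
#' rows outside the universe get `NA`. A cell whose denominator is zero or
#' entirely missing yields missing values with a warning.
#'
#' @param table Table with `amount_fmol`.
#' @param grouping Character vector of grouping columns
#'   (default `"acquisition_id"`).
#' @param universe Logical vector (recycled) or a one-argument function of
#'   the table returning the rows forming the normalisation universe;
#'   default: all non-IS rows with a non-missing amount.
#' @return Table with a `mol_percent` column.
#' @export
mol_percent <- function(table, grouping = "acquisition_id", universe = NULL) {
  if (!"amount_fmol" %in% names(table)) {
    stop("mol_percent requires amount_fmol (run compute_amounts first)",
         call. = FALSE)
  }
  if (is.null(universe)) {
    in_univ <- !table$is_internal_standard & !is.na(table$amount_fmol)
  } else if (is.function(universe)) {
    in_univ <- universe(table)
  } else {
    in_univ <- rep_len(as.logical(universe), nrow(table))
  }
  in_univ <- in_univ & !is.na(table$amount_fmol)
  cell <- do.call(paste, c(lapply(grouping, function(g) table[[g]]),
                           list(sep = "\r")))
  denom_by_cell <- tapply(ifelse(in_univ, table$amount_fmol, 0), cell, sum)
  denom <- unname(denom_by_cell[cell])
  bad <- in_univ & (is.na(denom) | denom <= 0)
  if (any(bad)) warning("zero mol% denominator in ",
                        length(unique(cell[bad])), " grouping cell(s)")
  table$mol_percent <- ifelse(in_univ & denom > 0,
                              table$amount_fmol / denom * 100, NA_real_)
  table
}
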