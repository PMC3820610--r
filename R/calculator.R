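#' Theoretical and offset-adjusted m/z of a database species
#'
#' Computes the adduct ion m/z of a named species and the value adjusted for
#' an FT MS calibration offset. The offset shifts theoretical values toward
#' the instrument (`adjusted = raw + offset`); measured values are never
#' modified.
#'
#' @param db Lipid database.
#' @param species_name Sum-composition species name present in `db`.
#' @param adduct Adduct name; must be allowed for the species' class.
#' @param offset Calibration offset in Da (|offset| < 1).
#' @param adducts Adduct catalog.
#' @return Tibble with `species_name`, `adduct`, `mz` (raw) and
#'   `adjusted_mz`, both at full precision.
#' @examples
#' db <- build_lipid_database()
#' species_mz(db, "PC 32:0", "+H", offset = -0.0010)
#' @export
species_mz <- function(db, species_name, adduct, offset = 0,
                       adducts = default_adducts()) {
  check_offset(offset)
  row <- db_species(db, species_name)
  allowed <- strsplit(row$adducts, ",", fixed = TRUE)[[1]]
  if (!adduct %in% trimws(allowed)) {
    stop("adduct ", adduct, " not allowed for class ", row$class, call. = FALSE)
  }
  mz <- ion_mz(row$formula, adduct, adducts)
  tibble::tibble(
    species_name = species_name,
    adduct = adduct,
    mz = mz,
    offset = offset,
    adjusted_mz = mz + offset
  )
}

check_offset <- function(offset) {
  if (!is.numeric(offset) || length(offset) != 1 || !is.finite(offset) ||
      abs(offset) >= 1) {
    stop("calibration offset must be a finite value with |offset| < 1 Da",
         call. = FALSE)
  }
  invisible(offset)
}

#' Database candidates for a measured m/z value
#'
#' All (species, adduct) pairs of the requested polarity whose
#' offset-adjusted theoretical m/z lies within a closed tolerance window of
#' the measured value, sorted by absolute m/z error (ties broken by species
#' name).
#'
#' The mass error in ppm is `delta_mz / measured_mz * 1e6`; display
#' conventions are 5 decimals for `delta_mz` and 1 decimal for ppm.
#'
#' @param db Lipid database.
#' @param measured_mz Measured m/z (Da).
#' @param tolerance Tolerance window half-width in Da (> 0).
#' @param offset Calibration offset in Da applied to theoretical values.
#' @param polarity `"positive"` or `"negative"`.
#' @param adducts Adduct catalog.
#' @return Tibble with `species_name`, `adduct`, `theoretical_mz`,
#'   `adjusted_mz`, `delta_mz` (measured minus adjusted) and `delta_ppm`;
#'   empty when nothing matches.
#' @export
mz_candidates <- function(db, measured_mz, tolerance, offset = 0,
                          polarity = c("positive", "negative"),
                          adducts = default_adducts()) {
  polarity <- match.arg(polarity)
  stopifnot(tolerance > 0)
  check_offset(offset)
  ions <- db_ion_table(db, adducts)
  ions <- ions[ions$polarity == polarity, ]
  adj <- ions$theoretical_mz + offset
  keep <- abs(measured_mz - adj) <= tolerance
  out <- ions[keep, c("species_name", "adduct", "theoretical_mz")]
  out$adjusted_mz <- adj[keep]
  out$delta_mz <- measured_mz - out$adjusted_mz
  out$delta_ppm <- out$delta_mz / measured_mz * 1e6
  out[order(abs(out$delta_mz), out$species_name), ]
}

# expand a database into one row per (species, allowed adduct) with ion m/z;
# memoised on the database object via an attribute-keyed cache
db_ion_table <- function(db, adducts = default_adducts()) {
  reps <- strsplit(db$adducts, ",", fixed = TRUE)
  n <- lengths(reps)
  ions <- tibble::tibble(
    species_name = rep(db$species_name, n),
    formula = rep(db$formula, n),
    adduct = trimws(unlist(reps))
  )
  ai <- match(ions$adduct, adducts$name)
  if (anyNA(ai)) {
    stop("class allows unknown adduct: ",
         paste(unique(ions$adduct[is.na(ai)]), collapse = ", "), call. = FALSE)
  }
  ions$polarity <- adducts$polarity[ai]
  # ion mass = neutral mass + signed delta mass, vectorised over adducts
  delta_mass <- vapply(seq_len(nrow(adducts)), function(i) {
    adducts$delta_sign[i] * monoisotopic_mass(adducts$delta_formula[i])
  }, numeric(1))
  neutral <- rep(db$mono_mass, n)
  ions$theoretical_mz <- (neutral + delta_mass[ai] -
                            adducts$charge[ai] * .ELECTRON_MASS) /
    abs(adducts$charge[ai])
  ions
}
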