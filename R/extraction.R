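#' Three-point quadratic centroid interpolation
#'
#' Vertex abscissa of the unique parabola through three profile points
#' around an apex. Points need not be uniformly spaced. A flat or
#' upward-curved triplet has no apex and is an error.
#'
#' @param p0,p1,p2 Numeric length-2 vectors `c(mz, intensity)` in ascending
#'   m/z order.
#' @return Centroid m/z (Da).
#' @export
centroid_quadratic <- function(p0, p1, p2) {
  x <- c(p0[1], p1[1], p2[1])
  y <- c(p0[2], p1[2], p2[2])
  # divided differences for y = a x^2 + b x + c through the three points
  d1 <- (y[2] - y[1]) / (x[2] - x[1])
  d2 <- (y[3] - y[2]) / (x[3] - x[2])
  a <- (d2 - d1) / (x[3] - x[1])
  if (!is.finite(a) || a >= 0) {
    stop("degenerate triplet: no apex (zero or non-negative curvature)",
         call. = FALSE)
  }
  b <- d1 - a * (x[1] + x[2])
  -b / (2 * a)
}

#' Estimate the FT MS calibration offset from lock mass ions
#'
#' For each lock mass the most intense profile bin within
#' `theoretical_mz +/- search_window` is located; if its intensity reaches
#' `min_intensity` the centroid m/z is computed by [centroid_quadratic()]
#' over the apex and its two neighbouring bins, and the lock's offset is
#' `centroid - theoretical`. The combined per-acquisition offset is the
#' unweighted arithmetic mean (in Da) of the per-lock offsets that were
#' found; it is missing when no lock was found. A lock that cannot be
#' centroided (apex at the spectrum edge or a degenerate triplet) falls back
#' to the apex bin m/z.
#'
#' @param spectrum A [profile_spectrum()].
#' @param locks Target entries flagged `is_lock_mass` (a `target_list` or
#'   subset thereof).
#' @param search_window Half-width of the lock search window in Da
#'   (default 0.01, deliberately wider than the identification tolerance).
#' @param min_intensity Minimum apex intensity for a lock to count as
#'   detected.
#' @return List of class `offset_estimate` with `acquisition_id`,
#'   `scan_range_id`, `locks` (tibble: name, theoretical_mz, centroid_mz,
#'   offset, apex_intensity, detected) and `combined_offset` (Da or NA).
#' @export
estimate_lock_offset <- function(spectrum, locks, search_window = 0.01,
                                 min_intensity = 0) {
  stopifnot(search_window > 0)
  locks <- locks[locks$is_lock_mass, , drop = FALSE]
  n <- nrow(locks)
  res <- tibble::tibble(
    name = character(n), theoretical_mz = numeric(n),
    centroid_mz = rep(NA_real_, n), offset = rep(NA_real_, n),
    apex_intensity = rep(NA_real_, n), detected = logical(n)
  )
  for (i in seq_len(n)) {
    theo <- locks$theoretical_mz[i]
    res$name[i] <- locks$species_name[i]
    res$theoretical_mz[i] <- theo
    win <- which(spectrum$mz >= theo - search_window &
                   spectrum$mz <= theo + search_window)
    if (length(win) == 0) next
    apex_rel <- which.max(spectrum$intensity[win])
    apex <- win[apex_rel]
    apex_int <- spectrum$intensity[apex]
    res$apex_intensity[i] <- apex_int
    if (apex_int < min_intensity || apex_int <= 0) next
    centroid <- NA_real_
    if (apex > 1 && apex < length(spectrum$mz)) {
      centroid <- tryCatch(
        centroid_quadratic(
          c(spectrum$mz[apex - 1], spectrum$intensity[apex - 1]),
          c(spectrum$mz[apex], spectrum$intensity[apex]),
          c(spectrum$mz[apex + 1], spectrum$intensity[apex + 1])),
        error = function(e) NA_real_)
    }
    if (is.na(centroid)) centroid <- spectrum$mz[apex]
    res$centroid_mz[i] <- centroid
    res$offset[i] <- centroid - theo
    res$detected[i] <- TRUE
  }
  combined <- if (any(res$detected)) mean(res$offset[res$detected]) else NA_real_
  structure(
    list(acquisition_id = spectrum$acquisition_id,
         scan_range_id = spectrum$scan_range_id,
         locks = res, combined_offset = combined,
         mode = "automatic"),
    class = "offset_estimate"
  )
}

#' @export
print.offset_estimate <- function(x, ...) {
  cat(sprintf("<offset_estimate> %s | %s | combined %s Da (%d/%d locks)\n",
              x$acquisition_id, x$scan_range_id,
              ifelse(is.na(x$combined_offset), "NA",
                     sprintf("%+.5f", x$combined_offset)),
              sum(x$locks$detected), nrow(x$locks)))
  invisible(x)
}

#' Targeted identification and intensity export from one profile spectrum
#'
#' For every entry of the target list the theoretical m/z is shifted by the
#' calibration offset, and the maximum profile intensity inside the closed
#' window `adjusted_mz +/- tolerance` is exported together with the m/z bin
#' of the maximum (ties resolved to the lowest m/z) and a trapezoidal peak
#' area over the window. A row is emitted for every target; targets with no
#' bins in the window get zero intensity and a missing measured m/z.
#'
#' @param spectrum A [profile_spectrum()].
#' @param targets A `target_list` for the spectrum's scan range.
#' @param tolerance Identification tolerance half-width in Da
#'   (default 0.0020, appropriate for FT MS at resolution 100,000).
#' @param offset_mode `"none"`, `"constant"` or `"automatic"`.
#' @param offset Constant offset value (Da) for `offset_mode = "constant"`.
#' @param locks Lock-mass target entries for `offset_mode = "automatic"`
#'   (defaults to the lock rows of `targets`).
#' @param search_window,min_intensity Passed to [estimate_lock_offset()].
#' @return List with `rows` (tibble, one row per target) and
#'   `offset_estimate` (an `offset_estimate` or NULL).
#' @export
extract_targets <- function(spectrum, targets, tolerance = 0.0020,
                            offset_mode = c("none", "constant", "automatic"),
                            offset = 0, locks = NULL,
                            search_window = 0.01, min_intensity = 0) {
  offset_mode <- match.arg(offset_mode)
  stopifnot(tolerance > 0)
  if (length(spectrum$mz) == 0) stop("empty spectrum", call. = FALSE)
  est <- NULL
  applied <- 0
  if (offset_mode == "constant") {
    check_offset(offset)
    applied <- offset
  } else if (offset_mode == "automatic") {
    if (is.null(locks)) locks <- targets[targets$is_lock_mass, , drop = FALSE]
    est <- estimate_lock_offset(spectrum, locks, search_window = search_window,
                                min_intensity = min_intensity)
    applied <- if (is.na(est$combined_offset)) 0 else est$combined_offset
  }
  adjusted <- targets$theoretical_mz + applied
  lo <- findInterval(adjusted - tolerance, spectrum$mz,
                     left.open = TRUE) + 1L    # first bin >= lower edge
  hi <- findInterval(adjusted + tolerance, spectrum$mz)  # last bin <= upper edge
  n <- nrow(targets)
  intensity <- numeric(n)
  peak_area <- numeric(n)
  measured <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (hi[i] < lo[i]) next
    idx <- lo[i]:hi[i]
    ints <- spectrum$intensity[idx]
    k <- which.max(ints)  # which.max returns the first (lowest m/z) maximum
    intensity[i] <- ints[k]
    measured[i] <- spectrum$mz[idx[k]]
    if (length(idx) > 1) {
      mzs <- spectrum$mz[idx]
      peak_area[i] <- sum(diff(mzs) * (head(ints, -1) + tail(ints, -1)) / 2)
    }
  }
  rows <- tibble::tibble(
    acquisition_id = spectrum$acquisition_id,
    scan_range_id = spectrum$scan_range_id,
    species_name = targets$species_name,
    adduct = targets$adduct,
    intensity = intensity,
    peak_area = peak_area,
    measured_mz = measured,
    theoretical_mz = targets$theoretical_mz,
    adjusted_mz = adjusted,
    delta_mz = measured - adjusted,
    applied_offset = applied,
    is_internal_standard = targets$is_internal_standard,
    is_lock_mass = targets$is_lock_mass,
    class = targets$class,
    category = targets$category,
    c_index = targets$c_index,
    db_index = targets$db_index,
    oh_index = targets$oh_index,
    formula = targets$formula,
    mono_mass = targets$mono_mass,
    isotope_m0 = targets$isotope_m0,
    isotope_m1 = targets$isotope_m1,
    isotope_m2 = targets$isotope_m2
  )
  list(rows = rows, offset_estimate = est)
}

#' Merge per-scan-range result tables into one unified table
#'
#' Row-wise concatenation of extractor outputs with a `rangeID` column
#' populated from each table's scan range. All inputs must share an
#' identical column set.
#'
#' @param range_outputs List of result-row tibbles (each carrying a
#'   `scan_range_id` column).
#' @return Unified tibble with a `rangeID` column.
#' @export
unify_ranges <- function(range_outputs) {
  stopifnot(length(range_outputs) >= 1)
  cols <- lapply(range_outputs, names)
  if (!all(vapply(cols[-1], identical, logical(1), cols[[1]]))) {
    stop("column-set mismatch between range outputs", call. = FALSE)
  }
  out <- dplyr::bind_rows(range_outputs)
  out$rangeID <- out$scan_range_id
  out
}

#' Lock-mass quality control table
#'
#' One row per (acquisition, lock) across a series of injections, carrying
#' the per-lock offset and apex intensity and a flag for locks that were not
#' detected. Injection order defaults to the sort order of acquisition ids.
#'
#' @param estimates List of `offset_estimate` objects (one per acquisition
#'   and scan range).
#' @param injection_order Optional named integer vector mapping
#'   acquisition_id to injection number.
#' @return Tibble with `injection`, `acquisition_id`, `scan_range_id`,
#'   `lock`, `theoretical_mz`, `offset`, `apex_intensity`, `detected`,
#'   `combined_offset`.
#' @export
qc_lockmass <- function(estimates, injection_order = NULL) {
  if (length(estimates) == 0) {
    return(tibble::tibble(injection = integer(), acquisition_id = character(),
                          scan_range_id = character(), lock = character(),
                          theoretical_mz = numeric(), offset = numeric(),
                          apex_intensity = numeric(), detected = logical(),
                          combined_offset = numeric()))
  }
  acq_ids <- vapply(estimates, function(e) e$acquisition_id, character(1))
  if (is.null(injection_order)) {
    ord <- sort(unique(acq_ids))
    injection_order <- setNames(seq_along(ord), ord)
  }
  rows <- lapply(estimates, function(e) {
    lk <- e$locks
    tibble::tibble(
      injection = unname(injection_order[e$acquisition_id]),
      acquisition_id = e$acquisition_id,
      scan_range_id = e$scan_range_id,
      lock = lk$name,
      theoretical_mz = lk$theoretical_mz,
      offset = lk$offset,
      apex_intensity = lk$apex_intensity,
      detected = lk$detected,
      combined_offset = e$combined_offset)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$injection, .data$scan_range_id, .data$lock)
}

#' Plot lock-mass offset and intensity against injection order
#'
#' @param qc Table from [qc_lockmass()].
#' @return A ggplot object (requires ggplot2).
#' @export
plot_lockmass_qc <- function(qc) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires ggplot2", call. = FALSE)
  }
  long <- tidyr::pivot_longer(qc, c("offset", "apex_intensity"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$injection, y = .data$value,
                                     colour = .data$lock)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_grid(metric ~ scan_range_id, scales = "free_y") +
    ggplot2::labs(x = "injection", y = NULL)
}
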