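#' Construct a profile-mode spectrum
#'
#' A profile spectrum is an ordered (m/z, intensity) trace identified by the
#' acquisition it came from and the FT MS scan range it covers.
#'
#' @param mz Numeric vector of m/z values; sorted on construction, must be
#'   strictly increasing after sorting.
#' @param intensity Non-negative intensities, same length as `mz`.
#' @param acquisition_id Source identifier (typically the file stem).
#' @param scan_range_id Scan range label, e.g. `"+FTMS 500-1200"`.
#' @return List of class `profile_spectrum`.
#' @export
profile_spectrum <- function(mz, intensity, acquisition_id = "",
                             scan_range_id = "") {
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have equal length", call. = FALSE)
  }
  if (anyNA(mz) || anyNA(intensity)) {
    stop("mz and intensity must not contain NA", call. = FALSE)
  }
  o <- order(mz)
  mz <- mz[o]
  intensity <- intensity[o]
  if (length(mz) > 1 && any(diff(mz) <= 0)) {
    stop("m/z values must be strictly increasing (duplicates present)",
         call. = FALSE)
  }
  if (any(intensity < 0)) stop("intensities must be non-negative", call. = FALSE)
  structure(
    list(mz = mz, intensity = intensity,
         acquisition_id = acquisition_id, scan_range_id = scan_range_id),
    class = "profile_spectrum"
  )
}

#' @export
print.profile_spectrum <- function(x, ...) {
  cat(sprintf("<profile_spectrum> %s | %s | %d points [%.4f..%.4f]\n",
              x$acquisition_id, x$scan_range_id, length(x$mz),
              if (length(x$mz)) min(x$mz) else NA, if (length(x$mz)) max(x$mz) else NA))
  invisible(x)
}

#' Read a two-column profile peak list from a text file
#'
#' Accepts tab- or whitespace-separated files with two numeric columns
#' (m/z, intensity) and an optional single header line. Rows are sorted by
#' m/z on load; a non-numeric data row is an error naming its line number.
#'
#' @param path File path; the acquisition id defaults to the file stem.
#' @param scan_range_id Scan range label to attach.
#' @param acquisition_id Override for the acquisition id.
#' @return A [profile_spectrum()].
#' @export
read_peaklist <- function(path, scan_range_id = "", acquisition_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines_trim <- trimws(lines)
  keep <- nzchar(lines_trim)
  if (!any(keep)) stop("empty peak list: ", path, call. = FALSE)
  idx <- which(keep)
  first <- idx[1]
  parse_row <- function(s) suppressWarnings(as.numeric(strsplit(s, "[\t ,]+")[[1]]))
  start <- first
  v <- parse_row(lines_trim[first])
  if (anyNA(v)) start <- first + 1  # header line
  data_idx <- idx[idx >= start]
  if (length(data_idx) == 0) stop("empty peak list: ", path, call. = FALSE)
  vals <- lapply(lines_trim[data_idx], parse_row)
  bad <- vapply(vals, function(v) length(v) != 2 || anyNA(v), logical(1))
  if (any(bad)) {
    stop("non-numeric or malformed row at line ", data_idx[which(bad)[1]],
         " of ", path, call. = FALSE)
  }
  m <- do.call(rbind, vals)
  if (is.null(acquisition_id)) {
    acquisition_id <- sub("\\.[^.]*$", "", basename(path))
  }
  profile_spectrum(m[, 1], m[, 2], acquisition_id = acquisition_id,
                   scan_range_id = scan_range_id)
}

#' Write a profile spectrum as a two-column text file
#' @param spectrum A [profile_spectrum()].
#' @param path Output path.
#' @export
write_peaklist <- function(spectrum, path) {
  write.table(
    data.frame(mz = sprintf("%.6f", spectrum$mz),
               intensity = sprintf("%.4f", spectrum$intensity)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read profile spectra from an mzML file
#'
#' Thin wrapper over the Bioconductor `mzR` reader. Spectra are grouped into
#' scan ranges by their recorded low/high m/z bounds
#' (`"<polarity>FTMS <low>-<high>"`).
#'
#' @param path mzML file path.
#' @return List of [profile_spectrum()] objects.
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package", call. = FALSE)
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  acquisition_id <- sub("\\.[^.]*$", "", basename(path))
  lapply(seq_len(nrow(hdr)), function(i) {
    pk <- mzR::peaks(handle, i)
    pol <- if (!is.null(hdr$polarity) && hdr$polarity[i] < 0) "-" else "+"
    rid <- sprintf("%sFTMS %d-%d", pol, round(hdr$lowMZ[i]), round(hdr$highMZ[i]))
    profile_spectrum(pk[, 1], pk[, 2], acquisition_id = acquisition_id,
                     scan_range_id = rid)
  })
}

#' Average repeated profile scans of one scan range
#'
#' When all scans share an identical m/z grid the intensities are averaged
#' point-wise. Otherwise each scan is linearly interpolated onto the first
#' scan's grid (zero outside its own support) before averaging; the reference
#' grid is preserved exactly.
#'
#' @param scans List of [profile_spectrum()] objects with a common
#'   `scan_range_id`.
#' @return A single averaged [profile_spectrum()].
#' @export
average_scans <- function(scans) {
  if (length(scans) == 0) stop("no scans to average", call. = FALSE)
  rid <- unique(vapply(scans, function(s) s$scan_range_id, character(1)))
  if (length(rid) != 1) {
    stop("cannot average scans from mixed scan ranges: ",
         paste(rid, collapse = ", "), call. = FALSE)
  }
  ref <- scans[[1]]
  if (length(scans) == 1) return(ref)
  same_grid <- all(vapply(scans[-1], function(s) {
    length(s$mz) == length(ref$mz) && all(s$mz == ref$mz)
  }, logical(1)))
  if (same_grid) {
    total <- Reduce(`+`, lapply(scans, function(s) s$intensity))
  } else {
    total <- Reduce(`+`, lapply(scans, function(s) {
      stats::approx(s$mz, s$intensity, xout = ref$mz, method = "linear",
                    yleft = 0, yright = 0)$y
    }))
  }
  profile_spectrum(ref$mz, total / length(scans),
                   acquisition_id = ref$acquisition_id, scan_range_id = rid)
}

#' Organize acquisitions into per-scan-range folders of averaged peak lists
#'
#' Mirrors the converter output layout: one folder per FT MS scan range,
#' inside which each acquisition contributes one averaged peak-list `.txt`
#' named after its source. Overlapping scan ranges are never merged.
#'
#' @param aset Acquisition set: a list of acquisitions, each a list with
#'   `acquisition_id` and `scans`, a named list mapping scan_range_id to a
#'   list of [profile_spectrum()] scans.
#' @param out_dir Output directory.
#' @return Manifest tibble (`scan_range_id`, `folder`, `file`,
#'   `acquisition_id`, `n_scans`).
#' @export
organize_acquisitions <- function(aset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  seen <- character(0)
  for (acq in aset) {
    if (length(acq$scans) == 0) {
      stop("acquisition ", acq$acquisition_id, " has no scans", call. = FALSE)
    }
    for (rid in names(acq$scans)) {
      folder <- scan_range_folder(rid)
      dir.create(file.path(out_dir, folder), showWarnings = FALSE)
      file <- paste0(acq$acquisition_id, ".txt")
      key <- file.path(folder, file)
      if (key %in% seen) stop("peak list name collision: ", key, call. = FALSE)
      seen <- c(seen, key)
      avg <- average_scans(acq$scans[[rid]])
      write_peaklist(avg, file.path(out_dir, folder, file))
      rows[[length(rows) + 1]] <- tibble::tibble(
        scan_range_id = rid, folder = folder, file = file,
        acquisition_id = acq$acquisition_id,
        n_scans = length(acq$scans[[rid]]))
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(scan_range_id = character(), folder = character(),
                          file = character(), acquisition_id = character(),
                          n_scans = integer()))
  }
  dplyr::bind_rows(rows)
}

# file-system-safe folder name for a scan range id
scan_range_folder <- function(scan_range_id) {
  gsub("[^A-Za-z0-9+-]+", "_", scan_range_id)
}

#' Read every averaged peak list under a converter-style folder tree
#'
#' @param dir Directory produced by [organize_acquisitions()].
#' @param scan_ranges Named character vector mapping folder name to
#'   scan_range_id; by default folder names with `_` restored to a space.
#' @return List of [profile_spectrum()] objects.
#' @export
read_acquisition_tree <- function(dir, scan_ranges = NULL) {
  folders <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
  out <- list()
  for (folder in folders) {
    rid <- if (!is.null(scan_ranges) && folder %in% names(scan_ranges)) {
      scan_ranges[[folder]]
    } else {
      gsub("_", " ", folder)
    }
    files <- sort(list.files(file.path(dir, folder), pattern = "\\.txt$"))
    for (f in files) {
      out[[length(out) + 1]] <- read_peaklist(file.path(dir, folder, f),
                                              scan_range_id = rid)
    }
  }
  out
}
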