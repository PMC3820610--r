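#' @importFrom rlang .data
#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.table write.table head tail
NULL

# Monoisotopic atomic masses (Da), IUPAC values, and the electron mass.
# Frozen here so that 5-decimal ion m/z values are reproducible.
.ELEMENT_MASSES <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809
)

.ELECTRON_MASS <- 0.00054857990946

# Heavy-isotope distributions per element: nominal mass shift -> abundance.
# Shift 0 (the monoisotopic peak) is implied as 1 - sum(heavier).
.ISOTOPE_SHIFTS <- list(
  C  = c("1" = 0.0107),
  H  = c("1" = 0.000115),
  N  = c("1" = 0.00364),
  O  = c("1" = 0.00038, "2" = 0.00205),
  P  = c(),
  S  = c("1" = 0.0075, "2" = 0.0425, "4" = 0.0001),
  Na = c()
)

#' Atomic constants used for mass calculations
#'
#' Returns the frozen table of monoisotopic atomic masses, the electron mass
#' and per-element heavy-isotope abundances used throughout the package.
#'
#' @return A list with elements `masses` (named numeric, Da), `electron_mass`
#'   (Da) and `isotope_shifts` (per-element named vectors of abundance by
#'   nominal mass shift).
#' @export
atomic_mass_table <- function() {
  list(
    masses = .ELEMENT_MASSES,
    electron_mass = .ELECTRON_MASS,
    isotope_shifts = .ISOTOPE_SHIFTS
  )
}

#' Construct an elemental composition
#'
#' An elemental composition is a named integer vector mapping element symbols
#' to non-negative atom counts. Only the elements in [atomic_mass_table()] are
#' recognised.
#'
#' @param counts Named numeric vector of atom counts.
#' @param allow_negative Permit negative counts (used internally for adduct
#'   deltas); user-facing compositions must be non-negative.
#' @return Named integer vector of class `elemental_composition`, with
#'   zero-count elements dropped and elements in a canonical order.
#' @export
composition <- function(counts = c(), allow_negative = FALSE) {
  if (length(counts) == 0) {
    out <- integer(0)
    names(out) <- character(0)
    class(out) <- "elemental_composition"
    return(out)
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("composition counts must be named by element symbol", call. = FALSE)
  }
  unknown <- setdiff(names(counts), names(.ELEMENT_MASSES))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts != round(counts))) {
    stop("atom counts must be integers", call. = FALSE)
  }
  if (!allow_negative && any(counts < 0)) {
    stop("atom counts must be non-negative", call. = FALSE)
  }
  # canonical Hill-ish order: C, H, then alphabetical
  counts <- tapply(counts, names(counts), sum)
  ord <- intersect(c("C", "H", sort(setdiff(names(.ELEMENT_MASSES), c("C", "H")))),
                   names(counts))
  out <- as.integer(counts[ord])
  names(out) <- ord
  out <- out[out != 0L]
  class(out) <- "elemental_composition"
  out
}

#' Parse a chemical formula string
#'
#' @param text Formula such as `"C40H80NO8P"`; an absent count means one atom.
#' @return An [composition()] object.
#' @examples
#' parse_formula("C40H80NO8P")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    stop("formula must be a single character string", call. = FALSE)
  }
  text <- trimws(text)
  if (!nzchar(text)) return(composition())
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("malformed formula string: '", text, "'", call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", tokens)
  num <- sub("^[A-Z][a-z]?", "", tokens)
  cnt <- ifelse(nzchar(num), suppressWarnings(as.integer(num)), 1L)
  unknown <- setdiff(sym, names(.ELEMENT_MASSES))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unique(unknown), collapse = ", "),
         call. = FALSE)
  }
  composition(setNames(cnt, sym))
}

#' Combine two compositions element-wise
#'
#' @param a,b Compositions (or formula strings).
#' @param sign `+1` to add `b`, `-1` to subtract it.
#' @return The combined composition; subtracting more atoms than available is
#'   an error.
#' @export
comp_combine <- function(a, b, sign = 1L) {
  a <- as_composition(a)
  b <- as_composition(b)
  all_el <- union(names(a), names(b))
  va <- setNames(rep(0L, length(all_el)), all_el)
  va[names(a)] <- as.integer(a)
  vb <- setNames(rep(0L, length(all_el)), all_el)
  vb[names(b)] <- as.integer(b)
  res <- va + sign * vb
  if (any(res < 0)) {
    neg <- all_el[res < 0]
    stop("composition arithmetic yields negative count for: ",
         paste(neg, collapse = ", "), call. = FALSE)
  }
  composition(res)
}

#' Scale a composition by an integer factor
#' @param comp Composition or formula string.
#' @param k Non-negative integer multiplier.
#' @export
comp_scale <- function(comp, k) {
  comp <- as_composition(comp)
  stopifnot(k >= 0, k == round(k))
  composition(setNames(as.integer(comp) * as.integer(k), names(comp)))
}

#' Coerce to an elemental composition
#' @param x A composition or a formula string.
#' @export
as_composition <- function(x) {
  if (inherits(x, "elemental_composition")) return(x)
  if (is.character(x)) return(parse_formula(x))
  if (is.numeric(x)) return(composition(x))
  stop("cannot coerce to elemental composition", call. = FALSE)
}

#' Format a composition as a formula string
#' @param comp Composition.
#' @return A string such as `"C40H80NO8P"` (count 1 omitted).
#' @export
format_composition <- function(comp) {
  comp <- as_composition(comp)
  if (length(comp) == 0) return("")
  paste0(names(comp), ifelse(as.integer(comp) == 1L, "", as.integer(comp)),
         collapse = "")
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("<elemental composition> ", format_composition(x), "\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a composition
#'
#' Sum of atom counts times frozen monoisotopic atomic masses; full floating
#' precision, no rounding.
#'
#' @param comp Composition or formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")
#' @export
monoisotopic_mass <- function(comp) {
  comp <- as_composition(comp)
  if (length(comp) == 0) return(0.0)
  sum(.ELEMENT_MASSES[names(comp)] * as.numeric(comp))
}

#' Default adduct catalog
#'
#' Singly charged adducts used in positive and negative ion mode shotgun
#' lipidomics. The `delta_sign` column states whether the delta composition is
#' added to or removed from the neutral molecule.
#'
#' @return Tibble with columns `name`, `delta_formula`, `delta_sign`,
#'   `charge`, `polarity`.
#' @export
default_adducts <- function() {
  tibble::tibble(
    name          = c("+H", "+NH4", "+Na", "-H", "-CH3"),
    delta_formula = c("H", "NH4", "Na", "H", "CH3"),
    delta_sign    = c(1L, 1L, 1L, -1L, -1L),
    charge        = c(1L, 1L, 1L, -1L, -1L),
    polarity      = c("positive", "positive", "positive", "negative", "negative")
  )
}

#' Read an adduct catalog from a tab-separated file
#'
#' Columns: name, delta_formula, delta_sign, charge, polarity.
#' @param path File path.
#' @export
read_adducts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  req <- c("name", "delta_formula", "delta_sign", "charge", "polarity")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("adduct file missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  adducts <- tibble::as_tibble(df[req])
  validate_adducts(adducts)
  adducts
}

validate_adducts <- function(adducts) {
  if (any(adducts$charge == 0)) stop("adduct charge must be non-zero", call. = FALSE)
  ok <- (adducts$charge > 0) == (adducts$polarity == "positive")
  if (!all(ok)) {
    stop("adduct polarity inconsistent with charge sign for: ",
         paste(adducts$name[!ok], collapse = ", "), call. = FALSE)
  }
  invisible(adducts)
}

lookup_adduct <- function(adduct_name, adducts = default_adducts()) {
  i <- match(adduct_name, adducts$name)
  if (is.na(i)) stop("unknown adduct: ", adduct_name, call. = FALSE)
  as.list(adducts[i, ])
}

#' Adduct ion m/z
#'
#' m/z of the ion formed by applying an adduct to a neutral molecule:
#' `(mass(M +/- delta) - z * m_e) / |z|`. The electron mass is always
#' subtracted for positive ions and added for negative ions; this correction
#' is required to reproduce printed 5-decimal FT MS values.
#'
#' @param comp Neutral composition or formula string.
#' @param adduct Adduct name (looked up in `adducts`) or a one-row adduct
#'   specification as returned by [default_adducts()].
#' @param adducts Adduct catalog.
#' @return m/z in Da (full precision; round for display).
#' @examples
#' ion_mz("C54H98O6", "+NH4") # 860.77017 at 5 decimals
#' @export
ion_mz <- function(comp, adduct, adducts = default_adducts()) {
  comp <- as_composition(comp)
  a <- if (is.character(adduct)) lookup_adduct(adduct, adducts) else as.list(adduct)
  ion <- comp_combine(comp, parse_formula(a$delta_formula), sign = a$delta_sign)
  (monoisotopic_mass(ion) - a$charge * .ELECTRON_MASS) / abs(a$charge)
}

# per-atom isotopologue distribution for one element (index i = shift i-1)
.atom_dist <- function(element) {
  heavy <- .ISOTOPE_SHIFTS[[element]]
  if (length(heavy) == 0) return(1.0)
  shifts <- as.integer(names(heavy))
  d <- numeric(max(shifts) + 1L)
  d[1] <- 1 - sum(heavy)
  d[shifts + 1L] <- heavy
  d
}

# truncated polynomial product of two distributions
.conv_trunc <- function(a, b, n) {
  la <- length(a); lb <- length(b)
  out <- numeric(min(n, la + lb - 1L))
  for (i in seq_len(la)) {
    jmax <- min(lb, length(out) - i + 1L)
    if (jmax < 1) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

# distribution^k by exponentiation with truncation to n terms
.dist_power <- function(d, k, n) {
  result <- 1.0
  base <- d
  while (k > 0) {
    if (k %% 2 == 1) result <- .conv_trunc(result, base, n)
    k <- k %/% 2
    if (k > 0) base <- .conv_trunc(base, base, n)
  }
  result
}

#' Isotopologue envelope of a composition
#'
#' Relative abundances of the M+0 ... M+(n-1) isotopologue peaks from the
#' polynomial expansion over per-element heavy-isotope abundances (13C, 2H,
#' 15N, 17/18O, 33/34S). Abundances are fractions of all isotopologues, so
#' they sum to at most 1; `normalize = TRUE` rescales the returned prefix to
#' sum to 1.
#'
#' @param comp Composition or formula string.
#' @param n_peaks Number of peaks (>= 1).
#' @param normalize Rescale the returned abundances to sum to 1.
#' @return Numeric vector of length `n_peaks`.
#' @examples
#' isotope_envelope("C40H80NO8P", 3)
#' @export
isotope_envelope <- function(comp, n_peaks = 3, normalize = FALSE) {
  stopifnot(n_peaks >= 1)
  comp <- as_composition(comp)
  env <- 1.0
  for (el in names(comp)) {
    env <- .conv_trunc(env, .dist_power(.atom_dist(el), as.integer(comp[el]), n_peaks),
                       n_peaks)
  }
  out <- numeric(n_peaks)
  out[seq_along(env)] <- env
  if (normalize) {
    s <- sum(out)
    if (s > 0) out <- out / s
  }
  out
}
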