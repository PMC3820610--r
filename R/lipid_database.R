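#' Default lipid class templates
#'
#' Building-block templates for the 20 lipid classes routinely monitored in
#' multiplexed positive/negative ion mode FT MS analysis of tissue extracts.
#' A species formula is assembled as
#' `backbone + sum(chains) - n_chains * H2O (+ ether adjustment)` for
#' acyl-chain classes, where a summed fatty-acyl moiety of C index `c` and
#' db index `db` contributes `C_c H_(2c-2db) O_(2*n_chains)`. Ether classes
#' (`PC O-`, `PE O-`) replace one ester bond by an ether bond, a net
#' `+H2 -O` adjustment. Sphingolipid classes use a long-chain-base core
#' contributing `C_c H_(2c+1-2db) N O_(oh+1)` plus a class head group.
#'
#' Each template also carries the class's lipid category, its allowed
#' adducts, the annotation grammar (with or without an OH index) and default
#' enumeration ranges for the C, db and OH indices.
#'
#' @return Tibble with one row per lipid class.
#' @export
default_lipid_classes <- function() {
  t <- tibble::tribble(
    ~class,     ~category,             ~backbone,     ~n_chains, ~chain_kind, ~ether, ~adducts,   ~c_min, ~c_max, ~db_min, ~db_max, ~oh_min, ~oh_max,
    "LPC",      "glycerophospholipid", "C8H20NO6P",   1L, "acyl",      0L, "+H",    14L, 22L, 0L, 6L, 0L, 0L,
    "LPE",      "glycerophospholipid", "C5H14NO6P",   1L, "acyl",      0L, "+H",    14L, 22L, 0L, 6L, 0L, 0L,
    "PC",       "glycerophospholipid", "C8H20NO6P",   2L, "acyl",      0L, "+H",    28L, 44L, 0L, 6L, 0L, 0L,
    "PC O-",    "glycerophospholipid", "C8H20NO6P",   2L, "acyl",      1L, "+H",    28L, 44L, 0L, 6L, 0L, 0L,
    "PE",       "glycerophospholipid", "C5H14NO6P",   2L, "acyl",      0L, "+H",    28L, 44L, 0L, 6L, 0L, 0L,
    "PE O-",    "glycerophospholipid", "C5H14NO6P",   2L, "acyl",      1L, "+H",    28L, 44L, 0L, 6L, 0L, 0L,
    "LPA",      "glycerophospholipid", "C3H9O6P",     1L, "acyl",      0L, "-H",    14L, 22L, 0L, 6L, 0L, 0L,
    "LPS",      "glycerophospholipid", "C6H14NO8P",   1L, "acyl",      0L, "-H",    14L, 22L, 0L, 6L, 0L, 0L,
    "LPI",      "glycerophospholipid", "C9H19O11P",   1L, "acyl",      0L, "-H",    14L, 22L, 0L, 6L, 0L, 0L,
    "PA",       "glycerophospholipid", "C3H9O6P",     2L, "acyl",      0L, "-H",    28L, 44L, 0L, 6L, 0L, 0L,
    "PS",       "glycerophospholipid", "C6H14NO8P",   2L, "acyl",      0L, "-H",    28L, 44L, 0L, 6L, 0L, 0L,
    "PI",       "glycerophospholipid", "C9H19O11P",   2L, "acyl",      0L, "-H",    28L, 44L, 0L, 6L, 0L, 0L,
    "PG",       "glycerophospholipid", "C6H15O8P",    2L, "acyl",      0L, "-H",    28L, 44L, 0L, 6L, 0L, 0L,
    "DAG",      "glycerolipid",        "C3H8O3",      2L, "acyl",      0L, "+NH4",  30L, 44L, 0L, 6L, 0L, 0L,
    "TAG",      "glycerolipid",        "C3H8O3",      3L, "acyl",      0L, "+NH4",  40L, 60L, 0L, 10L, 0L, 0L,
    "CE",       "sterol lipid",        "C27H46O",     1L, "acyl",      0L, "+NH4",  14L, 22L, 0L, 6L, 0L, 0L,
    "Cer",      "sphingolipid",        "",            1L, "sphingoid", 0L, "+H",    30L, 44L, 0L, 3L, 2L, 2L,
    "SM",       "sphingolipid",        "C5H12NO3P",   1L, "sphingoid", 0L, "+H",    30L, 44L, 0L, 3L, 2L, 2L,
    "HexCer",   "sphingolipid",        "C6H10O5",     1L, "sphingoid", 0L, "+H",    28L, 44L, 0L, 3L, 2L, 2L,
    "SHexCer",  "sphingolipid",        "C6H10O8S",    1L, "sphingoid", 0L, "-H",    28L, 44L, 0L, 3L, 2L, 2L
  )
  t
}

# formula of one species from a class template
.species_formula <- function(template, c_index, db_index, oh_index) {
  if (template$chain_kind == "sphingoid") {
    core <- composition(c(
      C = c_index,
      H = 2 * c_index + 1 - 2 * db_index,
      N = 1,
      O = oh_index + 1
    ))
    if (nzchar(template$backbone)) {
      core <- comp_combine(core, template$backbone)
    }
    return(core)
  }
  n <- template$n_chains
  chains <- composition(c(C = c_index, H = 2 * c_index - 2 * db_index, O = 2 * n))
  f <- comp_combine(template$backbone, chains)
  f <- comp_combine(f, comp_scale("H2O", n), sign = -1L)
  if (template$ether > 0) {
    f <- comp_combine(f, comp_scale("H2", template$ether))
    f <- comp_combine(f, comp_scale("O", template$ether), sign = -1L)
  }
  f
}

#' Sum-composition species name
#'
#' Glycerophospholipid/glycerolipid/sterol grammar: `"<class> <C>:<db>"`
#' (e.g. `PI 34:1`); sphingolipid grammar: `"<class> <C>:<db>;<OH>"`
#' (e.g. `SM 36:1;2`). For ether classes whose name ends in `"-"` the index
#' block is appended without a space (`PC O-34:1`).
#'
#' @param class_name Lipid class name.
#' @param c_index,db_index,oh_index Summed chain indices.
#' @param sphingoid Use the OH-index grammar.
#' @return Character vector of species names.
#' @export
annotate_species <- function(class_name, c_index, db_index, oh_index = 0,
                             sphingoid = FALSE) {
  sep <- ifelse(endsWith(class_name, "-"), "", " ")
  base <- paste0(class_name, sep, c_index, ":", db_index)
  ifelse(rep(sphingoid, length.out = length(base)),
         paste0(base, ";", oh_index), base)
}

#' Parse a sum-composition species name
#'
#' Inverse of [annotate_species()].
#'
#' @param name Species name, e.g. `"PC 34:1"`, `"SM 36:1;2"`, `"PC O-34:1"`.
#' @return A list with `class`, `c_index`, `db_index`, `oh_index` (NA when
#'   the name has no OH block).
#' @export
parse_annotation <- function(name) {
  m <- regmatches(name, regexec("^(.*?)[ ]?([0-9]+):([0-9]+)(;([0-9]+))?$", name,
                                perl = TRUE))[[1]]
  if (length(m) == 0) stop("cannot parse species name: '", name, "'", call. = FALSE)
  cls <- m[2]
  # ether classes carry a trailing "-" glued to the C index
  list(
    class = cls,
    c_index = as.integer(m[3]),
    db_index = as.integer(m[4]),
    oh_index = if (nzchar(m[6])) as.integer(m[6]) else NA_integer_
  )
}

#' Enumerate sum-composition species for one lipid class
#'
#' One species per (C, db, OH) combination within the inclusive ranges that
#' passes the double-bond sanity cap (`db <= floor(c * max_db_per_c)` by
#' default).
#'
#' @param template One-row tibble from [default_lipid_classes()].
#' @param c_range,db_range,oh_range Integer vectors of indices to enumerate
#'   (defaults taken from the template).
#' @param max_db_per_c Double-bond cap as a fraction of the C index
#'   (default 0.5, i.e. `db <= floor(c/2)`).
#' @return Tibble of species with formula, monoisotopic mass and accessory
#'   features.
#' @export
enumerate_class <- function(template,
                            c_range = NULL, db_range = NULL, oh_range = NULL,
                            max_db_per_c = 0.5) {
  template <- as.list(template)
  if (is.null(c_range)) c_range <- seq(template$c_min, template$c_max)
  if (is.null(db_range)) db_range <- seq(template$db_min, template$db_max)
  if (is.null(oh_range)) oh_range <- seq(template$oh_min, template$oh_max)
  empty <- tibble::tibble(
    species_name = character(), class = character(), category = character(),
    c_index = integer(), db_index = integer(), oh_index = integer(),
    formula = character(), mono_mass = numeric(), adducts = character()
  )
  if (length(c_range) == 0 || length(db_range) == 0 || length(oh_range) == 0) {
    return(empty)
  }
  grid <- expand.grid(c_index = as.integer(c_range),
                      db_index = as.integer(db_range),
                      oh_index = as.integer(oh_range))
  grid <- grid[grid$db_index <= floor(grid$c_index * max_db_per_c), , drop = FALSE]
  if (nrow(grid) == 0) return(empty)
  sphingoid <- template$chain_kind == "sphingoid"
  formulas <- character(nrow(grid))
  masses <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    f <- .species_formula(template, grid$c_index[i], grid$db_index[i],
                          grid$oh_index[i])
    formulas[i] <- format_composition(f)
    masses[i] <- monoisotopic_mass(f)
  }
  out <- tibble::tibble(
    species_name = annotate_species(template$class, grid$c_index, grid$db_index,
                                    grid$oh_index, sphingoid = sphingoid),
    class = template$class,
    category = template$category,
    c_index = grid$c_index,
    db_index = grid$db_index,
    oh_index = grid$oh_index,
    formula = formulas,
    mono_mass = masses,
    adducts = template$adducts
  )
  dplyr::arrange(out, .data$c_index, .data$db_index, .data$oh_index)
}

#' Build a sum-composition lipid database
#'
#' Union of [enumerate_class()] over all class templates. Keys
#' (class, C, db, OH) are unique; species names round-trip through the
#' annotation grammar.
#'
#' @param templates Class template tibble; defaults to
#'   [default_lipid_classes()].
#' @param max_db_per_c Double-bond sanity cap passed to [enumerate_class()].
#' @return Tibble of class `lipid_database`.
#' @export
build_lipid_database <- function(templates = default_lipid_classes(),
                                 max_db_per_c = 0.5) {
  if (anyDuplicated(templates$class)) {
    stop("duplicate class names in templates", call. = FALSE)
  }
  parts <- lapply(seq_len(nrow(templates)), function(i) {
    enumerate_class(templates[i, ], max_db_per_c = max_db_per_c)
  })
  db <- dplyr::bind_rows(parts)
  key <- paste(db$class, db$c_index, db$db_index, db$oh_index)
  if (anyDuplicated(key)) stop("database key collision", call. = FALSE)
  class(db) <- c("lipid_database", class(db))
  db
}

#' Look up one database species by name
#' @param db Lipid database.
#' @param species_name Sum-composition species name.
#' @return One-row tibble.
#' @export
db_species <- function(db, species_name) {
  i <- match(species_name, db$species_name)
  if (is.na(i)) stop("unknown species: '", species_name, "'", call. = FALSE)
  db[i, ]
}

#' Write a lipid database as a collection of text files
#'
#' One tab-separated file per lipid class (named after the class with
#' characters unsafe in file names replaced) plus an `index.tsv` mapping
#' class names to files. A database written and re-read compares equal.
#'
#' @param db Lipid database.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the index tibble.
#' @export
write_lipid_database <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  classes <- unique(db$class)
  files <- paste0(gsub("[^A-Za-z0-9_-]+", "_", classes), ".tsv")
  if (anyDuplicated(files)) stop("class file name collision", call. = FALSE)
  for (i in seq_along(classes)) {
    part <- db[db$class == classes[i], ]
    write.table(as.data.frame(part), file.path(dir, files[i]),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  index <- tibble::tibble(class = classes, file = files)
  write.table(as.data.frame(index), file.path(dir, "index.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(index)
}

#' Read a lipid database written by [write_lipid_database()]
#' @param dir Directory containing `index.tsv` and per-class files.
#' @return Tibble of class `lipid_database`.
#' @export
read_lipid_database <- function(dir) {
  index <- read.table(file.path(dir, "index.tsv"), header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  parts <- lapply(index$file, function(f) {
    tibble::as_tibble(read.table(file.path(dir, f), header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE,
                                 colClasses = c(
                                   species_name = "character", class = "character",
                                   category = "character", c_index = "integer",
                                   db_index = "integer", oh_index = "integer",
                                   formula = "character", mono_mass = "numeric",
                                   adducts = "character")))
  })
  db <- dplyr::bind_rows(parts)
  class(db) <- c("lipid_database", class(db))
  db
}
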