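hi_pos <- list(id = "+FTMS 500-1200", low = 500, high = 1200)

test_that("index predicates select the expected species", {
  tl <- generate_target_list(TEST_DB, hi_pos, classes = "PC",
                             c_range = 32, db_range = 0:1)
  expect_equal(sort(tl$species_name), c("PC 32:0", "PC 32:1"))
  expect_true(all(tl$adduct == "+H"))
})

test_that("scan range bounds exclude out-of-range ions", {
  tl <- generate_target_list(TEST_DB, hi_pos, classes = c("LPC", "PC"))
  expect_true(all(tl$theoretical_mz >= 500 & tl$theoretical_mz <= 1200))
  # short-chain LPC ions sit below m/z 500 and are excluded
  expect_false("LPC 14:0" %in% tl$species_name)
  expect_true("LPC 14:0" %in% TEST_DB$species_name)
})

test_that("filters are monotone: widening a C range never removes entries", {
  narrow <- generate_target_list(TEST_DB, hi_pos, classes = "PC",
                                 c_range = 32:36)
  wide <- generate_target_list(TEST_DB, hi_pos, classes = "PC",
                               c_range = 30:40)
  expect_true(all(paste(narrow$species_name, narrow$adduct) %in%
                    paste(wide$species_name, wide$adduct)))
})

test_that("entries are internally consistent with the mass calculator", {
  tl <- generate_target_list(TEST_DB, hi_pos,
                             classes = c("PC", "TAG", "SM"))
  set.seed(3)
  for (i in sample(nrow(tl), 20)) {
    expect_equal(tl$theoretical_mz[i], ion_mz(tl$formula[i], tl$adduct[i]),
                 tolerance = 1e-9)
  }
  expect_false(anyDuplicated(paste(tl$species_name, tl$adduct)) > 0)
  expect_true(all(tl$isotope_m0 > 0 & tl$isotope_m0 <= 1))
})

test_that("standards and lock masses are carried with their roles", {
  std <- tibble::tibble(species_name = "TAG 51:3", label = "TAG 17:1/17:1/17:1")
  locks <- tibble::tibble(
    name = c("tris(ditert-butylphenyl) phosphate", "TAG 17:1/17:1/17:1"),
    species_name = c(NA, "TAG 17:1/17:1/17:1"),
    formula = c("C42H63O4P", "C54H98O6"),
    adduct = "+NH4")
  tl <- generate_target_list(TEST_DB, hi_pos, classes = "PC",
                             standards = std, locks = locks)
  is_row <- tl[tl$is_internal_standard, ]
  expect_equal(is_row$species_name, "TAG 17:1/17:1/17:1")
  expect_true(is_row$is_lock_mass)           # the IS doubles as a lock
  bg <- tl[tl$is_lock_mass & !tl$is_internal_standard, ]
  expect_equal(round(bg$theoretical_mz, 5), 680.48022)
  # out-of-range lock (by formula) is dropped silently
  low_pos <- list(id = "+FTMS 280-580", low = 280, high = 580)
  tl2 <- generate_target_list(TEST_DB, low_pos, classes = "LPC", locks = locks)
  expect_equal(sum(tl2$is_lock_mass), 0)
})

test_that("unknown classes and species are rejected", {
  expect_error(generate_target_list(TEST_DB, hi_pos, classes = "XX"),
               "unknown class")
  expect_error(generate_target_list(TEST_DB, hi_pos, classes = "PC",
                                    species = "PC 999:0"),
               "absent from database")
})

test_that("target lists round-trip through their text format", {
  tl <- generate_target_list(TEST_DB, hi_pos, classes = c("PC", "SM"),
                             c_range = 30:36)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_target_list(tl, f)
  back <- read_target_list(f)
  expect_equal(attr(back, "scan_range_id"), "+FTMS 500-1200")
  expect_equal(attr(back, "mz_low"), 500)
  expect_equal(back$species_name, tl$species_name)
  expect_equal(back$theoretical_mz, tl$theoretical_mz, tolerance = 1e-6)
  expect_equal(back$is_lock_mass, tl$is_lock_mass)
})
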