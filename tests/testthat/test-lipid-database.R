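pc_template <- default_lipid_classes()[default_lipid_classes()$class == "PC", ]
tag_template <- default_lipid_classes()[default_lipid_classes()$class == "TAG", ]

test_that("building-block arithmetic reproduces reference formulas", {
  # glycerophosphocholine backbone + 2 x C16H32O2 - 2 x H2O
  pc <- enumerate_class(pc_template, c_range = 32, db_range = 0)
  expect_equal(nrow(pc), 1)
  expect_equal(pc$formula, "C40H80NO8P")
  # glycerol + 3 fatty acids - 3 H2O
  tag <- enumerate_class(tag_template, c_range = 51, db_range = 3)
  expect_equal(tag$formula, "C54H98O6")
  # sphingolipid: ceramide d18:1/17:0 at sum composition 35:1;2
  cer_t <- default_lipid_classes()[default_lipid_classes()$class == "Cer", ]
  cer <- enumerate_class(cer_t, c_range = 35, db_range = 1, oh_range = 2)
  expect_equal(cer$formula, "C35H69NO3")
  # ether PC replaces one ester bond: +H2 -O relative to diacyl
  pco_t <- default_lipid_classes()[default_lipid_classes()$class == "PC O-", ]
  pco <- enumerate_class(pco_t, c_range = 34, db_range = 1)
  expect_equal(pco$formula, "C42H84NO7P")
})

test_that("empty ranges yield empty enumerations and the db cap filters", {
  expect_equal(nrow(enumerate_class(pc_template, c_range = integer(0))), 0)
  # db <= floor(c/2): c = 5 cannot carry 3 double bonds
  few <- enumerate_class(pc_template, c_range = 5, db_range = 0:3)
  expect_true(all(few$db_index <= 2))
})

test_that("mass ladders step by CH2 across C and by H2 across double bonds", {
  ch2 <- monoisotopic_mass("CH2")
  h2 <- monoisotopic_mass("H2")
  sp <- enumerate_class(pc_template, c_range = 30:40, db_range = 0:4)
  for (dbi in 0:4) {
    ladder <- sp[sp$db_index == dbi, ]
    ladder <- ladder[order(ladder$c_index), ]
    expect_equal(diff(ladder$mono_mass), rep(ch2, nrow(ladder) - 1),
                 tolerance = 1e-10)
  }
  for (ci in c(30, 36, 40)) {
    ladder <- sp[sp$c_index == ci, ]
    ladder <- ladder[order(ladder$db_index), ]
    expect_equal(diff(ladder$mono_mass), rep(-h2, nrow(ladder) - 1),
                 tolerance = 1e-10)
  }
})

test_that("annotation grammar matches conventions and round-trips", {
  expect_equal(annotate_species("PI", 34, 1), "PI 34:1")
  expect_equal(annotate_species("SM", 36, 1, 2, sphingoid = TRUE), "SM 36:1;2")
  expect_equal(annotate_species("PC O-", 34, 1), "PC O-34:1")
  for (i in seq(1, nrow(TEST_DB), by = 17)) {
    p <- parse_annotation(TEST_DB$species_name[i])
    expect_equal(p$class, TEST_DB$class[i])
    expect_equal(p$c_index, TEST_DB$c_index[i])
    expect_equal(p$db_index, TEST_DB$db_index[i])
    if (!is.na(p$oh_index)) expect_equal(p$oh_index, TEST_DB$oh_index[i])
  }
})

test_that("database build is keyed uniquely and save/load round-trips", {
  key <- paste(TEST_DB$class, TEST_DB$c_index, TEST_DB$db_index, TEST_DB$oh_index)
  expect_false(anyDuplicated(key) > 0)
  dir <- withr::local_tempdir()
  write_lipid_database(TEST_DB, dir)
  back <- read_lipid_database(dir)
  expect_equal(as.data.frame(back)[order(back$species_name), ],
               as.data.frame(TEST_DB)[order(TEST_DB$species_name), ],
               ignore_attr = TRUE)
  dup <- dplyr::bind_rows(default_lipid_classes(), default_lipid_classes()[1, ])
  expect_error(build_lipid_database(dup), "duplicate class")
})

test_that("every database species has a finite positive ion m/z", {
  ions <- shotgunlipids:::db_ion_table(TEST_DB)
  expect_true(all(is.finite(ions$theoretical_mz)))
  expect_true(all(ions$theoretical_mz > 0))
  expect_setequal(unique(TEST_DB$class),
                  c("LPC", "LPE", "SM", "Cer", "DAG", "PC", "PC O-", "PE",
                    "PE O-", "TAG", "LPA", "LPS", "LPI", "PA", "PS", "PI",
                    "PG", "SHexCer", "HexCer", "CE"))
})
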