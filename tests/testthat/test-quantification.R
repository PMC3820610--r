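# minimal long-format result table for quantification unit tests
quant_table <- function() {
  tibble::tibble(
    acquisition_id = rep(c("a1", "a2", "b1"), each = 4),
    scan_range_id = "+FTMS 500-1200",
    rangeID = "+FTMS 500-1200",
    species_name = rep(c("PC 34:1", "PC 32:0", "PI 40:3", "PC 18:3/18:3"), 3),
    adduct = "+H",
    intensity = c(2e6, 1e6, 3e3, 2e6,    # a1
                  4e6, 2e6, 3e3, 4e6,    # a2 (all doubled: scale invariance)
                  0,   0,   3e3, 2e6),   # b1 blank (IS spiked, species absent)
    is_internal_standard = rep(c(FALSE, FALSE, FALSE, TRUE), 3),
    is_lock_mass = FALSE,
    class = "PC",
    isotope_m0 = rep(c(0.60, 0.62, 0.58, 0.61), 3))
}

sample_info_fix <- tibble::tibble(
  acquisition_id = c("a1", "a2", "b1"),
  sample_name = c("s1", "s2", "blank"),
  tissue = c("x", "x", "blank"),
  is_blank = c(FALSE, FALSE, TRUE))

spikes_fix <- tibble::tibble(class = "PC", standard_species = "PC 18:3/18:3",
                             spike_pmol = 137)

test_that("sample-info join preserves rows and rejects unknown acquisitions", {
  tbl <- quant_table()
  j <- join_sample_info(tbl, sample_info_fix)
  expect_equal(nrow(j), nrow(tbl))
  expect_true(all(c("sample_name", "tissue", "is_blank") %in% names(j)))
  expect_equal(j[names(tbl)], tbl)   # original columns unchanged
  expect_error(join_sample_info(
    dplyr::mutate(tbl, acquisition_id = "mystery"), sample_info_fix),
    "mystery")
})

test_that("intensity filter is a strict threshold matching a linear scan", {
  tbl <- quant_table()
  expect_equal(filter_intensity(tbl, 0), tbl)
  expect_equal(nrow(filter_intensity(tbl, 1e12)), 0)
  set.seed(5)
  for (t in c(1, 3e3, 1e6, 2.5e6)) {
    expect_equal(nrow(filter_intensity(tbl, t)), sum(tbl$intensity >= t))
  }
})

test_that("blank subtraction floors at zero and exempts standards", {
  j <- join_sample_info(quant_table(), sample_info_fix)
  s <- subtract_blank(j)
  # background-only species zeroed in all samples
  bg <- s[s$species_name == "PI 40:3" & !s$is_blank, ]
  expect_equal(bg$corrected_intensity, c(0, 0))
  # IS rows keep their raw intensity although blanks contain the IS
  is_rows <- s[s$is_internal_standard & !s$is_blank, ]
  expect_equal(is_rows$corrected_intensity, is_rows$intensity)
  # unaffected species: blank intensity zero
  pc <- s[s$species_name == "PC 34:1" & !s$is_blank, ]
  expect_equal(pc$corrected_intensity, pc$intensity)
  expect_true(all(s$blank_consumed == s$is_blank))
  no_blanks <- j[!j$is_blank, ]
  expect_warning(sb <- subtract_blank(no_blanks), "no blank")
  expect_equal(sb$corrected_intensity, sb$intensity)
})

test_that("type2 isotope correction divides by the monoisotopic fraction", {
  tbl <- quant_table()
  tbl$corrected_intensity <- tbl$intensity
  expect_equal(isotope_correct(tbl, "none"), tbl)
  t2 <- isotope_correct(tbl, "type2")
  expect_equal(t2$corrected_intensity, tbl$intensity / tbl$isotope_m0)
  # composition without heavy-isotope-bearing atoms has M+0 = 1: unchanged
  free <- tbl[1, ]
  free$isotope_m0 <- isotope_envelope("P", 1)[1]
  expect_equal(isotope_correct(free, "type2")$corrected_intensity,
               free$corrected_intensity)
  bad <- tbl; bad$isotope_m0[1] <- 0
  expect_error(isotope_correct(bad, "type2"), "M\\+0")
})

test_that("molar amounts follow the internal-standard ratio equation", {
  j <- join_sample_info(quant_table(), sample_info_fix)
  j$corrected_intensity <- j$intensity
  amt <- compute_amounts(j, spikes_fix)
  a1 <- amt[amt$acquisition_id == "a1", ]
  expect_equal(a1$amount_fmol[a1$species_name == "PC 34:1"], 137000)
  expect_equal(a1$amount_fmol[a1$species_name == "PC 32:0"], 68500)
  # scale invariance: acquisition a2 has all intensities doubled
  a2 <- amt[amt$acquisition_id == "a2", ]
  expect_equal(a2$amount_fmol[a2$species_name == "PC 34:1"], 137000)
  # missing IS: amounts missing, rows retained
  no_is <- j
  no_is$intensity[no_is$acquisition_id == "a1" & no_is$is_internal_standard] <- 0
  no_is$corrected_intensity <- no_is$intensity
  amt2 <- compute_amounts(no_is, spikes_fix)
  expect_true(all(is.na(amt2$amount_fmol[amt2$acquisition_id == "a1" &
                                           !amt2$is_internal_standard])))
  expect_equal(nrow(amt2), nrow(amt))
  expect_error(compute_amounts(dplyr::mutate(j, class = "QQ"), spikes_fix),
               "QQ")
})

test_that("mol% normalises to 100 within each grouping cell", {
  j <- join_sample_info(quant_table(), sample_info_fix)
  j$corrected_intensity <- j$intensity
  amt <- compute_amounts(j, spikes_fix)
  mp <- mol_percent(amt)
  per_cell <- tapply(mp$mol_percent[!is.na(mp$mol_percent)],
                     mp$acquisition_id[!is.na(mp$mol_percent)], sum)
  expect_true(all(abs(per_cell - 100) < 1e-9))
  # single-species universe; the blank's cell has a zero denominator
  expect_warning(
    one <- mol_percent(amt, universe = function(t) t$species_name == "PC 34:1"),
    "denominator")
  expect_equal(one$mol_percent[one$species_name == "PC 34:1" &
                                 one$acquisition_id == "a1"], 100)
  expect_true(all(is.na(one$mol_percent[one$species_name != "PC 34:1"])))
  # equal amounts split 50/50
  eq <- amt
  eq$amount_fmol[!eq$is_internal_standard] <- 5
  mp_eq <- mol_percent(eq, universe = function(t) !t$is_internal_standard)
  expect_true(all(abs(
    mp_eq$mol_percent[!is.na(mp_eq$mol_percent)] - 100 / 3) < 1e-9))
  expect_error(mol_percent(quant_table()), "amount_fmol")
})
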