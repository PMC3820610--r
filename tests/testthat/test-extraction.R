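lock_targets <- function(names, mzs) {
  tibble::tibble(species_name = names, theoretical_mz = mzs,
                 is_lock_mass = TRUE)
}

# symmetric three-point peaks centred exactly on the requested m/z values
triplet_spectrum <- function(centres, apexes, step = 0.0005, ...) {
  mz <- c(t(outer(centres, c(-step, 0, step), `+`)))
  intensity <- c(t(outer(apexes, c(0.4, 1, 0.4))))
  o <- order(mz)
  profile_spectrum(mz[o], intensity[o], ...)
}

test_that("quadratic centroid equals the closed-form parabola vertex", {
  expect_equal(centroid_quadratic(c(1, 1), c(2, 4), c(3, 1)), 2.0)
  # y = -x^2 + 4x through (0,0),(1,3),(2,4): vertex at -b/2a = 2
  expect_equal(centroid_quadratic(c(0, 0), c(1, 3), c(2, 4)), 2.0)
  expect_error(centroid_quadratic(c(0, 1), c(1, 1), c(2, 1)), "no apex")
  expect_error(centroid_quadratic(c(0, 5), c(1, 1), c(2, 5)), "apex")
  set.seed(11)
  for (i in 1:30) {
    a <- -runif(1, 0.1, 5); b <- runif(1, -4, 4); c0 <- runif(1, 0, 10)
    x <- sort(runif(3, -1, 1) + c(-1.5, 0, 1.5))   # non-uniform spacing
    y <- a * x^2 + b * x + c0
    if (y[2] < y[1] || y[2] < y[3]) next
    expect_equal(centroid_quadratic(c(x[1], y[1]), c(x[2], y[2]),
                                    c(x[3], y[3])),
                 -b / (2 * a), tolerance = 1e-9)
  }
})

test_that("lock offsets and their combination reproduce printed values", {
  sp <- triplet_spectrum(c(680.47945, 860.76889), c(5e5, 4e5),
                         acquisition_id = "inj01")
  locks <- lock_targets(c("tris phosphate", "TAG IS"),
                        c(680.48022, 860.77017))
  est <- estimate_lock_offset(sp, locks)
  expect_equal(round(est$locks$offset, 5), c(-0.00077, -0.00128))
  expect_equal(est$combined_offset, mean(c(-0.00077, -0.00128)),
               tolerance = 1e-9)
  expect_equal(round(est$combined_offset, 4), -0.0010)
})

test_that("undetected locks are data, not errors", {
  sp <- triplet_spectrum(680.47945, 100, acquisition_id = "inj07")
  locks <- lock_targets(c("bg", "is"), c(680.48022, 860.77017))
  est <- estimate_lock_offset(sp, locks, min_intensity = 10)
  expect_equal(est$locks$detected, c(TRUE, FALSE))
  expect_true(is.na(est$locks$offset[2]))
  none <- estimate_lock_offset(sp, locks, min_intensity = 1e9)
  expect_true(is.na(none$combined_offset))
  expect_false(any(none$locks$detected))
})

extraction_targets <- function(names, mzs, lock = FALSE) {
  n <- length(names)
  tibble::tibble(
    species_name = names, adduct = "+H", theoretical_mz = mzs,
    is_internal_standard = FALSE, is_lock_mass = lock,
    class = "PC", category = "glycerophospholipid",
    c_index = 32L, db_index = 0L, oh_index = 0L,
    formula = "C40H80NO8P", mono_mass = 733.56216,
    isotope_m0 = 0.63, isotope_m1 = 0.28, isotope_m2 = 0.07)
}

test_that("window extraction reports the max bin and emits a row per target", {
  mz <- seq(734.560, 734.578, by = 0.0005)
  intensity <- rep(0, length(mz))
  intensity[which.min(abs(mz - 734.56872))] <- 5e6
  intensity[which.min(abs(mz - 734.56872)) + c(-1, 1)] <- 2e6
  sp <- profile_spectrum(c(mz, 900), c(intensity, 0), "a", "+FTMS 500-1200")
  tg <- extraction_targets(c("PC 32:0", "far away"),
                           c(734.56943, 900.5))
  res <- extract_targets(sp, tg, tolerance = 0.0020,
                         offset_mode = "constant", offset = -0.0010)
  expect_equal(nrow(res$rows), nrow(tg))
  hit <- res$rows[1, ]
  expect_equal(hit$intensity, 5e6)
  expect_equal(round(hit$measured_mz, 5), round(734.56872, 5), tolerance = 3e-4)
  expect_equal(hit$delta_mz, hit$measured_mz - (734.56943 - 0.0010),
               tolerance = 1e-9)
  miss <- res$rows[2, ]
  expect_equal(miss$intensity, 0)
  expect_true(is.na(miss$measured_mz))
  expect_gt(hit$peak_area, 0)
})

test_that("equal maxima tie-break to the lower m/z bin", {
  sp <- profile_spectrum(c(700.000, 700.001, 700.002), c(5, 5, 1), "a", "r")
  tg <- extraction_targets("x", 700.001)
  res <- extract_targets(sp, tg, tolerance = 0.002)
  expect_equal(res$rows$measured_mz, 700.000)
  expect_error(extract_targets(profile_spectrum(numeric(0), numeric(0)), tg),
               "empty spectrum")
})

test_that("automatic offset shifts the search windows", {
  centre <- 734.56943 - 0.0025   # true peak, shifted beyond tolerance
  sp <- gaussian_spectrum(c(centre, 680.48022 - 0.0025),
                          c(1e6, 5e5), 600, 800,
                          acquisition_id = "a")
  tg <- extraction_targets("PC 32:0", 734.56943)
  locks <- lock_targets("bg", 680.48022)
  res_auto <- extract_targets(sp, tg, 0.0020, "automatic", locks = locks)
  expect_lt(abs(res_auto$offset_estimate$combined_offset - (-0.0025)), 1e-5)
  expect_lt(abs(res_auto$rows$measured_mz - centre), 2.6e-4)
  res_none <- extract_targets(sp, tg, 0.0020, "none")
  # apex outside the unadjusted window: reported bin pinned at the edge
  expect_gt(abs(res_none$rows$measured_mz - centre), 2.6e-4)
})

test_that("unifier concatenates ranges, preserves rows and tags rangeID", {
  t1 <- extract_targets(
    gaussian_spectrum(700.1, 1e5, 700, 701), extraction_targets(
      paste0("s", 1:10), seq(700.05, 700.5, length.out = 10)))$rows
  t2 <- extract_targets(
    gaussian_spectrum(300.1, 1e5, 300, 301, scan_range_id = "+FTMS 280-580"),
    extraction_targets(paste0("t", 1:15),
                       seq(300.05, 300.5, length.out = 15)))$rows
  u <- unify_ranges(list(t1, t2))
  expect_equal(nrow(u), 25)
  expect_setequal(unique(u$rangeID), c("+FTMS 500-1200", "+FTMS 280-580"))
  one <- unify_ranges(list(t1))
  expect_equal(nrow(one), 10)
  expect_error(unify_ranges(list(t1, t2[, -3])), "column-set mismatch")
})

test_that("lock-mass QC flags missing locks per injection", {
  locks <- lock_targets(c("bg", "is"), c(680.48022, 860.77017))
  sp_ok <- triplet_spectrum(c(680.47945, 860.76889), c(5e5, 4e5),
                            acquisition_id = "inj01")
  sp_no_is <- triplet_spectrum(680.47945, 5e5, acquisition_id = "inj02")
  qc <- qc_lockmass(list(estimate_lock_offset(sp_ok, locks),
                         estimate_lock_offset(sp_no_is, locks)))
  expect_equal(nrow(qc), 4)
  flagged <- qc[!qc$detected, ]
  expect_equal(flagged$acquisition_id, "inj02")
  expect_equal(flagged$lock, "is")
  expect_equal(unique(qc$injection[qc$acquisition_id == "inj01"]), 1)
})
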