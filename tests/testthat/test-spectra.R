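test_that("peak-list reading parses, sorts and validates", {
  f <- withr::local_tempfile(lines = c("700.0\t10", "700.002\t5", "700.001\t20"))
  sp <- read_peaklist(f, scan_range_id = "+FTMS 500-1200")
  expect_length(sp$mz, 3)
  expect_equal(sp$mz, c(700.0, 700.001, 700.002))
  expect_equal(sp$intensity, c(10, 20, 5))
  expect_equal(sp$scan_range_id, "+FTMS 500-1200")

  hdr <- withr::local_tempfile(lines = c("mz\tintensity", "700.0 10", "700.5 3"))
  expect_length(read_peaklist(hdr)$mz, 2)

  bad <- withr::local_tempfile(lines = c("700.0\t10", "oops\tgarbage", "701\t2"))
  expect_error(read_peaklist(bad), "line 2")
  empty <- withr::local_tempfile(lines = character(0))
  expect_error(read_peaklist(empty), "empty")
})

test_that("spectrum invariants are enforced", {
  expect_error(profile_spectrum(c(1, 1), c(2, 3)), "strictly increasing")
  expect_error(profile_spectrum(c(1, 2), c(2, -3)), "non-negative")
  expect_error(profile_spectrum(c(1, 2), c(2)), "equal length")
})

test_that("scan averaging is the per-point mean and keeps the reference grid", {
  mz <- seq(500, 501, by = 0.0005)
  one <- profile_spectrum(mz, runif(length(mz)), "a", "r1")
  expect_identical(average_scans(list(one)), one)

  i1 <- runif(length(mz), 0, 100)
  s1 <- profile_spectrum(mz, i1, "a", "r1")
  s3 <- profile_spectrum(mz, 3 * i1, "a", "r1")
  expect_equal(average_scans(list(s1, s3))$intensity, 2 * i1)

  set.seed(31)
  scans <- lapply(1:25, function(i) {
    profile_spectrum(mz, runif(length(mz), 0, 1e6), "a", "r1")
  })
  avg <- average_scans(scans)
  brute <- rowMeans(vapply(scans, function(s) s$intensity,
                           numeric(length(mz))))
  expect_equal(avg$intensity, brute, tolerance = 1e-9)
  expect_identical(avg$mz, mz)

  other <- profile_spectrum(mz, i1, "a", "r2")
  expect_error(average_scans(list(s1, other)), "mixed scan ranges")
})

test_that("averaging shifted grids interpolates onto the reference grid", {
  mz1 <- seq(500, 500.01, by = 0.0005)
  mz2 <- mz1 + 0.00025
  s1 <- profile_spectrum(mz1, rep(10, length(mz1)), "a", "r")
  s2 <- profile_spectrum(mz2, rep(20, length(mz2)), "a", "r")
  avg <- average_scans(list(s1, s2))
  expect_identical(avg$mz, mz1)
  # interior points: mean of 10 and interpolated 20
  expect_equal(avg$intensity[2:(length(mz1) - 1)],
               rep(15, length(mz1) - 2))
})

test_that("acquisition trees contain one averaged file per acquisition x range", {
  mz <- seq(500, 500.01, by = 0.0005)
  mkscan <- function(a, r) profile_spectrum(mz, runif(length(mz)), a, r)
  aset <- list(
    list(acquisition_id = "s1", scans = list("+FTMS 500-1200" = list(mkscan("s1", "+FTMS 500-1200"), mkscan("s1", "+FTMS 500-1200")),
                                             "+FTMS 280-580" = list(mkscan("s1", "+FTMS 280-580")))),
    list(acquisition_id = "s2", scans = list("+FTMS 500-1200" = list(mkscan("s2", "+FTMS 500-1200"))))
  )
  dir <- withr::local_tempdir()
  manifest <- organize_acquisitions(aset, dir)
  expect_equal(nrow(manifest), 3)
  expect_setequal(unique(manifest$folder), c("+FTMS_500-1200", "+FTMS_280-580"))
  expect_equal(sum(manifest$folder == "+FTMS_500-1200"), 2)
  # total file count equals sum over acquisitions of their scan ranges
  expect_equal(nrow(manifest),
               sum(vapply(aset, function(a) length(a$scans), integer(1))))
  back <- read_acquisition_tree(dir)
  expect_length(back, 3)
  expect_equal(nrow(organize_acquisitions(list(), withr::local_tempdir())), 0)
  expect_error(organize_acquisitions(c(aset, aset[2]), withr::local_tempdir()),
               "collision")
})
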