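test_that("csv parsing handles plain, shuffled and malformed input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1000,0", "2000,5", "3000,1"), f)
  s <- read_spectrum(f, "csv")
  expect_s3_class(s, "raw_spectrum")
  expect_equal(s$mz, c(1000, 2000, 3000))
  expect_equal(s$intensity, c(0, 5, 1))

  shuf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,intensity", "3000,1", "1000,0", "2000,5"), shuf)
  s2 <- read_spectrum(shuf, "csv")
  expect_equal(s2$mz, s$mz)
  expect_equal(s2$intensity, s$intensity)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1000,1", "2000,oops"), bad)
  expect_error(read_spectrum(bad, "csv"), "row 2")
  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1000,1", "2000,-4"), neg)
  expect_error(read_spectrum(neg, "csv"), "negative intensity")
  expect_error(read_spectrum("/nonexistent/file.csv", "csv"), "cannot read")
})

test_that("mzML write-read round-trips the arrays", {
  set.seed(11)
  s <- raw_spectrum(seq(2000, 2500, by = 0.7), abs(rnorm(715, 100, 50)),
                    isolate_id = "iso1", replicate_id = "r1")
  f <- withr::local_tempfile(fileext = ".mzML")
  write_spectrum_mzml(s, f)
  s2 <- read_spectrum(f, "mzml", isolate_id = "iso1", replicate_id = "r1")
  expect_identical(s2$mz, s$mz)
  expect_identical(s2$intensity, s$intensity)
})

test_that("baseline subtraction removes flat and ramp baselines, keeps peak area", {
  mz <- seq(2000, 4000, by = 1)
  flat <- raw_spectrum(mz, rep(37, length(mz)))
  out <- subtract_baseline(flat)
  expect_equal(out$intensity, rep(0, length(mz)))
  expect_identical(out$mz, mz)

  zero <- raw_spectrum(mz, rep(0, length(mz)))
  expect_equal(subtract_baseline(zero)$intensity, rep(0, length(mz)))

  # Gaussian peak (known area) on a linear ramp
  amp <- 500; sigma <- 15; ctr <- 3000
  peak <- amp * exp(-(mz - ctr)^2 / (2 * sigma^2))
  ramp <- 0.05 * (mz - 2000) + 20
  s <- raw_spectrum(mz, peak + ramp)
  rec <- subtract_baseline(s, half_window = 100, iterations = 30)
  true_area <- sum(peak)
  expect_lt(abs(sum(rec$intensity) - true_area) / true_area, 0.05)

  expect_error(subtract_baseline(raw_spectrum(1:50, rep(1, 50)),
                                 half_window = 100), "too short")
  expect_error(subtract_baseline(s, half_window = 0), ">= 1")
})

test_that("smoothing reproduces polynomials and shrinks white noise", {
  mz <- seq(2000, 2600, by = 1)
  const <- raw_spectrum(mz, rep(5, length(mz)))
  expect_equal(smooth_spectrum(const)$intensity, rep(5, length(mz)),
               tolerance = 1e-8)
  line <- raw_spectrum(mz, 0.3 * (mz - 2000) + 2)
  sm <- smooth_spectrum(line, window = 21, polyorder = 3)
  inner <- 30:570  # away from filter edges
  expect_equal(sm$intensity[inner], line$intensity[inner], tolerance = 1e-6)
  expect_identical(sm$mz, mz)

  set.seed(42)
  vr <- replicate(1000, {
    y <- rnorm(300, mean = 50, sd = 4)
    s <- raw_spectrum(seq_len(300) + 2000, pmax(y, 0))
    var(smooth_spectrum(s)$intensity[30:270])
  })
  expect_lt(mean(vr), 16)  # well under sigma^2

  expect_error(smooth_spectrum(const, window = 20), "odd")
  expect_error(smooth_spectrum(const, window = 5, polyorder = 7), "smaller")
})

test_that("peak detection recovers noise-free peaks exactly and respects SNR", {
  mz <- seq(2000, 4000, by = 1)
  zero <- raw_spectrum(mz, rep(0, length(mz)))
  expect_length(detect_peaks(zero), 0)

  truth <- c(2300, 2650, 3000, 3411, 3820)
  amps <- c(100, 80, 120, 60, 90)
  y <- rowSums(vapply(seq_along(truth), function(i)
    amps[i] * exp(-(mz - truth[i])^2 / 18), numeric(length(mz))))
  s <- raw_spectrum(mz, y)
  p <- detect_peaks(s, snr = 3)
  expect_length(p, 5)
  expect_true(all(abs(p$mz - truth) <= 1))

  # same five peaks, one amplitude pushed below snr * noise; detection runs
  # on the smoothed trace, as in the pipeline
  set.seed(5)
  amps2 <- c(100, 80, 120, 1, 90)
  y2 <- rowSums(vapply(seq_along(truth), function(i)
    amps2[i] * exp(-(mz - truth[i])^2 / 18), numeric(length(mz))))
  s2 <- smooth_spectrum(raw_spectrum(mz, pmax(y2 + rnorm(length(mz), 0, 1), 0)))
  p2 <- detect_peaks(s2, snr = 3)
  expect_length(p2, 4)
  expect_true(all(abs(p2$mz - truth[-4]) <= 1))
})

test_that("peak detection is invariant to positive intensity rescaling", {
  mz <- seq(2000, 4000, by = 1)
  set.seed(9)
  truth <- c(2400, 2900, 3500)
  y <- rowSums(vapply(truth, function(m)
    80 * exp(-(mz - m)^2 / 18), numeric(length(mz)))) +
    pmax(rnorm(length(mz), 0, 1), 0)
  a <- detect_peaks(raw_spectrum(mz, y))
  b <- detect_peaks(raw_spectrum(mz, 73.5 * y))
  expect_equal(a$mz, b$mz)
  expect_equal(a$intensity, b$intensity, tolerance = 1e-12)
  if (length(a)) expect_equal(max(a$intensity), 1)
})

test_that("qc flags flat lines and cohort outliers, order-invariantly", {
  mz <- seq(2000, 3000, by = 1)
  render <- function(centers) {
    y <- rowSums(vapply(centers, function(m)
      100 * exp(-(mz - m)^2 / 18), numeric(length(mz))))
    raw_spectrum(mz, y)
  }
  centersA <- seq(2050, 2950, by = 60)  # 16 peaks
  centersB <- centersA + 30             # interleaved, disjoint
  cohortA <- lapply(1:9, function(i) {
    s <- render(centersA); s$replicate_id <- paste0("a", i); s
  })
  specB <- render(centersB); specB$replicate_id <- "b"

  zero <- raw_spectrum(mz, rep(0, length(mz)))
  r0 <- qc_spectrum(zero, cohortA)
  expect_true(r0$flat_line)
  expect_match(r0$reason, "dynamic range|peaks")

  rA <- qc_spectrum(cohortA[[1]], cohortA)
  expect_false(rA$flat_line); expect_false(rA$outlier)

  rB <- qc_spectrum(specB, c(cohortA, list(specB)))
  expect_true(rB$outlier)

  rB2 <- qc_spectrum(specB, rev(c(cohortA, list(specB))))
  expect_identical(rB$outlier, rB2$outlier)
  expect_identical(rB$flat_line, rB2$flat_line)
  expect_error(qc_spectrum(specB, list()), "cohort")
})

test_that("preprocessing never changes the m/z axis", {
  fp <- make_fingerprint(12, mass_range = c(2000, 5000), seed = 3)
  s <- simulate_spectrum(fp, noise_model(), seed = 4)
  b <- subtract_baseline(s)
  sm <- smooth_spectrum(b)
  expect_identical(b$mz, s$mz)
  expect_identical(sm$mz, s$mz)
})
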