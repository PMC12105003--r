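# NMR I/O, baseline correction, referencing, binning.

test_that("two-column reader normalizes axis order and round-trips", {
  d <- withr::local_tempdir()
  # ascending file comes back descending with intensities in lockstep
  p <- file.path(d, "asc.txt")
  writeLines(sprintf("%.4f %.6e", seq(0, 10, 0.1), seq_along(seq(0, 10, 0.1))), p)
  s <- read_nmr_spectrum(p)
  expect_true(all(diff(s$ppm) < 0))
  expect_equal(s$intensity, rev(seq_along(seq(0, 10, 0.1))))

  # write-then-read round trip on a rendered fixture
  st <- mini_study(seed = 2, n = 4, n_fractions = 8)
  render_fixtures(st$cons, st$series, st$activity, d, seed = 2, n_points = 512)
  orig <- simulate_nmr_spectra(st$cons, st$series, n_points = 512)[[3]]
  back <- read_nmr_spectrum(file.path(d, "nmr", paste0(orig$fraction_id, ".txt")))
  expect_equal(back$ppm, orig$ppm, tolerance = 1e-9)
  expect_equal(back$intensity, orig$intensity, tolerance = 1e-9)

  # degenerate inputs
  empty <- file.path(d, "empty.txt"); file.create(empty)
  expect_error(read_nmr_spectrum(empty), "empty")
  bad <- file.path(d, "bad.txt")
  writeLines(c("1.0 2.0", "2.0 NaN", "3.0 1.0"), bad)
  expect_error(read_nmr_spectrum(bad), "line 2")
  nonmono <- file.path(d, "nm.txt")
  writeLines(c("1.0 1", "3.0 1", "2.0 1"), nonmono)
  expect_error(read_nmr_spectrum(nonmono), "monotone")
})

test_that("minimal JCAMP-DX subset is parsed", {
  d <- withr::local_tempdir()
  p <- file.path(d, "spec.jdx")
  y <- round(1000 * exp(-((0:63) - 30)^2 / 20))
  body <- vapply(split(y, (0:63) %/% 8), function(v, xs = NULL)
    paste(c(0, v), collapse = " "), character(1))
  # X values per line are ordinal; FIRSTX/LASTX with XFACTOR set the axis
  lines <- c("##TITLE=synthetic", "##JCAMP-DX=4.24", "##XUNITS=PPM",
             "##FIRSTX=10", "##LASTX=0", "##NPOINTS=64",
             "##XFACTOR=1", "##YFACTOR=0.001",
             "##XYDATA=(X++(Y..Y))", body, "##END=")
  writeLines(lines, p)
  s <- read_nmr_spectrum(p, format = "jcamp_dx")
  expect_length(s$ppm, 64)
  expect_true(all(diff(s$ppm) < 0))
  expect_equal(max(s$intensity), max(y) * 0.001, tolerance = 1e-9)
})

test_that("asymmetric least squares removes smooth baselines and preserves peaks", {
  # flat spectrum plus a linear ramp: corrected residual is < 1% of ramp span
  n <- 1024
  ramp <- seq(0, 50, length.out = n)
  s <- flat_ppm_spectrum(0, n = n)
  s$intensity <- rev(ramp)
  out <- baseline_correct(s)
  expect_lt(max(abs(out$intensity)), 0.01 * 50)
  expect_length(out$intensity, n)
  expect_identical(out$ppm, s$ppm)

  # known peaks on a quadratic baseline: integrals preserved within 2%
  ppm_asc <- seq(0, 10, length.out = 4096)
  areas <- c(4, 7, 2.5)
  centers <- c(2.2, 5.0, 7.8)   # bin centers of the 0.4 ppm grid used below
  sp <- peaks_spectrum(centers, areas, fwhm = 0.03, n = 4096)
  quad <- 3 + 0.8 * ppm_asc - 0.05 * ppm_asc^2
  sp$intensity <- sp$intensity + rev(quad)
  corr <- baseline_correct(sp)
  binned <- bin_spectra(list(corr), bin_width = 0.4, range = c(0, 10),
                        exclude = NULL)
  for (k in seq_along(centers)) {
    got <- binned$matrix[1, which.min(abs(binned$bin_centers - centers[k]))]
    expect_equal(unname(got), areas[k], tolerance = 0.02)
  }

  # near-idempotence: a second pass changes peak integrals by < 0.5%
  twice <- baseline_correct(corr)
  b1 <- bin_spectra(list(corr), bin_width = 0.4, exclude = NULL)$matrix
  b2 <- bin_spectra(list(twice), bin_width = 0.4, exclude = NULL)$matrix
  pk_bins <- vapply(centers, function(cc)
    which.min(abs(binned$bin_centers - cc)), integer(1))
  expect_equal(unname(b2[1, pk_bins]), unname(b1[1, pk_bins]),
               tolerance = 0.005)

  expect_error(baseline_correct(s, lambda = -1), "lambda")
  expect_error(baseline_correct(s, p = 1.5), "p must")
})

test_that("reference alignment is a rigid shift to the tallest window peak", {
  s <- peaks_spectrum(c(2.53, 7.0), c(10, 3), fwhm = 0.02, n = 8192)
  out <- reference_align(s, ref_target = 2.50)
  expect_lt(abs(attr(out, "shift") - (-0.03)), 1e-3)
  # rigid translation: pairwise ppm differences unchanged exactly
  expect_equal(diff(out$ppm), diff(s$ppm))

  # already referenced: shift is (numerically) zero
  out2 <- reference_align(out, ref_target = 2.50)
  expect_lt(abs(attr(out2, "shift")), 1e-6)

  # two candidates in the window: the taller wins (argmax oracle)
  s3 <- peaks_spectrum(c(2.44, 2.55), c(3, 9), fwhm = 0.015)
  out3 <- reference_align(s3, ref_target = 2.50)
  win <- which(abs(s3$ppm - 2.5) <= 0.2)
  tallest <- s3$ppm[win[which.max(s3$intensity[win])]]
  expect_equal(attr(out3, "shift"), 2.50 - tallest, tolerance = 1e-12)

  # no peak in the window: flagged, unshifted
  s4 <- peaks_spectrum(7.0, 5, fwhm = 0.02)
  expect_warning(out4 <- reference_align(s4, ref_target = 2.50), "no reference peak")
  expect_false(attr(out4, "aligned"))
  expect_identical(out4$ppm, s4$ppm)
})

test_that("binning conserves integrals and splits straddling peaks exactly", {
  # rectangular peak wholly inside one bin
  n <- 2001
  ppm_asc <- seq(0, 10, length.out = n)
  y <- as.numeric(ppm_asc >= 5.51 & ppm_asc <= 5.58)
  s <- new_nmr_spectrum(rev(ppm_asc), rev(y), "R1")
  b <- bin_spectra(list(s), bin_width = 0.1, exclude = NULL)
  hot <- which.min(abs(b$bin_centers - 5.55))
  expect_equal(sum(b$matrix[1, ]), b$matrix[1, hot], tolerance = 1e-12)
  expect_true(all(b$matrix[1, -hot] == 0))

  # peak straddling a bin edge: split parts sum to the full integral
  s2 <- peaks_spectrum(5.0, 3, fwhm = 0.05, n = 4096)
  b2 <- bin_spectra(list(s2), bin_width = 0.1, exclude = NULL)
  direct <- bin_integrals(s2$ppm, s2$intensity, c(0, 10))
  expect_equal(sum(b2$matrix[1, ]), direct, tolerance = 1e-9)

  # random spectrum: sum over bins equals the direct integral to 1e-6 relative
  set.seed(42)
  for (rep in 1:5) {
    yr <- runif(1500)
    sr <- new_nmr_spectrum(seq(10, 0, length.out = 1500), yr, "RND")
    br <- bin_spectra(list(sr), bin_width = 0.013, exclude = NULL)
    expect_equal(sum(br$matrix[1, ]),
                 bin_integrals(sr$ppm, sr$intensity, c(0, 10)),
                 tolerance = 1e-6)
  }

  # coverage error names the offending fraction
  short <- new_nmr_spectrum(seq(8, 2, length.out = 100), runif(100), "MF07")
  expect_error(bin_spectra(list(short)), "MF07")

  # solvent windows are excluded by default
  bd <- bin_spectra(list(s2))
  expect_false(any(bd$bin_centers > 2.45 & bd$bin_centers < 2.55))
  expect_false(any(bd$bin_centers > 3.2 & bd$bin_centers < 3.4))
})
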