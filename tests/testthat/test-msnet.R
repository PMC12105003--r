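# MGF / quant-table I/O, modified cosine, network construction.

test_that("MGF round-trips and repairs unsorted blocks", {
  d <- withr::local_tempdir()
  st <- mini_study(seed = 13, n = 5, n_fractions = 10)
  fd <- simulate_feature_data(st$cons, st$series, seed = 13)
  p <- file.path(d, "f.mgf")
  write_mgf(fd$spectra, p)
  back <- read_mgf(p)
  expect_length(back, length(fd$spectra))
  expect_identical(vapply(back, `[[`, character(1), "feature_id"),
                   vapply(fd$spectra, `[[`, character(1), "feature_id"))

  # hand-written block with unsorted peaks comes back sorted (sort oracle)
  p2 <- file.path(d, "unsorted.mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=400.2", "SCANS=9", "CHARGE=1+",
               "150.1 30", "90.05 100", "120.2 55", "END IONS"), p2)
  s <- read_mgf(p2)[[1]]
  expect_identical(s$peaks[, "mz"], sort(c(150.1, 90.05, 120.2)))
  expect_identical(s$peaks[, "intensity"], c(100, 55, 30))

  # degenerate / malformed inputs
  p3 <- file.path(d, "empty.mgf"); file.create(p3)
  expect_identical(read_mgf(p3), list())
  p4 <- file.path(d, "nopep.mgf")
  writeLines(c("BEGIN IONS", "SCANS=1", "100 1", "END IONS"), p4)
  expect_error(read_mgf(p4), "PEPMASS")
})

test_that("quant tables round-trip against the generator's ground truth", {
  d <- withr::local_tempdir()
  st <- mini_study(seed = 13, n = 5, n_fractions = 10)
  fd <- simulate_feature_data(st$cons, st$series, seed = 13)
  p <- file.path(d, "q.csv")
  write_quant_table(fd$table, p)
  tab <- read_quant_table(p)
  expect_identical(tab$fraction_ids, st$series$fraction_ids)
  expect_equal(tab$intensities, fd$table$intensities, tolerance = 1e-6)

  # an all-zero fraction column is retained and reported
  t2 <- fd$table
  t2$intensities[, 1] <- 0
  write_quant_table(t2, p)
  expect_message(tab2 <- read_quant_table(p), "MF01")
  expect_identical(dim(tab2$intensities), dim(fd$table$intensities))

  # contract violations
  writeLines(c("row ID,row retention time,MF01 Peak area", "1,0.5,100"), p)
  expect_error(read_quant_table(p), "row m/z")
  writeLines(c("row ID,row m/z,row retention time,MF01 Peak area",
               "1,100,0.5,10", "1,200,0.6,20"), p)
  expect_error(read_quant_table(p), "duplicate")
})

test_that("modified cosine matches self, disjoint and brute-force cases", {
  a <- toy_spectrum("a", c(100, 150, 200, 250), c(50, 100, 80, 20),
                    precursor = 500)
  self <- modified_cosine(a, a)
  expect_equal(self$score, 1.0, tolerance = 1e-9)
  expect_equal(self$matched_peaks, 4L)

  b <- toy_spectrum("b", c(101, 151, 201, 251), c(50, 100, 80, 20),
                    precursor = 500)   # all 1 Da off, same precursor
  expect_equal(modified_cosine(a, b)$score, 0.0)

  # 4 vs 4 peaks with a nonzero precursor shift: greedy equals the
  # exhaustive enumeration over all one-to-one matchings
  cc <- toy_spectrum("c", c(100, 120.5, 150, 229.5), c(30, 90, 60, 45),
                     precursor = 520.5)  # shift 20.5: direct + shifted hits
  g <- modified_cosine(a, cc)
  o <- brute_modified_cosine(a, cc)
  expect_equal(g$score, o$score, tolerance = 1e-9)
  expect_equal(g$matched_peaks, o$matched_peaks)

  # symmetry on generated pairs, score bounds, matched-peak cap
  set.seed(77)
  for (k in 1:20) {
    x <- random_spectrum("x", sample(3:8, 1))
    y <- random_spectrum("y", sample(3:8, 1))
    mxy <- modified_cosine(x, y); myx <- modified_cosine(y, x)
    expect_equal(mxy$score, myx$score, tolerance = 1e-12)
    expect_lte(mxy$score, 1 + 1e-9)
    expect_lte(mxy$matched_peaks, min(nrow(x$peaks), nrow(y$peaks)))
  }
})

test_that("network families equal connected components with the > 3 size filter", {
  # constructed case: chain A-B-C-D plus isolated E
  mk <- function(id, mzs) toy_spectrum(id, mzs, rep(100, length(mzs)),
                                       precursor = 400)
  base <- seq(100, 250, by = 25)  # 7 shared peaks
  spectra <- list(mk("A", base), mk("B", base + 0.001),
                  mk("C", base + 0.002), mk("D", base + 0.003),
                  toy_spectrum("E", c(60, 75, 90, 105, 130, 145),
                               rep(100, 6), precursor = 800))
  net <- build_network(spectra, min_score = 0.7, min_matched = 6)
  expect_equal(sort(net$families$size, decreasing = TRUE), c(4, 1))
  fam <- family_summary(net, min_size = 3)
  expect_equal(nrow(fam), 1)
  expect_setequal(strsplit(fam$feature_ids, ";")[[1]], c("A", "B", "C", "D"))

  # union-find oracle on the realized edge list
  ids <- net$nodes$feature_id
  e <- cbind(match(net$edges$a, ids), match(net$edges$b, ids))
  oracle <- union_find_components(length(ids), e)
  expect_equal(length(unique(net$nodes$family)), length(unique(oracle)))
  expect_true(all(tapply(net$nodes$family, oracle,
                         function(f) length(unique(f)) == 1)))

  # impossible threshold: edgeless network, all-singleton families
  net0 <- build_network(spectra, min_score = 1.01, min_matched = 1)
  expect_equal(nrow(net0$edges), 0)
  expect_true(all(net0$families$size == 1))
})

test_that("congener adduct nodes land in one family and top_k is monotone", {
  cons <- generate_constituents(8, n_active = 1, seed = 31,
                                congener_groups = 2, n_fractions = 20)
  series <- elute(cons, n_fractions = 20)
  fd <- simulate_feature_data(cons, series, seed = 31)
  net <- build_network(fd$spectra, feature_table = fd$table)

  grp <- vapply(cons, `[[`, integer(1), "group")
  for (g in unique(grp)) {
    members <- vapply(cons[grp == g], `[[`, character(1), "id")
    feats <- fd$feature_map$feature_id[fd$feature_map$constituent %in% members]
    fams <- unique(net$nodes$family[net$nodes$feature_id %in% feats])
    expect_length(fams, 1)
  }

  # raising top_k never removes an edge; the final set is thresholded
  net_small <- build_network(fd$spectra, top_k = 3)
  key <- function(n) paste(n$edges$a, n$edges$b)
  expect_true(all(key(net_small) %in% key(net)))
  expect_true(all(net$edges$score >= 0.7 & net$edges$matched_peaks >= 6))
})
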