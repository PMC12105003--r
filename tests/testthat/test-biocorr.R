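# Feature-activity correlation, network annotation, joint ranking.

make_table <- function(inten, rt = NULL, mz = NULL) {
  n <- nrow(inten)
  new_feature_table(
    features = data.frame(feature_id = as.character(seq_len(n)),
                          mz = mz %||% (100 + seq_len(n)),
                          rt = rt %||% seq_len(n),
                          stringsAsFactors = FALSE),
    intensities = inten,
    fraction_ids = colnames(inten))
}

test_that("features tracking activity are red; absent features are gray", {
  fr <- sprintf("MF%02d", 19:23)
  y <- c(20, 45, 70, 50, 30)
  inten <- rbind(tracker = 1000 * y,
                 absent = c(0, 0, 0, 0, 0),
                 constant = rep(5, 5),
                 anti = 1000 * (100 - y))
  rownames(inten) <- NULL; colnames(inten) <- fr
  tab <- make_table(inten)
  act <- activity_from_values(y, fr)
  ann <- correlate_features(tab, act, fr[1:3])

  expect_equal(ann$r[1], 1.0)
  expect_equal(ann$color[1], "red")
  expect_false(ann$in_package[2])
  expect_equal(ann$color[2], "gray")
  expect_true(is.na(ann$r[2]))
  expect_true(ann$degenerate[3])
  expect_equal(ann$color[3], "yellow")
  expect_equal(ann$r[4], -1.0)

  expect_error(correlate_features(tab, act, fr[1:2]), "package error")
})

test_that("the MS kernel agrees with the oracle and with the NMR kernel", {
  set.seed(91)
  fr <- sprintf("MF%02d", 1:5)
  inten <- matrix(runif(30 * 5, 0, 1000), 30, 5,
                  dimnames = list(NULL, fr))
  y <- runif(5, 10, 90)
  tab <- make_table(inten)
  act <- activity_from_values(y, fr)
  ann <- correlate_features(tab, act, fr)
  oracle <- apply(inten, 1, pearson_oracle, y = y)
  expect_equal(ann$r, oracle, tolerance = 1e-12)

  # kernel sharing: identical intensity vectors give identical r on both sides
  binned <- binned_from_matrix(t(inten), centers = 0.005 + 0.01 * (1:30),
                               ids = fr)
  ps <- compute_hetca(binned, act, fr)
  expect_identical(sort(ps$r), sort(ann$r))

  # permuting fractions (with matching activity) leaves r unchanged
  p <- c(3, 1, 5, 2, 4)
  tab_p <- make_table(inten[, p])
  # not consecutive in the original series, so re-declare the series order
  tab_p$fraction_ids <- fr[p]
  act_p <- activity_from_values(y[p], fr[p])
  ann_p <- correlate_features(tab_p, act_p, fr[p])
  expect_equal(ann_p$r, ann$r, tolerance = 1e-14)
})

test_that("annotation colors nodes without touching topology and survives GraphML", {
  st <- mini_study(seed = 17, n = 6, n_fractions = 14)
  fd <- simulate_feature_data(st$cons, st$series, seed = 17)
  net <- build_network(fd$spectra, feature_table = fd$table)
  pkg <- select_package(st$activity, 3)
  ann <- correlate_features(fd$table, st$activity, pkg)
  net2 <- annotate_network(net, ann)

  expect_identical(net2$edges, net$edges)
  expect_identical(net2$families, net$families)
  expect_identical(net2$nodes$family, net$nodes$family)
  expect_true(all(net2$nodes$color[!net2$nodes$in_package] == "gray"))

  # attribute round trip through GraphML preserves r to 1e-9
  d <- withr::local_tempdir()
  p <- file.path(d, "net.graphml")
  write_network_graphml(net2, p)
  g <- read_network_graphml(p)
  r_back <- igraph::vertex_attr(g, "r")[match(net2$nodes$feature_id,
                                              igraph::vertex_attr(g, "name"))]
  ok <- !is.na(net2$nodes$r)
  expect_equal(r_back[ok], net2$nodes$r[ok], tolerance = 1e-9)

  # a package covering no feature turns every node gray
  empty_pkg_ann <- ann
  empty_pkg_ann$in_package <- FALSE
  empty_pkg_ann$color <- "gray"
  empty_pkg_ann$r <- NA_real_
  net3 <- annotate_network(net, empty_pkg_ann)
  expect_true(all(net3$nodes$color == "gray"))
})

test_that("joint ranking groups by co-elution and excludes gray features", {
  fr <- sprintf("MF%02d", 1:5)
  y <- c(10, 40, 80, 35, 15)
  act <- activity_from_values(y, fr)
  # two co-eluting features (RT 3.13) + one distinct (RT 3.31): distinct
  # retention times are distinct compounds at the 0.05 min tolerance
  inten <- rbind(1000 * y, 400 * y, c(50, 60, 40, 55, 45),
                 c(0, 0, 0, 0, 0))
  colnames(inten) <- fr
  tab <- make_table(inten, rt = c(3.13, 3.15, 3.31, 7.0),
                    mz = c(401.1, 423.1, 510.2, 999.9))
  spectra <- list(
    toy_spectrum("1", c(100, 120, 140, 160, 180, 200), rep(9, 6), 401.1, 3.13),
    toy_spectrum("2", c(100, 120, 140, 160, 180, 200), rep(9, 6), 423.1, 3.15),
    toy_spectrum("3", c(90, 111, 133, 155, 177, 199), rep(9, 6), 510.2, 3.31),
    toy_spectrum("4", c(61, 83, 105, 127, 149, 171), rep(9, 6), 999.9, 7.0))
  net <- annotate_network(build_network(spectra, feature_table = tab),
                          correlate_features(tab, act, fr[1:3]))
  rep_ <- rank_candidates(net, tab)

  expect_equal(nrow(rep_), 2)            # gray feature 4 never appears
  expect_equal(rep_$n_features[1], 2)    # co-eluting pair is one group
  expect_equal(rep_$rank, 1:2)
  expect_true(grepl("401.1", rep_$mz[1]))
  expect_gt(rep_$ms_r[1], rep_$ms_r[2])

  # empty network -> empty report
  net0 <- build_network(list())
  net0$nodes$r <- numeric(0)
  expect_equal(nrow(rank_candidates(net0, make_table(inten[0, , drop = FALSE]))), 0)
})

test_that("NMR regions attach to groups through the feature-to-ppm map", {
  y <- c(5, 30, 60)
  fr <- sprintf("MF%02d", 1:3)
  inten <- rbind(100 * y, 3 * y)
  colnames(inten) <- fr
  tab <- make_table(inten, rt = c(2.0, 4.0), mz = c(300.1, 500.5))
  act <- activity_from_values(y, fr)
  X <- cbind(outer(y, c(8)), matrix(1, 3, 1))
  binned <- binned_from_matrix(X, centers = c(6.005, 6.015), ids = fr)
  ps <- compute_hetca(binned, act, fr)
  regions <- quantify_correlated_signals(ps, binned, fr)
  spectra <- list(toy_spectrum("1", c(100, 125, 150, 175, 200, 225),
                               rep(5, 6), 300.1, 2.0),
                  toy_spectrum("2", c(91, 117, 143, 169, 195, 221),
                               rep(5, 6), 500.5, 4.0))
  net <- annotate_network(build_network(spectra, feature_table = tab),
                          correlate_features(tab, act, fr))
  rep_ <- rank_candidates(net, tab, regions = regions,
                          nmr_ppm = data.frame(feature_id = "1", ppm = 6.005))
  expect_equal(rep_$nmr_region_r[rep_$mz == "300.1000"],
               max(regions$mean_r))
  expect_true(is.na(rep_$nmr_region_r[rep_$mz == "500.5000"]))
})
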