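# Heterocovariance analysis: correlate binned NMR intensities (or any
# feature matrix) with bioactivity over a package of consecutive fractions.

#' Pearson correlation of matrix columns with an activity vector
#'
#' The single correlation kernel shared by the NMR (HetCA) and MS
#' (feature-table) branches, so both report identical coefficients for
#' identical intensity vectors. Zero-variance columns (or a zero-variance
#' activity vector) are flagged degenerate with `r = 0` and never produce
#' `NaN`.
#'
#' @param X numeric matrix, observations (fractions) in rows.
#' @param y numeric activity vector, `length(y) == nrow(X)`.
#' @return list with `r`, `cov` (sample covariance, n-1 denominator), and
#'   logical `degenerate`, each of length `ncol(X)`.
#' @export
cor_bioactivity <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop_param("length(y) must equal nrow(X)")
  if (n < 3) stop_param("need at least 3 observations")
  xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  cv <- colSums(xc * yc) / (n - 1)
  sx2 <- colSums(xc^2) / (n - 1)
  sy2 <- sum(yc^2) / (n - 1)
  degen <- sx2 <= 0 | sy2 <= 0
  r <- numeric(ncol(X))
  r[!degen] <- cv[!degen] / sqrt(sx2[!degen] * sy2)
  r <- pmin(1, pmax(-1, r))
  list(r = r, cov = cv, degenerate = degen)
}

#' Validate a fraction package
#'
#' A package is a run of at least three consecutive fractions of the parent
#' series, the unit over which all correlations are computed.
#'
#' @param ids candidate fraction ids (ordered).
#' @param series_ids the full ordered fraction id vector.
#' @return `ids`, invisibly, after validation.
#' @export
fraction_package <- function(ids, series_ids) {
  if (length(ids) < 3) stop_param("package error: need >= 3 fractions")
  pos <- match(ids, series_ids)
  if (anyNA(pos)) stop("key error: fraction ", ids[which(is.na(pos))[1]],
                       " not found in series", call. = FALSE)
  if (!all(diff(pos) == 1))
    stop_param("package error: fractions are not consecutive in the series")
  invisible(ids)
}

#' Pick a package of consecutive fractions around the activity maximum
#'
#' @param activity a `bioactivity` object.
#' @param k package size (default 3).
#' @return character vector of fraction ids.
#' @export
select_package <- function(activity, k = 3L) {
  n <- length(activity$fraction_ids)
  if (k < 3 || k > n) stop_param("package size must be in [3, n_fractions]")
  c0 <- which.max(activity$values)
  lo <- min(max(1L, c0 - (k - 1L) %/% 2L), n - k + 1L)
  activity$fraction_ids[lo:(lo + k - 1L)]
}

#' Compute a HetCA pseudospectrum
#'
#' For each NMR bin, the Pearson correlation `r` and sample covariance
#' between the bin intensities and the bioactivity over the package
#' fractions. The displayed intensity is `r * mean(bin intensity)`
#' (correlation-signed mean intensity), so the pseudospectrum looks like a
#' 1H NMR spectrum with positively correlated signals pointing up (red) and
#' negatively correlated ones pointing down (blue).
#'
#' @param binned a `binned_nmr`.
#' @param activity a `bioactivity` covering the package fractions.
#' @param package fraction ids (consecutive, >= 3), e.g. from
#'   [select_package()].
#' @param breaks color break points `c(t1, t2)` passed to
#'   [classify_colors()].
#' @param display `"r_mean"` (default), `"cov"`, or `"r"`: which quantity to
#'   put on the display axis.
#' @return a `hetca_pseudospectrum` data.frame with columns `bin_center`,
#'   `r`, `cov`, `display`, `color`, `degenerate`; package ids, activity
#'   values and display mode are carried as attributes.
#' @export
compute_hetca <- function(binned, activity, package,
                          breaks = c(0.3, 0.7),
                          display = c("r_mean", "cov", "r")) {
  display <- match.arg(display)
  fraction_package(package, binned$fraction_ids)
  fraction_package(package, activity$fraction_ids)
  X <- binned$matrix[match(package, binned$fraction_ids), , drop = FALSE]
  y <- activity$values[match(package, activity$fraction_ids)]
  k <- cor_bioactivity(X, y)
  disp <- switch(display,
                 r_mean = k$r * colMeans(X),
                 cov = k$cov,
                 r = k$r)
  disp[k$degenerate] <- 0
  ps <- data.frame(bin_center = binned$bin_centers,
                   r = k$r, cov = k$cov, display = disp,
                   color = classify_colors(k$r, breaks = breaks),
                   degenerate = k$degenerate,
                   stringsAsFactors = FALSE)
  ps$color[ps$degenerate] <- "yellow"
  class(ps) <- c("hetca_pseudospectrum", "data.frame")
  attr(ps, "package") <- package
  attr(ps, "activity") <- y
  attr(ps, "display_mode") <- display
  attr(ps, "bin_width") <- binned$bin_width
  ps
}

#' Map correlation coefficients to the pseudospectrum color code
#'
#' Positive correlation is drawn in red (`r >= t2`) and orange
#' (`t1 <= r < t2`), absent correlation in yellow (`-t1 < r < t1`), negative
#' in green (`-t2 < r <= -t1`) and blue (`r <= -t2`).
#'
#' @param r numeric coefficients in `[-1, 1]` (NA allowed, mapped to NA).
#' @param breaks `c(t1, t2)` with `0 < t1 < t2 < 1` (default 0.3, 0.7).
#' @return character vector of color classes.
#' @export
classify_colors <- function(r, breaks = c(0.3, 0.7)) {
  t1 <- breaks[1]; t2 <- breaks[2]
  if (!(t1 > 0 && t1 < t2 && t2 < 1))
    stop_param("breaks must satisfy 0 < t1 < t2 < 1")
  out <- rep(NA_character_, length(r))
  out[r >= t2] <- "red"
  out[r >= t1 & r < t2] <- "orange"
  out[r > -t1 & r < t1] <- "yellow"
  out[r > -t2 & r <= -t1] <- "green"
  out[r <= -t2] <- "blue"
  out
}

#' Quantify activity-correlated NMR regions
#'
#' Merges maximal runs of contiguous bins with `r >= threshold` into
#' regions and reports, for each, the ppm span, mean `r`, and its share of
#' the total positively-correlated integral in the package's most active
#' fraction — the quantitative NMR evidence for how much a correlated
#' constituent contributes to the fraction.
#'
#' @param ps a `hetca_pseudospectrum` from [compute_hetca()].
#' @param binned the `binned_nmr` the pseudospectrum was computed from.
#' @param package the same package of fraction ids.
#' @param threshold correlation cutoff in (0, 1) (default 0.7).
#' @return data.frame with `ppm_lo`, `ppm_hi`, `n_bins`, `mean_r`,
#'   `integral`, `integral_share`, sorted by `integral_share` descending
#'   (ties: higher ppm first). Empty when no bin passes.
#' @export
quantify_correlated_signals <- function(ps, binned, package, threshold = 0.7) {
  if (threshold <= 0 || threshold >= 1) stop_param("threshold must be in (0, 1)")
  y <- attr(ps, "activity")
  top <- package[which.max(y)]
  row <- binned$matrix[match(top, binned$fraction_ids), ]

  # work in ascending ppm so "contiguous" means adjacent bins
  o <- order(ps$bin_center)
  ctr <- ps$bin_center[o]
  pass <- (!ps$degenerate & ps$r >= threshold)[o]
  rr <- ps$r[o]
  val <- row[o]
  w <- binned$bin_width
  # break runs across excluded-window gaps
  gap <- c(FALSE, diff(ctr) > 1.5 * w)
  run_id <- cumsum(gap | c(TRUE, diff(pass) != 0))
  empty <- data.frame(ppm_lo = numeric(0), ppm_hi = numeric(0),
                      n_bins = integer(0), mean_r = numeric(0),
                      integral = numeric(0), integral_share = numeric(0))
  if (!any(pass)) return(empty)
  total <- sum(val[pass])
  regions <- lapply(split(which(pass), run_id[pass]), function(ix) {
    data.frame(ppm_lo = min(ctr[ix]) - w / 2, ppm_hi = max(ctr[ix]) + w / 2,
               n_bins = length(ix), mean_r = mean(rr[ix]),
               integral = sum(val[ix]),
               integral_share = if (total > 0) sum(val[ix]) / total else NA_real_)
  })
  out <- do.call(rbind, regions)
  out <- out[order(-out$integral_share, -out$ppm_hi), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot a HetCA pseudospectrum
#'
#' Upward red/orange bars mark proton signals positively correlated with
#' activity, downward blue/green bars negatively correlated ones; the ppm
#' axis runs right to left as in a conventional 1H NMR spectrum.
#'
#' @param ps a `hetca_pseudospectrum`.
#' @param file optional SVG path; when given the plot is written there.
#' @param main plot title.
#' @export
plot_pseudospectrum <- function(ps, file = NULL, main = "HetCA pseudospectrum") {
  pal <- c(red = "#d62728", orange = "#ff7f0e", yellow = "#e6c700",
           green = "#2ca02c", blue = "#1f77b4")
  if (!is.null(file)) { svg(file, width = 9, height = 4); on.exit(dev.off()) }
  plot(ps$bin_center, ps$display, type = "n",
       xlim = rev(range(ps$bin_center)),
       xlab = "chemical shift (ppm)", ylab = "r x mean intensity",
       main = main)
  abline(h = 0, col = "grey70")
  nz <- ps$display != 0
  segments(ps$bin_center[nz], 0, ps$bin_center[nz], ps$display[nz],
           col = pal[ps$color[nz]], lwd = 1.5)
  invisible(ps)
}

#' Write a pseudospectrum as CSV
#' @param ps a `hetca_pseudospectrum`.
#' @param path output path.
#' @export
write_pseudospectrum <- function(ps, path) {
  df <- as.data.frame(ps)
  df$bin_center <- sprintf("%.4f", df$bin_center)
  df$r <- sprintf("%.10g", df$r)
  df$cov <- sprintf("%.10g", df$cov)
  df$display <- sprintf("%.10g", df$display)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
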