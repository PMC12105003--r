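# 1H NMR handling: reading, baseline correction, referencing, binning.

#' Construct an NMR spectrum object
#'
#' @param ppm chemical-shift axis (strictly monotone; stored as given).
#' @param intensity intensities, same length as `ppm`.
#' @param fraction_id fraction label.
#' @param ref_shift nominal solvent reference shift (ppm).
#' @return an `nmr_spectrum`.
#' @export
new_nmr_spectrum <- function(ppm, intensity, fraction_id = "", ref_shift = 2.50) {
  stopifnot(length(ppm) == length(intensity), length(ppm) >= 2)
  structure(list(ppm = ppm, intensity = intensity,
                 fraction_id = fraction_id, ref_shift = ref_shift),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum %s> %d points, %.2f..%.2f ppm\n",
              x$fraction_id, length(x$ppm), max(x$ppm), min(x$ppm)))
  invisible(x)
}

#' Read a 1H NMR spectrum
#'
#' Supports plain two-column `ppm intensity` text and a minimal JCAMP-DX
#' subset (`##XYDATA=(X++(Y..Y))`, AFFN/fixed-point). The returned axis is
#' normalized to descending ppm regardless of file order.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"two_column"`, or `"jcamp_dx"`.
#' @param fraction_id id attached to the spectrum; defaults to the file
#'   base name.
#' @return an `nmr_spectrum`.
#' @export
read_nmr_spectrum <- function(path,
                              format = c("auto", "two_column", "jcamp_dx"),
                              fraction_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(jdx|dx|jcm)$", path, ignore.case = TRUE))
      "jcamp_dx" else "two_column"
  fraction_id <- fraction_id %||% sub("\\.[^.]*$", "", basename(path))

  if (format == "two_column") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("format error in ", path, ": file is empty")
    parts <- strsplit(trimws(lines), "[ \t,]+")
    bad <- which(vapply(parts, length, integer(1)) < 2)
    if (length(bad)) stop("format error in ", path, " at line ", bad[1],
                          ": expected two columns")
    ppm <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 1)))
    int <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2)))
    nab <- which(!is.finite(ppm) | !is.finite(int))
    if (length(nab)) stop("format error in ", path, " at line ", nab[1],
                          ": non-numeric or NaN value")
  } else {
    xy <- read_jcamp_xy(path)
    ppm <- xy$x; int <- xy$y
  }
  d <- diff(ppm)
  if (any(d == 0) || !(all(d > 0) || all(d < 0)))
    stop("format error in ", path, ": ppm axis is not strictly monotone")
  if (ppm[1] < ppm[length(ppm)]) { ppm <- rev(ppm); int <- rev(int) }
  new_nmr_spectrum(ppm = ppm, intensity = int, fraction_id = fraction_id)
}

# Minimal JCAMP-DX (X++(Y..Y), AFFN) reader.
read_jcamp_xy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_num <- function(key) {
    i <- grep(paste0("^##", key, "\\s*="), lines, ignore.case = TRUE)
    if (!length(i)) return(NA_real_)
    as.numeric(sub(".*=", "", lines[i[1]]))
  }
  firstx <- get_num("FIRSTX"); lastx <- get_num("LASTX")
  np <- get_num("NPOINTS")
  xf <- get_num("XFACTOR"); yf <- get_num("YFACTOR")
  if (is.na(xf)) xf <- 1
  if (is.na(yf)) yf <- 1
  i0 <- grep("^##XYDATA", lines, ignore.case = TRUE)
  if (!length(i0)) stop("format error in ", path, ": no ##XYDATA block")
  iend <- grep("^##", lines)
  iend <- iend[iend > i0[1]]
  body <- lines[(i0[1] + 1):(if (length(iend)) iend[1] - 1 else length(lines))]
  ys <- list()
  for (ln in body) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[ \t]+")[[1]]))
    if (any(is.na(v))) stop("format error in ", path, ": non-AFFN data line")
    if (length(v) >= 2) ys[[length(ys) + 1L]] <- v[-1]
  }
  y <- unlist(ys) * yf
  n <- if (!is.na(np)) np else length(y)
  if (length(y) != n) stop("format error in ", path, ": NPOINTS mismatch (",
                           length(y), " vs ", n, ")")
  x <- seq(firstx * xf, lastx * xf, length.out = n)
  list(x = x, y = y)
}

#' Asymmetric least squares baseline correction
#'
#' Estimates a smooth baseline by iteratively reweighted penalized least
#' squares (Whittaker smoother with asymmetric weights: points above the
#' baseline get weight `p`, points below `1 - p`), and subtracts it. The
#' standard automatic replacement for manual baseline correction.
#'
#' @param s an `nmr_spectrum` (>= 10 points).
#' @param lambda smoothness penalty (> 0, default 1e5).
#' @param p asymmetry parameter in (0, 1), default 0.001.
#' @param maxit maximum reweighting iterations (default 20).
#' @return the corrected `nmr_spectrum`; the estimated baseline is attached
#'   as attribute `"baseline"`.
#' @export
baseline_correct <- function(s, lambda = 1e5, p = 0.001, maxit = 20L) {
  if (lambda <= 0) stop_param("lambda must be > 0")
  if (p <= 0 || p >= 1) stop_param("p must be in (0, 1)")
  y <- s$intensity
  m <- length(y)
  if (m < 10) stop_param("spectrum too short for baseline correction")
  D <- Matrix::bandSparse(m - 2, m, k = 0:2,
                          diagonals = list(rep(1, m - 2), rep(-2, m - 2),
                                           rep(1, m - 2)))
  DtD <- Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  for (it in seq_len(maxit)) {
    W <- Matrix::Diagonal(x = w)
    z <- as.numeric(Matrix::solve(W + lambda * DtD, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  out <- s
  out$intensity <- y - z
  attr(out, "baseline") <- z
  out
}

#' Reference a spectrum to the residual solvent signal
#'
#' Rigidly shifts the ppm axis so that the tallest peak (strict local
#' maximum) within `+/- window` ppm of `ref_target` sits exactly at
#' `ref_target`. If no peak is found, the spectrum is returned unshifted
#' with attribute `"aligned" = FALSE` and a warning.
#'
#' @param s an `nmr_spectrum`.
#' @param ref_target target chemical shift (default 2.50 ppm, residual
#'   DMSO-d6).
#' @param window search half-width in ppm (default 0.2).
#' @param min_height minimum peak height; default 5x the median absolute
#'   intensity of the spectrum.
#' @return the aligned `nmr_spectrum` with attributes `"aligned"` (logical)
#'   and `"shift"` (applied ppm offset).
#' @export
reference_align <- function(s, ref_target = 2.50, window = 0.2,
                            min_height = NULL) {
  min_height <- min_height %||% (5 * median(abs(s$intensity)))
  idx <- which(s$ppm >= ref_target - window & s$ppm <= ref_target + window)
  pk <- idx[idx > 1 & idx < length(s$ppm)]
  pk <- pk[s$intensity[pk] > s$intensity[pk - 1] &
           s$intensity[pk] >= s$intensity[pk + 1] &
           s$intensity[pk] >= min_height]
  if (!length(pk)) {
    warning("no reference peak within ", window, " ppm of ", ref_target,
            " for ", s$fraction_id, "; spectrum left unshifted")
    attr(s, "aligned") <- FALSE
    attr(s, "shift") <- 0
    return(s)
  }
  at <- pk[which.max(s$intensity[pk])]
  shift <- ref_target - s$ppm[at]
  s$ppm <- s$ppm + shift
  attr(s, "aligned") <- TRUE
  attr(s, "shift") <- shift
  s
}

#' Exact trapezoidal integrals of a spectrum over bins
#'
#' Treats the spectrum as piecewise linear, augments the grid with the bin
#' edges (linearly interpolated), and integrates by the trapezoid rule, so
#' the bin integrals sum exactly to the integral over the covered range.
#' With a single pair of edges this is the plain integral over an interval.
#'
#' @param ppm axis values (any order).
#' @param intensity intensities matching `ppm`.
#' @param edges ascending bin edge positions (length `n_bins + 1`).
#' @return numeric vector of `n_bins` integrals.
#' @export
bin_integrals <- function(ppm, intensity, edges) {
  o <- order(ppm)
  x <- ppm[o]; y <- intensity[o]
  ye <- approx(x, y, xout = edges, rule = 2)$y
  xi <- c(x, edges)
  yi <- c(y, ye)
  flag <- c(rep(FALSE, length(x)), rep(TRUE, length(edges)))
  oo <- order(xi, flag)  # edges sort after coincident data points
  xi <- xi[oo]; yi <- yi[oo]; flag <- flag[oo]
  ct <- c(0, cumsum(diff(xi) * (yi[-1] + yi[-length(yi)]) / 2))
  ce <- ct[flag]
  diff(ce)
}

#' Bin spectra into a fractions x bins matrix
#'
#' Each cell is the trapezoidal integral of the spectrum over one bin; by
#' construction the bin integrals of a row sum exactly to the spectrum's
#' integral over the analysis range. Bins are laid out from `range[2]` down
#' to `range[1]` (descending ppm, the plotting convention); bins
#' overlapping an exclusion window (residual solvent, water) are dropped.
#'
#' @param spectra list of `nmr_spectrum` objects covering `range`.
#' @param bin_width bin width in ppm (default 0.01).
#' @param range analysis range `c(lo, hi)` in ppm (default 0..10).
#' @param exclude list of `c(lo, hi)` ppm windows to drop (default residual
#'   DMSO 2.45-2.55 and water 3.2-3.4); `NULL` keeps everything.
#' @param normalize divide each row by its total integral (default FALSE:
#'   fractions are measured at equal nominal concentration).
#' @return a `binned_nmr`: list with `matrix` (fractions x bins, columns in
#'   descending ppm), `bin_edges` (descending), `bin_centers`, `bin_width`,
#'   `fraction_ids`.
#' @export
bin_spectra <- function(spectra, bin_width = 0.01, range = c(0, 10),
                        exclude = list(c(2.45, 2.55), c(3.2, 3.4)),
                        normalize = FALSE) {
  if (bin_width <= 0) stop_param("bin_width must be > 0")
  lo <- min(range); hi <- max(range)
  n_bins <- max(1L, round((hi - lo) / bin_width))
  edges_asc <- lo + bin_width * (0:n_bins)
  edges_asc[n_bins + 1] <- hi
  centers_asc <- (edges_asc[-1] + edges_asc[-length(edges_asc)]) / 2

  keep <- rep(TRUE, n_bins)
  for (w in exclude %||% list())
    keep <- keep & !(edges_asc[-1] > w[1] & edges_asc[-(n_bins + 1)] < w[2])

  ids <- vapply(spectra, `[[`, character(1), "fraction_id")
  if (anyDuplicated(ids)) stop_param("duplicate fraction ids in spectra")
  mat <- t(vapply(spectra, function(s) {
    if (min(s$ppm) > lo + 1e-9 || max(s$ppm) < hi - 1e-9)
      stop("coverage error: spectrum ", s$fraction_id,
           " does not cover [", lo, ", ", hi, "] ppm")
    bin_integrals(s$ppm, s$intensity, edges_asc)
  }, numeric(n_bins)))
  rownames(mat) <- ids

  mat <- mat[, keep, drop = FALSE]
  centers_asc <- centers_asc[keep]
  # descending ppm column order
  ord <- order(centers_asc, decreasing = TRUE)
  mat <- mat[, ord, drop = FALSE]
  centers <- centers_asc[ord]
  colnames(mat) <- sprintf("%.4f", centers)
  if (normalize) {
    tot <- rowSums(mat)
    tot[tot == 0] <- 1
    mat <- mat / tot
  }
  structure(list(matrix = mat, bin_edges = rev(edges_asc),
                 bin_centers = centers, bin_width = bin_width,
                 fraction_ids = ids, range = c(lo, hi),
                 normalized = normalize),
            class = "binned_nmr")
}

#' @export
print.binned_nmr <- function(x, ...) {
  cat(sprintf("<binned_nmr> %d fractions x %d bins (%.3g ppm each, %.1f..%.1f ppm)\n",
              nrow(x$matrix), ncol(x$matrix), x$bin_width,
              x$range[2], x$range[1]))
  invisible(x)
}

#' Write a binned NMR matrix as CSV (rows = fractions, columns = bin centers)
#' @param binned a `binned_nmr`.
#' @param path output CSV path.
#' @export
write_binned_nmr <- function(binned, path) {
  df <- data.frame(fraction = binned$fraction_ids,
                   binned$matrix, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
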