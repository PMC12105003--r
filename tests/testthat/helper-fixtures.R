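# Small in-code fixture builders shared across test files.

toy_spectrum <- function(id, mz, intensity, precursor = 500, rt = 5) {
  new_fragment_spectrum(id, precursor_mz = precursor, rt = rt,
                        peaks = cbind(mz = mz, intensity = intensity))
}

random_spectrum <- function(id, n_peaks, precursor = runif(1, 300, 900),
                            mz_range = c(50, 280)) {
  toy_spectrum(id,
               mz = sort(runif(n_peaks, mz_range[1], mz_range[2])),
               intensity = runif(n_peaks, 10, 1000),
               precursor = precursor)
}

flat_ppm_spectrum <- function(y, id = "S1", n = 512, range = c(0, 10)) {
  ppm <- seq(range[2], range[1], length.out = n)
  new_nmr_spectrum(ppm = ppm, intensity = rep_len(y, n), fraction_id = id)
}

# Gaussian peaks (compact support not required here) on an arbitrary axis.
peaks_spectrum <- function(centers, areas, fwhm = 0.05, id = "S1",
                           n = 2048, range = c(0, 10), baseline = 0) {
  ppm_asc <- seq(range[1], range[2], length.out = n)
  sd <- fwhm / (2 * sqrt(2 * log(2)))
  y <- rep_len(baseline, n)
  for (k in seq_along(centers))
    y <- y + areas[k] * dnorm(ppm_asc, centers[k], sd)
  new_nmr_spectrum(ppm = rev(ppm_asc), intensity = rev(y), fraction_id = id)
}

# Minimal simulated study shared by several test files (small but complete).
mini_study <- function(seed = 11, n = 8, n_fractions = 20) {
  cons <- generate_constituents(n, n_active = 1, seed = seed,
                                congener_groups = 2,
                                n_fractions = n_fractions)
  series <- elute(cons, n_fractions = n_fractions, seed = seed)
  activity <- simulate_bioactivity(series, cons, seed = seed)
  list(cons = cons, series = series, activity = activity)
}

activity_from_values <- function(values, ids = sprintf("MF%02d", seq_along(values))) {
  structure(list(fraction_ids = ids, values = values, assay = "scavenging",
                 replicate_sd = rep(0, length(values))),
            class = "bioactivity")
}

binned_from_matrix <- function(mat, centers, width = 0.01,
                               ids = sprintf("MF%02d", seq_len(nrow(mat)))) {
  rownames(mat) <- ids
  o <- order(centers, decreasing = TRUE)
  structure(list(matrix = mat[, o, drop = FALSE],
                 bin_edges = c(centers[o] + width / 2,
                               min(centers) - width / 2),
                 bin_centers = centers[o], bin_width = width,
                 fraction_ids = ids,
                 range = range(centers) + c(-1, 1) * width / 2,
                 normalized = FALSE),
            class = "binned_nmr")
}
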