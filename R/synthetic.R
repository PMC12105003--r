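# Synthetic microfractionation experiments with known ground truth.
#
# The generator emulates the statistical structure of a microfractionated
# plant extract: ~34 consecutive fractions, constituents eluting as smooth
# unimodal profiles over several neighbouring fractions, each constituent
# carrying a set of 1H NMR multiplets and a set of MS ions (adducts and
# in-source fragments sharing one retention time and one MS2 spectrum), and
# bioactivity driven by one or a few designated actives plus assay noise.
# Concentrations below a relative detection limit are recorded as zero, as
# feature detection in preprocessing would do.

#' Generate synthetic extract constituents
#'
#' Creates `n` constituents organised into `congener_groups` structural
#' families. Members of one family share their dominant MS2 fragment ions
#' (>= 60% of each member's peak list), so that fragment-similarity
#' networking groups them into one spectral family; families are separated in
#' fragment m/z so between-family sharing stays low. Exactly `n_active`
#' constituents receive a positive potency.
#'
#' @param n number of constituents.
#' @param n_active number of bioactive constituents (`0 <= n_active <= n`).
#' @param seed integer master seed; results are bit-identical per seed.
#' @param congener_groups number of structural families (>= 1).
#' @param n_fractions fraction count the elution centers are laid out over.
#' @param activity_peak_z target of the saturating activity transform at the
#'   strongest active's elution maximum, on the transform's natural scale
#'   (default 0.65, i.e. ~57% assay response at the peak fraction).
#' @return a list of `constituent` objects. Each has `id`, `nmr_peaks`
#'   (data.frame `center`/`fwhm`/`rel_area`, ppm), `ms_ions` (data.frame
#'   `mz`/`kind`/`rel_abundance`), `ms2_peaks` (data.frame `mz`/
#'   `rel_intensity`, sorted ascending), `rt` (minutes), `elution_center`,
#'   `elution_width` (fractions), `amount`, `potency`, and `group`.
#' @export
generate_constituents <- function(n, n_active = 1L, seed = 1L,
                                  congener_groups = 3L,
                                  n_fractions = 34L,
                                  activity_peak_z = 0.65) {
  if (n_active > n) stop_param("n_active (", n_active, ") exceeds n (", n, ")")
  if (n_active < 0 || n < 1) stop_param("need n >= 1 and n_active >= 0")
  if (congener_groups < 1) stop_param("congener_groups must be >= 1")

  with_stream(seed, "generate_constituents", {
    group <- rep_len(seq_len(congener_groups), n)

    # Backbone MS2 fragment pools, one per family, globally spaced so that
    # between-family peak sharing is (deterministically) zero.
    all_ms2 <- numeric(0)
    backbone <- lapply(seq_len(congener_groups), function(g) {
      p <- sort(draw_spaced(10L, 60, 280, min_gap = 0.5, avoid = all_ms2))
      all_ms2 <<- c(all_ms2, p)
      p
    })

    mol_mass <- draw_spaced(n, 300, 800, min_gap = 2)
    rts <- sort(draw_spaced(n, 1, 1 + 0.45 * n, min_gap = 0.2))

    # Elution centers: spread over the interior of the series, then shuffled
    # so family membership and elution order are unrelated.
    centers <- seq(3, n_fractions - 2, length.out = n) + runif(n, -0.4, 0.4)
    centers <- sample(centers)
    widths <- runif(n, 0.8, 1.2)
    amounts <- rlnorm(n, meanlog = 0, sdlog = 0.4)
    active_idx <- if (n_active > 0) sample.int(n, n_active) else integer(0)

    solvent_windows <- list(c(2.40, 2.60), c(3.15, 3.45))
    all_nmr <- numeric(0)

    out <- vector("list", n)
    for (i in seq_len(n)) {
      npk <- sample(2:4, 1)
      # 0.07 ppm global separation keeps every signal resolvable at the
      # default 0.01 ppm bin width, so bins are attributable to constituents
      ctr <- draw_spaced(npk, 0.8, 9.2, min_gap = 0.07, avoid = all_nmr,
                         exclude = solvent_windows)
      all_nmr <- c(all_nmr, ctr)
      nmr_peaks <- data.frame(center = ctr,
                              fwhm = runif(npk, 0.015, 0.03),
                              rel_area = runif(npk, 0.5, 3))

      m <- mol_mass[i]
      ms_ions <- data.frame(
        mz = c(m + 1.00728, m + 22.98922, m + 1.00728 - 18.01056),
        kind = c("adduct", "adduct", "fragment"),
        rel_abundance = c(1, runif(1, 0.2, 0.6), runif(1, 0.1, 0.4)),
        stringsAsFactors = FALSE
      )

      # Family backbone fragments dominate; a few low-abundance peaks are
      # unique to the constituent (spaced away from every other MS2 peak).
      uniq <- draw_spaced(3L, 60, 280, min_gap = 0.5, avoid = all_ms2)
      all_ms2 <- c(all_ms2, uniq)
      ms2 <- data.frame(
        mz = c(backbone[[group[i]]], uniq),
        rel_intensity = c(runif(10L, 0.3, 1), runif(3L, 0.05, 0.25))
      )
      ms2 <- ms2[order(ms2$mz), , drop = FALSE]
      rownames(ms2) <- NULL

      # Potency scaled so the strongest fraction of an active reaches
      # activity_peak_z on the transform scale (peak concentration of a
      # unit-spaced Gaussian profile ~ amount / (width * sqrt(2*pi))).
      pot <- 0
      if (i %in% active_idx) {
        peak_conc <- amounts[i] / (widths[i] * sqrt(2 * pi))
        pot <- activity_peak_z / peak_conc * rlnorm(1, 0, 0.1)
      }

      out[[i]] <- structure(list(
        id = sprintf("C%02d", i),
        nmr_peaks = nmr_peaks,
        ms_ions = ms_ions,
        ms2_peaks = ms2,
        rt = rts[i],
        elution_center = centers[i],
        elution_width = widths[i],
        amount = amounts[i],
        potency = pot,
        group = group[i]
      ), class = "constituent")
    }
    out
  })
}

#' @export
print.constituent <- function(x, ...) {
  cat(sprintf("<constituent %s> rt %.2f min, elutes %.1f +/- %.1f, %s\n",
              x$id, x$rt, x$elution_center, x$elution_width,
              if (x$potency > 0) sprintf("active (potency %.3g)", x$potency)
              else "inactive"))
  invisible(x)
}

#' Elute constituents over a fraction series
#'
#' Each constituent's concentration profile is a discretized Gaussian over
#' the fraction index, centered at `elution_center` with sd `elution_width`,
#' truncated where it falls below `detection_limit` of its own maximum
#' (emulating finite instrument dynamic range / compact chromatographic
#' support), and scaled so the profile sums to the constituent's `amount`.
#'
#' @param constituents list of constituents from [generate_constituents()].
#' @param n_fractions number of consecutive fractions (>= 3, default 34).
#' @param seed kept for interface symmetry; elution is deterministic.
#' @param detection_limit relative concentration below which a fraction's
#'   contribution is set to exactly zero (default 0.02, i.e. 2% of the
#'   profile maximum — the order of peak-detection cutoffs applied during
#'   MS preprocessing). At the default width this gives a constituent a
#'   support of ~5-6 consecutive fractions.
#' @return a `fraction_series`: list with `concentration` (constituents x
#'   fractions matrix), `fraction_ids`, `constituent_ids`, `n_fractions`.
#' @export
elute <- function(constituents, n_fractions = 34L, seed = 1L,
                  detection_limit = 0.02) {
  if (n_fractions < 3) stop_param("n_fractions must be >= 3")
  ids <- vapply(constituents, `[[`, character(1), "id")
  conc <- t(vapply(constituents, function(cn) {
    w <- exp(-((seq_len(n_fractions) - cn$elution_center) / cn$elution_width)^2 / 2)
    w[w < detection_limit * max(w)] <- 0
    cn$amount * w / sum(w)
  }, numeric(n_fractions)))
  rownames(conc) <- ids
  fr <- sprintf("MF%02d", seq_len(n_fractions))
  colnames(conc) <- fr
  structure(list(concentration = conc, fraction_ids = fr,
                 constituent_ids = ids, n_fractions = n_fractions,
                 seed = seed),
            class = "fraction_series")
}

#' @export
print.fraction_series <- function(x, ...) {
  cat(sprintf("<fraction_series> %d constituents x %d fractions\n",
              nrow(x$concentration), x$n_fractions))
  invisible(x)
}

#' Saturating activity transform
#'
#' Maps summed potency-weighted concentration to a bounded assay response:
#' `S(z) = 100 * tanh(z)` (monotone, `S(0) = 0`, capped below 100).
#'
#' @param z nonnegative dose scale.
#' @return activity in assay percent units.
#' @export
activity_transform <- function(z) 100 * tanh(z)

#' Simulate a bioactivity assay over a fraction series
#'
#' Noiseless activity per fraction is `S(sum_c potency_c * conc_c,f)` with
#' the saturating transform [activity_transform()]; additive Gaussian noise
#' with sd `noise_sd_activity * range(noiseless)` emulates assay replication
#' scatter.
#'
#' @param series a `fraction_series` from [elute()].
#' @param constituents the matching constituent list.
#' @param seed integer master seed.
#' @param noise_sd_activity noise sd as a fraction of the activity range
#'   (default 0.05).
#' @param assay `"scavenging"` (radical scavenging %) or `"viability"`.
#' @return a `bioactivity` object: list with `fraction_ids`, `values`,
#'   `assay`, `replicate_sd`, and attribute `"noiseless"`.
#' @export
simulate_bioactivity <- function(series, constituents, seed = 1L,
                                 noise_sd_activity = 0.05,
                                 assay = c("scavenging", "viability")) {
  assay <- match.arg(assay)
  pot <- vapply(constituents, `[[`, numeric(1), "potency")
  if (length(pot) != nrow(series$concentration))
    stop_param("constituents do not match series dimensions")
  raw <- as.numeric(pot %*% series$concentration)
  act0 <- activity_transform(raw)
  rng <- diff(range(act0))
  nsd <- noise_sd_activity * rng
  noise <- with_stream(seed, "simulate_bioactivity",
                       rnorm(length(act0), 0, nsd))
  structure(list(fraction_ids = series$fraction_ids,
                 values = act0 + noise,
                 assay = assay,
                 replicate_sd = rep(nsd, length(act0))),
            class = "bioactivity", noiseless = act0)
}

#' @export
print.bioactivity <- function(x, ...) {
  cat(sprintf("<bioactivity: %s> %d fractions, max %.1f at %s\n", x$assay,
              length(x$values), max(x$values),
              x$fraction_ids[which.max(x$values)]))
  invisible(x)
}

#' DPPH free-radical scavenging capacity
#'
#' Scavenging capacity from blank and sample absorbances:
#' `(blank - sample) / blank`, returned as a fraction (multiply by 100 for
#' the conventional percentage).
#'
#' @param blank absorbance of the reagent without test sample (> 0).
#' @param sample absorbance with the test sample (>= 0).
#' @return scavenging capacity as a fraction.
#' @export
scavenging_capacity <- function(blank, sample) {
  if (any(blank <= 0)) stop_param("blank absorbance must be > 0")
  if (any(sample < 0)) stop_param("sample absorbance must be >= 0")
  (blank - sample) / blank
}

# Add one Gaussian peak (given area) to an intensity vector on an ascending
# ppm axis. The lineshape has compact support (+/- 4 sd, omitting ~6e-5 of
# the area): signals do not bleed into bins attributed to other signals.
add_gaussian_peak <- function(intensity, ppm_asc, center, sd, area) {
  lo <- findInterval(center - 4 * sd, ppm_asc) + 1L
  hi <- findInterval(center + 4 * sd, ppm_asc)
  if (hi < lo) return(intensity)
  idx <- lo:hi
  intensity[idx] <- intensity[idx] + area * dnorm(ppm_asc[idx], center, sd)
  intensity
}

#' Synthesize per-fraction 1H NMR spectra for a fraction series
#'
#' Each fraction's spectrum is the concentration-weighted sum of its
#' constituents' Gaussian multiplets, plus a constant residual-solvent peak.
#' Spectra are noise-free: at typical acquisition concentrations the 1H NMR
#' signal-to-noise is high and assay noise dominates the workflow.
#'
#' @param constituents constituent list.
#' @param series matching `fraction_series`.
#' @param n_points points of the ppm axis (default 4096).
#' @param ppm_range axis coverage, default `c(0, 10)` ppm.
#' @param solvent_shift residual solvent position (default 2.50 ppm, DMSO).
#' @param solvent_area area of the solvent peak (default 5).
#' @param axis_offset rigid miscalibration added to the whole axis (ppm),
#'   useful for exercising reference alignment; default 0.
#' @return list of `nmr_spectrum` objects (descending ppm), one per fraction.
#' @export
simulate_nmr_spectra <- function(constituents, series, n_points = 4096L,
                                 ppm_range = c(0, 10), solvent_shift = 2.50,
                                 solvent_area = 5, axis_offset = 0) {
  ppm_asc <- seq(ppm_range[1], ppm_range[2], length.out = n_points)
  k <- 1 / (2 * sqrt(2 * log(2)))  # fwhm -> sd
  lapply(seq_along(series$fraction_ids), function(f) {
    y <- numeric(n_points)
    for (i in seq_along(constituents)) {
      cc <- series$concentration[i, f]
      if (cc == 0) next
      pk <- constituents[[i]]$nmr_peaks
      for (j in seq_len(nrow(pk)))
        y <- add_gaussian_peak(y, ppm_asc, pk$center[j], pk$fwhm[j] * k,
                               cc * pk$rel_area[j])
    }
    if (solvent_area > 0)
      y <- add_gaussian_peak(y, ppm_asc, solvent_shift, 0.02 * k, solvent_area)
    new_nmr_spectrum(ppm = rev(ppm_asc) + axis_offset, intensity = rev(y),
                     fraction_id = series$fraction_ids[f])
  })
}

#' Simulate the MS feature table and fragment spectra
#'
#' One MS feature per (constituent, ion). Per-fraction feature intensity is
#' `conc_c,f * rel_abundance_i * lognormal noise` with multiplicative
#' coefficient of variation `noise_cv`; fractions where a constituent is
#' below its detection limit stay exactly zero. All ions of one constituent
#' share its retention time (small jitter) and its MS2 fragment peaks.
#'
#' @param constituents constituent list.
#' @param series matching `fraction_series`.
#' @param seed integer master seed.
#' @param noise_cv multiplicative intensity CV (default 0.10).
#' @param intensity_scale overall intensity scale (default 1e6 counts).
#' @return list with `table` (a `feature_table`), `spectra` (list of
#'   `fragment_spectrum`), and `feature_map` (data.frame feature_id,
#'   constituent, kind).
#' @export
simulate_feature_data <- function(constituents, series, seed = 1L,
                                  noise_cv = 0.10, intensity_scale = 1e6) {
  with_stream(seed, "simulate_feature_data", {
    sdlog <- sqrt(log(1 + noise_cv^2))
    nf <- series$n_fractions
    rows <- list(); spectra <- list(); map <- list()
    fid <- 0L
    for (i in seq_along(constituents)) {
      cn <- constituents[[i]]
      for (j in seq_len(nrow(cn$ms_ions))) {
        fid <- fid + 1L
        conc <- series$concentration[i, ]
        noise <- rlnorm(nf, -sdlog^2 / 2, sdlog)
        inten <- intensity_scale * conc * cn$ms_ions$rel_abundance[j] * noise
        rt <- cn$rt + runif(1, -0.01, 0.01)
        rows[[fid]] <- data.frame(feature_id = as.character(fid),
                                  mz = cn$ms_ions$mz[j], rt = rt,
                                  t(inten), check.names = FALSE)
        pk <- cn$ms2_peaks
        spectra[[fid]] <- new_fragment_spectrum(
          feature_id = as.character(fid),
          precursor_mz = cn$ms_ions$mz[j],
          rt = rt, charge = 1L,
          peaks = cbind(mz = pk$mz + runif(nrow(pk), -0.005, 0.005),
                        intensity = 1000 * pk$rel_intensity *
                          rlnorm(nrow(pk), 0, 0.05)))
        map[[fid]] <- data.frame(feature_id = as.character(fid),
                                 constituent = cn$id,
                                 kind = cn$ms_ions$kind[j],
                                 stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    inten <- as.matrix(df[, -(1:3), drop = FALSE])
    colnames(inten) <- series$fraction_ids
    rownames(inten) <- df$feature_id
    tab <- new_feature_table(features = df[, 1:3],
                             intensities = inten,
                             fraction_ids = series$fraction_ids)
    list(table = tab, spectra = spectra, feature_map = do.call(rbind, map))
  })
}

#' Write a complete synthetic fixture set to disk
#'
#' Renders a fraction series as the file formats the analysis consumes:
#' per-fraction NMR spectra (two-column `ppm intensity` text), an MGF of
#' fragment spectra, an MZmine-dialect feature quantification CSV, a
#' bioactivity CSV (`fraction,value,sd`), a ground-truth JSON (which
#' features/bins belong to which constituent and which are active), and a
#' manifest with the seed and per-file MD5 hashes. Fixed seeds give
#' bit-identical files.
#'
#' @param constituents constituent list.
#' @param series matching `fraction_series`.
#' @param activity a `bioactivity` object for the same fractions.
#' @param dir output directory (created if missing).
#' @param seed master seed used for the stochastic parts (MS noise).
#' @param noise_cv MS intensity CV, see [simulate_feature_data()].
#' @param n_points,axis_offset passed to [simulate_nmr_spectra()].
#' @return invisibly, a character vector of written file paths.
#' @export
render_fixtures <- function(constituents, series, activity, dir,
                            seed = 1L, noise_cv = 0.10, n_points = 4096L,
                            axis_offset = 0) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("cannot create output directory: ", dir)
  files <- character(0)

  spectra <- simulate_nmr_spectra(constituents, series, n_points = n_points,
                                  axis_offset = axis_offset)
  nmr_dir <- file.path(dir, "nmr")
  dir.create(nmr_dir, showWarnings = FALSE)
  for (s in spectra) {
    p <- file.path(nmr_dir, paste0(s$fraction_id, ".txt"))
    writeLines(sprintf("%.10f %.10e", s$ppm, s$intensity), p)
    files <- c(files, p)
  }

  fd <- simulate_feature_data(constituents, series, seed = seed,
                              noise_cv = noise_cv)
  mgf <- file.path(dir, "features.mgf")
  write_mgf(fd$spectra, mgf)
  quant <- file.path(dir, "feature_quant.csv")
  write_quant_table(fd$table, quant)
  act <- file.path(dir, "bioactivity.csv")
  writeLines(c("fraction,value,sd",
               sprintf("%s,%.6f,%.6f", activity$fraction_ids,
                       activity$values, activity$replicate_sd)), act)

  truth <- list(
    seed = seed,
    fraction_ids = series$fraction_ids,
    constituents = lapply(constituents, function(cn) list(
      id = cn$id, active = cn$potency > 0, potency = cn$potency,
      amount = cn$amount, rt = cn$rt,
      elution_center = cn$elution_center, elution_width = cn$elution_width,
      group = cn$group,
      nmr_peaks = cn$nmr_peaks)),
    features = fd$feature_map
  )
  gt <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, gt, auto_unbox = TRUE, digits = NA)

  files <- c(files, mgf, quant, act, gt)
  manifest <- file.path(dir, "manifest.json")
  hashes <- tools::md5sum(files)
  jsonlite::write_json(list(seed = seed,
                            files = as.list(setNames(unname(hashes),
                                                     basename(names(hashes))))),
                       manifest, auto_unbox = TRUE)
  invisible(c(files, manifest))
}
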