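# Simulation experiment: can the joint workflow recover a known active
# constituent from a synthetic microfractionation series?

#' Run one synthetic recovery trial
#'
#' Simulates a complete microfractionation study (constituents, elution,
#' bioactivity, MS feature data, NMR spectra), selects the 3-fraction
#' package spanning the active's elution peak, runs both biochemometric
#' branches in memory, and reports whether the active was recovered:
#' whether its co-elution feature group ranks first in the joint report,
#' whether the HetCA region with the highest mean correlation covers one of
#' its proton signals, and how strongly features/bins exclusive to distant
#' inactive constituents correlate with activity.
#'
#' @param seed integer master seed for this trial.
#' @param n_constituents,n_active,congener_groups constituent design
#'   (defaults 12, 1, 3).
#' @param n_fractions series length (default 34).
#' @param noise_sd_activity assay noise as fraction of activity range
#'   (default 0.05).
#' @param noise_cv MS intensity coefficient of variation (default 0.10).
#' @param far_distance elution-center separation (fractions) defining
#'   "distant" inactives (default 5).
#' @param bin_width NMR bin width in ppm (default 0.01).
#' @param region_threshold HetCA region cutoff (default 0.7).
#' @param n_points NMR axis points (default 4096).
#' @return one-row data.frame: `seed`, `active_id`, `top_ranked`,
#'   `nmr_max_at_active`, `active_ms_r`, `active_nmr_r`,
#'   `far_inactive_max_abs_r` (max |r| over MS features and NMR bins
#'   exclusive to distant inactives; 0 when all are excluded or degenerate),
#'   `n_nodes`, `n_edges`, `n_families_gt3`, `top_region_share`.
#' @export
recovery_trial <- function(seed, n_constituents = 12L, n_active = 1L,
                           congener_groups = 3L, n_fractions = 34L,
                           noise_sd_activity = 0.05, noise_cv = 0.10,
                           far_distance = 5, bin_width = 0.01,
                           region_threshold = 0.7, n_points = 4096L) {
  cons <- generate_constituents(n_constituents, n_active = n_active,
                                seed = seed,
                                congener_groups = congener_groups,
                                n_fractions = n_fractions)
  series <- elute(cons, n_fractions = n_fractions, seed = seed)
  activity <- simulate_bioactivity(series, cons, seed = seed,
                                   noise_sd_activity = noise_sd_activity)

  act_idx <- which(vapply(cons, `[[`, numeric(1), "potency") > 0)[1]
  active <- cons[[act_idx]]
  peak_f <- which.max(series$concentration[act_idx, ])
  lo <- min(max(1L, peak_f - 1L), n_fractions - 2L)
  package <- series$fraction_ids[lo:(lo + 2L)]

  # --- MS branch ----------------------------------------------------------
  fd <- simulate_feature_data(cons, series, seed = seed, noise_cv = noise_cv)
  net <- build_network(fd$spectra, feature_table = fd$table)
  ann <- correlate_features(fd$table, activity, package)
  net <- annotate_network(net, ann)

  # --- NMR branch ---------------------------------------------------------
  spectra <- simulate_nmr_spectra(cons, series, n_points = n_points)
  binned <- bin_spectra(spectra, bin_width = bin_width)
  ps <- compute_hetca(binned, activity, package)
  regions <- quantify_correlated_signals(ps, binned, package,
                                         threshold = region_threshold)

  # ground-truth feature -> proton shift mapping for the joint report
  nmr_ppm <- do.call(rbind, lapply(seq_along(cons), function(i) {
    ids <- fd$feature_map$feature_id[fd$feature_map$constituent == cons[[i]]$id]
    expand.grid(feature_id = ids, ppm = cons[[i]]$nmr_peaks$center,
                stringsAsFactors = FALSE)
  }))
  report <- rank_candidates(net, fd$table, regions = regions,
                            nmr_ppm = nmr_ppm)

  active_features <- fd$feature_map$feature_id[
    fd$feature_map$constituent == active$id]
  top_ranked <- FALSE
  if (nrow(report)) {
    grp <- coelution_groups(fd$table)
    top_members <- fd$table$features$feature_id[grp == report$group[1]]
    top_ranked <- any(top_members %in% active_features)
  }

  active_ms_r <- suppressWarnings(
    max(ann$r[ann$feature_id %in% active_features], na.rm = TRUE))

  nmr_max_at_active <- FALSE
  active_nmr_r <- NA_real_
  if (nrow(regions)) {
    best <- which.max(regions$mean_r)
    nmr_max_at_active <- any(active$nmr_peaks$center >= regions$ppm_lo[best] &
                             active$nmr_peaks$center <= regions$ppm_hi[best])
    hit <- vapply(seq_len(nrow(regions)), function(k)
      any(active$nmr_peaks$center >= regions$ppm_lo[k] &
          active$nmr_peaks$center <= regions$ppm_hi[k]), logical(1))
    if (any(hit)) active_nmr_r <- max(regions$mean_r[hit])
  }

  # --- distant inactives --------------------------------------------------
  far_ids <- vapply(cons, function(cn)
    cn$potency == 0 &&
      abs(cn$elution_center - active$elution_center) >= far_distance,
    logical(1))
  far_r <- 0
  if (any(far_ids)) {
    far_cons <- vapply(cons[far_ids], `[[`, character(1), "id")
    far_features <- fd$feature_map$feature_id[
      fd$feature_map$constituent %in% far_cons]
    ms_r <- ann$r[ann$feature_id %in% far_features & ann$in_package]
    ms_r <- ms_r[!is.na(ms_r)]
    # NMR bins holding a distant inactive's peak center (centers of all
    # constituents are >= 0.05 ppm apart, so these bins are exclusive)
    far_ppm <- unlist(lapply(cons[far_ids], function(cn) cn$nmr_peaks$center))
    bin_ix <- vapply(far_ppm, function(pp)
      which.min(abs(ps$bin_center - pp)), integer(1))
    nmr_r <- ps$r[bin_ix][!ps$degenerate[bin_ix]]
    far_r <- max(abs(c(0, ms_r, nmr_r)))
  }

  data.frame(seed = seed, active_id = active$id,
             top_ranked = top_ranked,
             nmr_max_at_active = nmr_max_at_active,
             active_ms_r = active_ms_r,
             active_nmr_r = active_nmr_r,
             far_inactive_max_abs_r = far_r,
             n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
             n_families_gt3 = sum(net$families$size > 3),
             top_region_share = if (nrow(regions)) regions$integral_share[1]
                                else NA_real_,
             stringsAsFactors = FALSE)
}

#' Run a batch of recovery trials
#'
#' @param n_seeds number of independent trials.
#' @param base_seed trial `i` uses seed `base_seed + i`.
#' @param ... passed to [recovery_trial()].
#' @return row-bound data.frame of trial results.
#' @export
recovery_study <- function(n_seeds = 200L, base_seed = 0L, ...) {
  do.call(rbind, lapply(seq_len(n_seeds), function(i)
    recovery_trial(seed = base_seed + i, ...)))
}
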