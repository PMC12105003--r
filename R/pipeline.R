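# End-to-end orchestration: file inputs -> NMR/HetCA branch + MS/network
# branch -> joint report, with a run log capturing every parameter.

#' Read a bioactivity CSV (`fraction,value,sd`)
#'
#' @param path CSV path.
#' @param assay assay label attached to the object.
#' @return a `bioactivity` object.
#' @export
read_bioactivity <- function(path, assay = "scavenging") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("fraction", "value")
  if (!all(need %in% names(df)))
    stop("format error in ", path, ": need columns 'fraction' and 'value'")
  structure(list(fraction_ids = as.character(df$fraction),
                 values = as.numeric(df$value),
                 assay = assay,
                 replicate_sd = if ("sd" %in% names(df)) as.numeric(df$sd)
                                else rep(NA_real_, nrow(df))),
            class = "bioactivity")
}

#' Run the complete biochemometric workflow from files
#'
#' Executes both branches over one fraction package: (NMR) read spectra,
#' optional baseline correction and referencing, binning, HetCA
#' pseudospectrum and region quantification; (MS) read MGF and
#' quantification table, build the molecular network, correlate features
#' with activity, annotate the network; then the joint candidate ranking.
#' All outputs and a JSON run log (every parameter, defaults included) are
#' written to `out_dir`.
#'
#' @param nmr_dir directory of per-fraction two-column spectra (`<id>.txt`).
#' @param mgf_path MGF of fragment spectra.
#' @param quant_path MZmine-dialect feature quantification CSV.
#' @param activity_path bioactivity CSV (`fraction,value,sd`).
#' @param package fraction ids (>= 3 consecutive); default: 3-fraction
#'   window around the activity maximum.
#' @param out_dir output directory.
#' @param baseline apply asymmetric least squares baseline correction
#'   (default FALSE: synthetic and pre-corrected spectra need none).
#' @param reference apply residual-solvent referencing (default FALSE).
#' @param bin_width,bin_range,exclude,normalize binning parameters, see
#'   [bin_spectra()].
#' @param lambda,p baseline parameters, see [baseline_correct()].
#' @param ref_target referencing target, see [reference_align()].
#' @param frag_tol,min_score,min_matched,top_k,family_min network
#'   parameters, see [build_network()] and [family_summary()].
#' @param breaks color break points, see [classify_colors()].
#' @param region_threshold HetCA region cutoff, see
#'   [quantify_correlated_signals()].
#' @param presence_min,rt_tol MS correlation/grouping parameters.
#' @param nmr_ppm optional feature-to-ppm mapping for the joint report.
#' @return invisibly, a list with `pseudospectrum`, `regions`, `network`,
#'   `annotations`, `report`, `package`, and `files` (paths written).
#' @export
run_biochemometrics <- function(nmr_dir, mgf_path, quant_path, activity_path,
                                package = NULL, out_dir,
                                baseline = FALSE, reference = FALSE,
                                bin_width = 0.01, bin_range = c(0, 10),
                                exclude = list(c(2.45, 2.55), c(3.2, 3.4)),
                                normalize = FALSE,
                                lambda = 1e5, p = 0.001, ref_target = 2.50,
                                frag_tol = 0.02, min_score = 0.7,
                                min_matched = 6L, top_k = 10L,
                                family_min = 3L,
                                breaks = c(0.3, 0.7),
                                region_threshold = 0.7,
                                presence_min = 0, rt_tol = 0.05,
                                nmr_ppm = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  activity <- read_bioactivity(activity_path)
  package <- package %||% select_package(activity, 3L)

  # --- NMR branch -> HetCA -------------------------------------------------
  paths <- sort(list.files(nmr_dir, pattern = "\\.txt$", full.names = TRUE))
  if (!length(paths)) stop("stage nmr: no spectra found in ", nmr_dir)
  spectra <- lapply(paths, read_nmr_spectrum)
  if (baseline) spectra <- lapply(spectra, baseline_correct,
                                  lambda = lambda, p = p)
  if (reference) spectra <- lapply(spectra, reference_align,
                                   ref_target = ref_target)
  binned <- bin_spectra(spectra, bin_width = bin_width, range = bin_range,
                        exclude = exclude, normalize = normalize)
  ps <- compute_hetca(binned, activity, package, breaks = breaks)
  regions <- quantify_correlated_signals(ps, binned, package,
                                         threshold = region_threshold)

  # --- MS branch -> annotated network --------------------------------------
  fragments <- read_mgf(mgf_path)
  table <- read_quant_table(quant_path)
  net <- build_network(fragments, min_score = min_score,
                       min_matched = min_matched, top_k = top_k,
                       frag_tol = frag_tol, feature_table = table)
  ann <- correlate_features(table, activity, package,
                            presence_min = presence_min, breaks = breaks)
  net <- annotate_network(net, ann)
  report <- rank_candidates(net, table, regions = regions, rt_tol = rt_tol,
                            nmr_ppm = nmr_ppm)

  # --- outputs -------------------------------------------------------------
  files <- c(
    pseudospectrum = write_pseudospectrum(ps, file.path(out_dir, "pseudospectrum.csv")),
    regions = {
      fp <- file.path(out_dir, "nmr_regions.csv")
      write.csv(format(regions, digits = 10), fp, row.names = FALSE, quote = FALSE)
      fp
    },
    graphml = write_network_graphml(net, file.path(out_dir, "network.graphml")),
    nodes = {
      fp <- file.path(out_dir, "node_attributes.csv")
      write.csv(format(net$nodes, digits = 10), fp, row.names = FALSE, quote = FALSE)
      fp
    },
    families = {
      fp <- file.path(out_dir, "families.csv")
      write.csv(family_summary(net, min_size = family_min), fp,
                row.names = FALSE, quote = FALSE)
      fp
    },
    report = {
      fp <- file.path(out_dir, "joint_report.csv")
      write.csv(format(report, digits = 10), fp, row.names = FALSE, quote = FALSE)
      fp
    },
    run_log = {
      fp <- file.path(out_dir, "run_log.json")
      jsonlite::write_json(list(
        inputs = list(nmr_dir = nmr_dir, mgf = mgf_path, quant = quant_path,
                      activity = activity_path),
        package = package,
        nmr = list(baseline = baseline, reference = reference,
                   lambda = lambda, p = p, ref_target = ref_target,
                   bin_width = bin_width, bin_range = bin_range,
                   exclude = exclude, normalize = normalize,
                   region_threshold = region_threshold),
        network = list(frag_tol = frag_tol, min_score = min_score,
                       min_matched = min_matched, top_k = top_k,
                       family_min = family_min),
        correlation = list(breaks = breaks, presence_min = presence_min,
                           rt_tol = rt_tol)
      ), fp, auto_unbox = TRUE, digits = NA)
      fp
    }
  )
  invisible(list(pseudospectrum = ps, regions = regions, network = net,
                 annotations = ann, report = report, package = package,
                 binned = binned, activity = activity, files = files))
}
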