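# MS-side biochemometrics: correlate feature intensities with bioactivity
# over a fraction package, annotate the network, and produce the joint
# MS + NMR candidate ranking.

#' Correlate MS feature intensities with bioactivity over a package
#'
#' A feature is "in the package" iff its intensity exceeds `presence_min`
#' (strictly positive at the default `presence_min = 0`) in at least one
#' package fraction; features absent from the package are colored gray and
#' carry no coefficient, mirroring the gray-node rule of biochemometric
#' molecular networks. In-package features get the Pearson coefficient over
#' the package fractions, computed with the same kernel as the NMR HetCA
#' branch ([cor_bioactivity()]); zero-variance features are flagged
#' degenerate and colored yellow.
#'
#' @param table a `feature_table`.
#' @param activity a `bioactivity` object.
#' @param package consecutive fraction ids (>= 3).
#' @param presence_min intensity threshold for package membership
#'   (default 0).
#' @param transform `"none"` (default) or `"log10"` (`log10(1 + x)`).
#' @param breaks color break points, see [classify_colors()].
#' @return data.frame `feature_id`, `r`, `color`, `in_package`,
#'   `degenerate`, `n`.
#' @export
correlate_features <- function(table, activity, package, presence_min = 0,
                               transform = c("none", "log10"),
                               breaks = c(0.3, 0.7)) {
  transform <- match.arg(transform)
  fraction_package(package, table$fraction_ids)
  fraction_package(package, activity$fraction_ids)
  X <- table$intensities[, match(package, colnames(table$intensities)),
                         drop = FALSE]
  y <- activity$values[match(package, activity$fraction_ids)]
  in_pkg <- rowSums(X > presence_min & X > 0) >= 1
  if (transform == "log10") X <- log10(1 + X)
  out <- data.frame(feature_id = table$features$feature_id,
                    r = NA_real_, color = "gray",
                    in_package = in_pkg, degenerate = FALSE,
                    n = length(package), stringsAsFactors = FALSE)
  if (any(in_pkg)) {
    k <- cor_bioactivity(t(X[in_pkg, , drop = FALSE]), y)
    out$r[in_pkg] <- k$r
    out$degenerate[in_pkg] <- k$degenerate
    cols <- classify_colors(k$r, breaks = breaks)
    cols[k$degenerate] <- "yellow"
    out$color[in_pkg] <- cols
  }
  out
}

#' Annotate a molecular network with correlation coefficients
#'
#' Adds `r`, `color` and `in_package` node attributes; nodes without an
#' annotation default to gray. Topology (edges, families) is unchanged.
#'
#' @param net a `molecular_network`.
#' @param ann data.frame from [correlate_features()].
#' @return the annotated `molecular_network`.
#' @export
annotate_network <- function(net, ann) {
  m <- match(net$nodes$feature_id, ann$feature_id)
  unmatched <- sum(!ann$feature_id %in% net$nodes$feature_id)
  if (unmatched) message(unmatched, " annotation(s) without a matching node")
  net$nodes$r <- ann$r[m]
  net$nodes$color <- ifelse(is.na(m), "gray", ann$color[m])
  net$nodes$in_package <- !is.na(m) & ann$in_package[m]
  net$graph <- igraph::set_vertex_attr(net$graph, "r", value = net$nodes$r)
  net$graph <- igraph::set_vertex_attr(net$graph, "color",
                                       value = net$nodes$color)
  net$graph <- igraph::set_vertex_attr(net$graph, "in_package",
                                       value = net$nodes$in_package)
  net
}

#' Group features by co-elution (shared retention time)
#'
#' Single-linkage grouping on retention time: features whose RTs differ by
#' at most `rt_tol` minutes chain into one group (adducts and in-source
#' fragments of one compound).
#'
#' @param table a `feature_table`.
#' @param rt_tol retention-time tolerance in minutes (default 0.05).
#' @return integer group id per table row.
#' @export
coelution_groups <- function(table, rt_tol = 0.05) {
  rt <- table$features$rt
  o <- order(rt)
  grp <- cumsum(c(TRUE, diff(rt[o]) > rt_tol))
  grp[order(o)]
}

#' Joint MS + NMR candidate ranking
#'
#' Groups in-package features by co-elution, scores each group by its best
#' Pearson coefficient (the MS evidence), and — when a feature-to-ppm
#' mapping is supplied — attaches the best matching HetCA region coefficient
#' (the NMR evidence). The report is sorted by MS `r` descending (ties:
#' larger summed intensity first). Gray (out-of-package) features never
#' enter the ranking. Co-eluting passengers are indistinguishable from
#' actives by correlation alone; the group structure makes them visible.
#'
#' @param net an annotated `molecular_network` (see [annotate_network()]).
#' @param table the `feature_table` the annotations came from.
#' @param regions HetCA region table from [quantify_correlated_signals()],
#'   or NULL.
#' @param rt_tol co-elution tolerance in minutes (default 0.05).
#' @param nmr_ppm optional data.frame `feature_id`, `ppm` linking features
#'   to proton shifts (e.g. from ground truth or expert assignment); used to
#'   match groups to NMR regions.
#' @return data.frame with one row per co-elution group: `rank`, `group`,
#'   `rt`, `family`, `n_features`, `mz` (collapsed member m/z values),
#'   `ms_r`, `nmr_region_r`, `total_intensity`.
#' @export
rank_candidates <- function(net, table, regions = NULL, rt_tol = 0.05,
                            nmr_ppm = NULL) {
  empty <- data.frame(rank = integer(0), group = integer(0), rt = numeric(0),
                      family = integer(0), n_features = integer(0),
                      mz = character(0), ms_r = numeric(0),
                      nmr_region_r = numeric(0), total_intensity = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(net$nodes)) return(empty)
  if (is.null(net$nodes$r)) stop_param("network is not annotated; run annotate_network() first")
  grp <- coelution_groups(table, rt_tol = rt_tol)
  m <- match(table$features$feature_id, net$nodes$feature_id)
  keep <- net$nodes$in_package[m] & !is.na(net$nodes$r[m])
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) return(empty)

  tot_int <- rowSums(table$intensities)
  rows <- lapply(split(which(keep), grp[keep]), function(ix) {
    rr <- net$nodes$r[m[ix]]
    best <- ix[which.max(rr)]
    nmr_r <- NA_real_
    if (!is.null(regions) && nrow(regions) && !is.null(nmr_ppm)) {
      ppms <- nmr_ppm$ppm[nmr_ppm$feature_id %in% table$features$feature_id[ix]]
      if (length(ppms)) {
        hit <- vapply(seq_len(nrow(regions)), function(k)
          any(ppms >= regions$ppm_lo[k] & ppms <= regions$ppm_hi[k]),
          logical(1))
        if (any(hit)) nmr_r <- max(regions$mean_r[hit])
      }
    }
    data.frame(group = grp[ix[1]],
               rt = mean(table$features$rt[ix]),
               family = net$nodes$family[m[best]],
               n_features = length(ix),
               mz = paste(sprintf("%.4f", sort(table$features$mz[ix])),
                          collapse = ";"),
               ms_r = max(rr),
               nmr_region_r = nmr_r,
               total_intensity = sum(tot_int[ix]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$ms_r, -out$total_intensity), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
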