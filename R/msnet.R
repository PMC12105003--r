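# Feature-based molecular networking: MGF / quantification-table I/O,
# modified-cosine fragment similarity, network construction.

#' Construct a fragment (MS2) spectrum object
#'
#' Peaks are sorted ascending by m/z; duplicates within 1e-6 Da are merged.
#'
#' @param feature_id feature identifier.
#' @param precursor_mz precursor m/z in Da.
#' @param rt retention time in minutes.
#' @param charge precursor charge (>= 1).
#' @param peaks two-column matrix-like (`mz`, `intensity`).
#' @return a `fragment_spectrum`.
#' @export
new_fragment_spectrum <- function(feature_id, precursor_mz, rt = NA_real_,
                                  charge = 1L, peaks) {
  peaks <- as.matrix(peaks)
  colnames(peaks) <- c("mz", "intensity")
  if (nrow(peaks) < 1) stop_param("fragment spectrum needs at least 1 peak")
  peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  # merge duplicate m/z (within 1e-6 Da)
  if (nrow(peaks) > 1) {
    grp <- cumsum(c(TRUE, diff(peaks[, "mz"]) > 1e-6))
    if (max(grp) < nrow(peaks)) {
      peaks <- do.call(rbind, lapply(split(seq_len(nrow(peaks)), grp), function(ix)
        c(mz = peaks[ix[1], "mz"], intensity = sum(peaks[ix, "intensity"]))))
    }
  }
  structure(list(feature_id = as.character(feature_id),
                 precursor_mz = precursor_mz, rt = rt,
                 charge = as.integer(charge), peaks = peaks),
            class = "fragment_spectrum")
}

#' @export
print.fragment_spectrum <- function(x, ...) {
  cat(sprintf("<fragment_spectrum %s> precursor %.4f, %d peaks\n",
              x$feature_id, x$precursor_mz, nrow(x$peaks)))
  invisible(x)
}

#' Construct a feature quantification table
#'
#' @param features data.frame with `feature_id`, `mz`, `rt`.
#' @param intensities features x fractions intensity matrix (non-finite
#'   entries become 0).
#' @param fraction_ids ordered fraction labels matching the columns.
#' @return a `feature_table`.
#' @export
new_feature_table <- function(features, intensities, fraction_ids) {
  if (anyDuplicated(features$feature_id))
    stop("format error: duplicate feature ids", call. = FALSE)
  intensities[!is.finite(intensities)] <- 0
  structure(list(features = features, intensities = intensities,
                 fraction_ids = fraction_ids),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d fractions\n",
              nrow(x$features), length(x$fraction_ids)))
  invisible(x)
}

#' Read fragment spectra from an MGF file
#'
#' One `fragment_spectrum` per `BEGIN IONS` block. `FEATURE_ID` (or, failing
#' that, `SCANS`) becomes the feature id, `PEPMASS` the precursor m/z,
#' `RTINSECONDS` the retention time (converted to minutes). Peaks are sorted
#' ascending by m/z.
#'
#' @param path MGF file path.
#' @return list of `fragment_spectrum` objects (empty list for empty files).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  begins <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(begins) != length(ends))
    stop("format error in ", path, ": unbalanced BEGIN/END IONS")
  out <- vector("list", length(begins))
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1):(ends[b] - 1)]
    kv <- grep("=", block, fixed = TRUE, value = TRUE)
    keys <- toupper(sub("=.*", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    getv <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    pep <- getv("PEPMASS")
    if (is.na(pep)) stop("record error in ", path, ": block ", b,
                         " has no PEPMASS")
    pep <- as.numeric(strsplit(trimws(pep), "[ \t]+")[[1]][1])
    fid <- getv("FEATURE_ID")
    if (is.na(fid)) fid <- getv("SCANS")
    if (is.na(fid)) fid <- as.character(b)
    rt <- suppressWarnings(as.numeric(getv("RTINSECONDS"))) / 60
    ch <- getv("CHARGE")
    charge <- if (is.na(ch)) 1L else as.integer(sub("[+-]$", "", ch))
    pk_lines <- block[!grepl("=", block, fixed = TRUE) & nzchar(trimws(block))]
    if (!length(pk_lines)) stop("record error in ", path, ": block ", b,
                                " has no peaks")
    pk <- do.call(rbind, lapply(strsplit(trimws(pk_lines), "[ \t]+"),
                                function(v) as.numeric(v[1:2])))
    out[[b]] <- new_fragment_spectrum(fid, pep, rt = rt, charge = charge,
                                      peaks = pk)
  }
  out
}

#' Write fragment spectra as MGF
#' @param spectra list of `fragment_spectrum` objects.
#' @param path output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 sprintf("FEATURE_ID=%s", s$feature_id),
                 sprintf("PEPMASS=%.5f", s$precursor_mz),
                 sprintf("SCANS=%s", s$feature_id),
                 sprintf("RTINSECONDS=%.3f", s$rt * 60),
                 sprintf("CHARGE=%d+", s$charge),
                 sprintf("%.5f %.2f", s$peaks[, "mz"], s$peaks[, "intensity"]),
                 "END IONS"), con)
  }
  invisible(path)
}

#' Read an MZmine-dialect feature quantification table
#'
#' Expects `row ID`, `row m/z` and `row retention time` columns plus one or
#' more per-sample intensity columns ending in `" Peak area"` (the sample
#' name is the part before the suffix). Blank cells become 0; all-zero
#' sample columns are kept with a message.
#'
#' @param path CSV path.
#' @return a `feature_table`.
#' @export
read_quant_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(df)
  id_col <- grep("^row ID$", nm, ignore.case = TRUE)
  mz_col <- grep("^row m/z$", nm, ignore.case = TRUE)
  rt_col <- grep("^row retention time$", nm, ignore.case = TRUE)
  if (!length(id_col) || !length(mz_col) || !length(rt_col))
    stop("format error in ", path,
         ": need 'row ID', 'row m/z' and 'row retention time' columns")
  sample_cols <- grep(" Peak area\\s*$", nm)
  if (!length(sample_cols))
    stop("format error in ", path, ": no '<sample> Peak area' columns")
  ids <- as.character(df[[id_col[1]]])
  if (anyDuplicated(ids)) stop("format error in ", path,
                               ": duplicate feature ids")
  inten <- as.matrix(df[, sample_cols, drop = FALSE])
  mode(inten) <- "numeric"
  inten[is.na(inten)] <- 0
  fr <- trimws(sub(" Peak area\\s*$", "", nm[sample_cols]))
  colnames(inten) <- fr
  rownames(inten) <- ids
  zero <- fr[colSums(inten) == 0]
  if (length(zero)) message("all-zero intensity for fraction(s): ",
                            paste(zero, collapse = ", "))
  new_feature_table(features = data.frame(feature_id = ids,
                                          mz = df[[mz_col[1]]],
                                          rt = df[[rt_col[1]]],
                                          stringsAsFactors = FALSE),
                    intensities = inten, fraction_ids = fr)
}

#' Write a feature table in MZmine export dialect
#' @param table a `feature_table`.
#' @param path output CSV path.
#' @export
write_quant_table <- function(table, path) {
  hdr <- c("row ID", "row m/z", "row retention time",
           paste(table$fraction_ids, "Peak area"))
  rows <- vapply(seq_len(nrow(table$features)), function(i) {
    paste(c(table$features$feature_id[i],
            sprintf("%.5f", table$features$mz[i]),
            sprintf("%.4f", table$features$rt[i]),
            sprintf("%.6e", table$intensities[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(paste(hdr, collapse = ","), rows), path)
  invisible(path)
}

#' Modified-cosine similarity between two fragment spectra
#'
#' Peaks match either directly (`|dmz| <= frag_tol`) or shifted by the
#' precursor mass difference (`|dmz - (pm_a - pm_b)| <= frag_tol`).
#' Intensities are square-root transformed and L2-normalized; a greedy
#' highest-product-first one-to-one assignment (ties broken by lower m/z in
#' `a`, then in `b`) yields the score.
#'
#' @param a,b `fragment_spectrum` objects.
#' @param frag_tol fragment m/z tolerance in Da (default 0.02).
#' @return list with `score` in `[0, 1]` and `matched_peaks`.
#' @export
modified_cosine <- function(a, b, frag_tol = 0.02) {
  if (frag_tol <= 0) stop_param("frag_tol must be > 0")
  if (!nrow(a$peaks) || !nrow(b$peaks))
    return(list(score = 0, matched_peaks = 0L))
  mza <- a$peaks[, "mz"]; mzb <- b$peaks[, "mz"]
  wa <- sqrt(a$peaks[, "intensity"]); wb <- sqrt(b$peaks[, "intensity"])
  na2 <- sqrt(sum(wa^2)); nb2 <- sqrt(sum(wb^2))
  if (na2 == 0 || nb2 == 0) return(list(score = 0, matched_peaks = 0L))
  wa <- wa / na2; wb <- wb / nb2
  shift <- a$precursor_mz - b$precursor_mz
  dm <- outer(mza, mzb, "-")
  hit <- abs(dm) <= frag_tol | abs(dm - shift) <= frag_tol
  idx <- which(hit, arr.ind = TRUE)
  if (!nrow(idx)) return(list(score = 0, matched_peaks = 0L))
  prod <- wa[idx[, 1]] * wb[idx[, 2]]
  o <- order(-prod, mza[idx[, 1]], mzb[idx[, 2]])
  used_a <- logical(length(mza)); used_b <- logical(length(mzb))
  score <- 0; matched <- 0L
  for (k in o) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    score <- score + prod[k]
    matched <- matched + 1L
  }
  list(score = min(score, 1), matched_peaks = matched)
}

#' Build a molecular network from fragment spectra
#'
#' Candidate edges are feature pairs with modified-cosine `score >=
#' min_score` and at least `min_matched` matched peaks. Each node keeps at
#' most its `top_k` highest-score candidates, and an edge survives only if
#' it is within the top `top_k` for both endpoints (mutual-rank rule).
#' Spectral families are the connected components of the surviving edge set.
#'
#' @param spectra list of `fragment_spectrum` objects.
#' @param min_score minimum modified-cosine score (default 0.7).
#' @param min_matched minimum matched peak count (default 6).
#' @param top_k neighbour cap per node (default 10).
#' @param frag_tol fragment tolerance in Da (default 0.02).
#' @param feature_table optional `feature_table`; when given, nodes carry
#'   their m/z, retention time and summed MS1 intensity (node-size proxy).
#' @return a `molecular_network`: list with `graph` (igraph), `nodes`,
#'   `edges`, `families` data.frames, and the parameters used.
#' @export
build_network <- function(spectra, min_score = 0.7, min_matched = 6L,
                          top_k = 10L, frag_tol = 0.02,
                          feature_table = NULL) {
  if (min_score <= 0 || min_matched < 1 || top_k < 1)
    stop_param("network parameters must be positive")
  ids <- vapply(spectra, `[[`, character(1), "feature_id")
  n <- length(spectra)
  ea <- integer(0); eb <- integer(0); sc <- numeric(0); mp <- integer(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      m <- modified_cosine(spectra[[i]], spectra[[j]], frag_tol = frag_tol)
      if (m$score >= min_score && m$matched_peaks >= min_matched) {
        ea <- c(ea, i); eb <- c(eb, j)
        sc <- c(sc, m$score); mp <- c(mp, m$matched_peaks)
      }
    }
  }
  keep <- mutual_top_k(ea, eb, sc, n, top_k)
  edges <- data.frame(a = ids[ea[keep]], b = ids[eb[keep]],
                      score = sc[keep], matched_peaks = mp[keep],
                      stringsAsFactors = FALSE)

  g <- igraph::graph_from_data_frame(edges,
                                     directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  family_id <- comp$membership[ids]

  nodes <- data.frame(feature_id = ids,
                      mz = vapply(spectra, `[[`, numeric(1), "precursor_mz"),
                      rt = vapply(spectra, `[[`, numeric(1), "rt"),
                      family = as.integer(family_id),
                      family_size = as.integer(comp$csize[family_id]),
                      stringsAsFactors = FALSE)
  nodes$size <- if (!is.null(feature_table)) {
    unname(rowSums(feature_table$intensities)[
      match(ids, feature_table$features$feature_id)])
  } else rep(NA_real_, length(ids))
  g <- igraph::set_vertex_attr(g, "mz", value = nodes$mz)
  g <- igraph::set_vertex_attr(g, "rt", value = nodes$rt)
  g <- igraph::set_vertex_attr(g, "size", value = nodes$size)
  g <- igraph::set_vertex_attr(g, "family_id", value = nodes$family)

  fam <- data.frame(family_id = seq_len(comp$no),
                    size = as.integer(comp$csize))
  structure(list(graph = g, nodes = nodes, edges = edges, families = fam,
                 params = list(min_score = min_score,
                               min_matched = min_matched,
                               top_k = top_k, frag_tol = frag_tol)),
            class = "molecular_network")
}

# mutual top-k rule on an edge list; returns indices of surviving edges
mutual_top_k <- function(ea, eb, sc, n, top_k) {
  if (!length(ea)) return(integer(0))
  rank_ok <- rep(TRUE, length(ea))
  for (v in unique(c(ea, eb))) {
    inc <- which(ea == v | eb == v)
    if (length(inc) <= top_k) next
    partner <- ifelse(ea[inc] == v, eb[inc], ea[inc])
    o <- inc[order(-sc[inc], partner)]
    rank_ok[o[-seq_len(top_k)]] <- FALSE
  }
  which(rank_ok)
}

#' @export
print.molecular_network <- function(x, ...) {
  cat(sprintf("<molecular_network> %d nodes, %d edges, %d families (%d with > 3 nodes)\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$families),
              sum(x$families$size > 3)))
  invisible(x)
}

#' Summarize spectral families
#'
#' @param net a `molecular_network`.
#' @param min_size report families strictly larger than this (default 3,
#'   the conventional "> 3 nodes" family definition).
#' @return data.frame `family_id`, `size`, `n_red` (if annotated),
#'   `feature_ids`, sorted by size descending.
#' @export
family_summary <- function(net, min_size = 3L) {
  fam <- net$families[net$families$size > min_size, , drop = FALSE]
  if (!nrow(fam)) return(data.frame(family_id = integer(0), size = integer(0),
                                    feature_ids = character(0)))
  fam$feature_ids <- vapply(fam$family_id, function(f)
    paste(net$nodes$feature_id[net$nodes$family == f], collapse = ";"),
    character(1))
  if (!is.null(net$nodes$color))
    fam$n_red <- vapply(fam$family_id, function(f)
      sum(net$nodes$color[net$nodes$family == f] %in% "red"), integer(1))
  fam <- fam[order(-fam$size, fam$family_id), , drop = FALSE]
  rownames(fam) <- NULL
  fam
}

#' Write / read a molecular network as GraphML
#'
#' Node attributes (m/z, rt, size, family and, after annotation, `r`,
#' `color`, `in_package`) and edge attributes (score, matched peaks) are
#' preserved.
#'
#' @param net a `molecular_network`.
#' @param path GraphML file path.
#' @return `write_network_graphml`: the path, invisibly;
#'   `read_network_graphml`: an igraph graph.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
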