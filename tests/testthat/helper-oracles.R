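# Independent oracles, coded from first principles and kept separate from
# the implementation paths they check.

# Textbook sum-formula Pearson coefficient (raw sums, not centered moments).
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# Exhaustive maximum over all one-to-one peak matchings (direct or
# precursor-shifted) of the sqrt-intensity-normalized product sum.
brute_modified_cosine <- function(a, b, frag_tol = 0.02) {
  mza <- a$peaks[, "mz"]; mzb <- b$peaks[, "mz"]
  wa <- sqrt(a$peaks[, "intensity"]); wb <- sqrt(b$peaks[, "intensity"])
  wa <- wa / sqrt(sum(wa^2)); wb <- wb / sqrt(sum(wb^2))
  shift <- a$precursor_mz - b$precursor_mz
  cand <- which(abs(outer(mza, mzb, "-")) <= frag_tol |
                abs(outer(mza, mzb, "-") - shift) <= frag_tol,
                arr.ind = TRUE)
  if (!nrow(cand)) return(list(score = 0, matched_peaks = 0L))
  best <- new.env()
  best$score <- 0; best$matched <- 0L
  recurse <- function(k, used_a, used_b, acc, cnt) {
    if (k > nrow(cand)) {
      if (acc > best$score + 1e-15) { best$score <- acc; best$matched <- cnt }
      return(invisible())
    }
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_b[j]) {
      ua <- used_a; ua[i] <- TRUE
      ub <- used_b; ub[j] <- TRUE
      recurse(k + 1L, ua, ub, acc + wa[i] * wb[j], cnt + 1L)
    }
    recurse(k + 1L, used_a, used_b, acc, cnt)
  }
  recurse(1L, logical(length(mza)), logical(length(mzb)), 0, 0L)
  list(score = min(best$score, 1), matched_peaks = best$matched)
}

# Union-find connected components over an edge list on nodes 1..n.
union_find_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
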