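# Independent oracles used across the suite. These deliberately avoid the
# package's own vectorised implementations: plain loops and textbook
# formulas only.

oracle_bases <- c("A", "C", "G", "T")

# Enumerate all 256 ordered 4-base patterns and classify ABBA/BABA by the
# definition (x,y,y,x) / (x,y,x,y), x != y. Returns masses by brute force.
oracle_pattern_masses <- function(f1, f2, f3, f4, drop_transitions = FALSE) {
  is_ts <- function(a, b) {
    p <- sort(c(a, b))
    identical(p, c(1L, 3L)) || identical(p, c(2L, 4L))
  }
  pABBA <- 0; pBABA <- 0
  for (a1 in 1:4) for (a2 in 1:4) for (a3 in 1:4) for (a4 in 1:4) {
    pr <- f1[a1] * f2[a2] * f3[a3] * f4[a4]
    if (a1 != a2 && a2 == a3 && a1 == a4 &&
        !(drop_transitions && is_ts(a1, a2))) pABBA <- pABBA + pr
    if (a1 != a2 && a1 == a3 && a2 == a4 &&
        !(drop_transitions && is_ts(a1, a2))) pBABA <- pBABA + pr
  }
  list(pABBA = pABBA, pBABA = pBABA)
}

# Dense 256x256 group error matrix by explicit loops (no kronecker()).
oracle_dense_E <- function(e1, e2, e3, e4) {
  E <- matrix(0, 256, 256)
  idx <- function(a) (a[1] - 1) * 64 + (a[2] - 1) * 16 + (a[3] - 1) * 4 + a[4]
  el <- list(e1, e2, e3, e4)
  for (a1 in 1:4) for (a2 in 1:4) for (a3 in 1:4) for (a4 in 1:4)
    for (b1 in 1:4) for (b2 in 1:4) for (b3 in 1:4) for (b4 in 1:4)
      E[idx(c(a1, a2, a3, a4)), idx(c(b1, b2, b3, b4))] <-
        e1[a1, b1] * e2[a2, b2] * e3[a3, b3] * e4[a4, b4]
  E
}

# Textbook unweighted delete-one jackknife for the ratio sum(X)/sum(Y).
oracle_unweighted_jackknife <- function(X, Y) {
  g <- length(X)
  D <- sum(X) / sum(Y)
  loo <- sapply(seq_len(g), function(b) sum(X[-b]) / sum(Y[-b]))
  SE <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
  list(D = D, SE = SE)
}

# A small deterministic site_table: counts[site, individual, base].
toy_site_table <- function(counts, chrom = NULL, pos = NULL, ids = NULL) {
  ns <- dim(counts)[1]
  site_table(chrom %||% rep("chr1", ns),
             pos %||% seq_len(ns),
             counts,
             ids %||% paste0("ind", seq_len(dim(counts)[2])))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Random simplex vectors.
rsimplex <- function() { x <- stats::rexp(4); x / sum(x) }
rsimplex256 <- function() { x <- stats::rexp(256); x / sum(x) }
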