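# Allele-frequency estimation from read counts.
#
# Reads of individual l at a site are modelled as binomial draws from the
# individual's allele frequency, so the read fraction x_hat = count/n is an
# unbiased per-individual estimator. The population estimator is the
# weighted sum q_hat = sum_l w_l x_hat_l with raw weights 2n/(n+1),
# normalised over the individuals with n >= 1 — the linear combination of
# minimal variance under drift + read sampling. Weights grow with depth and
# saturate at 2, so a 100x genome does not completely drown out a 2x one.

#' Per-individual allele frequency from base counts
#'
#' @param counts length-4 base count vector (A,C,G,T).
#' @param focal_allele focal base: index 1..4 or one of `"A","C","G","T"`.
#' @return list with `x_hat` (read fraction of the focal base) and `n`
#'   (total depth). With `n = 0` the frequency is undefined and `x_hat`
#'   is `NA`; callers must then exclude the individual at this site.
#' @examples
#' individual_freq(c(3, 0, 1, 0), "A")$x_hat  # 0.75
#' @export
individual_freq <- function(counts, focal_allele) {
  stopifnot(length(counts) == 4, all(counts >= 0))
  if (is.character(focal_allele)) focal_allele <- base_index(focal_allele)
  n <- sum(counts)
  list(x_hat = if (n >= 1) counts[focal_allele] / n else NA_real_, n = n)
}

#' Raw depth-dependent weight 2n/(n+1)
#'
#' Strictly increasing in the depth `n`, equal to 0 at `n = 0` and
#' saturating at 2 as `n` grows: beyond moderate depth, extra reads add
#' almost no information about a diploid individual's allele frequency.
#'
#' @param n non-negative integer depth (vectorised).
#' @return numeric weight(s), not yet normalised.
#' @export
raw_weight <- function(n) {
  stopifnot(all(n >= 0))
  2 * n / (n + 1)
}

#' Minimal-variance weighted population allele frequency
#'
#' Combines the per-individual read fractions of one population at one
#' site into the population frequency estimate
#' `q_hat = sum_l w_l * x_hat_l`, with `w_l` proportional to
#' [raw_weight()] of the individual's depth and normalised to sum to 1
#' over the individuals with at least one read. Individuals with `n = 0`
#' receive weight 0 (the site itself is kept).
#'
#' @param counts_list list of length-4 base-count vectors, one per
#'   individual, or an `individuals x 4` matrix.
#' @param focal_allele focal base (index or letter) for the di-allelic
#'   estimate.
#' @return list with `q_hat` (scalar), `f_hat` (length-4 simplex vector:
#'   the same weights applied to each base), and `weights` (normalised,
#'   zero where `n = 0`). All-`NA` when every individual has `n = 0`.
#' @examples
#' # (x_hat=1, n=9) and (x_hat=0, n=1): q_hat = 1.8 / (1.8 + 1)
#' population_freq(list(c(9, 0, 0, 0), c(0, 1, 0, 0)), "A")$q_hat
#' @export
population_freq <- function(counts_list, focal_allele) {
  m <- if (is.matrix(counts_list)) counts_list
       else do.call(rbind, counts_list)
  stopifnot(ncol(m) == 4)
  if (is.character(focal_allele)) focal_allele <- base_index(focal_allele)
  n <- rowSums(m)
  if (all(n == 0))
    return(list(q_hat = NA_real_, f_hat = rep(NA_real_, 4),
                weights = rep(0, nrow(m))))
  w <- raw_weight(n)
  w <- w / sum(w)
  x <- m / ifelse(n > 0, n, 1)           # rows with n=0 have w=0 anyway
  f_hat <- as.vector(crossprod(x, w))
  names(f_hat) <- BASES
  list(q_hat = f_hat[[focal_allele]], f_hat = f_hat, weights = w)
}

# Vectorised population frequency over all sites of a site_table.
#
# counts: array sites x individuals x 4 restricted to one population's
# columns. Returns list(f = sites x 4 simplex matrix, depth = pooled
# population depth vector). Rows where no individual has reads are NA.
pop_freq_matrix <- function(counts) {
  ns <- dim(counts)[1]; ni <- dim(counts)[2]
  n <- counts[, , 1, drop = FALSE] + counts[, , 2, drop = FALSE] +
    counts[, , 3, drop = FALSE] + counts[, , 4, drop = FALSE]
  dim(n) <- c(ns, ni)
  w <- raw_weight(n)
  wsum <- rowSums(w)
  w <- w / (wsum + (wsum == 0))
  r <- w / (n + (n == 0))      # per-read weight; zero rows stay zero
  f <- matrix(0, ns, 4, dimnames = list(NULL, BASES))
  for (b in 1:4) {
    xb <- counts[, , b, drop = FALSE]
    dim(xb) <- c(ns, ni)
    f[, b] <- rowSums(r * xb)
  }
  f[wsum == 0, ] <- NA_real_
  list(f = f, depth = rowSums(n))
}

# Per-population frequency simplex matrices for all populations in config.
# Returns a named list of sites x 4 matrices.
population_freqs_all <- function(x, config, pops = names(config$populations)) {
  out <- list()
  for (p in pops) {
    cols <- match(config$populations[[p]], x$individuals)
    if (anyNA(cols)) stop_config("individuals of ", p, " absent from data")
    out[[p]] <- pop_freq_matrix(x$counts[, cols, , drop = FALSE])$f
  }
  out
}
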