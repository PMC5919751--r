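# Correction for gene flow from an external population H5, and estimation
# of the admixture proportion alpha.
#
# If an ingroup (H1 or H2) received a fraction alpha of its genome from an
# external population H5, the observed pattern distribution of the tree
# (((H1,H2)H3)H4) is the mixture p_1to4 = (1-alpha) * p_un + alpha * p_out,
# where p_out is the pattern distribution of the tree with H5 substituted
# for the admixed ingroup and p_un is the (unobservable) distribution the
# tree would have had without admixture. Solving for p_un removes the gene
# flow; requiring E[D_un] = 0 identifies alpha when it is unknown.

#' Remove external admixture from a pattern distribution
#'
#' Computes `p_un = (p_1to4 - alpha * p_out) / (1 - alpha)` entrywise,
#' followed by the negativity policy. At `alpha = 0` this is the identity.
#'
#' @param p_1to4 observed pattern masses of the core tree (length-256
#'   vector or `blocks x 256` matrix; per-site frequency-quadruple terms
#'   work the same way since the map is entrywise affine).
#' @param p_out pattern masses with the introgressing population H5 in
#'   place of the admixed ingroup; same shape as `p_1to4`.
#' @param alpha admixture proportion in `[0, 1)`.
#' @param negativity `"clamp"` or `"strict"`.
#' @return corrected masses, same shape as the input.
#' @export
correct_admixture <- function(p_1to4, p_out, alpha, negativity = "clamp") {
  if (alpha < 0 || alpha >= 1) stop_config("alpha must lie in [0, 1)")
  stopifnot(length(p_1to4) == length(p_out))
  apply_negativity_policy((p_1to4 - alpha * p_out) / (1 - alpha), negativity)
}

# D of the admixture-corrected statistic at a given alpha, from block X/Y
# sums of the two trees. The (1-alpha) factors cancel in the ratio.
d_un_value <- function(alpha, Xp, Yp, Xq, Yq) {
  (sum(Xp) - alpha * sum(Xq)) / (sum(Yp) - alpha * sum(Yq))
}

#' Estimate the admixture proportion from an external population
#'
#' Finds the `alpha` at which the admixture-corrected D-statistic `D_un`
#' crosses zero (the corrected tree then satisfies the null hypothesis of
#' treeness). `D_un(alpha)` is a ratio of functions affine in `alpha` and
#' is monotone between the bracket ends, so the root is located by
#' bisection. The standard error is a delete-one-block jackknife of the
#' root itself (the root is re-estimated on every leave-one-block-out
#' dataset).
#'
#' @param x a [site_table()] or [simulate_scenario()] result.
#' @param config a [pop_config()] with an `H5` (or `h5`-named) population.
#' @param h5 label of the introgressing population.
#' @param admixed which ingroup (`"H1"` or `"H2"`) received the gene flow.
#' @param alpha_max upper end of the search bracket (default 0.5; beyond
#'   that the "minor contributor" reading of alpha inverts).
#' @param tol bisection tolerance on alpha.
#' @param error_matrices optional per-population error matrices applied to
#'   both trees before estimation (error correction precedes admixture
#'   correction).
#' @param block_size jackknife block length in bp.
#' @param grid_n number of points of the returned `D_un(alpha)` curve.
#' @return object of class `alpha_estimate`: `alpha_hat`, `SE`, `curve`
#'   (data.frame of alpha vs `D_un`), `n_blocks`. If `D_un` does not
#'   change sign on `[0, alpha_max]`, `alpha_hat` is `NA` and the curve is
#'   returned for inspection.
#' @export
estimate_alpha <- function(x, config = NULL, h5 = "H5", admixed = "H1",
                           alpha_max = 0.5, tol = 1e-4,
                           error_matrices = NULL, block_size = NULL,
                           grid_n = 51) {
  pure <- NULL
  if (inherits(x, "sim_data")) {
    config <- config %||% x$config
    pure <- x$pure_sites
    x <- x$site_table
  }
  if (is.null(config)) stop_config("a pop_config is required")
  if (is.null(config$populations[[h5]]))
    stop_config("population ", h5, " not configured")
  if (!(admixed %in% c("H1", "H2"))) stop_config("admixed must be H1 or H2")
  block_size <- block_size %||% config$block_size
  x <- intersect_sites(x, config)
  bidx <- block_index(x$chrom, x$pos, block_size)
  pops4 <- c("H1", "H2", "H3", "H4")
  pops_out <- pops4; pops_out[pops_out == admixed] <- h5
  freqs <- population_freqs_all(x, config, union(pops4, h5))
  PB <- add_pure_sites(pattern_block_sums(freqs, pops4, bidx), pure)
  PBo <- add_pure_sites(pattern_block_sums(freqs, pops_out, bidx), pure)
  Pp <- PB$P; Pq <- PBo$P
  if (!is.null(error_matrices)) {
    elist <- lapply(pops4, function(p) error_matrices[[p]] %||% diag(4))
    elist_o <- lapply(pops_out, function(p) error_matrices[[p]] %||% diag(4))
    Pp <- correct_pattern_probs(Pp, elist, negativity = "strict")
    Pq <- correct_pattern_probs(Pq, elist_o, negativity = "strict")
  }
  bp <- blocks_from_patterns(Pp, PB$m)
  bq <- blocks_from_patterns(Pq, PBo$m)
  # D_un(alpha) = 0 iff its numerator X_p - alpha * X_q = 0 (affine and
  # strictly monotone in alpha when X_q != 0), so bisection brackets the
  # numerator; the denominator may cross zero inside the bracket, which
  # would fool a sign test on the ratio itself.
  root1 <- function(keep) {
    f <- function(a) sum(bp$X[keep]) - a * sum(bq$X[keep])
    f0 <- f(0); f1 <- f(alpha_max)
    if (is.na(f0) || is.na(f1)) return(NA_real_)
    if (f0 * f1 > 0) {
      # no root inside the bracket; if the unconstrained affine root lies
      # below zero the constrained (alpha >= 0) estimate is the boundary
      Xq <- sum(bq$X[keep])
      if (Xq != 0 && sum(bp$X[keep]) / Xq < 0) return(0)
      return(NA_real_)
    }
    lo <- 0; hi <- alpha_max
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  g <- nrow(bp)
  all_b <- rep(TRUE, g)
  alpha_hat <- root1(all_b)
  grid <- seq(0, alpha_max, length.out = grid_n)
  curve <- data.frame(
    alpha = grid,
    D_un = vapply(grid, d_un_value, numeric(1),
                  Xp = bp$X, Yp = bp$Y, Xq = bq$X, Yq = bq$Y))
  if (is.na(alpha_hat)) {
    warning("D_un does not change sign on [0, ", alpha_max,
            "]; returning the curve only")
    return(structure(list(alpha_hat = NA_real_, SE = NA_real_,
                          curve = curve, n_blocks = g),
                     class = "alpha_estimate"))
  }
  loo <- vapply(seq_len(g), function(b) {
    keep <- all_b; keep[b] <- FALSE; root1(keep)
  }, numeric(1))
  ok <- !is.na(loo)
  SE <- if (sum(ok) >= 2) {
    gg <- sum(ok)
    sqrt((gg - 1) / gg * sum((loo[ok] - mean(loo[ok]))^2))
  } else NA_real_
  structure(list(alpha_hat = alpha_hat, SE = SE, curve = curve,
                 n_blocks = g),
            class = "alpha_estimate")
}

#' @export
print.alpha_estimate <- function(x, ...) {
  cat(sprintf("admixture proportion estimate: alpha = %s (jackknife SE %s), %d blocks\n",
              format(x$alpha_hat, digits = 4), format(x$SE, digits = 3),
              x$n_blocks))
  invisible(x)
}
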