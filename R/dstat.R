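# Core D-statistic machinery: per-site ABBA/BABA terms, the three
# evaluation modes (extended = weighted frequencies from all reads,
# one_base = classic single sampled base, genotype = known genotypes),
# block aggregation and the weighted block jackknife.

#' Per-site numerator/denominator terms of the D-statistic
#'
#' For focal-allele frequencies `q1..q4` of populations H1..H4 the per-site
#' terms are `X = (q1-q2)(q3-q4)` and
#' `Y = (q1+q2-2*q1*q2)(q3+q4-2*q3*q4)`, together with the di-allelic
#' pattern probabilities `pABBA = q1*q4*(1-q2)*(1-q3) + (1-q1)*(1-q4)*q2*q3`
#' and `pBABA = (1-q1)*q2*(1-q3)*q4 + q1*(1-q2)*q3*(1-q4)`. Identities
#' `X = pBABA - pABBA` and `Y = pABBA + pBABA` hold exactly, so positive
#' `X` means an excess of BABA.
#'
#' @param q1,q2,q3,q4 numeric vectors of frequencies in `[0,1]`.
#' @return list of numeric vectors `X`, `Y`, `pABBA`, `pBABA`.
#' @export
site_terms <- function(q1, q2, q3, q4) {
  pABBA <- q1 * q4 * (1 - q2) * (1 - q3) + (1 - q1) * (1 - q4) * q2 * q3
  pBABA <- (1 - q1) * q2 * (1 - q3) * q4 + q1 * (1 - q2) * q3 * (1 - q4)
  list(X = (q1 - q2) * (q3 - q4),
       Y = (q1 + q2 - 2 * q1 * q2) * (q3 + q4 - 2 * q3 * q4),
       pABBA = pABBA, pBABA = pBABA)
}

# sites x 256 matrix of pattern probabilities prod_j f_j(a_j), columns in
# lexicographic order AAAA..TTTT (position 4 fastest).
pattern_prob_matrix <- function(f1, f2, f3, f4) {
  if (is.null(dim(f1))) {
    f1 <- matrix(f1, 1); f2 <- matrix(f2, 1)
    f3 <- matrix(f3, 1); f4 <- matrix(f4, 1)
  }
  A <- f1[, rep(1:4, each = 4), drop = FALSE] *
    f2[, rep(1:4, times = 4), drop = FALSE]
  B <- A[, rep(1:16, each = 4), drop = FALSE] *
    f3[, rep(1:4, times = 16), drop = FALSE]
  B[, rep(1:64, each = 4), drop = FALSE] *
    f4[, rep(1:4, times = 64), drop = FALSE]
}

#' Four-allele pattern probabilities and D terms
#'
#' Works on the full 4-base simplex: the probability of the ordered allele
#' pattern `(a1,a2,a3,a4)` is the product `f1(a1)*f2(a2)*f3(a3)*f4(a4)` of
#' the population frequency vectors. `pABBA` sums the 12 patterns
#' `(x,y,y,x)` with `x != y`, `pBABA` the 12 patterns `(x,y,x,y)`;
#' `X = pBABA - pABBA`, `Y = pABBA + pBABA`. With `drop_transitions` the
#' patterns whose allele pair is \{A,G\} or \{C,T\} are excluded from both
#' sums.
#'
#' @param f1,f2,f3,f4 length-4 simplex vectors (or `sites x 4` matrices).
#' @param drop_transitions exclude transition-pair patterns?
#' @param tol tolerance for the simplex (sum-to-1) check.
#' @return list of vectors `X`, `Y`, `pABBA`, `pBABA` plus `patterns`
#'   (the `sites x 256` probability matrix).
#' @export
pattern_terms <- function(f1, f2, f3, f4, drop_transitions = FALSE,
                          tol = 1e-6) {
  for (f in list(f1, f2, f3, f4)) {
    s <- if (is.null(dim(f))) sum(f) else rowSums(f)
    if (any(abs(s - 1) > tol) || any(f < -tol))
      stop("frequency vectors must lie on the 4-simplex")
  }
  P <- pattern_prob_matrix(f1, f2, f3, f4)
  ai <- pattern_abba_idx(drop_transitions)
  bi <- pattern_baba_idx(drop_transitions)
  pABBA <- rowSums(P[, ai, drop = FALSE])
  pBABA <- rowSums(P[, bi, drop = FALSE])
  list(X = pBABA - pABBA, Y = pABBA + pBABA,
       pABBA = pABBA, pBABA = pBABA, patterns = P)
}

#' Sample one base per site from pooled read counts
#'
#' The classic D-statistic replaces a population's allele frequency by a
#' single base drawn with probabilities proportional to the pooled base
#' counts. Uses R's RNG; call `set.seed()` for reproducibility.
#'
#' @param counts length-4 count vector or `sites x 4` matrix of pooled
#'   population counts (every row must have depth >= 1).
#' @return integer base index (1=A..4=T) per site.
#' @export
sample_one_base <- function(counts) {
  m <- if (is.null(dim(counts))) matrix(counts, 1) else counts
  n <- rowSums(m)
  if (any(n < 1)) stop("sample_one_base: site with zero pooled depth")
  u <- stats::runif(nrow(m)) * n
  c1 <- m[, 1]; c2 <- c1 + m[, 2]; c3 <- c2 + m[, 3]
  b <- 1L + (u > c1) + (u > c2) + (u > c3)
  as.integer(b)
}

#' Population allele frequency from called genotypes
#'
#' @param g vector of diploid dosages in `{0,1,2}` (`NA` = missing).
#' @return frequency `sum(g) / (2 * n_called)`, or `NA` if all missing.
#' @export
genotype_freq <- function(g) {
  ok <- !is.na(g)
  if (!any(ok)) return(NA_real_)
  sum(g[ok]) / (2 * sum(ok))
}

#' Transition-site filter
#'
#' Returns `TRUE` for sites whose segregating allele pair is a
#' transversion (kept) and `FALSE` for the transition pairs \{A,G\} and
#' \{C,T\} (removed) — the standard mitigation for post-mortem deamination
#' damage in ancient DNA.
#'
#' @param major,minor integer base indices (1=A..4=T) of the two observed
#'   alleles per site.
#' @return logical keep-vector.
#' @export
remove_transitions <- function(major, minor) {
  !is_transition_pair(major, minor)
}

#' Sum per-site D terms into genomic blocks
#'
#' @param terms list/data.frame with per-site `X`, `Y` (and optionally
#'   `pABBA`, `pBABA`).
#' @param chrom,pos site coordinates.
#' @param block_size block length in bp (default 5 Mb).
#' @return data.frame with one row per non-empty block: `block`, `X`, `Y`,
#'   `m` (site count), `pABBA`, `pBABA` when available.
#' @export
aggregate_blocks <- function(terms, chrom, pos, block_size = 5e6) {
  b <- block_index(chrom, pos, block_size)
  out <- data.frame(block = sort(unique(b)))
  out$X <- as.vector(rowsum(terms$X, b))
  out$Y <- as.vector(rowsum(terms$Y, b))
  out$m <- as.vector(rowsum(rep(1L, length(b)), b))
  if (!is.null(terms$pABBA)) {
    out$pABBA <- as.vector(rowsum(terms$pABBA, b))
    out$pBABA <- as.vector(rowsum(terms$pBABA, b))
  }
  out
}

#' Weighted block-jackknife D-statistic
#'
#' Computes `D = sum(X_b) / sum(Y_b)` over genomic blocks and its standard
#' error by the weighted delete-one-block jackknife for ratio estimators
#' (Busing-style pseudovalues), with block weights proportional to the
#' denominator mass `Y_b`. `Z = D / SE` is referred to the standard
#' normal; the conventional rejection threshold `|Z| > 3` corresponds to a
#' two-tailed p-value of about 0.001. Blocks with `Y_b = 0` carry no
#' information and are dropped.
#'
#' @param blocks data.frame with columns `X`, `Y` (and optionally `m`,
#'   `pABBA`, `pBABA`), one row per block.
#' @param weights optional non-negative jackknife block masses. Default is
#'   the denominator mass `Y_b` (and blocks with `Y_b <= 0` are dropped as
#'   uninformative). Corrected pattern data can carry legitimately
#'   negative or zero `Y_b` fluctuations; such callers pass the per-block
#'   site counts instead, and every block is kept in the sums.
#' @param mode label stored in the result.
#' @param corrections character vector of applied corrections (metadata).
#' @param sign_convention `"baba-abba"` (positive D = BABA excess; the
#'   orientation of the defining equation) or `"abba-baba"` (negated, the
#'   common ABBA-minus-BABA orientation).
#' @return object of class `dresult`: `D`, `SE`, `Z`, `p` (two-tailed
#'   normal), `n_blocks`, `n_sites`, `abba_mass`, `baba_mass`, `mode`,
#'   `corrections`, `sign_convention`. `Z`/`p` are `NA` when `SE = 0`.
#' @export
jackknife_D <- function(blocks, weights = NULL, mode = "extended",
                        corrections = character(0),
                        sign_convention = c("baba-abba", "abba-baba")) {
  sign_convention <- match.arg(sign_convention)
  if (is.null(weights)) {
    blocks <- blocks[blocks$Y > 0, , drop = FALSE]
    w <- blocks$Y
    if (nrow(blocks) == 0) stop("D undefined: no denominator mass")
  } else {
    stopifnot(length(weights) == nrow(blocks), all(weights >= 0))
    blocks <- blocks[weights > 0, , drop = FALSE]
    w <- weights[weights > 0]
    if (nrow(blocks) == 0) stop("D undefined: no blocks with weight")
    # corrected denominators may fluctuate to or below zero when the true
    # ABBA/BABA mass is tiny; the ratio then degenerates but its jackknife
    # SE inflates in step, so Z correctly reports "no signal"
  }
  TY <- sum(blocks$Y)
  if (TY == 0) stop("D undefined: zero denominator mass")
  sgn <- if (sign_convention == "baba-abba") 1 else -1
  TX <- sum(blocks$X)
  D <- sgn * TX / TY
  g <- nrow(blocks)
  if (g < 2) {
    res <- list(D = D, SE = NA_real_, Z = NA_real_, p = NA_real_,
                n_blocks = g, n_sites = sum(blocks$m %||% NA))
  } else {
    Tw <- sum(w)
    D_del <- sgn * (TX - blocks$X) / (TY - blocks$Y)
    h <- Tw / w                              # inverse relative block weight
    theta_J <- g * D - sum((1 - w / Tw) * D_del)
    ps <- h * D - (h - 1) * D_del
    v <- sum((ps - theta_J)^2 / (h - 1)) / g
    SE <- sqrt(max(v, 0))
    if (SE < 1e-12 * (abs(D) + 1)) SE <- 0   # identical blocks: no spread
    Z <- if (SE > 0) D / SE else NA_real_
    p <- if (SE > 0) 2 * stats::pnorm(-abs(Z)) else NA_real_
    res <- list(D = D, SE = SE, Z = Z, p = p, n_blocks = g,
                n_sites = if (is.null(blocks$m)) NA_integer_
                          else sum(blocks$m))
  }
  res$abba_mass <- if (is.null(blocks$pABBA)) NA_real_ else sum(blocks$pABBA)
  res$baba_mass <- if (is.null(blocks$pBABA)) NA_real_ else sum(blocks$pBABA)
  res$mode <- mode
  res$corrections <- corrections
  res$sign_convention <- sign_convention
  structure(res, class = "dresult")
}

#' @export
print.dresult <- function(x, ...) {
  cat(sprintf("D-statistic (%s mode, %s)\n", x$mode, x$sign_convention))
  cat(sprintf("  D = %.6f  SE = %.6f  Z = %.3f  p = %.3g\n",
              x$D, x$SE, x$Z, x$p))
  cat(sprintf("  blocks = %d  sites = %s  ABBA mass = %.4g  BABA mass = %.4g\n",
              x$n_blocks, format(x$n_sites), x$abba_mass, x$baba_mass))
  if (length(x$corrections))
    cat("  corrections:", paste(x$corrections, collapse = ", "), "\n")
  invisible(x)
}

# Pooled counts (sites x 4) for one population.
pooled_counts <- function(x, config, pop) {
  cols <- match(config$populations[[pop]], x$individuals)
  m <- matrix(0, n_sites(x), 4)
  for (b in 1:4)
    m[, b] <- rowSums(x$counts[, cols, b, drop = FALSE])
  m
}

# Major/minor allele per site from counts pooled over the given
# populations; ties broken in A<C<G<T order. Returns list(major, minor).
major_minor <- function(pooled) {
  major <- max.col(pooled, ties.method = "first")
  p2 <- pooled
  p2[cbind(seq_len(nrow(p2)), major)] <- -1
  minor <- max.col(p2, ties.method = "first")
  list(major = as.integer(major), minor = as.integer(minor))
}

# Block-level 256-pattern sums for four populations (IDs of config pops).
# Returns list(P = blocks x 256, m = per-block site counts, block = ids).
# Sites where every population's frequency vector is degenerate (a single
# base) contribute a unit delta to one pattern; they are accumulated by
# tabulation so that genomes dominated by invariant positions stay cheap.
pattern_block_sums <- function(freqs, pops, bidx) {
  f <- freqs[pops]
  nb <- max(bidx)
  m <- as.vector(rowsum(rep(1L, length(bidx)), bidx))
  amax <- lapply(f, max.col, ties.method = "first")
  fmax <- mapply(function(fj, aj) fj[cbind(seq_along(aj), aj)],
                 f, amax, SIMPLIFY = TRUE)
  pure <- if (is.matrix(fmax)) rowSums(fmax >= 1 - 1e-12) == 4L
          else all(fmax >= 1 - 1e-12)   # single-site input
  kidx <- (amax[[1]] - 1L) * 64L + (amax[[2]] - 1L) * 16L +
    (amax[[3]] - 1L) * 4L + amax[[4]]
  PB <- matrix(0, nb, 256)
  if (any(pure)) {
    tab <- tabulate((bidx[pure] - 1L) * 256L + kidx[pure], nbins = nb * 256L)
    PB <- matrix(tab, nb, 256, byrow = TRUE)
  }
  if (any(!pure)) {
    mx <- which(!pure)
    # chunked so the sites x 256 product stays within ~200 MB
    for (chunk in split(mx, ceiling(seq_along(mx) / 100000))) {
      P <- pattern_prob_matrix(f[[1]][chunk, , drop = FALSE],
                               f[[2]][chunk, , drop = FALSE],
                               f[[3]][chunk, , drop = FALSE],
                               f[[4]][chunk, , drop = FALSE])
      S <- rowsum(P, bidx[chunk])
      PB[as.integer(rownames(S)), ] <- PB[as.integer(rownames(S)), ] + S
    }
  }
  list(P = PB, m = m, block = seq_len(nb))
}

# Fold per-block pure-site masses (invariant covered sites, one delta on
# the monomorphic pattern of their base) into pattern block sums.
add_pure_sites <- function(ps, pure) {
  if (is.null(pure)) return(ps)
  if (nrow(pure) != nrow(ps$P))
    stop("pure-site block count does not match pattern blocks")
  mono_idx <- (1:4 - 1L) * 85L + 1L      # AAAA, CCCC, GGGG, TTTT
  for (a in 1:4) ps$P[, mono_idx[a]] <- ps$P[, mono_idx[a]] + pure[, a]
  ps$m <- ps$m + as.integer(rowSums(pure))
  ps
}

blocks_from_patterns <- function(PB, m, drop_transitions = FALSE) {
  ai <- pattern_abba_idx(drop_transitions)
  bi <- pattern_baba_idx(drop_transitions)
  pABBA <- rowSums(PB[, ai, drop = FALSE])
  pBABA <- rowSums(PB[, bi, drop = FALSE])
  data.frame(block = seq_len(nrow(PB)), X = pBABA - pABBA,
             Y = pABBA + pBABA, m = m, pABBA = pABBA, pBABA = pBABA)
}

#' Block-level pattern sums for a population quartet
#'
#' Accumulates, per genomic block, the 256-pattern probability masses of
#' the four populations' weighted frequency estimates. This is the
#' intermediate the pattern-space corrections operate on; computing it
#' once and deriving several corrected/uncorrected statistics with
#' [D_from_pattern_blocks()] avoids repeating the frequency estimation.
#'
#' @param x a [site_table()] or [simulate_scenario()] result.
#' @param config a [pop_config()].
#' @param pops four population labels in tree order (substitute `"H5"`
#'   for an ingroup to build the outgroup-replaced tree of the admixture
#'   correction).
#' @param block_size block length in bp.
#' @return object of class `pattern_blocks`: `P` (`blocks x 256` matrix),
#'   `m` (per-block site counts), `block`, `pops`.
#' @export
pattern_blocks <- function(x, config = NULL,
                           pops = c("H1", "H2", "H3", "H4"),
                           block_size = NULL) {
  pure <- NULL
  if (inherits(x, "sim_data")) {
    config <- config %||% x$config
    pure <- x$pure_sites
    x <- x$site_table
  }
  if (is.null(config)) stop_config("a pop_config is required")
  block_size <- block_size %||% config$block_size
  x <- intersect_sites(x, config)
  if (n_sites(x) == 0) stop("no usable sites after filtering")
  bidx <- block_index(x$chrom, x$pos, block_size)
  freqs <- population_freqs_all(x, config, unique(pops))
  ps <- add_pure_sites(pattern_block_sums(freqs, pops, bidx), pure)
  structure(list(P = ps$P, m = ps$m, block = ps$block, pops = pops),
            class = "pattern_blocks")
}

#' D-statistic from precomputed pattern blocks
#'
#' Applies the optional error and admixture corrections to block-level
#' pattern sums (see [pattern_blocks()]) and runs the block jackknife.
#'
#' @param pb a `pattern_blocks` object for the core tree.
#' @param error_matrices named list (population -> 4x4 matrix) for the
#'   group error correction; matched against `pb$pops`.
#' @param alpha optional admixture proportion; requires `pb_out`.
#' @param pb_out `pattern_blocks` for the tree with the introgressing
#'   population substituted for the admixed ingroup.
#' @param transversions_only exclude transition-pair patterns?
#' @param negativity `"strict"` (default) or `"clamp"`.
#' @param sign_convention see [jackknife_D()].
#' @return a `dresult`.
#' @export
D_from_pattern_blocks <- function(pb, error_matrices = NULL,
                                  alpha = NULL, pb_out = NULL,
                                  transversions_only = FALSE,
                                  negativity = "strict",
                                  sign_convention = c("baba-abba",
                                                      "abba-baba")) {
  sign_convention <- match.arg(sign_convention)
  PB <- pb$P
  corrections <- character(0)
  if (!is.null(error_matrices)) {
    elist <- lapply(pb$pops, function(p) error_matrices[[p]] %||% diag(4))
    PB <- correct_pattern_probs(PB, elist, negativity = negativity)
    corrections <- c(corrections, "error")
  }
  if (!is.null(alpha)) {
    if (is.null(pb_out)) stop_config("alpha correction requires pb_out")
    PBo <- pb_out$P
    if (!is.null(error_matrices)) {
      elist_o <- lapply(pb_out$pops,
                        function(p) error_matrices[[p]] %||% diag(4))
      PBo <- correct_pattern_probs(PBo, elist_o, negativity = negativity)
    }
    PB <- correct_admixture(PB, PBo, alpha, negativity = negativity)
    corrections <- c(corrections, sprintf("admixture(alpha=%g)", alpha))
  }
  if (transversions_only) corrections <- c(corrections, "transversions-only")
  blocks <- blocks_from_patterns(PB, pb$m,
                                 drop_transitions = transversions_only)
  jackknife_D(blocks, weights = pb$m, mode = "extended",
              corrections = corrections, sign_convention = sign_convention)
}

#' Compute the D-statistic from counts (or genotypes)
#'
#' End-to-end pipeline: site filtering (pooled depth >= 1 in each of
#' H1..H4), per-population frequency estimation according to `mode`,
#' optional filters and corrections, per-site terms, 5-Mb (default) block
#' aggregation and the weighted block jackknife.
#'
#' Modes:
#' * `"extended"` — minimal-variance weighted allele frequencies from all
#'   reads of all individuals (see [population_freq()]).
#' * `"one_base"` — one base sampled per population per site from the
#'   pooled read counts (the classic statistic; uses R's RNG).
#' * `"genotype"` — frequencies from true/called genotypes; requires
#'   `genotypes` (or a simulation object that carries them).
#'
#' Error correction (`error_matrices`) and external-admixture correction
#' (`alpha`) operate on the 256-pattern block sums of the extended mode:
#' pattern distributions are corrected per block before the jackknife, so
#' the standard error reflects the corrected quantities. Both corrections
#' compose; errors are removed first.
#'
#' @param x a [site_table()] or the result of [simulate_scenario()].
#' @param config a [pop_config()] (defaults to the simulation's own).
#' @param mode `"extended"`, `"one_base"` or `"genotype"`.
#' @param block_size jackknife block length in bp.
#' @param transversions_only drop transition sites/patterns (\{A,G\},
#'   \{C,T\})?
#' @param outgroup_monoallelic restrict to sites where the pooled outgroup
#'   reads show a single base?
#' @param error_matrices optional named list of per-population 4x4 error
#'   matrices (entries for `H1..H4`, optionally `H5`; missing entries are
#'   treated as error-free). Use [mean_population_error()] to average
#'   per-individual estimates.
#' @param alpha optional known admixture proportion of an external
#'   population `h5` into `admixed`; applies the pattern-space
#'   admixture correction.
#' @param h5,admixed population labels for the admixture correction.
#' @param genotypes named list (per population) of `individuals x sites`
#'   dosage matrices for `mode = "genotype"`.
#' @param negativity policy for negative corrected masses: `"strict"`
#'   (default here: raw values propagate, so noise fluctuations cancel in
#'   the block sums and the statistic stays unbiased) or `"clamp"` (zero
#'   negatives and renormalise each block; safer for reporting pattern
#'   probabilities, but biases the test statistic).
#' @param sign_convention see [jackknife_D()].
#' @return a `dresult` (see [jackknife_D()]).
#' @export
compute_D <- function(x, config = NULL,
                      mode = c("extended", "one_base", "genotype"),
                      block_size = NULL,
                      transversions_only = FALSE,
                      outgroup_monoallelic = FALSE,
                      error_matrices = NULL,
                      alpha = NULL, h5 = "H5", admixed = "H1",
                      genotypes = NULL,
                      negativity = "strict",
                      sign_convention = c("baba-abba", "abba-baba")) {
  mode <- match.arg(mode)
  sign_convention <- match.arg(sign_convention)
  pure <- NULL
  if (inherits(x, "sim_data")) {
    config <- config %||% x$config
    genotypes <- genotypes %||% x$genotypes
    pure <- x$pure_sites
    x <- x$site_table
  }
  if (is.null(config)) stop_config("a pop_config is required")
  block_size <- block_size %||% config$block_size
  mask <- intersect_mask(x, config)
  x <- subset_sites(x, mask)
  if (!is.null(genotypes))
    genotypes <- lapply(genotypes, function(G) G[, mask, drop = FALSE])
  if (n_sites(x) == 0) stop("no usable sites after filtering")
  corrections <- character(0)
  if (outgroup_monoallelic) {
    mono <- rowSums(pooled_counts(x, config, "H4") > 0) == 1L
    x <- subset_sites(x, mono)
    if (!is.null(genotypes))
      genotypes <- lapply(genotypes, function(G) G[, mono, drop = FALSE])
    if (n_sites(x) == 0) stop("no usable sites after filtering")
    corrections <- c(corrections, "monoallelic-outgroup")
  }
  bidx <- block_index(x$chrom, x$pos, block_size)

  pattern_mode <- !is.null(error_matrices) || !is.null(alpha)
  if (pattern_mode) {
    if (mode != "extended")
      stop_config("error/admixture corrections require mode = 'extended'")
    pops4 <- c("H1", "H2", "H3", "H4")
    need <- pops4
    if (!is.null(alpha)) {
      if (!(admixed %in% c("H1", "H2")))
        stop_config("admixed must be H1 or H2")
      if (is.null(config$populations[[h5]]))
        stop_config("population ", h5, " not configured")
      need <- union(need, h5)
    }
    freqs <- population_freqs_all(x, config, need)
    ps <- add_pure_sites(pattern_block_sums(freqs, pops4, bidx), pure)
    PB <- ps$P
    if (!is.null(error_matrices)) {
      elist <- lapply(pops4, function(p) error_matrices[[p]] %||% diag(4))
      PB <- correct_pattern_probs(PB, elist, negativity = negativity)
      corrections <- c(corrections, "error")
    }
    if (!is.null(alpha)) {
      pops_out <- pops4
      pops_out[pops_out == admixed] <- h5
      PBo <- add_pure_sites(pattern_block_sums(freqs, pops_out, bidx),
                            pure)$P
      if (!is.null(error_matrices)) {
        elist_o <- lapply(pops_out, function(p) error_matrices[[p]] %||% diag(4))
        PBo <- correct_pattern_probs(PBo, elist_o, negativity = negativity)
      }
      PB <- correct_admixture(PB, PBo, alpha, negativity = negativity)
      corrections <- c(corrections, sprintf("admixture(alpha=%g,%s<-%s)",
                                            alpha, admixed, h5))
    }
    if (transversions_only) corrections <- c(corrections, "transversions-only")
    blocks <- blocks_from_patterns(PB, ps$m,
                                   drop_transitions = transversions_only)
    return(jackknife_D(blocks, weights = ps$m, mode = mode,
                       corrections = corrections,
                       sign_convention = sign_convention))
  }

  pops4 <- c("H1", "H2", "H3", "H4")
  pooled <- lapply(pops4, function(p) pooled_counts(x, config, p))
  names(pooled) <- pops4
  all_pooled <- pooled$H1 + pooled$H2 + pooled$H3 + pooled$H4
  mm <- major_minor(all_pooled)
  keep <- rep(TRUE, n_sites(x))
  if (transversions_only && mode != "genotype") {
    keep <- keep & remove_transitions(mm$major, mm$minor)
    corrections <- c(corrections, "transversions-only")
  }

  q <- matrix(NA_real_, n_sites(x), 4)
  if (mode == "extended") {
    # collapse to the two most frequent pooled alleles; reads of other
    # bases are discarded (depth weights recomputed from the remaining)
    for (j in 1:4) {
      cols <- match(config$populations[[pops4[j]]], x$individuals)
      cnt <- x$counts[, cols, , drop = FALSE]
      ns <- dim(cnt)[1]; ni <- dim(cnt)[2]
      idx <- cbind(rep(seq_len(ns), ni), rep(seq_len(ni), each = ns))
      cmaj <- matrix(cnt[cbind(idx, mm$major[idx[, 1]])], ns, ni)
      cmin <- matrix(cnt[cbind(idx, mm$minor[idx[, 1]])], ns, ni)
      n2 <- cmaj + cmin
      w <- raw_weight(n2)
      wsum <- rowSums(w)
      w <- w / ifelse(wsum > 0, wsum, 1)
      q[, j] <- rowSums(w * cmaj / ifelse(n2 > 0, n2, 1))
      q[wsum == 0, j] <- NA_real_
    }
  } else if (mode == "one_base") {
    for (j in 1:4) {
      b <- sample_one_base(pooled[[pops4[j]]])
      q[, j] <- as.numeric(b == mm$major)
    }
  } else {
    if (is.null(genotypes))
      stop_config("mode='genotype' requires genotype matrices")
    for (j in 1:4) {
      G <- genotypes[[pops4[j]]]
      if (is.null(G)) stop_config("genotypes missing for ", pops4[j])
      nc <- colSums(!is.na(G))
      q[, j] <- colSums(G, na.rm = TRUE) / (2 * nc)
      q[nc == 0, j] <- NA_real_
    }
    if (transversions_only)
      warning("transversions_only ignored in genotype mode (allele bases unknown)")
  }
  keep <- keep & rowSums(is.na(q)) == 0L
  if (!any(keep)) stop("no usable sites after filtering")
  st <- site_terms(q[keep, 1], q[keep, 2], q[keep, 3], q[keep, 4])
  blocks <- aggregate_blocks(st, x$chrom[keep], x$pos[keep], block_size)
  jackknife_D(blocks, mode = mode, corrections = corrections,
              sign_convention = sign_convention)
}
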