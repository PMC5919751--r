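# Synthetic-data generator for the validation scenarios: tree-structured
# allele-frequency drift, pulse migration/admixture, diploid genotypes,
# Poisson read depth and injected type-specific base errors.
#
# Drift along a branch of t generations in a population of diploid
# effective size Ne is modelled by the Balding-Nichols distribution with
# fixation index F = 1 - exp(-t / (2 Ne)): the child frequency is a Beta
# draw with mean equal to the parent frequency and variance F p (1 - p).
# This frequency-level approximation replaces full coalescent simulation;
# it realises the moment structure the D-statistic tests (E[child] =
# parent, Var growing with branch length) at desk-scale speed. Sites are
# simulated independently; genomic blocks are synthetic coordinate
# assignments.

#' Identity-plus-one-substitution error matrix
#'
#' Convenience constructor for a type-specific error matrix with a single
#' elevated substitution rate, e.g. the A-to-G deamination-like error.
#'
#' @param rate substitution probability.
#' @param from,to bases (letters or indices).
#' @return an [error_matrix()].
#' @export
type_error_matrix <- function(rate, from = "A", to = "G") {
  if (is.character(from)) from <- base_index(from)
  if (is.character(to)) to <- base_index(to)
  stopifnot(from != to, rate >= 0, rate <= 1)
  e <- diag(4)
  e[from, from] <- 1 - rate
  e[from, to] <- rate
  error_matrix(e)
}

# Balding-Nichols drift of frequencies x over t generations.
drift_freq <- function(x, t, Ne) {
  if (t == 0) return(x)
  F <- 1 - exp(-t / (2 * Ne))
  out <- x
  seg <- x > 0 & x < 1
  if (!any(seg)) return(out)
  if (F >= 1 - 1e-12) {
    out[seg] <- stats::rbinom(sum(seg), 1L, x[seg])
    return(out)
  }
  k <- (1 - F) / F
  out[seg] <- stats::rbeta(sum(seg), k * x[seg], k * (1 - x[seg]))
  out
}

# Ancestral frequency from a neutral-SFS-like density proportional to 1/x
# on [1/(2Ne), 1 - 1/(2Ne)] (inverse-CDF sampling).
rancestral <- function(n, Ne) {
  a <- 1 / (2 * Ne)
  b <- 1 - a
  a * (b / a)^stats::runif(n)
}

#' Scenario presets for the simulator
#'
#' Returns the parameter set of one of the three validation scenarios:
#'
#' * `fig2A` — quartet tree (((H1,H2)H3)H4) with split times 0.5, 0.75,
#'   1.0 in units of 4Ne generations and a migration pulse from H3 into H1
#'   over the window 0.2-0.201. The ms-style rescaled migration rate
#'   `migration_ms` (0..280) converts to a per-generation fraction
#'   `migration_ms / (4 Ne)` (280 -> 0.7%) and is applied as a single
#'   pulse of total fraction `1 - (1 - rate)^window` over the 40-generation
#'   window. 5 diploids per population.
#' * `fig2B` — the same quartet without migration but with an A-to-G
#'   type-specific error of 0.005 injected in populations H1 and H3;
#'   1 diploid per population. Blocks are full 5-Mb regions with
#'   invariable positions included (theta = 100 per block), carried in
#'   an exact sparse representation (`sparse_invariants`): covered
#'   error-free invariant sites enter as per-block monomorphic-pattern
#'   masses and only error-hit plus polymorphic positions become
#'   explicit counts. Such simulations support the pattern-space
#'   (`pattern_blocks()`/corrections) and di-allelic count modes, but
#'   carry no genotype matrices.
#' * `fig2C` — quintet: an external population H5 admixes into H1 with
#'   proportion `alpha = 0.1` at 0.1 x 4Ne generations; ingroup splits at
#'   0.25, 0.5, 0.75. The source lineage separates from sampled H5 8000
#'   generations ago (so source and sample are separated by drift).
#'   5 diploids per population.
#'
#' Defaults shared by all presets: `Ne = 1e4`, mean depth 2x, 200 blocks
#' of 5 Mb with 2000 segregating sites each (override `n_blocks` /
#' `sites_per_block` for desk-scale runs).
#'
#' @param name `"fig2A"`, `"fig2B"` or `"fig2C"`.
#' @param overrides named list of fields to replace (e.g.
#'   `list(n_blocks = 20, migration_ms = 280)`).
#' @return object of class `scenario`.
#' @export
scenario_preset <- function(name, overrides = list()) {
  base <- list(Ne = 1e4, depth = 2, n_blocks = 200L, sites_per_block = 2000L,
               block_size = 5e6, error_matrices = NULL,
               segregating_only = TRUE)
  sc <- switch(name,
    fig2A = utils::modifyList(base, list(
      topology = "quartet",
      n_dip = c(H1 = 5L, H2 = 5L, H3 = 5L, H4 = 5L),
      t12 = 0.5, t123 = 0.75, t1234 = 1.0,      # units of 4Ne generations
      migration_ms = 0,
      migration_time = 0.2, migration_window = 0.001)),
    fig2B = utils::modifyList(base, list(
      topology = "quartet",
      n_dip = c(H1 = 1L, H2 = 1L, H3 = 1L, H4 = 1L),
      t12 = 0.5, t123 = 0.75, t1234 = 1.0,
      migration_ms = 0,
      migration_time = 0.2, migration_window = 0.001,
      # Type-specific errors act genome-wide: the bias of the uncorrected
      # statistic comes from spurious polymorphism at the (vastly more
      # numerous) invariable positions, so this scenario keeps them.
      # Blocks are full 5-Mb regions at the stated mutation density
      # (theta = 100 per block); the invariant positions are carried as
      # per-block pattern masses (sparse_invariants), with only the
      # polymorphic and error-affected positions materialised as counts,
      # which is exact because reads are Poisson and thin independently.
      segregating_only = FALSE,
      n_blocks = 20L,
      sites_per_block = 5000000L,
      theta_per_block = 100,
      sparse_invariants = TRUE,
      error_matrices = list(H1 = type_error_matrix(0.005, "A", "G"),
                            H3 = type_error_matrix(0.005, "A", "G")))),
    fig2C = utils::modifyList(base, list(
      topology = "quintet",
      n_dip = c(H1 = 5L, H2 = 5L, H3 = 5L, H4 = 5L, H5 = 5L),
      alpha = 0.1, admixed = "H1",
      t_admix = 0.1, t12 = 0.25, t123 = 0.5, t1234 = 0.75,
      t_src_split = 0.2,      # source lineage separates from sampled H5
      t_h5_root = 1.5)),      # truncated from the effectively infinite
                              # stated depth so ancestral variation survives
    stop_config("unknown preset '", name,
                "'; available: fig2A, fig2B, fig2C"))
  for (nm in names(overrides)) sc[[nm]] <- overrides[[nm]]
  sc$name <- name
  structure(sc, class = "scenario")
}

#' Migration-rate unit conversions for the simulation grid
#'
#' Converts an ms-style rescaled migration rate `4*Ne*m` into the
#' per-generation migrant fraction `m`, and into the equivalent single
#' pulse over the migration window.
#'
#' @param migration_ms rescaled rate (e.g. 280).
#' @param Ne diploid effective size.
#' @param window_4Ne window length in 4Ne-generation units (default 0.001).
#' @return list with `per_generation` (fraction) and `pulse` (total
#'   fraction `1 - (1 - m)^window_generations`).
#' @export
migration_units <- function(migration_ms, Ne = 1e4, window_4Ne = 0.001) {
  m <- migration_ms / (4 * Ne)
  w <- window_4Ne * 4 * Ne
  list(per_generation = m, pulse = 1 - (1 - m)^w)
}

# One batch of present-day frequencies (no segregation filter).
# Returns matrix n x npop. Times in the scenario are in 4Ne-generation
# units; converted to generations here.
sim_freqs_batch <- function(sc, n) {
  g <- function(t_units) t_units * 4 * sc$Ne
  Ne <- sc$Ne
  x0 <- rancestral(n, Ne)
  if (sc$topology == "quartet") {
    tm <- g(sc$migration_time)
    mig <- migration_units(sc$migration_ms %||% 0, Ne,
                           sc$migration_window %||% 0.001)$pulse
    x4 <- drift_freq(x0, g(sc$t1234), Ne)
    x123 <- drift_freq(x0, g(sc$t1234) - g(sc$t123), Ne)
    x12 <- drift_freq(x123, g(sc$t123) - g(sc$t12), Ne)
    x3_tm <- drift_freq(x123, g(sc$t123) - tm, Ne)
    x3 <- drift_freq(x3_tm, tm, Ne)
    x1_tm <- drift_freq(x12, g(sc$t12) - tm, Ne)
    x1 <- drift_freq((1 - mig) * x1_tm + mig * x3_tm, tm, Ne)
    x2 <- drift_freq(x12, g(sc$t12), Ne)
    cbind(H1 = x1, H2 = x2, H3 = x3, H4 = x4)
  } else {
    ta <- g(sc$t_admix); ts <- g(sc$t_src_split); tr <- g(sc$t_h5_root)
    x5_anc <- drift_freq(x0, tr - ts, Ne)        # H5 lineage at source split
    xsrc <- drift_freq(x5_anc, ts - ta, Ne)      # admixture source at pulse
    x5 <- drift_freq(x5_anc, ts, Ne)             # sampled H5 today
    x1234 <- drift_freq(x0, tr - g(sc$t1234), Ne)
    x4 <- drift_freq(x1234, g(sc$t1234), Ne)
    x123 <- drift_freq(x1234, g(sc$t1234) - g(sc$t123), Ne)
    x3 <- drift_freq(x123, g(sc$t123), Ne)
    x12 <- drift_freq(x123, g(sc$t123) - g(sc$t12), Ne)
    x2 <- drift_freq(x12, g(sc$t12), Ne)
    x1p <- drift_freq(x12, g(sc$t12) - ta, Ne)
    alpha <- sc$alpha %||% 0
    x1m <- if ((sc$admixed %||% "H1") == "H1")
      (1 - alpha) * x1p + alpha * xsrc else x1p
    x1 <- drift_freq(x1m, ta, Ne)
    if ((sc$admixed %||% "H1") == "H2") {
      # pulse into H2 instead: mix at the same time
      x2p <- drift_freq(x12, g(sc$t12) - ta, Ne)
      x2 <- drift_freq((1 - alpha) * x2p + alpha * xsrc, ta, Ne)
    }
    cbind(H1 = x1, H2 = x2, H3 = x3, H4 = x4, H5 = x5)
  }
}

#' Simulate present-day population allele frequencies
#'
#' Draws ancestral frequencies from a truncated 1/x density and pushes
#' them through the scenario's tree with Balding-Nichols drift per branch
#' (`F = 1 - exp(-t / (2 Ne))`) and pulse migration/admixture events.
#' Only sites still segregating somewhere among the sampled populations
#' (not all fixed for the same allele) are retained; batches are redrawn
#' until `n_sites` such sites have accumulated.
#'
#' @param scenario a [scenario_preset()] object.
#' @param n_sites number of segregating sites to return.
#' @return numeric matrix `n_sites x populations` of frequencies in
#'   `[0,1]`, columns named H1..H4(H5).
#' @export
simulate_freqs <- function(scenario, n_sites) {
  if (!isTRUE(scenario$segregating_only %||% TRUE))
    return(sim_freqs_batch(scenario, n_sites))
  got <- NULL
  need <- n_sites
  for (round in 1:200) {
    batch <- sim_freqs_batch(scenario, max(need * 2L, 1000L))
    seg <- !(rowSums(batch > 0) == 0L | rowSums(batch < 1) == 0L)
    batch <- batch[seg, , drop = FALSE]
    got <- rbind(got, batch)
    if (nrow(got) >= n_sites) break
    need <- n_sites - nrow(got)
  }
  if (nrow(got) < n_sites)
    stop("could not accumulate enough segregating sites")
  got[seq_len(n_sites), , drop = FALSE]
}

#' Simulate diploid genotypes from population frequencies
#'
#' Each genotype is an independent `Binomial(2, freq)` dosage draw.
#'
#' @param freqs numeric vector (one population) or matrix
#'   `sites x populations` of allele frequencies.
#' @param n_dip number of diploid individuals; a named vector (matching
#'   the frequency columns) when `freqs` is a matrix.
#' @return an `individuals x sites` integer matrix, or a named list of
#'   such matrices for matrix input.
#' @export
simulate_genotypes <- function(freqs, n_dip) {
  if (is.matrix(freqs)) {
    pops <- colnames(freqs)
    out <- lapply(pops, function(p)
      simulate_genotypes(freqs[, p], n_dip[[p]]))
    names(out) <- pops
    return(out)
  }
  ns <- length(freqs)
  p <- rep(freqs, each = n_dip)
  g <- integer(ns * n_dip)
  g[p >= 1] <- 2L
  mid <- p > 0 & p < 1
  if (any(mid)) g[mid] <- stats::rbinom(sum(mid), 2L, p[mid])
  matrix(g, nrow = n_dip, ncol = ns)
}

# Pass per-site true base counts (sites x 4) through the read-level error
# channel e by sequential binomial thinning; exact multinomial split.
channel_counts <- function(true_counts, e) {
  if (is.null(e) || all(unclass(e) == diag(4))) return(true_counts)
  e <- unclass(e)
  ns <- nrow(true_counts)
  out <- true_counts
  for (a in 1:4) {
    if (all(e[a, ] == (1:4 == a))) next      # identity row: reads unchanged
    idx <- which(true_counts[, a] > 0L)
    if (!length(idx)) next
    out[idx, a] <- 0L
    rem <- true_counts[idx, a]
    remp <- 1
    for (b in 1:4) {
      if (remp <= 0) break
      p <- min(e[a, b] / remp, 1)
      draw <- if (p >= 1 - 1e-12) rem
              else stats::rbinom(length(idx), rem, p)
      out[idx, b] <- out[idx, b] + draw
      rem <- rem - draw
      remp <- remp - e[a, b]
    }
  }
  out
}

#' Simulate reads from genotypes
#'
#' Per site and individual the read depth is `Poisson(lambda)`; each read
#' carries the individual's first allele with probability `dosage / 2`,
#' and the resulting true base counts are passed through the type-specific
#' error channel (a read with true base `a` is recorded as `b` with
#' probability `e(a,b)`).
#'
#' @param genotypes `individuals x sites` dosage matrix (one population).
#' @param lambda mean depth per individual.
#' @param alleles list with integer vectors `base1`, `base2` (per-site
#'   base indices of the allele counted by the dosage and of the other
#'   allele). Default A/C at every site.
#' @param e optional 4x4 error matrix applied to every individual.
#' @return array `sites x individuals x 4` of observed base counts.
#' @export
simulate_reads <- function(genotypes, lambda,
                           alleles = NULL, e = NULL) {
  ni <- nrow(genotypes); ns <- ncol(genotypes)
  if (is.null(alleles))
    alleles <- list(base1 = rep(1L, ns), base2 = rep(2L, ns))
  counts <- array(0L, c(ns, ni, 4))
  for (j in seq_len(ni)) {
    n <- stats::rpois(ns, lambda)
    g <- genotypes[j, ]
    k1 <- integer(ns)
    k1[g == 2L] <- n[g == 2L]
    het <- g == 1L
    if (any(het)) k1[het] <- stats::rbinom(sum(het), n[het], 0.5)
    true_counts <- matrix(0L, ns, 4)
    idx1 <- cbind(seq_len(ns), alleles$base1)
    idx2 <- cbind(seq_len(ns), alleles$base2)
    true_counts[idx1] <- true_counts[idx1] + k1
    true_counts[idx2] <- true_counts[idx2] + (n - k1)
    counts[, j, ] <- channel_counts(true_counts, e)
  }
  counts
}

#' Simulate a full scenario into count data
#'
#' End-to-end generator: population frequencies along the scenario's tree,
#' random di-allelic base pairs per site, diploid genotypes, Poisson-depth
#' reads through the per-population error channels, and synthetic genomic
#' coordinates (blocks of `block_size` bp on one chromosome). All
#' randomness flows from `seed`.
#'
#' @param scenario a [scenario_preset()] object.
#' @param seed integer seed.
#' @return object of class `sim_data`: `site_table` (the counts),
#'   `genotypes` (named list of dosage matrices, for genotype-mode D;
#'   `NULL` for sparse-invariant scenarios), `config` (a [pop_config()]
#'   naming individuals `H1_1`, ...), `pure_sites` (per-block counts of
#'   covered invariant sites by base, sparse scenarios only) and `truth`
#'   (frequencies, allele bases, the scenario).
#' @export
simulate_scenario <- function(scenario, seed = 1) {
  if (isTRUE(scenario$sparse_invariants))
    return(simulate_sparse_scenario(scenario, seed))
  set.seed(seed)
  ns <- scenario$n_blocks * scenario$sites_per_block
  if (!is.null(scenario$theta_per_block)) {
    # positions are mostly invariant; ancestrally polymorphic positions
    # occur at the Watterson-expected density for the sampled haplotypes
    nhap <- 2 * sum(scenario$n_dip)
    p_poly <- min(scenario$theta_per_block * sum(1 / seq_len(nhap - 1)) /
                    scenario$sites_per_block, 1)
    poly <- stats::runif(ns) < p_poly
    sub <- scenario; sub$segregating_only <- FALSE
    fp <- simulate_freqs(sub, sum(poly))
    freqs <- matrix(1, ns, ncol(fp), dimnames = list(NULL, colnames(fp)))
    freqs[poly, ] <- fp
  } else {
    freqs <- simulate_freqs(scenario, ns)
  }
  pops <- colnames(freqs)
  # random ordered pair of distinct bases per site
  base1 <- sample.int(4L, ns, replace = TRUE)
  base2 <- 1L + ((base1 - 1L + sample.int(3L, ns, replace = TRUE)) %% 4L)
  alleles <- list(base1 = base1, base2 = base2)
  genotypes <- simulate_genotypes(freqs, scenario$n_dip)
  ids <- lapply(pops, function(p)
    paste(p, seq_len(scenario$n_dip[[p]]), sep = "_"))
  names(ids) <- pops
  ntot <- sum(scenario$n_dip)
  counts <- array(0L, c(ns, ntot, 4))
  off <- 0L
  for (p in pops) {
    e <- scenario$error_matrices[[p]]
    cp <- simulate_reads(genotypes[[p]], scenario$depth, alleles, e)
    counts[, off + seq_len(dim(cp)[2]), ] <- cp
    off <- off + dim(cp)[2]
  }
  individuals <- unlist(ids, use.names = FALSE)
  pos_in_block <- round(seq(1, scenario$block_size,
                            length.out = scenario$sites_per_block))
  pos <- rep((seq_len(scenario$n_blocks) - 1) * scenario$block_size,
             each = scenario$sites_per_block) + pos_in_block
  st <- site_table(rep("sim1", ns), pos, counts, individuals)
  cfg <- pop_config(H1 = ids$H1, H2 = ids$H2, H3 = ids$H3, H4 = ids$H4,
                    H5 = ids$H5, block_size = scenario$block_size)
  structure(list(site_table = st, genotypes = genotypes, config = cfg,
                 truth = list(freqs = freqs, alleles = alleles,
                              scenario = scenario)),
            class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf("sim_data (%s): %d sites, %d individuals\n",
              x$truth$scenario$name, n_sites(x$site_table),
              length(x$site_table$individuals)))
  invisible(x)
}

#' Simulate base-mismatch counts for a (T, R, O) error trio
#'
#' Generates the two 4x4 outgroup-stratified count matrices that
#' [estimate_error_matrix()] consumes: an outgroup base per site, a shared
#' true base for the T/R ancestor (equal to the outgroup base except for a
#' small divergence, uniform over the three other bases), Poisson read
#' depths, and the error channel `e_true` applied to T's reads only.
#'
#' @param e_true 4x4 error matrix affecting the T individual.
#' @param n_sites number of sites.
#' @param depth mean read depth of T and R.
#' @param divergence probability that the T/R true base differs from the
#'   outgroup base.
#' @return list with `counts_T_vs_O`, `counts_R_vs_O` (4x4 integer
#'   matrices, rows = outgroup base, columns = observed base).
#' @export
simulate_error_trio <- function(e_true, n_sites = 2e5, depth = 5,
                                divergence = 0.01) {
  a <- sample.int(4L, n_sites, replace = TRUE)
  flip <- stats::runif(n_sites) < divergence
  g <- a
  g[flip] <- 1L + ((a[flip] - 1L + sample.int(3L, sum(flip), replace = TRUE)) %% 4L)
  nT <- stats::rpois(n_sites, depth)
  nR <- stats::rpois(n_sites, depth)
  key <- (a - 1L) * 4L + g
  aggT <- rowsum(nT, key)
  aggR <- rowsum(nR, key)
  keys <- as.integer(rownames(aggT))
  counts_T <- matrix(0L, 4, 4)
  counts_R <- matrix(0L, 4, 4)
  eM <- unclass(e_true)
  for (i in seq_along(keys)) {
    ka <- (keys[i] - 1L) %/% 4L + 1L
    kg <- (keys[i] - 1L) %% 4L + 1L
    NT <- aggT[i]
    if (NT > 0)
      counts_T[ka, ] <- counts_T[ka, ] +
        as.integer(stats::rmultinom(1, NT, eM[kg, ]))
  }
  keysR <- as.integer(rownames(aggR))
  for (i in seq_along(keysR)) {
    ka <- (keysR[i] - 1L) %/% 4L + 1L
    kg <- (keysR[i] - 1L) %% 4L + 1L
    counts_R[ka, kg] <- counts_R[ka, kg] + as.integer(aggR[i])
  }
  dimnames(counts_T) <- dimnames(counts_R) <- list(outgroup = BASES,
                                                   observed = BASES)
  list(counts_T_vs_O = counts_T, counts_R_vs_O = counts_R)
}

# ---- sparse invariant-dominated genome simulation -----------------------
#
# For the error scenarios the genome is dominated by invariant positions
# whose reads are all one base except for type-specific error reads.
# Because per-individual read counts are Poisson, the error reads of
# individual i at an invariant-a site form an independent
# Poisson(lambda * (1 - e_i(a,a))) stream (thinning), so sites split
# exactly into three classes: dropped (some population uncovered), pure
# (covered, no error reads -> a unit delta on pattern (a,a,a,a)), and
# explicit "hit" sites carrying at least one error read, which are the
# only invariant sites that need materialised counts. Polymorphic
# positions are materialised in full.

# truncated-at->=1 Poisson draws
rpois_pos <- function(n, lambda) {
  if (n == 0L) return(integer(0))
  p0 <- stats::dpois(0, lambda)
  stats::qpois(p0 + stats::runif(n) * (1 - p0), lambda)
}

simulate_sparse_scenario <- function(scenario, seed = 1) {
  set.seed(seed)
  L <- scenario$sites_per_block
  nb <- scenario$n_blocks
  pops <- names(scenario$n_dip)
  n_dip <- scenario$n_dip
  ntot <- sum(n_dip)
  ind_pop <- rep(pops, n_dip)
  lambda <- scenario$depth
  emats <- lapply(pops, function(p) scenario$error_matrices[[p]])
  names(emats) <- pops
  # per-individual error matrix rows; keep rate e(a,a)
  e_of <- function(i) {
    m <- emats[[ind_pop[i]]]
    if (is.null(m)) diag(4) else unclass(m)
  }
  keep_rate <- vapply(seq_len(ntot), function(i) diag(e_of(i)), numeric(4))
  # keep_rate[a, i]; off-rate per individual per true base a
  off_rate <- 1 - keep_rate

  nhap <- 2 * sum(n_dip)
  p_poly <- min(scenario$theta_per_block * sum(1 / seq_len(nhap - 1)) / L, 1)

  # coverage probability per population for a pure invariant-a site
  # (error reads absent by conditioning; kept reads are Poisson thinned)
  p_cov_pure <- function(a) {
    pr <- 1
    for (p in pops) {
      lam_pop <- sum(lambda * keep_rate[a, ind_pop == p])
      pr <- pr * (1 - exp(-lam_pop))
    }
    pr
  }

  sub <- scenario; sub$segregating_only <- FALSE

  pure_counts <- matrix(0, nb, 4)       # covered hit-free sites per base
  site_chunks <- list()                 # per-block explicit count arrays
  pos_chunks <- list()
  freq_rows <- list()
  for (b in seq_len(nb)) {
    n_poly_b <- stats::rbinom(1, L, p_poly)
    inv_b <- stats::rmultinom(1, L - n_poly_b, rep(0.25, 4))[, 1]
    # polymorphic positions: full machinery
    fp <- simulate_freqs(sub, n_poly_b)
    base1 <- sample.int(4L, n_poly_b, replace = TRUE)
    base2 <- 1L + ((base1 - 1L + sample.int(3L, max(n_poly_b, 1),
                                            replace = TRUE)[seq_len(n_poly_b)]) %% 4L)
    geno <- simulate_genotypes(fp, n_dip)
    cnt_poly <- array(0L, c(n_poly_b, ntot, 4))
    off <- 0L
    for (p in pops) {
      cp <- simulate_reads(geno[[p]], lambda,
                           list(base1 = base1, base2 = base2), emats[[p]])
      cnt_poly[, off + seq_len(n_dip[[p]]), ] <- cp
      off <- off + n_dip[[p]]
    }
    # invariant positions, per true base a
    cnt_hits <- vector("list", 4)
    for (a in 1:4) {
      lam_err_i <- lambda * off_rate[a, ]          # error-read rate per ind
      lam_err <- sum(lam_err_i)
      if (lam_err > 0) {
        n_hit <- stats::rbinom(1, inv_b[a], 1 - exp(-lam_err))
      } else n_hit <- 0L
      if (n_hit > 0) {
        Tn <- rpois_pos(n_hit, lam_err)
        ch <- array(0L, c(n_hit, ntot, 4))
        # distribute error reads over individuals and observed bases
        reads_site <- rep(seq_len(n_hit), Tn)
        who <- sample.int(ntot, length(reads_site), replace = TRUE,
                          prob = lam_err_i)
        for (i in unique(who)) {
          sel <- which(who == i)
          erow <- e_of(i)[a, ]
          erow[a] <- 0
          obs <- sample.int(4L, length(sel), replace = TRUE, prob = erow)
          tab_idx <- cbind(reads_site[sel], i, obs)
          for (r in seq_len(nrow(tab_idx)))
            ch[tab_idx[r, 1], tab_idx[r, 2], tab_idx[r, 3]] <-
              ch[tab_idx[r, 1], tab_idx[r, 2], tab_idx[r, 3]] + 1L
        }
        # kept (true-base) reads of every individual
        for (i in seq_len(ntot))
          ch[, i, a] <- ch[, i, a] +
            stats::rpois(n_hit, lambda * keep_rate[a, i])
        cnt_hits[[a]] <- ch
      }
      # pure sites: covered, no error reads
      rem <- inv_b[a] - n_hit
      pure_counts[b, a] <- stats::rbinom(1, rem, p_cov_pure(a))
    }
    n_hit_tot <- sum(vapply(cnt_hits, function(x)
      if (is.null(x)) 0L else dim(x)[1], integer(1)))
    n_exp <- n_poly_b + n_hit_tot
    cnt <- array(0L, c(n_exp, ntot, 4))
    if (n_poly_b > 0) cnt[seq_len(n_poly_b), , ] <- cnt_poly
    off <- n_poly_b
    for (a in 1:4) if (!is.null(cnt_hits[[a]])) {
      k <- dim(cnt_hits[[a]])[1]
      cnt[off + seq_len(k), , ] <- cnt_hits[[a]]
      off <- off + k
    }
    pos_b <- sort(sample.int(L, n_exp)) + (b - 1L) * L
    site_chunks[[b]] <- cnt
    pos_chunks[[b]] <- pos_b
    freq_rows[[b]] <- fp
  }
  n_all <- sum(vapply(site_chunks, function(x) dim(x)[1], integer(1)))
  counts <- array(0L, c(n_all, ntot, 4))
  off <- 0L
  for (b in seq_len(nb)) {
    k <- dim(site_chunks[[b]])[1]
    counts[off + seq_len(k), , ] <- site_chunks[[b]]
    off <- off + k
  }
  ids <- unlist(lapply(pops, function(p)
    paste(p, seq_len(n_dip[[p]]), sep = "_")), use.names = FALSE)
  st <- site_table(rep("sim1", n_all), unlist(pos_chunks), counts, ids)
  idl <- split(ids, ind_pop)[pops]
  cfg <- pop_config(H1 = idl$H1, H2 = idl$H2, H3 = idl$H3, H4 = idl$H4,
                    H5 = idl$H5, block_size = L)
  structure(list(site_table = st, genotypes = NULL, config = cfg,
                 pure_sites = pure_counts,
                 truth = list(freqs = do.call(rbind, freq_rows),
                              scenario = scenario)),
            class = "sim_data")
}
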