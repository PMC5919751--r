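---
title: "The extended D-statistic: model, corrections and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The extended D-statistic: model, corrections and simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abbababa)
```

## The four-population test

The ABBA-BABA (Patterson's D) test asks whether four populations fit the
tree (((H1,H2)H3)H4), with H4 an outgroup. Under the null hypothesis of
treeness without gene flow, a derived allele shared by H1 and H3 (a BABA
configuration) is exactly as probable as one shared by H2 and H3 (ABBA),
so the normalised difference of their probabilities is zero in
expectation. With per-population allele frequencies $q_{1},\dots,q_{4}$
at a site, the package accumulates

$$X_i = (q_1 - q_2)(q_3 - q_4), \qquad
  Y_i = (q_1 + q_2 - 2q_1q_2)(q_3 + q_4 - 2q_3q_4),$$

and reports $D = \sum_i X_i / \sum_i Y_i$. Two algebraic identities —
$X_i = P(\mathrm{BABA}_i) - P(\mathrm{ABBA}_i)$ and
$Y_i = P(\mathrm{ABBA}_i) + P(\mathrm{BABA}_i)$ — are enforced by tests
to $10^{-12}$, and imply $|D| \le 1$. Note the orientation: **positive D
means BABA excess** (H1–H3 sharing). Many tools print the negated
$(n_{ABBA} - n_{BABA})$ statistic; `sign_convention = "abba-baba"` gives
that orientation. The test is two-tailed, so inference is identical
either way.

## Frequencies from reads: all reads, all individuals

Genotype calling at low depth (1–10×) is unreliable, and the classic
remedy — sampling a single read per population per site — discards most
of the data. Instead, each individual's read fraction
$\hat x_l = k_l / n_l$ (an unbiased binomial estimate) is combined into

$$\hat q = \sum_l w_l\, \hat x_l, \qquad
  w_l \propto \frac{2 n_l}{n_l + 1},$$

the linear combination of minimal variance under the two-stage sampling
of a diploid genotype plus reads. The weight rises from 0 at $n=0$ to an
asymptote of 2: once an individual's genotype is well determined, more
reads add nothing, so a 25× genome cannot drown out the 2× genomes in
its population. Unbiasedness and the variance dominance over uniform
weights are verified by simulation in the test suite. Individuals with
zero reads at a site get weight zero; the site is kept as long as every
population has pooled depth ≥ 1.

Three evaluation modes are available in `compute_D()`:

* `extended` — the weighted estimator above (the package's reason to
  exist);
* `one_base` — one base sampled per population from the pooled counts
  (the classic statistic, kept for comparison);
* `genotype` — frequencies from known dosages (only meaningful in
  simulation, where truth is available).

At one individual per population and depth one, `extended` and
`one_base` coincide read-for-read; the power gain appears as soon as
there is more than one read to use.

## Block jackknife

Nearby sites are linked, so the standard error comes from a weighted
delete-one-block jackknife over 5-Mb blocks (the default; linkage in
humans decays well inside that span). Blocks are weighted by denominator
mass $Y_b$ for uncorrected data. For corrected pattern data a block's
$Y_b$ can legitimately be zero or negative (the correction subtracts an
expected error mass from a noisy observed mass), and using $Y_b$ as a
weight — or dropping non-positive blocks, which selects on the sign of
the noise — would bias D upward; those paths therefore weight blocks by
their site counts. $Z = D/\mathrm{SE}$ is referred to the standard
normal; the customary threshold $|Z| > 3$ corresponds to a two-tailed
p ≈ 0.001 and is a reporting convention, not a hard-coded decision. Null
calibration (normality of Z, false-positive rate at $|Z|>3$) is checked
empirically on 500 simulated null replicates in the acceptance tests.

## Type-specific error correction

Ancient genomes carry base-specific damage (deamination inflates A→G /
C→T-type mismatches). The error model is a row-stochastic $4\times4$
matrix $e$ with $e(a,b)$ the probability of reading $b$ when the truth
is $a$; a read-frequency vector transforms as $p_T = e^{\top} p_G$.

*Estimation* uses a trio: an error-prone target T, an effectively
error-free reference R, and an outgroup O, in the tree ((T,R),O).
Stratifying observed bases by the outgroup base gives conditionals
$P_T(b\mid a)$ and $P_R(g\mid a)$ with $P_T = P_R\,e$, because T and R
share their true base distribution given O. `estimate_error_matrix()`
solves this by least squares constrained to row-stochastic non-negative
matrices (projected gradient from the row-projected exact solution).
The reference implementation (ANGSD's doAncError/doAbbababa2 workflow)
does not document its exact estimator; constrained least squares is this
package's choice, and it
recovers an injected $e(A{\to}G) = 0.005$ within Monte-Carlo error on
$10^6$ sites.

*Correction* could invert $e$ per individual and site (the relation above), but
that is costly and can yield negative frequencies. The implemented
group-level variant therefore works on whole populations: with population mean
matrices $e_{(j)}$, the $256\times256$ operator on four-population
pattern probabilities factorises as the Kronecker product
$E = e_{(1)}\otimes e_{(2)}\otimes e_{(3)}\otimes e_{(4)}$, so its
inverse is the product of four $4\times4$ inverses and is applied in
factored form (`build_group_error_matrix()`, verified against a dense
brute-force construction). Correction happens per block *before* the
jackknife so the SE reflects corrected quantities. The known
approximation is kept and should be kept in mind: the group correction
ignores the per-individual depth weights, so low-weight individuals may
be over-corrected.

**Negativity policy.** Inverting $E$ (or the admixture relation below)
can produce small negative pattern masses. Two policies exist: `clamp`
(zero them and renormalise — sensible when the corrected vector is
reported as probabilities) and `strict` (propagate raw values). For
*inference* the package defaults to `strict`: per-block corrected masses
fluctuate around small values, and censoring the negative half of that
noise would systematically inflate the corrected D. This is a deliberate
deviation from a clamp-by-default design; the standalone `correct_*`
helpers still clamp by default.

## Correction for introgression from a fifth population

A rejected tree need not mean H3 gene flow: admixture from an external
population H5 into H1 or H2 also shifts the pattern masses. If a
fraction $\alpha$ of the admixed ingroup's genome derives from H5, the
observed pattern distribution is the mixture
$p_{1:4} = (1-\alpha)\,p_{un} + \alpha\,p_{out}$, where $p_{out}$ is
computed with H5 substituted for the admixed population and $p_{un}$ is
the distribution the unadmixed tree would have shown. Hence

$$p_{un} = \frac{1}{1-\alpha}\left(p_{1:4} - \alpha\, p_{out}\right),$$

applied per block, after error correction (the relation is stated for
error-free probabilities, so errors are removed first). Which ingroup is
admixed is declared by the user, not inferred.

If $\alpha$ is unknown it is estimated as the value at which the
corrected statistic crosses zero, $E[D_{un}(\alpha)] = 0$. Both the
numerator and denominator of $D_{un}$ are affine in $\alpha$, so the
root of the *numerator* is bracketed and bisected (tolerance $10^{-4}$);
bracketing the ratio itself can be fooled by the denominator's pole. The
search runs on $[0, 0.5]$ — beyond 0.5 the "minor contributor" reading
of $\alpha$ inverts — and an unconstrained root below zero maps to the
boundary estimate $\hat\alpha = 0$. The standard error re-estimates the
root on each leave-one-block-out dataset (reported SDs for such
estimates rarely state the resampling scheme; delete-one re-estimation
is this package's choice). The multilinearity of $X$ and
$Y$ in the population frequencies makes the mixture relation exact in
expectation even though H5 keeps drifting after the pulse — which is why
recovery of $\alpha$ tolerates drift between the admixing and admixed
lineages, as the acceptance tests confirm.

As an external, non-desk-scale benchmark (requiring the public
human/archaic genomes, so not part of this package's test suite): on the
tree (((Han Chinese, Dinka) Yoruban) chimpanzee) with the Neandertal
genome as H5, this procedure is reported to give
$\hat\alpha \approx 0.03$ (SD 0.0042), consistent with earlier estimates
of the Neandertal contribution to non-Africans.

## The simulator: a stated world

`simulate_scenario()` reproduces the structure of the three validation
scenarios at desk scale. It is a *frequency-level* drift simulator, not
a coalescent: ancestral frequencies are drawn from a density
$\propto 1/x$ truncated to $[1/(2N_e), 1 - 1/(2N_e)]$ (the neutral SFS
shape), and each branch of $t$ generations applies a Balding–Nichols
step with $F = 1 - \exp(-t/(2N_e))$, which preserves the mean and
realises the Wright–Fisher variance. Migration and admixture are single
pulses: frequency mixing $x \mapsto (1-m)x + m\,x_{src}$ at the event
time. Defaults are the validation scenarios' stated parameters: $N_e = 10^4$,
split times 0.5 / 0.75 / 1.0 (in $4N_e$ generations) for the quartet,
mean depth 2×, 5-Mb blocks; the ms-style migration grid 0–280 converts
to per-generation fractions 0–0.7% (`migration_units()`), applied as the
pulse equivalent of the 40-generation migration window.

Deliberate departures from the scenarios' coalescent command lines,
chosen once:

* **fig2C root depth.** The stated command joins H5 to the tree at
  $30\times4N_e$ generations — effectively infinite. Pure drift over
  such a branch fixes every site, which in a frequency-level simulator
  (where all polymorphism originates at the root) would destroy the
  shared variation the test needs. The H5 root is truncated to
  $1.5\times4N_e$ generations, still well outside the H4 root at 0.75.
  The admixture-relevant structure is kept exactly: the source lineage
  separates from sampled H5 8000 generations ago and admixes 4000
  generations ago, so source and sample are separated by real drift.
* **fig2B composition.** Type-specific errors bias D through the vastly
  more numerous *invariable* positions (a spurious BABA needs the same
  error in H1 and H3 at the same monomorphic site, so the signal per
  site is $O(e^2)$ but the site count is genomic). This scenario
  therefore keeps invariable sites — the other scenarios retain only
  segregating sites — and a world of
  a few thousand polymorphic sites cannot show the error effect at any
  sample size — nor can one with too few polymorphic sites support the
  corrected statistic, whose denominator is the true ABBA/BABA mass.
  The preset therefore simulates the full-scale composition — 5-Mb
  blocks at the human-like mutation density $\theta = 100$ per block —
  using an
  exact sparse representation: per-individual read counts are Poisson,
  so error reads thin off as independent Poisson streams and every
  invariant position falls into one of three classes — uncovered
  (dropped by the intersection rule), covered with no error read (a
  unit delta on its monomorphic pattern, accumulated as a per-block
  mass), or carrying at least one error read (materialised as real
  counts, about 50k per block at the stated rates). Only the error-hit
  and polymorphic positions are ever represented site-by-site, which
  keeps a 100-Mb genome at roughly a million explicit sites. The
  scaling to desk size is purely in block count (20, matching the
  jackknife setup under test, vs 200) and replicate count.
* **Linkage is not simulated.** Sites are independent and blocks are
  synthetic coordinate assignments; the jackknife's correctness under
  independence is what the tests exercise. Power values therefore match
  full-coalescent power curves qualitatively (ordering, saturation), not
  digit-for-digit.

What a green test establishes, and what it does not: the simulator
realises the moment structure the statistic tests (drift covariances,
pulse admixture, Poisson depth, error channels), so calibration, power
ordering and the two corrections are genuinely exercised; it does not
emulate recombination, linked selection, reference bias or base-quality
strings, so agreement here does not certify behaviour on real aligned
data.

## Numerical choices

* Coordinates are 1-based; blocks are `block_size` windows counted from
  position 1 per chromosome. ms positions map to
  `floor(pos * L) + 1`, first wins on collisions.
* Di-allelic mode collapses raw sites with more than two observed
  alleles to the two most frequent pooled alleles (ties A<C<G<T),
  discarding other reads; pattern mode keeps all four bases.
* "Removal of transitions" excludes the pairs {A,G} and {C,T}, the
  standard ancient-DNA damage filter (deamination inflates exactly
  those substitution types).
* The mapping-quality filter cannot be applied from pileup text (the
  per-read MQ is absent); apply it upstream, e.g.
  `samtools mpileup -q 30`.
* `estimate_error_matrix` refuses ill-conditioned reference
  distributions (`rcond < 1e-10`) and excludes outgroup bases with no
  observations, with a warning.
* The jackknife treats a sub-`1e-12` SE as exactly zero (identical
  blocks), signalling an undefined Z rather than an astronomical one.

## Known limitations

Population structure predating the H1/H2 split violates the model and
can produce false positives, as for any D-statistic. The group error
correction ignores frequency weights (above). The drift simulator's
power curves are qualitative analogues of full-coalescent ones. Mapping
bias, contamination and base-quality miscalibration are out of scope:
counts are taken at face value after the base-quality threshold.
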