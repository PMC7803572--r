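---
title: "Models and methods in methkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in methkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

methkin analyses count-based whole-genome bisulfite sequencing (WGBS) data
from pedigreed study designs: the canonical case is a 20-sample layout of
twelve skeletal-muscle and eight testis samples from two pig breeds, with
the native-breed animals spanning three adult ages (1, 4 and 9 years)
across two pedigrees. This vignette is the package's own account of the
statistical machinery: the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data validation
does and does not establish.

## Data model and filtering

The central object is a `MethCountMatrix`: per-CpG methylated and total
read counts across samples, with CpGs on the two strands kept as distinct
records (symmetric-pair merging is available but off by default). A cell
that was not observed, or observed with zero coverage, is *missing*, never
zero — a 0/0 cell carries no level information and treating it as level 0
would bias every downstream mean.

Coverage filtering follows the standard practice for deep WGBS: a cell
passes when its total lies in `[min_cov, max_cov]` (defaults 10 and 300 —
the lower bound controls level noise, the upper bound removes collapsed
repeats and PCR stacks), and a site is retained when at least
`ceiling(0.5 * n_samples)` cells pass. With an odd sample count the
ceiling makes the rule conservative. Filtering is idempotent and the
retained-site count is monotone in both thresholds; the test suite checks
both properties.

## CpG context

CpG islands are detected from sequence by a sliding-window union: every
200-bp window with GC fraction strictly above 0.50 and CpG
observed/expected ratio strictly above 0.60 is kept, overlapping windows
are unioned, and each merged interval is re-verified against all three
criteria including length strictly greater than 200 bp. This is a
self-contained approximation of the classical Gardiner-Garden-style
annotation; a user-supplied island BED bypasses detection. The
observed/expected ratio is `#CpG x L / (#C x #G)` with N bases excluded.
On chromosomes up to 10 kb the implementation is tested for exact
equality against a brute-force enumeration of every window.

Shores are the bands within 2 kb of an island edge and shelves the next
2 kb. Bands are half-open on the integer edge distance (the base adjacent
to an island has distance 1): shore is `[1, 2000)`, shelf `[2000, 4000)`,
beyond is open sea. The island/shore/shelf/open-sea classes partition all
sites. Distances are measured from island *edges*; measuring from
midpoints would make the bands depend on island length, which has no
support in standard usage.

Genic context uses the precedence `5'UTR > exon > intron > intergenic`
across all overlapping genes, because 5'UTR methylation behaves
distinctively (hypomethylated when island-associated) and is reported
separately from exon statistics. Two promoter notions coexist
deliberately: the *expression-correlation* promoter is 800 bp upstream to
200 bp downstream of the TSS, while *DMR screening* near genes uses 1 kb
upstream plus the first exon — both are field conventions for their
respective tasks and are not interchangeable.

## Differential methylation

### Beta-posterior minimum-difference test

For pooled two-group comparisons, each group's counts are summed and given
a Beta posterior under a uniform prior: counts `(m, u)` give
`Beta(m + 1, u + 1)`, whose mean `(m + 1)/(m + u + 2)` shrinks
low-coverage estimates toward 1/2 — this is the "correcting the effect of
sequencing depth" role of the posterior. The test statistic is
`P_small = P(|theta_A - theta_B| < delta)` with `delta = 0.3`; a site is
differential when `P_small <= 0.01`, i.e. when at least 99% of the joint
posterior mass lies at a level difference of 0.3 or more.

`P_small` is computed by deterministic 512-point Gauss-Legendre quadrature
*in the probability transform* of each posterior (integrating
`F_B(Q_A(u) + delta) - F_B(Q_A(u) - delta)` over uniform `u`), which is
robust to arbitrarily spiky posteriors, and is symmetrized over the two
orientations so that swapping groups is an exact identity (checked to
1e-12). A seeded Monte-Carlo oracle with 1e6 draws agrees within 1e-3 in
the tests. Within-group pooling (rather than a per-sample hierarchical
model) matches the group-level question the test answers; the kinship
GLMM below is the per-sample model.

### Binomial GLMM with kinship (PQL)

The model for methylated counts `y_i` out of `r_i` reads is
`y_i ~ Binomial(r_i, pi_i)`, `logit(pi) = X beta + g`,
`g ~ N(0, sigma2 K)`, with age in years as a default fixed covariate and
`K` the additive relationship matrix from the pedigree (tabular method;
parent-offspring 0.5, full sibs 0.5). Because the same animal contributes
both a muscle and a testis sample, `K` is expanded to sample level by
repeating individual entries — omitting this would ignore the strong
within-animal covariance.

Fitting is penalized quasi-likelihood: each iteration linearizes to the
working response `z = eta + (y/r - pi)/(pi(1 - pi))` with weights
`w = r pi (1 - pi)` and solves the Gaussian mixed model exactly via the
eigendecomposition of `W^1/2 K W^1/2` (so the variance profile is a
cheap one-dimensional search). Three numerical choices matter:

* **Estimated dispersion.** Bisulfite counts are overdispersed relative
  to the binomial (the generator's beta-binomial concentration of 20
  inflates count variance roughly 2.4-fold at 30x coverage). A
  multiplicative quasi-likelihood dispersion is therefore profiled out of
  the working model, exactly as in quasibinomial GLM practice. With the
  dispersion fixed at 1 and `sigma2 = 0` the fit reproduces `glm`'s IRLS
  estimates and standard errors to 1e-3, which the tests verify on 50
  seeded datasets.
* **Satterthwaite reference.** With estimated variance parameters at
  n = 20, a standard-normal Wald reference is anticonservative —
  measured null rejection at the 0.01 level was near 10% with fixed unit
  dispersion and still ~4.5% with estimated dispersion and a normal
  reference, concentrated at sites with extreme methylation where the
  effective information is small. The Wald statistic is therefore
  referred to a t distribution whose per-coefficient degrees of freedom
  come from a Satterthwaite approximation based on the numeric REML
  information of the two variance parameters (the approach of lmerTest).
  This brings null rejection to about 1% with no change to any
  threshold.
* **Boundary handling.** `sigma2` is bounded below at 0; convergence
  requires both `beta` and `sigma2` to move less than 1e-5. Sites with
  identical proportions in every sample, non-converged fits and
  quasi-separated sites are excluded from DMC lists and counted.

Wald p-values are used rather than likelihood-ratio tests because PQL
objective values are not true likelihoods. Raw `p <= 0.01` thresholds are
applied, matching the convention of large-scale WGBS scans; FDR control is
available to callers via `p.adjust` on the `keep_all = TRUE` output.

### DMRs and promoter screening

Differential CpGs within 500 bp of one another merge transitively into
DMRs (singletons allowed), with per-region direction counts. Promoter
DMRs are those overlapping the 1-kb-upstream/first-exon region with at
least 5 same-direction member DMCs. Merging is tested against a
brute-force transitive closure on 1,000 random sites.

## Pedigree-shared (inheritable) windows

A site is a *pedigree DMC* when (i) the pooled minimum-difference test
between the two pedigrees passes (`delta = 0.3`, `alpha = 0.01`) and
(ii) the per-individual posterior mean levels separate completely — every
cross-pedigree pair of individuals differs in the same direction. Rule
(ii) is the strictest reading of requiring the difference "for all
individuals"; it is a deliberate convention, stated here because the
underlying notion admits weaker operationalizations.

Pedigree DMCs merge with a 500-bp gap; windows with at least `N = 5`
synclastic DMCs are scored by the genome-wide corrected false-positive
bound

`P_fp(X >= N) = 2 (1 - P(X < N)) GS / L`, with `X ~ Bin(round(ECG), p/2)`,

where `ECG = #C x #G / L` is the window's expected CpG count computed
from its actual base composition over a span of `max(500, window length)`
bp, `p` is the genome-wide pedigree-DMC ratio (estimated from the scan
unless overridden), the factor `p/2` demands one shared direction, and
`GS / L` Bonferroni-corrects over windows with a factor 2 for the two
directions. The bound is reported uncapped, since it is a bound rather
than a probability. The binomial support uses `round(ECG)`, which
reproduces the reference evaluation `ECG = 31.25 -> 31`,
`P_fp(X >= 5) = 0.012` at `p = 0.003`, `GS = 2.5e9`, `L = 500`; the tail
is verified against exhaustive pmf summation to relative error 1e-12.

## Methylation-expression integration

Promoter methylation is the unweighted mean of per-site levels over
non-missing cells in the -800/+200 promoter, for genes with at least 10
retained promoter CpGs. Correlation with FPKM is Spearman's rho with
average-rank ties and a t-approximation p-value (alpha 0.01), tested to
1e-12 against a rank-then-Pearson oracle. Site-level correlations assign
each CpG to its promoter-owner gene first, host gene second.

Group expression comparisons use the unpaired Wilcoxon-Mann-Whitney
rank-sum test (exact for small tie-free samples, tie-corrected normal
approximation otherwise). A *signed-rank* test, sometimes named for such
comparisons, requires paired observations; for unpaired tissue groups the
rank-sum test is the statistically valid choice, and a paired variant is
available behind the `paired` flag for genuinely paired designs. FPKM is
used untransformed, as rank statistics are invariant to monotone
transforms.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions and were chosen once:

* **Design**: 20 samples (12 muscle + 8 testis) over 12 individuals; two
  native-breed pedigrees of four males each (9Y founders with 4Y and 1Y
  descendants through explicit sire links and unobserved dams; one pair
  of 9Y full sibs), plus four unrelated 7-month commercial-breed
  founders, two of each sex.
* **Genome**: 2 chromosomes x 100 kb at background GC 0.38 (iid bases,
  so background 200-bp windows fail the GC > 50% island criterion with
  overwhelming probability) with 4 planted 600-bp islands per chromosome
  at GC 0.70 (iid composition gives observed/expected near 1); islands
  are re-drawn until they satisfy the detection criterion, making planted
  truth self-consistent. 16 genes, half with island TSSs. These sizes
  keep a full simulate-analyse cycle in seconds while leaving thousands
  of CpGs; they are stated here as the package's validation scale.
* **Methylomes**: baseline logit-normal mixture (island mean 0.08,
  background mean 0.80, logit SD 0.8) tuned to a global mean near 70%,
  the bimodal shape characteristic of vertebrate methylomes;
  negative-binomial coverage (mean 30x, size 8, truncated at 1);
  beta-binomial counts at concentration 20, a realistic WGBS
  overdispersion that the analysis model must absorb; genetic random
  effect `g ~ N(0, 0.5 K)` per site.
* **Planted signals**: logit-scale effects (tissue +/-2, age slope
  0.35/year, breed +/-2, sex +/-2) on disjoint random site sets,
  restricted to sites where the shift implies a level-scale difference of
  at least 0.3 — the field's definition of a differential CpG; sites
  where a 2-unit logit shift moves the level by less than 0.3 (saturated
  baselines) are not meaningful truth. Pedigree-shared windows are
  planted inside islands (the only places 14 CpGs fit in 130 bp) at
  +/-2 logit around 0.5, giving complete between-pedigree separation.
  Promoter methylation of coupled-candidate genes receives a per-sample
  logit shift (SD 1.5) so promoter levels vary across samples;
  expression then follows `log(FPKM + 1) = 5 +/- 4 m + eps` with noise
  SD 0.5 for coupled genes and independent noise otherwise.
* **Reproducibility**: each generator draws from its own stream seeded by
  (master seed, generator name), so adding a generator never perturbs
  another's output; equal seeds give byte-identical files.

What passing tests on this generator *show*: the estimators are unbiased
at realistic coverage and overdispersion, type-I error is near nominal
under the model's own null with kinship structure, planted effects of the
configured sizes are recovered at the configured thresholds, and the
end-to-end window statistic flags a planted 130-bp pedigree-shared region
while remaining silent on null data. What they *do not* show: robustness
to alignment and conversion artefacts, non-CpG methylation, copy-number
variation, cell-composition heterogeneity between samples, or island
structure beyond the iid composition model — real WGBS carries all of
these.

## Known limitations

* PQL is approximate; at very low coverage or near-separation its
  estimates are biased toward zero, and such sites are flagged rather
  than rescued.
* One PQL engine is provided; consensus across multiple BGLMM
  implementations can be emulated by intersecting DMC tables from
  external tools with this package's output, but no re-implementation of
  MCMC or Laplace-approximation solvers is attempted.
* The heritable-window statistic is a Bonferroni-style bound, not a
  calibrated p-value; its `p` parameter is a plug-in estimate.
* The generator plants effects on independent sites; spatially correlated
  methylation (comethylation blocks) is represented only through planted
  windows.
* Sample-level promoter variability (the coupled-gene shifts) can align
  with pedigree by chance in an eight-sample comparison: with complete
  per-individual separation required, a promoter-wide shift has a few
  percent probability of ordering the two pedigrees perfectly, so the
  default simulation occasionally yields a spurious heritable window at a
  coupled promoter in addition to the planted ones. This mirrors the
  real-data caveat that sample-level confounders masquerade as
  inheritance when pedigrees are small.
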