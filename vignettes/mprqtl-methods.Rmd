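---
title: "Mapping virus-resistance QTL in multiparent RIL panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping virus-resistance QTL in multiparent RIL panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mprqtl)
```

`mprqtl` implements the statistical pipeline used to dissect the genetic
architecture of a quantitative trait — here, virus resistance in
*Drosophila melanogaster* — in a multiparent advanced-intercross panel of
recombinant inbred lines (RILs) such as the DSPR. Each RIL genome is a
homozygous fine-scale mosaic of eight founder haplotypes, summarised at
evenly spaced 10-kb positions by the probability that the local haplotype
descends from each founder. The pipeline maps QTL by regressing phenotypes
on those probabilities, judges significance by permutation, classifies
founder alleles at each QTL, decomposes the genetic variance, and scans for
epistatic modifiers. A panel simulator generates synthetic data with the
same structure so that every stage can be verified by parameter recovery.

## The vial phenotype model

Phenotypes are measured on vials of ~20 infected flies: for a lethal virus
(the `dcv` assay) the vial mean day of death over a 15-day window, for a
persistent virus (`sigma`) the proportion of flies showing infection
symptoms. The baseline model for vial $k$ of RIL $j$ injected on day $i$ is

$$ y_{ijk} = \beta + \mathrm{date}_i + \mathrm{RIL}_j + \varepsilon_{ijk}, $$

with random injection-date and RIL effects, fitted by REML (`fit_baseline()`,
via `lme4`). Assay repeatability is the single-day intraclass correlation

$$ R = \frac{\sigma^2_{\mathrm{RIL}}}{\sigma^2_{\mathrm{RIL}} + \sigma^2_\varepsilon}, $$

deliberately excluding $\sigma^2_{\mathrm{date}}$. Its 95% interval is
obtained by profiling the REML criterion over $R$ (re-optimising the date
component at each value and cutting at $\chi^2_{1,0.95}$), with a parametric
bootstrap (1000 refits) as fallback when the profile is flat. Proportions in
the sigma assay are analysed untransformed, exactly as the model above is
written; this keeps effect sizes on the interpretable percentage-point scale
at the cost of mild heteroscedasticity near the boundaries.

Fly-level records are collapsed to vials by `build_vial_phenotypes()`.
Flies dying within 24 h are excluded as injection casualties. Flies still
alive at day 15 are included at the window bound — the observation ends,
not the fly; this choice is configurable (`include_censored = FALSE` drops
them) because it is not externally fixed, and it only matters for very
resistant lines.

## Genome scans and permutation significance

The scan phenotype is each RIL's BLUP — its shrunken deviation net of
injection date (`ril_blups()`). At each grid position the BLUPs are
regressed on the eight founder probabilities. The rows sum to one, so the
design uses an intercept plus founders 2–8; fitted values are invariant to
which column is dropped. The F statistic (7 numerator df, fewer when a
founder is absent) is converted to

$$ \mathrm{LOD} = \frac{n}{2}\,\log_{10}\frac{\mathrm{RSS}_0}{\mathrm{RSS}_1}, $$

the Gaussian log₁₀ likelihood ratio. Genomewide significance comes from
permuting BLUPs across RIL labels (2000 permutations at study scale) and
recording the maximum LOD of each permuted scan; genotypes — and any
genotype-linked covariate — stay attached to their genomes, preserving the
panel's linkage structure under the null. The threshold at level $\alpha$ is
the $\lceil \alpha N \rceil$-th largest null maximum and the p-value uses
the add-one convention $(r+1)/(N+1)$, so 2000 permutations bound p below at
$1/2001 < 0.0005$.

Secondary QTL are found by rescanning with the mapped QTL as covariates in
both the null and full models, so the LOD measures each position's
increment. `run_pipeline()` iterates this until no peak clears the
$\alpha = 0.05$ threshold, re-deriving the permutation null for every
covariate scan.

QTL locations are refined locally (`refine_interval()`) on the same 10-kb
grid — no sub-grid interpolation, since the genotype probabilities are only
tabulated at grid points. Two intervals are reported: a 95% Bayesian
credible interval (smallest contiguous set of grid positions, grown outward
from the peak, holding ≥95% of the normalized $10^{\mathrm{LOD}}$ mass) and
a 2-LOD support interval (outermost positions within 2 LOD of the peak).
Profiles with multiple local modes inside the 2-LOD band are reported via a
message; the credible interval is grown from the highest mode. Exact ties in
the maximum break toward the lowest (arm order, position) — a deterministic,
if arbitrary, rule.

## Founder allele classes and effect sizes

At each QTL the eight founder alleles are divided into resistant and
susceptible classes: RILs are hard-assigned to founders where their
probability is ≥0.95 (the computable analogue of resolving ambiguous lines
by direct genotyping — ambiguous RILs are excluded, and the threshold is a
parameter), founders are ranked by mean BLUP, and each of the $k-1$ ranked
cuts is scored by a one-way ANOVA F; the best cut wins
(`best_two_class_partition()`). Only ranked cuts are searched because the
between-class sum of squares for a two-class split of one-dimensional means
is maximized on an interval of the sorted means; the test suite nonetheless
checks the ranked optimum against exhaustive bipartition search. F ties
break toward the smaller resistant class (a conservative minor-allele
designation). Founders absent at a QTL are placed in the susceptible class
so that resistant probabilities remain well defined; they are flagged in the
output.

Each RIL's probability of carrying the resistant allele is the sum of its
founder probabilities over the resistant class. These per-RIL probabilities
drive three downstream analyses:

* **Variance explained** (`variance_explained()`): the baseline model and
  the model with the QTL as a fixed effect (its eight founder probabilities)
  are both fitted by a Gibbs sampler for the Gaussian mixed model, and the
  proportion of genetic variance explained is the relative drop in the
  posterior median of $\sigma^2_{\mathrm{RIL}}$. Comparing posterior medians
  from a common Bayesian fit keeps the two variances on the same footing.
  Priors are weak inverse-gamma(0.001, 0.001) on variances and flat on fixed
  effects; the default chain is 13 000 iterations, 3000 burn-in, thinned by
  10 — conventional settings, exposed in `mcmc_control()`. Results carry an
  effective-sample-size convergence flag, and a negative proportion (pure
  sampling noise around a null effect) is reported as-is with a flag, never
  silently truncated.
* **Joint effect sizes** (`effect_sizes_joint()`): all mapped QTL enter one
  model simultaneously, each as its resistant probability on the 0→1 scale,
  so a coefficient is the trait change from certainly-susceptible to
  certainly-resistant. Posterior medians, 95% quantile intervals and
  two-sided posterior p-values come from the same Gibbs sampler; Wald tests
  from the matching REML fit (each QTL net of all others — type II for these
  single-df terms) are attached. Covariate pairs with $|r| > 0.99$ are
  flagged as collinear.
* **Linkage disequilibrium** (`ld_fisher()`): pairs of QTL are tested for
  non-random association by cross-classifying hard-assigned resistant/
  susceptible alleles in a 2×2 table with Fisher's exact test; a table with
  an empty margin is reported degenerate with p = 1.

## Epistasis

Pairwise epistasis between mapped QTL (`pairwise_epistasis()`) compares
maximum-likelihood fits of the vial model with and without a QTL×QTL
interaction (random date and RIL retained) by a 1-df likelihood-ratio test.
The test is skipped, with the reason recorded, when any of the four joint
genotype classes holds fewer than `min_class_n = 10` RILs — with rare
genotype combinations the interaction is not estimable.

Modifiers without main effects are sought by an interaction genome scan
(`modifier_scan()`): at every position, ordinary least squares of the BLUPs
on QTL + locus + QTL×locus versus the main-effects model, with the
interaction LOD the log₁₀ likelihood ratio. This is deliberately the plain
fixed-effects regression written above — not a mixed model — applied to
date-corrected BLUPs. The QTL enters as its continuous resistant
probability, which avoids discarding ambiguously assigned RILs (a two-level
class can be passed instead). Founder columns carrying less than
`min_mass = 5` effective RILs of probability mass are pooled and the
degrees of freedom adjusted, since near-empty founder columns make the
interaction design singular. Genomewide significance again comes from
permuting BLUPs (1000 permutations by default — interaction scans cost
roughly double a main scan) with the full scan, including the
main-effects-only fit, recomputed in every permutation.

## The panel simulator

`simulate_panel()` emulates the construction of an eight-founder synthetic
population: balanced founder representation at generation 0 (every
generation-0 individual is a homozygous founder-line fly), `n_generations
= 50` of random mating in a finite pedigree of monogamous pairs with two
offspring each, then full-sib inbreeding of a random founding pair per RIL
until genomewide heterozygosity falls below 1%, retaining one haplotype.
Meioses place a Poisson number of crossovers per arm (mean = genetic length
in Morgans) uniformly on the genetic map, without interference; genetic and
physical positions are related linearly per arm. With `n_generations = 0`
no intercrossing has occurred and each RIL is an intact founder line. The
recombination core is compiled (Rcpp), as in the field's pedigree
simulators.

Defaults encode the study conditions: five major arms at reference-v5
physical lengths on a 10-kb grid, 20 flies per vial, vials injected in
batches of ~50 per day with replicate vials of a RIL on different days, and
trait-scale variance components giving repeatabilities near 0.77 (survival
assay: $\sigma^2_{\mathrm{RIL}} = 3.35$, $\sigma^2_\varepsilon = 1$) and
0.74 (infection assay). The intercross census is not a published quantity;
the default is 10 000 mating pairs (a 20 000-fly cage population) because
multiparent panels are deliberately maintained at large census to keep
founder proportions near 1/8 — at a census of a few thousand flies, 50
generations of drift move individual founders' genomewide shares by more
than a percentage point, which is incompatible with the design intent.
Replicated small experiments (permutation calibration, power studies) pass
a smaller census explicitly, trading drift realism for runtime where drift
is irrelevant to the property under study.

Planted QTL assign the eight founders to resistant/susceptible classes with
an additive effect in trait units, plus optional pairwise interaction
coefficients (a coefficient of $-2\times$ the main effect produces a
sign-reversing modifier). Genetic values are computed from the *true*
mosaic; emitted probability rows are unit vectors by default, with an
optional `blur` mixing toward uniform to emulate inference uncertainty.
Sigma-assay phenotypes are built on the linear probability scale (matching
the analysis model), clipped to [0, 1], and observed as binomial counts over
the vial — so the simulated data contain the boundary clipping and counting
noise that the Gaussian analysis model ignores, exactly the mismatch a real
study faces.

What the simulator does not emulate: sequence-level variation (no founder
FASTA/VCF, no marker-based probability inference — probabilities are exact
or uniformly blurred, whereas real HMM output has position-dependent
uncertainty), crossover interference, sex-specific recombination or X dosage
(the X is treated as an autosome), shared pedigree bottlenecks between arms
beyond the common pedigree, and selection during panel construction.
Passing recovery tests therefore demonstrates correctness of the estimators
under the assumed generative structure, not robustness to genotyping error
or to selection-driven distortions in a real panel.

## Numerical choices and degenerate inputs

* Scan designs are solved by QR with rank detection: an absent founder
  reduces the numerator df rather than producing an error; a numerically
  constant response yields F = LOD = 0 rather than 0/0.
* A single injection date fixes $\sigma^2_{\mathrm{date}} = 0$ with a
  warning; a constant phenotype short-circuits to a degenerate fit with all
  variances 0.
* `repeatability()` signals an error when both variances are 0 (R is
  undefined).
* Genotype-probability rows off unit sum by ≤1e-6 are renormalized; worse
  rows are rejected with the offending line named.
* The Gibbs sampler ridge-stabilizes an exactly singular fixed-effects
  cross-product (collinear covariates are already flagged upstream).
* All stochastic stages are driven by explicit seeds; with a fixed seed the
  pipeline's numeric outputs are byte-identical across runs.

## Problem sizes used in the test suite

The packaged tests verify the pipeline by parameter recovery at reduced
problem sizes chosen to keep a full run within minutes: permutation
calibration uses 200 replicates of a 150-RIL, 1000-position genome with 200
permutations each; major-QTL recovery uses 50 replicates of 600 RILs × 2
vials on a 600-position genome with shortened MCMC chains (3000/500/5);
modifier power and calibration use 300 RILs on a 300-position genome.
Study-scale settings (full genome, 2000 permutations, 13 000-iteration
chains) are the package defaults used by `run_pipeline()`.
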