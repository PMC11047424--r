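---
title: "Drug-target Mendelian randomization with targetmr: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization with targetmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

## The problem

Drug-target Mendelian randomization asks whether perturbing a target gene or
protein would change disease risk, using only published summary statistics.
Genetic variants that alter the target's expression (cis-eQTLs) or protein
abundance (pQTLs) act as lifelong, randomized "natural experiments": under
the instrumental-variable assumptions (relevance, independence from
confounders, and effect on disease only through the target), the ratio of a
variant's disease association to its expression association estimates the
causal effect of expression on disease. `targetmr` implements this workflow
end to end for panels of targets, tissues and disease outcomes, together
with the two standard follow-ups: Bayesian colocalization, which guards
against the QTL and GWAS signals being distinct variants in linkage
disequilibrium (LD), and two-step MR mediation, which decomposes a causal
effect into direct and mediated paths.

Because the original cohort-level resources (tissue eQTL atlases, brain
pQTL panels, psychiatric GWAS) cannot be redistributed, the package carries
a simulator that generates summary statistics with the same statistical
structure and *known* causal truth. All calibration and recovery claims in
the test suite are statements about that simulator.

## Data model

A `summary_panel` holds one trait's per-SNP marginal associations: SNP id,
chromosome, 1-based position, effect/other allele, effect-allele frequency
(possibly missing), effect estimate (log-OR for case-control traits, SD
units for quantitative ones), standard error, two-sided p-value, sample
size. An `ld_matrix` is the square correlation matrix r (not r²) over the
same SNPs, symmetrized when asymmetry is below 1e-8 and rejected otherwise;
its diagonal must be 1 within 1e-6. Files are UTF-8 tab-separated with "."
for missing values, a dialect chosen so that write-then-read roundtrips all
fields losslessly, including scientific notation. `validate_panel()`
reports (never raises) duplicate ids, non-positive SEs and p-values that
disagree with the two-sided normal tail of |beta/se| by more than 10%
relative — a cheap screen for corrupted or re-scaled inputs.

Genomic windows are inclusive on both ends, and positions are 1-based;
nothing in the pipeline depends on a particular genome build because no
liftover or annotation is attempted.

## Instrument selection and QC

* **eQTL panels** contribute at most one instrument per gene: the SNP with
  the smallest p-value, admitted only if p < 1e-4 (strict). Ties are broken
  by smaller position, then lexicographic SNP id, so selection is
  deterministic under permutation of the input rows.
* **pQTL panels** are LD-clumped: restrict to p < 0.05, then repeatedly
  promote the most significant remaining SNP to index SNP and drop all
  remaining SNPs within the window (default 10,000 kb, the conventional
  clumping default) whose r² with it exceeds 0.001. The retained set is
  pairwise r² ≤ 0.001 by construction, and the output is invariant to input
  row order.
* **Weak instruments** are removed by the F-statistic gate: F = (beta/se)²
  must be at least 10; F = 10 exactly passes ("less than 10" is excluded).
* **Confounded instruments** — SNPs with a reported association at
  p < 5e-8 to any screened phenotype in a local lookup table (the offline
  stand-in for a PhenoScanner-style query) — are removed and logged with
  the offending phenotype. All thresholds use strict inequalities.

## Causal estimation

Records are harmonized to a common effect allele before estimation: matched
on SNP id; outcome effects are negated (and allele frequencies reflected)
when the allele labels are swapped; palindromic SNPs (A/T, C/G) are dropped
whenever either study's allele frequency is missing or falls in
[0.42, 0.58], since strand cannot then be resolved; incompatible allele
sets are dropped with a warning. Harmonization is idempotent, and all
estimates are invariant to flipping the allele orientation of either input.

A single instrument yields the Wald ratio `beta_y / beta_x` with the
first-order delta-method SE `se_y / |beta_x|`. This SE ignores the
uncertainty in the exposure association and is therefore anti-conservative
for weak instruments; the F ≥ 10 gate is the designed mitigation, and with
the strong instruments this pipeline admits the residual undercoverage of
the nominal 95% interval is on the order of one to two percentage points.
Multiple instruments are combined by fixed-effect IVW; the estimate equals
weighted least squares of `beta_y` on `beta_x` through the origin with
weights `1/se_y²`, a property the test suite uses as an independent oracle.
Fixed-effect weighting is the default because drug-target analyses rarely
have more than a handful of instruments per target, too few to estimate a
between-instrument dispersion usefully; a multiplicative random-effects
inflation is available as an option but off by default. P-values come from
the standard normal, two-sided, floored at 1e-300 so extreme signals never
collapse to zero.

Reporting follows the OR convention: OR = exp(beta), CI bounds
exp(beta ± 1.959964·se), so the OR is the geometric mean of its CI bounds —
which is also how the package back-derives point estimates from published
intervals. Multiplicity is controlled by a factorial Bonferroni threshold,
alpha divided by the product of panel counts (for example
0.05/(95·13·7) = 5.78e-6 for a 95-target, 13-tissue, 7-outcome eQTL screen
and 0.05/(48·7) = 1.49e-4 for the corresponding pQTL screen).

## Colocalization

The model assumes at most one causal variant per trait in the analyzed
region. Evidence per SNP is Wakefield's approximate Bayes factor: with
z = beta/se, V = se², and prior effect variance W,

$$\mathrm{lABF} = \tfrac12\left[\log(1 - r) + r z^2\right],
\qquad r = \frac{W}{W + V}.$$

The prior SD is 0.15 for quantitative traits and 0.2 (log-OR) for
case-control traits — the cited defaults for this class of analysis, chosen
here because the package's inputs are (beta, se) pairs without allele
frequencies or case counts. The five hypothesis masses are assembled from
the per-SNP lABFs with priors p1 = p2 = 1e-4 (either trait associated) and
p12 = 1e-5 (shared causal variant); all sums use log-sum-exp, and the H3
mass (both traits, different variants) is computed as a log-space
difference with explicit clamping to zero when it is numerically
non-positive — which makes PP.H3 exactly zero for a single-SNP region
rather than a small negative-mass artifact.

The analysis window is ±100 kb (inclusive) around the top SNP of trait 1,
where trait 1 is by convention the disease GWAS and trait 2 the QTL; the
convention matters when the two traits peak at different positions, and is
applied consistently in the pipeline and its outputs. The decision rule is
PP.H4 > 0.5, and `p12_sensitivity()` recomputes the posteriors over a
log-spaced p12 grid (reusing the cached lABFs, since only the H4 prior mass
changes) to show the p12 range over which the rule holds; the grid is
bounded above by min(p1, p2), the coherence limit for a joint prior.

## Two-step mediation

Step 1 estimates the exposure→mediator effect *a* with the exposure's
instruments; step 2 estimates the mediator→outcome effect *b* with the
mediator's own instruments, selected at genome-wide significance (5e-8)
with clumping and the F gate — the conventional choice for a mediator
backed by a large GWAS. Step 2 additionally screens out candidate
instruments that are themselves genome-wide associated with the exposure.
This screen is an exclusion-restriction requirement, not an optimization:
a SNP that instruments the exposure affects the outcome through the direct
exposure path too, so its mediator Wald ratio identifies
*b* + direct/*a* rather than *b*; in simulations with a direct effect this
inflates the proportion mediated by tens of percentage points.

The indirect effect is the product *a·b* with delta-method SE
√(a²·se_b² + b²·se_a²); the proportion mediated is *a·b*/total with the
total effect taken from the main MR fit. Proportions are reported
unclamped — they may exceed 100% or be negative — and interpretation is
carried by the label: `mediating` when indirect and total effects share a
sign, `suppressing` when they oppose, and `not_significant` unless both
step p-values are below 0.05. Because the total-effect estimate appears in
a denominator, the per-replicate proportion is heavy-tailed when the total
is imprecise; summaries across replicates should use the median in that
regime (the package's own tests do).

## The simulator

`simulate_trait_sumstats()` draws one cohort's observed marginal effects
from MVN(R·b, R/n) on the standardized-genotype scale, where R is the LD
matrix and b the sparse causal-effect vector; every SE is 1/√n and the
expected z-score of an isolated causal SNP is b·√n. This parameterization
keeps closed-form truth for every downstream estimand while reproducing the
two features that matter to the pipeline: LD-correlated marginal effects
and LD-correlated noise. `make_ld_ar1()` supplies the AR(1) structure
r[i,j] = ρ^|i−j| with positions on a uniform grid over a 200 kb region.

`simulate_mr_study()` builds a full two-sample study: exposure, outcome and
mediator panels are drawn from three independent cohorts (seeds split
deterministically from one master seed, so identical seeds give
bit-identical bundles), sharing SNP metadata (ids, positions,
non-palindromic alleles, frequencies from U(0.05, 0.95) — the frequencies
exist only to exercise harmonization). The causal chain is
exposure → mediator → outcome with an optional direct path; the total
effect is direct + a·b by construction, the mediator receives its own
causal SNP (placed at the far end of the region, in negligible LD with the
exposure's), and the outcome's causal-effect vector is
theta·b_x + b·b_m so that every estimand has a known target value.
Defaults — 50 SNPs, ρ = 0.5, one causal eQTL of effect 0.3, cohorts of
10⁴ — put the instrument near F ≈ 900 and the outcome signal near z ≈ 9, a
strong-but-finite regime representative of a well-powered cis-QTL screen;
the mediator-specific effect 0.1 at n = 10⁴ gives the mediator its own
genome-wide hit (z ≈ 10). Case-control outcomes are simulated on the same
linear scale and only labelled case-control (the label drives the coloc
prior SD); no logistic sampling is performed, which keeps the truth
closed-form at the cost of realism in the tails of rare-disease effect
sizes.

`simulate_coloc_scenario()` sizes causal effects as z_target/√n and places
them to realize each colocalization hypothesis: one SNP shared by both
traits (H4), two SNPs with pairwise r² < 0.01 (H3), one trait null (H1/H2),
or both null (H0).

What the simulator does *not* emulate — allele-frequency-dependent power,
sample overlap between cohorts, population stratification, horizontal
pleiotropy other than the modelled direct path, multi-causal-variant loci,
and genome-scale multiplicity — bounds what passing tests show: they
establish that the estimators and decision rules are correct and calibrated
under the stated generative model, not that the pipeline is robust to every
failure mode of real summary data.

## Numerical choices and degenerate inputs

* All posterior mass arithmetic in log space; log-sum-exp throughout;
  H3 mass clamped to zero when the log-difference is non-positive.
* Simulated and estimated p-values floored at 1e-300.
* MVN draws use a pivoted Cholesky factorization, so rank-deficient LD
  matrices (duplicate SNPs, perfect proxies) are handled without jitter.
* Selection tie-breaks: ascending p, then position, then SNP id — full
  determinism under row permutation.
* Wald ratio with beta_x = 0 is a domain error; IVW excludes such pairs
  with a warning and degenerates to the Wald ratio when one usable pair
  remains.
* `coloc_posteriors()` requires pre-aligned panels and refuses silently
  mismatched SNP orders; `run_coloc()` performs the windowing and
  intersection.
* The pipeline isolates per-combination failures (a degenerate panel skips
  that combination with a log entry) but aborts before any computation if a
  configured input file is missing.

## Problem sizes in the test suite

The suite simulates studies of 50–100 SNPs with cohorts of 10⁴: 500
replicates each for CI coverage and type-I error of the estimator, 200
replicates each for mediation recovery and the null-gate rate, 1,000 random
panels of up to 8 SNPs for the clumping-vs-oracle comparison, and a
54-point grid for the lABF quadrature check. These sizes give Monte Carlo
standard errors comfortably inside the asserted bands (e.g. ~1.1
percentage points for a 500-replicate coverage estimate) while keeping the
whole suite under a minute on one core.

## Known limitations

* First-order Wald SEs are anti-conservative at low instrument strength;
  the F gate bounds but does not eliminate the effect.
* No MR-Egger, weighted-median, heterogeneity or Steiger diagnostics; the
  package deliberately implements only the estimators of the screening
  workflow it supports.
* Colocalization assumes a single causal variant per trait; loci with
  allelic heterogeneity need fine-mapping-aware methods.
* The confounder screen is only as good as its lookup table; it cannot
  discover unreported pleiotropy.
* Proportions mediated are ratio estimates with no delta-method CI
  reported; they are screening quantities, not effect sizes to be carried
  into downstream inference.
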