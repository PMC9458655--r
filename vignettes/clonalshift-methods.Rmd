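---
title: "Methods: germline-somatic interaction analysis with clonalshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline-somatic interaction analysis with clonalshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalshift)
```

## Scientific setting

Myelofibrosis and related myeloproliferative neoplasms sit at the
intersection of inherited and acquired genetics. A germline risk
haplotype at *JAK2* (the "46/1" haplotype, tagged here by the allele
string G-G-C over rs3780367, rs10974944 and rs12343867) raises the
probability of acquiring the activating somatic *JAK2* V617F mutation
(GRCh38 chr9:5,073,770), and the mutation is preferentially acquired in
*cis* — on the risk haplotype itself. On top of point mutations, a large
fraction of cases carry mosaic chromosomal alterations (mCAs): clonal
gains, losses or copy-neutral loss of heterozygosity (CNLOH) present in
a fraction of blood cells. These events interact: mCAs spanning *JAK2*
preferentially duplicate or retain the risk (and mutated) haplotype,
amplifying the driver. Inherited long telomere length raises disease
risk, while clonal expansion itself erodes measured telomere length.

`clonalshift` implements this analysis stack as a reusable, tested
pipeline: an mCA caller on phased SNP-array signal, a targeted long-read
haplotype/mutation caller with its QC rules, the allelic-shift and
ordering statistics, and a telomere polygenic-score / Mendelian
randomization suite — all exercisable on a synthetic cohort whose joint
structure mirrors a myelofibrosis case series, so that every stage can
be validated without access to restricted individual-level data.

## mCA detection model

### Signal model

The caller consumes per-site B-allele frequency (BAF), log2 R ratio
(LRR) and phased genotypes (`A|B` coding, haplotype 1 left of the bar).
With an event at cellular fraction $f$, expected haplotype copy numbers
are (favored haplotype first):

| state | copies | total | het BAF | LRR |
|-------|--------|-------|---------|-----|
| CNLOH | $(1+f,\,1-f)$ | 2 | $(1\pm f)/2$ | 0 |
| loss  | $(1,\,1-f)$ | $2-f$ | $1/(2-f)$ or $(1-f)/(2-f)$ | $\log_2\frac{2-f}{2}$ |
| gain  | $(1+f,\,1)$ | $2+f$ | $(1+f)/(2+f)$ or $1/(2+f)$ | $\log_2\frac{2+f}{2}$ |

Expected BAF at a site is the B-allele copy share. Inverting the
deviation $d = |BAF - 0.5|$ at heterozygous sites gives the
cellular-fraction estimators used by `estimate_cell_fraction()`:
$f = 2d$ (CNLOH), $f = 4d/(1+2d)$ (loss) and $f = 4d/(1-2d)$ (gain,
capped at 1 because the gain deviation saturates at $d = 1/6$).

### Segmentation

`segment_baf()` is a two-tier scan:

1. a **phase-oriented pass** on $(BAF-0.5)$ signed by the phased
   genotype, which is a mean-shift scan with null mean 0 and detects
   subtle haplotype imbalance;
2. an **unphased pass** on $|BAF-0.5|$ minus its null mean
   $\sigma\sqrt{2/\pi}$, which does not depend on phase and rescues
   high-cell-fraction CNLOH, where phase-based detection is fragile in
   real data.

Each pass finds the interval maximizing $|S|/\sqrt{L}$ (segment sum over
square-root length), declares it an event if the Bonferroni-corrected
normal p-value over all $n(n+1)/2$ candidate intervals falls below
$\alpha = 10^{-4}$, and recurses on the flanks (up to 5 events per
chromosome). Ties in the scan score are broken toward the longer
interval. Intervals from the two passes are overlap-merged. The noise
SD is estimated as $\mathrm{mad}(\Delta)/\sqrt{2}$ of successive
differences of the oriented signal, which is insensitive to contained
mean shifts. On small inputs the returned boundaries equal the
exhaustive best-scoring changepoint pair by construction, and the test
suite verifies this against an independent brute-force search.

The cellular fraction is computed from the phase-oriented mean shift
(an unbiased estimate of $d$; the unphased mean $|BAF-0.5|$ is inflated
by noise folding), and the favored haplotype is the sign of that shift.

### State and region classification

State thresholds are deterministic stand-ins for the manual review used
around HMM-based callers, exposed in `mca_params()`: gain if median LRR
$> 0.04$, loss if $< -0.10$, CNLOH if LRR lies between the cutoffs and
the mean BAF deviation is at least $0.02$, otherwise *undetermined*
(the sub-threshold convention; no published criterion exists for it).
One structural consequence, documented rather than hidden: a true loss
at cellular fraction $\approx 0.10$–$0.14$ has expected median LRR
$\log_2(1.9/2) = -0.074$, above the loss cutoff, and is classified
CNLOH with a cell-fraction error up to $\approx 0.05$. This affects a
fraction of a percent of events under the default cellular-fraction
distribution and is why the recovery suite states its cell-fraction
accuracy as a 95th-percentile bound.

Region classes follow the coordinate convention: *whole-chromosome* if
the call covers the full analyzed site extent, *telomeric* if contained
entirely within 1 Mb of either chromosome end, *interstitial*
otherwise. "Within the margin" is read as containment, not endpoint
proximity. Coordinates are 1-based inclusive internally; BED export is
0-based half-open.

## Long-read haplotype calling

Reads over the targeted *JAK2* amplicon report four sites: the three
46/1-tagging SNPs and the V617F position. The caller:

1. collapses reads to exact 4-site haplotype counts;
2. removes haplotypes with frequency strictly below 1% of the sample's
   total reads (a haplotype at exactly 1.000% is retained; frequencies
   are deliberately **not** renormalized after filtering);
3. applies QC: fail on depth < 1000, more than two distinct germline
   (3-SNP) backgrounds, or mutations on more than one background
   (biallelic samples are flagged with a distinct status, not silently
   dropped, since replicated biallelic cases do occur);
4. calls 46/1 carriage (any background equals GGC), the mutation's
   background, its allelic fraction (mutant reads on that background
   over all reads on that background), and phase: *cis* when the
   mutated background is the risk haplotype in a heterozygous sample,
   *trans* when reversed, *uninformative* for homozygous backgrounds.

The allelic fraction is only a per-haplotype quantity when the two
backgrounds are distinguishable; for homozygous backgrounds the
denominator necessarily pools both haplotypes. Downstream ordering
statistics therefore use only distinct-background samples.

## Interaction statistics

All count statistics are exact binomials. The two-sided convention is
tail doubling, $p = \min(1,\, 2\min(P[X \le k], P[X \ge k]))$, which is
symmetric at $p_0 = 0.5$ (the allelic-shift null); the
minimum-likelihood convention is available behind a flag. Allelic-shift
tests count, among informative heterozygous carriers, events favoring
the risk haplotype (duplicated by gains and CNLOH, retained by losses)
against a 50:50 null. The clonal-ordering test is a classical sign test
on paired (mutation allelic fraction, mCA cellular fraction), ties
dropped by default. Co-occurrence uses Fisher's exact test for tables
up to 5000 observations and chi-square beyond, with a Haldane 0.5
correction on the cross-product odds ratio when a cell is zero; the
method used is recorded in the output. Enrichment against an external
population rate (e.g. ~3% mCA carriage in population surveys) is the
one-sided exact binomial.

Because the exact doubled test is discrete, its size at nominal
$\alpha = 0.05$ depends on $n$: it is within $[0.04, 0.06]$ at e.g.
$n = 200$ or $500$ but conservative (0.036) at $n = 59$. The test suite
asserts the calibration band where it is attainable and conservatism
elsewhere; no anti-conservative $n$ exists for this statistic.

## Telomere genetics

**PRS.** Weighted sum of effect-allele dosages, z-scored with the
population (denominator $n$) SD, matching a score "standardized to mean
0 and SD 1". Allele flips are resolved when the counted allele matches
the known other allele; unresolvable mismatches are errors, not silent
drops.

**MR estimators.** For instruments with exposure effects $\beta_{X_j}
(\sigma_{X_j})$ and outcome effects $\beta_{Y_j} (\sigma_{Y_j})$:

- *IVW*: $\hat\theta = \sum \beta_X\beta_Y/\sigma_Y^2 \big/ \sum
  \beta_X^2/\sigma_Y^2$, fixed-effect SE, inflated by
  $\sqrt{Q/(n-1)}$ when Cochran's $Q$ exceeds its df (multiplicative
  random effects, recorded).
- *Egger*: WLS of $\beta_Y$ on $\beta_X$ with intercept, weights
  $1/\sigma_Y^2$, after flipping instruments so $\beta_X \ge 0$ (the
  standard identifiability orientation); residual dispersion floored at
  1.
- *Median*: simple median of Wald ratios, or weighted 50th percentile
  with weights $\beta_X^2/\sigma_Y^2$; SEs by seeded parametric
  bootstrap (default 10,000 draws, seed 20260921) redrawing summary
  statistics from their sampling distributions.
- *Maximum likelihood*: joint-normal likelihood over $(\theta,
  \xi_1..\xi_n)$ with the true exposure effects as nuisance parameters,
  maximized by BFGS from the IVW start; SE from the observed
  information. On homogeneous instruments (identical Wald ratios) the
  estimate coincides with IVW, which the suite checks to $10^{-6}$.

**Pleiotropy pruning.** The published analysis delegates to an external
package without printing its algorithm; here the filter is realized as
leave-one-out $Q$ contributions — each variant's squared residual from
the IVW estimate computed without it, variance
$\sigma_Y^2 + \theta^2\sigma_X^2$ — converted to $\chi^2_1$ p-values
and pruned by Benjamini–Hochberg at FDR 0.2. This is an approximation
to the published procedure; removal lists are reported for audit.

**Liability conversion.** The Lee transformation
$h^2_{liab} = h^2_{obs}\, K^2(1-K)^2 / (z^2 P(1-P))$ with $z$ the
normal density at the threshold $\Phi^{-1}(1-K)$; linear in
$h^2_{obs}$ by construction.

**qPCR.** Per-reaction quantities are interpolated on a monotone
standard curve (Cq versus log10 quantity), T and S are triplicate
means, and the T/S ratio passes through a configurable transform. The
exact "exponentiation to assure normality" used in practice is not
published, so the transform is a named option (default `exp`) recorded
in the output. The intraclass correlation is the one-way
random-effects ICC(1) over per-reaction T/S ratios (the published ICC's
form — one-way vs two-way — is unstated; one-way is the conservative
choice for technical replicates), with an F-based confidence interval,
and triplicate coefficients of variation above a configurable limit
flag the sample.

## The synthetic cohort: what it emulates, and what not

`simulate_cohort()` draws, per individual: two germline haplotypes
(risk-allele frequency solved from the 68.61% carrier rate), V617F
status (group rates solved from the 60.82% prevalence and the 2.69
carrier odds ratio), cis placement at 0.80 among informative
heterozygotes (implying ~66% of mutated samples carry the mutation on a
risk background, consistent with the observed 65.84%), biallelic
mutations at 0.5%, one mCA per sample at 73.31% prevalence with state
mix 28:16:59, *JAK2*-region probability 378/684, and per-state
risk-haplotype retention 23/28, 14/16, 51/59 among informative
heterozygotes.

Cellular fractions follow Beta(2, 1.2). Allelic fractions follow
Beta(0.884, 0.517) — quantile-fitted to a detected-carrier profile with
median ~0.70 and IQR ~0.38–0.93 — **truncated at 0.03**: carrier status
emulates *detected* mutations, and a mutant haplotype must clear the 1%
read-frequency filter (~2% AF on a balanced heterozygote), so the
printed AF summaries are left-truncated by construction and the truth
model inherits that truncation. In double positives the AF is drawn
above the cellular fraction with probability 0.95. Relative telomere
length is baseline Normal(2.0, 0.3) plus slope × cellular fraction
(−1.17 for *JAK2*-spanning events, −0.57 otherwise), floored at 0.05;
the baseline is set high enough that the positivity floor truncates a
negligible fraction of samples, preserving the linear attrition
structure (a baseline of 1.0 would truncate roughly half of the
high-fraction *JAK2* samples and visibly bias slope recovery). The two
printed marginal regression coefficients (−0.57 overall, −1.17 for
*JAK2* events) are not jointly representable in a single per-sample
linear model given the *JAK2* event share, so the generator assigns
−0.57 to non-*JAK2* events and the pipeline reports separately labeled
marginal, *JAK2*-only and non-*JAK2* slopes.

Array signal uses per-site phased genotypes at 50% heterozygosity,
Gaussian noise (BAF SD 0.03, LRR SD 0.14 — typical array noise), and
the allele-copy means above; with zero noise it reproduces the closed
forms exactly. Reads are drawn from the two haplotypes with shares
shifted by any *JAK2*-spanning event; the error model is **per read**:
a read is erroneous with probability `read_error_rate` (default 0.005)
and has one of its four sites flipped. A per-site error model at 1%
would place single-error derivative haplotypes of homozygous
backgrounds at exactly the 1% filter boundary, making the caller's
replicate concordance undefined by construction — residual consensus
miscalls in the emulated assay are far rarer than 1% per site, and the
per-read model keeps derivatives near 0.1%.

Randomness: one root seed; each sample owns child streams derived as
`(seed * 48271 + index * 7919 + purpose * 104729) mod (2^31 - 19)`,
with distinct purpose offsets for array signal (1), reads (2) and
downstream draws, so identical configurations reproduce byte-identical
outputs and per-sample emission is order-independent.

The generator does **not** emulate: recurrent multi-event genomes (one
event per sample keeps ordering statistics unambiguous), genotyping
batch effects or GC waves in LRR, population phasing errors (phase is
taken as given, so phase-based detection is optimistic relative to real
switch-error rates), ancestry structure, age/sex effects on event
rates, or read-level sequence context. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated signal
model, not robustness to artifacts absent from it.

## Test problem sizes

The recovery suites run at sizes chosen to keep the full check fast
while leaving comfortable statistical margins: 200 event samples plus
100 nulls for the mCA caller (1500-site grids, so *JAK2*-region events
contain well over 100 heterozygous sites), 300 samples at the default
depth of 2000 reads for the haplotype caller (at much lower depth the
0.03 AF accuracy bound is unattainable from binomial noise alone), 1000
simulations for MR coverage with 500-draw bootstrap SEs for the median
estimators, and 60 replicates for pleiotropy-filter power. The
acceptance script mirrors these at slightly smaller sizes and also runs
the full pipeline on a 933-sample cohort.

## Known limitations

- The segmentation scan assumes a single shift level per event and
  Gaussian noise; heavy-tailed BAF noise would need a robust scan.
- State classification by fixed LRR cutoffs misclassifies low-fraction
  losses as CNLOH (see above); a likelihood-based joint (BAF, LRR)
  classifier would resolve this at the cost of a noise model for LRR.
- The pleiotropy filter is a leave-one-out heterogeneity heuristic, not
  a reimplementation of the published package's algorithm.
- Cis-enrichment binomials whose null probabilities are not published
  are computed only under the documented 50:50 informative-heterozygote
  null.
- Measured-telomere regression coefficients, externally-estimated MR
  odds ratios and liability heritability values from real cohorts are
  out of desk-scale reach; the package covers those code paths with
  parameter-recovery simulations instead.
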