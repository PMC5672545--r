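---
title: "Concentration-response modeling and POD estimation for targeted RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concentration-response modeling and POD estimation for targeted RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crpod)
```

## The problem crpod addresses

Targeted probe-sequencing assays (TempO-Seq and kin) read ligated 50-mer
detector probes directly from cell lysate, making transcriptome-scale
concentration-response screening affordable: a single plate carries a few
thousand probes, a couple dozen shared vehicle controls, and several
chemicals at a handful of concentrations, often with a *single* replicate
per concentration. crpod implements the full analysis path for such
experiments:

1. **Counting** -- demultiplexed FASTQ files are matched against the probe
   manifest to produce a gene x sample count matrix.
2. **QC and normalization** -- low-count features and samples are filtered,
   outlier vehicle controls are detected, and counts are depth-normalized.
3. **Differential expression** -- each chemical's maximum concentration is
   contrasted against the pooled vehicle controls with a negative-binomial
   test.
4. **Concentration-response modeling** -- statistical flags route
   gene-treatment pairs into curve fitting; four candidate models compete by
   AIC; the point of departure (POD) is the concentration at which the
   winning curve departs one control standard deviation from baseline.

Every stage takes a data frame (or matrix) and returns tibbles, so the
stages compose with ordinary tidyverse tooling; `crpod_run()` chains them
end to end.

## Stage I: probe counting

Because the reference is a panel of fixed-length probes rather than a
genome, alignment reduces to direct matching of each read's first L bases:
a hash lookup resolves exact hits, and remaining reads are assigned to the
probe at minimum Hamming distance, up to a configurable tolerance
(`max_mismatch`, default 2 -- substitution errors at typical Illumina rates
leave the overwhelming majority of 50-mers within two mismatches of their
source probe, while random panel probes are dozens of mismatches apart).
Ties between probes of the same gene are assigned to the gene, since genes
are the downstream unit; ties across genes are left ambiguous. Reverse
complement search is off by default because the assay reads the probe
strand. Quality scores are ignored: matching is sequence-driven, and the
panel's specificity means a corrupted read simply fails to match.

The per-sample summary always satisfies
`assigned + ambiguous + unassigned + short = total`, and FASTQ structure is
validated strictly (4-line records; any malformed record fails the run,
naming the file and record).

## Stage II: QC and normalization

The defaults mirror common practice for ~3,000-feature panels:

* **Feature filter**: keep genes with more than one count across the
  experiment (`min_row_total = 2`).
* **Sample filter**: keep samples with at least 100,000 total counts
  (`min_col_total`), a depth at which a 3,000-probe panel averages tens of
  reads per probe.
* **Control diagnostics**: PCA of log2(count + 0.5), gene-centered control
  profiles is reported for visual inspection only; no automatic exclusion
  is tied to it.
* **D statistic**: for each control, D is its mean Pearson correlation
  (computed on log2(count + 0.5) values, which stabilizes the variance;
  Spearman is available) with the other controls. Controls more than 3 SD
  below the mean D are dropped, in a single pass -- one application of the
  rule, no iteration. A zero-variance control is dropped with an explicit
  reason since its correlation is undefined.
* **Normalization**: median-of-ratios size factors (reference genes are
  rows nonzero in every sample; each sample's factor is the median ratio to
  the per-gene geometric mean). Full NB dispersion machinery lives in the
  DE stage; the normalized matrix consumed downstream is this size-factor
  scaling. When no reference row exists the package falls back to
  total-count scaling with a warning.

The pipeline applies the steps in the order features, samples, control
exclusion; the order matters only when filters interact, and that order is
the one reported by the QC summary.

Note one algebraic subtlety: median-of-ratios factors are defined relative
to per-gene geometric means, so rescaling one sample by c rescales its
factor by c *relative to every other sample* while the absolute factors
all absorb c^(1/m); normalized matrices before and after differ by one
global constant. Tests assert the ratio-form identity.

## Stage III: differential expression

For each chemical, the maximum tested concentration is contrasted with the
pooled vehicle controls. The test is a self-contained NB Wald test:

* per-gene dispersion by method of moments on normalized counts within
  replicated groups -- with a single treated replicate the estimate
  necessarily comes from the pooled controls (documented low-power mode);
* shrinkage toward a parametric trend `alpha(mu) = a0 + a1/mu`, weighted
  like `prior_df` pseudo-replicates (default 10) against the per-gene
  residual degrees of freedom;
* a NB GLM per gene with log link and log size-factor offsets, Wald
  statistic on the group coefficient, and **a t reference with n - 2
  degrees of freedom**. The t reference is a finite-sample correction for
  the plug-in dispersion: in null simulations at these group sizes the
  normal reference is measurably liberal (empirical size ~0.06 at nominal
  0.05), while the t reference is well calibrated. Fold changes are raw
  MLEs -- no shrinkage -- and BH adjustment is applied within each
  chemical, excluding untestable (all-zero) genes from the denominator.

`deg_count()`, `l2fc_pca()` and `l2fc_summary()` reproduce the standard
per-chemical summaries (DEG counts, fold-change PCA across chemicals,
dispersion of absolute fold changes).

## Stage IV-a: series construction and statistical flags

For a gene-chemical pair, treatment doses are log10 concentrations and the
vehicle controls receive a pseudo-dose one *average* log10 spacing below
the lowest tested concentration (for 0.1/1/10 uM that is -2; for the
uneven 0.1/1/100 design the spacings 1 and 2 average 1.5, giving -2.5).
Responses are log2(normalized count + 0.5) -- the 0.5 pseudocount admits
zero counts -- centered so the controls average exactly zero. The control
SD of those centered responses defines the baseline deviation unit used
for the POD.

Three flags are computed per pair:

* **overall trend**: association between dose and response over all points;
* **treatment-only trend**: the same test restricted to treated samples;
* **control vs treatment**: two-sided Wilcoxon rank sum (exact enumeration
  for small untied groups, tie/continuity-corrected normal approximation
  otherwise -- the base R implementation already provides both regimes and
  is used directly; tests verify it against a brute-force assignment
  enumerator).

The trend statistic is the Pearson correlation between dose and response,
referred to its permutation distribution. Three interchangeable engines are
provided:

* exact enumeration of all n! permutations (n <= 8);
* Monte Carlo permutation (default 10,000 draws, add-one estimator);
* a moment approximation: the exact second, third and fourth permutation
  moments of the correlation have closed forms in the power sums of the
  two vectors; a shifted, scaled beta (Pearson type I) is matched to those
  moments and the tail is read off the fitted distribution. For n <= 8
  this path simply enumerates, since enumeration there is both cheaper
  and exact; the continuous fit serves longer series. At the 26-point
  study design its empirical size at nominal 0.05 is inside the binomial
  confidence band over 5,000 null simulations, and against a 200,000-draw
  Monte Carlo reference its p-values agree to a few hundredths.

The pipeline's default engine is the moment approximation: unlike Monte
Carlo it has no p-value floor (a floor of 2/(B+1) makes small q-values
unreachable after BH adjustment across ~3,000 genes), and it is three
orders of magnitude faster. The permutation engines remain the ground
truth in the test suite. Two-sided p-values are twice the smaller tail
throughout, and q-values (BH by default, optional Storey pi0) are computed
separately for each flag family across genes *within* a chemical -- the
natural family for per-chemical decision making; per-experiment pooling is
a configuration flag.

The decision tree is a pure function of the three q-values and the
threshold (default q < 0.05):

1. no overall trend: the maximum tested dose is the POD;
2. otherwise, controls differing from treatments (Wilcoxon): fit curves;
3. otherwise, a significant treatment-only trend: fit curves;
4. otherwise: the pair is reported for manual review.

With a single replicate per concentration the treatment-only trend has
only 3 points and its exact permutation p cannot fall below 1/3, so route
3 is effectively inert in that design -- a property of the design, not of
the implementation; it becomes active with replicated concentrations.

## Stage IV-b: models, AIC, POD

Four curves compete on each fitted pair (x is log10 dose):

* constant: `mu`
* three-parameter Hill (floor fixed at 0): `tp / (1 + 10^((ga - x) gw))`
* gain-loss (floor 0): the gain sigmoid times a loss sigmoid
  `1 / (1 + 10^((x - la) lw))`, capturing rise-then-fall responses
* four-parameter Hill: free floor and top.

Fitting is Gaussian maximum likelihood (least squares) under bounded
deterministic multi-start optimization: midpoints start at quartiles of
the dose range, slopes at {0.5, 1, 4}, amplitudes at the response
extremes; bounds keep amplitudes within 1.2x the data range, midpoints
within one decade of the tested range, and slopes in [0.3, 8]. No
randomness enters the fits. The floor-0 models are fit to the response and
its negation and the better sign is kept, recording the direction of
regulation; the four-parameter Hill covers both directions natively. A
heavy-tailed t(4) error model is available behind `error_model = "t4"`;
the Gaussian default admits closed-form oracles for testing. Gain-loss
optima with the loss midpoint left of the gain midpoint are flagged
degenerate.

AIC is `2k - 2 loglik` with the residual scale counted in k (constant 2,
hill3 4, hill4 5, gainloss 6); the smallest AIC among converged fits wins,
ties resolving to fewer parameters, then to the fixed order constant,
hill3, hill4, gainloss. A practical note from simulation: on completely
flat series, noise-chasing by the bidirectional 3-parameter Hill defeats
the penalty of 4 in roughly 8-12% of replicates, so the constant model
wins about nine times in ten, not always; genuinely responsive series are
essentially never routed to a constant winner.

The POD is the smallest log10 dose in [pseudo-dose, max dose] at which
|f(x)| reaches the baseline deviation (1 control SD by default,
configurable multiplier). The crossing is bracketed on a 513-point grid
and bisected to 1e-6; the absolute value makes the search symmetric in
direction, covering the open question of signed versus unsigned crossings
conservatively. A constant winner or a curve bounded below the BSD yields
the maximum dose with basis `max_dose_no_crossing`; no-trend pairs carry
`max_dose_no_trend`; crossings below the lowest tested concentration are
flagged extrapolated rather than truncated, preserving the information.
For the 3-parameter Hill the crossing has the closed form
`ga - log10(tp/BSD - 1)/gw`, which the bisection reproduces to 1e-5 across
a broad parameter grid in the test suite.

## The synthetic-data generator

`simulate_counts()` emulates the shared-control plate design: 2,982 genes,
24 vehicle controls, four chemicals at 0.1/1/10 uM with one replicate
each, a per-sample depth of 632,000 reads (about 212 reads per gene), and
NB counts with dispersion 0.05 -- typical overdispersion for targeted
sequencing. A `replicated` preset provides the smaller illustration
design (12 controls, three replicates per concentration). Baseline log2
expression is N(log2 150, 1.5^2) across genes; responsive genes shift
their mean log2 expression by a 3-parameter Hill curve in log10 dose, with
tops 0.5-3 log2 units, midpoints within the tested decade, slopes 0.5-4,
and random direction.

Responsiveness is per-chemical and deliberately heterogeneous by default
(32%, 15%, ~1%, ~1% of the panel, each responsive gene tied to exactly one
chemical), reflecting how real screens behave: one strongly active
compound, one moderate, and near-inert comparators. This matters for the
decision logic, whose BH-adjusted flags only open the fitting route when a
chemical perturbs many genes; a uniformly sprinkled signal at these sample
sizes routes almost nothing to fitting, which is faithful to the method
but uninformative as a test bed.

Planted defects exercise the QC stage: low-depth samples (depth scaled by
0.05), shuffled outlier controls (gene labels permuted within the
column), and sub-threshold genes (rows forced to total counts of 0 or 1).
The truth table records, per gene, the generating model and parameters and
a closed-form expected POD using the delta-method control SD
`sqrt(1/mu + alpha)/ln 2`.

What the generator does *not* emulate -- and hence what green tests do not
establish about real data: plate-position and batch effects, probe-level
GC or efficiency biases, correlated gene modules (genes are independent
given depth), heavy-tailed outlier counts, and chemicals with overlapping
signatures. The counting fixtures likewise use iid substitution errors
only, with no quality-score structure.

## Numerical choices and degenerate inputs

* Pseudocount 0.5 in every log2 transform, matching the response
  definition.
* Constant response in a trend test returns p = 1; a constant dose vector
  is an error.
* Dispersion estimates are clipped to [1e-8, 10]; genes with all-zero
  counts in a contrast return NA p-values and leave the BH denominator.
* The permutation-moment beta fit falls back to a normal tail outside the
  Pearson type I region (it is used only when the moment configuration
  admits no valid beta).
* Optimizer non-convergence excludes a model from AIC comparison; if no
  model converges the constant fallback wins by construction.
* Bisection tolerance 1e-6 on the log10 scale; series grids of 513 points
  bracket the first crossing.
* Seeds: simulation configs carry their seed and restore the caller's RNG
  stream; the pipeline seeds once before the flag stage so Monte Carlo
  trend modes are reproducible end to end.

## Problem sizes in the test suite

Unit tests run on matrices of tens to hundreds of genes; the calibration
checks use 2,000 null genes (DE), 5,000 null series (trend tests), and a
200-case oracle battery (small-n enumeration); the end-to-end determinism
check runs a 150-gene two-chemical bundle twice. These sizes were chosen
to keep each statistical assertion's Monte Carlo error well below the
tolerance it checks.

## Known limitations

* Exact numerical parity with external toolchains (aligner-based probe
  counters, established NB differential-expression packages, ToxCast-style
  curve fitters) is not a goal;
  statistical calibration and oracle agreement are the contract.
* Single-replicate designs make the treatment-only trend route inert and
  force treatment dispersion to be borrowed from controls.
* No batch correction, no multi-factor designs, no fold-change shrinkage,
  no benchmark-dose confidence limits, no model averaging, no pathway-level
  aggregation.
* The moment-approximation engine's accuracy degrades for the heavily tied
  dose designs at very small tail probabilities; q-value decisions at the
  0.05 flag threshold are insensitive to this, but exact permutation modes
  are available where tail precision matters.
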