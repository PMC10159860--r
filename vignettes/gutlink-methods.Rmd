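---
title: "Statistical methods behind gutlink"
author: "gutlink authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind gutlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gutlink)
```

gutlink re-implements, as a tested toolkit, the statistical core of a
case/control gut-microbiome multi-omics analysis: deconfounded differential
abundance, ecological diversity and PERMANOVA, trans-kingdom compositional
correlation networks, bacterial replication-rate (peak-to-trough ratio)
inference, structural-variant profiling, and triplet-screened bidirectional
causal mediation. This vignette explains each model, its assumptions, the
tunable parameters that matter, and the design decisions taken where the
design was genuinely open.

## The data model

All stages start from sample-by-feature abundance tables (`feature_table`:
bacterial or viral relative abundances, or metabolite concentrations) and a
per-sample metadata table (`sample_metadata`: binary case/control status,
optional subtype, covariates, phenotype scores). Relative-abundance rows must
sum to at most 1; missing covariates are refused rather than imputed, because
silent imputation changes every downstream adjustment. Samples and features
keep the order of the input files; all I/O is plain TSV.

## Rank-based elementary statistics

Because microbiome abundances and questionnaire scores are heavily skewed,
all association modelling happens on the **empirical normal quantile
(rank-normal) scale**: values are replaced by
$\Phi^{-1}\!\big((r - 0.375)/(n + 0.25)\big)$, the Blom variant of the
normal-scores transform, with average ranks for ties. The offset constant is
one of several in common use and none is canonical; Blom's is the documented,
switchable default (`offset` argument). Group contrasts use the two-sided
Wilcoxon rank-sum test (exact enumeration for tie-free pooled samples of at
most 12; otherwise the tie-corrected normal approximation *without*
continuity correction, so null p-values are calibrated rather than
conservative) and Cliff's delta
$\delta = \big(\#\{x_i > y_j\} - \#\{x_i < y_j\}\big)/(nm)$
as the effect size. Multiplicity is handled by Benjamini–Hochberg throughout,
always within an explicitly named family (per target, per covariate set, per
species list). Fisher's exact test (two-sided, by hypergeometric tail
summation of tables no more probable than the observed one) compares network
edge counts.

## Deconfounded differential abundance

The screen (`univariate_screen`) drops features with prevalence below 10%
(the same inclusive 10% rule the virome filter uses), tests abundance against
status by rank-sum, and BH-adjusts across retained features. Each significant
feature then receives a **status label** (`confounder_label`):

* covariates univariately associated with the feature (rank-sum for binary,
  Spearman for continuous; BH within the covariate family at $\alpha=0.05$)
  become confounding candidates;
* for each candidate $Z$, two nested linear-model comparisons on the
  rank-normal abundance decide who carries the signal:
  LRT1 — does status add to $Z$? LRT2 — does $Z$ add to status?
* no candidates → `OK_nc`; status survives every candidate → `OK_d`; for
  some $Z$ status does not survive while $Z$ does → `C:Z` (confounded);
  anything else → `AD` (ambiguous). A covariate collinear with status
  (|r| > 0.99) yields `AD` with a warning rather than an error, since neither
  model is identified.

The underlying pipeline this mirrors publishes its label vocabulary but not
its internal thresholds; both gates default to raw $p < 0.05$ and are
configurable. Whether nested-test p-values should be corrected across
features is equally unstated; we correct within feature (across covariates)
only, since the labels are per-feature descriptions rather than discoveries.

`association_scan` fits `target ~ feature + age + BMI + smoking + medication`
with feature and target rank-normalized, so the reported coefficient is a
standardized partial effect. For metabolic-trait targets BMI is dropped from
the covariates (`adjust_bmi = FALSE`): in a cohort defined by extreme
leanness, BMI is an outcome there, not a nuisance. The scan is computed by QR
residualization against the covariate design, which is algebraically
identical to per-pair `lm()` fits (asserted in the tests) but linear in the
number of features.

## Ecology

Chao1 richness uses the bias-corrected form
$S_{obs} + F_1(F_1-1)/\big(2(F_2+1)\big)$, finite even without doubletons.
It requires integer counts and errors on fractional input — richness
estimation from relative abundances is undefined, and silently accepting
them would hide a unit error. Shannon diversity is reported in nats (base-2
via flag) over renormalized positive entries. The Canberra distance is the
plain coordinate-normalized L1 sum (double-zero coordinates contribute
nothing), which weights rare features heavily — the reason it is favoured
for virome and SV profiles. PERMANOVA permutes labels freely (no strata are
described for this design), reports the pseudo-F from among/within squared
distances, and uses the permutation p-value $(1 + \#\{F_\pi \ge F\})/(1+P)$
with $P = 999$ by default, so the smallest attainable p is $1/(P+1)$; the
permutation engine is vegan's, driven by an explicit seed.

## Trans-kingdom SparCC networks

Viral and bacterial tables are filtered (prevalence ≥ 10% *and* mean
relative abundance ≥ 0.01%, both inclusive), joined, and passed to an
in-package SparCC implementation: per Dirichlet resample, log-ratio
variances $t_{ij} = \mathrm{Var}\log(x_i/x_j)$ — which cancel each sample's
total exactly, making the estimate compositionally scale-invariant — feed
the sparsity-approximated system
$\sum_{j \ne i} t_{ij} = (D-2)\,\omega_i + \sum_j \omega_j$
for the basis variances $\omega$, from which
$\rho_{ij} = (\omega_i + \omega_j - t_{ij})/(2\sqrt{\omega_i\omega_j})$;
the most correlated pair above 0.1 is iteratively excluded from the system
(at most 10 times, never reducing a feature below 3 partners) and the median
over 20 Dirichlet draws is reported. Input is always renormalized to
fractions and resampled at a nominal depth of $10^5$ with unit pseudocount:
the study design this emulates sequences deeply (millions of reads per
sample), so posterior resampling noise should be far smaller than biological
variance; a much smaller nominal depth would visibly attenuate true
correlations of rare taxa. The approximation needs at least 4 features and
genuinely sparse correlations — a dense correlation structure violates its
central assumption.

Edge significance uses permutation pseudo-p-values (each permutation
shuffles every feature independently and re-runs SparCC;
$p = (1+\#\{|\rho_\pi| \ge |\rho|\})/(1+B)$, $B = 100$ by default). The
source analysis states the algorithm but not its edge rule; the defaults
$|\rho| \ge 0.2$, $p \le 0.05$ follow common SparCC practice and are
configurable. The Fisher 2×2 comparing two groups' networks counts
significant edges against tested non-edges over **all post-filter
virus×bacteria pairs** — that universe is asserted identical between the
two networks, because the comparison is meaningless otherwise.

## Replication rates (PTR)

Coverage profiles binned at 10 kbp are smoothed by a circular moving median
after masking zero bins and outliers beyond 3 MAD of the positive-bin
median; a profile with more than 40% masked bins is unusable. The smoothing
window defaults to 5% of the genome: a moving median of width $w$ (as a
genome fraction) attenuates the tent-shaped log-coverage extrema by a factor
$\mathrm{PTR}^{-w}$, so a 10% window would bias a PTR of 3 by more than 10%
while 5% keeps the bias near 5% and still rejects isolated artefacts.

Origin and terminus are located jointly across samples (`fit_ori_ter`): a
grid search over circular (peak, trough) pairs with separation constrained
to 45–55% of the genome — the geometry of bidirectional replication — fits
each sample's log2 smoothed coverage piecewise-linearly in the normalized
arm position, with slopes constrained non-positive so the peak really is the
maximum (the unconstrained objective is mirror-symmetric in peak and
trough), and minimizes the pooled squared error. Flat (non-replicating)
profiles make every pair fit equally well; that tie is detected and flagged
`indeterminate` rather than returning an arbitrary location. The per-sample
PTR is then the smoothed coverage at the fitted origin over that at the
terminus, on the linear scale per the estimator's definition; ratios below 1
are inverted with an orientation flag. QC requires at least 60% unmasked
bins and positive trough coverage. Cohort-level comparisons keep species
with at least 20 QC-passing samples and rank-sum-test PTR between groups,
BH across species.

## Structural variants

Per-species 1-kbp coverage matrices are normalized by each sample's median
bin coverage; samples under 1× median coverage are masked as unevidenced,
and a cell is called deleted below 25% of the sample median. Bin-level
population deletion rates over unmasked samples classify bins by the
canonical rule — < 25% variable SV, 25–75% (inclusive at both bounds,
reading "between" inclusively) deletion SV, > 75% excluded — and adjacent
same-class bins merge into regions (no gap tolerance by default;
configurable). A sample carries a dSV region when more than half the
region's bins are deleted in it (the source works at segment granularity
without defining per-sample calls; majority vote is the simplest monotone
rule); vSV regions are summarized as across-sample z-scores of normalized
coverage averaged over the region. Note that under this literal rule a bin
never deleted in anyone is a (signal-free) vSV bin; such regions carry zero
variance and are inert downstream. Species profiled in fewer than 10% of
samples are dropped (inclusive). SV β-diversity concatenates dSV genotypes
and min-shifted vSV scores over the species shared by each sample pair
(pairwise-complete; pairs sharing nothing are recorded as missing), computes
Canberra distances, and compares within-group distance distributions by
rank-sum. SV–phenotype associations delegate to the association scan with
dSV features entered as binary regressors and vSV features rank-normalized.
The per-sample deletion-evidence model of the original read-level tool is
not public; bin-coverage thresholding is an explicit simplification.

## Bidirectional mediation

Candidate (microbe, metabolite, phenotype) triplets must pass three
covariate-adjusted association gates at BH-adjusted $p < 0.1$ (within each
feature-set × target family) before any mediation model is fit — the
mediation engine runs on exactly the surviving triplets. For a triplet,
`mediate` fits $M \sim T + X$ and $Y \sim T + M + X$ on rank-normal scales
and propagates coefficient uncertainty quasi-Bayesianly: `n_sims` draws from
each model's asymptotic normal give per-draw ACME $= a b$, ADE $= c'$ and
total $= ab + c'$ (linear, no interaction), with percentile intervals, a
sign-crossing two-sided p (floored at $1/n_{sims}$), and the proportion
mediated as the simulation median of ACME/total bounded to $[-5, 5]$.
Quasi-Bayesian propagation rather than bootstrap: it matches the standard
mediation framework's default and costs two model fits regardless of
`n_sims`.

Direction 1 treats the metabolite as mediator of the microbe's effect on the
phenotype; direction 2 swaps mediator and outcome. In linear-Gaussian
systems a reverse-wired chain $T \to Y \to M$ still yields a nonzero
direction-1 ACME ($\approx c\,d^2(1-c^2)$ for paths $c, d$), so a pure
significance threshold on direction 1 cannot certify direction — with any
wiring strong enough to detect, both directions go significant. The default
verdict rule is therefore **dominance**: direction 1 is called when its ACME
is significant at $\alpha = 0.05$ *and* its simulation z-statistic exceeds
direction 2's. The pure-threshold rule (`acme1`) and the strict
`dir1 AND NOT dir2` rule (`exclusive`) remain available; both fail one side
of the forward/reverse discrimination that the dominance rule passes.

## The synthetic cohort generator

`generate_cohort` is the package's oracle: every downstream claim is tested
against its planted truth. Abundances are the closure of exponentiated
multivariate-normal log-basis abundances (unit variances, heterogeneous
baselines), so planted basis correlations are exact on the latent scale —
that is what makes it a valid SparCC oracle, and the reason a Dirichlet
generator (whose negative correlations are uncontrollable) was not used.
Differential features receive a log-scale mean shift
$\Delta = \sqrt{2}\,\Phi^{-1}\!\big((\delta+1)/2\big)$ calibrated to a target
Cliff's delta (default 0.6 on 10 of 200 species). Confounded features depend
*only* on a medication flag whose prevalence is 65% in cases versus 5% in
controls — psychotropic medication is largely restricted to the patient
group in such cohorts — which is the minimal structure that must earn a
`C:medication` label. Covariates: age ~ N(24, 4); BMI ~ N(16.5, 2) in cases
versus N(21.5, 2) in controls — severely underweight against normal-weight,
while keeping enough distributional overlap that status effects remain
identifiable after BMI adjustment (with nearly disjoint BMI distributions
the nested tests lose identification and every label degrades to ambiguous);
smoking 20% everywhere. Mediation paths are wired on standardized latent
scales ($a = 0.5$, $b = 0.4$, $c' = 0.3$ by default), metabolites are
exponentiated to log-normal concentrations (rank-normalization in the
analysis recovers the latent scale), and phenotypes add a small age effect
so covariate adjustment is exercised. Under this construction the true ACME
is $ab$ in expectation.

What the generator does **not** emulate: zero inflation and detection
limits, overdispersed counts, batch effects, phylogenetic correlation
structure, non-linear mediation, and measurement error in phenotypes.
Passing tests therefore demonstrate correctness of the estimators under the
stated model, not robustness to everything real data do.

`generate_coverage` draws Poisson counts around the exact piecewise
log-linear expectation (ori/ter ratio equals the true PTR by construction);
`generate_sv_population` plants per-region Bernoulli deletion fractions over
log-normal background coverage.

## Numerical choices and degenerate inputs

Seeds are explicit everywhere; no function touches the caller's RNG state,
and fixed seeds reproduce results bit-for-bit (asserted in the tests).
Boundary handling is inclusive wherever the source says "at least"
(prevalence 10%, abundance 0.01%, deletion 25%/75%), with a 1e-9 tolerance
guard against floating-point rate arithmetic. Constant features and
covariates are skipped with warnings, not errors; collinearity beyond
|r| = 0.99 degrades to `AD`; all-zero count vectors give Chao1 = 0 with a
warning; an all-identical distance matrix makes PERMANOVA error rather than
return NaN. SparCC basis variances are floored at $10^{-10}$ before the
square root, and correlations clipped to $[-1, 1]$.

## Validation problem sizes

The test suite validates: oracle equivalence of the elementary statistics on
1,000 randomized instances each; null calibration on 100 seeded cohorts at
study scale (77 + 70 samples; 200 bacteria, 100 viruses, 50 metabolites) —
screen false-positive rate, PERMANOVA p uniformity at 199 permutations, and
pseudo-p uniformity on a 12-feature sub-table at 99 permutations (one fixed
pair per cohort, since pair p-values within a cohort are dependent);
parameter recovery for PTR (true 1.2–3.0, 100 bins, depth 200, 50 samples),
SparCC (planted 0.8 at D = 50, n = 200, 50 replicates), and mediation (200
replicates at n = 500 with interval-coverage checks); label recovery over 50
planted cohorts plus an exhaustive deletion-rate sweep in 0.01 steps; and
directional mediation over 50 forward and 50 reverse replicates at n = 300.
These sizes were chosen so the whole suite runs on a laptop in well under
half an hour while keeping the binomial uncertainty of every rate assertion
comfortably inside its acceptance band.

## Known limitations

The SparCC sparsity approximation degrades when many features are strongly
correlated; the nested-model labels assume linear covariate effects on the
rank-normal scale; mediation verdicts are model-based direction assessments,
not proof of causality (sequential ignorability is assumed, not tested);
PTR estimation requires a usable fraction of the genome at adequate depth
and a separation window that small plasmid-like replicons violate; and the
SV caller operates on bin coverage rather than read-level evidence.
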