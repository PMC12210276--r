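---
title: "Statistical methods in ocrstats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods in ocrstats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ocrstats` packages the statistical machinery of a case/control study of
chromatin accessibility in sorted brain nuclei, together with the
calcium-imaging statistics used to characterize neuronal modulation in the
companion behavioural experiments, and the gene-set overlap statistics used
to interpret both. Everything runs on synthetic data with planted ground
truth, so each stage can be validated without access to restricted human
data. This vignette explains the models, the tunable parameters, the
numerical choices, and what the simulations do and do not establish.

## The differential accessibility model

The unit of analysis is the OCR (open chromatin region): a called ATAC-seq
peak with an integer fragment count per sample. Samples are paired — each
subject contributes one neuronal and one non-neuronal library — and the
design crosses cell type with diagnosis.

### Filtering and normalization

Regions with essentially no signal are removed first: a region is kept iff
its counts-per-million (CPM) reach `cpm_threshold` (default 1) in at least
`ceiling(min_fraction * n_samples)` samples (default 10%). The ceiling makes
the "at least 10% of samples" rule exact for cohorts of any size; with 70
samples the cut is exactly 7. Filtering is idempotent.

Normalization is two-stage. First, TMM scaling factors (trimmed mean of
M-values, via `edgeR::calcNormFactors`) correct for composition differences:
M-values are doubly trimmed (30% per tail; 5% per tail on A-values),
combined with inverse-asymptotic-variance weights, and the factors are
rescaled to geometric mean 1. The reference sample is the one whose
75th-percentile CPM is closest to the mean of those percentiles — the
method's customary automatic choice. Second, log2 CPM values (computed with
TMM-adjusted effective library sizes and a damping prior count of 0.5) are
quantile normalized **within cell type**: neuronal and non-neuronal samples
have genuinely different accessibility distributions, and forcing them onto
a common distribution would erase the cell-type signal the model must
estimate. Ties in the quantile step receive the mean of their target
quantiles, which is deterministic; as a consequence, exact distribution
identity across samples holds on tie-free data, and only up to tie groups on
discrete counts.

Where the quantile step operates was a genuinely open choice (counts vs
log-CPM); we normalize log-CPM, because the downstream linear model consumes
log-CPM and quantile normalization of heavy-tailed raw counts is dominated
by the extreme tail.

### The covariate ledger

Candidate nuisance covariates (library QC metrics and similar sample-level
measurements) are screened with a per-region BIC comparison. For each
candidate, every region is fitted by OLS under the base design — the cell
type × diagnosis interaction (4 levels) plus sex — and under the base design
plus the candidate. The BIC is the Gaussian `n·ln(RSS/n) + k·ln(n)` with `k`
counting coefficients plus the variance; because the variance is counted in
both models it affects the comparison only through the RSS. A candidate is
admitted when at least `min_fraction` (default 5%) of regions improve by at
least `delta_bic` (default 4, the conventional "positive evidence" cut); a
sensitivity grid over `delta_bic ∈ {2, 4, 10}` × `min_fraction ∈ {2%, 5%}`
is available. The report also carries the improved-minus-worse "net" count;
inclusion follows the thresholded fraction, which is the sharper of the two
criteria. Numeric candidates are median-centered within cell type before
entering the ledger, mirroring how technical metrics are normalized to the
cell-type median. The ledger deliberately uses plain OLS without the subject
random intercept: it is a screening heuristic, not the inference model, and
the intercept affects both compared models nearly equally.

Degenerate candidates (collinear with the base design) add no rank; the
extended model then equals the base model, every improvement is zero, and
the candidate is excluded — no error surfaces to the caller.

### The weighted fit

The inference model per region is weighted least squares on the normalized
values with three variance components:

1. **Observation precision weights.** The square root of each region's
   residual SD is lowess-smoothed (span 0.5) against average abundance, the
   trend is evaluated at each fitted value, and weights are `trend^-4`. For
   count-derived log-CPM, variance falls with abundance, so low-abundance
   observations are down-weighted. This is the standard mean-variance
   modelling for normalized count data.
2. **Sample quality weights.** Each sample's relative residual variance is
   estimated as its mean squared standardized residual across regions;
   weights are the inverse, rescaled to geometric mean 1. A noisy library is
   down-weighted rather than discarded.
3. **Subject correlation.** The paired design induces correlation between a
   subject's two libraries. We estimate a per-region intra-subject residual
   correlation (mean within-subject residual cross-product over the mean
   squared residual), combine regions by the median on the atanh scale, and
   fit a generalized least squares model with this single consensus
   correlation shared across regions (via `limma::lmFit` with
   `block`/`correlation`). This is the standard practical treatment of a
   subject random intercept inside a weighted-LS framework; a full
   per-region mixed model is out of scope. The estimator carries a small
   downward bias of order p/n from fitting the fixed effects; at the
   cohort sizes simulated here it recovers a planted intra-class correlation
   of 0.5 within ±0.1.

The case/control contrast is tested within a cell type. Residual variances
are moderated by empirical Bayes (`limma::eBayes`) before the two-sided
t-test; with `moderate = FALSE` the fit reproduces ordinary OLS t-statistics
exactly (verified to 1e-9 against hand-computed OLS). Multiplicity is
controlled by Benjamini–Hochberg; the study convention is q < 0.05 for OCRs
and q < 0.1 for genes.

### Validation of the differential set

**Permutation.** Case/control labels are permuted at the *subject* level —
both libraries of a subject flip together, preserving the paired structure —
and the entire pipeline (weights, correlation, fit) is rerun per permutation
with identical settings (default n = 100). The report counts significant
regions per permuted dataset and an add-one empirical p,
`(1 + #{perm ≥ obs}) / (n_perm + 1)`, which can never be 0. Two numerical
details: the identity permutation is rejected whenever alternatives exist,
and "≥" between tied significant-region counts is resolved by the smallest
per-region p-value. The tie-break matters: under a global null almost every
dataset yields zero significant regions, and without a continuous secondary
statistic the empirical p would collapse to 1 rather than being uniform.
With it, the empirical p is uniform across independent null runs (checked by
KS). The observed p-value distribution is additionally summarized by its KS
distance from Uniform(0,1) and a QQ table — for a well-calibrated null test,
p-values should be uniform, which is how we operationalize "the p-value
ranking looks like noise".

**Classifier discrimination.** Six classifiers — naive Bayes, random forest,
nearest neighbour, logistic regression, and SVMs with linear and polynomial
kernels — are evaluated by stratified 5-fold cross-validation repeated 10
times, on (a) the differential-region features and (b) 10 draws of equally
sized random region sets. The readout is the per-classifier accuracy
improvement of (a) over (b); AUC is reported alongside. Because the
differential regions are selected on the full data, absolute accuracies are
optimistic (selection leakage); the delta against size-matched random sets
is the meaningful quantity, and the report says so explicitly. The CV engine
is implemented directly on top of the standard classifier packages (e1071,
randomForest, class, nnet) rather than through a meta-framework; folds are
stratified by class and seeded.

### Sample identity QC

Genetic sex is inferred by a majority vote of three binarized metrics:
chromosome-X heterozygosity outside the pseudoautosomal regions (computed on
variants with MAF ≥ 5%; near zero in males), summed CPM over female-marker
regions (XIST/FIRRE-like), and summed CPM over chrY non-PAR regions. The
binarization cutoffs default to a deterministic exact two-means split of
each metric across the cohort, because no numeric cutoffs are part of the
published procedure; they are overridable, and the split is only meaningful
when the cohort actually contains both sexes. A sample whose inferred sex
contradicts its annotation is flagged as an exclusion candidate. Sample
identity is checked by the fraction of concordant genotype calls between
libraries over common variants (MAF ≥ 25%); duplicate libraries score
≥ 0.99 while unrelated pairs concentrate near the random-match expectation
computed from allele frequencies. Kinship coefficients are deliberately not
reimplemented; concordance alone separates the two groups cleanly. PBC
(nonredundant / uniquely mapped reads) and FRiP (reads in peaks / total) are
provided as guarded ratios.

## Peri-event calcium statistics

Traces are dF/F at 10 Hz. Social-zone occupancy bouts separated by less than
2 s are merged before analysis. The modulation statistic per cell is the
mean over events of (mean activity in the 1–3 s post-entry window minus mean
activity in the pre-entry window). The pre window is the mirror image
(−3, −1) s of the stated post window — the published procedure says only
"before and after", so the symmetric choice is recorded here. Windows are
half-open on the right and discretized by round-half-up at the session rate.

The null distribution is built by circular permutation: per shuffle, one
uniform offset is added to *all* event times modulo the recording length
(inter-event structure preserved), and the statistic is recomputed. The
trace itself is never touched, so its autocorrelation is preserved exactly —
this is what makes the null valid for autocorrelated calcium signals, where
naive event-time shuffling without the circular structure would not be.
Offsets are drawn on the sample grid, and during null computation windows
wrap circularly so every shuffle retains all events; dropping
boundary-crossing events would shrink some null statistics' sample size and
bias the calibration. The bootstrap probability uses the add-one convention
`(1 + #{null ≥ obs})/(n_shuffles + 1)` (never exactly 0 or 1), with exact
ties counted at half weight so a degenerate constant trace sits
mid-distribution, and the
two-tailed rule at α = 0.05 labels a cell up-modulated if p < α/2,
down-modulated if p > 1 − α/2, and non-modulated otherwise. On null AR(1)
simulations the modulated fraction matches the nominal 5% within binomial
error; per-event baseline subtraction is not applied before averaging, as
the published procedure does not state it.

Supporting statistics: per-cell mean dF/F inside (and outside) the
interaction zone; pairwise Pearson correlation between cell traces
restricted to in-zone samples (zero-variance cells are reported and masked);
and the per-neuron difference in rescaled mean activity between paired
pre/post sessions, where each session is independently standardized to zero
mean and unit SD per cell (population SD, idempotent) so cells are compared
on a common scale.

## Gene-set statistics

Overlap between two gene sets in a universe is summarized by the 2×2 sample
odds ratio `ad/bc` (reported as infinite when `bc = 0` and `ad > 0`; no
Haldane correction) with a two-sided Fisher exact p — verified against
exhaustive hypergeometric enumeration. "Rescue" of a stress-responsive gene
is operationalized as: significant in the stress contrast (q < 0.1), and
significant in the intervention contrast with the opposite sign — expression
moved back toward control levels. Because the published wording does not pin
down whether significance in the rescue contrast is required, a
`sign_only` mode drops that requirement; the significant mode is the
default. Redundant gene sets are pruned by iteratively locating the pair
with the highest Jaccard index ≥ 0.5 and removing the smaller set
(lexicographically later name on ties, making the procedure deterministic),
until all pairwise indices fall below the threshold; the procedure is
idempotent.

## The simulators: what they emulate, and what they do not

The ATAC simulator draws negative-binomial counts with mean
`library_size × region_weight × 2^(design effects)` and a constant
dispersion (default 0.2). Region weights are log-normal so CPM filtering has
non-trivial behaviour; library sizes are uniform on a configurable range.
The default cohort mirrors the study's structure: 39 subjects (20 cases),
two cell types, paired libraries. A planted fraction of regions carries the
case/control effect in one cell type; sample-level covariates act
multiplicatively on a planted region subset; female-marker chrX regions are
depleted 8-fold in males and chrY regions ~30-fold in females, giving the
sex-inference metrics realistic bimodality. The genotype simulator fixes the
missing-call rate at 1%, draws MAFs in [0.05, 0.5] (so both the 5% and 25%
MAF filters retain variants), codes male chrX non-PAR calls hemizygously,
and lets duplicate pairs share ≥ 99.8% of calls.

The calcium simulator produces stationary AR(1) Gaussian traces with
marginal SD 1 (so transient amplitudes are in noise-SD units), default
coefficient 0.8 at 10 Hz. Modulated cells add exponentially decaying
transients at each event time; the decay constant defaults to 2 s, chosen
once as representative of slower calcium indicators and of sustained
bout-locked activity — a transient must persist into the 1–3 s analysis
window to be detectable by this statistic at all. Events keep a minimum
spacing of 6 s (twice the window reach) so peri-event windows never overlap,
a configuration the published procedure leaves unaddressed.

These simulators support calibration and recovery claims about the
*statistics*, not about real data: they contain no fragment-length or GC
structure, no motif-driven sequence composition, no spatially overlapping
cell footprints, no motion artifacts, and Gaussian rather than
spike-derived calcium noise. Passing tests establish that the
implementations compute their definitions correctly and are calibrated under
their stated noise models — not that the biological conclusions of any
particular dataset follow.

## Problem sizes and numerical conventions

The test suite exercises the pipeline at desk scale, as the package's own
choice of simulation size: cohorts of 8–30 subjects, 100–2,000 regions,
permutation validation with up to 100 permutations (39 in the 50-replicate
calibration study), 400-cell null sessions with 1,000 circular shuffles.
Key numerical conventions, gathered in one place: RSS floored at 1e-12 in
BIC computations (with a warning); TMM factors and sample weights normalized
to geometric mean 1; time-to-index conversion by round-half-up with
half-open windows; add-one conventions for all permutation p-values;
BH with monotonicity enforcement; all randomness seeded, with per-cell
shuffle seeds derived deterministically from the session seed, so every
pipeline output is byte-reproducible given its config.
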