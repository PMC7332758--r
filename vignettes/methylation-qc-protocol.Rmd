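---
title: "Cleaning and comparing blood and CSF methylation arrays: the methods behind methclean"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleaning and comparing blood and CSF methylation arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methclean)
```

# The problem

Epigenome-wide association studies (EWAS) on Illumina 450K-style arrays
stand or fall on data cleaning. The problems compound when a study spans
two tissues -- here venous blood and cerebrospinal fluid (CSF) drawn
longitudinally from patients after aneurysmal subarachnoid hemorrhage --
and when one of the tissues (CSF) has no published cell-type reference
methylome, so cell-mixture heterogeneity cannot be adjusted by
reference-based deconvolution. `methclean` implements the full protocol
as reusable, tested functions: sample-level quality control,
normalization, probe-level filtering, blood cell deconvolution,
surrogate-variable adjustment validated by a null EWAS, and the
cross-tissue concordance analysis that asks whether blood methylation
can stand in for CSF methylation.

Because the study's raw data are access-controlled, the package ships a
synthetic-data generator whose defaults emulate the study design. Every
stage of the pipeline is tested by parameter recovery against the
generator's ground truth.

# Data model

Intensities live in probe x sample matrices (`meth`, `unmeth`, `beads`)
bundled with a long table of control-probe intensities and a sample
sheet (`methylation_dataset()`). Methylation is summarized two ways:

* beta-values, `meth / (meth + unmeth + 100)` -- the fraction
  methylated, bounded in [0, 1). The offset of 100 is the conventional
  regularizer for low-intensity probes.
* M-values, `log2(beta / (1 - beta))` -- the variance-stabilized scale
  used for all statistics. Betas are clipped to `[1e-6, 1 - 1e-6]`
  first so fully (un)methylated probes stay finite. This logit2
  definition is the single M definition used everywhere downstream.

All tabular artifacts round-trip through plain text (TSV/CSV, optional
gzip), so a dataset can be regenerated, written, and re-read without
loss.

# Sample-level quality control

`sample_qc_report()` combines four failure modes, mirroring how failed
bisulfite conversion, hybridization dropout, and gross assay failure
present on real arrays:

* **Low bisulfite-conversion signal.** The mean intensity of the
  bisulfite-conversion control probes must not fall more than 3 SD
  below the across-sample mean (computed per tissue; pooling plates
  within tissue). Incomplete conversion depresses these controls
  specifically.
* **Poor detection.** Detection p-values model the probability that a
  probe's total signal arose from background. The background is normal,
  estimated per sample and channel from the negative-control probes;
  for Type II probes the two channels' means and SDs are summed, for
  Type I probes the single channel's background is doubled. A probe is
  inadequately detected at p > 0.01 or fewer than 3 beads; a sample
  fails when more than 1% of its probes are inadequately detected.
* **Total-intensity outliers.** A sample whose median log2 total
  intensity falls below the cohort median by more than 3 scaled MADs
  *and* by at least 0.5 log2 units is flagged. The absolute floor
  matters: in a technically tight cohort the MAD can shrink toward
  zero, and a sample within ~1.4x of the rest is not a failed assay.
* **Beta-distribution outliers.** Each sample's beta distribution is
  compared with the profile of per-probe median betas by the
  Kolmogorov-Smirnov distance; samples beyond 0.15 are flagged.

The intensity and beta outlier rules are explicit, configurable
stand-ins for unpublished internals of the array-QC tools used in
practice; their thresholds are all arguments. Tissue-level differences
in failure rates are tested with `tissue_failure_test()`, a two-sided
Fisher exact test on pass/fail counts.

# Normalization

`normalize_dataset()` chains three corrections:

1. **Background correction** by normal-exponential deconvolution, per
   sample and channel: the normal background component is estimated
   from negative controls, the exponential signal mean from the
   observed intensities, and each intensity is replaced by its positive
   posterior mean (computed by `limma::normexp.signal`). A provenance
   tag guards against double application: the deconvolution is not
   mathematically idempotent (a second pass would re-estimate a small
   positive background from the already-corrected negative controls),
   so a corrected dataset is returned unchanged.
2. **Dye-bias correction** by per-sample linear scaling of each channel
   so both channels' normalization-control means equal their grand
   mean. This simplified scaling (rather than a regression-based
   method) is exact for multiplicative dye imbalance and is
   mathematically idempotent.
3. **Functional normalization**, an extension of quantile
   normalization. Per probe stratum (Type I-green, I-red, II; meth and
   unmeth separately) each sample's 500 empirical quantiles are
   computed on the log2 scale; at each quantile level, the variation
   across samples explained by the first k = 2 principal components of
   the control-probe summaries is regressed out; each sample's
   intensities are then mapped through monotone interpolation between
   its raw and adjusted quantile curves (endpoints pinned, adjusted
   curves sorted to preserve monotonicity, hence within-stratum rank
   order). With k = 0 the procedure reduces to plain within-stratum
   quantile normalization. Control summaries -- mean log2 intensity per
   control type x channel, standardized -- are taken from the *raw*
   control intensities: background correction shrinks negative
   controls toward zero, where their log-intensities carry noise
   rather than signal and would rotate the control PCs.

The order raw -> background -> dye -> functional normalization is a
package decision (the protocol source does not state which intensities
feed functional normalization); it is configurable by calling the
stages individually.

Whether normalization helped is measured where it matters: technical
replicates. `replicate_concordance_test()` compares the squared
differences of replicate-pair median M-values before and after
normalization with a one-sided paired t-test (groups larger than two
contribute all unordered pairs, a choice needed because one CSF sample
recurs on every plate).

# Probe-level quality control

`filter_probes()` applies five sequential filters -- SNP-overlapping
probes, cross-reactive probes, sex-chromosome probes, probes with
multimodal beta distributions, and probes inadequately detected in more
than 1% of samples -- charging each probe to the first step that
removes it, so the per-step counts obey the bookkeeping identity
`retained_after = retained_before - filtered` (asserted on every run).
SNP overlap and cross-reactivity are annotation inputs, not computed:
the real lists are external resources, and the synthetic annotation
plants them.

Multimodality is detected by kernel density estimation (bandwidth 0.05
on the beta scale): a probe is flagged when at least two density modes
each hold at least 5% of samples, their peaks are separated by at least
0.2, and both peaks rise at least 2x above the valley between them. The
prominence requirement distinguishes genuinely separated modes (a
two-point mixture has an essentially empty valley) from the undulations
of one broad continuous distribution. Mode counting is unreliable below
a few dozen samples -- the function warns under 20 -- and small cohorts
(like a single 28-sample blood plate) will show some false positives;
the exact-recovery guarantees in the test suite are therefore asserted
on the CSF-sized cohort.

Cross-tissue differences in filter outcomes over the shared probe
universe are tested by McNemar's test with continuity correction.

# Cell-type deconvolution for blood

`estimate_cell_proportions()` projects each sample's betas onto the
reference profiles of six leukocyte types (CD4+ T, CD8+ T, NK,
monocytes, B cells, granulocytes) on the 100 most discriminating
reference probes (largest between-cell-type variance), solving the
quadratic program `min ||y - Xw||^2` subject to `w >= 0, sum(w) = 1`
with `quadprog`. The joint simplex constraint (rather than a
non-negative fit followed by renormalization) guarantees estimates on
the simplex by construction; the test suite checks the QP against a
0.01-resolution grid search over the simplex. A collinearity guard
rejects references that are not identifiable on the selected probes.

`flag_composition_outliers()` screens one cell type's fractions against
a median + 4 scaled-MAD fence -- the pattern by which an undiagnosed
chronic lymphocytic leukemia revealed itself as a gross B-cell excess
in the original cohort. Flagged subjects are excluded from downstream
analysis by the pipeline.

No deconvolution is attempted for CSF: no reference methylome exists
for post-hemorrhage CSF cell populations, which is precisely why the
protocol leans on surrogate variable analysis.

# Surrogate variables and the null EWAS

For CSF, repeated measures are first organized into cross-sectional
subsets centered on target days 1, 4, 7, 10, 13
(`csf_day_subsets()`): per subject and target, the exact-day sample is
preferred, then day minus one, then day plus one (minus-first is a
package decision; the source is silent), and no sample serves two
targets.

Within each subset (and for blood), the number of surrogate variables
is chosen by permutation parallel analysis
(`estimate_num_sv()`, Buja-Eyuboglu criterion, 20 permutations,
seeded); the variables themselves come from iteratively re-weighted
surrogate variable analysis conditional on the primary model
(`compute_surrogate_variables()`, wrapping `sva::sva`, 5 iterations,
columns orthonormalized). Conditioning on the phenotype is what keeps
the surrogate variables from absorbing trait-driven variation. Note
the permutation criterion carries roughly 10% per-component
false-positive mass at 20 permutations, so occasional off-by-one SV
counts on null data are expected behavior, not defects.

Whether the adjustment helps is judged under the null: a binary
DCI-like trait is randomly permuted (`permute_trait()`, class counts
preserved) and a per-CpG ordinary least-squares EWAS
(`run_ewas()`; M ~ trait + age + sex [+ SVs], two-sided t-test on the
trait coefficient) is run with and without the surrogate variables.
Calibration is summarized by the genomic inflation factor
`lambda = median(observed chi-square) / 0.4549364`
(`genomic_inflation()`). With unmodeled sample-level heterogeneity the
unadjusted lambda strays from 1 -- in either direction, depending on
how the realized permutation aligns with the latent factors; deflation
arises when cross-CpG correlation reduces the effective number of
independent tests -- while the SV-adjusted scan should sit near 1. The
test suite predicts the direction of the unadjusted deviation for each
seed from the generator's noiseless systematic component (closed-form
OLS on truth) and checks the observed sign against it, rather than
asserting a fixed direction that the null does not possess.

# Cross-tissue concordance

`extreme_beta_filter()` first drops CpGs at which *every* beta in
*both* tissues is above 0.90 or below 0.10: such sites have no
biological variation and would correlate (or fail to) for uninteresting
reasons. M-values are then adjusted for age, sex, and the subset's own
surrogate variables (`adjust_mvalues()`); covariates are centered and
their fitted effects removed while the probe-level mean is retained by
default, keeping adjusted values on the M scale -- within-CpG
correlations are unaffected by the per-probe constant, and
within-individual profile correlations remain meaningful (plain
residuals, orthogonal to the full design, are available via
`keep_intercept = FALSE`).

Two complementary summaries follow:

* `within_cpg_correlation()` -- Pearson r at each CpG across paired
  subjects (Spearman by flag). Correlation, not absolute difference, is
  the comparison of record because blood and CSF sit on different
  plates: r is invariant to the systematic shifts in mean and scale a
  plate batch induces.
* `within_individual_correlation()` -- Pearson r across CpGs for each
  subject's blood/CSF pair.

The two scales can legitimately disagree: tissues share most of the
probe-level methylation architecture, which dominates the
across-CpG (within-individual) correlation, while the within-CpG
correlation measures the coupling of individual deviations and can be
low at the same time. The generator reproduces this dissociation by
construction, and the test suite asserts it.

`stratified_comparison()` summarizes per-CpG r within CpG-island
regions (island / shore / shelf / open sea) and gene orientations, and
tests between-stratum differences with a Kruskal-Wallis omnibus test
plus pairwise two-sided Mann-Whitney tests under Bonferroni correction
-- a distribution-free choice, since per-CpG correlations are bounded
and skewed. NA correlations (zero-variance CpGs) are excluded and
counted.

# The synthetic study

`simulate_dataset()` (see `default_sim_config()` for every knob)
emulates the design features the pipeline's statistics rely on:

* **Cohort and design.** 24 subjects, each with one blood sample and
  longitudinal CSF targeted at days 1/4/7/10/13 with 85% per-day
  availability and occasional one-day substitutes. Samples are placed
  by `generate_plate_layout()`: 96-well plates of eight 6x2 chips, all
  of a subject's samples on one chip, trait cases and controls
  checkerboarded within chips by position parity, four
  fixed-methylation control samples (0/30/70/100%; two at fixed
  positions on every plate, two placed at seeded random) and four
  technical replicates per plate, with one CSF sample recurring as a
  replicate on every CSF plate.
* **Biology.** Per-tissue cell mixtures drawn from Dirichlet
  distributions over tissue-specific reference methylomes that share a
  bimodal baseline architecture (so within-individual cross-tissue
  correlation is high). CSF has no published cell-type reference; the
  generator's four CSF compartments (lymphocytes, monocytes,
  neutrophils, erythrocyte-lysis remnants) are a modeling choice, not
  literature values. Subject-level deviations on the M scale
  (SD 0.5) are coupled across tissues with region-dependent
  correlation targets (island 0.45 > shore 0.35 > shelf 0.20 >
  open sea 0.10, chosen so the overall mean lands near the low
  within-CpG concordance regime the protocol reports), and k = 3
  latent rank-1 factors (loading SD 0.4) provide the unmodeled
  heterogeneity that surrogate variable analysis exists to find.
* **Technical artifacts.** Batch effects enter as per-sample monotone
  intensity distortions `x -> T0 (x / T0)^gamma` with
  `log2(gamma)` summed from plate/chip/row/column terms, each drawn
  uniformly on bounded half-widths (0.14/0.20/0.10/0.05); the anchor
  T0 = 3000 sits at the typical probe intensity so the distortion
  reshapes quantiles and scales M-values without shifting the median
  total intensity. Dye imbalance multiplies the green channel by
  `2^d` and red by `2^-d`, d uniform on half-width 0.17. Both effects
  imprint on the control probes, which is what makes them removable by
  functional normalization but not by dye scaling alone. Channel noise
  is multiplicative log-normal (sigma 0.1) plus additive normal
  background (mean 150, SD 20 per channel). Bounded (uniform) rather
  than Gaussian draws control the worst case: technical variation is
  sized to dominate the sampling noise of a 2,000-probe median -- at
  this scale the median M of a bimodal distribution sits in a
  low-density valley and wobbles by ~0.07 between replicates from
  channel noise alone -- while staying inside the sample-QC outlier
  fences for clean samples.
* **Planted defects**, each constructed past its threshold with margin
  and recorded in the truth record: one sample per failure mode
  (bisulfite controls scaled to 0.25x; 5% of probes dropped to
  background with low bead counts; all probe intensities scaled to
  0.25x; betas replaced by a mid-range uniform), 20 multimodal probes
  (two beta modes at 0.15/0.85), 15 poorly detected probes (background
  signal and low beads in at least two samples of each tissue), and
  one blood sample with B-cell fraction 0.65. Defect classes are
  disjoint from each other and from the reference's discriminating
  probes so each is caught by exactly one mechanism.

The generator is fully deterministic given a seed, and returns the
truth record (cell fractions, batch and dye effects per sample, planted
defects, latent factor scores and loadings, the noiseless systematic M
matrix, and the references) alongside the dataset.

What the generator does *not* emulate -- and hence what green tests do
not establish about real data: the 485k-probe manifest and its
chromosomal coordinates, genotype (SNP) artifacts, sex-specific
methylation on X/Y, day-structured drift in CSF cell composition,
spatial within-chip gradients beyond row/column offsets, and any
departure of real CSF biology from the mixture-plus-factors model.
Passing recovery tests show the pipeline correctly inverts the
generative model it was pointed at, at desk scale; they cannot certify
performance on the access-controlled study data.

# Problem sizes and numerical choices

The default study is 2,000 probes by roughly 120 study samples (plus
controls and replicates), which runs the full pipeline in seconds; all
sizes are configuration. Statistical checks in the test suite choose
sizes where their quantities are stable: the replicate-concordance
check pools pairs from three generated studies (~39 pairs) because a
paired t-test on squared differences -- essentially scaled chi-square
draws -- is skew-limited with the ~13 pairs a two-plate design yields;
the null-EWAS calibration uses 4,000 probes and 60 subjects so the
median-based lambda has sampling SD well inside the +/-0.1 band and is
summarized by its median over five seeds.

Other numerical conventions: quantile type 7 with 500 anchors and
linear interpolation (endpoints pinned); adjusted quantile curves
sorted per sample to keep mappings monotone; KDE on [0, 1] with 256
evaluation points; QP solutions clipped at zero and renormalized to
absorb solver round-off (order 1e-12); EWAS fits via Cholesky-based
least squares with explicit rank checks that name collinear columns;
constant covariates (e.g., single-sex subsets) are dropped before
model construction; single seeds fan out to per-stage sub-seeds drawn
once, so stages are individually reproducible.

# Limitations

Beyond the generator's scope listed above: the detection p-value model
is the standard normal-background convention, not a replica of any
vendor tool; the multimodality and outlier rules are documented
stand-ins for unpublished internals and will disagree with other
implementations at the margin; deconvolution quality depends entirely
on the reference's discriminating probes; and the cross-sectional
day-subset treatment of CSF deliberately forgoes longitudinal
mixed-effects modeling, trading efficiency for the protocol's
simplicity.
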