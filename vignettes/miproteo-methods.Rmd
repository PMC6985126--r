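---
title: "Methods: microscaled proteogenomic analysis with miproteo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microscaled proteogenomic analysis with miproteo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

miproteo implements the downstream analysis of a microscaled proteogenomics
design: a small cohort of breast-cancer patients biopsied before and shortly
after starting anti-ERBB2 therapy, with each core profiled at the copy-number,
RNA, protein and phosphosite level, proteins quantified by TMT plexes that
share a pooled common-reference (CR) channel. Everything upstream of
quantification — spectral search, variant calling, segmentation — is out of
scope; the package starts from PSM tables, count matrices and segment tables.

# Quantification model

## Common-reference ratios

Within a plex, reporter-ion intensities are comparable across channels but not
across plexes. Dividing each channel by the CR channel of the same PSM removes
plex-level effects; rollup to a protein or phosphosite takes the **median of
linear-scale ratios over that feature's PSMs** and reports log2. The median is
taken on linear ratios and log2-transformed afterwards; the alternative
(median of log ratios) is identical because log2 is monotone — both orders are
covered by a regression test against the groupby-median oracle.

PSMs are excluded when they lack a TMT label, have precursor purity below 50%
(the boundary is inclusive: exactly 50% is retained), or a negative delta
forward-reverse score. Zero or missing intensities never produce infinities;
they become missing values, because a log-ratio of a zero intensity is
measurement failure, not evidence of infinite fold change.

## Per-sample normalization

Each sample (column) is median-centered and scaled by its median absolute
deviation with consistency constant 1.4826, so the scaled MAD estimates the SD
under normality. The operation is idempotent and rank-preserving per column; a
zero-MAD column is an error naming the sample rather than a silent division by
zero. RNA counts are upper-quartile normalized: zeros are treated as missing,
all-zero genes removed, each column divided by the 75th percentile of its
non-zero values, rescaled by a fixed constant (1000 — an arbitrary fixed scale
so normalized values are of convenient magnitude), and log2-transformed with
no pseudocount (zeros are already missing).

## QC gates

Cores require an average tumor content (mean over slide readings) of at least
50%; the exclusion rule is strictly "below 50%", so exactly 50 passes. TMT
plexes require partial labeling strictly above 99%, full labeling strictly
above 94%, and every channel's mixing deviation — `|median(channel/CR) − 1|` —
within 15%.

# Copy number

Gene-level copy number is the overlap-length-weighted mean of segment log2
ratios intersecting the gene model. The chromosome instability score weights
`|log2 r|` by segment length; by default the weights are normalized to the
chromosome's total segmented length. The normalization is a design choice the
upstream description leaves open: unnormalized sums grow with segmentation
granularity and chromosome size, so normalized scores are the cross-sample
comparable default, with `normalize = FALSE` exposing the raw
`Σ |log2 r| · L` variant. The genome-wide index sums the 22 autosomes only.
Coordinates are 1-based inclusive end-to-end (SEG convention), so file
round-trips are bit-exact.

# Outlier Z-scores

The reference distribution of each feature is estimated from the pre-treatment
cores of the pCR patients: mean, sample SD (n−1), variance and a Shapiro-Wilk
p-value. A feature is eligible when the variance is at least 1.5 **and**
Shapiro-Wilk does not reject normality at alpha = 0.05; removal on either
ground is the conservative reading of a grammatically ambiguous rule, and the
`filter` switch exposes variance-only and normality-only gating. Alpha = 0.05
is a default, not an upstream-stated value. Query Z-scores are
`(x − μ) / σ`; the query set must be disjoint from the reference set (a
leakage guard that tests may disable to verify the self-normalization
property: reference samples scored against their own reference have
per-feature mean 0 and SD 1).

Two practical consequences of a clustered reference panel deserve note. The
panel is 15 cores from 9 patients; replicate cores share patient-level
biology, so the Shapiro-Wilk gate — an alpha-level test under i.i.d.
normality — rejects well above its nominal level for features whose
patient-to-patient variance dominates core-level noise. This is a property of
the filter, not a bug: clustered cores genuinely violate its assumptions. The
test suite therefore measures spiked-outlier attainment (|Z| ≥ 2) among
replicates where the feature passes the gates and tracks the gate pass rate
separately, and the targeted ERBB2-locus interrogation (`ampliconProfiles()`)
computes Z-scores from the reference mean/SD regardless of eligibility:
eligibility protects genome-wide, hypothesis-free discovery from unstable
references, while the amplicon genes are interrogated by prior hypothesis.

Phosphoprotein-level analysis takes the mean of each protein's sites'
non-missing values before Z-scoring.

# Enrichment

The single-sample enrichment score walks the identifiers in descending score
order; in-set identifiers add `|score|^w` normalized over the set, out-of-set
identifiers subtract `1/(N − m)`. The reported ES is the area variant — the
sum of running-sum values divided by N — which is smoother than the maximum
deviation and is the variant used by the ssGSEA family this module emulates.
Defaults: weight `w = 0.75`, minimum overlap 5, identifier-permutation null
with 1000 permutations. NES divides ES by the mean |null ES| of matching
sign; the nominal p is the same-sign tail with a +1 continuity correction;
FDR is Benjamini-Hochberg across sets with a reporting flag at FDR < 0.25.
Numerical parity with any specific external ssGSEA release is not claimed;
the statistic is fully specified here and oracle-tested against a brute-force
running-sum evaluation. Degenerate edge: if every in-set score is exactly
zero with `w > 0`, members receive equal weights rather than 0/0.

Rankings for cohort-level enrichment use signed log10 p-values
(`sign · −log10 p`, p floored at 1e-15 so p = 0 stays finite), collapsed to
gene level by keeping the most significant feature per symbol; |score| ties
with opposite signs are broken by lexicographic feature identifier and
flagged, so results are deterministic.

PTM-signature enrichment keys sites by their ±7-amino-acid flanking windows
(15-mers, center = modified residue; only fully localized sites should be
supplied). Signature members may carry `;u`/`;d` suffixes; down-tagged
members have their site scores negated before ranking — the natural reading
of a bidirectional signature under a running-sum statistic. Negating member
scores moves the set to the other end of the ranking, so the ES changes sign;
its magnitude is not exactly preserved because the area statistic is not
antisymmetric under partial re-ranking.

# Treatment-response statistics

Replicate cores are averaged per patient and timepoint before paired
analysis. This replaces the duplicate-correlation approach used inside the
original linear-model fit: with at most triplicate cores, a per-patient mean
is simpler, transparent, and behaves equivalently at this scale (verified by
simulation in the test suite). Exact Wilcoxon tests enumerate the full null —
all 2^n sign patterns for the signed-rank statistic (by convolution), all
C(N, n_small) rank assignments for the rank-sum statistic — whenever the data
are tie-free and the enumeration is small; otherwise they fall back to the
mid-rank normal approximation with tie correction and continuity correction,
with a message. Zero paired differences are dropped (classical convention)
and counted. Two-sided p-values are twice the smaller tail, capped at 1,
matching the base-R convention so the implementations can be cross-checked
against `wilcox.test` exhaustively at small n.

The moderated-t analysis fits each feature to a linear model with one
coefficient per group-by-timepoint cell and per TMT plex (batch), then
shrinks residual variances toward a prior estimated by moment matching on the
log-variance distribution, exactly the empirical-Bayes scheme limma
implements; miproteo delegates to limma rather than re-deriving it, and the
surface exposes the prior df and prior variance. Rank-deficient designs are
an error naming the confounded coefficients, not a silent drop. The batch
coefficient absorbs any constant per-plex offset — a property the tests
assert directly.

Replicate-concordance clustering selects the k = 500 most-variable features
and clusters samples by average linkage on correlation distance (1 − Pearson
over pairwise-complete values). Metric and linkage are unstated upstream;
correlation distance with average linkage is the common choice for expression
profiles and is configurable. A replicate pair is "adjacent" when its
cophenetic distance is smaller than either member's distance to any
non-replicate.

# ERBB2 amplicon classification

A patient is **false ERBB2-positive** when the locus shows no copy-number
gain (log2 < 0.3) and ERBB2 protein sits below Z = −2 against the pCR
reference; **pseudo ERBB2-positive** when copy-number gain is present but
ERBB2 protein (or the mean of the flanking amplicon genes STARD3, PGAP3,
GRB7) is low; otherwise **true ERBB2-positive**. The thresholds
(`cnGainMin = 0.3` log2 units ≈ 1.23-fold; `zLow = −2` reference SDs) are
package defaults, documented and configurable — the original analysis
classified by inspection and group tests rather than printed cut-offs, so the
accuracy claim of this module is recovery of the synthetic generator's truth
labels, not reproduction of specific patients. Every comparison is recorded
in the call's evidence trail.

# The synthetic cohort: what it emulates and what it does not

`generateCohort()` produces the full study geometry: 14 patients (9 pCR),
pre-treatment cores for all, on-treatment cores for 10 (7 pCR / 3 non-pCR),
duplicate pre+on cores in four patients and a triplicate in one — 35 cores —
randomized into TMT 11-plexes with one pooled CR channel each; RNA for 11
patients; per-patient segment tables; GISTIC-style integer calls; slide-level
tumor content; a PSM table consistent with the protein matrix; and a citation
fixture. Every spiked effect is recorded in the truth labels, so recovery
tests never re-derive truth from data.

The generative model is deliberately minimal: per feature, sample value =
patient effect + copy-number dosage or spike effects + treatment effect +
per-plex batch residual + Gaussian noise (noiseSd = 0.45 log2 units;
per-gene patient-effect SDs are log-normal around ~1.1 so the variance
eligibility gate bites realistically). Key stated-world choices:

- **Amplicon dosage**: amplified patients draw a focal chr17 copy-number gain
  from a left-truncated normal (mean 1.5, SD 1.0, floor 0.6 log2 units —
  ERBB2 amplifications are large and right-skewed); protein tracks CN with
  coefficient 2 in true positives, giving the reference panel a dosage-driven
  spread whose hard lower bound keeps true positives away from the Z = −2
  boundary. Pseudo/false positives instead receive a −3 log2 protein shift.
  RNA tracks CN (coefficient 1) whenever the gain is present — pseudo
  positives are RNA-high but protein-low.
- **Treatment effects**: pCR patients suppress ERBB2 protein (and sites) by
  −1.2 log2 and mTOR-target phosphosites by −1.0 on treatment, scaled by a
  per-patient response multiplier ~N(1, 0.25); non-pCR patients show 15% of
  the effect. These magnitudes give the paired signed-rank test a clear
  signal at n = 7 while keeping the n = 7-vs-3 comparison realistically
  noisy.
- **Spiked outliers replace the patient effect** for the spiked feature
  (mucin overexpression IS that patient's biology, not an addition to random
  biology), so any spike of at least 3 feature-SDs yields |Z| ≥ 2 up to
  core-level noise. The mucin spike is +8 log2 across four panel genes whose
  patient-effect SD is 2.5.
- **mRNA-protein coupling**: RNA shares the protein patient effect; per-gene
  RNA noise is solved analytically so the per-gene Pearson correlation equals
  `2·sin(π·ρ_s/6)` for the target Spearman ρ_s = 0.38. Counts are
  Poisson-lognormal (Poisson draws around the latent log2 level at ~
  2^6.5-count depth) rather than negative-binomial: at this depth Poisson
  noise is negligible next to core-level lognormal noise, the correlation
  target stays analytically controlled, and no extra dispersion knob is
  needed. The correlation target is evaluated on one pre-treatment core per
  RNA patient (n = 11, independent across patients), mirroring the design's
  per-patient correlation; pooling all 31 RNA cores attenuates the median
  sample Spearman by a few hundredths through patient clustering, still
  within the ±0.05 contract.
- **PSM table**: channel intensities are 2^(matrix value) around a per-PSM
  base; the CR channel is the geometric mean of member channels, and sample
  channels are rescaled within each plex to a median CR ratio of ~1 —
  emulating the physical step of mixing channels to equal amounts after the
  mixing-ratio check. Label-state/purity/delta-score violations are drawn at
  configurable rates (defaults pass all QC gates).

What the generator does **not** emulate: missing-value structure driven by
abundance (missingness is only by design: zero-count genes, plex membership),
peptide-level interference and ratio compression, isotope-impurity effects,
correlated pathway co-regulation beyond the designated gene groups, subclonal
copy-number heterogeneity, and realistic gene-length/GC effects in RNA. A
green recovery test therefore establishes that the pipeline computes the
stated statistics correctly on data with the stated covariance structure — it
does not establish robustness to the artifacts listed above.

# Degenerate inputs and numerical conventions

- Ratios of non-positive intensities, features without PSMs in a plex, genes
  without overlapping segments: missing, never infinite.
- Zero-MAD samples, all-zero count columns, empty slide lists, empty gene
  panels, rank-deficient designs, reference/query leakage: errors naming the
  offending object.
- Identical group values in the Welch amplicon test: t = 0, p = 1.
- The exact-test enumerations require tie-free data; ties trigger the
  mid-rank normal approximation with a message, never a silent switch.
- All determinism contracts are seed-based; identical config + seed gives
  byte-identical bundles, and permutation nulls are reproducible under a
  fixed seed.

# Known limitations

- The moderated-t module performs complete-case, feature-wise fits; it does
  not model duplicate-core correlation (cores are averaged first) nor
  missing-not-at-random intensity dropout.
- Literature tallying is offline by design; a live query adapter would sit
  behind the same citation-record interface but is intentionally absent.
- Patient-level reproduction of the original cohort's classifications is not
  claimed anywhere: the deposited data are controlled-access, and the
  package's accuracy surface is synthetic-truth recovery plus the printed
  exact-test values.
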