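---
title: "Chromatin accessibility aging clocks: models, parameters and design choices"
author: "atacage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin accessibility aging clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`atacage` reimplements, as a tested and reusable pipeline, the analysis path
from per-sample ATAC-seq peak calls and fragment files to an epigenetic aging
clock: consensus open-chromatin-region (OCR) construction, Tn5 cut-site
quantification and quality control, genome-wide age-association statistics
with multi-omic integration, preranked gene set enrichment, an elastic-net
age predictor validated by age-balanced nested cross-validation, cell
composition and sex correction, and condition-effect testing on clock
output. Upstream read processing (trimming, alignment, deduplication, peak
calling) and RNA-seq preprocessing are out of scope: the pipeline consumes
peak calls, fragment BED files, and normalized expression/methylation
matrices.

Because the real blood-cohort data cannot ship with the package, a
first-class synthetic-cohort generator reproduces the statistical structure
the analysis relies on and carries full ground truth, so every stage is
validated by parameter recovery rather than by eyeballing.

# Consensus OCRs and annotation

Per-sample peak sets are merged into a union (book-ended intervals merged;
all coordinates BED-style 0-based half-open), and the union is filtered to
peaks that overlap, by at least one base, a region called as a peak in at
least `min_samples` samples (default 50, the threshold appropriate for a
cohort of ~150 samples). Peaks overlapping a blacklist are discarded. The
one-base overlap rule is a deliberate choice where a minimum overlap width
would also have been defensible; the per-base brute-force oracles in the
test suite pin the exact semantics.

OCRs are annotated as promoters when they intersect the closed window of
±1000 bp around a TSS (both window ends inclusive; an OCR qualifies on a
single base of intersection), as enhancers when they intersect any enhancer
region from a link resource, as both when both rules fire, and as
unannotated otherwise. Promoter-class OCRs are linked to the nearest gene by
the distance from OCR midpoint to TSS; ties break to the lexicographically
smallest gene symbol for determinism. Strand is carried but does not enter
the distance, since TSS positions are already strand-resolved upstream.

# Quantification and QC

Accessibility is quantified by Tn5 cut sites rather than whole fragments:
each fragment contributes its start and its last covered base (`end - 1`) as
two 1-bp insertion events, and an event increments an OCR when it falls
inside it. Fragment files are assumed Tn5-shift-corrected; `read_fragments()`
can apply the conventional (+4, −5) offset to raw fragments.

Counts are normalized to densities (counts per kbp of OCR) divided by the
sample's reads-in-peaks in millions, so the length-weighted sum of
normalized values is exactly 1e6 per sample — a conservation law asserted to
1e-6 relative tolerance in the tests. The log matrix uses a pseudocount of
1.0 on the normalized scale (configurable).

Sample QC fails samples with fewer than 11 million good alignments or FRIP
(fraction of cut sites in peaks) below 0.18; boundary values pass, since the
failure conditions are phrased strictly ("less than", "below"). A robust
elliptic envelope (minimum-covariance-determinant ellipse) on the first two
principal components of the log-normalized matrix (features centered, not
scaled) flags approximately a `contamination` fraction (default 0.10) of
samples as outliers: samples whose robust Mahalanobis distance exceeds the
empirical `(1 - contamination)` quantile. Degenerate score clouds flag
nothing, and the robust-covariance subsampling seed is a required argument
so runs are reproducible.

# Age-association statistics

Per feature, the Spearman rank correlation with age is computed with
average ranks for ties, a two-sided p-value from the t approximation, and
Benjamini–Hochberg q-values over all features of the modality. Features are
classed *opening* (r > 0, q < 0.01), *closing* (r < 0, q < 0.01) or
*stable*; constant features are flagged and forced to (r = 0, p = 1,
stable).

Annotation enrichment among opening/closing OCRs uses Fisher's exact test
(two-sided — the direction of the test is not obvious a priori) on the 2×2
table of class membership against annotation, with the background being all
OCRs outside the class; the reported odds ratio is the sample cross-product
ratio, flagged when infinite. Distribution shifts of expression age
correlations between linked-gene groups use a one-sided two-sample
Kolmogorov–Smirnov statistic with the asymptotic p-value
`exp(-2 n_eff D²)`; exact ECDF enumeration backs it in the tests.

Cross-modality integration correlates the per-feature age-correlation
vectors of two modalities over linked feature pairs (CpG→host OCR, OCR→gene,
CpG→gene); each link is one observation, so a gene linked to several CpGs
contributes several pairs, matching the pair-level scatter such analyses
display.

# Preranked GSEA

Gene scores come from a bespoke OCR→gene ranking: OCR–gene pairs without a
linked or expressed gene are dropped; when a gene has several OCRs, either
the pair with the largest |Spearman| correlation between accessibility and
expression over the samples shared by both assays is kept (`best_pair`), or
only promoter pairs are kept (`promoter_only`); the kept OCR's
accessibility–age Spearman correlation is the gene's score.

The enrichment score is the classic weighted Kolmogorov–Smirnov running sum
(hit steps `|s|^p / Σ_hits |s|^p` with p = 1 by default, miss steps
`1/(N - N_h)`), and significance comes from gene-label permutations (the
only scheme available to a preranked list): NES is the observed ES divided
by the mean |ES| of same-sign permutation scores, the nominal p the fraction
of same-sign null scores at least as extreme, and q-values BH across terms.
Ties in scores keep stable input order; callers with heavily tied scores
should jitter deterministically. Calibration is tested: over random gene
sets the mean |NES| must lie in [0.9, 1.1] at 1000 permutations.

# The elastic-net clock

The clock minimizes
`(1/2n)·Σ(y − ŷ)² + λ·(α·‖β‖₁ + (1−α)/2·‖β‖₂²)` with an unpenalized
intercept, on features standardized with training means and population
standard deviations (both stored in the model and reapplied at prediction).
The solver warm-starts from a `glmnet` regularization path — corrected for
glmnet's internal response standardization, which silently rescales the
ridge term — and finishes with an exact active-set solve of the stationarity
system, so the KKT conditions hold at 1e-6 (in practice machine precision)
and `α = 0` matches the ridge closed form. Zero-variance features are
dropped per training split with coefficient zero.

Cross-validation groups are built by sorting samples by age and dealing
consecutive blocks of `k` (default 11) round-robin with a seeded
within-block shuffle, so each group's ages cover the cohort range
approximately uniformly; the trailing partial block is dealt to a random
subset of groups. Nested leave-one-group-out CV selects `(λ, α)` per outer
fold by mean inner-fold RMSE over the default grids (20 log-spaced λ in
[1e-3, 1e2] on the standardized scale; α ∈ {0.1, 0.5, 0.9}); ties resolve
deterministically toward larger λ and smaller α. Metrics are RMSE, *median*
absolute error, and Pearson r, aggregated as mean ± sd over folds. The
honesty contract — corrupting a test group's ages cannot change its
predictions — is asserted directly.

Multi-omic clocks stack accessibility and expression matrices over shared
samples with `atac:`/`rna:`-prefixed feature ids; standardization inside
training brings both blocks to the same scale.

# Cell-composition and sex correction

Per feature, accessibility is regressed on intercept, age and the measured
cell fractions; only the composition component (fractions centered at
training means) is subtracted, so the age effect is preserved and test
samples are corrected with train-estimated coefficients — the form of the
correction that is honest inside cross-validation. Setting
`preserve_age = FALSE` removes shared age/composition variance along with
the covariates. Fractions enter as raw proportions (not logit-transformed).
Of the eight measured populations, the non-redundant subset {monocytes,
granulocytes, B, NK, CD4 T, CD8 T} is used by default because the derived
totals (T, lymphocytes) are linear combinations of it; rank-deficient
designs error naming the collinear columns. The inverse experiment — keeping
only the composition-explained component — is provided as
`composition_explained_matrix()`.

# Condition effects on clock output

Prediction errors (`delta = predicted − chronological`) are compared between
condition groups by a Welch t-test (the unequal-variance form, since the
pooled form's equal-variance assumption buys nothing here), and by an
age-adjusted linear model `delta ~ 1 + age + condition` whose condition
coefficient is the effect in years; the reference level is the
lexicographically first label, and non-overlapping group age ranges trigger
a confounding warning.

# The synthetic cohort generator

`generate_cohort()` draws, per seed-substream so layers can be regenerated
independently: ages uniform on 20–74; six base cell populations
(logistic-normal around PBMC-like baselines, with per-year latent slopes —
the NK slope calibrated so the NK–age Pearson correlation is ≈ 0.3 at
n = 150, and CD8 T declining); per-OCR, per-cell-type log-accessibility
profiles mixed by the *true* fractions; planted cell-intrinsic effects
(default 4% opening + 4% closing, strong/weak tiers of 0.25/0.10 log units
per age-sd, small Gaussian background on the rest); negative-binomial counts
(dispersion 0.05 — the standard overdispersed choice absent any published
count model) with log-normal reads-in-peaks around 3e5, giving OCR means
near 60 counts at the default 5000 OCRs.

Coupling is generated gene-first: each gene owns at most one promoter OCR
(1:1), its expression age-effect is correlated ρ_promoter = 0.32 with that
OCR's effect, enhancer OCRs couple to their linked gene's effect at
ρ_enhancer = 0.25, and CpG effects couple to their host OCR at −0.20
(enhancers) / −0.05 (promoters); methylation–expression coupling is then the
small product of the two paths, matching the near-zero value integration
analyses observe. These defaults are the observed pairwise correlations such
blood cohorts report; because both sides of a recovered
correlation-of-correlations carry estimation noise, recovered entries
attenuate by roughly 10–25% relative to the planted values at n = 150 — the
tests budget for this.

Measured cell fractions in the sample table carry flow-gating noise
(sd 0.01) on top of the true fractions; without it the six fractions sum
exactly to one and the correction design would be exactly collinear with the
intercept, which measured flow data never are. The condition label shifts
case samples' accessibility along the planted aging axis by
`condition_effect_years` worth of age-sd. A fragment-level generator
(`generate_fragments()`) emits per-sample fragment BEDs hitting a FRIP
target exactly (background fragments are placed in guaranteed OCR-free
inter-slot gaps) and per-sample peak calls with dropout and boundary jitter,
which feeds the consensus/counting path end to end.

What the generator does *not* emulate: sequence content and GC bias,
fragment-length periodicity, batch effects between protocols, non-linear
age trajectories, and realistic LD-like correlation among neighboring OCRs.
Passing tests therefore demonstrate the pipeline's internal correctness and
its behavior under the modeled structure, not performance on real cohorts.

# Problem sizes and numerical choices

The default desk-scale cohort is n = 150 samples × 5000 OCRs × 2000 genes ×
3000 CpGs, the size at which the full nested CV (11 × 10 leave-one-group-out
with the default grids) runs in well under a minute per clock. The
correction comparison uses a composition-noise-dominated scenario
(composition sd 1.0, cell-type profile sd 2.0, dispersion 0.1, 1% + 1%
planted effects of 0.15/0.08) in which composition variability genuinely
limits the uncorrected clock; in the default scenario the intrinsic signal
is strong enough that correction has nothing to remove, consistent with the
observation that correction matters exactly when composition noise is the
binding constraint.

Two numerical points deserve mention. First, the regularized clock's
response to a shift along the aging axis is attenuated by its calibration
slope (predicted-vs-true ≈ 0.9 at these settings), so a condition planted
as +5 years is recovered as ≈ 5 × slope by the age-adjusted model; the
module-level recovery test plants the effect directly in the deltas, and
the end-to-end test checks coverage of the slope-adjusted target. Second,
`glmnet`'s internal response standardization changes the effective ridge
penalty for unstandardized responses; the solver corrects the call
(`λ' = cλ`, `α' = α/c`, `c = α + (1−α)·sd(y)`) and then solves the
stationarity system exactly on the active set, with a cyclic
coordinate-descent fallback for pathological cases.

# Known limitations

Real-data headline numbers (nested-CV RMSE ≈ 7.3 years on ~143 blood
samples, external-set RMSE ≈ 19.7, the published opening/closing counts)
require the original cohorts and are deliberately not reproduced here. The
KS p-value is asymptotic and anticonservative for very small samples (the
tests use exact enumeration there). The preranked NES normalization follows
the canonical algorithm; implementations that normalize differently will
differ in the second decimal. The elliptic-envelope flag rule uses the
empirical distance quantile, so the flagged fraction is approximate at
small n.
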