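---
title: "Methods: uORF discovery and differential translational efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uORF discovery and differential translational efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, parameter choices and numerical
decisions behind `uorfte`. It states no empirical result beyond what the
package's tests and `scripts/acceptance.R` themselves compute.

## Coordinate and sequence conventions

All coordinates are 0-based, half-open, in transcript space, 5′→3′. Strand
resolution and P-site offsetting are assumed to have happened upstream: the
input tracks are per-position P-site counts on transcripts. Sequences are
held in the RNA alphabet internally (`T` is accepted on input and converted
to `U`). A transcript carries `utr5_len == cds_start` (the first nucleotide
of the mAUG) and `cds_end`, the half-open end of the stop codon.

## Upstream start sites

A USS is any AUG or near-cognate triplet (exactly one mismatch to AUG:
UUG/CUG/GUG at the first base, AAG/ACG/AGG at the second, AUC/AUA/AUU at the
third) starting fully inside the 5′-UTR. Its ORF extends to the first
in-frame stop codon lying wholly within the UTR; without one it is truncated
at the UTR end to whole codons, except when the start is in frame with the
mAUG and no stop intervenes — then the record is an N-terminal extension
(NTE) ending exactly at the mAUG. `n_codons` counts sense codons *including*
the start codon and *excluding* the stop; records shorter than 3 codons are
dropped (so a 2-sense-codon uORF is deliberately outside the pipeline's
scope, and `quantify_uorfs()` accepts arbitrary manual regions for such
cases). Multiple USSs sharing one stop are kept as distinct records. Several
USSs of one transcript can therefore overlap; none extends past the mAUG.

The −3 context rule classifies a start as `good` (A/G at −3) or `poor`
(U/C). Starts within 3 nt of the cap have no −3 base; they are classified
`poor` and flagged `kozak_truncated` — a conservative choice that affects
only cap-proximal starts.

## Detection and validation

Detection operates on the *combined* RPF track (all replicates and
conditions summed, as discovery should see every condition's evidence at
once; per-condition discovery is available by passing `sample_ids`).
The thresholds `r = 4`, `c = 15`, `z = 0.5`, `min_codons = 3` act on **raw
counts** — detection sensitivity therefore scales with sequencing depth by
design, and `c = 15` is equivalent to "more than 14 combined reads". The
`+1`/`−1` windows are codon-wide (3 nt); with fewer than 3 nt available
before the cap, `minus1` uses the available positions and the record is
flagged. A zero `minus1` enters the ratio as `max(minus1, 1)`, the most
permissive finite convention. The frame counts `n0, n1, n2` cover the body
*downstream of the start codon*, so the start-codon peak cannot dominate the
frame test.

Validation computes, over the full sense body, the frame-0 fraction f₀ and
the uniformity U = H / log(n_codons), H the Shannon entropy of per-codon
totals (0·log 0 = 0; a body with no reads scores (0, 0)). The translating
probability is a fixed two-feature logistic

$$P = \mathrm{logistic}(\beta_0 + \beta_1 f_0 + \beta_2 U), \qquad
(\beta_0, \beta_1, \beta_2) = (-6,\, 9,\, 3),$$

monotone in both features, with the coefficients anchored so that the
aperiodic-but-uniform point (f₀ = 1/3, U = 1) sits exactly at P = 0.5: a
signal with no frame preference can never pass the strict `P > 0.5` call.
This is a documented, testable decision surface, not a re-implementation of
any trained classifier; `fit_probability_coeffs()` can recalibrate β by
logistic regression when labeled data (e.g. simulation truth) are available.

## Quantification

Region density is `reads × 10⁶ / library size` (rpm). TE_uORF divides the
uORF's RPF density by the **mORF's** mRNA density, because the short uORF
window makes its own mRNA signal noisy; TE_mORF uses the CDS for both
assays. Descriptive TEs are computed per replicate (pairing RPF and RNA
libraries by condition and replicate) and then averaged within condition;
inference never uses these averages — it comes from the GLM below. The
relative ribosome occupancy RRO uses replicate-*summed* counts at the
reference condition (the combined-track convention), with bins
{<0.1, 0.1–0.5, >0.5}. Features with zero mORF mRNA density are excluded
with reason `zero_mrna` rather than producing infinities.

## The negative-binomial GLM

For each feature the counts across samples follow
NB(μ, α) with variance μ + αμ², and

$$\log \mu = \log(\text{size factor}) + \beta_{\text{assay}}
 + \beta_{\text{cond}} + \beta_{\text{assay:cond}},$$

with RNA and the reference condition as baselines, so the interaction is the
log TE fold change. Fitting is IRLS via `stats::glm` with the
`MASS::negative.binomial` family at fixed per-feature α (Poisson at α = 0);
standard errors come from the information at the fixed dispersion
(`summary(fit, dispersion = 1)` — the NB family already encodes the
variance, and letting `summary.glm` rescale by a 4-df Pearson estimate
destroys Wald calibration). Wald p = 2Φ(−|β̂/se|), BH-adjusted across tested
features. Features whose mean raw mRNA count across the condition pair's
four RNA samples is below 10 are `low_count` and never tested;
non-convergence marks `outlier`. There is no independent filtering, no
Cook's-distance outlier replacement and no LFC shrinkage — deliberate
simplifications, documented here.

Size factors are median-of-ratios, computed **within assay** (RPF and RNA
libraries have unrelated capture efficiencies); with no all-positive
feature the total-count ratio is used with a warning.

Dispersion is estimated in three steps. (1) A method-of-moments estimate
per feature, pooling (variance − mean) across design cells with df
weighting. (2) A mean–dispersion trend α(μ) = a₀ + a₁/μ fit by a Gamma GLM
with identity link — the moment estimates are strongly right-skewed at 4
residual df, and a robust linear fit would track their median and bias the
trend low. (3) Log-scale shrinkage
α̂ = exp(w·log α_mm + (1−w)·log α_tr) with
w = s²_prior / (s²_prior + s²_lik), where s²_lik = trigamma(df/2)
approximates the sampling variance of log α_mm and s²_prior is the excess
spread of log α_mm about the trend (floored at 0.25). Boundary estimates
(α_mm ≤ 0) carry no information and take the trend; estimates more than two
combined standard deviations above the trend are kept unshrunk (dispersion
outliers); and when df ≤ 8 the shrunk values are floored at the trend — at
two replicates per cell a below-trend moment estimate is not evidence of
genuinely low dispersion, and letting features fall below the trend makes
the Wald test anticonservative.

Regulation calls apply the dual criterion: activated iff ΔTE_uORF ≥ 2 and
Δrelative-TE ≥ 2 with q ≤ 0.1; repressed iff both ≤ 0.5 with q ≤ 0.1.
Δrelative-TE is the ratio of the two point estimates (no propagated CI) —
it acts as a fold filter only, and no FDR is required of the mORF test.
`select_extremes()` ranks by point estimate with ties broken by smaller p,
then feature id, making the TE_up/TE_down sets reproducible.

## Feature analyses

Positional features are pure transcript arithmetic (cap distance = start
position; mAUG distance = utr5_len − start). The context window is
−6..−1 and +4..+6 around the start codon (codon excluded); the published
context-adaptation scores do not come with a reproducible formula, so the
package uses a log-odds PWM against the uniform background,
Σ log₂(f(base, pos)/0.25), trained with pseudocount 1 on the mORF AUG
contexts of the top 2% of transcripts by a supplied ribosome-load metric
(in synthetic mode, mORF RPF density). This stand-in preserves the intended
ordering (similarity to the high-load consensus); `N` padding at truncated
windows contributes 0. Secondary-structure scores are accepted as an
ingested annotation column and never computed.

Spearman correlation is the Pearson correlation of mid-ranks with the
t-approximation p-value on n − 2 df; below n = 10 a seeded permutation test
(10⁴ permutations) replaces the approximation. Quadrants classify the fold
pair (low-T, high-T): Q1 repressed-then-activated, Q2 both up, Q3
activated-then-repressed, Q4 both down; folds exactly 1 are counted on the
activation side and flagged `on_axis` (a measure-zero event kept auditable).
Group summaries use type-7 quantiles and the notch half-width
1.58·IQR/√n.

## The synthetic-data generator

The generator *defines* the study conditions under which the package's
guarantees are tested: 2 biological replicates at three temperatures
(20/30/37, reference 30), NB dispersion α = 0.05, frame weights
(0.70, 0.20, 0.10), an 8-fold start-codon peak on the first codon of every
translated ORF (RPF only), 2×10⁶ expected mapped reads per library,
lognormal transcript abundance (median 0.5 expected RNA reads/nt/million),
UTR lengths 90–250 nt, CDS 100–300 codons, half the transcripts carrying
one planted uORF (4–12 codons, start codons drawn from a yeast-like usage
mix dominated by first-base NCCs), and untranslated RPF background at 2% of
the transcript's abundance with uniform frames. Decoy USSs arise at their
natural density in the random UTR sequence. Planted condition effects
default to ±2 log2 units on 20% of uORFs per non-reference temperature.
RNA counts are positionally uniform; RPF counts cycle the frame weights
from each ORF's start, so wiggle export and peak detection see realistic
tracks. Per-sample library sizes are reported as the *realized* totals of
simulated reads (the configured size sets expectations), which keeps
`library_size ≥ per-transcript sums` exact.

What the generator does **not** emulate: ligation/digestion biases, codon-
level pausing, overlapping transcription, alternative TSS isoforms, 3′-UTR
signal, and mapping artifacts. Passing tests therefore demonstrate
correctness of the algorithms under the stated generative model, not
robustness to every artifact of real libraries.

## Problem sizes and determinism

The shipped analyses use 200-transcript transcriptomes (~100 planted uORFs,
thousands of decoy USSs), 500-feature count matrices for calibration and
800 for parameter recovery — sizes chosen so each check completes in
seconds to a couple of minutes while leaving Monte-Carlo error well inside
the asserted margins. All randomness flows from explicit integer seeds;
`run_pipeline()` run twice with one seed produces byte-identical outputs,
which the acceptance script verifies.

## Known limitations

- Discovery thresholds act on raw counts, so sensitivity depends on depth;
  there is no depth normalization in detection (by design, documented).
- The translating probability is a fixed logistic, not a trained
  classifier; its coefficients encode the decision boundary described
  above and can be recalibrated on labeled data.
- The GLM supports exactly the assay×condition design; multi-factor
  extensions (batch, genotype) are out of scope.
- Δrelative-TE carries no uncertainty; a uORF with a noisy mORF estimate
  can be mis-sorted near the 2-fold boundary.
- uORFs extending past the mAUG out of frame are not enumerated (only NTEs
  reach the mAUG); the 5′-UTR isoform confound is addressed only
  diagnostically via `check_utr_isoform_confound()`.
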