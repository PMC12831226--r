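---
title: "Methods: trans-tissue methylation risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trans-tissue methylation risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the pipeline answers

Psychiatric disorders are brain disorders, but brain tissue can only be
assayed postmortem, while peripheral blood can be sampled from living
patients. A methylation risk score (MRS) aggregates many small case-control
methylation differences — each too weak to survive genome-wide multiple
testing on its own — into one per-person number. The trans-tissue question
is whether an MRS *trained* in one tissue (a discovery epigenome-wide
association study, EWAS, of diagnosis) carries diagnostic signal when
*evaluated* in the other tissue, in an independent cohort. `transmrs`
implements that experiment end to end, for real normalized array data or
for fully synthetic paired cohorts with known ground truth.

## The model, stage by stage

**Scales.** Methylation arrives as beta-values (methylated fraction,
`(0,1)`). All regression is done on M-values, `M = log2(beta/(1-beta))`,
which are variance-stabilized and unbounded; betas are clipped to
`[1e-6, 1-1e-6]` before the logit so the transform is finite. The clip
bound is configurable; round-trip error away from the boundary is below
1e-10.

**Quality control.** Measurements fail by detection p-value
(`> 0.01`) or bead count (`< 3`). A sample is dropped when more than 10% of
its probes fail either rule; a probe is dropped when more than 10% of
samples fail it. The 10% rules are *strict* inequalities — a probe failing
in exactly 2 of 20 samples survives, 3 of 20 does not — and this boundary
is pinned by tests. Samples are filtered before probes by default; the
order is configurable and recorded in the QC report, since the upstream
convention is not uniquely determined. Sex is predicted from the contrast
`mean(M on Y) - mean(M on X)` with a 2-means split (collapsed to one
cluster when the centers are closer than 1 M-unit); a sample is flagged at
10 cluster SDs or on predicted/recorded mismatch. This is a deliberate
simplification of array-specific sex predictors: it is identifiable,
testable, and sufficient for the mismatch-detection contract. Sex
chromosomes are then excluded from all analysis.

**Covariates.** Cell composition is estimated by constrained least squares
of each sample's beta vector on reference profiles (proportions
non-negative, summing to one exactly — an equality constraint, not an
inequality, because the estimates are interpreted as proportions). A cell
type enters the covariate set only when its proportions differ between
diagnostic groups (Mann-Whitney, p < 0.05); a neuronal fraction can be
admitted unconditionally for brain-style data. Principal components of the
centered beta matrix are screened against slide by one-way ANOVA (slide is
categorical, so "correlated with slide" is operationalized as ANOVA rather
than a correlation coefficient) and admitted at p < 0.05 among the first
`max_pcs` (default 10 in the module, 5 in the pipeline for speed at
simulation scale). Surrogate variables are the top left singular vectors of
the M-matrix residualized on the phenotype and known covariates; the count
is fixed or chosen by a permutation threshold (20 permutations, alpha
0.05). No specific published SVA algorithm is cloned: the contract is
latent-structure adjustment, and the residual-PCA construction is the
simplest implementation that satisfies it.

**Discovery EWAS.** Per CpG, ordinary least squares of M on
`[1, phenotype, covariates]`, with the homoskedastic two-sided t-test on
the phenotype coefficient. No moderated or robust variance is used: the
contract is plain linear regression, and a dual-route test checks five
random CpGs per run against stock `lm()` fits. Genome-wide significance
uses the strict threshold p < 9.0e-8 regardless of array size. Zero-variance
CpGs are reported as NA rows, never silently dropped.

**Score construction.** The discovery and target CpG universes are
intersected (the 450K array is essentially a subset of the EPIC array, so
one direction always loses sites). Correlated sites are pruned
co-methylation-style: an edge joins two CpGs on the same chromosome within
2 kb (inclusive) whose target-data Spearman correlation is at least 0.3 in
absolute value (inclusive, with a 1e-9 epsilon so exactly-rational boundary
correlations are not decided by floating-point rounding); connected
components are merged transitively, so a chain 1-2-3 merges even when sites
1 and 3 are more than 2 kb apart (a strict-pairwise mode exists behind a
flag); each component retains the single CpG with the smallest discovery
p-value, ties broken by position. The retention rule is a
polygenic-score-style clumping analogy — the upstream co-methylation
literature *aggregates* regions rather than picking representatives, and
the source analyses do not say which was done, so the rule is ours and is
stated here. Correlations are computed on cases and controls pooled.

The MRS of sample *i* at threshold `P_T` is
`S_i = sum over {j : p_j < P_T} effect_j * m_ij`, with `p_j <= 1` at the
final threshold so every site contributes. The seven thresholds are 0.001,
0.01, 0.05, 0.1, 0.2, 0.5, 1. `m_ij` is the target methylation on the
M scale by default — "methylation degree" is ambiguous between beta and M
in the source description, and M matches the scale on which the discovery
effects were estimated; a beta mode exists behind a flag. Missing target
values are mean-imputed with a logged count. Locus subsets keep (or drop)
sites within lead-SNP +-100 kb windows, inclusive bounds, 1-based
coordinates; BED input is converted from 0-based half-open with
`start + 1`.

**Association.** For each threshold, a covariate-only and a
covariate-plus-MRS logistic model are fitted by explicit IRLS on identical
samples. Variance explained is Nagelkerke's pseudo-R²,
`R2_N = (1 - exp((2/n)(ll0 - ll1))) / (1 - exp((2/n) ll0))`, and the
incremental ΔR² is the full-model value minus the covariate-only value.
Surrogate variables are not recomputed in the target model (the target
covariate list is age, sex, admitted cell fractions, slide PCs).

**Why the headline p-value is a score test.** The natural choice — the Wald
test on the MRS coefficient — fails in exactly the regimes this pipeline
produces. Under complete separation (an MRS that perfectly splits small
cohorts, which happens routinely when many shared causal sites are planted)
the Wald statistic is undefined; in near-separated fits that still converge,
the Wald p collapses toward 1 even as ΔR² approaches its maximum — the
Hauck-Donner effect; we observed p_Wald = 1.0 alongside ΔR² = 0.95 on a
default synthetic replicate. The Rao score test of the MRS term, computed
at the covariate-only fit, is well defined and calibrated in both regimes,
so it is the headline `p`; the Wald p is reported alongside (`p_wald`, NA
under separation) and separation is always flagged. A fit that exhausts
its iteration budget without converging is treated like separation.

## What the synthetic generator emulates — and what it does not

Per tissue, a sample's beta vector is built as: convex cell-type mixture of
reference profiles (Dirichlet proportions per sample, optionally with a
case-control concentration shift) → transformed to M → plus the case effect
at causal CpGs → plus confounder effects → plus per-slide per-probe batch
offsets → plus block-correlated noise → back to beta. Baselines are bimodal
(most probes near 0.1 or 0.9 methylation, as on real arrays). Co-methylated
blocks are consecutive CpGs sharing an equicorrelated Gaussian noise
component (`block_rho`, default 0.5 across 5 CpGs at 600-bp spacing, so
blocks span roughly 2 kb); the mean within-block Spearman correlation
tracks `block_rho` within +-0.15 at n >= 50. Detection p-values are
Uniform(0, 0.005) for good measurements and Uniform(0.01, 1) for planted
failures; bead counts are Poisson-shifted with planted low counts — both
chosen so the QC rules have decidable, known outcomes. Sex-chromosome
probes carry a clear male/female M contrast so sex prediction and the
planted-mislabel test are exercisable. Tissue A measures a random 70%
subset of tissue B's autosomal universe, forcing the intersection step.

**Causal structure.** The disorder has one causal CpG pool (fraction
`frac_causal` of the universe, default 2%), fully expressed in tissue B;
`cross_tissue_share` is the fraction of the pool *also expressed* in
tissue A, and tissue A has no private causal sites. This directional
semantics was chosen deliberately: with independent per-tissue causal sets,
a zero-sharing world is *not* a null for the trans-tissue test — random
discovery weights at the target's own causal sites create genuine
per-replicate association (the standard polygenic-score inflation under
zero cross-trait correlation but nonzero target heritability) and the
rejection rate sits far above alpha. Under the pool/expression semantics,
`cross_tissue_share = 0` genuinely removes all diagnosis signal from the
target tissue and the test is calibrated. Effects are planted on the M
scale (the analysis scale) with random signs and magnitude `effect_size_m`
(default 1.0); per-tissue magnitude overrides exist for
direction-asymmetry experiments. Default residual SD on the M scale is 0.5,
typical of array probe variability.

**Confounders.** Suicide (60% of cases, absent in controls), smoking
(45% vs 13%) and BMI mirror a postmortem psychiatric cohort; each drives
its own small causal CpG set shared across tissues. Note these are *true*
diagnosis-correlated signals: in a type-I-error study they must be disabled
(`trans_tissue_replicate(clean_null = TRUE)` does this), because
confounder-mediated trans-tissue association is real association, which is
precisely why the confounder-MRS control battery exists.

**What a green test does not establish.** The generator has no probe-type
chemistry, no control probes, no genuine IDAT-level noise, no genetic
(meQTL) structure, no age trends, and its co-methylation is block-local
rather than genome-realistic. Green acceptance tests establish that the
pipeline's statistics behave as designed under the stated generative
assumptions — not that the original cohort results would reproduce.

## The direction-asymmetry experiment

A real finding this pipeline is designed around: hippocampus-trained scores
separated blood cases from controls while blood-trained scores did nothing
in hippocampus. It is worth stating plainly that with one cohort per
tissue, the *expected* trans-tissue signal is the cross-product
`sum(w_A * w_B)` over shared sites — symmetric in direction. Strict one-way
signal is therefore impossible in expectation; asymmetry is a *power*
phenomenon. Two levers produce it: (i) the direction whose target tissue
carries strong causal sites benefits from those sites amplifying even noisy
discovery weights; (ii) large weights from a strong-effect discovery tissue
inflate the score noise in the weak-effect target. The packaged asymmetry
experiment uses the cleanest version: a causal pool expressed only in
tissue B (`cross_tissue_share = 0`, `frac_causal = 0.1`,
`effect_size_m = 2.5`, cohorts 40 and 63). Tissue-A-trained scores tested
in B then reject in roughly two-thirds of replicates while B-trained scores
tested in A stay at the nominal 5%. This world is intentionally much
stronger than the motivating data (which had zero genome-wide-significant
hippocampal DMPs); with realistically weak effects the direction contrast
has little power at these cohort sizes — a limitation, not a bug.

## Numerical choices

- Logistic IRLS: tolerance 1e-8 on coefficient change, 100 iterations;
  divergence guard at `|eta| > 30` (fitted probabilities within 1e-13 of
  0/1, unreachable without separability); slow quasi-separation flagged
  when the fit classifies perfectly with `|eta| > 10` at iteration
  exhaustion.
- Deconvolution: equality-constrained least squares via a small active-set
  loop (clamp negative coordinates, re-solve on the support), with a ridge
  fallback for singular supports. Checked against exact mixtures to 1e-6.
- Mann-Whitney: normal approximation with tie-corrected variance and a 0.5
  continuity correction; z is signed so larger case-group values are
  positive. Within 0.02 of the exact permutation p at 8 per group.
- Pearson chi-squared on 2x2 tables uses no continuity correction — this is
  the variant that reproduces all five printed cohort-table statistics to
  one decimal (Yates-corrected values do not).
- Pruning representative ties (equal discovery p) break by smaller
  position; pruning is invariant to input order.
- EWAS listwise-deletes samples missing the phenotype or a covariate and
  records n per CpG.

## Known limitations

- No Firth penalization: separation is flagged and score-tested, never
  "fixed".
- No DMR calling, no meQTL/LD-aware clumping, no cross-platform liftover
  beyond exact id matching, no IDAT parsing or functional normalization —
  inputs are assumed normalized.
- Confounder-phenotype EWASs adjust for diagnosis by default (the source
  analyses do not say whether they did); a flag disables it, and the model
  descriptor records the choice.
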