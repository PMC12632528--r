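---
title: "Models and methods: perturbation phosphoproteomics with phosphodia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: perturbation phosphoproteomics with phosphodia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphodia)
```

# The analysis problem

Stimulating primary immune cells with a cytokine such as IFN-β triggers two
responses on very different clocks: phosphorylation of pathway components
(e.g. STAT tyrosine sites) within minutes, and induction of
interferon-stimulated proteins over hours. Layering genetic perturbations —
CRISPR knockouts of pathway genes, or base edits that remove a single
phosphosite — over the stimulation turns descriptive profiling into causal
pathway mapping: a perturbation that abolishes the downstream protein
signature identifies a required node.

`phosphodia` implements the statistical workflow for such screens on DIA
(data-independent acquisition) proteomics data, from the search engine's
long-format report to kinase-activity and signature-level conclusions. This
vignette documents the models, the defaults and why they are set where they
are, the behaviour of every stage on degenerate input, and what the
simulation-based validation does and does not establish.

# Input contracts

**Long report.** One row per quantified precursor: sample, protein group,
modified sequence, site key (`PROTEIN_[STY]POS`, 1-based), localization
probability in [0, 1], positive intensity. Spectronaut-style headers
(`PG.ProteinGroups`, `EG.ModifiedSequence`, `EG.PTMAssayProbability`,
`R.FileName`, `FG.Quantity`) are accepted via an alias table covering common
v18–v20 exports. Rows with non-numeric or non-positive intensities are
dropped with a reported count; empty fields and `NaN` both read as missing,
and missing is never encoded as zero.

**Design manifest.** One row per sample: genotype, donor, replicate,
treatment, dose, timepoint (minutes), assay, cell type, optional cell input.
The *condition* — the unit of replication throughout the package — is the
tuple (genotype, treatment, dose, timepoint, cell type). Every treated
condition must have a vehicle condition matched on genotype, timepoint,
donor and cell type; `validate_design()` reports violations without
throwing, so a manifest can be audited before anything is computed.

# Preprocessing

**Site collapse.** Multiple precursors covering one site in one sample are
collapsed to the maximum intensity and the maximum localization
probability. Both rules are order-independent and idempotent. (Search
engines apply a comparable collapse internally; the exact aggregate they use
is not standardized, and max-intensity is the common convention.)

**Class-I filter.** Sites are retained when localization probability is
*strictly* greater than 0.75. The strictness is deliberate and documented
because many tools use `>=`; at the usual probability resolution the
difference is cosmetic, but the boundary case `p = 0.75` is dropped here.

**Replicate-presence filter.** A feature is kept if at least one condition
quantifies it in at least k of that condition's n replicates — 3 of 4 by
default, 2 of 3 for macrophage-style triplicate designs, or a fraction
applied as `ceiling(f·n)` per condition. The output is always a row subset
of the input and refiltering is a no-op.

**Normalization.** Intensities are log2-transformed and each sample column
is shifted so the median of its observed values is zero. Median centering is
idempotent and leaves missing entries untouched; all-missing columns are
left unchanged with a warning.

**QC.** Enrichment purity is the *count* fraction of phospho precursors
among all precursors per sample (an identification-based readout, not
intensity-weighted). CVs are computed on linear-scale replicate intensities
— the CV of log-scale values is not scale-free, whereas linear-scale CV is
invariant to multiplying a condition by any constant, which the test suite
asserts. Replicate correlations are Pearson on log2 values over mutually
observed features. Input linearity (per-feature Pearson r of linear
intensity against cell input) is computed only for features observed at
three or more input levels, and only when the design carries `cell_input`.

# Missing-value model and imputation

Missingness in DIA phosphoproteomics mixes two mechanisms, and imputing with
the wrong one distorts fold changes. The package separates them with the
block rule standard in proteomics practice:

* a gap inside a **partially observed** condition block is *missing at
  random* (MAR) — the peptide was detectable in that condition, so the gap
  is stochastic;
* a block that is **missing in its entirety** (while the feature is observed
  elsewhere) is *missing not at random* (MNAR) — the feature sat below the
  detection limit in that condition.

MAR gaps are filled by profile information:

* **k-NN** (global proteomics; default k = 10): neighbours are features
  ranked by root-mean-square distance over mutually observed samples;
  candidates must share at least 3 observed samples and be observed in the
  gap's sample; the imputed value is the neighbours' mean there. With fewer
  than k eligible neighbours all available are used with a warning; with
  none, the gap is left for the downshift fallback.
* **SLSA-style replicate imputation** (phosphoproteomics): the gap is the
  feature's observed replicate mean in that condition plus a sample offset —
  the median, over fully observed features, of (value in the sample − mean
  of its other replicates). The method is deterministic. The downstream
  literature names this method without printing formulas; the definition
  above is this package's fixed, testable interpretation, chosen because it
  is exactly recoverable in simulation (a sample shifted by +0.5 on
  observed features is imputed at replicate mean + 0.5).

MNAR gaps are filled by **downshift sampling**: draws from
`Normal(μ − shift·σ, (width·σ)²)` per sample column with `shift = 1.8`,
`width = 0.3` (the field's customary defaults; the source workflows do not
print theirs). Columns with fewer than two observed values fall back to the
global mean and SD with a warning. Draws are deterministic given the seed.

`impute_mixed()` chains classification, the matched MAR method, and
downshift for MNAR plus any MAR leftovers, and guarantees a complete matrix
for features that passed the replicate filter. Observed entries are
bit-identical before and after every imputation — asserted in the tests.

# Differential statistics

**Donor centering** subtracts each donor's per-feature mean, removing
additive donor batch effects exactly while preserving every within-donor
treated-minus-vehicle contrast to machine precision (single-donor designs
pass through unchanged).

**Fold changes** are `mean(log2 treated) − mean(log2 time-matched vehicle)`
per condition; a treated condition without its matched vehicle is an error
naming the condition, not a silent skip.

**Student's t** is the two-sided pooled-variance test (not Welch). Zero
pooled variance with equal means returns t = 0, p = 1; with unequal means it
returns infinite t, p = 0 and a degenerate flag, so downstream code can
distinguish "no evidence" from "no variance".

**Moderated t** shrinks per-feature variances toward a prior. With
per-feature pooled variance s²_g on d_g degrees of freedom, the prior
(d₀, s₀²) is estimated by method of moments on e_g = log s²_g −
ψ(d_g/2) + log(d_g/2), whose excess variance over trigamma(d_g/2) equals
trigamma(d₀/2); the trigamma inversion is a Newton iteration. The posterior
variance is s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g) and t̃_g is referred to a
t distribution on d₀ + d_g degrees of freedom. When the observed spread of
log variances does not exceed its sampling expectation, d₀ = ∞ and every
feature uses s₀² with normal tails. The limits are exact: `prior_df = 0`
reproduces Student's t to 1e-10 and `prior_df = Inf` uses s₀² exactly. The
implementation is cross-checked in the test suite against `limma`'s
empirical-Bayes machinery (prior, statistics and p-values agree to 1e-6 or
better) without depending on it.

**Multiple testing** is Benjamini–Hochberg, applied *within* each comparison
(each volcano panel), not pooled across comparisons. Model fits are per
timepoint contrast; no single model is fit across timepoints — the
time-course structure enters only through the time-matched vehicle pairing.
"Upregulated" throughout the package means adj. p < 0.05 **and**
log2FC > 0.75, both strict.

# Kinase-activity inference

KSEA uses the mean-based z form against the whole-dataset background:
`z = (mean(FC_S) − mean(FC_all))·√m / sd(FC_all)` for a kinase with m ≥ 3
quantified substrates. The published KSEA lineage contains several variants
(mean-z vs delta-count); the mean-z variant is fixed here as the contract.
Properties asserted numerically: z is invariant to shifting all fold changes
by a constant and to scaling them by any positive factor; z = 0 when
substrates match the background mean; the sign of z matches the sign of the
simulated kinase effect. Substrate sites stay in the background — removing
them changes z by under 5% when substrates are under 1% of sites, which the
tests check. Kinases under the substrate minimum are reported as not
quantifiable rather than given unstable scores. Matching is exact on site
keys; isoform or position offsets are out of scope.

# Signature derivation and perturbation scoring

The stimulation signature is empirical: features upregulated (thresholds
above) in **every** control comparison supplied — by construction monotone
in the thresholds. Because protein induction starts hours after stimulation
while substrate phosphorylation is immediate, the meaningful control
comparisons for a protein-level signature are the late-timepoint ones;
passing all of a multi-timepoint design's control comparisons instead
selects the fast responders. `run_pipeline()` derives a signature over all
control comparisons for completeness, and the function-level API
(`derive_signature()` on any subset of comparisons) is the intended route
for timepoint-resolved signatures, as the README example shows.

Scoring a perturbation counts members still significant at the signature's
own thresholds and summarizes the density shift (mean member vs non-member
fold change). Member classification uses two ratio cutoffs: *abolished* =
not significant and FC below 0.25× the control's; *retained* = significant
and FC at least 0.75× the control's; *attenuated* otherwise. The 0.25/0.75
ratios are package defaults exposed as arguments — the underlying
grey/red partitions in the screening literature are drawn without printed
rules, so these are declared interpretations, not reproductions.
Perturbation-vs-perturbation comparison reports Pearson r, OLS slope and
intercept (regression with intercept, B on A), and the Jaccard index of the
two significant-member sets; r and Jaccard are symmetric and
slope(A,B)·slope(B,A) = r² ≤ 1.

# The synthetic-data generator

`simulate_dataset()` draws linear-scale intensities
`2^(baseline + treated·effect·ablation + donor + noise)`:

| parameter | default | rationale |
|---|---|---|
| baseline log2 intensity | Normal(20, 2) | typical DIA precursor dynamic range |
| induced-protein effect | 2 (log2) | strong but realistic induction |
| kinase substrate effect | 1.5 (log2) | phospho-level stimulation response |
| induction onset | 240 min | proteins induced from hours; kinase effects at all treated timepoints — reproduces the fast-phospho / slow-abundance separation |
| donor effect | Normal(0, 0.5) per donor × feature | additive, constant within donor, hence exactly removable by donor centering |
| residual noise | Normal(0, 0.5) | replicate-level scatter |
| ablation multiplier | per genotype in [0, 1] | 0 = full pathway knockout, 1 = no effect |
| localization probabilities | Beta(9, 1) confident, Beta(2, 2) ambiguous, 20% ambiguous | only the > 0.75 cut matters downstream; the Beta forms give a realistic mix of clear and borderline sites |
| MAR rate | 0.05 | sporadic uniform dropout |
| MNAR detection curve | logistic, midpoint 16, slope 3 | limit of detection two baseline SDs below the mean |

MNAR dropout, when a design is supplied, is decided once per (feature,
condition) block from the logistic detection probability at the block-mean
log2 intensity, dropping the whole replicate block together. This is the
deliberate generative picture of limit-of-detection censoring in DIA:
whether a peptide is detectable in a condition is a property of its
abundance in that condition, so replicate dropout is strongly correlated —
and it is exactly the structure the MAR/MNAR block classifier assumes, which
makes mechanism labels recoverable (classification accuracy is ~1.0 in the
acceptance runs). Without a design, entries drop independently, and the
marginal dropout probability is the same decreasing logistic either way.
Under these defaults roughly 7% of entries go missing, about a third of them
MNAR.

**What the generator does not emulate** — and therefore what passing tests
do *not* establish about real data: inter-feature correlation beyond shared
effects (real proteomes are heavily co-regulated, which helps k-NN),
intensity-dependent noise, peptide-level digestion and ionization
variability, retention-time or mobility artefacts, compositional effects of
normalization, isoform ambiguity in protein inference, and heavy lower
abundance tails. The last point matters for interpreting the imputation
benchmark: with Gaussian baselines censored two SDs below the mean, the true
values behind MNAR gaps concentrate just below the detection midpoint, so
neighbour-based imputation — scored only on the gaps it can fill, i.e.
features observed well elsewhere — attains slightly lower MNAR error than
downshift sampling in this simulator, while downshift is the only method
that covers the deeply censored features at all (several hundred gaps per
run have no eligible neighbours). The decisive, robust result is the
matched-vs-mismatched contrast: routing MAR gaps to downshift inflates their
RMSE about five-fold (≈3.6 vs ≈0.8 on defaults), so mechanism-matched
imputation beats the swapped assignment in every seed.

# Validation problem sizes and numerical choices

The simulation-backed checks run at sizes chosen for a laptop-class single
core while leaving comfortable statistical margins: 500–2,000 features,
4 replicates, 8–80 samples, and 20 seeds for every stochastic claim.
Specific settings worth recording:

* Moderated-t prior recovery uses 200 features with a true scaled
  inverse-chi-square prior (d₀ = 8, s₀² = 0.25, d_g = 6); median relative
  errors are well inside 25%.
* KSEA recovery plants 5 active kinases (effect 1.5) among 50 with
  10 substrates each in 1,500 sites at noise 0.5; all five rank top-5 by |z|
  in 20/20 seeds.
* Signature recovery uses three scrambled control arms (effect 2, noise 0.5,
  n = 4, 40 induced of 400 proteins): mean recall ≈ 0.97 with zero false
  members, and a full-ablation knockout scores 0 significant members.
* The Student-vs-moderated rank-agreement property is asserted at
  10 replicates, where per-feature variances are well estimated and the two
  engines converge (Spearman ≈ 0.995); at n = 4 the Student ranking is
  dominated by variance sampling noise and agreement is ~0.97–0.98 — a
  property of the statistics, not of any implementation.
* BH adjustment is compared to a brute-force step-up with tolerance zero on
  1,000 random vectors; the oracle evaluates `n/i·p` in the same IEEE
  ordering so "exact" means bit-exact.
* All pipeline outputs are written with fixed row orderings (feature, then
  sample, lexicographic), so a rerun with the same configuration and seed is
  byte-identical — checked via file checksums.

# Known limitations

* The SLSA definition is this package's interpretation of a named method
  (see above); results labelled SLSA elsewhere may differ in detail.
* Substrate annotation matching is exact on `PROTEIN_[STY]POS`; no attempt
  is made to reconcile isoforms or position offsets between annotation
  sources and search-engine output.
* The pipeline's built-in signature derivation intersects all control
  comparisons; timepoint-resolved signatures should be derived through the
  function API.
* Downshift imputation is per sample column; a global variant (one μ, σ for
  the whole matrix) is available only as the degenerate fallback for
  near-empty columns.
* GO / transcription-factor enrichment on signature members is out of scope;
  the member lists are exported for use with external annotation tools.
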