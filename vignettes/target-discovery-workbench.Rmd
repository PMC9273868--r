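---
title: "Methods: multi-cohort ALS target prioritization and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort ALS target prioritization and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alstargets)
```

# The analysis this package implements

Amyotrophic lateral sclerosis (ALS) target-discovery studies of the
AI-platform style combine several distinct computations: differential
expression across many small case-control cohorts, pooling of those cohorts
into subtype- and modality-specific meta-analysis groups, ranking of genes
by aggregated evidence scores, a druggability filter cascade with a top-50
cut, retrospective ("time machine") validation of any ranking against a
clinical-trial chronology, pathway-level dysregulation calling with
process enrichment and similarity networks, and finally in-vivo triage of
candidates in a *Drosophila* c9ALS modifier screen. This package implements
each of those stages as plain, testable functions, together with a
synthetic study generator that plants known truth so every stage can be
checked end to end without any external data. The packaged fixtures
transcribe the source study's three summary tables (comparison inventory,
candidate list, screen results), and the `analysis/` scripts walk the whole
pipeline on a synthetic study with the same layout: 12 CNS case-control
comparisons (5 familial, 7 sporadic) and 4 iPSC-derived motor-neuron (diMN)
comparisons (transcriptomic and proteomic, per subtype).

# The synthetic study generator

The generator is the package's model of what the analysis assumes about the
data, not of everything real cohorts do.

**Signal model.** Expression is simulated directly on the log2 scale:
per-gene baselines are `N(8, 1.5^2)` shared across comparisons, and each
sample adds independent Gaussian noise (`noise_sd`, default 0.5 for
transcriptomic and 0.7 for proteomic matrices — proteome quantification is
noisier, but the analysis treats both modalities identically downstream).
A planted target adds `direction x effect_size` log2 units to the case arm
of each comparison it penetrates; `penetrance` is the probability that a
comparison carries the effect, drawn once per target. A planted pathway
shifts all of its member genes coherently by `direction x magnitude` in the
case arms of every comparison, which is exactly the signal shape the
activation scorer integrates.

**Pathway collection.** Pathways are gene sets assigned cyclically to 27
top-level processes (Reactome-style labels shipped as a text fixture). Each
process owns a disjoint pool of the universe; a pathway draws about 80% of
its members from its pool, and with probability 0.5 a later pathway of a
process is a "sibling" keeping ~70% of an earlier one's genes. The sibling
structure matters: similarity networks over gene sets get their clusters
from nested, heavily overlapping sets, and collections of independent
random subsets of a 2000-gene universe essentially never exceed a Jaccard
coefficient of 0.35.

**What the generator does not emulate:** batch and platform effects,
count-based sampling noise, correlated genes within a comparison beyond the
planted structure, missingness in proteomic panels, and any relationship
between the chronology and the expression data (trial years are drawn
independently). Passing recovery tests therefore show that the pipeline's
logic is correct under its own assumptions — not that the statistical power
claims transfer to real cohorts.

# Differential effects

`compute_effects()` reports, per gene, the log2 fold change (case mean
minus control mean, both arms already on log2 scale) and a two-sided
Welch's t-test p-value. The choice is deliberately assumption-light; no
moderation or count model is used, and the test sits behind a single
function so it can be replaced. Raw p-values are reported — the candidate
tables downstream print raw per-comparison p-values, some above 0.05, so a
multiplicity correction at this stage would change the published
bookkeeping. Genes with zero variance in both arms get `p = 1` and the fold
change as computed, so constant genes can never surface as findings.
Degenerate designs (fewer than two samples in an arm) are an error, not a
warning.

# Consistency, scores, and the filter cascade

**Directional consistency** is the share of a group's comparisons with
strictly positive (up) or strictly negative (down) fold change; an lfc of
exactly 0 counts toward neither. Percentages are rounded half-up to whole
percent (`floor(x + 0.5)`), which is required to reproduce the published
quantization: 6 of 7 comparisons is 85.71%, printed as 86%. The ≥80% CNS
candidate gate is evaluated on the rounded value for the same reason.

**Omics evidence.** Each comparison contributes `sign(lfc) * -log10(p)` per
gene; the group's omics score is the magnitude of the mean contribution,
with the net sign reported separately. Signing before averaging makes
direction-inconsistent evidence cancel; taking the magnitude afterwards
makes the score an association strength, so consistently *down*-regulated
genes rank as high as up-regulated ones. The platform score this stands in
for is proprietary; this one is documented, simple, and pluggable — any
table with a `gene` column and score families can be fed to `metascore()`.

**Metascore.** Score families (`omics`, `text`, `finance`, `kol`) live on
arbitrary scales, so each enabled family is rank-normalized to (0, 1]
before a weighted mean. Ranking ties break lexicographically by gene ID, so
every ranking the package emits is deterministic. The external families are
accepted as input tables only; nothing in the package mines literature or
finance data.

**Filters.** The cascade (druggable class present, small-molecule
association, non-essential, and in novel mode a minimum novelty level) is
order-preserving and idempotent, followed by the top-50 cut. Novel mode
forces omics-only scoring, mirroring how a prior-knowledge-free list is
built. A gene missing from the annotation table fails the druggable-class
requirement rather than erroring: an unannotated gene is not actionable.

# Time-machine validation

A ranking built from pre-cutoff knowledge is scored on the genes that
entered clinical trials strictly after the cutoff year (the cutoff year
itself is training data). Two metrics are computed from the counts
(`targets_k` of `targets_N` held-out targets in the top `k` of `N` genes):

* **ELFC** `= log2((targets_k / k) / (targets_N / N))`, with 0.1
  substituted for a zero `targets_k` so an empty prefix reads as a strong
  negative enrichment instead of `-Inf`. The substitution applies only
  here, not to the tail probability.
* **HGPV** `= -log10 P(X > targets_k)` for `X` hypergeometric — the strict
  tail, exactly as the defining formula is printed. A strict tail excludes
  the observed count, so it is smaller than the exact p-value
  `P(X >= targets_k)` by the point mass at the observation; under random
  rankings the strict variant is therefore anti-conservative, and the
  calibration property (the fraction of random rankings with
  `HGPV >= -log10(alpha)` staying within `alpha` plus binomial error) holds
  for the inclusive variant, available as `hgpv(..., inclusive = TRUE)`.
  The default remains the printed strict form. A tail of exactly zero (the
  observed count is the deterministic maximum) is clamped to 300 rather
  than infinity.

Both metrics are label-agnostic: the caller decides which gene set is the
evaluation set, so "known" and "novel" are roles, not properties of the
functions.

# Pathway dysregulation

**Activation scoring.** The bundled scorer is a documented simplified
stand-in, not a reimplementation of the proprietary topology-aware
algorithm the source platform uses: a pathway's score in a comparison is
the weighted mean of member-gene fold changes, with optional per-gene
topology weights and a soft significance gate (genes with `p >= 0.05` keep
half weight rather than being dropped — hard gating makes scores
discontinuous in the data). Scores are signed: positive is activation in
cases.

**Calling.** A pathway is dysregulated in a group when (1) the share of the
group's comparisons agreeing on a sign reaches 0.80 — compared exactly,
without rounding, so 7 comparisons need 6 — and (2) the maximum absolute
score over the group's comparisons reaches 0.01. The magnitude condition is
applied to `max |score|` across all comparisons regardless of sign, the
natural reading of "reached the threshold in at least one comparison" when
signs are mixed. A score of exactly 0 counts toward neither direction. Note
that a single-comparison group (the diMN groups) trivially satisfies the
80% rule, so its calls are gated by magnitude alone; this mirrors the
published design rather than a choice made here.

**Process enrichment.** The hypergeometric formula is implemented exactly
as printed: `p = 1 - sum_{i=0}^{r-1} C(K, i) C(N-K, n-i) / C(N, n)` with
`N` total pathways, `K` dysregulated pathways in the process, `n` total
dysregulated, `r` pathways in the process. In this orientation the roles of
`K` and `r` are swapped relative to the conventional test, and the value
degenerates to 0 whenever `r > K`; the conventional orientation (population
successes `r`, observed `K`, tail `P(X >= K)`) is available behind
`conventional = TRUE` and is what the analysis drivers report. Bonferroni
adjustment multiplies by the number of processes tested and caps at 1.

**Similarity network.** Nodes are called pathways; edges connect pairs with
similarity strictly above 0.35. The default coefficient is Jaccard; the
EnrichmentMap-style combined coefficient `(Jaccard + overlap)/2` is a
config option, since the published network names only the threshold and the
two coefficients disagree precisely on nested sets (the worked example
`{a,b,c,d}` vs `{c,d,e,f}` gives 1/3 vs 5/12 — no edge vs edge at 0.35).
Reported clusters are connected components with at least four pathways.

# The fly screen scale

RNAi crosses are scored per offspring on the integer scale -4 (strongest
rescue of eye degeneration) to 2 (strongest enhancement); an ortholog's
score is the offspring mean, which is how half-scores like -3.5 arise.
Classification thresholds are inclusive and applied in decreasing severity:
`<= -3` strong rescue, `<= -2` moderate, `<= -1` mild, `>= 2` moderate
enhancement, `>= 1` mild, otherwise no effect. This is the only reading
consistent with every printed interpretation cell (-2.5 must be moderate,
-0.5 and 0.5 no effect). A human gene with several orthologs is represented
by the score of maximal absolute value, with ties resolved toward rescue;
lethal crosses are excluded from aggregation and never imputed as zero.
Strong-rescue genes with no citation anywhere in their rows are counted as
unreported.

```{r screen}
s <- summarize_screen(load_screen_table())
c(with_model = s$n_with_model, orthologs = s$n_orthologs,
  strong_or_moderate = s$n_strong_or_moderate_rescue,
  strong_unreported = s$n_strong_rescue_unreported)
```

# Numerical choices and degenerate inputs

* Percent rounding is half-up at integer precision; base `round()`'s
  half-even rule would not change the published examples but is avoided for
  predictability.
* p-values are floored at the smallest positive double so `(0, 1]` holds
  even for astronomically significant genes.
* Hypergeometric tails are delegated to `stats::phyper`; unit tests verify
  them against exhaustive subset enumeration for every configuration with
  `N <= 12` at `1e-12`.
* Ranking ties break by gene ID; screen-score ties break toward rescue;
  enrichment with an empty process (`r = 0`) is `p = 1` (empty sum).
* Empty comparison lists, empty target backgrounds, all-lethal ortholog
  sets and absent fly models are explicit error or missing states, never
  silently 0.

# Study conditions used by the test suite

Recovery checks run at desk scale, chosen once as realistic for this field:
planted-target recovery uses the 16-comparison layout with 10 case / 10
control arms, 2000 genes and log2 effect 1.5 at full penetrance over 20
seeds; planted-pathway recovery uses a five-comparison group with 25/25
arms, pathways of 40-60 genes and activation magnitude 0.05 over 40 seeds;
metric calibration uses 2000 random rankings. The analysis scripts use the
real per-cohort sample sizes from the comparison inventory.

# Known limitations

* The activation scorer is a stand-in; absolute score values are not
  comparable to the proprietary algorithm's, only the calling logic around
  them is.
* Published process-level adjusted p-values depend on the study's full
  dysregulated-pathway lists (supplementary data not in the main text) and
  are not recomputable here; the package reproduces the machinery, not
  those numbers.
* The published candidate table contains one manual-curation override
  (a CNS gene at 50%/14% consistency) that the selection rule, applied as
  stated, would not produce; the package applies the rule as stated.
* External score families are synthetic placeholders unless the user
  supplies real tables.
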