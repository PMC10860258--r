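---
title: "Methods: the molecular-guided therapy decision pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the molecular-guided therapy decision pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtbkit)
```

`mtbkit` models the analytic core of a pediatric precision-oncology
workflow: tumor/normal exome and tumor transcriptome results flow through
expression-outlier scoring, somatic landscape summarization and mutational
signature decomposition into a tiered drug–gene matching algorithm that
assembles a combination treatment plan, while response and feasibility
statistics summarize what happened to the cohort. This vignette is the
package's account of each model, its assumptions, the knobs that matter,
and the choices made where the design was genuinely open.

## Expression outliers against a normal reference (NRZ)

The central transcriptomic statistic is a per-gene Z-score of one tumor
against a whole-body panel of normal tissues (22 in the intended use):

$$z_g = \frac{x_g - \mu_g}{\sigma_g}$$

with $\mu_g$, $\sigma_g$ the reference mean and SD (n−1 denominator) on a
normalized-log scale. The assumptions are the usual ones for outlier
Z-scores: scores are comparable across genes only after normalization, and
the panel is small, so $\sigma_g$ is itself noisy — with 22 reference
samples, a true +4 SD outlier is recovered at |z| ≥ 2 about 96–98% of the
time, not always. Genes whose reference expression is nearly constant would
otherwise produce unbounded scores, so $\sigma_g$ is floored at `sd_floor`
(default 0.1 on the log2 scale, configurable in
`build_normal_reference()`).

Two semantics are fixed deliberately:

* **Threshold inclusivity.** A gene at exactly $z = \tau$ is actionable.
  The default τ = 2 is exposed everywhere (`nrz_score()`, `match_tier3()`,
  `run_subject()`).
* **Scale explicitness.** `expr_matrix` objects carry a `scale` flag
  (`raw_counts` vs `normalized_log`), and `build_normal_reference()`
  refuses raw counts. `normalize_counts()` provides median-of-ratios size
  factors with a `log2(x/s + pseudocount)` transform. A regularized-log
  transform is intentionally *not* reimplemented: the outlier statistic,
  not the variance-stabilizing transform, is the method, and pre-normalized
  matrices are accepted directly.

The companion CRC score places each tumor gene on a cancer-reference
cohort. No closed-form definition of such a cumulative-distribution
statistic is fixed by convention, so the package documents its choice: the
mid-rank empirical CDF, $p_g = 100\,(\#\{r < x\} + \tfrac12\#\{r = x\})/n$,
which is symmetric under ties and invariant under any strictly monotone
transform applied jointly to tumor and reference.

## Somatic landscape

**Arm-level events.** Copy-number segments qualify when they contain at
least `min_genes` genes (default 50) and their log2 tumor/normal ratio is
≥ `log2_thresh` for gains or ≤ −`log2_thresh` for losses (default 0.5; all
thresholds inclusive). Qualifying segments are intersected with each
chromosome arm, their overlaps **unioned** per arm and direction — so
overlapping calls can never push the covered fraction above 1 — and an
event is emitted when coverage reaches `arm_fraction` (default 0.5) of the
arm. Arm length is taken from the arm map as-is; no centromeric gap is
subtracted. Cohort recurrence (`cohort_arm_recurrence()`) counts distinct
subjects, so longitudinal biopsies of one subject count once.

**TMB.** Somatic point mutations (SNV class only; indels excluded) per
callable megabase. The callable footprint is an explicit parameter with a
documented default of 30 Mb (a typical exome); because the denominator
dominates cross-study comparability, it is echoed in every result row.

## Mutational signatures

Catalogs are length-96 count vectors over the canonical
pyrimidine-centered trinucleotide contexts, substitution-class major
(C>A, C>G, C>T, T>A, T>C, T>G) with the 5′ flank varying slowest;
purine-centered input contexts are reverse-complemented onto the
pyrimidine strand. Decomposition is plain non-negative least squares
(`decompose_lcd()`), solved by the Lawson–Hanson active-set algorithm:
deterministic, unregularized, with an optional per-signature proportion
cutoff that defaults to 0 (off) — when set, signatures below the cutoff
are dropped and the fit repeated on the survivors. The signature matrix is
a *user-supplied input*, never embedded: baking in a particular catalog
version would silently couple results to an external database release, and
the package's tests use synthetic, well-separated signatures instead.
Per-type summaries are unweighted means of per-subject proportions, so
each subject contributes equally regardless of mutation load.

## Tiered drug matching and combination assembly

The matching algorithm has three tiers, in priority order:

1. **Direct** — a somatic event (variant, either fusion partner, or a
   gene-level copy-number event) hits a gene with a direct literature rule.
2. **Inferred** — the altered gene maps, through a curated single-hop
   gene→target link, to a gene with a direct or inferred rule. The hop
   limit is a contract: chains are never followed.
3. **Expression** — an NRZ flag matches an expression rule's direction
   (`over`/`under`) at the shared τ.

A human tumor board weighs candidates qualitatively; software needs a
deterministic surrogate, so within a tier candidates rank by a score —
|z| for expression matches, and a fixed event-class weight for DNA matches
(fusion 4 > protein-annotated SNV 3 > other small variant 2 > gene-level
CNV 1, configurable via `default_event_weights()`) — with the drug name as
the final alphabetic tie-break. Resistance-mode matches are **hard vetoes**
for their drug: the conservative machine-checkable reading of a rule set
that marks both sensitivity and resistance. `assemble_combination()` then
cycles greedily: optionally seed a priority regimen when it is fully
supported and internally conflict-free, then repeatedly add the top-ranked
remaining drug that neither duplicates nor conflicts (interaction
blacklist) with the plan, stopping at `max_drugs` (default 4) or
exhaustion. Non-molecular exclusions (tolerability, line access) enter
only as configured per-drug exclusion flags. Reports embed no timestamps,
so identical inputs give byte-identical JSON.

## Response, benefit and feasibility

`classify_best_response()` works from target-lesion diameter sums with
timepoint 0 as the pre-cycle-1 baseline. Two reference conventions coexist
deliberately and are both documented: progression is **nadir-referenced**
(≥ +20% above the running nadir *and* ≥ 5 mm absolute, the rulebook
definition), while `best_percent_change` for waterfall displays is
**baseline-referenced**. A trajectory that reaches CR or PR before any
progression event keeps that response as its best class. The boundary at
exactly −30% classifies as PR by default; `pr_boundary = "exclusive"`
flips to the stricter reading in which the stable-disease band is closed
at 30%, since central-review conventions differ and the choice is not
recoverable from summary statistics. Confirmation scans and
non-target/new-lesion rules are out of scope: class is computed from
target-lesion sums and the post-surgical NED flag only.

Benefit, cycle-start and waterfall percentages are always recomputed from
counts, never transcribed: the clinical benefit rate is
(CR+PR+SD+NED)/(CR+PR+SD+NED+PD), with headline percentages rounded half
away from zero to the printed precision (integers for benefit, two
decimals for feasibility-style percents) — base R's round-half-even would
disagree at exact halves.

## The synthetic cohort generator

`generate_cohort()` exists so every stage can be tested closed-loop with
no access to protected patient data. Its defaults are the study conditions
the pipeline was designed around: 144 subjects split 31 neuroblastoma /
41 CNS / 72 rare; a 22-tissue normal reference; per-gene log2 expression
drawn normal around a lognormal-like location (mean uniform on [3, 10], SD
on [0.3, 0.8]); 20 over- and 10 under-expression spikes per tumor at
k = 4 reference SDs; five synthetic signatures mixed per type by a
Dirichlet favoring one signature each, with mean mutation counts 100 / 21 /
36 (neuroblastoma / CNS / rare), spanning a low-to-moderate TMB range;
arm events planted at the recurrence frequencies typical of these tumor
types (17q gain in 78% of neuroblastomas, 17p loss in 27% of CNS tumors,
and so on); driver variants, a fusion, lesion trajectories drawn over all
five response classes at pooled best-response proportions; and milestone
days centered near 10 / 17 / 23 / ~38 along the biopsy-to-treatment
timeline. Every draw flows through the single config seed.

One generator choice deserves emphasis: **spiked genes are pinned at
$\mu_g \pm k\sigma_g$** rather than shifted on top of the tumor's own
noisy draw. With a full extra noise term of SD $\sigma_g$, a +4σ spike
lands below z = 3 about one time in six, and "the generator's spikes are
strong outliers" stops being a property one can assert tightly; pinning
makes reference estimation the only noise source, which is the property
the recovery suite quantifies. The NRZ criterion itself (≥ 95% of spikes
flagged at τ = 2) is still exercised under the harder model — fully noisy
tumors plus additive spikes — where it holds with margin.

What the generator does *not* emulate, and hence what green tests do not
show: real RNA-seq mean–variance structure and batch effects, correlated
genes, subclonal mutation structure, indel/DBS signatures, segmentation
noise around arm boundaries, purity/ploidy distortion of log2 ratios, and
any realistic joint distribution between molecular features and outcome
(responses are planted independently of the molecular data). Passing the
recovery suite demonstrates internal consistency of the pipeline's logic,
not clinical validity.

## Numerical choices and degenerate inputs

* All genomic coordinates are 1-based inclusive in memory; readers convert
  declared 0-based half-open dialects at the boundary.
* Gene identity is exact, case-sensitive symbol matching; no alias
  resolution.
* `sd_floor` (0.1 log2) bounds Z-scores on degenerate reference genes; the
  NNLS residual is reported so ill-fitting catalogs are visible; an
  all-zero catalog is an error (proportions undefined) rather than a NaN
  vector.
* Ties: candidate ranking breaks ties by drug name; oncoprint gene rows
  break frequency ties alphabetically; the mid-rank CDC handles expression
  ties symmetrically.
* A subject with no eligible candidates is a distinct `no_plan` status,
  not an error; a missing input class skips its stage with an explicit
  note and disables dependent tiers.

## Problem sizes used in the test and acceptance suites

The suites favor many small seeded replicates over single large runs:
signature recovery uses 100 replicates of 1000-mutation catalogs over 5
signatures (observed mean absolute exposure error ≈ 0.011 against a 0.05
bound); NRZ spike recovery uses 100 tumors of 200 genes against a
22-sample reference; arm-event recovery uses a 30-subject synthetic
cohort; the RECIST round-trip classifies 500 generated series; plan
invariants are checked over 1000 random matching configurations; and the
end-to-end cohort tests run 10–30 subjects with 150–300 genes. These sizes
were chosen as the smallest at which the assessed proportions are stable
to well under their acceptance margins.

## Known limitations

The package consumes upstream calls (alignment, variant/fusion/CNV
calling, annotation are out of scope) and trusts their gene symbols and
effect strings verbatim. Tier-2 inference is only as good as the supplied
single-hop map. The combination assembler is a deterministic surrogate of
a deliberative process; it makes no dosing, pharmacokinetic or
drug-interaction predictions beyond the supplied blacklist, and its output
is decision support, never a clinical recommendation.
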