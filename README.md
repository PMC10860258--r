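# mtbkit

Children with relapsed or refractory solid tumors — neuroblastoma, CNS
tumors, sarcomas and other rare cancers — often lack standard treatment
options, and their tumors rarely carry the single actionable DNA mutations
that drive adult precision oncology. Molecular-guided therapy (MGT) programs
instead combine tumor/normal exome and tumor transcriptome profiling with a
molecular tumor board (MTB) that assembles an individualized combination of
up to four targeted agents, leaning heavily on RNA expression outliers.

`mtbkit` is an R implementation of that decision pipeline, for
bioinformaticians and trial analysts who need a reproducible, testable
surrogate of the MTB workflow: every stage is a plain function over tidy
tables, and a seeded synthetic-cohort generator stands in for protected
patient data so the whole pipeline can be exercised end to end.

## What it computes

* **Expression outliers (NRZ).** For gene *g* with normal-reference mean
  μ<sub>g</sub> and SD σ<sub>g</sub> (a whole-body panel of 22 normal
  tissues, on a normalized-log scale), the tumor's score is
  *z<sub>g</sub> = (x<sub>g</sub> − μ<sub>g</sub>)/σ<sub>g</sub>*; genes with
  |z| ≥ τ (default τ = 2, inclusive) are actionable outliers. A
  cancer-reference percentile (CRC, mid-rank empirical CDF against a cohort
  of other relapsed/refractory tumors) complements it.
* **Somatic landscape.** Arm-level copy-number events (segments with ≥ 50
  genes and |log2 ratio| ≥ 0.5 whose union covers ≥ 50% of an arm), a ≥ 15
  distinct-subject cohort recurrence filter, oncoprint assembly, and tumor
  mutational burden (somatic SNVs per callable Mb).
* **Mutational signatures.** 96-trinucleotide-context catalogs decomposed by
  non-negative least squares, *e* = argmin<sub>e≥0</sub> ‖W·e − m‖₂, against
  a user-supplied signature matrix W; exposure proportions averaged per
  tumor type.
* **Three-tier drug matching.** Tier 1: direct variant/drug literature
  rules; tier 2: single-hop inferred matches through a gene→target map;
  tier 3: expression rules fired by NRZ flags. Resistance rules veto their
  drug; a greedy ranked cycle (tier, then score, then name) assembles a ≤
  4-drug plan honoring an interaction blacklist and optional priority
  regimens, and emits a deterministic JSON/markdown report.
* **Outcomes and feasibility.** RECIST v1.1 best-response classification
  from target-lesion sums (CR/PR/SD/PD/NED; nadir-referenced progression
  with the 5 mm rule), clinical benefit rate
  (CR+PR+SD+NED)/(CR+PR+SD+NED+PD), waterfall tables of best
  baseline-referenced percent change, milestone (biopsy → sequencing →
  report → decision → treatment) summaries, and cycle-start feasibility
  percentages.
* **Longitudinal analytics.** Shared/unique Venn partitions of canonical
  event keys across 2–3 serial biopsies and targetable-gene Z-score
  matrices with chosen-drug flags.

## Worked example

```r
library(mtbkit)

sim <- generate_cohort(simulation_config(
  seed = 12, n_subjects = c(neuroblastoma = 10, CNS = 10, rare = 10),
  n_genes = 250
))
run <- run_subject(sim$bundle, "S001", signatures = sim$signatures, seed = 12)
run
#> <subject_run> S001 [ok]
#> <treatment_plan> 4 drug(s): drug_over_17 + drug_over_4 + drug_under_4 + drug_over_7
#>   excluded: drug_res_1 (resistance_veto)
tidy(run$plan)
#> # A tibble: 4 × 6
#>   drug          tier gene  event                            score evidence
#> 1 drug_over_17     3 G0017 G0017 overexpressed (z = 5.44)    5.44 overexpressio…
#> 2 drug_over_4      3 G0004 G0004 overexpressed (z = 4.79)    4.79 overexpressio…
#> 3 drug_under_4     3 G0024 G0024 underexpressed (z = -4.73)  4.73 underexpressi…
#> 4 drug_over_7      3 G0007 G0007 overexpressed (z = 4.18)    4.18 overexpressio…
run$tmb
#> # A tibble: 1 × 4
#>   subject_id n_point_mutations callable_mb   tmb
#> 1 S001                      99          30   3.3
```

The plan is read bottom-up from the report: each chosen drug carries the
tier it matched at, the molecular event supporting it (here tier-3
expression outliers with their Z-scores), and the evidence string from the
rules knowledge base; `drug_res_1` was excluded because a resistance rule
fired. TMB is 99 SNVs over a 30 Mb callable exome = 3.3 mutations/Mb, a
neuroblastoma-like burden.

Cohort views aggregate the same stages:

```r
cr <- run_cohort(sim$bundle, signatures = sim$signatures, min_subjects = 3)
cr$benefit_by_type
#> # A tibble: 3 × 5
#>   tumor_type    n_benefit n_total proportion percent
#> 1 CNS                   5      10        0.5      50
#> 2 neuroblastoma         6      10        0.6      60
#> 3 rare                  6      10        0.6      60
glance(cr$waterfall)
#> # A tibble: 1 × 5
#>       n n_decrease n_no_change n_increase percent_decrease
#> 1    26         12           0         14             46.2
autoplot(cr$waterfall)   # sorted best-percent-change bars with the ±30/20% bands
```

`percent` is the clinical benefit rate per stratum (subjects with
CR/PR/SD/NED over all response-evaluable subjects), and the waterfall
glance counts measurable-disease subjects whose best tumor-burden change
was a decrease, exactly zero, or an increase.

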