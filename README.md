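# iddakit

Tools for quantifying disease activity in inborn errors of immunity (IEI)
with immune dysregulation. The package computes the **IDDA2.1 score** — a
per-visit, physician-reported activity measure — tracks it longitudinally
across therapy phases, aggregates cohorts into 17-axis feature-presence
("kaleidoscope") radar profiles, and clusters disease-by-feature frequency
matrices into annotated heatmaps. A seedable synthetic cohort generator
with disease-archetype structure makes every stage testable without
patient data.

It is aimed at clinicians and registry analysts working with primary
immune regulatory disorders (PIRDs), combined immunodeficiencies and
antibody deficiencies, where infection-centred severity scores miss the
autoimmune/lymphoproliferative disease burden.

## The score

A visit record holds 22 items: 14 organ/feature involvements graded 0–4,
the Karnofsky/Lansky performance scale, hospitalization and ICU days out
of the last 100 days, four supportive-care items, and a malignancy flag
(noted, never scored). The total is

```
total = ( sum(lines 1–14)
        + min(0.1 * hosp_days, capped at 4 from 40 days)
        + min(0.8 * icu_days,  capped at 8 from 10 days)
        + sum(lines 18–21) )
        * (150 / performance   if performance > 29%, else 6)
```

i.e. `(organ sum + hospitalization term + ICU term + supportive sum) × M`,
with `M ∈ [1.5, 6]`. The attainable range is 0–498. Line 18 (IgG
substitution) scores 0 none / 2 sporadic / 3 regular (IV or SC).

## Worked example

```r
library(iddakit)

v <- idda_visit("P1", "2024-03-01",
                organ_grades = c(2, 0, 3, 2, 0, 1, 0, 0, 0, 2, 0, 0, 1, 2),
                performance = 70, hosp_days = 20, igg = "iv",
                infestation = 2, other_organ = 1, nutrition = 2)
idda_score(v)[, c("organ_sum", "hosp_term", "icu_term",
                  "supportive_sum", "multiplier", "total")]
#>   organ_sum hosp_term icu_term supportive_sum multiplier    total
#> 1        13         2        0              8   2.142857 49.28571
```

The 14 organ grades sum to 13; 20 hospital days contribute 2 points; the
supportive items contribute 3 (regular IVIG) + 2 + 1 + 2 = 8; and the
subtotal of 23 is multiplied by 150/70 ≈ 2.14 for a performance scale of
70%, giving a total of 49.29.

Cohort profiling and clustering on synthetic data:

```r
study <- sample_study(example_archetypes(),
                      cohorts_per_archetype = 8, n_per_cohort = 50,
                      seed = 42)
render_kaleidoscope(study$profiles[[1]], "tregopathy_c01.svg")

m   <- as_phenotype_matrix(study$profiles)   # 24 cohorts x 17 features
res <- cluster_phenotypes(m)                 # truncated logit + complete linkage
render_heatmap(m, res, "phenotype_array.svg")
table(cut_phenotype_clusters(res, 3),
      sub("_c\\d+.*", "", rownames(m)))
#>    cvid_like ebv_susceptible tregopathy
#>  1         0               0          8
#>  2         8               0          0
#>  3         0               8          0
```

Cutting the disease dendrogram at k = 3 recovers the three planted
archetypes exactly (adjusted Rand index 1.0 under these conditions).

A command-line interface wrapping these functions ships in
`inst/cli/idda.R` (`score`, `trajectory`, `kaleidoscope`, `cluster`,
`simulate`, `validate`), e.g.

```sh
Rscript inst/cli/idda.R simulate --n 50 --cohorts 8 --seed 42 --out visits.csv
Rscript inst/cli/idda.R score visits.csv --out scores.csv
```

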