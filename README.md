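# fimd

Structured validation of animal disease models for drug-efficacy research.

Preclinical teams usually pick an animal model by precedent. `fimd`
implements the Framework to Identify Models of Disease (FIMD), a weighted
questionnaire that makes the choice explicit and comparable: one *validation
sheet* per model and indication, covering eight validation domains —
Epidemiological, Symptomatology and Natural History, Genetic, Biochemical,
Aetiological, Histological, Pharmacological and Endpoint validation. The
package is for meta-researchers, pharmacologists and 3Rs-minded reviewers
who need model validations that are scoreable, auditable and repeatable.

## The scoring model

Under the same-weight (SW) system, 100 points are split equally over the
8 domains (12.5 each) and then equally over the questions within a domain
(non-terminating splits round half-up to 2 decimals with the remainder on
the domain's last question: 4.17 / 4.17 / 4.16). For a sheet with answers
*a<sub>q</sub>* and weights *w<sub>q</sub>*:

- question score: *s<sub>q</sub>* = *w<sub>q</sub>* (YES), *w<sub>q</sub>*/2
  (PARTIAL), 0 (NO or UNCLEAR)
- raw total: *S* = Σ *s<sub>q</sub>* over non-excluded questions;
  attainable maximum *M* = Σ *w<sub>q</sub>* (100 minus excluded weight)
- equivalent score: *E* = 100 · *S* / *M* (two decimals, half-up)
- domain ratio (radar axis): earned / attainable per domain, in [0, 1]
- uncertainty factor: % of items answered UNCLEAR; similarity factor:
  % of comparable items answered identically in two sheets
- validation level from the % of definite (non-UNCLEAR) answers:
  0–40 insufficiently, 41–60 slightly, 61–80 moderately, 81–100 highly
  validated

Per-study reporting-quality (ARRIVE-adapted) and risk-of-bias
(SYRCLE-adapted) checklists aggregate to per-model and pooled percentage
tables for the drug-intervention studies behind the Pharmacological domain.

## Worked example

```r
library(fimd)
q <- default_questionnaire()
ids <- setdiff(q$questions$id, c("4.3", "4.4"))
ans <- stats::setNames(as.list(c(rep("YES", 8), "PARTIAL", "PARTIAL",
                                 rep("YES", 4), "UNCLEAR", "YES",
                                 "PARTIAL", "NO", "YES")), ids)
sheet <- validation_sheet(
  "mdx mouse", "Mus musculus", "Duchenne muscular dystrophy",
  answers = ans,
  exclusions = list(
    exclusion("4.3", "No prognostic biomarkers identified for this indication"),
    exclusion("4.4", "No prognostic biomarkers identified for this indication")))
score_sheet(sheet)
#> FIMD score breakdown: mdx mouse — Duchenne muscular dystrophy
#>   raw 77.085 / 93.75, equivalent score 82.22
#>   uncertainty 5.3%, definite 94.7% (flat items) -> Highly validated
#>   domain ratios: 1=1.00, 2=1.00, 3=0.67, 4=1.00, 5=1.00, 6=1.00, 7=0.50, 8=0.50
```

Excluding the two prognostic-biomarker questions lowers the attainable
maximum to 93.75, so the raw 77.085 rescales to an equivalent score of
82.22. One UNCLEAR answer among 19 questions gives the 5.3% uncertainty
factor; 94.7% definite answers lands in the 81–100 band, "Highly
validated". Domain ratios feed the radar plot (`radar_svg()`,
`plot_radar()`); `compare_sheets()` adds the similarity factor and ratio
deltas against a second model, and `render_report()` writes the full
Markdown sheet report.

Sheets are YAML/JSON documents (`read_sheet()` / `write_sheet()`), study
assessments a published CSV dialect (`read_assessments()`); a command-line
wrapper is installed at `system.file("scripts", "fimd", package = "fimd")`
with subcommands `validate`, `score`, `compare`, `quality`, `report`,
`synth`. Seeded generators (`generate_sheet()`,
`generate_assessments()`) produce complete synthetic inputs.

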