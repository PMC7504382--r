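# lpac — Level of Preventive Action risk assessment for construction works

`lpac` implements the **Level of Preventive Action** (L_pac) method of
occupational risk assessment for construction sites: an extension of the
William T. Fine multiplicative risk score that measures how far the
preventive situation observed on site deviates from the baseline written
into the Health & Safety Plan, and how much control of preventive action
is therefore required.  It is aimed at health-and-safety coordinators,
site assessors and researchers who need a reproducible, auditable scoring
chain from inspection rubrics and a short psychosocial survey to control
recommendations.

## The method in brief

At the plan stage each risk carries a qualitative probability and
consequence rating, quantified as 1/3/5 via `f(x) = 2x + 1`; their product
is the **absolute risk** `Ab_r = P·C` on the characteristic scale
`{1, 3, 5, 9, 15, 25}` with its INSST-style tolerance label (trivial …
intolerable).  On site, six parameters are scored on the same scale:

| Parameter | Effect | Source |
|---|---|---|
| `R_r` relative risk | aggravates | 8-factor complexity rubric |
| `B_r` borderline risk | aggravates | platform geometry grid (height band × zone) |
| `E` degree of exposure | aggravates | 2-criterion exposure rubric |
| `E_c` economic capacity | corrects | 5-factor organization/protection rubric |
| `P_i` participative interest | corrects | 4-factor participation rubric |
| `L_s` level of satisfaction | corrects | 10-question worker+assessor survey |

They combine into the **preventive action assessment**

    A_pac = (R_r · B_r · E) / (E_c · P_i · L_s)

and the headline per-risk output

    L_pac % = 100 · A_pac / Ab_r ,

classified into six control bands — optimal, adequate, more, greater,
intensive, exhaustive control — with thresholds `ε·{1, 3, 5, 9, 15, 25}`
for an exigency scale factor `ε` adjusted to the worst risk.  Technique
(Safety at Work, Industrial Hygiene, Ergonomics, Psychosociology) and
site-wide aggregates average the unrounded per-risk percentages.

## Worked example

The canonical inspection — a bare brick façade on the first floor — ships
both as a builder (`make_worked_example()`) and as a YAML fixture
(`inst/extdata/worked_example.yaml`):

```r
library(lpac)
fit <- assess(make_worked_example())
fit
#> Level of Preventive Action assessment
#>   scale factor epsilon = 4 (thresholds 4/12/20/36/60/100)
#>
#> Base characteristic values:
#>  parameter      raw cv
#>        r_r  8.25000  9
#>        b_r  6.00000  6
#>          e 12.00000 15
#>        e_c  5.40000  5
#>        p_i  3.50000  3
#>        l_s 12.33333 15
#>
#> Per-risk results (excerpt):
#>  code description                                     tolerance   A_pac L_pac control
#>  010  Risk of people falling from a different height  intolerable 4.38  18%   more
#>  110  Risk of entrapment by or between objects        tolerable   2.00  67%   exhaustive
#>  570  Risk due to incorrect work organization         tolerable   0.73  24%   greater
#>
#> Technique aggregates:
#>  safety 32% | hygiene 34% | ergonomics 51% | psychosociology 20%
#>
#> Global: 34% -> greater control (10 risks)
```

Reading: the fall-from-height risk (010) was rated intolerable in the
plan, but the observed preventive situation deviates only 18% from the
baseline — "more control" is enough; entrapment (110), although tolerable
on paper, shows a 67% deviation and demands exhaustive control.
`tidy(fit)` returns the per-risk tibble (exact and display-rounded
columns), `glance(fit)` a one-row summary, `autoplot(fit)` the control
chart, and `write_report()` CSV/JSON/text reports.

Other entry points: `read_inspection()` / `write_inspection()` for YAML
records, `assess_batch()` for a directory of inspections (campaign mode
with a per-inspection trend series), `campaign_scenario()` +
`generate_campaign()` for seeded synthetic campaigns, and the `exec/lpac`
command-line front end (`lpac assess <file>`, `lpac batch <dir>`,
`lpac synth`, `lpac validate <file>`).

See the vignette (`vignettes/lpac-method.Rmd`) for the full account of
the model, its numerical choices and limitations.

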