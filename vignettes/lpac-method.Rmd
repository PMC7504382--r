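---
title: "The Level of Preventive Action method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Level of Preventive Action method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpac)
```

## The model

Classical occupational risk scores multiply the probability of an accident
by its consequences, $R = P \cdot C$; the William T. Fine family adds
corrective factors for exposure and for the feasibility of correction.
The Level of Preventive Action (L\_pac) method extends this line to the
particular complexity of construction sites.  The plan-stage estimate

$$Ab_r = P \cdot C$$

is the *absolute risk*: the baseline written into the Health & Safety
Plan before work starts.  On site, six observed parameters form the
*preventive action assessment*

$$A_{pac} = \frac{R_r \cdot B_r \cdot E}{E_c \cdot P_i \cdot L_s},$$

where the numerator collects the parameters that aggravate the baseline —
relative risk $R_r$ (complexity of the unit of work), borderline risk
$B_r$ (position of the workers relative to the fall hazard), degree of
exposure $E$ — and the denominator the parameters that correct it —
economic capacity $E_c$ (organization and protection systems),
participative interest $P_i$, and level of satisfaction $L_s$ (emotional
state and risk-perception congruence).  The headline per-risk output is
the percentage

$$L_{pac}\,[\%] = 100 \cdot \frac{A_{pac}}{Ab_r},$$

the deviation of the observed preventive situation from the plan
baseline; the package also reports the companion absolute score
$Ab_r \cdot A_{pac}$.  Percentages are classified into six control bands
(optimal, adequate, more, greater, intensive, exhaustive control) whose
thresholds are $\varepsilon \cdot \{1, 3, 5, 9, 15, 25\}$ for an exigency
scale factor $\varepsilon$.

## The characteristic-value scale

Every parameter is scored on the same six-point ladder $\{1, 3, 5, 9,
15, 25\}$.  Its first three points quantify the qualitative
probability/consequence levels through $f(x) = 2x + 1$ (so no parameter
can ever be 0 and collapse the product), and the full ladder is the set
of pairwise products of $\{1,3,5\}$ — on the diagonal,
$f(x) = 4x^2 + 4x + 1$.  Rubric parameters average several selected
characteristic values; the mean is rounded to the nearest ladder value
with the method's explicit tie rule: an average landing exactly on a
midpoint (2, 4, 7, 12, 20) rounds *up*, the conservative direction.
`round_cv()` implements this and is property-tested against a
brute-force nearest-with-upper-tie oracle on a dense grid.

Borderline risk is the one parameter not confined to the ladder: the
platform grid assigns whole numbers 1..25 by height band (up to 1, 3, 5,
9, 15, and above 15 m; depth counts in absolute magnitude) and zone
(safe area, close to borderline, borderline, close to risk, risk area).
The border sits at 100/100/125/150/175/200 cm from the hazard depending
on the band, with 25 cm strips on either side.  Zone boundaries are
upper-inclusive toward the safer side (a worker exactly on the border
distance is *borderline*, not *close to borderline*), which is the
reading consistent with the printed grid; height bands are
upper-inclusive ("up to 1.0 m").

## The survey and congruence

Ten questions on a 1..6 scale: four personal, two environment, four
safety.  Personal answers convert through the performance curve
1-3-5-25-15-9 — the peak is at "focused", and both apathy and
over-excitement score low.  Environment and safety answers are not used
directly: the worker's answers are compared against the assessor's
through the *congruence ratio*, implemented as the mean of per-question
worker/assessor ratios, clamped to $[0, 2]$ and snapped to the 0.2 grid.
Perfect congruence (ratio 1) earns the maximal value 25; the tent map
1-3-5-9-15-25-15-9-5-3-1 decays symmetrically toward both ends,
penalising over- and under-confidence alike.  Two numerical choices were
genuinely open and are resolved as follows:

* *Ratio definition.*  The method's description ("combined ... sum ...
  average ... closeness to the unit") underdetermines the arithmetic; a
  per-question ratio averaged across questions is the only reading
  compatible with the published $[0, 2]$ grid and reproduces both
  printed congruence values (0.6 for safety, 1.1 for environment).
* *Midpoint snapping.*  A ratio exactly midway between grid points (such
  as 1.1) snaps *away* from 1.0.  This reproduces the printed
  1.1 → perception 15 example and is conservative: less congruence means
  a lower $L_s$, hence more required preventive action.

The per-worker personal value is the integer-rounded mean of the four
converted personal answers, computed from worker answers only — the
assessor's view of a worker's emotional state is not the worker's.  An
externally established personal value can be supplied instead
(`survey_personal_cv`), which is how the packaged worked example carries
its reference value 13.  Site- or crew-level $L_s$ averages the
per-worker raw means *before* rounding.

## Per-risk adjustment, classification, aggregation

The six base values are re-examined against each assessed risk: the
evaluator may override any parameter per risk within $[1, 25]$.
Deviations beyond one step of the characteristic ladder are accepted but
logged (condition class `lpac_log_deviation`), so the audit trail for
the verification phase is complete.  The exact min/max adjustment bands
of the method are not published; bounding by $[1, 25]$ with logging is
the package's choice.

Classification uses strict lower bounds: a percentage exactly on a
threshold falls in the less demanding band (4% at $\varepsilon = 4$ is
still optimal control).  The scale factor adjusts to the worst risk: the
smallest menu value $\varepsilon \in \{0.4, 1, 2, 4, 5.4, 10, 20\}$ with
$25\varepsilon \geq \max L_{pac}\%$, so the worst observed risk still
falls within the exhaustive band's reach; an explicit $\varepsilon$
always wins.  The threshold table is *regenerated* from
$\varepsilon \cdot \{1,3,5,9,15,25\}$ rather than hard-coded, because
the published comparative table contains arithmetic slips in its
$\varepsilon = 0.4$ and $\varepsilon = 2$ columns while the remaining
columns confirm the rule.

Technique and global aggregates average the *unrounded* per-risk
percentages and round only for display (half-up, like every displayed
figure).  Averaging already-rounded figures is not equivalent — for the
worked example's safety technique it gives 33 instead of 32 — and the
test suite asserts the distinction.

Two internal inconsistencies of the method's published worked example
are handled explicitly: the base parameter row prints $L_s = 5$ where
its own $A_{pac} = 3.60$ requires $L_s = 15$ (the package trusts the
computed chain, which the survey figures support), and one risk labelled
"intensive control" at 35% sits below the stated 36% bound (the package
follows the stated bounds).  Both are flagged in tests rather than
reproduced.

## The synthetic generator

`campaign_scenario()` + `generate_campaign()` simulate inspection
campaigns so the whole pipeline is testable without site data.  Each
rubric parameter draws from a categorical distribution over six *risk
levels*, where level 1 is always the safest end of the rubric: for the
aggravating parameters level 1 maps to characteristic value 1, for the
correcting parameters to 25 (best organization, highest participation).
This orientation makes scenarios comparable — "all mass on level 1"
yields the closed-form minimum of the scoring chain and lands every risk
in optimal control, and shifting mass upward can only raise L\_pac, which
is the basis of the stochastic-dominance tests.  Worker survey answers
are drawn per question; the assessor's answers are drawn conditionally
on the rounded worker mean with a configurable shift plus $\pm 1$ noise,
so the congruence ratio sweeps the $[0, 2]$ grid.  The default
(`baseline`) profile uses a negative shift — workers perceiving more
risk than the assessor — mirroring the qualitative pattern reported for
the real campaign the method was developed on, without claiming to
reproduce that campaign numerically: no per-inspection data from it is
available, so those published trend figures are covered only by the
dominance and monotonicity properties of the synthetic campaigns.

The generator default of 34 weekly inspections matches the reference
campaign's structure; test and demonstration code uses 3–50 inspections,
which keeps the whole suite under a minute on one CPU while leaving the
dominance comparisons well separated.

## What passing tests do and do not show

The worked facade example exercises every stage with published expected
values and is reproduced exactly (all ten per-risk rows, the technique
aggregates 32/34/51/20%, the selected $\varepsilon = 4$).  The
property-based suite covers the structural invariants: the exhaustive
3×3 tolerance matrix, the rounding oracle, tent-map symmetry,
monotonicity of $A_{pac}$ in all six parameters, classification
monotonicity and partition, generator determinism and dominance.  What
none of this shows is criterion validity on real sites — whether the
rubric wordings elicit consistent selections from different assessors,
or whether the survey conversions capture real emotional states.  Those
are measurement questions outside the scope of a scoring engine.

## Worked example

```{r}
fit <- assess(make_worked_example())
tidy(fit)[, c("code", "tolerance", "a_pac_display", "lpac_pct_display", "control")]
glance(fit)
```

```{r, fig.width = 7, fig.height = 4}
autoplot(fit)
```
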