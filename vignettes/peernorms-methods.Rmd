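---
title: "Methods: simulating and analysing peer-norm adjustment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing peer-norm adjustment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peernorms)
```

## The measurement model

A participant rates a behaviour twice on a discrete 11-point approval
scale: P1 before and P2 after seeing a normative cue NI. The adjustment
weight

$$S = \frac{P_2 - P_1}{NI - P_1}$$

is defined exactly when NI differs from P1 and inverts the weighted-average
update rule $P_2 = (1-S)P_1 + S\,NI$. On filler trials (NI = P1) the weight
is undefined; `compute_adjustment()` returns `NA` as the filler marker and
never divides by zero. Rounds are classified *conform* (0 ≤ S ≤ 1),
*anticonform* (S < 0) or *overshoot* (S > 1); only conform rounds enter the
models, mirroring the analysis convention that the second rating should be
a weighted average of the first rating and the cue. Because ratings are
integers, S on a distance-2 trial can only be 0, 0.5 or 1 — which is
exactly why the strategy classifier (*stay*/*compromise*/*copy*) uses a
zero tolerance by default (`tol = 0`); `tol = 0.05` is offered for
continuous re-analyses.

A consequence worth knowing: the *inversion* property holds exactly in
continuous mode and within half a grid step, $1/(2|NI-P_1|)$, in integer
mode; and on the distance-2 grid a drawn compromise weight above 0.75
rounds to a response indistinguishable from copying. With compromise
weights concentrated near their mean (Beta precision 20, below) this
relabelling affects only a few percent of compromise rounds.

## Social sources

*Majority* information is the mode of classmates' wave-1 ratings for the
item, with the focal participant's own rating excluded — "the most chosen
rating in your classroom" logically describes the others. Mode ties break
towards the smallest rating: deterministic and auditable; a
"closest-to-the-classroom-mean" rule was considered and rejected as harder
to audit for no analytical gain. *Popular-peer* information is the rating
of one of the five most-nominated classmates on a single "who is most
popular?" nomination. Popularity is nomination in-degree only; ties break
by participant id so the top five is deterministic. When the design needs
a specific cue value, the builder walks the top five in rank order
(skipping the focal participant) and uses the first peer holding that
value — whether the original task fixed one popular peer per classroom or
varied peers across items is not knowable from the published description,
and the walk-down rule is this package's choice.

## The wave-2 design builder

Each designable participant receives 12 distinct items in two 6-trial
blocks (popular / majority, order alternating across participants within a
classroom, so the popular-first and majority-first counts differ by at
most one). Within each block the layout is fully crossed: one extreme, one
moderate and one filler trial per domain. This is the only layout that
satisfies both stated marginals (2 extreme / 2 moderate / 2 filler and
3 risk / 3 prosocial) symmetrically.

Normative trials target initial ratings near the domain's typical value
(risk P1 ∈ {2,3,4}, prosocial P1 ∈ {8,9,10}) and place the cue at distance
2 towards the pole for extreme trials (risk pole 1, prosocial pole 11) and
away from it for moderate trials. A cue is only usable if the source can
actually supply it — the self-excluded mode equals it, or a top-five peer
holds it. Cells are filled scarcest-first with random tie-breaking, which
empirically maximises designability.

When a cell has no exact candidate, a relaxation ladder is tried, and any
trial it produces is flagged `relaxed`: distance 1, then distance 3, then
the same distances again with the P1 window widened by one rating. The
third stage goes beyond relaxing only the distance. The reason is
structural: in the generator (and plausibly in any real classroom),
an item's classroom mode and a participant's own rating share the item's
overall popularity, so participants near the classroom centre rarely see a
mode a full 2 points away from their own rating inside the narrow window.
With distance-only relaxation about 45% of generated participants were
undesignable; with the window stage this drops to ~20–25%, while all
exact-distance guarantees (and the structural acceptance checks, which
exclude relaxed trials) are untouched. Participants for whom some cell
still cannot be filled are excluded as *undesignable* with the failing
cell logged — the synthetic analogue of pupils the original task could not
programme.

## The generator's stated world

Defaults are fixed once, from the published cohort description where
available:

| parameter | default | why |
|---|---|---|
| classrooms × size | 5 × (15–21) | five classes, N ≈ 75–105 around 89 |
| age | truncated N(14.8, 2.1) on [12, 19] | published mean/sd/range |
| items | 36, half risk | published item bank size |
| risk means | 3.13 (sd 0.97) | published participant-level summary |
| prosocial means | 8.45 (sd 0.98) | published participant-level summary |
| risk age slope | 0.45 per sd age | clear positive trend ("older less disapproving") while the marginal sd stays within sampling error of 0.97 |
| item offsets | sd 1.0, sum-to-zero per domain | items must differ for distance-2 modes to exist; centring keeps participant-level means calibrated |
| item noise | sd 1.1 | realistic within-person spread on an 11-point scale; smaller values starve the design builder |
| nominations | 1 per pupil, P(nominee) ∝ exp(1.5·z) | simplest model with a right-skewed in-degree and a stable top five |
| update policy | calibrated mixture (below) | published condition means and strategy shares |
| filler jitter | P(±1) = 0.4, P(0) = 0.2 | E\|Δ\| = 0.8, the scale of reported baseline drift |

Ratings are generated as participant mean + item offset + noise, rounded
and clipped to 1–11. Clipping compresses means towards the scale centre
(the risk floor alone is worth ≈ +0.15), so the latent domain location is
solved by root-finding such that the *clipped* expectation equals the
configured mean — the configured values describe observed, scale-limited
data, and the generated data should too. With this correction the
generated risk mean is 3.13 ± 0.08 across seeds.

The update policy is a mixture per source × direction × domain cell:
stay (S = 0), copy (S = 1), anticonformity (−U(0, 0.5)), overshoot
(1 + U(0, 0.5)), remainder a Beta compromise. Stay/copy probabilities per
source follow the published strategy shares (28/50/22 popular, 15/39/46
majority, scaled by the 88% conform rate); anticonformity and overshoot
get their published overall rates (7%, 5%). Each cell's compromise mean is
then *solved* so the cell's conditional mean equals the source mean (0.47
popular, 0.67 majority) plus the direction-by-domain offset around the
grand mean (cell means 0.65/0.47/0.63/0.50 at the published cell sizes).
Beta precision 20 keeps compromise draws near the cell mean, so
integer-grid rounding rarely relabels them. For majority cells the
compromise mean additionally shifts by −0.07 per sd of age, emulating the
majority's declining pull across adolescence.

What the generator does **not** emulate: item content (labels are
placeholders), gender effects (composition only), classroom-level age
clustering (ages are drawn per pupil, school years assigned by cohort age
tertiles — so a classroom mixes years, unlike real year-group classes),
participation dynamics (participation rates are supplied, not modelled),
and any trial-order or session effects. A green test therefore establishes
that the pipeline's arithmetic, exclusion rules and models behave as
specified on data *with the published moments* — not that the generator
reproduces classroom micro-structure.

## Inference

Model 1 regresses conform-round S on source (majority = 1), standardized
age and their interaction; model 2 adds a four-level direction-by-domain
factor with extreme-approval-prosocial as reference. Both are
random-intercept (participant) models fitted by maximum likelihood via
`lme4::lmer` with REML off — matching the original analysis tooling — and
reported with Wald 95% CIs (± 1.96 SE) and two-tailed normal p-values.
Age enters z-scored: the published intercept equals the popular-condition
grand mean, which implies centred age; shifting all ages by a constant
leaves every coefficient unchanged. Singular fits (participant variance on
the zero boundary) are flagged, not errors; at that boundary the fixed
effects coincide with OLS, which the tests assert against `lm()`.

The stay/copy indicators get a random-intercept logistic model written in
the package rather than borrowed: the participant intercept is integrated
out by adaptive Gauss–Hermite quadrature (20 nodes centred and scaled at
each participant's Laplace mode; 50 nodes on poor convergence), the
likelihood is maximised by BFGS on (β, log σ), and standard errors come
from the numerical Hessian. Keeping the implementation in-package
preserves a genuine dual route: the test suite checks the quadrature
log-likelihood against brute-force `integrate()` to 1e-6 on small
instances, and the σ = 0 path against plain `glm()`. Likely complete
separation (runaway coefficients or a non-invertible Hessian) is flagged
in the result. The published logistic coefficient values are *not*
reproduction targets — they require the original data.

`anova_by_year` is a one-way ANOVA of participant-level wave-1 domain
means across the three school-year groups, giving (2, N − 3) degrees of
freedom — (2, 86) at the study size. Zero within-group variance is
reported as an infinite F with a degenerate flag.

## Numerical and procedural choices

- **Seeds.** One global seed; stages derive child seeds as
  `(seed + 1000003·stage) mod (2^31 − 1)`, so stages can be re-run in
  isolation and the whole pipeline is byte-identical under a fixed seed.
- **CSV dialect.** Comma, UTF-8, header row, `.` decimal, empty string for
  missing. Every stage output is re-readable by the next stage, and schema
  violations fail with named columns before any computation.
- **Classroom inclusion.** Classrooms below a 50% participation threshold
  are dropped (their sources cannot be identified robustly), with one
  machine-parsable log line per exclusion.
- **Degenerate inputs.** Filler rounds never enter S-based summaries or
  models; empty summary cells are reported `NA` (never NaN); a single
  trial yields an `NA` standard error; sub-6 classrooms are rejected at
  configuration time because a majority needs enough peers.
- **Condition-mean simulations.** Recovery targets draw S from a normal
  truncated to [0, 1] (sd 0.25) whose *truncated* mean is set to the
  target by root-finding — so truncation does not bias the generative
  mean.

## Known limitations

- Designability is ~75–80% under the default generator; the original study
  designed all retained participants, presumably because real item
  heterogeneity is richer than the generator's two variance components.
- The copy-share recovery at the stated 356-trial sample has a binomial
  standard error of ~2.6 points; checks at ±5 points will fail for
  occasional seeds. This is sampling noise at the stated size, not bias.
- The reported mean absolute change on normative trials (2.82) exceeds the
  2-point maximum implied by a strict distance-2 design with conform
  weights; this package reproduces the design's arithmetic (≈ 2 × mean S),
  and treats the published pair 0.97/2.82 as descriptive, not a target.
- The logistic model's Wald inference is asymptotic; with very few
  participants the intercept-variance estimate can sit on the boundary,
  where its standard error is not meaningful (the flag says so).
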