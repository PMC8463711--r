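---
title: "Methods: trait-linked representation bias between citizen-science platforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-linked representation bias between citizen-science platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its method: the
representation statistic, the trait construction, the mixed models, the
synthetic-data generator that validates them, and the places where the
design was genuinely open and a choice had to be made.

## The representation statistic

The unit of comparison is the (state, species) pair. On the
semi-structured platform an observation is one (checklist, species)
record; on the unstructured platform it is one occurrence row. Within
each state we regress, by ordinary least squares,

$$\log_{10} N^{\text{inat}}_{is} \;=\; a_s + b_s \,\log_{10}
N^{\text{ebird}}_{is} + \varepsilon_{is},$$

and take the residual as the species' representation score in that state:
positive means over-represented in the unstructured platform. Fitting per
state absorbs everything that differs between states but is not of
interest — observer base, effort, regional avifauna. The fit is plain OLS
(`stats::lm`); the test suite checks it against the closed-form normal
equations and its exact identities (residuals sum to zero and are
orthogonal to the predictor) on random fixtures.

**Zero counts.** A pair with zero unstructured observations cannot enter
a log model. The default `zero_policy = "drop"` excludes the pair from
that state's fit and counts it in the state fit's report; the
`"add_one"` policy (log10 of count + 1 on both axes) is available for
sensitivity analysis. Dropping matches the plain reading of
"log-transformed number of observations"; the report keeps the impact
auditable.

**Degenerate states.** States with fewer than 3 usable species are
skipped with a warning and listed in the residual table's
`skipped_states` attribute, never silently merged: with fewer points the
residual degrees of freedom vanish.

## Checklist quality filtering

Retained checklists are complete, use a non-excluded protocol (incidental
and historical are excluded by default), travelled at most 5 km, and
lasted 5–240 minutes. The exclusions are worded as strict inequalities
(travelled *more than* 5 km, lasted *less than* 5 min / *more than* 240
min), so the boundaries themselves are retained; the generator plants
checklists at exactly 5 km, 5 min and 240 min to pin this down.

Missing effort fields are resolved conservatively: a missing distance on
a stationary checklist is treated as 0 km (stationary implies no travel);
a missing distance otherwise, and a missing duration always, fail the
corresponding criterion. The filter report counts removals once per
violated criterion (a checklist can violate several) while removing each
checklist once, so `retained + removed = input` exactly.

**Prevalence trimming.** Species on fewer than `cutoff` (default 1%) of a
state's retained checklists are trimmed, per state — a species may
survive in one state and not another. The inequality is strict: a species
exactly at the cutoff survives. The denominator is the *retained*
checklist set, since trimming is described downstream of the quality
filters. Survivor sets are nested in the cutoff by construction, which
the tests verify over the standard sweep {0, 0.5, 1, 1.5%}.

## Trait construction

*Body mass*: adult body mass in grams, log10-transformed (normality of
the predictor scale).

*Color index*: from six plumage patches (upper breast, lower breast,
crown, forehead, nape, throat) per sex with RGB channels in 0–255. Two
components per species: the maximum Euclidean distance of any patch from
a brown reference, and the maximum relative luminance
$0.2126R + 0.7152G + 0.0722B$. Each component is min–max scaled over the
species set, combined as an equal-weight mean (weights configurable), and
the combination rescaled to [0, 1] — so both endpoints are attained by
some species, and the index is relative to the species set under study.

Three choices here were genuinely open:

- **Brown reference.** Sources disagree on the channel order of the brown
  anchor; the default is the standard brown (R = 102, G = 68, B = 0), and
  `brown_reference(printed = TRUE)` gives the transposed variant
  (R = 102, G = 0, B = 68) so both are one flag apart.
- **Color space.** The distance formula is defined on RGB ("cubic RGB
  color space") and that is the default; a CIE Lab variant
  (`space = "lab"`, sRGB → Lab under D65 via `grDevices::convertColor`)
  is provided because perceptually uniform distances are a defensible
  alternative.
- **Combination rule.** Scale-then-average with equal weights is the
  simplest rule that treats colorfulness and brightness symmetrically;
  the weights are exposed rather than hard-coded.

*Flock size*: the mean reported count over all checklists reporting the
species, pooled across states. Present-but-uncounted records ("X") cannot
be averaged and are excluded from numerator and denominator; their rate
is reported, and a species with only "X" records gets a missing flock
size rather than an invented one. Counts are positive integers, so the
mean is ≥ 1 and the log10 is well-defined.

*IUCN score*: ordinal, equally spaced, with Least Concern highest:
LC = 2, VU = 1, NT = 0. Equal spacing is what a single linear coefficient
for an ordinal predictor implicitly assumes. Endangered and rarer
categories are excluded (`NA`) — there are too few such species for the
level to be estimable — which is why IUCN-bearing model frames can be
smaller than the residual table.

Missing traits are flagged per species and resolved *per model*: the
global model drops a row missing any of the four predictors, while each
single-trait model only needs its own predictor. Single-trait models can
therefore use more rows than the global model, never fewer.

## The mixed models

The global model regresses the residual on all four predictors with a
random intercept per state; four single-trait models repeat it with one
predictor each. Estimation is REML via `lmerTest::lmer`; p-values use
Satterthwaite degrees of freedom (recorded in the result's method
string); 95% confidence intervals are Wald intervals, `estimate ±
z·SE` — reproducible and cheap, with the method recorded so a profile
variant could be compared. Predictors enter on their raw scales (no
standardization), so estimates read as "residual log10 units per log10
gram" and the like.

Numerical edge cases are explicit rather than accidental:

- a single state makes the random intercept unidentifiable; the fit
  degenerates to OLS on the same frame, `method = "ols"`, zero random
  intercept variance (and the tests check the fixed effects agree with
  `lm` to 1e-6);
- a singular fit (random-intercept variance estimated at zero) is
  reported with `singular = TRUE`, not an error — in this design it is
  *expected*, because per-state OLS centers the residuals within states,
  leaving almost no state-level variance for the random intercept;
- a constant predictor is refused by name;
- nonconvergence sets `converged = FALSE` with lme4's diagnostics
  attached instead of throwing.

Sign disagreement between a global estimate and its single-trait
counterpart is flagged only when both intervals exclude zero; with
independently generated traits the two agree up to omitted-variable
leakage through finite-sample trait correlations, which shrinks as
$1/\sqrt{n_{\text{species}}}$.

## What the generator emulates — and what it does not

`generate_traits()` draws a species pool: log10 body mass Normal(1.6,
0.45) (median ≈ 40 g, spanning kinglets to raptors), log10 flock size
Normal(0.4, 0.35) truncated at 0 (flocks of at least one bird), a
Beta(1.2, 1.8) colorfulness target (most species dull, a bright tail),
and Red List categories with probabilities (0.92, 0.04, 0.03, 0.01) for
(LC, NT, VU, EN) — a Least-Concern-dominated pool with a handful of
endangered species so their exclusion is exercised. Plumage patches are
constructed along the brown→white segment so that the *computed* color
index tracks each species' target; both index components are strictly
increasing along that segment. Traits are drawn independently by default;
a correlation knob links body and flock size if wanted.

`generate_counts_direct()` plants the representation model itself:
semi-structured counts are log-normal on the count scale, truncated at 1
and scaled by state effort (positively skewed, as real per-species counts
are); unstructured counts follow
$\log_{10} N^{\text{inat}} = a_s + b\,\log_{10} N^{\text{ebird}} +
\sum_j \gamma_j x_j^{(c)} + \text{Normal}(0, \sigma)$
with *centered* traits (so state intercepts and trait effects are
orthogonal by construction), rounded to a nonnegative integer. Rounded-to-
zero rows are flagged, never dropped, so the zero policy is testable. The
default state intercepts center on −2.3 — a ~200:1 ratio between the
platforms, the order observed in aggregate US data.

`generate_event_level()` builds checklist-level data: per-state
checklists with planted, disjoint, *labeled* quality violations
(defaults: 16% incomplete, 6% excluded protocols, 4% over-distance, 3%
under-duration, 2% over-duration — plausible rates for a raw
semi-structured export), per-checklist species detections with reported
counts and a 3% "X" rate, and unstructured occurrences generated from the
planted model applied to the clean aggregates. Because desk-scale
checklist counts (hundreds per state) times a 200:1 ratio would round
almost every unstructured count to zero, event-level truth defaults to
intercepts around −0.5; this is a scale choice for the checklist-level
regime, not a claim about real platform ratios.

One master seed drives everything through deterministic sub-streams, so
identical configs give byte-identical tables — the full pipeline is
bit-reproducible, and its artifacts deliberately carry no timestamps.

Not emulated: spatial structure, observer-level behavior, seasonal effort
cycles, taxonomy mismatches between platforms, and misidentification.
Passing recovery tests therefore show that *the pipeline's inference is
correct when the data follow its model*; they do not show that real
platform bias is fully captured by these four traits.

## Validation design and problem sizes

The recovery harness (`simulate_recovery()`) runs replicates of 40 states
× 150 species with planted effects (body 0.05, flock 0.05, color 0, IUCN
0.03 on the log10 scale) and residual noise 0.05; the acceptance checks
use 200 replicates with consecutive seeds, and report per-trait bias,
RMSE, 95% CI coverage and the null effect's 5%-level rejection rate.
Filter validation uses a 10,000-checklist labeled bundle; the OLS
identities use 100 random fixtures; prevalence trimming is recounted
brute-force on 20.

**Count scale.** Recovery runs at state efforts with median 200,000
checklists, which puts the simulated semi-structured volume at the order
of the real aggregate extracts (~10^8 records) and makes unstructured
counts large. This matters: at much smaller scales the integer rounding
of unstructured counts stops behaving like independent noise — a species
stuck at the same small count across many states acquires
species-correlated errors that the iid mixed model does not represent,
and CI coverage degrades even though bias stays negligible. That regime
is a documented limitation of the statistic at low counts, not of the
estimator: interval coverage is nominal when counts are large, and
applications with mostly single-digit unstructured counts should expect
intervals that are somewhat too short.

## Known limitations

- The color index is relative to the species set; indices from different
  species pools are not comparable.
- Flock size from reported counts conflates gregariousness with local
  density; it is a proxy, and measurement error in it attenuates its
  coefficient in real data (the generator plants the trait the model
  sees, so recovery tests do not probe this).
- The zero policy interacts with the planted model: dropping zero pairs
  is a mild selection on the noise at very small counts.
- Wald intervals and Satterthwaite p-values are approximations; at the
  validated problem sizes they are accurate, but tiny designs (few
  states, few species) should prefer the single-state OLS degenerate
  path or profile intervals computed externally.
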