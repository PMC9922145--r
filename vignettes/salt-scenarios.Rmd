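---
title: "Modelling salt reduction through umami substitution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling salt reduction through umami substitution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltscen)
library(dplyr)
```

## The question and the model

Reformulating processed foods with umami substances — monosodium glutamate,
calcium diglutamate, inosinate, guanylate — lets manufacturers remove part of
a product's sodium without loss of palatability. Given a food-diary survey of
adults, `saltscen` asks: *how much daily salt could this population forgo if
umami reformulation were applied to the food categories where taste-panel
evidence exists?*

The pipeline works at the level of the individual diary. For participant $i$,
every diary record contributes sodium equal to `amount_g x density / 100` mg
(or an explicit per-record total where the extract provides one), converted
to salt equivalent by the fixed factor

$$\text{salt (g)} = \text{sodium (mg)} \times 2.54/1000,$$

and averaged over the participant's own recorded diary length (3 or 4 days)
to give a daily intake. Records are resolved to at most one of eleven
umami-substitutable categories (cheese, sausage, chicken broth, salted fish,
miso, soy sauce, snacks, vegetable soup, potato chips, salted vegetables,
butter); $S_{ij}$ denotes participant $i$'s daily salt from category $j$.
Each category carries a lower and an upper sodium-reduction rate
$(L_j, U_j)$ from the taste-panel literature — the fraction of that
category's sodium removable without taste loss — and a market-share scenario
$M_k \in \{0, 0.3, 0.6, 0.9\}$ assumes that a fraction $M_k$ of consumed
products is already low-sodium, leaving only $(1 - M_k)$ of the salt
addressable. The achievable reduction is bounded by

$$\Delta^{L}_{ijk} = S_{ij} \, L_j \, (1 - M_k), \qquad
  \Delta^{U}_{ijk} = S_{ij} \, U_j \, (1 - M_k),$$

summed over categories per individual and averaged, unweighted, within
gender × decade age-band strata.

### Why the multiplicative form

The model is deliberately multiplicative in the rate. Two structural facts
pin it down: a category whose entire sodium content can be replaced (butter,
rate 1.0) must be eliminated completely at $M = 0$, and the reduction under
market share $M$ must be exactly $(1 - M)$ times the share-0 reduction —
scenario 4 is one tenth of scenario 1. Both follow immediately from
$\Delta = S \cdot r \cdot (1 - M)$ and from no other attachment of the rate,
and both are enforced as exact (tolerance $10^{-12}$) properties in the test
suite. The wider rate bound is attached to the upper reduction
($U_j \ge L_j$ implies $\Delta^U \ge \Delta^L$).

No uncertainty is propagated beyond the lower–upper interval: the rates are
reported as ranges, not distributions, so the output is a deterministic
envelope rather than a confidence interval.

## The category registry

`default_registry()` holds the eleven categories with their rate bounds
(percent in config files, fractions in memory) and match specifications.
Matching is two-stage and suffix-blind: a record's *main-group code* is
checked first; only if no rule claims it is the digit part of the subgroup
*food code* compared against registry prefixes. Validation at load time
rejects any specification in which one code could reach two rules
(overlapping main groups, nested prefixes, or a prefix equal to another
rule's main-group code), so matching is a pure function.

Six categories (chicken broth, salted fish, miso, soy sauce, vegetable soup,
salted vegetable) ship **unmatchable**: their source literature identifies
them only as "codes whose first one or two digits correspond", without
stating the codes, and survey code books change between releases. Shipping a
guess would silently change results; shipping nothing makes the omission
explicit and forces the analyst to supply codes for their survey version.
`synthetic_prefix_overlay()` assigns clearly-labelled placeholder prefixes
(50–55) so that simulations and tests can exercise all eleven categories;
the example file `inst/extdata/synthetic_prefix_registry.yaml` shows the
config format.

## Reporting conventions

Strata are total/women/men × seven decade bands (20–29 … 70–79, 80+,
inclusive lower edges) plus an "All" row; means are unweighted arithmetic
means (sampling weights are intentionally unsupported — the pipeline
describes the individual-level intake distribution of the diary sample) and
SDs use the $n-1$ denominator. Empty strata are omitted with a warning,
never zero-filled.

Printed precision is 2 decimals, except the 90 %-share gram column, which
gets 3 decimals because its values are an order of magnitude smaller.
Rounding is half-up at the printed precision, implemented directly
(`round_half_up()`) because base R rounds halves to even.

The percentage table divides the *rounded* stratum mean reduction by the
*rounded* stratum mean intake, then rounds to 2 decimals. Computing rates
from rounded tables rather than from unrounded microdata is a deliberate
fidelity-over-elegance choice: it is the only convention a reader can verify
from the printed tables alone, and it is the convention the published UK
tables this package is calibrated against are internally consistent with
(e.g. the share-30 % cells reproduce only when the rate is formed from the
2-decimal gram values). `reduction_rate_table(..., rounded = FALSE)` gives
the unrounded variant.

```{r printed-reconstruction}
reduction_rate_table(reference_reduction_g(), reference_intake()) |>
  filter(age_band == "All", stratum == "total") |>
  select(k, market_share, rate_lower_pct, rate_upper_pct)
```

## The synthetic survey generator

Access-restricted microdata cannot ship with a package, so `saltscen`
includes a generator whose defaults emulate the published structure of the
UK National Diet and Nutrition Survey adult cohort 2016/2017–2018/2019:
1834 adults aged 20+ (1076 women, 758 men) with the published gender ×
age-band counts, ages uniform within bands (80+ drawn from 80–95), and a 3 %
chance of a 3-day rather than 4-day diary.

Each participant's mean daily salt intake is drawn from a log-normal
distribution moment-matched to the published mean and SD of their stratum —
the publication reports only means and SDs, and log-normality keeps intakes
positive and right-skewed, as dietary intakes are. Salt is spread over diary
days evenly up to multiplicative log-normal noise (SD 0.1 on the log scale),
renormalised so the diary mean reproduces the drawn value exactly; since the
analysis uses only the mean, the day split is inert by construction. A fixed
fraction of each individual's salt is assigned to the eleven categories (one
pseudo-record per category per day — sufficient because the pipeline is
linear in sodium) and the remainder to unmatched filler codes. Sodium
densities per category are drawn from plausible mg/100 g ranges; they only
determine the consumed grams, to which the analysis is insensitive.

Two generator parameters have no published counterpart and are explicit
placeholders:

* **category share weights** — no UK data describe how salt from these
  eleven categories splits between them, so the default is uniform;
* **`substitutable_fraction`**, the share of total salt coming from the
  eleven categories, default **0.327**. This is calibrated in closed form:
  the expected share-0 upper reduction is
  $f \cdot \bigl(\textstyle\sum_j w_j U_j\bigr) \cdot \bar S
  = 0.327 \times 0.568 \times 4.95 \approx 0.92$ g/day, matching the
  published all-adult upper bound, and placing the default run's scenario-1
  rates (≈12.5–18.6 %) inside the published 9–19 % band. With uniform
  weights both bounds cannot be matched at once
  ($\sum_j w_j L_j / \sum_j w_j U_j = 0.67$, versus 0.49 in the published
  bounds); matching the upper bound was chosen once, at the closed form,
  and the lower bound is simply what uniform weights imply.

Because each individual's reduction is an exact linear multiple of their
intake under this generator, the closed-form expectation
$(1 - M_k) \, f \, \sum_j w_j r_j \, \bar S$ is also the exact per-capita
value given the realised intakes — the Monte-Carlo error lives entirely in
the intake draw. `recover_parameters()` reports z-scores of every stratum
mean against its target using the configured SD and stratum size; the test
suite requires $|z| < 3$ throughout.

What passing these tests shows — and does not show. They demonstrate that
the pipeline is arithmetically faithful: conversion, matching, scenario
scaling, aggregation and rounding reproduce the published table arithmetic
exactly, and parameter recovery works at survey scale. They do not validate
the generator as a model of real diets: real diaries have item-count,
portion-size and day-of-week structure, nutrient correlations, and a
non-uniform category composition that the placeholders above do not attempt
to capture. Results on real microdata depend on the registry codes supplied
for the six unmapped categories.

## Numerical and degenerate-input choices

* Day divisor: each participant's own recorded diary length. Diaries of
  length 2 or less are rejected at validation (the survey design permits
  only 3 or 4); a participant with no diary records raises an explicit
  error rather than contributing zero, to surface linkage bugs.
* Conservation: category rows (including the unmatched remainder) partition
  each total intake to within $10^{-9}$; the remainder is computed by
  subtraction so the partition is exact by construction.
* Single-member strata report a mean and a missing SD.
* Zero intake, zero reduction, empty cohorts and empty files all
  short-circuit to well-typed empty or zero results, tested explicitly.
* Problem sizes in the test suite: property checks run on 50-person random
  fixtures; recovery runs once at the full 1834-participant default (a few
  seconds) and once on a reduced 14 × 60 cohort.

## Limitations

Discretionary (cooking and table) salt is outside the diary-based estimate,
so intakes are lower than urinary-excretion estimates for the same
population; the market share $M$ is assumed uniform across categories; rate
evidence is thin for some categories and enters only as a lower–upper
envelope; and the six unmapped categories contribute nothing until codes
are supplied, making default-registry results on real data conservative.
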