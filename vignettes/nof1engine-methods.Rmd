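---
title: "Methods and design choices in nof1engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in nof1engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nof1engine)
```

## The experimental design

An N-of-1 trial applies one or two conditions to a single person in a
sequence of phases with crossover, so the comparison of interest is *within*
the individual rather than across a population. `nof1engine` implements the
two simplest single-case designs:

* **withdrawal**: one intervention, evaluated by alternating intervention (A)
  and no-intervention (B) phases;
* **alternating treatment**: two interventions compared head-to-head, the
  first in A phases, the second in B phases.

Phase label A is always bound to the first-entered intervention. The design
is coupled to the intervention count (1 for withdrawal, 2 for alternating
treatment) and `validate_trial()` enforces the coupling.

### Balanced phase sequences

Phases are always generated in AB or BA *pairs*, so every sequence contains
equally many A and B phases. Unbalanced sequences such as AABB confound the
condition with time when temporal effects (trends, learning, season) are
present; pairing removes that degree of freedom by construction. Two orders
are offered:

* `alternating`: the AB pair repeated, ABAB…;
* `counterbalanced`: pair orientation alternates — odd pairs AB, even pairs
  BA — giving ABBA for $p = 2$.

The classical counterbalanced motif is only defined for two pairs (ABBA).
For $p > 2$ this package extends it **blockwise**: every consecutive group
of two pairs forms an ABBA block, so $p = 3$ yields ABBAAB. This is a design
choice of the package, not a published rule; it preserves balance, keeps the
ABBA motif in every complete 4-phase block, and reduces to the classical
sequence at $p = 2$. Randomized phase orders are deliberately not offered:
blinding and randomization are hard to execute faithfully in self-administered
trials, and the engine's scope is the descriptive, user-run setting.

The default schedule is $d = 7$ days per phase and $p = 2$ pairs in
alternating order — ABAB over 28 days. One week per phase is long enough for
slow-acting behavioural interventions to show while keeping a first trial
to a month.

Day indexing is 1-based with inclusive spans; calendar dates are whole local
days with no time component, matching an engine whose data never leave one
device (no cross-timezone semantics are defined).

## Trial documents

A trial serializes to a single JSON object with exactly four component
categories (`goal`, `interventions`, `measures`, `schedule`) plus `id`,
`design`, `created_at`. Serialization is canonical — sorted keys, arrays kept
as arrays, optional fields omitted — so documents are diffable and
`trial_from_json(trial_to_json(s))` is the identity, which the test suite
asserts on thousands of randomly generated specs. Parsing distinguishes
malformed JSON (*parse* error) from well-formed JSON that is not a valid
trial (*schema* error), and a `partial = TRUE` mode tolerates missing
sections so that completeness can be *reported* by `validate_trial()` rather
than thrown, mirroring a step-by-step creation flow. Ids are caller-supplied
or auto-generated UUID-format strings.

## Tasks and reminders

Each intervention and measure carries its own reminder policy: one or more
strictly increasing times of day and a recurrence, `daily` or
`every_x_days` with $x \ge 2$. `every_x_days` is anchored at trial day 1
(days $1, 1+x, 1+2x, \dots$), not at phase boundaries — the simplest
consistent reading of "every x days"; re-anchoring at each phase start would
make task counts depend on phase length in unintuitive ways.

The task calendar is the cross product of covered days and reminder times,
with one policy interaction: **intervention tasks are suppressed on
withdrawal B days**. Whether a real app does this is not observable from the
outside; the engine suppresses them because a reminder to perform the
intervention during a no-intervention phase would instruct the participant to
break the design. Measures are collected in *all* phases regardless of
design, since phase comparison needs data on both sides. A task not completed
by the end of its calendar day becomes `missed`; adherence is
completed / (completed + missed + pending past-due).

## Recording

Values are validated against the measure's input type at entry, with a
distinct condition class per failure (not a number, item not in list, scale
out of range, timestamp outside the trial), so front-ends can branch on the
class. Scale values are treated as real numbers within $[\min, \max]$ — the
engine does not assume integer ticks — and scale annotations are display
metadata only. Units are labels, not dimensioned quantities; no conversion is
attempted. Multiple observations of one measure on the same day are all
retained.

The log stores values as text (numbers formatted losslessly), which lets
numeric and categorical measures share one tidy container and makes the CSV
round-trip exact; aggregation re-parses numerics on the fly.

## Summaries

The by-day and by-phase aggregates use the arithmetic mean. The phase mean
**pools raw observations** rather than averaging daily means: days with more
entries weigh proportionally more. Both readings of "averaged by phase" are
defensible; pooling was chosen because it equals the sample mean whose
standard error the accompanying t-test uses, and the equivalence with a
brute-force pooled computation is asserted property-style in the tests. Days
and phases without data are omitted, never imputed.

The phase contrast is $\bar{y}_A - \bar{y}_B$ (intervention minus control,
or first minus second intervention). The optional test is the **Welch**
(unequal-variance) two-sample $t$-test — a robust default since nothing
guarantees equal variances across phases — computed via `stats::t.test` and
cross-checked in the tests against the textbook formula at $10^{-10}$
tolerance. Only a single contrast per measure is computed, so no
multiple-testing correction is applied; observations are treated as
exchangeable within phase type, i.e. autocorrelation and carryover are
ignored. That makes the p-value descriptive rather than confirmatory, which
matches the engine's purpose.

## The simulated participant

The simulator exists so the whole engine is testable without human data. Its
outcome model for a completed measurement on day $t$ is

$$ y = \mu + \delta_{\text{active}(t)} + \beta t + \varepsilon,
   \qquad \varepsilon \sim N(0, \sigma^2), $$

where $\delta_{\text{active}(t)}$ is the effect of the intervention active on
day $t$ (zero on withdrawal B days). Every task is completed independently
with probability $q$; missed measurement tasks leave no observation. Scale
values are clipped to the instrument's bounds *after* noise, as a bounded
instrument would censor them. List measures are skipped by default or drawn
uniformly at random on request — no effect-shifted categorical model is
implemented.

Defaults ($\mu = 5$, $\delta = 1$, $\beta = 0$, $\sigma = 1$, $q = 0.9$)
describe a mildly effective intervention — a standardized effect of one noise
SD — measured daily by an engaged but imperfect self-tracker; $q = 0.9$ is at
the optimistic end of self-report adherence. These values are fixed once and
used as the stated world of the parameter-recovery tests.

What the generator does **not** emulate: autocorrelated or carryover
responses, learning/placebo dynamics, time-varying adherence (e.g. weekend
dips), or informative missingness. A green parameter-recovery test therefore
establishes that the pipeline is unbiased under its own assumptions, not that
the Welch contrast is valid for strongly autocorrelated real series.

Cohorts derive per-participant seeds from a master seed via the fixed scheme
$(10007 \cdot \text{master} + i) \bmod (2^{31}-1)$, keeping every seed a
valid 32-bit integer while giving distinct, reproducible streams. The
simulator saves and restores the global RNG state, so it never perturbs a
caller's random sequence.

## Numerical and degenerate-input choices

* Day→phase lookup is integer arithmetic ($\lceil t/d \rceil$), exact for
  all inputs; out-of-range days are rejected, not clamped.
* Contrasts require at least one observation per phase type (two with the
  test); anything less raises `nof1_error_insufficient_data` rather than
  returning NaNs.
* Task status only moves `pending → completed` or `pending → missed`;
  re-completion is an error.
* Ties in the task calendar (same time) order by kind, then component id, so
  the calendar is deterministic.
* The equal-variance zero-noise edge case ($t = 0/0$) cannot arise from the
  contrast's guard: with identical samples the numerator is exactly 0 and
  `t.test`'s statistic is 0 whenever the pooled SE is positive; all-constant
  samples raise an error from `stats::t.test`, surfaced as-is.

## Known limitations

One goal per trial (multi-goal trials are out of scope); exactly the two
designs above, no washout phases; no blinding or randomization; no
imputation; no Bayesian or mixed-model analysis; no power-based schedule
recommendation. The component library ships four linked goals with three
suggested interventions each plus a small set of general templates — the
general entries are implementer-chosen examples, marked as such by their
presence outside the linked set, and the library file can be extended without
code changes.
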