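---
title: "Speaker knowledge, contextual alternatives, and the strength of scalar implicature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speaker knowledge, contextual alternatives, and the strength of scalar implicature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altrsa)
library(dplyr)
```

## The phenomenon and the model

When a speaker says "some of the letters have checks inside", listeners often
conclude that *not all* of them do — a scalar implicature driven by the
utterance the speaker chose *not* to use ("all"). Two contextual factors
modulate this inference. First, **speaker knowledgeability**: if the speaker
has only examined two of the three letters, they may not have been in a
position to assert "all", so the implicature weakens. Second, the **set of
alternative utterances** the speaker plausibly chooses among: a speaker who
habitually uses numerals ("2 of today's rooms...") could have said "two" after
seeing two positive cases, so hearing "some" instead is informative even when
their knowledge is partial.

`altrsa` implements a Rational Speech Acts (RSA) model that combines both
factors and a simulation/analysis pipeline for the 2×2
(knowledgeability × numeral-exposure) rating experiments used to test it.

### Model structure

The world is the number of property-bearing objects among $N$ (all scenarios
here use $N = 3$), with prior $P(w)$ over $\{0, \dots, N\}$. Three layers of
recursion:

1. **Literal listener** $L_0(w \mid u) \propto P(w)\,\mathbb{1}_{w \in [\![u]\!]}$:
   the prior restricted to the utterance's literal meaning
   (`literal_listener()`).
2. **Knowledge-limited speaker.** The speaker has examined $a$ of the $N$
   objects — a uniformly random subset without replacement, so the number of
   positives they observe is hypergeometric (`observation_model()`). Their
   belief over worlds is the Bayesian update of the prior by that likelihood
   (`knowledge_state()`). An utterance's utility is the belief-weighted log
   score $U_1(u \mid s) = \sum_w P(w \mid s)\log L_0(w \mid u)$, $-\infty$ if
   the utterance is false in any belief-supported world, and the speaker
   chooses by softmax, $S_1(u \mid s, A) \propto e^{\alpha U_1(u \mid s)}$
   over the alternative set $A$ (`speaker_distribution()`).
3. **Pragmatic listener**
   $L_1(w \mid u) \propto \sum_A P(A) \sum_o P(w)\,P(o \mid w)\,S_1(u \mid s(a, o), A)$:
   Bayesian inversion of the speaker, marginalizing over the speaker's
   unobserved knowledge state *and* over which alternative set the speaker is
   using (`pragmatic_listener()`).

Alternative sets: the core inventory is {none, some, all}; the with-numerals
set adds {one, two, three} under *lower-bounded* semantics ("two" = at least
two); exact readings of numerals emerge pragmatically, not lexically. No
numeral above $N$ is consistent with the scenario, so the inventory stops
there. $P(A)$ is a two-point mixture with weight `p_with_numerals` on the
with-numerals set; 0 and 1 are the experimental conditions and intermediate
values model a listener who is unsure which inventory the speaker uses.

### Parameters that matter

* `alpha` (softmax rationality, unitless, default 1): 0 gives an indifferent
  but still truthful speaker; large values approach utility maximization. The
  plain softmax corresponds to `alpha = 1`. The headline condition table uses
  `alpha = 3`, which makes both full-knowledge cells round to 98%; the
  qualitative predictions below hold over the whole `alpha` in [1, 10] range
  (they are tested as properties, not at a single point).
* `access_partial` / `access_full` (objects examined, default 2 vs 3): the
  knowledgeability manipulation.
* `p_with_numerals` in [0, 1]: the alternatives manipulation.
* The world prior (default uniform). The experimental cover stories suggest a
  prior tilted toward the all-world; a uniform prior is the most conservative
  neutral choice, and tilting the prior moves all four cells up without
  changing the ordinal predictions.

### What the model predicts

```{r predictions}
tab <- predict_condition_table(rsa_config(alpha = 3))
tab
```

Three qualitative signatures, all of which are verified as properties in the
test suite:

* a **knowledgeability effect**: both full-knowledge cells exceed both
  partial-knowledge cells;
* **no effect of alternatives under full knowledge**: with full access, "all"
  dominates "three" and the numerals barely matter (the two full cells agree
  to within 0.02 for `alpha` in [1, 5]);
* an **interaction**: under partial knowledge, numeral availability
  strengthens the implicature (here 0.797 vs 0.625), so the knowledgeability
  gap shrinks when numerals are available.

A useful structural fact: with the core alternatives only, a partial-access
speaker who saw at least one positive can assert *only* "some", so the
softmax sharpness cancels and the partial/no-numerals cell is exactly
`alpha`-invariant (5/8 under the uniform prior). This is why the rationality
parameter can be probed with the other three cells alone.

### Numerical conventions

All products in the listener recursion are accumulated in log space and
normalized with log-sum-exp. A knowledge state in which *no* alternative is
assertable (e.g. examined 2 of 3, saw 0, core alternatives only — "none" is
false at the unexamined letter's world, "some" is false at the observed
zeros) is a **mute state**: softmax over all-$-\infty$ utilities is
undefined, and treating the state as producing nothing is the unique
convention that keeps $L_1$ a proper conditional. Degenerate priors are
allowed; utterances whose meaning has no prior mass raise an explicit
"uninterpretable utterance" error rather than propagating NaNs, and an
utterance no reachable state would produce raises an "unproducible
utterance" error. Percentages in condition tables are rounded to the nearest
integer for display; raw probabilities are kept at full precision.

## The synthetic-data generator

`generate_dataset()` emulates the structure of the rating experiments:

* 240 participants by default, split into equal between-subject exposure
  groups (numerals vs no numerals in the filler trials);
* 32 trials per participant: 8 targets (4 partial-, 4 full-knowledge, the
  within-subject factor) and 24 exposure trials, pseudo-randomized so that
  the first trial is an exposure trial and no two targets are adjacent;
* ratings on the 0–100 "probability that all items have the property" scale:
  cell mean + participant effect + item effect + residual (all Gaussian),
  **truncated** to [0, 100] by drawing the residual from its conditional
  distribution on the admissible window (truncation, not clamping);
* knowledgeability is assigned to target items independently per participant,
  so item effects counterbalance out of all three effect contrasts;
* two Boolean comprehension answers per trial, wrong independently with
  `comprehension_error_rate` (default 0).

The default calibration (`gen_params_exp2()`) takes the four observed cell
means of the second rating study (45.4 / 52.3 / 64.7 / 62.0 on the not-all
scale) and the pooled total SD of its cells (≈ 33.5). The study reports no
variance decomposition, so the split is an explicit assumption — 40%
participant, 10% item, 50% residual, exposed as an argument. Exposure-trial
ratings are centered on the grand mean of the four cell means; they are
generated for realism but never analyzed.

**Truncation bias.** With SDs this large, the [0, 100] bounds bind: the
population mean of a cell differs from its nominal (latent) mean by several
points, and by different amounts in different cells (a cell at 35 is pulled
up more than a cell at 55 is pulled down). `expected_cell_means()` computes
the exact population means in closed form (truncated-normal mean integrated
over the participant + item shift), and `expected_effects()` the implied
contrasts. Parameter-recovery checks therefore compare estimates to these
population quantities — the quantities the data actually carry — not to the
latent inputs. When the bounds barely bind (cell means a few total SDs inside
the scale), the two coincide to within a rating point.

What the generator does *not* emulate: order/adaptation effects across
trials, non-Gaussian response styles (end-point clumping, 5-point rounding),
per-cell variance differences, and any dependence of comprehension errors on
condition. Passing tests on this generator show that the pipeline recovers
the effects present in data of this factorial shape and noise scale — not
that the behavioral effects themselves are true.

## The analysis pipeline

The studies fit mixed-effects regressions with ±0.5 contrast codes. This
package deliberately estimates the same fixed-effect quantities with a fully
specifiable substitute (`estimate_effects()`): per-participant cell means of
the not-all rating, averaged into the four design cells, combined by the
contrast algebra

* intercept = grand cell mean,
* knowledgeability = full − partial,
* exposure = with − without numerals,
* interaction = knowledgeability effect with numerals − without
  (negative when numerals shrink the gap),

with percentile intervals from a nonparametric bootstrap that resamples
participants within exposure group (2000 resamples by default; exposure is
between-subject, so groups are resampled separately). On balanced data this
estimator coincides with the regression's fixed effects; no REML machinery,
degrees of freedom, or p-values are involved. The test of "significance" is
the 1 − `alpha_level` percentile interval excluding zero. Participants with a
missing cell (possible after trial-level exclusions) contribute their
available cells, with the count reported.

`simple_effects()` gives the follow-up exposure contrast within one
knowledgeability level, `exclusion_filter()` applies the participant-accuracy
(default 87.5%) and per-trial comprehension exclusions, and
`power_analysis()` wraps the generate–fit loop into a Monte-Carlo power curve
for the interaction. Under a zero-interaction generator the same loop is a
type-I error check; the suite verifies the rejection rate sits within
Monte-Carlo error of the nominal 5% at 500 simulations.

Problem sizes used in the shipped tests (the package's own choices, balancing
resolution against Monte-Carlo error): recovery at 2000 participants over 10
seeds, size calibration with 500 simulations of 240 participants at 1000
bootstrap resamples, coverage checks with 100 simulations.

## Open design choices made here

* **Rationality parameter.** The printed softmax has no sharpness parameter;
  `alpha` is exposed as a generalization with default 1. `alpha = 3`
  reproduces the two full-knowledge table values (98, 98). The published
  partial-knowledge table values (86, 91.2) are *not* reproducible under
  these equations for any `alpha` with the conventions above (this model
  yields 62.5 and ≈ 79.7 at `alpha = 3`); whatever convention produced them
  is not recoverable from the printed equations, so the partial cells are
  validated ordinally (direction of the simple effect, shrinkage and sign of
  the interaction, `alpha`-invariance of the no-numerals cell), never
  numerically.
* **Observation law.** "Examined a subset" is formalized as a uniformly
  random subset without replacement — hypergeometric — which exchangeability
  of indistinguishable objects forces unless examination order carries
  information.
* **Speaker belief.** The speaker's belief over worlds is the genuine
  Bayesian posterior (prior × hypergeometric likelihood), not a uniform
  distribution over the compatible set.
* **Fixed access.** The listener is assumed to know `a` exactly (it is
  asserted in the stimulus sentence); uncertainty over access is not
  modeled.
* **No recursion beyond $L_1$**, and no exact-semantics numerals.

## Reproducibility

The core model is deterministic. All simulation entry points take one master
seed; per-participant generator streams are derived from it, so participant
$i$'s data do not depend on how many participants are requested, and
identical config + seed yields byte-identical CSV output. The command-line
driver (`inst/cli/altrsa.R`) writes a JSON manifest (command, config
snapshot, seed, package version, timestamp, outputs) next to every output
file.
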