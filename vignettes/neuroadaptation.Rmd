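---
title: "Modeling neuroadaptation to chronic antidepressants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling neuroadaptation to chronic antidepressants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monoadapt)
```

## The scientific question

Clinically, antidepressants block their targets within hours but help only
after weeks, and identical regimens produce heterogeneous outcomes. The
model in this package formalizes one explanation: chronic drug
administration perturbs the collective activity of the monoamine-producing
nuclei; the brain then adapts *homeostatically* by adjusting receptor
sensitivities until activity is restored toward baseline; and because many
different receptor configurations restore activity about equally well,
individuals can arrive at different endpoints — only some of which also
elevate the monoamines enough to relieve depression.

## The network

Six sigmoidal rate units interact recurrently: the dorsal raphe (DR,
releasing 5HT and co-releasing galanin and glutamate), locus coeruleus
(LC, releasing NE and galanin), ventral tegmental area (VTA, releasing
DA), and three non-monoaminergic systems standing for the CRF-, galanin-,
and glutamate-releasing populations (tCRF, Tgal, Tglu). Connections onto
the three nuclei are mediated by the predominant receptor for each
arriving transmitter, each with a fixed polarity and a strength in
$[0, 10]$; connections onto the non-monoaminergic units are 18 generic
signed weights, because those units stand for heterogeneous populations
with no single predominant receptor. `mono_connections()` lists the full
wiring.

Each unit computes the sum of its drives, adds a bias, and squashes:

$$a_u(t+1) = \sigma\!\Big(\textstyle\sum_i d_i(t) + b_u\Big), \qquad
\sigma(x) = \frac{1}{1+e^{-x}}.$$

Release is proportional to activation. The transported monoamines (5HT,
NE, DA) are additionally reduced by reuptake: the presented amount is
$(a + r)(1-\tau_\mathrm{eff})$ where $r$ sums any releaser-drug
magnitudes and $\tau_\mathrm{eff} = \tau \prod_i (1-b_i)$ composes
reuptake blockades multiplicatively on the transporter efficacy
$\tau \in [0,1]$. Galanin, glutamate, and CRF are presented at the
releasing unit's activity unchanged — there is no transporter term for
them, which is why receptor strengths on those pathways have a much
stronger effective gain than equal-valued monoamine receptor strengths.

A receptor population on a nucleus has *one* strength parameter even when
its ligand arrives from several sources (galanin reaches DR's galR1 from
both LC and Tgal): the receptor population on the neuron is single, so
the drives share the strength while summing over sources.

### Numerical and structural choices

* **Squashing function.** The standard logistic: smooth, strictly
  increasing, range $(0,1)$, $\sigma(0)=0.5$. Any gain factor is absorbed
  by the calibrated strengths and biases, so no slope parameter is
  exposed.
* **Update scheme.** Synchronous update of all six units per step, the
  standard choice for discrete-time rate models. Time steps are unitless;
  the model reproduces average activations, not oscillation frequencies.
* **Evaluation protocol.** Activities start at 0 and run for $T = 150$
  steps under a maintained regimen. The *activation* of a unit is the
  mean of steps 75–150 inclusive (76 samples). Inhibitory autoreceptor
  self-connections and asymmetric interconnections make the units
  oscillate; after the initial transient the window average is stable to
  well under $10^{-3}$, which the test suite asserts on the shipped
  fixture from step 50 onward.
* **Drug mechanisms.** Antagonists scale the transmitter-bound drive of
  their site by $(1-m)$ — occupancy scaling rather than subtraction, so a
  full antagonist exactly silences the transmitter term and can never
  invert a drive's sign. Agonists add a direct occupancy term
  $\mathrm{polarity}\times\mathrm{strength}\times m$, counted once per
  site. Partial agonists (aripiprazole at D2) are an agonist + antagonist
  pair at the same site. Releasers add to the pre-reuptake amount.
  Drug-target magnitudes all live in $[0,1]$ and are members of the
  parameter set, i.e. calibrated quantities: the shipped registry fixes
  each drug's *targets and mechanisms* (from their established
  pharmacology) but not their effect sizes.
* **Affine compilation.** All drug and transporter effects are affine in
  the source activities, so a (parameter set, regimen) pair compiles once
  to $x \mapsto \sigma(Mx + c)$; the simulator iterates that map. The
  explicit per-connection update (`step_network()`) is retained and the
  tests verify both paths agree to machine precision.

## Calibration

The composite calibration error simulates every regimen referenced by a
target table plus the no-drug baseline and returns the weighted RMS of
the residuals over rows. Three row types are supported: percent
activation changes of a nucleus under a regimen, baseline activations,
and absolute transmitter levels. Rows are equally weighted by default and
per-row weights are user-configurable, since the appropriate mix of
percent-scale and activation-scale rows is an empirical choice.

Optimization uses a real-coded genetic algorithm (binary tournaments,
BLX-$\alpha$ crossover, Gaussian mutation with per-generation geometric
decay, two-member elitism, reflection at the box bounds). Annealed
mutation matters here: early generations explore the box, late
generations refine, which is what lets small recovery problems reach
errors below $10^{-3}$. A run stops when the best error improves by less
than `tol` (default $10^{-12}$) over a `stall` window of 25 generations —
an elitist GA routinely has single flat generations, so a one-generation
test would stop far too early. `calibrate_params()` runs independent
seeded restarts (restart $i$ uses `seed + i`, so enlarging the restart
count keeps earlier runs identical and can only improve the best error)
and returns all fits ranked by error.

Default problem sizes are a population of 100 and up to 200 restarts,
mirroring a full calibration campaign; the shipped tests and the
acceptance script use a scaled-down recovery experiment (4 free
parameters, population 60, 2 restarts, targets restricted to the
escitalopram and reboxetine regimens) chosen to finish in minutes on one
CPU while still exercising the full objective.

Two diagnostics support choosing a representative fit.
`screen_parameterization()` probes, for each adjustable receptor, a unit
strength decrement and compares the windowed oscillation's mean (offset)
and peak-to-trough range (amplitude) before and after: a usable
parameterization changes window averages mainly through offset shifts,
and a fit whose amplitude shifts dominate is flagged, because the
compressive squashing lets amplitude changes masquerade as offset
changes. `representative_report()` combines error rank, a
robust-5HT-rise check under escitalopram, and that flag; the final choice
is deliberately left to the user, since it involves judgment.

## Neuroadaptation

The eleven adjustable receptors are the three monoaminergic autoreceptors
(DR 5HT1A, LC $\alpha$2, VTA D2) and specific galanin, CRF, and AMPA
receptors on the nuclei — the receptor populations reported to change
strength under chronic antidepressants. A configuration is stored as
calibrated base strengths plus an integer count of adjustments; the
realized strength is $\mathrm{clamp}(\mathrm{base}+\delta, 0, 10)$, so a
step within 1 of a bound moves by exactly the fraction that lands on the
bound, bound violations are impossible by construction, and two
configurations are equal iff their integer deltas are equal — an exact
identity that makes memoization safe with no floating-point tolerance.

`adapt_path()` draws a uniformly random legal (receptor, direction) pair
per step and keeps the adjustment only if the activation error strictly
decreases; ties are rejected, since a tie is not a homeostatic
improvement. Steps count *proposals*, accepted or not. The baseline is
always the same parameter set's own no-drug summary, recomputed.
`terminal_adapt()` continues until no legal single move reduces the
error, and certifies termination by exhaustively evaluating every legal
move from the terminal configuration. Evaluating a proposal requires a
full 150-step simulation; results are memoized per exact configuration
within a run, never across parameter sets or regimens.

On the shipped fixture, batches of terminal adaptations accept around
2–14 adjustments (mean near 6.5 at the default seed set) and reach many
distinct terminal configurations — the heterogeneity at the core of the
model's claim.

## Exhaustive search and efficacy estimates

`enumerate_tree()` elaborates every legal adjustment sequence to depth 3
breadth-first, *whether or not* each step reduces error, because
low-error configurations can sit behind higher-error intermediate steps.
From a strictly interior start there are 22 legal moves, so levels 0–3
hold $1 + 22 + 484 + 10{,}648 = 11{,}155$ sequences; eight steps would
already exceed $22^8 > 5.4\times10^{10}$, which is why exhaustive search
stops at depth 3 while stochastic pathways probe deeper. Deeper searches
are allowed but gated by an explicit node-count cap. Memoization on the
integer-delta identity cuts the distinct simulations to the unique
configurations (under half the sequence count at depth 3), and the full
depth-3 search of the six-unit fixture runs in well under a minute.

Classification follows two strict rules. A configuration at level 2 or 3
is **adapted** iff its error is strictly below the *minimum level-1
error* for that regimen — the drug-specific criterion that scales the
bar to how strongly each regimen unbalances the network; a node exactly
at the threshold is not adapted, and level-0/1 nodes never are. A
configuration is **therapeutic** for 5HT when its level exceeds 400% of
the no-drug baseline, and for NE or DA above 200% — thresholds anchored
to published microdialysis values accompanying symptom relief (chronic
SSRI near 420%, NE near 212% under reboxetine, DA at 140% *not* reaching
the criterion). "More than" is read as strictly greater.

Reports tally, over adapted configurations, the seven monoamine
combinations (5HT, DA, NE, and their conjunctions; a combination column
requires all its members elevated, whatever the others do), with
percentages relative to the adapted count. Because many sequences reach
the same configuration, counts are reported both per raw sequence and per
deduplicated configuration; published tallies of this kind are ambiguous
between the two, so both views are kept, with deduplicated counts as the
default rendering.

## The synthetic fixture

No calibrated reference parameter vector is publicly available, so the
package generates one (`make_reference_params()`) rather than pretending
to the real one. The fixture anchors the three printed autoreceptor
strengths (3.1 for DR 5HT1A, 3.2 for LC $\alpha$2 and VTA D2), keeps all
adjustable strengths strictly inside $(2, 8)$ so depth-3 trees are
combinatorially complete, uses transporter efficacies of 0.8 and an SSRI
blockade of 0.9 so that a fully restored DR activation puts 5HT near
460% of baseline (above the 400% criterion, with the acute level near
310%), and derives the biases analytically so the designed mid-range
activation offsets are the exact no-drug operating point. A single
excitation/inhibition loop between the CRF and galanin systems is tuned
to the edge of instability, giving every unit a small oscillation whose
window average settles within 50 steps. Non-anchored values receive a
seeded ±2% jitter so no test silently depends on one invented vector.

What the fixture does *not* emulate: real acute-response magnitudes (its
calibration targets are generated from the fixture itself, optionally
with Gaussian noise on the percent rows), receptor-level binding
kinetics, pharmacokinetics, and any quantitative match to published
adapted-state tallies — those depend on the unpublished calibration.
Passing tests on the fixture therefore demonstrates the *machinery*
(bound mechanics, classification rules, search completeness, calibration
behavior) and the *qualitative* phenomena (acute SSRI imbalance,
autoreceptor desensitization restoring activity, post-adaptation 5HT
above acute, heterogeneous terminal states), not agreement with any
particular animal dataset.

Reduced toy models (`make_toy_model()`) close the loop on correctness: a
one-unit reduction whose fixed point is checkable by scalar bisection, a
two-unit oscillator for the screening diagnostic, and 2–3-receptor
restrictions whose full adjustment trees are compared node-for-node
against a brute-force nested-loop enumeration in the tests.

## Known limitations

* Single-unit regions: each nucleus is one rate unit, so within-region
  heterogeneity and spiking dynamics are out of scope, as is matching
  real oscillation frequencies.
* Histamine is excluded: it is not co-released by monoaminergic neurons
  and lacks evidence of receptor-strength adjustment under chronic
  antidepressants.
* The exact error-term weighting that produced published RMS values
  cannot be reconstructed; weights are exposed per row instead.
* Whether published adapted-state tallies count sequences or unique
  configurations is ambiguous; both are reported.
* Efficacy estimates inherit the monoamine hypothesis: therapeutic
  classification is a threshold on transmitter elevation, not a model of
  symptom change.
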