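---
title: "Estimating therapeutic windows from logical network dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating therapeutic windows from logical network dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(therawin)
```

## The model and its assumptions

`therawin` treats a signaling pathway as a weighted-sum Boolean network: each
node carries a binary state, an integer basal level $b_i$, and integer-weighted
directed links $w_{ji}$; all nodes update synchronously by
$s_i(t+1) = \mathbf{1}[\sum_j w_{ji} s_j(t) + b_i > 0]$. The comparison is
*strict*: with an all-zero input sum and zero basal level a node switches OFF.
This is a deliberate resolution of an under-determined point — the weighted-sum
reconstruction of a logic table does not by itself fix the boundary case — and
the non-strict variant remains available through `sim_config(strict = FALSE)`
for sensitivity checks.

Three layers of forcing sit on top of the logic, applied after each update in
this order: status clamps from genomic alterations (A-status nodes to 1,
I-status to 0), scenario clamps of input nodes (e.g. DNA damage ON or OFF),
and drug suppression (targeted nodes to 0). Suppression therefore wins over
logic and over the A-clamp, matching the semantics of "fixing the state of the
node to 0". Link suppression acts earlier, by zeroing the link's weight inside
the sum.

A trajectory is run for 100 transient steps and then 100 steady steps; node
*activity* is the mean state over the steady window only, and a trajectory has
the cell-death phenotype when the death readout's activity exceeds 0.9
(sustained caspase activation, not a transient pulse). The fixed 100-step
window is used as-is rather than detecting the first attractor recurrence; for
the packaged models the test suite verifies that every trajectory enters its
attractor within the transient window, so the two conventions coincide there.

Drug dose is the per-step suppression probability $x \in [0,1]$. Draws are
independent Bernoulli($x$) across steps, components, initial states and
replicates ("without a bias of patterning"), and suppression operates during
both the transient and steady phases. Two exact equivalences anchor the
stochastic machinery and are asserted as properties: dose 0 reproduces the
unperturbed trajectory bit for bit, and dose 1 on a node is trajectory-
identical to clamping that node I.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `transient_steps`, `steady_steps` | 100, 100 | update steps | convergence horizon of the 16-node model; checked exactly by a successor-table recurrence test |
| `death_threshold` | 0.9 | activity fraction | sustained death-readout activation defines apoptosis |
| dose grid | 0, 0.1, …, 1 | probability | the standard 11-point screening grid |
| efficacy test | > 0.8 | death ratio | selective-control cut |
| toxicity gap / potency gap | > 0.5 | death-ratio difference | optimal-control cuts (O1, O2) |
| sMED/sMTD threshold | 0.25 | death ratio | dose "reaching" a response in either network |
| determinant radius | 0.1 | efficacy–potency distance | neighborhood defining "same drug response" |
| `n_replicates` | 1 | schedules per initial state | the death ratio is defined over initial states; replication is optional variance reduction |
| `enumeration_cap` | 22 | free nodes | exhaustive landscapes up to ~4M states; beyond it, seeded uniform sampling via `sample_states` |

IC50 is defined by linear interpolation at the 0.5 crossing. Two modes are
provided because the printed interpolation formula omits the grid-spacing
factor: `"scaled"` (default) returns
$x_1 + \frac{0.5 - f(x_1)}{f(x_2) - f(x_1)} (x_2 - x_1)$, which is
dimensionally consistent and always lies inside the bracketing interval;
`"literal"` applies the formula exactly as printed and may leave the grid. On
the worked five-point grid the two modes give 0.25 and 0.7 respectively (unit
tested). Curves whose efficacy is below 0.5 report IC50 = 1. sMED/sMTD use the
same first-crossing-from-below interpolation at 0.25; an absent control
crossing yields sMTD = ∞ (unbounded window), an absent cancer crossing an
undefined (NA) window.

## Response categorization

Selective control compares a drug's node route against its link route. For
single-target drugs the reference node is the target itself (node drugs) or
the link's source (link drugs): S1 both routes effective, S2 node only, S3
link only, S4 neither, with "effective" meaning some single-target sweep
exceeds the 0.8 efficacy cut. For combinations the rule follows the "at least
one drug of the combination" reading: the node side counts only node
components, the link side counts link components plus the outgoing links of
node components. These two readings genuinely differ — a pure link pair can be
S3 even when a component link's source node is itself effective — and the
package adopts the combination rule above as a design decision; the
single-target rule stays anchored to the node-and-its-links picture.

Optimal control is evaluated with precedence: O1 if max f − max g > 0.5
(low toxicity at all doses), else O2 if f(x) − g(x) > 0.5 at some dose (a
window via potency), else O3. Desirable responses are exactly S1–S3 × O1–O2.
All threshold comparisons are strict. Categorization runs under the
therapeutic scenario (the stress input clamped ON); database-style
sensitivity classification (`sensitivity_classify()`) instead uses the
unstressed scenario, mirroring how viability assays are run.

Basin filtering of mapped cohorts ("networks dying spontaneously are
excluded") is performed with inputs clamped OFF by default: the filter
expresses "does not die without a stimulus", and the stated procedure leaves
the clamp open. The boundary is kept exactly as worded — basins strictly
larger than ½ are excluded, 0.5 itself is retained.

## Critical determinants and dominance

For a cancer network with alteration set $A$, all $2^{|A|}$ subnetworks are
simulated under the drug and placed on the efficacy–potency plane (potency =
IC50, so both axes live in [0,1]; the distance is Euclidean, another point the
procedure leaves open). Neighbors are subsets within 0.1 of the original
network's point; the critical determinant is the intersection of the neighbor
subsets, accepted only if that intersection is itself a neighbor ("common and
minimum" read as set-minimal, not smallest-cardinality). An empty or
non-neighbor intersection means no determinant: the network responds like the
control.

Dominance is established by simulating, for every desirable × undesirable
determinant pair, the union network; the determinant whose label matches the
union's response wins. Levels are assigned so a determinant sits one level
above the highest determinant it dominates (level 1 = dominates nobody). The
procedure assumes a clean ordering; if the pairwise results ever form a cycle
the package reports the cycle as an error rather than silently breaking it.
Prediction walks the hierarchy top-down among determinants contained in a
profile; profiles with none fall back to the control response, and a
same-level conflict is an error, not a coin flip.

The conventional-biomarker baseline ranks single alterations by two-sided
Fisher's exact association with the D/U split (the enrichment statistic is a
free choice here; Fisher's exact test is the standard one for binary
presence × binary response) and predicts the enriched class for carriers.

## What the synthetic world does and does not establish

The packaged 16-node p53 model is a labelled synthetic reconstruction: the
published node set, input/output designations, the canonically named links
(MDM2⊣p53, MDM2→E2F1, CYCE⊣RB, WIP1⊣ARF, AKT→MDMX) and the six-target
screening combinatorics (27 outgoing links; 15/297/135 pairs; 480
perturbations) are preserved, while weights and basal levels are
package-chosen minimal integers. Its dynamics are sensible — the control
network never dies spontaneously under either input scenario, all
trajectories converge within the transient window, MDMX- or CYCE-inactivated
networks respond to MDM2 inhibition, and a BCL2-activating clamp confers
absolute resistance — but they are *not* the published model's numbers, so
cohort-count and census regressions tied to the published supplementary
tables are skipped rather than asserted. On this parameterization the dose–
response curves are switch-like (a 0.9 activity threshold over a pulsing p53
attractor), so the O1/O2 category variety is exercised on the hand-designed
`testbed_network()` instead, whose kill-path logic (a required causal locus, a
dominant resistance locus tie-broken by a bistable memory node, and an inert
passenger) gives every stratification test a provable ground truth.

The random generators state their world explicitly: `random_network()` draws
a connected backbone from input to death readout with one feedback link and
density-controlled extras; `random_alteration_profiles()` draws 1–4
alterations per sample uniformly over mappable nodes (the randomization scheme
for such cohorts is not specified anywhere authoritative; uniform-over-nodes
is the neutral choice and is configurable). `confounded_cohort()` builds its
design cells deterministically from the stated frequencies and labels every
profile by de novo simulation, never by assumption. A green determinant-
recovery test therefore establishes that the identification procedure inverts
implants the generator has *verified by simulation* (causal effect ≥ 0.3 in
the efficacy–potency plane, passengers inert alone and alongside the causal
alteration); it does not establish recovery under model misspecification or
measurement noise, which the framework does not model.

## Numerical choices and degenerate inputs

State enumeration counts in binary over free nodes in file order (first free
node fastest), making state indices stable across runs. Deterministic
landscapes use an exact successor-table pass (transient composition by
squaring, explicit stepping of the unique steady-entry states), which is also
how the convergence check is exact. All randomness flows from a single
integer seed; per-dose and per-landscape-cell seeds are derived arithmetically
so that the y = 0 row of a landscape is *identical* to the single-target
sweep, and every public entry point restores the caller's RNG state.
Degenerate cases are errors, not guesses: a flat segment at the 0.5 crossing,
double normalization, conflicting A/I statuses for one node (an optional
I-over-A precedence mode exists for exploratory use), duplicate perturbation
targets, and link targets absent from the network.

## Known limitations

Synchronous updating only; no asynchronous or ODE semantics, and no
pharmacokinetic translation from concentration to suppression probability.
Toxicity is read from a single genetically clean control network. The
curation pipeline that produces binarized alteration tables from raw genomic
data is out of scope — the package consumes already-binarized profiles. The
engine is pure R, vectorized over initial states; it comfortably handles the
16-node model's 2^15-state landscapes, but much larger models would warrant a
compiled core.
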