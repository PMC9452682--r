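# therawin

Therapeutic-window estimation from logical signaling-network dynamics.

`therawin` is for systems-biology and pharmacology modelers who want to ask,
*before* a wet experiment: over which dose range does inhibiting this target
(or this single interaction, or this pair) kill a tumor cell's signaling
network without killing the normal one — and which genomic alterations decide
who responds?

## The model

A signaling network is a weighted-sum Boolean model: node *i* holds a binary
state *s_i* and updates synchronously by

```
s_i(t+1) = 1  iff  sum_j w_ji * s_j(t) + b_i > 0
```

with integer link weights *w* and basal levels *b*. A sample's binarized
genomic alterations are projected onto ternary node clamps — constantly
activated (A), constantly inactivated (I), or input-dependent (N) — which
rewires the nominal network into a patient-specific one; the all-N profile is
the control network. A drug of dose *x* in [0,1] inhibits its target node or
link with probability *x* at every update step (dose 1 = permanent knockout,
dose 0 = untouched dynamics).

For each dose the package simulates every initial state (or a seeded sample of
them), calls a trajectory *cell death* when the steady activity of the death
readout (CASP3 in the p53 model) exceeds 0.9, and reports the death ratio.
From the normalized dose–response curves *f* (cancer) and *g* (control) it
derives:

* **efficacy** = max f(x); **toxicity** = max g(x); **potency** = IC50 by
  linear interpolation of the 0.5 crossing,
* **sMED / sMTD** = doses at which f and g reach 0.25; therapeutic window =
  sMTD − sMED,
* **combination index** CI = IC50_AB/IC50_A + IC50_AB/IC50_B (< 1 synergy),
* a 12-way response category (S1–S4 × O1–O3): selective control (is the node,
  only the node, only an outgoing link, or neither effective?) and optimal
  control (low toxicity everywhere; a window via higher potency; or no
  window). Categories in S1–S3 × O1–O2 are desirable (D), the rest
  undesirable (U).

Screening all single and pairwise node/link perturbations of designated
targets yields a *triangle map*; per-sample response variability is traced to
**critical determinants** — minimal alteration sets whose subnetworks stay
within distance 0.1 of the original network in the efficacy–potency plane —
which are ordered into a dominance hierarchy and used to stratify cohorts.

## Worked example

```r
library(therawin)

net  <- p53_network()
map  <- p53_gene_node_map(net)
ctrl <- control_profile(net)
cfg  <- sim_config(input_clamp = c(DNA_damage = 1), seed = 1, sample_states = 256)

cancer <- alterations_to_status("MDMX_inact", map, net)
f <- normalize_curve(dose_sweep(net, cancer, target_node("MDM2"), cfg))
f
#> Dose-response curve [MDM2] (normalized)
#>   0.0   0.1   0.2   0.3   0.4   0.5   0.6   0.7   0.8   0.9   1.0
#> 0.000 0.000 0.000 0.000 0.000 0.000 0.000 0.000 0.000 0.094 1.000

categorize(net, cancer, ctrl, target_node("MDM2"), cfg)
#> (S2,O3) undesirable  [MDM2]  eff=1.00 ic50=0.94 tox=1.00 window=0
```

An MDMX-inactivated network is fully killed by MDM2 inhibition (efficacy 1.0,
IC50 0.94), and only the node — not any single outgoing MDM2 link — is
effective (S2); but the control network is equally sensitive at top dose
(toxicity 1.0), so there is no therapeutic window (O3).

On the packaged ground-truth test bed, determinant analysis looks like:

```r
tb  <- testbed_network(); tbm <- full_gene_node_map(tb)
tcf <- sim_config(input_clamp = c(IN = 1), seed = 1)

categorize(tb, alterations_to_status("C_act", tbm, tb),
           control_profile(tb), target_node("T"), tcf)
#> (S1,O1) desirable  [T]  eff=1.00 ic50=0.92 tox=0.00 window=Inf

d1 <- find_critical_determinant(tb, c("C_act", "P_act"),  tbm, target_node("T"), config = tcf)
d2 <- find_critical_determinant(tb, c("C_act", "Dm_act"), tbm, target_node("T"), config = tcf)
dominance(list(d1, d2), tb, tbm, target_node("T"), config = tcf)
#> Lv2: C_act;Dm_act (U)
#> Lv1: C_act (D)
```

The activating `C` alteration is a desirable-response determinant, but the
composite determinant `{C, Dm}` dominates it (level 2), so a profile carrying
both — plus any passenger — is predicted U.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/therawin` (subcommands `map`, `sweep`, `screen`, `stratify`,
`fixtures`), and `run_pipeline()` drives the whole workflow with a manifest
recording seeds and artifact checksums.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main pipeline from scratch — loads the packaged p53
model, verifies the 480-perturbation screening set, runs a dose sweep and
categorization of an example cancer network against the control, and performs
determinant identification, dominance layering and cohort prediction on a
generated ground-truth cohort — then writes the JSON report to `--out`. All
randomness is governed by `--seed`.
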