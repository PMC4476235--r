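---
title: "The pathdose model: network connectivity as a dose-response predictor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pathdose model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathdose)
```

## The model and its assumptions

`pathdose` treats a signaling pathway as a directed graph with one exit
node — the measurable end product — and reads a drug's effect off the
graph's connectivity after inhibition has inflated edge resistances.
The chain of assumptions is:

1. **Non-competitive kinetics at every target.** An inhibitor at
   concentration $[I]$ with inhibition constant $K_I$ reduces its target's
   activity by the fraction
   $f_a = 1 - 1/(1 + [I]/K_I)$, independent of substrate concentration.
   Several mutually exclusive inhibitors at one target combine as
   $f_a = 1 - 1/(1 + \sum_i [I_i]/K_i)$, which depends only on the summed
   normalized dose. No competitive or uncompetitive variants are offered:
   a single mechanism keeps the dose-to-edge map one-dimensional, and the
   substrate term cancels out of $f_a$ anyway.

2. **Inhibition as edge resistance.** Each edge leaving an inhibited
   target gets the value $EV = 10^{2.303 f_a}$: 1 when untouched,
   saturating at $10^{2.303} \approx 200.9$ at full inhibition. The
   exponent is calibrated so a 99.5% block corresponds to a resistance
   near $1/(1-0.995) = 200$. Note the deliberate, documented mismatch:
   the *edge map* saturates at 200.9 (the formula taken literally), while
   the *bounds* below use exactly 200 (the nominal constant). We keep
   both as stated rather than silently reconciling them; the only visible
   consequence is that percent decreases can marginally exceed 100 near
   saturation, and are clamped (flagged in the result object).

3. **Connectivity readout.** With $d_{ij}$ the weighted shortest-path
   length (Dijkstra via igraph; all weights $\ge 1$),
   $NE = \sum_{i \ne j} 1/d_{ij}$ over *ordered* pairs and
   $NF = \sum_{i \ne exit} 1/d_{i,exit}$. Unreachable pairs contribute
   $1/\infty = 0$ — the standard convention of the efficiency formalism,
   and stated explicitly because most reverse pairs of a directed pathway
   are unreachable. $NEd$ and $NFd$ normalize $NE$ and $NF$ between the
   all-$EV{=}1$ maximum and all-$EV{=}200$ minimum of the same topology,
   and $NEF = \sqrt{NEd \cdot NFd}$ is the predicted percent inhibition.
   $NF$ exists because $NE$ weights all nodes equally while downstream
   nodes matter more for the output; the geometric mean balances the two.

4. **Dose-response and combinations.** Sweeping a compound's dose yields
   a monotone curve (inflating any edge value never increases $NE$ or
   $NF$), fitted with the four-parameter Hill-type model
   $y = E_{max} - (E_{max}-E_{min})/(1 + ([I]/EC50)^n)$. Two-drug dose
   pairs are scored with the Chou-Talalay combination index, with the
   single-drug equivalent doses $(D_x)$ obtained by inverting the model's
   own curve by bisection — not the fitted Hill curve — so fit error
   never contaminates CI. (A Hill-based inverse remains available for
   experimental data, where no model inverse exists: fit the curve, then
   solve the fitted equation.)

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `pki` | $-\log_{10}$(mol/L) | — | binding input; $K_I[\mu M] = 10^{6-pKi}$, fixed globally |
| dose | μM | — | matches EC50 reporting scale |
| `ev_cap` (validator) | — | $10^{2.303}$ | literal saturation of the edge map |
| `ev_min_value` (bounds) | — | 200 | nominal full-block resistance $1/(1-0.995)$ |
| curve grid | μM | 12 points, $[d_{50}/100,\,100\,d_{50}]$ | two decades either side of the half-plateau dose cover the whole transition |
| surface grid | μM | 0 + 24 log-spaced | resolution/runtime balance |
| isobole levels | % | 25, 50, 75 | conventional low/mid/high effect levels |
| `asymptote_margin` (fit) | % points | 20 | see below |

## Numerical choices

**Hill fit.** Levenberg-Marquardt (minpack.lm's `nls.lm`, driven
directly) with initialization $E_{max} = \max y$, $E_{min} = \min y$,
EC50 at the concentration nearest half-maximal response, $n = 1$; box
constraints keep each asymptote within 20 percentage points of the
corresponding observed extreme. For full-scale curves (0–100%) these
boxes are $[-20, 20]$ and $[80, 120]$ — bracketing the plausible range of
fitted asymptotes for percent data — but they are anchored to the data
rather than fixed, because model-predicted curves for weakly connected
compounds can plateau far below 80%, where a fixed box would force an
unreachable $E_{max}$ and destroy the fit. We drive the optimizer
directly instead of through `nlsLM` because the latter's post-fit model
construction takes parameter-proportional finite-difference steps and
spuriously reports a singular gradient whenever a converged parameter is
near zero — which $E_{min}$ routinely is here.

**Inversion and isoboles.** `single_dose_for_effect` brackets by dose
doubling and bisects to ~$10^{-12}$ relative; isobole points solve the
complementary dose the same way, and each point's CI then reduces to
$d_a/D_{x,a} + d_b/D_{x,b}$ with the axis intercepts computed once. The
optimal-ratio search scans the isobole and refines with golden-section
search on the sweep coordinate. Tight inversion tolerance is what makes
the sham-combination identity (CI = 1 for a drug combined with itself)
hold to ~$10^{-12}$ rather than just $10^{-6}$.

**Ties, degenerate inputs, conventions.** Equal-length path ties are
irrelevant (only lengths enter the measures). Self-distances are
excluded; self-loops would be ignored. Networks whose bounds degenerate
($NE_{max} = NE_{min}$) are rejected as perturbation-insensitive. A flat
curve refuses to fit; an effect level above a compound's plateau raises
an attainability error naming the compound. The EC50 agreement statistic
reports the *adjusted* $R^2$ as headline and the ordinary one alongside:
with five compounds the small-sample correction is material, the two
conventions are easily conflated, and exposing both removes the
ambiguity. Note this cross-compound $R^2$ is a different quantity from
the per-curve fit $R^2$; the package keeps them in separate objects.

## What the synthetic generator emulates — and what it does not

`random_pathway` builds a layered signal-flow DAG: a topological backbone
ending at the exit (so every node lies on a path to it) plus random
forward shortcuts. This mimics transduction cascades, for which network
flux is meaningful; an Erdős–Rényi graph would not have a natural exit.
`random_affinities` emulates a docking campaign: compounds receive 1 to
`n_targets` records against druggable nodes (nodes with outgoing edges)
with pKi uniform in $[4, 6]$ — $K_I$ from 100 μM down to 1 μM, typical of
docking-scored ligands. Both are seeded and leave the caller's RNG stream
untouched.

What passing tests on these systems shows: the machinery (measures,
monotonicity, inversion, Loewe consistency, fit behavior) is correct on
cascade-shaped topologies. What it does not show: that any *real*
pathway's transcription is complete, that docking pKi values are
accurate, or that the edge-resistance calibration transfers to other
biological systems — the model's predictions degrade with pathway
incompleteness and binding-prediction error, which no synthetic suite can
detect.

## Problem sizes used by the test and acceptance suites

Oracle-equivalence runs use 200 random networks of 4–12 nodes (checked
against a Floyd-Warshall reimplementation, and exhaustive simple-path
enumeration at 6 nodes); Loewe consistency uses 20 random systems of
10–13 nodes at three effect levels; curve-quality checks use the packaged
30-node network with five synthetic compounds scored against all 14
docking targets. These sizes make the suites exhaustive at small scale
while keeping a full run in the tens of seconds.

## Known limitations

- The packaged LPS→PGE2 network is a transcription constrained by the
  published node/edge counts, target list and prose motifs; other
  adjacencies satisfying the same constraints exist, and all packaged
  numeric examples are defined relative to this transcription.
- Percent-decrease readouts are clamped at 100 when edge values exceed
  the nominal bound 200 (possible by design, see above).
- The combination machinery evaluates any number of drugs through the
  generalized occupancy sum, but the search surface (isoboles, optimal
  ratio) is two-drug only, and only Chou's CI is offered — no Bliss, HSA
  or ZIP scores.
- No pathway retrieval from databases, no docking, no topology
  statistics; inputs are consumed as given.
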