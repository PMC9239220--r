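---
title: "Omics-contextualized flux analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Omics-contextualized flux analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxContext)
```

This vignette is the package's account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic data generator does and does not emulate, and the design
choices made where the method descriptions in the literature leave the
design open.

## The constraint-based core

A metabolic network with $m$ metabolites and $n$ reactions is
summarized by its stoichiometric matrix $S \in \mathbb{R}^{m \times n}$
(negative entries consume, positive produce). The steady-state
assumption — intracellular metabolite pools change slowly relative to
reaction time scales — gives the mass-balance constraint

$$ S\,v = 0, \qquad lb_j \le v_j \le ub_j , $$

with fluxes $v_j$ in mmol/gDW/h. Reversible reactions are encoded by a
negative lower bound; the solver layer splits fluxes into nonnegative
components where an absolute value is needed, but model files never
split reactions. Flux balance analysis (`solveFBA`) maximizes the flux
of a biomass reaction over this polytope. Energy maintenance follows
the usual convention: the growth-associated maintenance (GAM, default
55.3 mmol ATP/gDW) appears as ATP consumption inside the biomass
reaction's stoichiometry, and the non-growth-associated maintenance
(NGAM, default 0.7 mmol ATP/gDW/h) is a fixed-bound ATP-hydrolysis
reaction that no data can prune.

Every flux vector any function returns is checked against
$\max_i |(Sv)_i| \le 10^{-6}$ and its bounds; the tolerances
(`fluxTolerances()`: feasibility $10^{-9}$, balance $10^{-6}$,
zero-flux classification $10^{-6}$) are defined once and used
everywhere. Linear and mixed-integer programs are solved through the
GLPK command-line solver from generated CPLEX-LP files — with a fixed
input file the solver path is deterministic, which the reproducibility
guarantees below rely on.

## From gene values to reaction values

GPR rules are parsed with AND binding tighter than OR. Mapping follows
the standard min/max semantics: a complex (AND) is as available as its
scarcest subunit, isozymes (OR) add alternatives, so the reaction value
is `min` over AND children and `max` over OR children. Genes without a
measurement are skipped at their parent node rather than poisoning the
rule; a rule with no measured leaf, or no rule at all, yields the
unmapped marker (`NA`). This matters because real studies map partial
gene sets onto models with thousands of genes — missing data is a
defined state, not an error.

Percentiles (the activity threshold below) use linear interpolation
between closest ranks (`quantile(type = 7)`), stated explicitly so
results are reproducible bit for bit. Replicates are averaged
arithmetically on the raw scale before mapping.

## GIMME contextualization

Given mapped reaction values $x_j$ and a threshold $T$, reactions with
$x_j < T$ receive penalty $c_j = T - x_j$ and the algorithm solves

$$ \min \textstyle\sum_j c_j |v_j| \quad \text{s.t. } S v = 0,\;
   lb \le v \le ub,\; v_{\text{growth}} \ge f \cdot V_{\text{opt}} $$

with objective fraction $f = 0.5$ by default: the context may lose at
most half the generic model's growth capacity. The threshold default is
the 25th percentile of the sample's mapped reaction values. Unmapped
reactions carry no penalty and are always retained.

Three design points are the package's own:

- **Threshold scope.** The percentile is computed per sample over
  reaction-level (post-GPR) values, because that is the quantity the
  optimization consumes; a fixed `threshold` can be supplied instead
  when a gene-level or global convention is wanted.
- **Canonicalization.** The penalized LP usually has alternate optima;
  which optimum a solver returns is an implementation accident. A
  second LP fixes the inconsistency score at its optimum and minimizes
  total absolute flux, making the reported flux vector, active set and
  context model solver-independent.
- **Active set and pruning.** Active = above threshold, or unmapped,
  or carrying flux above the zero tolerance in the canonical solution.
  Everything else is removed, along with metabolites and genes
  orphaned by the removal. Dead-end reactions that survive are kept:
  no flux-consistency trimming is applied.

Combinatory models merge two channels: the union (intersection) binary
vector marks reactions active in either (both) channel model(s) with 1,
and is fed back through GIMME with threshold 0.5, so 0-marked reactions
get penalty 0.5 and are removed exactly where mass balance and the
growth floor allow.

## Two-stage FBA

Growth maximization alone leaves most fluxes undetermined. The
prediction pipeline therefore (1) computes $V_{\text{opt}}$, (2)
constrains $0.9\,V_{\text{opt}} \le v_{\text{growth}} \le
V_{\text{opt}}$ (slack 0.1 by default) and minimizes
$\sum_j |v_j|$ over intracellular reactions — a parsimonious
distribution in which enzyme-expensive futile routes vanish. The sum
excludes exchange reactions by default (`includeExchanges` flips
this); exchanges still settle by mass balance, so reported totals
include them. With slack 0 the second stage collapses onto the
optimum; with a zero optimum the stage is skipped with a warning and
the zero flux returned.

## Differential flux inference

Between two conditions, significant genes (q-value $< \alpha$, default
0.01, boundary excluded) contribute signed log2 fold changes, mapped to
reactions with the same min/max rules. The inference seeks
$\Delta v$ with $S\,\Delta v = 0$ and
$\Delta v_j \in [lb_j - ub_j,\, ub_j - lb_j]$:

1. **Consistency (MILP).** One binary $y_j$ per data reaction;
   $y_j = 1$ enforces $\mathrm{sign}(w_j)\,\Delta v_j \ge \varepsilon$
   through a big-M link ($M$ defaults to twice the widest bound range
   plus $\varepsilon$); maximize $\sum y_j$.
2. **Inconsistency (QP).** With the step-1 consistency set fixed,
   minimize $\sum_{j \notin D} \Delta v_j^2$. A ridge of $10^{-6}$ on
   the data reactions makes the program strictly convex, so the
   reported $\Delta v$ is unique; an L1 variant (solved as an LP) is
   available via `deltaFbaConfig(objective = "l1")`.

The relaxed threshold $\varepsilon = 0.1$ plays two roles — the
magnitude a consistent change must reach, and the cutoff for calling a
reaction altered. Both default to 0.1 but are independently
configurable (`epsilon`, `alteredEpsilon`), since the wording of such
procedures often leaves the distinction open. Fixing the binaries at
the step-1 optimum (rather than re-optimizing them inside the QP) is a
deliberate simplification: it keeps step 2 a convex QP, and ties among
equally consistent sets are immaterial because the step-2 objective is
evaluated on the complement. Altered reactions are
$\{j : |\Delta v_j| \ge \varepsilon\}$; their GPR leaves, in sorted
order, are the terminal gene-list output (downstream pathway-enrichment
services are out of scope).

## Evaluation

`compareFluxes` matches predicted and measured fluxes by reaction id
(at least four matches required) and reports Pearson's $r$ and the MSE
with denominator $n$ (not $n-1$; stated for bit-reproducibility).
Measured reactions without a prediction are listed, not fatal; zero
variance makes $r$ undefined and it is reported as `NA`. Correlations
are compared with Fisher's transform,
$z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2) /
\sqrt{1/(n_1-3) + 1/(n_2-3)}$, with a two-sided normal p-value and a
0.05 significance flag. Sample clustering uses Euclidean distance with
average linkage by default (the distance is the methodological
commitment; the linkage is a documented package default with
`complete`/`ward.D2` switches), columns sorted lexicographically first
so tied merges resolve by sample id, and cluster count is always an
explicit argument downstream — never auto-chosen.

## The synthetic study

The generator produces everything the pipeline consumes, with known
ground truth. Its defaults are the study conditions; they were fixed at
design time and the test suite measures against them.

**Network.** An 18-reaction central-carbon toy: glucose uptake (bound
1.45 mmol/gDW/h) into a glycolysis backbone (net 2 ATP per glucose),
a lumped respiration reaction (13 ATP per pyruvate, consuming O2), a
lumped fermentation reaction to ethanol (no extra ATP), a
storage-carbohydrate cycle, a PPP-like glycolysis bypass, a biomass
reaction consuming pyruvate, nitrogen and GAM ATP, and the NGAM
reaction. Two capacity limits shape the physiology, both deliberate:

- an **oxygen cap** (0.6 mmol/gDW/h) makes respiration saturable, so
  the generic optimum is respiro-fermentative (overflow metabolism, as
  in aerobic glucose-grown yeast) and a falsely retained fermentation
  pathway genuinely changes predicted fluxes;
- a **nitrogen cap** (0.015 mmol/gDW/h) bounds growth itself, keeping
  the generic optimum low enough that a purely fermentative context
  still satisfies the 0.5 objective-fraction floor. Without it, no
  extraction method could ever recover a fermentative phase — the
  floor would force the respiratory pathway back in, and the planted
  truth would be unrecoverable by construction.

The resulting growth rates are ~0.075 h⁻¹ (generic), ~0.065 h⁻¹
(respiratory phases) and ~0.040 h⁻¹ (fermentative phase).

**Phases and omics.** Three phases with planted module activity:
quiescent (glycolysis + respiration + storage), oxidative (glycolysis +
respiration + PPP), proliferative (glycolysis + fermentation + PPP).
Each gene's log2 mean is baseline + module activity
($\pm \log_2(\text{fold})/2$, fold 8), observed twice per phase in two
channels that share truth and baselines and differ only in lognormal
noise: σ = 0.15 (accessibility-like) versus σ = 0.45
(expression-like). The noise asymmetry encodes, as a generator
parameter, the hypothesis that accessibility data carry a better
signal-to-noise ratio than expression data — it is a testable setting,
not a claim about any real data set.

**Constitutive markers.** Two genes (PDC1, CIT1 — chosen because their
real counterparts are constitutively abundant) carry a fixed +2.5 log2
basal offset. In phases where their pathway is off they therefore sit a
small (~0.4 log2), nearly deterministic margin below the lowest active
reaction value. Whether they slip past the 25th-percentile threshold is
then decided almost entirely by channel noise (≈17% per phase for the
noisy channel versus ≈0.4% for the clean one, given two replicates).
This is the load-bearing design choice of the whole study: at fold 8
the active/inactive clusters are otherwise so well separated that no
smooth gene-to-gene variability makes threshold calls noise-sensitive —
either both channels always agree, or the calls are dominated by
baseline variation common to both channels, and in neither regime can
a lower-noise channel systematically win. Planting near-threshold
marker genes is what real data do at scale (thousands of genes form a
continuum through any percentile cut); the toy emulates that with two
carefully placed genes. A consequence worth knowing: each escape event
completes a whole (single-reaction) pathway, so prediction errors are
discrete rerouting events, not graded degradation.

**Measured fluxes.** Per phase, ground-truth fluxes come from
`twoStepFBA` on the true submodel; measured values add Gaussian noise
with sd `fluxNoiseFrac · (|v| + 0.01)` (exact at `fluxNoiseFrac = 0`),
over the central-carbon reactions. Differential tables carry the
replicate-mean log2 fold change and planted q-values (0.001 for genes
whose module switches, 0.5 otherwise).

**What passing tests do and do not show.** The generator emulates
planted module structure, channel noise asymmetry, replicate structure
and measurement noise. It does not emulate genome scale, normalization
artifacts, peak calling, promoter-to-gene assignment, batch effects, or
biological regulation beyond on/off modules. Results on it validate the
machinery — mapping, extraction, optimization, statistics — and the
direction of noise effects; they say nothing quantitative about real
chromatin or expression data.

**Numerical edge cases.** A phase design that leaves an intermediate
without an outlet would make the submodel infeasible (the NGAM bound
forces flux); `groundTruth` then re-adds the fermentation module as the
backbone outlet and records the rescue. Degenerate GIMME optima are
removed by the canonicalization stage; ΔFBA ties by the strictly convex
QP; hierarchical-clustering ties by lexicographic column order. The QP
drops linearly dependent mass-balance rows (currency-metabolite rows
can be collinear) before handing equalities to the solver.

## Problem sizes

The shipped study runs 20 seeds × 3 phases on the 18-reaction network
with 16 genes, 50 random ≤8-reaction networks for the
oracle-equivalence check, and 20 seeded perturbations for sign
recovery. These sizes give stable aggregate statistics (the channel
comparison pools 60 phase-runs) while the whole suite, including the
brute-force vertex-enumeration oracles, completes in a few minutes on
one CPU.

## Known limitations

- GIMME and ΔFBA are the implemented extraction and differential
  methods; iMAT/INIT/E-Flux-style alternatives are out of scope.
- The SBML reader covers the Level 3 + FBC constraint-based subset
  (species, stoichiometry, bounds via parameters, gene associations,
  active objective); it does not write SBML.
- The toy network's currency metabolites (ATP without an explicit ADP
  pool) are a deliberate simplification; stoichiometric realism beyond
  carbon/energy/nitrogen bookkeeping is not attempted.
- Percentile thresholds interact with sample composition: contexts are
  comparable within a study design, not across arbitrary data sets.
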