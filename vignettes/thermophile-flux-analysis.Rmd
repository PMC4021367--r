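---
title: "Constraint-based flux analysis of thermophile metabolic models"
author: "thermoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based flux analysis of thermophile metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoflux)
```

## The modeling framework

`thermoflux` implements the constraint-based analysis stack for genome-scale
metabolic models (GSMMs), oriented at thermophilic bacteria such as *Thermus
thermophilus*: organisms whose membranes embed branched-chain fatty acids and
carotenoid glucoside esters (thermozeaxanthins), which import sugars through
ATP-hydrolysing ABC transporters because they lack the PTS, and which carry a
comparatively high maintenance energy burden because their membranes leak
protons at growth temperature.

A model is a set of metabolites (cytosolic `[c]` or extracellular `[e]`),
reactions with flux bounds, and Boolean gene–protein–reaction (GPR) rules.
The stoichiometric matrix $S$ ($m$ metabolites $\times$ $n$ reactions)
collects the signed coefficients $S_{ij}$. Flux balance analysis (FBA) is
the linear program

$$\max Z = \sum_j c_j v_j \quad \text{s.t.} \quad \sum_j S_{ij} v_j = 0
\;\;\forall i, \qquad v_j^{\min} \le v_j \le v_j^{\max} \;\;\forall j,$$

where $c$ selects the biomass pseudo-reaction, so $Z$ is the specific growth
rate $\mu$ (h$^{-1}$); all other fluxes are in mmol gDCW$^{-1}$ h$^{-1}$.
Flux variability analysis (FVA) then minimises and maximises each $v_j$
subject to the same constraints plus $\sum_j c_j v_j = Z_{obj}$, exposing
alternate optima.

Media are not part of the model: a `MediumSpec` assigns bounds to exchange
pseudo-reactions (`"GLC[e] <=>"`), with uptake encoded as a negative lower
bound, a list of exchanges left unconstrained at $(-1000, 1000)$ for
minerals/water/protons, and every unlisted exchange closed to uptake. The
non-growth-associated maintenance (NGAM) is a lower bound on the ATP
hydrolysis reaction; the growth-associated maintenance (GAM) is the ATP term
inside the biomass equation.

## The linear-programming engine

No production LP solver is assumed: the package carries a dense two-phase
bounded-variable primal simplex (`R/lp.R`) sized for desk-scale models
(tens to a few hundred reactions). Design points that matter for
reproducibility and correctness:

* **Rank deficiency.** Stoichiometric matrices routinely contain dependent
  rows (conserved moieties). Phase 1 gives every row an artificial variable;
  rows that turn out dependent simply keep their artificial basic at zero,
  and all artificials are locked into $[0, 0]$ for phase 2.
* **Determinism.** Entering variables are chosen by largest reduced cost
  with lowest-index tie-breaks (Bland's rule after a stall budget guards
  against cycling), so repeated solves return the identical vertex and all
  pipeline outputs are byte-stable.
* **Tolerances.** Pivot tolerance $10^{-9}$, feasibility tolerance
  $10^{-7}$; optimal solutions are clipped onto the bound box. Steady state
  is verified in the tests to $10^{-6}$.
* **FVA at the optimum.** The objective is fixed through a slack variable
  bounded by $[f \cdot Z_{obj} - \varepsilon,\; Z_{obj} + \varepsilon]$ with
  relative slack $\varepsilon \sim 10^{-9}$ and fraction-of-optimum
  $f = 1$ by default: equality as the formulation demands, cushioned
  against round-off. Infeasible FBA problems (e.g. an NGAM floor the medium
  cannot pay) are reported as growth 0 with the status preserved, which the
  deletion scan relies on.

The engine is validated against an independent oracle: exhaustive vertex
enumeration over all choices of $n - \operatorname{rank}(S)$ variables fixed
at bounds, on random networks small enough to enumerate (about six free
fluxes). The test suite requires agreement to $10^{-8}$.

## Gene deletions and essentiality

Deleting a gene re-evaluates every GPR rule (`and` = complex, `or` =
isozymes; the empty rule is spontaneously active) and closes the bounds of
reactions that lost their enzyme. The scan solves FBA per gene and per
medium, recomputing wild-type growth in each medium; the growth ratio
$\mu_{ko}/\mu_{wt}$ classifies a gene as essential in a medium when the
ratio is $\le 0.05$ — the boundary value counts as essential. Genes
essential in all media are *completely essential*, in some but not all
*conditionally essential*, otherwise *non-essential*. Knockouts that render
the LP infeasible score ratio 0: with a maintenance floor, lethality often
manifests as infeasibility rather than zero growth.

## Biomass assembly

`assembleBiomass()` converts compositional measurements into a biomass
pseudo-reaction in mmol gDCW$^{-1}$:

* Amino acids: $\text{coeff}_a = P \cdot 1000 \cdot f_a / \sum_b f_b
  (MW_b - MW_{H_2O})$ with $P$ the protein mass fraction and $f$ the mole
  fractions — residue weights, i.e. the peptide-bond water is subtracted,
  so coefficients times residue weights reconstruct the polymer mass.
* Nucleotides: DNA base fractions follow the genomic GC content
  ($dG = dC = gc/2$), RNA defaults to the same rule unless measured; both
  blocks drain nucleoside monophosphates at phosphodiester residue weights.
  Polymerization energetics are folded into GAM rather than the RNA block,
  so the biomass ATP coefficient equals the GAM value exactly.
* Fatty acids: same scheme with one ester-bond water per acyl chain.
* Cell wall and soluble pool: no monomer detail is assumed; they enter as
  lumped precursors at a nominal 1000 g/mol residue weight so that mass
  closes by construction.

Assembly verifies mass closure — reconstructed dry mass within 1% of the
summed macromolecule fractions — and aborts otherwise. All blocks are
linear in their mass-fraction argument, which the tests exploit.

## Network quality control

Dead-end detection is solver-free iterative set propagation: a metabolite is
*producible* if some usable reaction direction makes it from producible
substrates (seeded by import directions with no substrates), and
*consumable* symmetrically towards export. On small random networks the
tests prove this equal to an independent least-closed-set computation. One
caveat is inherent to any topological rule: currency couples such as
ATP/ADP that only interconvert inside closed loops cannot bootstrap
topologically and are flagged as unreachable even when flux can circulate.
The LP-based `findBlockedReactions()` (FVA with the objective constraint
dropped, under a fully open medium) is the flux-aware complement and reports
no blocked reactions on the shipped fixture; carbon-source usability
(`checkCarbonSources()`) probes assimilation gaps one substrate at a time,
mirroring how draft reconstructions are debugged (e.g. a missing
α-glucosidase making trehalose unusable until the reaction is added).

## The amino-acid supply/demand accounting

For each amino acid, `aminoAcidBalance()` splits the steady-state fate of
the combined `[e]`+`[c]` pool of an optimal solution into supply from the
medium (exchange fluxes, sign-converted so positive = consumed), biomass
demand ($\mu \times$ coefficient), and the net of all other reactions,
reported one-sidedly as *from others* / *to others*. Because transport
cancels inside the pool, steady state makes every row close:
$\text{supply} + \text{from others} = \text{demand} + \text{to others}$
within $10^{-3}$ — the function asserts this rather than assuming it.
Negative supplies are additionally reported in a `secreted` column, since a
negative exchange-side balance can mean either secretion or mere non-use;
both readings are preserved.

## The synthetic generators

Two generators make every stage testable without any external data.

**Planted-optimum networks.** Independent substrate→product chains with
uptake bounds $u_k$, molar yields $y_k$ and biomass coefficients $a_k$ give
the FBA optimum in closed form, $\mu^* = \min_k u_k y_k / a_k$. Yields are
drawn from small rationals so the optimum is exact; `or`-isozymes,
`and`-complexes and removable steps plant redundancy and defects with known
consequences. All sampling runs on a locally seeded RNG (the caller's
`.Random.seed` is untouched) and the same seed reproduces the network
bit-for-bit.

**The thermophile fixture.** A 42-reaction model with the features the
package targets: ABC import for glucose and trehalose (1 ATP per sugar, no
PTS), a lumped glycolysis–TCA–oxidative-phosphorylation backbone (P/O = 2)
with an explicit NGAM reaction, a transhydrogenase as the sole NADPH
source, BCAA uptake and a reversible ilvE-style transaminase feeding
branched-chain fatty-acid synthesis from the leucine skeleton, a linear
four-step single-gene carotenoid chain ending in a thermozeaxanthin-like
essential membrane component, and a biomass equation over four amino acids,
the BCFA pool and the carotenoid plus GAM = 58.34 and NGAM = 14
mmol gDCW$^{-1}$ h$^{-1}$ — maintenance values in the range established for
this organism class. The minimal (DMM-like) medium supplies 2 mmol
gDCW$^{-1}$ h$^{-1}$ glucose and 10 oxygen with minerals free; the complex
(TM-like) medium adds trehalose (2) and leucine/valine/isoleucine/glutamate
(2/1/1/2). Uptake rates are fixture choices at realistic magnitudes — the
organism's measured exponential-phase rates exist only in figure form and
are therefore user inputs, never constants.

Under these conditions the fixture grows at $\mu \approx 0.116$ h$^{-1}$
minimally and $\approx 0.567$ h$^{-1}$ in complex medium (ratio $\approx
4.9$), reproducing the qualitative contrast between the two media; all
carotenoid-chain knockouts are lethal in both media (the chain has no
alternative route), amino-acid biosynthesis knockouts are lethal only
minimally, and isozyme-pair knockouts are silent. One emergent and
instructive behaviour: with oxygen capped, surplus NADH makes
NADPH-consuming biosynthesis partially cost-free, so amino-acid synthesis
does not vanish in the complex medium — but synthesis flux per unit biomass
drops several-fold, and the balance table shows leucine consumed far beyond
its protein demand with the surplus routed into fatty-acid synthesis.

**What the fixture does not emulate.** Real genome-scale networks have
hundreds of alternative routes, compartments beyond `[c]`/`[e]`,
thermodynamic and regulatory effects, and measured uptake kinetics. Passing
the fixture-based tests demonstrates the correctness of the machinery
(optimality, GPR logic, accounting identities), not predictive accuracy on
any real organism; analyses of a real model inherit that model's quality.

## Numerical and design choices, in brief

* Default bounds $(-1000, 1000)$ reversible, $(0, 1000)$ irreversible —
  conventional "effectively unbounded" sentinels.
* Uptake negative / secretion positive internally; reporting functions
  convert to the positive-supply convention of published balance tables.
* Two compartments; exchanges are identified by the `EX_` prefix or
  single-metabolite one-sided stoichiometry, both accepted.
* SBML level 2 version 1 predates the `fbc` extension, so GPRs travel in
  `GENE_ASSOCIATION:` notes lines and bounds/objective in kineticLaw
  parameters; the reader tolerates absent notes (one summary warning)
  rather than failing, since note conventions vary between distributions.
* Element balance checking uses ionized formulas where shipped (so ATP
  hydrolysis balances exactly); reactions touching any formula-less
  metabolite are reported `unchecked`, never flagged.
* Gap *filling* is out of scope by design: the QC module detects gaps and
  verifies user-supplied repairs, as curation was literature-driven.

## Problem sizes used in the shipped checks

The test-suite and acceptance computations run at desk scale by choice:
planted-optimum recovery over 100 seeded networks, vertex-enumeration
cross-checks on networks with ≤ 6 free fluxes, dead-end oracles on ≤ 7
metabolites, and the 42-reaction fixture for FBA/FVA/deletion/balance
stages. These sizes exercise every code path; the algorithms themselves are
dimension-generic.

## A worked example

```{r example, eval = FALSE}
fx <- buildThermophileFixture()
sol <- solveFBA(applyMedium(fx$model, fx$tm, ngam = fx$ngam))
objectiveValue(sol)              # 0.567 h^-1
bal <- aminoAcidBalance(sol, applyMedium(fx$model, fx$tm, ngam = fx$ngam))
bal[bal$amino_acid == "L_LEU[c]", c("supply", "demand", "to_others")]
rep <- classifyEssentiality(
  scanSingleDeletions(fx$model, list(DMM = fx$dmm, TM = fx$tm), ngam = 14),
  model = fx$model)
table(rep@classification)
```
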