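---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the model, the numerical choices, and the design
decisions behind `oleoflux`, in the spirit of a methods supplement. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## The constraint-based model

All analyses operate on the steady-state flux cone
$\{v : S v = 0,\ lb \le v \le ub\}$ of a compartmentalized
stoichiometric model. Conventions:

* Bounds are in mmol gDW⁻¹ h⁻¹; the biomass reaction's flux is the
  specific growth rate (h⁻¹). Irreversible reactions default to
  $[0, 1000]$, reversible to $[-1000, 1000]$; 1000 is the conventional
  "unbounded" sentinel.
* Exchange reactions are written `met[e] <=> (nothing)`; negative flux
  is uptake. User-facing uptake *rates* are positive magnitudes and are
  translated to negative lower bounds (`apply_medium()`, the CLI).
* A medium closes every exchange lower bound to zero except its
  overrides and an explicit *always-open* set (O₂, CO₂, water, protons,
  phosphate, sulfate). The always-open set is a modelling necessity —
  no genome-scale model is feasible without free water and protons —
  and is a visible, configurable field of the `medium` object, not a
  hidden default.
* GPR rules use infix boolean grammar with `AND` binding tighter than
  `OR`, case-insensitive keywords, and commas parsed as `OR` (tabular
  isozyme lists). Complexes are `AND`; isozyme sets are `OR`. Where the
  underlying biology names several candidate enzymes for one step
  without stating complex membership, the synthetic model encodes them
  as isozymes — the weaker assumption.

## Linear programming

No LP solver package ships in the target environment, so the LP core is
a bounded-variable primal simplex implemented in `lp_solve()`: Phase I
with signed artificial columns, Dantzig pricing with a Bland's-rule
fallback after $2(m+n)$ iterations (guaranteeing termination under
degeneracy), a product-form basis-inverse update with refactorization
every 60 pivots, and tolerances of $10^{-9}$ on reduced costs and
$10^{-7}$ on Phase-I feasibility. Status is always explicit
(`optimal` / `infeasible` / `unbounded`); infeasibility is never
reported as a zero objective.

Only objective values are contract-stable ($\le 10^{-9}$ across row or
column permutations); with degenerate alternate optima the returned
flux vector is *an* optimal vertex. The test suite checks the solver
against exhaustive vertex enumeration on every toy network and against
`boot::simplex` on random standard-form LPs.

## Quadratic programming (MOMA)

MOMA minimizes $\lVert v - v_{wt} \rVert_2$ over the knockout flux
cone. The projection is unique by strict convexity, but the raw QP is
numerically hostile: the equality system has conserved-moiety rank
deficiencies and hundreds of box constraints. `solve_moma()` therefore:

1. certifies feasibility by LP and builds a relative-interior anchor
   (midpoint of two opposite LP vertices) — anchoring at a single
   vertex leaves too many constraints exactly active and makes
   `quadprog::solve.QP`'s active-set method fail spuriously;
2. eliminates pinned variables ($lb = ub$) and parameterizes the
   remaining equality manifold with an orthonormal null-space basis, so
   the reduced Hessian is exactly the identity;
3. drops bound constraints whose null-space normal is numerically zero
   (variables fully determined by the equalities), after checking them
   for infeasibility;
4. retries `solve.QP` along a ladder of tiny feasibility relaxations
   ($0, 10^{-10}, 10^{-9}, 10^{-8}$); the solution shift is of the
   order of the relaxation, far below the $10^{-6}$ contract tolerance.

The *reference* flux vector is a convention, because FBA vertices are
not unique: the pipeline uses the FBA solution of the production
scenario (growth pinned, product exchange maximized) and records the
vector it used. MOMA results are defined relative to that stored
reference. Note one subtlety the tests make explicit: projecting the
wild-type vector onto a knockout cone generally moves *all* fluxes a
little rather than only rerouting the knocked branch; the
parallel-branch textbook answer (distance $\sqrt 2$) is recovered
exactly when the auxiliary fluxes are pinned to the reference, while
the free projection has distance $\sqrt{7}/2$. Both are asserted
against a Dykstra alternating-projection oracle.

An L1 variant (`solve_moma_l1()`) is provided as a labelled
alternative; its optimum need not be unique and it is never silently
substituted for the quadratic contract.

## Essentiality

A gene is essential on a medium when knockout growth falls below 1% of
wild type (`threshold = 0.01`). The literature states no universal
cutoff; 1% is the conservative standard and every report carries its
threshold as an attribute. Deletions that make the LP infeasible (e.g.,
by making forced maintenance unmeetable) are called essential. Genes
whose disabled reactions all carry zero flux in the wild-type optimum
are skipped without re-solving — the wild-type optimum remains feasible,
so the call is exact, not an approximation. On essential-gene
percentages: 86 of 1106 model genes is 7.78%, so published percentages
of this kind are computed against model genes, not genome genes; the
acceptance targets use that denominator.

## Gap detection

The spec'd detection primitive — a per-metabolite LP demanding net
production $\ge \varepsilon$ — misclassifies every conserved-moiety
cofactor (ATP/ADP, NAD(P)(H), CoA and the whole acyl-CoA pool) as a
gap, because a conserved pool can never show *net* production at steady
state. The gapFind MILP scores *gross* production: a binary indicator
per producing reaction. `find_blocked_metabolites()` therefore asks
whether any producing reaction direction can carry flux
($\ge 10^{-4}$) while other metabolites are allowed to accumulate
($S v \ge 0$; the consumption side mirrors this with $S v \le 0$), and
implements it as a certificate-sharing LP search: each feasibility LP
that activates one direction also certifies every direction carrying
flux in its solution, so a well-connected model needs only a handful of
LPs. "Root" gaps (no producing reaction at all) are reported
separately. Dead-end *reactions* (`find_blocked_reactions()`) use strict
steady-state semantics (FVA range exactly $[0,0]$) — hence an exchange
of a dead branch can be flux-blocked while its boundary species is
still "producible" under the accumulation relaxation.

## Biomass assembly

`build_biomass_reaction()` turns mass fractions into stoichiometry:
coefficient $= f_{component} \times w_{monomer} / M_{monomer} \times
1000$ mmol gDW⁻¹, plus a mass-neutral GAM ATP-hydrolysis cycle. The
invariant "1 g of monomer mass drained per unit flux" is asserted to
$10^{-6}$. NGAM is imposed by pinning the ATP-maintenance reaction
(`add_ngam()`, $lb = ub$). Consequence worth knowing: with NGAM pinned,
an all-closed medium is *infeasible* rather than zero-growth — the
maintenance demand cannot be met — and the screens treat that as "no
growth".

## The synthetic model: what it emulates and what it does not

`mini_alpina()` is the package's stated world: a deterministic,
elementally audited (for the formula-complete carbon/energy core)
network whose *structure* mirrors an oleaginous fungus. Parameter
choices, fixed once:

* **Biomass** (g/gDW): protein 0.42, cell wall 0.25, lipid 0.18, RNA
  0.06, DNA 0.015, small-molecule pool 0.075 — a literature-typical
  fungal composition, explicitly *not* the values of any published
  reconstruction (those live in journal supplements). Amino-acid
  weights are uniform (0.05 each); monomer masses are standard.
* **GAM 30 mmol gDW⁻¹, NGAM 1 mmol gDW⁻¹ h⁻¹** — round values in the
  fungal range; both are plain spec parameters with no hidden defaults.
* **Desaturases: 1 O₂ + 1 NADPH per double bond; elongation: 2 NADPH
  per C2 cycle** — the canonical costs; per-step values are spec
  toggles (`mini_alpina_spec()`), since the literature does not print
  them numerically.
* **Media**: MG = glucose (uptake 0.8) + nitrate + salts; YE = MG + all
  20 amino acids at uptake 0.01 each. Both ship as config files.
* Three reactions beyond the obvious sketch were *required* for the
  stated behaviours and are documented as such: a cytosolic-NADH
  shuttle lump (external NADH dehydrogenase / G3P shuttle; without it,
  malic enzyme was accidentally the only cytosolic NADH sink and its
  knockout killed growth outright), a gluconeogenesis lump (growth on
  glycerol and rhamnose), and the glyoxylate shunt plus PEP
  carboxykinase (growth on ethanol, acetate, lactate). The
  non-phosphorylating alternative oxidase gives the cell a way to burn
  excess oxygen at carbon cost, which is what makes the ARA-vs-O₂
  robustness curve fall beyond its optimum (the rising branch is
  desaturase O₂ demand; concavity of the LP value function in the
  pinned uptake guarantees single-peakedness).

What a green test on this model does **not** establish: agreement with
the published genome-scale numbers (growth 0.0690 h⁻¹, ARA 0.128,
86/49 essentials, oxygen optimum 2.0, 53 changed NADPH reactions).
Those require the published supplementary model file, which has no
database accession; the package reproduces the *behaviours* — the
YE ⊂ MG essential-gene nesting, the strict ARA drop under the
malic-enzyme MOMA knockout, the interior oxygen optimum, the
nitrate/nitrite-reductase essentiality, the rhamnose-lyase gap — at
synthetic scale, and records the published values as labelled reference
cells in `paper_report()`.

`random_viable_model()` serves the property suites: an embedded
uptake→biomass backbone guarantees viability; `mode = "acyclic"`
produces irreversible unimolecular DAGs on which LP gap detection must
(and does, 100/100 seeds) coincide with graph reachability.

## Numerical conventions

* LP feasibility/optimality $10^{-9}$; steady-state residual asserted
  $\le 10^{-6}$ (scaled); bound violations $\le 10^{-9}$.
* Differential-flux threshold $10^{-6}$ mmol gDW⁻¹ h⁻¹, strict `>`.
* Cofactor reports are per-compartment by default (cytosolic NADPH is
  not mitochondrial NADPH); `pooled = TRUE` merges compartments, since
  published reaction counts do not state which convention they used.
* Robustness scans pin uptake as an equality ($lb = ub = -u$); an upper
  bound would make the declining branch invisible, and the published
  decline at high uptake implies equality semantics. Infeasible scan
  points are `NA`, never 0.
* Coefficients are serialized as shortest exact decimals; biomass
  coefficients are never rounded on write.

## Known limitations

* The simplex is dense and single-threaded; it is sized for
  $\sim 10^2$–$10^3$ reactions, not for multi-compartment pan-genome
  models.
* SBML support is a constrained L3+fbc-v2 subset (plus a COBRA-style L2
  bounds/notes fallback) — enough for faithful round-trips and typical
  COBRA exports, not a validator.
* Gap *filling* is out of scope; only detection is automated, matching
  the curation-driven workflow it supports.
* Thermodynamic (loop-law) constraints are not imposed; charge
  imbalance is reported by the elemental audit as information, never
  enforced.
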