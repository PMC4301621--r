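# oleoflux

Constraint-based flux analysis for compartmentalized genome-scale
metabolic models, oriented towards polyunsaturated-fatty-acid (PUFA)
producing oleaginous fungi such as *Mortierella alpina*, the industrial
source of arachidonic acid (ARA, 20:4 n-6).

These organisms route glycolytic carbon through acetyl-CoA into a fatty
acid synthase, then elongate and desaturate the C16/C18 products step by
step — each desaturation consuming molecular oxygen and each
elongation/desaturation cycle consuming NADPH — up to ARA and, on the
omega-3 branch, eicosapentaenoic acid (EPA). Understanding and
engineering that flux requires a genome-scale stoichiometric model and
the standard constraint-based toolbox. `oleoflux` implements that
toolbox end to end in R, with no external solver dependency.

## The model and methods

A metabolic network with $M$ metabolites and $N$ reactions is encoded as
the stoichiometric matrix $S \in \mathbb{R}^{M \times N}$. A flux vector
$v$ is feasible when

$$S\,v = 0, \qquad lb \le v \le ub,$$

with bounds in mmol gDW⁻¹ h⁻¹ (negative exchange flux = uptake; the
biomass pseudo-reaction carries the specific growth rate in h⁻¹).

* **FBA** — `solve_fba()` maximizes an objective flux (growth, or a
  product exchange with growth pinned via `solve_fba_fixed_growth()`)
  by linear programming. The LP core is a bounded-variable primal
  simplex written in this package (`lp_solve()`).
* **FVA** — `fva()` reports each reaction's flux range at a stated
  fraction of the optimum (2 LPs per reaction).
* **Robustness** — `robustness_scan()` pins one exchange across a grid
  (e.g., oxygen uptake 0–20) and re-optimizes; infeasible points are
  reported as missing, never as zeros.
* **MOMA** — `solve_moma()` finds the knockout flux state of minimal
  Euclidean distance to a wild-type reference,
  $\min \lVert v - v_{wt}\rVert_2$ subject to the knockout constraints,
  via `quadprog` in null-space coordinates. An L1 variant
  (`solve_moma_l1()`) is provided as a labelled alternative.
* **Essentiality** — `single_gene_deletion()` /
  `single_reaction_deletion()` evaluate boolean gene–protein–reaction
  (GPR) rules (`AND` = complex, `OR`/comma = isozymes) under each
  deletion and call a gene essential when knockout growth falls below
  1% of wild type on the given medium.
* **Gap detection** — `find_blocked_metabolites()` /
  `find_blocked_reactions()` locate metabolites with no feasible
  producing (or consuming) reaction direction, gapFind-style, plus
  structural "root" gaps.
* **Biomass assembly** — `build_biomass_reaction()` converts a
  six-component macromolecular composition (protein, DNA, RNA, lipid,
  cell wall, small-molecule pool; coefficient = fraction × monomer
  fraction / molar mass × 1000) plus growth- and non-growth-associated
  ATP maintenance (GAM/NGAM) into a biomass reaction.
* **Cofactor accounting** — `differential_flux_report()` and
  `producer_consumer_split()` give metabolite-centric views: which
  NADPH reactions change between two conditions (strict threshold
  10⁻⁶), and which reactions produce/consume acetyl-CoA in what shares.

Models are read and written as SBML Level 3 + `fbc` v2 (`read_sbml()` /
`write_sbml()`) or as a plain TSV bundle (`read_tabular_model()` /
`write_tabular_model()`).

## The bundled synthetic model

`mini_alpina()` deterministically generates a compact oleaginous-fungus
network (132 metabolites × 167 reactions × 93 genes across
extracellular, cytosolic, mitochondrial and peroxisomal compartments):
lumped glycolysis and oxidative pentose phosphate pathway, the
pyruvate-carboxylase/malate/malic-enzyme transhydrogenation cycle, a
citrate shuttle, fatty-acid synthesis with the explicit
elongase/desaturase chain to ARA and EPA, nitrate assimilation, all 20
amino acids, several alternative carbon sources and peroxisomal
beta-oxidation. The generator also returns a ground-truth record
(NADPH reaction set, expected essential genes, the rhamnose-lyase gap
fixture) that the test suite checks against. It is a *synthetic*
model: structurally faithful to the oleaginous-fungus literature, not a
reproduction of any published reconstruction.

## Worked example

```r
library(oleoflux)

ma  <- mini_alpina()                 # model + ground truth
mg  <- apply_medium(ma$model, medium_mg())   # glucose 0.8 + nitrate + salts
ye  <- apply_medium(ma$model, medium_ye())   # MG + 20 amino acids @ 0.01

solve_fba(mg)$objective_value        # 0.0681  (growth on MG, h-1)
solve_fba(ye)$objective_value        # 0.0975  (growth on YE, h-1)

# ARA production mode: growth pinned at 0.03 h-1, ARA exchange maximized
prod <- solve_fba_fixed_growth(ye, 0.03, "EX_ara")
prod$objective_value                 # 0.1017  (mmol gDW-1 h-1)
prod$flux[["ME"]]                    # 0.9309  (malic enzyme active)

# malic-enzyme knockout under MOMA: ARA drops strictly
ko <- set_bounds(knockout_gene(ye, "gME"), "BIOMASS", 0.03, 0.03)
m  <- solve_moma(ko, prod)
m$flux[["EX_ara"]]                   # 0.0735  (-27.7%)
count_changed_reactions(prod, m)$count   # 70 reactions changed > 1e-6

# medium-conditioned essentiality: 35 genes on MG vs 7 on YE
print(single_gene_deletion(ma$model, medium_mg()))
print(single_gene_deletion(ma$model, medium_ye()))

# oxygen robustness: single-peaked with an interior optimum (1.25 here)
robustness_scan(ye, "EX_o2", seq(0.25, 6, 0.25),
                objective = "EX_ara", min_growth = 0.03)
```

The growth rates, the strict ARA drop after the malic-enzyme knockout,
the YE ⊂ MG essential-gene nesting and the interior oxygen optimum are
the synthetic-scale mirrors of the published genome-scale behaviour;
they are regenerated, not asserted, every test run.

A command-line front end ships in `inst/cli/oleoflux`
(`fba`, `fva`, `robustness`, `essentiality`, `sources`, `moma`,
`cofactor-report`, `gaps`, `report`, `make-model`).

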