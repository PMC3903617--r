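---
title: "Methods: in-silico CDR saturation screening and SPR binding energetics"
author: "abmature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico CDR saturation screening and SPR binding energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Affinity maturation of a therapeutic antibody asks: which single point
mutations in the complementarity-determining regions (CDRs) make the
antibody bind its antigen more tightly? `abmature` implements a two-stage
answer for the 11K2 scFv / MCP-1 system and for synthetic test systems:

1. **In-silico saturation screen.** Every CDR position is mutated to each
   of the other 19 amino acids. For each mutation an ensemble of
   randomized, relaxed models of the antibody–antigen complex is built and
   scored by the cross-partner nonbonded interaction energy (electrostatic
   plus van der Waals). The median energy shift against a wild-type
   reference ensemble, ΔE, ranks the candidates; negative ΔE suggests
   higher affinity.
2. **SPR characterization.** Candidate muteins are described by their
   Langmuir 1:1 kinetics (k_on, k_off, K_D = k_off/k_on), van't Hoff
   equilibrium thermodynamics (ΔH°, ΔS° from the temperature dependence of
   K_D), Eyring activation parameters (ΔH‡, ΔS‡ from the temperature
   dependence of k_on), ΔΔ tables against wild type, and an
   enthalpy–entropy compensation summary.

## The energy model

The affinity surrogate is the pairwise nonbonded energy between the two
binding partners,

E = Σ_{i∈A, j∈B} [ k_C q_i q_j / (ε r_ij) + ε_ij ((r_min,ij/r_ij)^12 − 2 (r_min,ij/r_ij)^6) ],

with k_C = 332.0637 kcal·Å·mol⁻¹·e⁻², a uniform dielectric ε = 80
(bulk-water-like screening), Lorentz-style combination
r_min,ij = r_min,i/2 + r_min,j/2 summed from per-atom half-minima and
ε_ij = √(ε_i ε_j). Intra-partner pairs never contribute. There is no
distance-dependent dielectric and no solvation term. The default is the
exact all-pairs sum; an optional hard cutoff (no switching function, a
documented discontinuity) is available for well-separated partners.

The parameter table is a **united heavy-atom** set bundled as plain text
(`inst/extdata/ff_params.tsv`): hydrogens are omitted and their charges
folded into the bonded heavy atoms, backbone groups are net neutral, side
chains carry the formal charge (Arg/Lys +1, Asp/Glu −1, His neutral, free
termini not modeled). This is a functional-form model in the AMBER 12-6
family, not a literal published force field: absolute energies are not
comparable to values computed with a full all-atom force field, and the
package therefore validates the screen **structurally** (sign, ranking,
oracle agreement) rather than against absolute published ΔE values. What
the model does preserve — deliberately — is the dominance of charge
complementarity across the interface, which is the signal the original
screen exploited.

## Mutation building and the model ensemble

Side chains are rebuilt from ideal internal coordinates (bundled bond
lengths/angles per residue type) and χ angles taken from a coarse
backbone-independent rotamer library (`inst/extdata/rotamer_library.tsv`,
≤ 81 rotamers per residue, priors summing to 1; user-replaceable
whitespace-delimited format). Backbone atoms (N, CA, C, O) and the Cβ
anchor are never moved, exactly. Gly targets simply lose the side chain;
Pro targets are rejected by default because the pyrrolidine ring is not
representable with a fixed backbone (`allow_risky = TRUE` overrides, and
the screen reports such rows as excluded rather than dropping them).

Each mutation is scored on an ensemble of `n_models` randomized models
(default 100; the benchmark analyses use 20). Per model:

1. every residue owning movable side-chain atoms is processed in
   deterministic (chain, residue) order; the **focal** (mutated) residue
   starts from a rotamer drawn from the library prior, all others from
   their current χ angles, each with an added Gaussian perturbation
   (σ = 15°, a package choice — the randomization magnitude of the
   original modelling protocol is not recoverable);
2. an **annealing stage** refines each side chain: an accept-if-lower scan
   over the full rotamer list (the barrier-crossing move that the original
   simulated-annealing protocol provided), then `n_anneal = 3` cooled
   Gaussian χ proposals (geometric cooling 0.6);
3. Cartesian **minimization** relaxes all movable atoms;
4. the full cross-partner interaction energy of the relaxed model is
   recorded, along with the minimum cross-partner heavy-atom distance.

Models whose minimum cross-partner heavy-atom distance exceeds the contact
cutoff (default 4.5 Å; the criterion for "no non-covalent interaction with
the antigen" is not standardized, so the cutoff is exposed as
configuration) are filtered out before statistics. The wild-type reference
ensemble uses the *same* protocol over the interface neighbourhood without
the focal resampling, so an identity "mutation" reproduces the reference
distribution — the package tests this (ΔE of X→X within twice the
bootstrap standard error of zero).

The movable set is the mutated side chain plus the side chains of every
residue (either partner) with a heavy atom within 6 Å of it. All seeds are
derived per mutation and per model from the master seed and the mutation
id, so screen results are byte-identical regardless of execution order.

## Minimization

The objective is the nonbonded energy over pairs with at least one movable
atom (cross-partner, or both within the movable selection) plus harmonic
ideal-geometry restraints. Angle and planarity restraints are implemented
as 1–3 and rigid-group (rings, guanidinium, carboxylate, amide) pairwise
*distance* harmonics whose equilibria are the ideal-build geometry —
identical in effect at these amplitudes to explicit angle/dihedral terms
but with much simpler exact gradients. Force constants are
k_bond = 100, k_1–3 = k_rigid = 40 kcal·mol⁻¹·Å⁻²: stiff enough that
kcal-scale nonbonded forces distort the geometry by well under 0.01 Å,
soft enough to keep the objective's conditioning tractable.

The minimizer is a preconditioned limited-memory quasi-Newton descent
(L-BFGS, memory 10, diagonal preconditioner from the restraint stiffness)
with Armijo backtracking, so the accepted-step energy trace is monotone
non-increasing by construction. Convergence is declared when the RMS
Cartesian gradient over movable atoms falls below 0.01 kcal·mol⁻¹·Å⁻¹
(the convergence threshold of the original minimization protocol, reading
its "mean square gradient" criterion as an RMS gradient), with
`max_steps = 2000`. A plain steepest-descent line search cannot reach this
threshold on the stiff/soft mixed objective in a reasonable step count,
which is why a quasi-Newton direction is used; the line-search descent
contract (monotone trace) is unchanged. The inner energy/gradient kernel
and the descent loop are compiled (Rcpp); a plain-R reference
implementation of both is kept in the package and the test suite asserts
that the two paths produce identical objectives, gradients, and early
descent traces. A non-finite starting energy (exact atom overlap) triggers
perturb-and-retry up to 3 times before a model is marked failed.

## Selection rule

The published selection was a visual judgment of histogram shifts; it is
concretized here as: selected ⇔ ΔE ≤ −1.0 kcal/mol AND at least 50% of the
ensemble's models are valid (contact-bearing). Both thresholds are
configuration. Ranking is ascending in ΔE with a deterministic
(chain, position, target) tie-break; mutations with no valid models are
ranked last and reported as excluded.

## The synthetic test bed

Real crystal structures are external inputs, so the package generates its
own: two ideal α-helices (rise 1.5 Å/residue, 100°/residue, Cα radius
2.3 Å) facing across a configurable axis separation, with side chains
built from the rotamer library and then **greedily packed** — per residue,
the rotamer with the lowest static nonbonded energy against the rest of
the structure is kept. Packing puts the template into its native
side-chain basin the way a crystal structure would be; without it the
generated template can start in a clashing or non-contact basin and the
wild-type reference (which, like the original protocol applied to the
x-ray structure, only relaxes locally) would not represent the bound
state.

The planted benchmark (`plant_mutation_benchmark()`) places a Gln at the
site on the antibody helix directly facing a Glu on the antigen helix at
13.5 Å axis separation. The wild-type site identity is deliberately a
residue of reach comparable to the charged candidates: with a small wild
type (Ser was tried first) every bulky substitution gains generic van der
Waals contact and even a like-charge Glu scores favorably — the benchmark
must isolate charge complementarity, not side-chain size. With the
Gln/Glu geometry the exhaustive static rotamer oracle (no minimization,
exactly reproducible) gives Arg ≈ −3.1 and Lys ≈ −1.6 kcal/mol as the only
favorable substitutions and Asp/Glu clearly unfavorable (+1.7/+1.1);
agreement between the oracle and the minimized pipeline is asserted at
sign and rank level only, by design.

Kinetics are simulated generatively from the same models the fits assume:
K_D(T) = exp((ΔH° − TΔS°)/RT), k_on(T) = (k_B T/h)·exp(−(ΔH‡ − TΔS‡)/RT),
k_off = K_D·k_on, with independent multiplicative lognormal noise
(median 1) on k_on and k_off. Sensorgrams follow the Langmuir 1:1
association/dissociation forms with additive Gaussian RU noise. The
synthetic temperature grid is 283–313 K in 7 steps (the experimental
temperatures are not published; this is a typical SPR range), and the
generator's wild-type parameters are the published WT values
(ΔH° = −7.3, −TΔS° = −5.0, ΔH‡ = 11.4, −TΔS‡ = −0.8 kcal/mol at 25 °C).

**What passing tests show — and what they do not.** The synthetic
complexes have ideal geometry, no backbone flexibility, no water, and a
single planted interaction; success there demonstrates that the machinery
(enumeration, building, relaxation, scoring, statistics, fitting) is
correct and that the screen detects planted electrostatic
complementarity. It does not demonstrate predictive accuracy on real
antibody–antigen interfaces, where conformational change, solvation and
entropy are unmodeled. Likewise the simulated kinetics satisfy the van't
Hoff/Eyring models exactly by construction; real data need not.

## SPR analysis conventions

All fits use unweighted OLS (`lm`); the published analysis gives no
weighting detail. Sign conventions are fixed to the dissociation-constant
binding direction: ln K_D = ΔH°/(RT) − ΔS°/R, so
ΔG° = RT ln K_D = ΔH° − TΔS° is negative for sub-molar binders, and the
signs of the ΔΔ tables match the published tables. All "at 25 °C"
quantities use T_ref = 298.15 K; R = 1.9872×10⁻³ kcal·mol⁻¹·K⁻¹;
k_B T/h = 6.21×10¹² s⁻¹ at 25 °C. The identity ΔG = ΔH − TΔS holds exactly
in every emitted parameter set because ΔG is constructed, never fitted
separately.

The sensorgram model is R(t) = R_eq(1 − e^{−(k_on C + k_off)t}) with
R_eq = R_max C/(C + K_D) during association and exponential decay from the
association end point during dissociation; k_on, k_off (log-scale, so
positivity is structural) and R_max are shared across concentrations and
fitted by Levenberg–Marquardt least squares (`minpack.lm`). Bulk
refractive-index jumps, baseline drift and mass-transport limitation are
not modeled, and the generator matches this — a documented limitation
relative to instrument-vendor evaluation software.

Published K_D values are never silently corrected: a reported K_D whose
product with k_on deviates from k_off by more than 10% relative is
flagged (`kd_inconsistent`), which in the bundled 25 °C panel flags
exactly the WT and H-N28D rows. Fold-improvements are recomputed from the
reported K_D values (giving 4.7 for the best mutein, where the published
table rounds to 4.6 and the running text says 4.7). Report printing
follows the field's table conventions (2 significant figures for K_D in
nM, one decimal for kcal/mol); machine-readable outputs keep full
precision.

## Structure handling

PDB I/O goes through `bio3d` behind `read_pdb()`/`write_pdb()`; author
numbering is preserved and never silently renumbered, insertion codes
verbatim, alternate locations other than blank/"A" dropped with a count,
duplicate atoms warn-and-keep-first. CDR selection takes explicit residue
lists or inclusive author-numbered ranges on the antibody partner; no
antibody numbering scheme is computed — numbering provenance is the
user's assertion. Buried surface area uses Shrake–Rupley sampling with a
deterministic golden-spiral point set (960 points/atom, probe 1.4 Å);
values are approximations for reporting, not validation targets.

## Problem sizes and reproducibility

The bundled analyses use: 20 models per mutation against a 30-model
wild-type reference on an 11+11-residue toy complex (the screen); 7
temperatures × 200 noise seeds (temperature-series recovery); 5
concentrations × 100 seeds (sensorgram recovery); 100 random complexes
(energy-oracle equivalence); 20 master seeds (benchmark stability). These
sizes were chosen so the complete analysis reruns in minutes on one core
while every statistic is comfortably inside its tolerance. All generators
and the screen are pure functions of (specification, seed).

## Repository shape

The package is organised as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers over the exported functions,
and `run_screen()`/`run_characterize()` are the programmatic entry points;
there is no shell CLI, since every consumer of this work drives it from R.
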