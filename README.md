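# dispermd

Desk-scale molecular-dynamics screening of drug–polymer pairs for amorphous
solid dispersions, in R.

Poorly water-soluble drugs (APIs) are often formulated as amorphous solid
dispersions: the drug dispersed molecularly in a polymeric excipient. Which
polymer suits which drug is largely a question of intermolecular
interactions, and molecular-dynamics screening answers it with three
statistics computed from short simulations of API/polymer mixture boxes:

* the time-averaged **interaction energy** between the API group and the
  polymer group, decomposed into electrostatic and Lennard-Jones parts,
  `E_total = E_coul + E_LJ` (more negative = stronger binding);
* the **energy ratio** `E_total(API–polymer) / E_total(API–API)` — how
  strongly the polymer outcompetes drug self-association;
* the number of geometric **hydrogen bonds** per API molecule
  (donor–acceptor distance ≤ 3.5 Å and hydrogen–donor–acceptor angle
  ≤ 30°).

`dispermd` provides the whole chain at desk scale: an OPLS-style force
field (LJ + Coulomb, geometric combining rules, 0.5-scaled 1-4 pairs,
harmonic bonds/angles), steepest-descent minimization, a leap-frog
integrator with stochastic velocity-rescale thermostatting and
weak-coupling barostatting, structure/trajectory/topology readers and
writers (PDB, GRO, XYZ, a documented binary format), a synthetic-system
generator (toy API and excipient archetypes, 10-monomer chains, mixture
boxes at prescribed wt%, crystal supercells), and the analysis layer
(group energies, energy ratio, H-bonds, RDF per the shell-count
normalization, center-of-mass MSD with an Einstein-relation diffusion fit,
crystal density/lattice validation).

The packaged molecules are coarse synthetic archetypes, not real drug
parameterizations; real OPLS-AA systems can be supplied through the
topology text format. See `vignettes/dispermd-methods.Rmd` for the model,
its assumptions, and what the packaged tests do and do not establish.

## Worked example

Crystal density from a unit cell — the force-field validation arithmetic:

```r
library(dispermd)
# monoclinic cell: a 13.30, b 5.76, c 7.87 A, beta 93.9 deg, Z = 2, M = 230.26
cell <- unit_cell_spec(13.30, 5.76, 7.87, 90, 93.9, 90,
                       z = 2, molar_mass = 230.26)
cell_density(cell)
#> [1] 1.271322
```

1.271 g/cc is the crystal density implied by that cell: Z × M over
Avogadro's number times the cell volume (601.5 Å³).

Screen one API archetype against two excipients (toy scale, ~1 minute):

```r
plan <- experiment_plan(apis = "DLO", excipients = c("HPP", "ELM"),
                        n_api = 4, t_run_ps = 1.5, seeds = 1L)
rep <- run_screening_matrix(plan)
rep
#> <screening_matrix_report> plan 787a84a6
#>   DLO: best ELM (ELM > HPP)
```

Each system is built (random insertion at the target wt%, compression to a
loose melt, minimization), simulated (NVT at 300 K, velocity-rescale
thermostat), and analyzed over the last 80% of the trajectory; the report
ranks excipients by most-negative `E_total` (ties: energy ratio, then
hydrogen bonds) and carries the plan hash and seeds so it can be
regenerated exactly.

Single-run statistics:

```r
res <- run_mixture_system("DLO", "HPP", wt = 5, temperature = 300,
                          plan = experiment_plan(n_api = 6, t_run_ps = 5),
                          seed = 1)
res$e_api_polymer
#> <interaction_energy> API -- polymer over 41 frames
#>   E_coul = -1705.02, E_LJ = 75.68, E_total = -1629.34 (+/- 106.89) kJ/mol; per molecule -271.56
res$hbonds
#> <hbond_result> API -- polymer: mean 18.05 bonds/frame (3.008 per molecule of API)
```

The ionic archetype is dominated by electrostatics (|E_coul| ≫ |E_LJ|) and
forms several hydrogen bonds per API — the behaviour the screening
statistics are designed to detect; neutral archetypes show the reverse
dominance.

A command-line interface wraps the same operations:

```sh
dispermd=$(Rscript -e 'cat(system.file("cli/dispermd", package = "dispermd"))')
Rscript "$dispermd" energy --traj traj.bin --top system.top \
        --group-a "resname DLO" --group-b "resname HPP" --window 2:10
Rscript "$dispermd" screen --out results/ --seed 1
```

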