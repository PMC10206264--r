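# bindsight

Binding-model analysis of protein–ligand molecular dynamics trajectories and
structure-guided, combinatorial R-group design — in R, with tibbles in and
tibbles out.

## Who it is for

Computational chemists and structural bioinformaticians who have an MD
trajectory of an inhibitor–kinase complex (the worked system is an
ATP-competitive CDK6 inhibitor) and want the standard end-state analysis
chain without leaving R:

* **hydrogen-bond occupancy** — a donor–H…acceptor triple counts as bonded
  when the donor–acceptor distance is < 3.5 Å and the acceptor–H–donor angle
  (vertex at H) is > 120°; occupancy is the percentage of bonded frames;
* **MM/GBSA binding free energy** with per-term accounting,

  ΔE·gas = ΔE·vdW + ΔE·ele,  ΔE·solv = ΔE·GB + ΔE·surf,
  ΔG = ⟨ΔE·gas + ΔE·solv⟩ − TΔS,

  using an OBC-II generalized-Born polar term, a Shrake–Rupley
  surface-area nonpolar term (E·surf = γ·SASA, γ = 0.0072 kcal/(mol·Å²)),
  and a quasi-harmonic entropy estimate (external TΔS values pass through);
* **per-residue decomposition** of the binding enthalpy with backbone /
  side-chain splits and a 0.50 kcal/mol key-residue threshold;
* **trajectory clustering** (average-linkage on pairwise RMSD) whose medoid
  frames become a rigid-receptor ensemble;
* **four-region R-group design**: one-region libraries, top-3 group selection
  per region, the full 3×3×3×3 = 81 cross-combination with positional
  `C{r1}{r2}{r3}{r4}` names, named variants (`C2213` → `C2213-A` by deleting
  a methylene linker), min-over-ensemble score aggregation and a
  −10.00 kcal/mol shortlist.

A seeded synthetic-data generator plants hydrogen bonds at chosen
occupancies, contacts at chosen distances and harmonic fluctuations, so every
stage is testable without any external trajectory.

## Worked example

```r
library(bindsight)

# assemble the reported abemaciclib/CDK6 delta components
comp <- reference_energy_components()
d <- setNames(comp$delta, comp$term)
bd <- energy_breakdown(d[["E_vdW"]], d[["E_ele"]], d[["E_GB"]], d[["E_surf"]])
binding_free_energy(bd, T_delta_S = d[["T_delta_S"]])
#> delta_G = -9.74 kcal/mol (enthalpy -33.92 - T*dS -24.18)
energy_accounting(bd)
#>   polar nonpolar vdw_minus_ele
#> 1  24.0    -57.9         -24.4
```

The vdW + electrostatic enthalpy (−79.01) is opposed by desolvation
(+45.09); binding is enthalpy-driven (ΔH = −33.92) and entropy-opposed
(TΔS = −24.18), netting ΔG = −9.74 kcal/mol.

```r
# a seeded synthetic complex with one hydrogen bond planted at 80% occupancy
spec <- synthetic_spec(n_receptor_residues = 8, n_ligand_atoms = 6,
                       n_frames = 500,
                       planted_hbonds = list(planted_hbond(19, 20, 49, 0.8)),
                       seed = 1)
traj <- generate_trajectory(generate_complex(spec), spec)
detect_hbonds(traj)[, c("donor", "acceptor", "occupancy", "mean_distance")]
#>   donor  acceptor occupancy mean_distance
#> 1 ALA4@N LIG1@N1         82          3.37
```

The detector recovers the planted 80% occupancy (82% observed over 500
frames, inside the binomial sampling band).

```r
# four-region cross-combination of the packaged abemaciclib-analogue library
lib  <- read_design_library()
comb <- combine_regions(lib$scaffold, lib$combination)
nrow(comb)
#> 81
apply_variant(comb[comb$name == "C2213", ], lib$variants[[1]])$name
#> "C2213-A"
```

Analysis functions return tibbles (or objects with `tidy()` / `glance()`
methods), so results chain straight into dplyr/ggplot2; `plot_rmsd()`,
`plot_hbond_occupancy()`, `plot_residue_contributions()` and
`autoplot()` give standard figures. `run_pipeline(pipeline_config(...))`
executes the whole chain (analysis → MM/GBSA → binding model → design →
ensemble scoring) into a directory of deterministic TSVs with a JSON
manifest.

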