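# metabind

Determining *where and how* a small ligand binds inside a receptor
pocket is a central problem in structure-based pharmacology,
particularly for G protein-coupled receptors where co-crystal
structures of the relevant complex are often missing. Enhanced-sampling
molecular dynamics can find binding events that plain simulation never
sees, but the same enhancement that crosses barriers also populates
high-energy poses — so the *preferred* binding mode has to be
recovered from the biased ensemble by a dedicated post-processing
protocol.

`metabind` implements that protocol end to end, at desk scale, for
synthetic receptor–ligand systems with analytically known answers:

1. **Funnel-restrained well-tempered metadynamics** along a single
   binding collective variable (CV) — the z-component of the distance
   from a receptor anchor atom to the ligand's amine nitrogen,
   s = z(N) − z(anchor). Harmonic walls confine the CV to
   (z_low, z_up) with energy κ(z − z_wall)², and a funnel of radius

       R(z) = d / (1 + exp(m (z − w))) + r1

   restrains the transverse distance r = √(x² + y²) via

       U(x, y, z) = h (1 − 1 / (1 + exp(λ (r − R(z)))))

   (defaults d = 1.6 nm, r1 = 0.8 nm, m = 10 nm⁻¹, w = 2.8 nm,
   h = 100 kJ mol⁻¹, λ = 500 nm⁻¹).
2. **Well-tempered hill deposition**: Gaussians of width σ are dropped
   at the walker's CV every `stride` steps with height
   W = w0·exp(−V(s)/(kB ΔT)), ΔT = (γ − 1)T.
3. **Shared-bias multiple walkers** seeded equidistantly along the CV,
   all depositing into and feeling one bias.
4. **Free-energy reconstruction** F(s) = −γ/(γ−1)·V(s) from the merged
   hills, with the global minimum located by parabolic refinement.
5. **Frame extraction** within ΔCV ≤ 3 Å of the minimum, backbone
   (Kabsch) superposition, and **hierarchical average-linkage
   clustering on the unfitted ligand heavy-atom RMSD**, ranked by
   population.
6. **Unbiased Langevin refinement** of every cluster representative
   with RMSD/CV time-series diagnostics and a four-way classification
   (converged to reference / alternative stable / dissociated /
   flexible). The protocol succeeds when the top-populated cluster
   converges to the reference mode.

The synthetic-system module provides the ground truth: a 1D double
well whose basin free-energy gap is calibrated exactly by Boltzmann
integration, a 3D pocket-plus-channel landscape with a planted bound
pose and a metastable decoy, and multi-mode conformational ensembles
with planted cluster populations. A BAOAB Langevin integrator with
in-loop hill deposition (Rcpp) drives everything. HILLS/COLVAR files
are read and written in the PLUMED v2 dialect; trajectories as
multi-frame XYZ or multi-model PDB.

## Worked example

```r
library(metabind)

sys <- make_binding_system()          # planted bound pose at CV = 0.5 nm
cfg <- pipeline_config(sys, out_dir = "run", seed = 1)
res <- run_pipeline(cfg)

print(res$fes)
#> fes_profile: 513 points on [-0.49, 4.63] nm, minimum at 0.4961 nm (gamma = 20)
res$extract$fraction
#> 18.2       # % of walker frames within 3 A of the minimum
print(res$cluster_report)
#>   cluster population ligand_rmsd pocket_rmsd
#> 1       1      84.45        0.28           0
#> 2       2       8.81        4.92           0
#> 3       3       4.03        4.23           0
#> 4       4       1.66        6.19           0
#> 5       5       1.06        5.58           0
print(res$report$table)
#>   cluster         classification final_rmsd final_cv
#> 1       1 converged_to_reference       0.70    0.479
#> ...
cat(res$report$note, "\n")
#> top-populated cluster converged to the reference binding mode
```

Reading the output: the reconstructed free-energy minimum (0.496 nm)
falls within 0.005 nm of the planted bound-pose CV (0.5 nm); 18% of
the multiple-walker frames lie within the 3 Å extraction window; the
most populated cluster (84%) has a representative 0.28 Å from the
planted pose, while the minor clusters are alternative orientations
and vestibule poses several Å away; and unbiased refinement confirms
the top cluster as the binding mode (RMSD plateau well below 2 Å at
the reference CV).

A thin command-line front end covers the same stages:

```sh
Rscript inst/cli/metabind.R make-toy --kind binding --seed 3 --out toy.yaml
Rscript inst/cli/metabind.R pipeline --system toy.yaml --seed 2 --out run
Rscript inst/cli/metabind.R fes --hills run/HILLS --out fes.dat
```

## Package layout

- `R/toy_systems.R` — synthetic systems and planted ensembles
- `R/restraints.R` — binding CV, walls, funnel (+ analytic gradients)
- `R/metadynamics.R` — hills, well-tempered heights, walker seeding,
  HILLS/COLVAR I/O
- `R/dynamics.R`, `src/engine.cpp` — BAOAB Langevin engine with shared
  bias
- `R/fes.R` — free-energy reconstruction and minimum location
- `R/binding_mode.R` — extraction, superposition, clustering, reports
- `R/refine.R` — unbiased refinement and classification
- `R/pipeline.R` — orchestrator, escape guard, manifest
- `vignettes/binding-mode-protocol.Rmd` — the methods vignette
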