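---
title: "Binding-mode determination by funnel-restrained multiple-walker metadynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-mode determination by funnel-restrained multiple-walker metadynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabind)
```

## The problem and the protocol

Metadynamics accelerates the sampling of a ligand-binding process by
depositing repulsive Gaussian "hills" along a binding collective
variable (CV), so that binding and unbinding — rare events on plain
molecular-dynamics timescales — happen many times in one simulation.
The price is that the resulting ensemble is biased: high-energy poses
are heavily over-represented, and the preferred binding mode cannot be
read off a single frame. The protocol implemented here recovers it by
combining three ingredients:

1. the *free-energy profile* along the CV, reconstructed from the
   deposited bias, whose global minimum identifies the energetically
   preferred ligand depth in the pocket;
2. *population-ranked clustering* of the frames near that minimum,
   which separates coexisting ligand orientations and ranks them by
   how often the biased ensemble visited them; and
3. *unbiased refinement* of each cluster representative, which tests
   whether a candidate mode is dynamically stable.

The protocol's empirical success criterion is that the most populated
cluster converges to the reference mode during refinement.

## Model components and assumptions

**Binding CV.** `binding_cv()` is the z-component of the displacement
from a receptor anchor atom to the ligand's amine-nitrogen analogue.
This presumes a binding path roughly perpendicular to the membrane
plane (receptor aligned with the laboratory z axis); the funnel axis
is likewise the z axis through the anchor atom, and no funnel tilt is
supported.

**Restraints.** CV walls are one-sided harmonics,
`kappa * (z - z_wall)^2` (note: no factor 1/2; `wall_bias()` matches
that convention exactly, and the engine applies its analytic
gradient). The funnel radius `R(z) = d/(1 + exp(m (z - w))) + r1` is
*wide* (`d + r1`) on the receptor side, where the protein itself
confines the ligand, and narrows to the limiting radius `r1` in the
solvent channel. The restraint energy rises sigmoidally from ~0 inside
the funnel to the plateau `h` outside, with steepness `lambda`
(treated as nm^-1 so the exponent is dimensionless). Defaults are the
published GPCR values (`d` = 1.6 nm, `r1` = 0.8 nm, `m` = 10 nm^-1,
`w` = 2.8 nm, `h` = 100 kJ/mol, `lambda` = 500 nm^-1). No
funnel-volume correction is applied to the reconstructed free energy:
the profile is used only to locate its minimum, and the bound-state
region is unaffected by the transverse restraint. Users comparing
absolute bound/unbound free-energy differences should be aware of this
deliberate omission.

**Well-tempered deposition.** Hills of width `sigma` (default 0.1 nm,
the conventional reading of a PLUMED length) are deposited every
`stride` steps (default 500, i.e. 1 ps at the 2 fs time step; the
deposition pace is an explicit assumption, configurable in
`metad_params()`). Heights follow `W = w0 exp(-V(s)/(kB dT))` with
`dT = (gamma - 1) T`. The pipeline uses bias factor 50 with 7 kJ/mol
initial hills for the exploratory pathway run and bias factor 20 with
5 kJ/mol hills for the production multiple-walker run.

**Multiple walkers.** Walkers advance in an interleaved round-robin
schedule (one deposition stride per walker per round) and share a
single bias: every hill is visible to every walker from its deposition
event onward. This preserves the behavioural contract of
file-synchronised walker implementations without their file mechanics.
`run_multiwalker()` with one walker *is* `run_segment()` — a true
reduction, not an approximation.

**Dynamics.** The engine is BAOAB-discretised Langevin dynamics in
vacuum at constant volume (default friction 1 ps^-1, temperature
310 K, time step 2 fs). The protocol's logic requires only canonical
sampling, not a particular thermostat, so a membrane barostat setup is
deliberately not emulated. The receptor scaffold is frozen and the toy
ligand is held rigid by stiff bonds rather than constraints; there are
no periodic boundaries, neighbour lists, or solvent.

**Free-energy reconstruction.** `reconstruct_fes()` applies the
standard well-tempered rescaling `F(s) = -(gamma/(gamma-1)) V(s)` on a
uniform grid (default 0.01 nm; range auto-set to the hill range
± 3 sigma) and shifts the global minimum to zero. No smoothing is
applied before minimum location; `locate_minimum()` refines the grid
minimum with a parabola through its two neighbours and breaks exact
ties (within 1e-9) toward the smaller CV. An empty hill list yields a
flat profile with a warning flag rather than an error, so that
pipeline plumbing can be exercised without sampling.

**Extraction, superposition, clustering.** Frames with
`|cv - minimum| <= delta_cv` (default 0.3 nm = 3 Å; closed interval,
with a 1e-9 guard so boundary frames survive floating-point noise) are
superposed on the receptor backbone by the Kabsch rotation (SVD with
reflection correction; collinear backbones are rejected) and clustered
by *unfitted* ligand heavy-atom RMSD — the coordinates as positioned
by the backbone fit, with no second superposition, so that both
position and orientation of the ligand distinguish modes. The linkage
criterion is average linkage (the common default of trajectory
clustering tools; the choice is recorded in the result), the cluster
count target is five, clusters are ranked by population, and the
representative is the member with the minimal sum of intra-cluster
RMSDs. Merge ties follow `stats::hclust`'s deterministic internal
ordering; for continuous coordinates exact ties have measure zero.
Fewer *frames* than clusters is an error; fewer *distinct
conformations* than clusters returns the achievable number with a
warning flag.

**Refinement classification.** The narrative outcomes of refinement
runs are made reproducible by a fixed rule evaluated on the final half
of the run: mean ligand RMSD ≤ 2 Å → `converged_to_reference`
(matching the 1–2 Å plateau that characterises a stable mode); else CV
beyond the funnel mouth `w` for more than half the frames →
`dissociated`; else RMSD standard deviation > 1.5 Å → `flexible`;
otherwise `alternative_stable`. All three thresholds are explicit
assumptions exposed as arguments.

**Escape guard.** If fewer than 20% of initial-run frames lie below
the pocket-entry CV, the upper wall is tightened to the pocket entry
(the ligand was escaping into the solvent instead of binding), and one
supplemental segment is run so the walker-seed pool still spans the
whole path. Threshold zero disables the guard.

## What the synthetic systems emulate — and what they do not

`make_double_well()` builds a single particle in a quartic double well
whose linear tilt is calibrated by root finding (tolerance 1e-12) so
that the Boltzmann-integrated basin free-energy difference equals the
requested value *exactly* at the stated temperature — the engine
validation target is therefore analytic, not itself simulated.

`make_binding_system()` is a miniature of the receptor problem: a
frozen 13-bead scaffold, a rigid asymmetric 4-bead ligand (so that
reversed-orientation binding modes exist), a binding well whose global
minimum is the planted reference pose at CV = 0.5 nm (the same scale
as a real aminergic bound pose), a shallower decoy in the vestibule at
CV = 1.3 nm, a z-gated cylindrical "receptor body" term that leaves
only a 0.35 nm cavity open below the pocket mouth (in the real system
the protein occupies that space), and an open channel to a flat
solvent region. Binding thermodynamics are sized like a tight binder:
total well depth 60 kJ/mol split over three contacts (50/30/20%), so
the bound pose is collectively held with a thermal RMSD well below the
2 Å convergence threshold and an unbinding time that exceeds the
refinement window by orders of magnitude, while the 20 kJ/mol decoy
remains genuinely metastable. The funnel shipped with the toy system
uses the same functional form as the GPCR funnel with geometry scaled
to the toy scaffold (d = 0.6, r1 = 0.4, w = 1.5 nm).

The build-time "analytic" profile of the binding system integrates the
axial site wells over the funnel cross-section at each z, treating the
ligand orientation adiabatically; it is an approximation used for
qualitative checks (minimum position), not an exact reference like the
double well's.

What passing on these systems shows: the bias bookkeeping, free-energy
algebra, extraction window, superposition, linkage clustering,
population ranking and classification logic are correct, and the
orchestrated protocol finds a planted mode under realistic noise. What
it does not show: force-field accuracy, membrane/solvent effects,
receptor flexibility (the scaffold is frozen, so pocket RMSDs are
identically zero and clustering never has to disentangle
backbone from ligand motion), ligand internal degrees of freedom, or
the sampling hardness of a μs-scale all-atom landscape.

## Numerical choices

- Units: nm, ps, K, kJ/mol internally; Å only in reports.
  kB = 0.0083144621 kJ mol^-1 K^-1.
- The engine evaluates the metadynamics bias from a shared grid
  (0.01 nm spacing, linear interpolation, updated incrementally at
  each deposition); for 0.1 nm hills the interpolation error is far
  below 1e-6 kJ/mol. The user-facing `total_bias()` is direct
  summation over the hill list, and tests pin the two against each
  other. Deposition heights computed from the interpolated bias agree
  with the exact well-tempered recursion to ~1e-4 relative.
- Determinism: one master seed; per-(walker, round) sub-seeds are
  derived arithmetically (all below 2^31), so any run — including the
  interleaved multiwalker schedule — is bitwise reproducible.
  Velocity initialisation is Maxwell–Boltzmann from the same seed.
- Degenerate inputs: negative bias rejected in `hill_height()`
  (the bias is a sum of positive Gaussians); empty extraction windows
  raise an error advising a larger `delta_cv`; non-finite
  energies abort integration with the step index; walker seeding with
  fewer frames than walkers reports the deficit.

## Problem sizes

The shipped defaults are sized for a workstation: the pipeline runs
one 400 000-step initial segment, 32 walkers × 150 000 steps of
production metadynamics (about 9 600 hills), caps clustering input at
4 000 frames (deterministic thinning), and refines five
representatives for 150 000 steps each. The test suite uses the same
components at smaller sizes (e.g. 4 walkers × 1.25 M steps on the 1D
double well, 5 000-frame planted ensembles for clustering). These
sizes are the package's validation choices; all are configurable
upward.

## Known limitations

- One-dimensional CV only; no multi-CV or adaptive-Gaussian variants.
- No funnel-volume (standard-state) correction of the profile.
- The toy engine is not a general MD code: no cut-off bookkeeping,
  no constraints, no pressure coupling, frozen receptor.
- Cluster-count selection is the user's (default five); no automatic
  model selection is attempted.
- PLUMED-dialect I/O covers the HILLS/COLVAR layouts written by this
  package and common single-CV files; exotic multi-CV headers are out
  of scope.
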