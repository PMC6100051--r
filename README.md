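# ProbeSpectra

Membrane probe orientation and nuclear-ensemble fluorescence spectra in R.

Solvatochromic probes such as Laurdan report the phase state of lipid
bilayers: their emission shifts between gel and liquid-crystalline
membranes. The mechanistic question is *why* — how the probe's orientation
and depth of embedding in the bilayer shape its absorption and emission.
ProbeSpectra implements the complete analysis chain needed to study this
with simulation data: geometric observables on bilayer trajectories, the
hierarchical snapshot-sampling protocol that builds excitation ensembles,
electrostatic-embedding input preparation for external TD-DFT engines,
nuclear-ensemble spectrum synthesis, and a permutation test relating
emission energy to probe geometry. A synthetic trajectory/excitation
generator with known ground truth makes every stage testable without
molecular dynamics or quantum chemistry runs.

It is intended for computational membrane biophysicists who have (or want
to emulate) classical MD trajectories of a probe in a bilayer plus tables
of vertical transitions from a TD-DFT engine.

## The observables and the model

* **Tilt angle** θ: the angle between the bilayer normal and the vector
  from the fluorophore's carbonyl carbon to its nitrogen. θ = 0° means the
  fluorophore is parallel to the normal with the nitrogen toward water,
  θ = 90° perpendicular, θ = 180° nitrogen toward the membrane interior.
  The normal is oriented per leaflet, so the semantics are
  leaflet-independent.
* **Penetration depth** d: the signed distance along the leaflet-oriented
  normal from the centre of mass of the host leaflet's phosphate atoms to
  the probe's centre of mass; positive = deeper than the phosphate plane.
* **Nuclear-ensemble spectrum**: for vertical transitions (ΔE_i, f_i) over
  N distinct snapshots,

      I(E) = (1/N) Σ_i f_i · L(E − ΔE_i; δ),
      L(E; δ) = (1/π) (δ/2) / (E² + (δ/2)²),

  a Lorentzian of full width at half maximum δ (default 0.1 eV).
* **Association statistic**: the difference in mean emission energy
  between the deep, weakly tilted subgroup (d > median, θ < 40°) and the
  rest of the ensemble, with a two-sided permutation p-value.

## Worked example

A fluid-phase-like synthetic membrane (bimodal tilt with modes at 28° and
120°, energies coupled to depth and tilt) run through the full emission
pipeline:

```r
library(ProbeSpectra)
res <- runEmissionPipeline(fluidPhaseConfig(seed = 7))
res$excitations
#> ExcitationSet (emission): 220 records, 220 snapshots, states 1-1
#>   energy: 2.327-3.150 eV; <f> = 0.295
#>   annotated with depth/tilt descriptors
res$bands
#>   position    height prominence
#> 1    2.525 0.5789938  0.2815246
#> 2    2.920 1.0000000  0.9950152
res$association
#> AssociationResult: deep (> 0.724 nm) & low-tilt (< 40 deg) group of 40 vs 180
#>   mean energy difference: -0.3581 eV; permutation p = 0.000999 (1000 perms)
```

The 220 records are the hierarchical emission protocol at work: 22
equidistant snapshots along the last 50 ns of the trajectory, each seeding
a short secondary trajectory from which 10 equidistant geometries between
1 and 2 ns are booked. The detected bands show the two-band emission
signature of the fluid-like membrane — the extra band at 2.525 eV
(≈ 491 nm) is the long-wavelength component — and the association test
attributes it to the deep, weakly tilted subpopulation, whose mean
emission energy is 0.36 eV below the rest (p < 0.001). Re-running
`gelPhaseConfig()` (unimodal tilt) yields a single band.

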