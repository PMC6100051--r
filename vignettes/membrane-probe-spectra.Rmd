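---
title: "Probe orientation, membrane embedding, and simulated fluorescence: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe orientation, membrane embedding, and simulated fluorescence: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProbeSpectra)
```

## The problem

Solvatochromic membrane probes (Laurdan and its relatives) are used to read
out lipid phase state from their emission colour. The probe sits in one
leaflet of the bilayer; how deep it sits and how its fluorophore is tilted
against the membrane normal modulate the electrostatic environment of its
excited state and hence its emission energy. ProbeSpectra implements the
analysis chain connecting trajectory geometry to simulated spectra:
geometric observables, ensemble sampling, electrostatic-embedding input
preparation, nuclear-ensemble spectrum synthesis, and an explicit
statistical test of the geometry/energy association. All stages run on
synthetic data with known ground truth, so the whole chain is testable
without molecular dynamics or quantum chemistry.

## Geometric observables

**Bilayer normal.** The normal is the laboratory z axis, not an
instantaneous fitted normal. This is the standard choice for planar
bilayer patches and is a documented limitation for strongly undulating
membranes. The normal is *leaflet-oriented*: it points toward the water
phase of the probe's leaflet (`+z` upper, `-z` lower), so tilt and depth
have identical meaning in either leaflet.

**Tilt angle** is the angle between the carbonyl-carbon-to-nitrogen vector
of the fluorophore and the leaflet-oriented normal: 0° = nitrogen toward
water, 90° = in-plane, 180° = nitrogen toward the membrane interior.

**Penetration depth** is the signed projection onto the leaflet-oriented
normal of (phosphate centre of mass − probe centre of mass), positive when
the probe lies deeper than the phosphate plane of its host leaflet.
Whether published depth histograms are signed or absolute is generally not
stated; we chose the signed convention so that "penetrates deeper" maps
monotonically to larger positive values. The probe centre of mass defaults
to the *fluorophore moiety* (the optical reporter whose position matters
for the spectroscopy), with `wholeMolecule = TRUE` switching to the
complete molecule including the alkyl tail — the literature is ambiguous
between the two, so both are exposed.

**Acyl-chain tilt** uses the first-to-last chain-atom vector folded to
[0°, 90°]. The endpoints of the chain vector are not standardised
anywhere; first-to-last is our choice and is stated as such.

**Leaflet assignment** compares the probe centre of mass with the mean z
of all phosphate atoms; a probe exactly at the midplane is an error rather
than a silent coin flip.

Selections are made whole across periodic boundaries (minimum image
relative to the first atom of the selection) before any centre-of-mass
computation.

**Histograms** are density-normalised with fixed bins: 5° on [0°, 180°]
for tilt, 0.05 nm for depth. Five-degree bins resolve the ~13° separation
between probe and chain tilt modes that matters in gel-phase membranes
while keeping per-bin counts stable at the ensemble sizes used here. The
mode is the centre of the highest-density bin (ties to the lower bin);
`localModes()` additionally filters local maxima by topographic prominence
(default 5% of the maximum density) so that bin-count noise does not
produce spurious modes.

## Snapshot sampling

Equidistant selection uses inclusive endpoints with (n − 1) equal
intervals; published protocols rarely state their convention, and the
inclusive rule is the simplest reproducible one. A single snapshot falls
at the window midpoint. Requested times snap to the nearest stored frame,
ties to the earlier frame. Random selection is uniform without replacement
and seeded.

The hierarchical emission protocol selects `nSecondary` equidistant
primary snapshots (canonically 22 along the last 50 ns of the
excited-state trajectory), treats each as the seed of a short secondary
(polarizable-water) trajectory, and books `nSub` equidistant times
(canonically 10 between 1 and 2 ns) within each — 220 geometries per
membrane. Running the secondary dynamics is out of scope: the manifest
records the book-keeping, and real secondary trajectories are inputs. For
synthetic end-to-end runs, secondary-snapshot descriptors inherit the
primary snapshot's tilt and depth plus small Gaussian jitter (3° and
0.02 nm by default), emulating the limited decorrelation of
nanosecond-scale dynamics.

## Electrostatic embedding

The quantum region defaults to the methyl-truncated fluorophore: the alkyl
tail carries no frontier orbitals, so it is removed beyond a cut bond and
the retained carbon capped by a hydrogen placed along the cut-bond
direction at 0.109 nm. Bonds are detected by distance (0.18 nm
heavy-heavy, 0.13 nm to hydrogen); cutting inside a ring is refused. A
flag retains the full chain instead, since for ground-state absorption the
complete molecule is sometimes kept in the quantum region.

The environment is every other atom as a fixed point charge at its
force-field partial charge, with two rules:

* **Whole molecules.** An environment molecule is included entirely or not
  at all, and each included molecule is first made whole and then shifted
  *as a unit* into the minimum image around the quantum region's centre of
  mass. Fragmenting molecules would create artificial net charges;
  wrapping per molecule preserves all intramolecular distances. No
  distance cutoff is applied by default (an optional molecule-COM cutoff
  exists).
* **Link-atom charges.** When the quantum region is a strict subset of its
  molecule, the leftover tail atoms follow standard link-atom charge
  handling: charges on tail atoms bonded to the quantum region are zeroed
  and their total spread uniformly over the remaining tail atoms, so the
  molecule's net charge is preserved exactly.

Environment points closer than 0.05 nm to any quantum atom trigger a
warning, not exclusion — such contacts indicate a broken wrap, which
should be fixed, not silently papered over.

## Nuclear-ensemble spectra

Each vertical transition contributes a Lorentzian centred at its energy,
weighted by its oscillator strength; contributions are summed and divided
by the number of *distinct snapshots* (multiple excited states within one
snapshot must add, not dilute each other). The broadening δ (default
0.1 eV) is the Lorentzian's **full width at half maximum** — the common
convention in nuclear-ensemble codes; the kernel is unit-normalised, so a
single line of strength f peaks at 2f/(πδ) and the spectrum integrates to
the mean per-snapshot summed oscillator strength.

Emission intensities use plain f-weighting by default; relative spectra
are what band-structure comparisons need, and no absolute semiclassical
prefactor is asserted. An optional E³ emission prefactor flag exists. The
default grids are 2–6 eV (absorption) and 1.5–4.5 eV (emission) at
0.005 eV, which resolves a 0.1 eV kernel by a factor of 20. The
wavelength axis is λ = 1239.841984/E nm; intensities are remapped
unchanged by default (band positions are compared, not densities), with a
Jacobian flag for true density conversion.

Band detection reports local maxima above a topographic-prominence
threshold (default 0.05 on a peak-normalised spectrum), which separates
genuine shoulders from grid-level ripple.

## Structure–spectrum association

The qualitative claim to quantify is that long-wavelength emission comes
from deep, weakly tilted fluorophores. The statistic is the difference in
mean emission energy between the subgroup with depth above a threshold
*and* tilt below a threshold, and its complement. Defaults: depth
threshold = ensemble median (guarantees a non-empty split on the depth
margin), tilt threshold = 40°, bracketing the weakly tilted orientation
mode near 28° without swallowing the perpendicular population. No
published cutoffs exist; both are configuration parameters surfaced in
the interface. The two-sided p-value uses label permutation with the
add-one estimator, seeded for reproducibility; ties are left as they
fall.

## The synthetic generator

The generator defines the study conditions under which the pipeline is
validated:

* 64 phosphate pseudo-atoms per leaflet on two planes 4 nm apart in a
  6.4 × 6.4 × 7 nm box — a 128-lipid bilayer patch's dimensions.
* Tilt drawn from a mixture of von Mises-type angular kernels restricted
  to [0°, 180°]; bounded support matches the tilt definition, and the
  concentration parameter maps smoothly from broad (fluid-like) to sharp
  (gel-like) distributions, with `Inf` collapsing to a point mass for
  degenerate-distribution tests. Gel-like preset: one mode at 28°
  (concentration 12). Fluid-like preset: modes at 28° and 120°
  (concentrations 12 and 8, weights 0.6/0.4) — the bimodal excited-state
  orientation distribution with a pronounced high-angle component.
* Depth Gaussian: N(0.8 nm, 0.15 nm) by default; the gel-like preset is
  deeper and narrower (0.9, 0.1), the fluid-like shallower and wider
  (0.7, 0.2).
* The probe is rigid — excited- and ground-state geometries of such
  fluorophores are nearly identical, so only orientation and position
  vary. It is placed so the recomputed observables equal the drawn ground
  truth to rounding error, which is what makes the generator an oracle.
* Emission energies follow E = 3.0 − 0.3·d − 0.25·cos θ + N(0, 0.05) eV:
  deeper and less tilted snapshots emit redder, with slopes chosen so the
  fluid-like preset's two orientation modes separate by ≈ 0.35 eV —
  resolvable at δ = 0.1 eV, producing the two-band emission signature.
  Oscillator strengths are Gaussian (mean 0.3, sd 0.05) truncated at
  zero.

What the generator does **not** emulate: force-field energetics, lipid
conformational detail, membrane undulations, hydrogen bonding or explicit
water polarisation, vibronic structure, and any dependence of oscillator
strength on geometry. Passing tests therefore demonstrate that the
*analysis chain* is correct and calibrated, not that real membranes
behave like the generator.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 20 000 frames for
distribution recovery (mode recovery within one 5° bin, depth mean within
3 standard errors), 10⁵ orientations for the isotropy check on mean
cos θ, 220-geometry ensembles for the association test (999 permutations
for the induced-shift check; 500 replicate null ensembles at 199
permutations for the size calibration), and 301-frame trajectories
spanning 150 ns for the protocol-arithmetic and pipeline checks. These
sizes give stable Monte-Carlo behaviour at interactive runtimes.

Degenerate inputs are errors, not guesses: empty selections, a probe
exactly at the midplane, all-zero spectra in normalisation, empty
association groups, cut bonds inside rings.

## External engines and benchmarks

The package contains no electronic-structure code. An engine adapter is a
registered function (or declared shell-command template) that receives a
molecule file, functional/basis names, a state count, and optionally a
point-charge file, and returns parsed transitions. Packaged reference
tables of vertical excitation energies and oscillator strengths (two
hybrid functionals, four correlation-consistent basis sets, gas phase and
implicit water/cyclohexane) let `compareToBenchmark()` verify any engine
at tolerances of 0.02 eV and 0.02 in f — roughly the cross-code spread
from differing quadrature grids and convergence settings. Because two of
the reference states are nearly degenerate (0.01 eV apart), benchmark
pairing can be done by energy order rather than state index; index-strict
pairing would misreport a mere state swap as an error.

## Known limitations

* The laboratory-z normal is wrong for vesicles or strongly undulating
  membranes.
* Only orthorhombic boxes are handled by the wrapping code.
* Chain-tilt endpoints (first-to-last atom) are a convention, not a
  standard.
* The emission spectra are relative; no absolute cross sections.
* The association test is descriptive, not causal, and its thresholds are
  choices surfaced in configuration.
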