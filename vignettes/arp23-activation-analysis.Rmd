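---
title: "Quantifying Arp2/3 complex activation: order parameters, interfaces, and a steered coarse-grained surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Arp2/3 complex activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arptraj)
```

## The scientific problem

The Arp2/3 complex is a seven-subunit machine (Arp2, Arp3, ARPC1–5) that
nucleates branched actin filaments. Activation requires two large
conformational changes:

1. **Splayed → short-pitch.** Twisting of the clamp subunits ARPC2/ARPC4
   rotates the bottom half of the complex so that Arp2 and Arp3 come to
   mimic two consecutive subunits along the short-pitch helix of an actin
   filament. We track this with the distance between the *inner-domain*
   centers of geometry (COGs) of the two Arps — the COG of subdomains 3+4
   of Arp2 versus that of Arp3, computed from backbone atoms (N, CA, C,
   O). In the deposited endpoint models this distance is 52.2 Å for the
   splayed (inactive) state and 42.7 Å at the branch junction
   (short-pitch, active); the same values are the default targets of the
   package's synthetic endpoint generator.
2. **Twisted → flattened.** Each Arp, like actin itself, can move its four
   subdomains toward a common plane. We quantify this with the signed
   torsion φ of the four subdomain COG beads taken in the order
   subdomain 2, 1, 3, 4.

Secondary metrics follow the same bead/COG machinery: the clamp-twist
torsion of four configured backbone bead sets on ARPC2/ARPC4, and named
Cα–Cα distances (the Arp2 W-loop opening F173–I140, which reports closure
of the barbed-end groove, and the Arp2 D-loop I41 to ARPC3 Y58 distance,
which reports the D-loop/ARPC3 contact that stabilizes the short-pitch
state).

Interfaces are quantified with a from-scratch Shrake–Rupley solvent
accessible surface area (SASA), a buried-surface-area (BSA) statistic, and
sigmoidal per-residue contact scores. A coarse-grained engine replays the
steered protocol that pulls the complex between its endpoint states with
moving harmonic restraints on pairwise subunit COG distances.

## Conventions and units

Coordinates and distances are in ångströms, areas in Å², dihedrals in
signed degrees on (−180°, 180°]. Torsions use the convention in which the
four points (0,0,0), (1,0,0), (1,1,0), (1,1,−1) give +90°; reversal of the
bead order leaves a torsion unchanged and mirror reflection negates it.
COGs are unweighted arithmetic means of the selected atom coordinates,
with backbone atoms (N, CA, C, O) used for all subdomain beads. One
sentence in the source protocol refers to centers of *mass* for the
relaxed spring lengths of the steered runs; the implementation uses the
COG for both the relaxed lengths and the bias, and this choice is
deliberately surfaced here rather than silently mixed.

## What is configuration, not code

Chain→subunit maps for each structure "dialect", subdomain residue ranges,
anchor residues, clamp-bead definitions, the SASA radii table and the
contact-score parameters all live in `inst/extdata/arptraj-config.yaml`.
Two warnings are worth repeating:

* The subdomain ranges shipped for the deposited dialects are canonical
  actin subdomain boundaries transferred onto Arp numbering. The
  authoritative per-structure boundaries are a property of each deposited
  model; treat the shipped ranges as defaults to override, not as ground
  truth. The ±0.5 Å tolerance used when checking the endpoint distances
  exists precisely to absorb this boundary freedom.
* The clamp-twist bead atom sets for deposited structures are provisional:
  the construction (four backbone bead COGs, torsion Bead 1–2–3–4) is
  fixed, but the residue windows are configurable data.

## The synthetic-data generator

Analysis code is validated against pseudo-atomic systems whose order
parameters are known exactly by construction:

* Each pseudo-subunit is a rigid cluster of pseudo-residues, four backbone
  atoms per residue, with non-coplanar, zero-sum offsets. Zero-sum offsets
  make each subdomain's backbone COG coincide *exactly* with its
  prescribed subdomain center, so a requested dihedral or distance is
  realized to construction precision (< 10⁻³ of the unit).
* The four subdomain centers of an Arp are placed by internal coordinates
  (bond 16 Å, angle 100°, torsion = requested φ); Arp2 is then rigidly
  placed so the inner-domain COG separation equals the requested
  short-pitch distance. Clamp beads sit on a second internal-coordinate
  chain carrying the requested clamp torsion; anchor residues realize the
  scheduled W-loop and D-loop distances.
* Trajectories realize piecewise-linear metric schedules; isotropic
  Gaussian noise (default σ = 0.5 Å) is added independently per atom and
  per frame. All randomness flows through one recorded seed, and
  regeneration with the same spec is bit-identical.
* Default endpoint targets are 42.7 Å/flattened (active) and
  52.2 Å/twisted (inactive). The flattening endpoints themselves are not
  printed numerically in the source structures' literature, so the
  generator uses −3° (flattened) and −20° (twisted) as emulation defaults,
  chosen once as representative of the actin-fold twisted/flat range.

What the generator does **not** emulate: physical dynamics (frames are
noise around a deterministic schedule, with no autocorrelation), sequence
realism, side chains, crowding, or solvent. Passing the recovery tests
therefore demonstrates that the measurement pipeline is unbiased and
correctly plumbed — not that the package would extract converged free
energies from a real, correlated MD trajectory.

A separate fixture, `make_branch_junction()`, is a *synthetic stand-in*
for a branch-junction coordinate model: seven complex pseudo-subunits
docked onto a ten-subunit mother filament such that exactly the designated
subunits (MA2, MA3, MA4, MA6, MA9) touch the complex, while the
non-interacting set excluded from trajectory BSA bookkeeping (MA1, MA0,
MA5, MA7, MA8) stays clear. Its interface area (~250 Å² with the default
shell geometry) is a property of this construction and is *not* calibrated
to any deposited structure's printed interface area; it exists to exercise
the exclusion-list logic and the BSA equation, and checks against
deposited models require downloading those entries (see
`inst/extdata/deposited/README.md`).

## Surface areas and contact scores

SASA follows Shrake–Rupley: each atom's van der Waals sphere is inflated
by the probe radius (1.4 Å) and covered with a deterministic
generalized-spiral point set (960 points by default); points inside any
neighbour's inflated sphere are buried. Determinism makes results
bit-reproducible; refinement from 240 to 960 points shifts the synthetic
junction interface area by about 1%. Because the spiral point set is
chiral, mirror-image systems agree to discretization accuracy (≈0.1%)
rather than bitwise. Radii are a Bondi-style table in the config;
hydrogens are excluded by default since the targeted crystal/cryo-EM
models carry none. The per-atom area is capped by the isolated-sphere
value 4π(r+p)², and adding neighbours can only decrease it — both
properties are tested.

Buried area between two groups uses
BSA = (SASA₁ + SASA₂ − SASA₁₂)/2, with each group's lone SASA computed
with the other group absent and only the two groups present in the
combined term. For trajectory bookkeeping against the mother filament,
subunits marked non-interacting in the registry are dropped from the
filament group first (`mother_filament_bsa()`).

Contact scores sum a sigmoidal pair weight w(d) = 1/(1+exp((d−d₀)/σ))
over heavy-atom pairs within a 10 Å neighbour list into residue pairs,
averaged over frames. The published analyses this reproduces used a GUI
contact tool whose exact parameters are not printed; the functional form
here is explicit with defaults d₀ = 4.0 Å, σ = 0.5 Å, so absolute
thresholds such as "score > 1" are calibration-dependent and any
comparison at that threshold is qualitative until calibrated.

## The steered coarse-grained surrogate

The all-atom steered runs of the source protocol are far beyond desk
scale, so the package preserves the *protocol* rather than the
forcefield: subunit (or Arp-subdomain) COG beads, an elastic network
(edges between beads within 60 Å, rest lengths from the starting
conformation), and one moving harmonic restraint per bead pair whose
relaxed length ramps linearly from the active-state distance to the
inactive-state distance. The restraint spring constant defaults to the
protocol's 10,000 energy Å⁻²; the restrained pair set defaults to *all*
bead pairs ("between each COG") and is configurable because the original
pair list is not enumerated. Three presets mirror the 60/100/150 ns pulls
as 60k/100k/150k ramp steps, each followed by an unbiased hold
(the restraint released), mirroring the continuation of the original runs
to ~200 ns.

Dynamics are overdamped (Brownian) Euler–Maruyama:
x ← x + (F/γ)dt + √(2kT·dt/γ)·η, stable for dt < 2γ/k_max; the run
aborts with the bound if violated and names the first step at which any
coordinate or energy turns non-finite. Defaults γ = 10⁶, dt = 1, kT = 2.5
put the stiffest default spring at 2% of the stability limit, make a
single restrained pair track its moving target with a closed-form lag
vγ/(2k) (tested against that analytic solution to 1%), and give thermal
bead fluctuations of a fraction of an ångström over a full ramp. A seed
is mandatory for stochastic runs and fixed-seed reruns are bit-identical.
Because the elastic network is single-welled at the starting conformation,
long unbiased holds relax back toward the start — unlike the metastable
all-atom system — so end-of-ramp values, which the engine records
separately, are the pull result; DRMSD to the target reference
(root-mean-square deviation of internal pairwise bead distances, rigid
motion invariant) is the convergence monitor.

## Numerical choices

* Torsions: atan2 formulation; collinear triples give NaN per frame
  (propagated, not dropped); range (−180°, 180°].
* Rolling smoothing: centered windows, truncated at the series edges,
  window in frames (default 50, i.e. 5 ns at a 100 ps frame interval);
  the reported band is the windowed standard deviation. NaN frames
  poison every window containing them, by design.
* 2D basins: 50×50 bins over the observed range padded 5% per side;
  pseudo-free energy −ln(p/p_max) with empty bins at +∞; the basin is the
  8-connected set of bins with energy ≤ 1 grown from every minimum-energy
  bin (all of them, when ties occur). Against a sampled bivariate
  Gaussian at n = 50,000 the basin area matches the analytic 1-kT contour
  ellipse within a binning-error band estimated as contour perimeter ×
  bin diagonal; the histogram-maximum normalization biases the area
  slightly low (observed ≈ 5–15% with the default binning), which is the
  expected price of the simple estimator.
* RMSF: per-atom RMS displacement from the first frame, with optional
  rigid superposition on a stated selection; per-residue values average
  backbone atoms. With isotropic jitter of σ per coordinate about a fixed
  reference the per-atom RMSF converges to σ√3 (tested by simulation);
  if the reference frame itself carries the same noise the expectation is
  σ√6 — worth remembering when interpreting small RMSF values.
* Problem sizes used by the shipped tests and the acceptance script —
  5,000-frame recovery runs, 8,000-step pulls, 50,000-sample basins,
  2×10⁵-point SASA quadrature oracles — were chosen as the smallest sizes
  at which the statistical checks have comfortable power.

## Trajectory formats

Input structures are PDB; trajectories are multi-model PDB or DCD (both
read through bio3d). XTC is not supported: no installed R-level reader
exists, and writing one was judged out of proportion to its value here —
convert with any standard MD toolchain instead. Alternate-location
conformers keep the highest occupancy; insertion codes are rejected
(absent from the targeted models).

## Known limitations

* Deposited-structure dialect maps (chain lettering for the 7TPT/4JD2
  entries) are provisional until verified against the downloaded files.
* The CG surrogate reproduces collective-variable-level behaviour of the
  steering protocol, not its energetics: no work/free-energy estimates,
  no force-field realism, and no claim that unbiased CG dynamics mirror
  the metastability of the all-atom system.
* Pseudo-free-energy surfaces from biased trajectories are not
  reweighted; `basin_2d` is a descriptive tool for unbiased sampling.
* Contact-score thresholds are calibration-dependent, as discussed above.

## A worked example

```{r example, eval = FALSE}
library(arptraj)

# synthetic dataset with known truth
ds <- make_trajectory(synthetic_spec(n_frames = 1000, noise_sd = 0.5,
                                     seed = 1))
reg <- resolve_registry(ds$trajectory, "synthetic")
spd <- rolling_smooth(short_pitch_distance(ds$trajectory, reg), 50)
phi <- flattening_dihedral(ds$trajectory, reg, "Arp3")
basin <- basin_2d(phi, spd)

# steering: pull the active endpoint to the splayed state
ep <- make_endpoints()
model <- build_cg(ep$active, reg, level = "subdomain", cutoff = 80)
sched <- schedule_from_endpoints(model, ep$inactive, reg,
                                 k = 10000, ramp_steps = 8000)
run <- run_steered(model, sched, kT = 2.5, seed = 1)
drmsd(run$end_of_ramp, arptraj:::bead_target(model, ep$inactive, reg))
```
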