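---
title: "Glycoform trajectory analysis and MM-GBSA energetics: methods"
author: "gfdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycoform trajectory analysis and MM-GBSA energetics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfdyn)
```

## Scope

`gfdyn` implements the analysis layer of a glycoform-comparison MD
study of a hormone–receptor complex: superposition-based RMSD/RMSF
profiling with threshold classification, interface salt-bridge
persistence statistics, Shrake–Rupley SASA averaging and differencing,
and MM-GBSA free-energy decomposition with snapshot averaging. The MD
engine itself (solvation, thermostats, integrators) is out of scope;
trajectories enter as multi-model PDB or a compact plain-text frame
format, and a seeded synthetic generator stands in for production MD so
that every stage can be validated against known ground truth.

## Superposition, RMSD and shift classification

All deviation measures superpose first: `kabschSuperpose()` finds the
proper rotation (reflections excluded via the sign-corrected SVD of the
weighted covariance) and translation minimizing weighted RMSD. Inputs
with fewer than 3 points or a rank-deficient covariance (collinear
points) are rejected rather than silently fitted.

`rmsdSeries()` reports per-frame RMSD of a selection after
superposition, so any rigid motion applied uniformly to a frame leaves
the series unchanged. The reference is a genuinely open design choice:
against the first frame (an "equilibrated structure" convention) or an
external structure such as crystal coordinates. Both are supported;
the default is the first frame, because it requires no extra input
and makes the series start at zero by construction. For glycoform
comparisons the default selection is the hormone's backbone only, since
receptor motion would otherwise dominate the ligand signal; whole-complex
superposition is available through the selection argument.

`classifyResidueShifts()` measures each residue's *settled* backbone
displacement — the time-averaged post-superposition structure against
the reference, not a per-frame maximum — on the reading that a reported
residue shift is a persistent repositioning rather than a transient
excursion. Residues are `shifted` above 1.5 Å, `contact` when any heavy
atom lies within 4.5 Å of the partner selection in the reference (the
contact cutoff is our choice of a conventional heavy-atom contact
distance; the threshold itself is the standard 1.5 Å rule), and
`contact+shifted` when both. The shifted fraction is non-increasing in
the threshold, which the suite property-tests.

`detectShiftFrame()` localizes an abrupt conformational transition as
the two-segment least-squares change point of the RMSD series (prefix
sums; ties broken toward the earliest minimizing split). On generator
fixtures with a planted step the estimate lands within ±2 frames.

## RMSF and flexibility bands

`rmsfProfile()` measures fluctuations about the window-mean structure:
frames are superposed onto the first window frame, re-meaned, and the
superpose/re-mean cycle applied twice — the standard fixed point is
reached to well below measurement noise after two iterations, and the
contract is documented rather than left implicit because the reference
choice shifts RMSF systematically. A single-frame window is an error.
The default analysis window skips the first 12.5 % of frames, the
5-of-40-ns equilibration convention, and is configurable.

Glycoform differences (`rmsfDifference()`) flag residues whose absolute
difference exceeds 0.50 Å; bound-versus-free comparisons use 1.0 Å.
Flexibility colour bands are a pure function of the RMSF value on a
right-closed scale (≤1 blue, (1,2] cyan, (2,3] green, (3,4] yellow,
(4,5] brown, >5 red); the source material gives the band anchors
loosely, so the right-closed convention (a residue at exactly 2.0 Å is
cyan, not green) is our documented tie-break.

## Salt bridges

A bridge is seeded from the reference structure when the minimum N–O
distance between a cationic side chain (Lys NZ; Arg NE/NH1/NH2) on one
side of the interface and an anionic side chain (Asp OD1/OD2; Glu
OE1/OE2) on the other falls below 4.0 Å. Histidine is excluded from the
cation set by default (only Arg/Lys are conventionally counted) with a
flag to include it. Distance series take the minimum over all
cation-N × anion-O pairs per sampled frame; the sampling stride
defaults to one sample per 2 ps (`defaultBridgeStride()`), the
"every 1000th 2-fs step" convention. Statistics are the sample median
(even length: mean of the central pair) and the occupancy, the fraction
of samples *strictly* below 3.5 Å ("less than" is read literally).
Both statistics use the same strided samples; whether the median should
instead use every frame is unspecified in the source conventions, and
using one sample set keeps the two numbers comparable.

## SASA

`sasaStructure()` is a deterministic Shrake–Rupley implementation:
per atom, the fraction of golden-spiral points on the expanded sphere
(radius `r + 1.4` Å) not buried inside any neighbour's expanded sphere,
times the sphere area. The spiral point set makes results reproducible
bit for bit; 960 points bring the single- and two-sphere cases within
1 % of their closed forms and the package agrees with an independent
Shrake–Rupley implementation within 2 % on a frozen 50-atom fixture.
Radii are a Bondi-style per-element table (`defaultRadii()`); the
study material never states radii, so the table is packaged data, and a
missing element is a named error rather than a silent default.
Hydrogens are excluded by default. Per-residue values sum all heavy
atoms of each protein residue; non-protein atoms (pseudo-glycan
occluders) bury protein surface but are not themselves reported —
matching the convention that glycans act on the protein profile by
steric occlusion. The trajectory average skips the first 12.5 % of
frames; differences above 40 Å² (strict) are highlighted. The 40
"Å" cutoff quoted in study tables is dimensionally an area and is
implemented as 40 Å².

## MM-GBSA

The component ledger is

\[
\mathrm{GBTOT} = \Delta E_{\mathrm{int}} + \Delta E_{\mathrm{ele}} +
\Delta E_{\mathrm{vdw}} + \mathrm{GBSOL},\qquad
\mathrm{GBSOL} = \Delta G_{\mathrm{pol}} + \Delta G_{\mathrm{nonpol}}
\]

and both identities hold exactly by construction for every snapshot and
for snapshot means (the mean sums are re-derived from component means
to remove summation-order noise). Conventions:

* **Bonded**: \(\sum k_b (r-r_0)^2 + \sum k_a(\theta-\theta_0)^2 +
  \sum V_n (1+\cos(n\phi-\gamma))\) — full force constants, no ½
  factors. Angle cosines are clamped into \([-1,1]\); a dihedral with
  three collinear atoms is an error, not a NaN.
* **Nonbonded**: no cutoff (gas phase); 1-2 and 1-3 pairs excluded,
  1-4 pairs scaled by 1/1.2 (electrostatic) and 1/2 (LJ) — the usual
  additive-force-field convention, chosen here and documented because
  the source conventions never state the factors. Coulomb constant
  332.0636 kcal·Å/(mol·e²). Coincident atoms raise a singularity error.
* **GB polar**: pairwise form with
  \(f_{GB}=\sqrt{r^2+R_iR_j\exp(-r^2/4R_iR_j)}\), self terms included,
  prefactor \(-\tfrac12 k_e(1/\varepsilon_{in}-1/\varepsilon_{out})\),
  \(\varepsilon_{in}=1\), \(\varepsilon_{out}=80\), zero added salt.
  Effective radii via HCT pairwise descreening or OBC-II rescaling
  (a = 1.0, b = 0.8, c = 4.85) on offset-reduced intrinsic radii
  (offset 0.09 Å, configurable); an isolated atom's effective radius is
  therefore `gb_radius − 0.09`. Non-positive radii after descreening
  are clamped to a 0.1 Å floor with a warning. The study material
  labels the method GBSA while mentioning a PBSA module for the
  solvation term; this package implements the GB route (both variants)
  and leaves Poisson–Boltzmann out of scope — the headline method name
  and the GBSOL ledger are the GB formulation.
* **Nonpolar**: \(\gamma\,\mathrm{SASA}+\beta\) exactly, with
  γ = 0.00542 kcal/(mol·Å²), β = 0.92 kcal/mol, SASA from the same
  Shrake–Rupley engine.
* **Entropy**: deliberately unsupported. The protocol omits −TΔS, and
  `energyModelConfig(includeEntropy = TRUE)` is an error rather than a
  silently ignored flag.

`mmgbsaSummary()` samples snapshots every 1 ns of simulated time (40
snapshots from a 40-ns-equivalent trajectory) and reports mean (sd) per
component. Two modes are exposed because reference energy tables at
magnitudes of ≈ −13,000 kcal/mol are absolute complex energies rather
than complex-minus-parts differences: `absolute` reproduces that
reporting convention, `binding` implements the textbook single-trajectory
approximation (ligand and receptor coordinates extracted from complex
frames), in which Δinternal and all intra-molecular nonbonded terms
cancel exactly — asserted in the suite on separated-chain fixtures.

## The synthetic generator: what it does and does not emulate

`buildToyComplex()` constructs two parallel simplified chains (backbone
N/CA/C/O plus CB, 3.8 Å residue spacing, 9 Å between chains) with
planted Lys/Arg → Asp/Glu bridges whose closed-state minimum N–O
distance is exact by construction, optional inert occluder spheres
(element X, LJ-only, zero charge) attached to ligand residues pointing
away from the interface, and a complete parameter table whose bonded
reference values match the constructed geometry. `sampleTrajectory()`
then draws i.i.d. Gaussian displacements per atom (per-residue σ
profile; default 0.5 Å background with 0.9 Å termini, chosen so the
recovered mean RMSF of ≈ 0.87 Å sits at the ~1 Å level typical of a
stable bound complex), applies an optional step displacement from a
given frame onward (the analog of an abrupt 5–10 ns structural
transition), and switches each bridge between closed and open tip
geometry via a two-state process whose stationary closed fraction
equals the target occupancy.

Design choices worth recording:

* **i.i.d. frames, not dynamics.** Frames are independent given the
  event schedule. This buys closed-form ground truth — RMSF → √3·σ,
  occupancy → the planted stationary fraction with exact binomial
  error — at the cost of all kinetic realism (no autocorrelation, no
  diffusive relaxation). The bridge process accepts a persistence
  parameter (default 0, i.e. i.i.d. Bernoulli states; positive values
  give a two-state Markov chain with the same stationary law), and the
  suite tests Markov recovery with a widened, effective-sample-size
  interval.
* **Charged tips jitter less** (σ 0.05 Å by default): the open/closed
  distance separation (2.8 vs 6.0 Å around the 3.5 Å cutoff) must not
  be blurred by displacement noise, or the measured occupancy would no
  longer equal the planted state fraction.
* **Occluder spheres are damped** (σ capped at 0.2 Å) — they are
  bulky, sluggish bodies, and the cap also keeps their LJ contact with
  the host side chain well-behaved.
* **Energetic caveat.** An i.i.d. Gaussian ensemble is *not* a
  Boltzmann ensemble of the toy force field: occasional deep
  inter-atomic overlaps produce heavy-tailed \(r^{-12}\) spikes, so
  absolute MM-GBSA means over synthetic trajectories carry large vdW
  variance. Energetics correctness is therefore established by the
  closed-form and naive-oracle tests (Born limit, Coulomb constant, LJ
  minimum, O(n²) loop equivalence at 1e-10) and by ledger and
  cancellation identities — not by energy statistics of the jitter
  ensemble. Kinematic observables (RMSD, RMSF, bridges, SASA) are the
  generator's ground-truth domain.
* **Determinism**: a fixed spec + seed yields bit-identical frames; the
  generator saves and restores the caller's RNG state.

`toyGlycoformSuite()` emits five systems differing only in occluder
load — none; two, then four sites of 1-sphere glycans; two, then four
sites of 4-sphere glycans — with the large 2-site analog additionally
carrying a shift event, mirroring a deglycosylated / partial / full ×
small / large glycan design matrix. Occluder geometry places sphere
pairs flanking the side chain so that a 4-sphere site buries more than
40 Å² of its residue (flagged by the SASA rule) while a 1-sphere site
stays below it, and immediate neighbours stay below the cutoff —
classification tests are therefore exact, not statistical.

What passing tests show — and what they do not: recovery on this
generator validates the estimators and thresholds against known inputs
under ideal sampling. It says nothing about force-field quality,
conformational sampling adequacy or glycan chemistry on real systems;
real trajectories bring autocorrelated noise, anisotropic fluctuations
and non-stationary drift that the generator deliberately omits.

## Numerical choices and degenerate inputs

* Residue identity is the verbatim (chain, residue number, insertion
  code) triple; no renumbering. Sequentially renumbered conventions
  (e.g. a 1–437 composite numbering across subunits) are reconciled by
  an offset map in the caller's configuration, never silently.
* Alternate locations: altloc `A` or blank kept, others dropped;
  occupancies ignored — a deterministic single-conformer model.
* The backbone atom set is fixed to heavy atoms {N, CA, C, O}; whether
  hydrogens belong to "backbone" is never stated in the conventions
  this package follows, and heavy-atom-only is the default reading.
* Empty selections are errors (every downstream stage needs ≥ 1 atom);
  unknown selection clauses are errors, not empty matches.
* Trajectory frame `i` is stamped at `i × spacing` ps so that frame
  count × spacing equals total simulated time, and 1-ns snapshot
  sampling of a 40-ns run yields exactly 40 snapshots.
* Occupancy uses strict inequality at the cutoff; a sample at exactly
  3.5 Å counts as open. SASA differences likewise highlight strictly
  above 40 Å².
* Energy-table ledger validation tolerates 0.02 kcal/mol to absorb
  printed rounding in reference tables; every identity computed by this
  package holds to 1e-9 or better.
* Standard deviations of energy differences are propagated as
  \(\sqrt{s_a^2+s_b^2}\), treating snapshot sets as independent —
  reference tables report per-system spreads but no difference
  uncertainty, so independence is the stated assumption.

## Problem sizes in the suite

The test suite and acceptance script size their simulations for
statistical decisiveness per check: 2,000 frames for √3·σ recovery
(sampling error ≈ 1 %, tested at 5 %), 20,000 samples for occupancy
recovery (99 % binomial half-width ≈ 0.9 percentage points at p =
0.62), 200–400 frames for change-point and snapshot-protocol checks,
and 96–960 sphere points for SASA depending on whether the check is
statistical or geometric. These sizes are the package's own choices
for decisive tests on the toy systems.

## Known limitations

* No Poisson–Boltzmann solver, no normal-mode or quasi-harmonic
  entropy, no forces/gradients — energies only.
* No mmCIF or binary trajectory formats (DCD/XTC); no protonation
  logic; no glycan topology construction — occluders are steric
  stand-ins, not chemical glycans.
* The deterministic point set makes SASA slightly
  orientation-dependent (worst case ≈ 1 % of the total on the planar
  toy complex at 960 points); increase `nPoints` where that matters.
* GB variants and radii conventions differ across MD packages;
  absolute GB energies here are validated against closed forms and
  internal oracles, not against any external engine's numbers.
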