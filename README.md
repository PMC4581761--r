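# gfdyn

Trajectory analysis and MM-GBSA binding energetics for glycoform
comparisons of a hormone–receptor complex.

## The problem

Follicle-stimulating hormone (FSH) is an α/β heterodimeric glycoprotein
whose N-glycosylation state (deglycosylated dgFSH, partially
glycosylated FSH15, fully glycosylated FSH24; single-GlcNAc "NAG" or
large tetra-antennary "TAG" glycans) modulates how it binds the
extracellular fragment of its receptor (FSHR). Molecular-dynamics
studies of such complexes compare glycoforms through a standard battery
of trajectory descriptors — backbone RMSD versus a reference, residue
shift classification at the interface, per-residue Cα RMSF and its
glycoform differences, interface salt-bridge persistence, per-residue
solvent-accessible surface area (SASA) — and through end-point MM-GBSA
free-energy decomposition. `gfdyn` implements that full analysis stack
in R, for structural bioinformaticians who want the descriptors and the
energy model as testable, scriptable components rather than as opaque
simulation-suite output.

Because multi-nanosecond explicit-solvent MD is not reproducible at
desk scale, the package ships a seeded synthetic generator that builds
toy two-chain complexes and trajectories with *known* ground truth
(fluctuation amplitudes, an abrupt conformational-shift event,
two-state salt-bridge dynamics with a target occupancy, pseudo-glycan
occluders), so every analysis stage is validated end to end by
parameter recovery.

## The model

MM-GBSA end-point free energy (conformational entropy omitted):

    ΔG_bind ≡ GBTOT = ΔE_MM + ΔG_sol
    ΔE_MM   = ΔE_int + ΔE_ele + ΔE_vdw
    ΔG_sol  ≡ GBSOL = ΔG_pol + ΔG_nonpol
    ΔG_nonpol = γ·SASA + β,   γ = 0.00542 kcal/(mol·Å²), β = 0.92 kcal/mol

with `ΔE_int` the bond/angle/dihedral internal energy, `ΔE_ele` gas-phase
Coulomb (k_e = 332.0636 kcal·Å/(mol·e²)), `ΔE_vdw` 12-6 Lennard-Jones with
Lorentz–Berthelot combining, and `ΔG_pol` pairwise Generalized Born,

    ΔG_pol = −½ k_e (1/ε_in − 1/ε_out) Σ_ij q_i q_j / f_GB(r_ij, R_i, R_j),
    f_GB = sqrt(r² + R_i R_j exp(−r²/(4 R_i R_j))),

ε_in = 1, ε_out = 80, with effective Born radii `R_i` from HCT pairwise
descreening or the OBC-II rescaling. Energies are averaged over
snapshots taken 1 ns apart (40 snapshots from a 40-ns run) and reported
per component as mean (sd); the ledger identities GBSOL = ΔG_pol +
ΔG_nonpol and GBTOT = ΔE_int + ΔE_ele + ΔE_vdw + GBSOL hold exactly.

Trajectory descriptors follow the field's conventions: Kabsch
least-squares superposition (proper rotations only) before every RMSD /
RMSF measurement; residues classified as *shifted* when the settled
backbone displacement exceeds 1.5 Å and as *interface* when any heavy
atom lies within 4.5 Å of the partner; RMSF differences flagged at
0.50 Å (1.0 Å for bound-versus-free); salt-bridge occupancy as the
fraction of strided samples with minimum N–O distance < 3.5 Å;
Shrake–Rupley SASA (probe 1.4 Å, deterministic golden-spiral points)
averaged after an equilibration skip, with per-residue glycoform
differences highlighted above 40 Å².

## Worked example

```r
library(gfdyn)

spec <- syntheticSpec(nFrames = 400L, seed = 42L)   # 40-ns-equivalent run
sys  <- buildToyComplex(spec)
traj <- sampleTrajectory(sys$model, spec)

bridges <- findSaltBridges(sys$model)
do.call(rbind, lapply(seq_len(nrow(bridges)), function(b)
  bridgeStatistics(bridgeDistanceSeries(traj, bridges[b, ]))))
#>  median_A occupancy occupancy_pct n_samples
#>  2.801504     1.000         100.0       400
#>  2.814571     0.970          97.0       400
#>  2.817738     0.900          90.0       400
#>  2.853200     0.655          65.5       400

rmsfProfile(traj, makeSelection(sys$model, "calpha and chain A"))
#> RmsfProfile 'system': 20 residues, mean RMSF 0.875 A
```

The four planted bridges had target occupancies 0.998 / 0.97 / 0.90 /
0.62: the strided 3.5-Å statistic recovers them to sampling error, and
the mean RMSF of ~0.87 Å reflects the planted 0.5-Å per-coordinate
jitter (√3·σ ≈ 0.866 Å). Energy tables obey the component ledger and
feed glycoform comparisons:

```r
tab <- readEnergyTable(system.file("extdata",
        "glycoform_energy_reference.csv", package = "gfdyn"))
validateEnergyTable(tab)
#>     system residual pass
#>      dgFSH     0.00 TRUE
#>  FSH15_NAG     0.00 TRUE
#>  FSH24_NAG     0.00 TRUE
#>  FSH15_TAG    -0.01 TRUE      (printed-rounding residual, within 0.02)
#>  FSH24_TAG     0.00 TRUE

cmp <- compareEnergies(tab)
cmp[cmp$system_a == "FSH15_TAG" & cmp$system_b == "FSH24_TAG", ]
#>   system_a  system_b delta_gbtot       sd delta_rounded
#>  FSH15_TAG FSH24_TAG    -1417.99 103.5509         -1418
```

i.e. the FSH15(TAG) complex is bound about 1418 kcal/mol more
favourably than FSH24(TAG) in this reference table, with the spread
propagated from the per-system standard deviations.

The full five-system comparison (deglycosylated baseline, 2× / 4× small
and large pseudo-glycan loads, one conformational-shift event) runs
from one config:

```r
suite <- toyGlycoformSuite("suite_dir")
runPipeline(suite$configPath, outdir = "suite_out")
```

writing per-system RMSD/shift/RMSF/bridge/SASA/energy CSVs, difference
reports against the baseline, a `summary.txt`, a run log and a
checksummed `manifest.json` (identical config ⇒ identical checksums).
A thin CLI wrapper lives at `inst/scripts/gfdyn.R`
(`run` / `synth` / `validate-table` subcommands).

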