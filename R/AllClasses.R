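#' @import methods
NULL

.CHAIN_ROLES <- c("ligand_alpha", "ligand_beta", "receptor", "other")

.ATOM_COLUMNS <- c("serial", "name", "element", "resname", "chain",
                   "resseq", "icode", "x", "y", "z")

#' StructureModel: a protein complex with chain roles
#'
#' Holds an ordered atom table (coordinates in Angstrom, identities taken
#' verbatim from file: residue identity is the triple chain / residue
#' number / insertion code) plus a role label per chain distinguishing the
#' hormone alpha and beta subunits from the receptor.
#'
#' @slot atoms `data.frame` with columns `serial`, `name`, `element`,
#'   `resname`, `chain`, `resseq`, `icode`, `x`, `y`, `z`.
#' @slot chainRoles Named character vector mapping each chain id to one of
#'   `ligand_alpha`, `ligand_beta`, `receptor`, `other`.
#' @seealso [readPDB()], [makeSelection()]
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", chainRoles = "character"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  if (!all(.ATOM_COLUMNS %in% names(a)))
    return(paste("atoms must have columns:",
                 paste(.ATOM_COLUMNS, collapse = ", ")))
  if (nrow(a) < 1L) return("structure must contain at least one atom")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) return("non-finite coordinates")
  if (anyDuplicated(a$serial)) return("duplicated atom serial numbers")
  if (any(!nzchar(a$element))) return("empty element symbol")
  chains <- unique(a$chain)
  roles <- object@chainRoles
  if (!all(chains %in% names(roles)))
    return(paste("chains without a role:",
                 paste(setdiff(chains, names(roles)), collapse = ", ")))
  if (!all(roles %in% .CHAIN_ROLES))
    return(paste("invalid chain role(s):",
                 paste(setdiff(roles, .CHAIN_ROLES), collapse = ", ")))
  # residues must form contiguous atom blocks within the file order
  key <- paste(a$chain, a$resseq, a$icode, sep = "|")
  if (anyDuplicated(rle(key)$values))
    return("atoms of one residue are not contiguous")
  TRUE
})

#' Trajectory: ordered frames over one topology
#'
#' Frames share a single [StructureModel-class] topology; coordinates are
#' stored as an `nFrames x nAtoms x 3` array in Angstrom. Frame `i` is
#' stamped at `i * frameSpacing` ps, so `nFrames * frameSpacing` equals
#' the total simulated time.
#'
#' @slot topology The shared [StructureModel-class].
#' @slot coords Numeric array, `dim = c(nFrames, nAtoms, 3)`.
#' @slot frameSpacing Time per frame, ps (> 0).
#' @seealso [readTrajectory()], [rmsdSeries()], [rmsfProfile()]
#' @export
setClass("Trajectory",
  representation(topology = "StructureModel", coords = "array",
                 frameSpacing = "numeric"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    return("coords must be an nFrames x nAtoms x 3 array")
  if (d[2] != nrow(object@topology@atoms))
    return(sprintf("coords hold %d atoms but topology has %d",
                   d[2], nrow(object@topology@atoms)))
  if (d[1] < 1L) return("trajectory must contain at least one frame")
  if (!all(is.finite(object@coords))) return("non-finite frame coordinates")
  if (length(object@frameSpacing) != 1L || object@frameSpacing <= 0)
    return("frameSpacing must be a single positive number (ps)")
  TRUE
})

#' ForceFieldTable: per-atom and bonded parameters
#'
#' Per-atom charges (e), Lennard-Jones sigma/epsilon (Angstrom, kcal/mol),
#' Generalized-Born intrinsic radii and descreening scale factors, plus
#' bond, angle and dihedral terms indexed by atom position (1-based, file
#' order of the matching [StructureModel-class]).
#'
#' @slot atoms `data.frame` with columns `charge`, `lj_sigma`,
#'   `lj_epsilon`, `gb_radius`, `gb_scale`; one row per topology atom.
#' @slot bonds `data.frame(i, j, kb, r0)` with `kb` in kcal/mol/A^2.
#' @slot angles `data.frame(i, j, k, ka, theta0)`; `ka` kcal/mol/rad^2,
#'   `theta0` rad.
#' @slot dihedrals `data.frame(i, j, k, l, barrier, periodicity, phase)`;
#'   barrier kcal/mol, phase rad.
#' @seealso [readForceField()], [snapshotEnergy()]
#' @export
setClass("ForceFieldTable",
  representation(atoms = "data.frame", bonds = "data.frame",
                 angles = "data.frame", dihedrals = "data.frame"))

setValidity("ForceFieldTable", function(object) {
  a <- object@atoms
  need <- c("charge", "lj_sigma", "lj_epsilon", "gb_radius", "gb_scale")
  if (!all(need %in% names(a)))
    return(paste("atom parameters must have columns:",
                 paste(need, collapse = ", ")))
  if (any(a$lj_epsilon < 0)) return("lj_epsilon must be >= 0")
  if (any(a$gb_radius <= 0)) return("gb_radius must be > 0")
  n <- nrow(a)
  idx <- c(object@bonds$i, object@bonds$j,
           object@angles$i, object@angles$j, object@angles$k,
           object@dihedrals$i, object@dihedrals$j,
           object@dihedrals$k, object@dihedrals$l)
  if (length(idx) && (any(idx < 1L) || any(idx > n)))
    return("bonded term references an atom index outside the topology")
  if (nrow(object@dihedrals) &&
      any(object@dihedrals$periodicity < 1))
    return("dihedral periodicity must be >= 1")
  TRUE
})

#' Selection: a named, ordered set of atom indices
#'
#' @slot name Selection label (usually the expression that produced it).
#' @slot indices Increasing, unique 1-based atom indices into a topology.
#' @seealso [makeSelection()]
#' @export
setClass("Selection",
  representation(name = "character", indices = "integer"))

setValidity("Selection", function(object) {
  i <- object@indices
  if (length(i) < 1L) return("selection is empty")
  if (any(i < 1L)) return("selection indices must be positive")
  if (anyDuplicated(i)) return("selection indices must be unique")
  if (is.unsorted(i)) return("selection indices must preserve atom order")
  TRUE
})

#' SuperpositionResult: optimal rigid-body fit
#'
#' @slot rotation 3x3 proper rotation matrix (det = +1).
#' @slot translation Length-3 translation vector, Angstrom. The fitted
#'   coordinates are `rotation %*% x + translation` for each mobile atom.
#' @slot rmsd Weighted RMSD after the fit, Angstrom.
#' @seealso [kabschSuperpose()]
#' @export
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric"))

setValidity("SuperpositionResult", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (abs(det(R) - 1) > 1e-9) return("rotation must be proper (det = +1)")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation must be orthonormal")
  if (object@rmsd < 0) return("rmsd must be >= 0")
  TRUE
})

#' RmsdSeries: positional deviation over time
#'
#' @slot times Frame time stamps, ps.
#' @slot values RMSD per frame, Angstrom.
#' @slot referenceLabel Which reference the deviations are taken against
#'   (e.g. `"first_frame"` or an external structure label).
#' @seealso [rmsdSeries()]
#' @export
setClass("RmsdSeries",
  representation(times = "numeric", values = "numeric",
                 referenceLabel = "character"))

setValidity("RmsdSeries", function(object) {
  if (length(object@times) != length(object@values))
    return("times and values differ in length")
  if (any(object@values < 0)) return("RMSD values must be >= 0")
  TRUE
})

#' RmsfProfile: per-residue fluctuation amplitudes
#'
#' @slot residues `data.frame(chain, resseq, icode)` identifying each
#'   residue (reported at its C-alpha).
#' @slot rmsf RMSF per residue, Angstrom.
#' @slot label System name.
#' @seealso [rmsfProfile()], [rmsfDifference()], [flexibilityBands()]
#' @export
setClass("RmsfProfile",
  representation(residues = "data.frame", rmsf = "numeric",
                 label = "character"))

setValidity("RmsfProfile", function(object) {
  if (nrow(object@residues) != length(object@rmsf))
    return("residue table and rmsf vector differ in length")
  if (any(object@rmsf < 0)) return("rmsf values must be >= 0")
  TRUE
})

#' SasaProfile: per-residue solvent accessibility
#'
#' @slot residues `data.frame(chain, resseq, icode)`.
#' @slot sasa Mean SASA per residue over the analysis window, Angstrom^2.
#' @slot label System name.
#' @seealso [sasaStructure()], [sasaTrajectory()], [sasaDifference()]
#' @export
setClass("SasaProfile",
  representation(residues = "data.frame", sasa = "numeric",
                 label = "character"))

setValidity("SasaProfile", function(object) {
  if (nrow(object@residues) != length(object@sasa))
    return("residue table and sasa vector differ in length")
  if (any(object@sasa < -1e-9)) return("sasa values must be >= 0")
  TRUE
})

#' EnergyModelConfig: MM-GBSA model constants
#'
#' Defaults follow the study conventions of the implemented protocol:
#' interior dielectric 1.0, solvent dielectric 80.0, nonpolar surface
#' coefficient gamma = 0.00542 kcal/(mol A^2) and intercept
#' beta = 0.92 kcal/mol, Coulomb constant 332.0636 kcal A / (mol e^2).
#' The conformational-entropy term is deliberately unsupported: the
#' protocol omits it, and constructing a config with
#' `includeEntropy = TRUE` is an error.
#'
#' @slot interiorDielectric Solute dielectric (> 0), default 1.0.
#' @slot solventDielectric Solvent dielectric (> 0), default 80.0.
#' @slot gamma Nonpolar surface-area coefficient, kcal/(mol A^2).
#' @slot beta Nonpolar intercept, kcal/mol.
#' @slot coulombConstant kcal A / (mol e^2).
#' @slot gbModel `"HCT"` (pairwise descreening) or `"OBC2"` (rescaled).
#' @slot gbOffset Intrinsic-radius offset subtracted from `gb_radius`
#'   before descreening, Angstrom (AMBER convention 0.09).
#' @slot bornRadiusFloor Clamp for non-positive effective Born radii, A.
#' @slot scaleEE14 Multiplier on 1-4 electrostatics (default 1/1.2).
#' @slot scaleLJ14 Multiplier on 1-4 Lennard-Jones (default 1/2).
#' @seealso [energyModelConfig()]
#' @export
setClass("EnergyModelConfig",
  representation(interiorDielectric = "numeric",
                 solventDielectric = "numeric",
                 gamma = "numeric", beta = "numeric",
                 coulombConstant = "numeric", gbModel = "character",
                 gbOffset = "numeric", bornRadiusFloor = "numeric",
                 scaleEE14 = "numeric", scaleLJ14 = "numeric"))

setValidity("EnergyModelConfig", function(object) {
  if (object@interiorDielectric <= 0 || object@solventDielectric <= 0)
    return("dielectric constants must be > 0")
  if (object@gamma < 0) return("gamma must be >= 0")
  if (!object@gbModel %in% c("HCT", "OBC2"))
    return("gbModel must be 'HCT' or 'OBC2'")
  if (object@bornRadiusFloor <= 0) return("bornRadiusFloor must be > 0")
  TRUE
})

#' EnergyComponents: the MM-GBSA component ledger for one snapshot
#'
#' All values kcal/mol. The two ledger identities
#' `gbsol = gb_polar + nonpolar` and
#' `gbtot = internal + electrostatic + vdw + gbsol`
#' hold exactly by construction and are enforced at 1e-9.
#'
#' @slot internal Bond + angle + dihedral energy (INT).
#' @slot electrostatic Gas-phase Coulomb energy (ELE).
#' @slot vdw Lennard-Jones energy (VDW).
#' @slot gbPolar Generalized-Born polar solvation energy.
#' @slot nonpolar SASA-linear nonpolar solvation energy.
#' @slot gbsol Total solvation energy (GBSOL).
#' @slot gbtot Total energy (GBTOT).
#' @seealso [snapshotEnergy()]
#' @export
setClass("EnergyComponents",
  representation(internal = "numeric", electrostatic = "numeric",
                 vdw = "numeric", gbPolar = "numeric",
                 nonpolar = "numeric", gbsol = "numeric",
                 gbtot = "numeric"))

setValidity("EnergyComponents", function(object) {
  if (abs(object@gbsol - (object@gbPolar + object@nonpolar)) > 1e-9)
    return("ledger violation: gbsol != gb_polar + nonpolar")
  if (abs(object@gbtot - (object@internal + object@electrostatic +
                          object@vdw + object@gbsol)) > 1e-9)
    return("ledger violation: gbtot != internal + ele + vdw + gbsol")
  TRUE
})

#' EnergySummary: snapshot mean and spread per component
#'
#' @slot means Named numeric vector of component means (same names as
#'   [energyVector()]).
#' @slot sds Named numeric vector of component standard deviations.
#' @slot nSnapshots Number of snapshots averaged.
#' @slot label System name.
#' @seealso [mmgbsaSummary()]
#' @export
setClass("EnergySummary",
  representation(means = "numeric", sds = "numeric",
                 nSnapshots = "integer", label = "character"))

.ENERGY_NAMES <- c("internal", "electrostatic", "vdw", "gb_polar",
                   "nonpolar", "gbsol", "gbtot")

setValidity("EnergySummary", function(object) {
  if (!identical(names(object@means), .ENERGY_NAMES) ||
      !identical(names(object@sds), .ENERGY_NAMES))
    return("means/sds must be named with the seven ledger components")
  if (any(object@sds < 0)) return("standard deviations must be >= 0")
  m <- object@means
  if (abs(m["gbsol"] - (m["gb_polar"] + m["nonpolar"])) > 1e-6)
    return("mean ledger violation: gbsol")
  if (abs(m["gbtot"] - sum(m[c("internal", "electrostatic", "vdw",
                               "gbsol")])) > 1e-6)
    return("mean ledger violation: gbtot")
  TRUE
})

#' SyntheticSpec: ground-truth recipe for a toy complex and trajectory
#'
#' Describes a two-chain toy complex (ligand chain `A`, receptor chain
#' `B`) with planted interface salt bridges, a per-residue fluctuation
#' amplitude profile, an optional abrupt conformational-shift event, and
#' optional pseudo-glycan occluder spheres. Identical spec + seed yields
#' bit-identical output.
#'
#' @slot nResLigand Residues in the ligand chain.
#' @slot nResReceptor Residues in the receptor chain.
#' @slot bridges `data.frame(ligand_res, receptor_res, occupancy,
#'   closed_distance, open_distance, cation, anion)`; `cation` in
#'   `{"LYS","ARG"}` (planted on the ligand), `anion` in `{"ASP","GLU"}`
#'   (planted on the receptor).
#' @slot sigmaProfile Per-residue Gaussian displacement sigma, Angstrom,
#'   length `nResLigand + nResReceptor` (ligand first).
#' @slot tipSigma Reduced jitter applied to the charged bridge tip atoms
#'   so the open/closed distance separation stays clean, Angstrom.
#' @slot shiftFrame Frame index from which the shift displacement applies
#'   (0 = no event).
#' @slot shiftResidues Ligand residue numbers displaced by the event.
#' @slot shiftDisplacement Length-3 displacement vector, Angstrom.
#' @slot occluders `data.frame(site_res, n_spheres)`: pseudo-glycan
#'   spheres attached to ligand residues, pointing away from the
#'   interface.
#' @slot bridgePersistence Probability that a bridge keeps its previous
#'   open/closed state before the stationary redraw (0 = i.i.d. states).
#' @slot nFrames Number of trajectory frames.
#' @slot frameSpacing Time per frame, ps.
#' @slot seed RNG seed.
#' @seealso [syntheticSpec()], [buildToyComplex()], [sampleTrajectory()]
#' @export
setClass("SyntheticSpec",
  representation(nResLigand = "integer", nResReceptor = "integer",
                 bridges = "data.frame", sigmaProfile = "numeric",
                 tipSigma = "numeric", shiftFrame = "integer",
                 shiftResidues = "integer", shiftDisplacement = "numeric",
                 occluders = "data.frame", bridgePersistence = "numeric",
                 nFrames = "integer", frameSpacing = "numeric",
                 seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  b <- object@bridges
  if (nrow(b)) {
    if (any(b$occupancy < 0 | b$occupancy > 1))
      return("bridge occupancies must lie in [0, 1]")
    if (any(b$open_distance <= b$closed_distance))
      return("open_distance must exceed closed_distance")
    if (any(b$ligand_res < 1 | b$ligand_res > object@nResLigand) ||
        any(b$receptor_res < 1 | b$receptor_res > object@nResReceptor))
      return("bridge residues out of range")
    if (!all(b$cation %in% c("LYS", "ARG")) ||
        !all(b$anion %in% c("ASP", "GLU")))
      return("bridge cation must be LYS/ARG and anion ASP/GLU")
  }
  nres <- object@nResLigand + object@nResReceptor
  if (length(object@sigmaProfile) != nres)
    return("sigmaProfile must have one value per residue")
  if (any(object@sigmaProfile < 0)) return("sigma values must be >= 0")
  if (object@bridgePersistence < 0 || object@bridgePersistence >= 1)
    return("bridgePersistence must lie in [0, 1)")
  if (object@nFrames < 1L) return("nFrames must be >= 1")
  if (object@frameSpacing <= 0) return("frameSpacing must be > 0")
  if (object@shiftFrame > 0 &&
      (length(object@shiftDisplacement) != 3L ||
       !length(object@shiftResidues)))
    return("shift event needs residues and a 3-vector displacement")
  TRUE
})
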