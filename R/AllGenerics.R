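#' @include AllClasses.R
NULL

#' Number of atoms in a structure or trajectory topology
#'
#' @param x A [StructureModel-class] or [Trajectory-class].
#' @return Integer atom count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Atom table of a structure
#'
#' @param x A [StructureModel-class] or [Trajectory-class].
#' @return A `data.frame` with one row per atom (serial, name, element,
#'   resname, chain, resseq, icode, x, y, z).
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' Cartesian coordinates
#'
#' @param x A [StructureModel-class].
#' @return Numeric `n x 3` matrix of coordinates in Angstrom.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @param value Replacement `n x 3` coordinate matrix.
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' Chain role assignments
#'
#' Roles label each chain as `ligand_alpha`, `ligand_beta`, `receptor` or
#' `other`, mirroring the hormone alpha/beta subunits and the receptor
#' fragment of a two-protein complex.
#'
#' @param x A [StructureModel-class].
#' @return Named character vector, one role per chain.
#' @export
setGeneric("chainRoles", function(x) standardGeneric("chainRoles"))

#' @rdname chainRoles
#' @param value Named character vector of roles (names are chain ids).
#' @export
setGeneric("chainRoles<-", function(x, value) standardGeneric("chainRoles<-"))

#' Number of frames in a trajectory
#'
#' @param x A [Trajectory-class].
#' @return Integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Time spacing between trajectory frames
#'
#' @param x A [Trajectory-class].
#' @return Frame spacing in picoseconds.
#' @export
setGeneric("frameSpacing", function(x) standardGeneric("frameSpacing"))

#' Coordinates of one trajectory frame
#'
#' @param x A [Trajectory-class].
#' @param i Frame index (1-based).
#' @return Numeric `n x 3` coordinate matrix for frame `i`.
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' Frame time stamps
#'
#' Frame `i` is stamped at `i * frameSpacing(x)` ps, so the last stamp
#' equals the total simulated time.
#'
#' @param x A [Trajectory-class].
#' @return Numeric vector of times in ps.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Mean per-residue fluctuation of a profile
#'
#' @param x An [RmsfProfile-class].
#' @return Arithmetic mean of the per-residue RMSF values, in Angstrom.
#' @export
setGeneric("meanRmsf", function(x) standardGeneric("meanRmsf"))

#' Total solvent-accessible surface area of a profile
#'
#' @param x A [SasaProfile-class].
#' @return Total SASA in Angstrom^2 (sum of the per-residue values).
#' @export
setGeneric("totalSasa", function(x) standardGeneric("totalSasa"))

#' Energy component vector
#'
#' @param x An [EnergyComponents-class] or [EnergySummary-class].
#' @return Named numeric vector with elements `internal`, `electrostatic`,
#'   `vdw`, `gb_polar`, `nonpolar`, `gbsol`, `gbtot` (kcal/mol). For an
#'   [EnergySummary-class] the per-snapshot means are returned.
#' @export
setGeneric("energyVector", function(x) standardGeneric("energyVector"))
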