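#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "StructureModel", function(x) nrow(x@atoms))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Trajectory", function(x) nrow(x@topology@atoms))

#' @rdname atomData
#' @export
setMethod("atomData", "StructureModel", function(x) x@atoms)

#' @rdname atomData
#' @export
setMethod("atomData", "Trajectory", function(x) x@topology@atoms)

#' @rdname coords
#' @export
setMethod("coords", "StructureModel", function(x)
  unname(as.matrix(x@atoms[, c("x", "y", "z")])))

#' @rdname coords
#' @export
setMethod("coords<-", "StructureModel", function(x, value) {
  value <- as.matrix(value)
  stopifnot(nrow(value) == nAtoms(x), ncol(value) == 3L)
  x@atoms$x <- value[, 1]
  x@atoms$y <- value[, 2]
  x@atoms$z <- value[, 3]
  validObject(x)
  x
})

#' @rdname chainRoles
#' @export
setMethod("chainRoles", "StructureModel", function(x) x@chainRoles)

#' @rdname chainRoles
#' @export
setMethod("chainRoles<-", "StructureModel", function(x, value) {
  x@chainRoles <- value
  validObject(x)
  x
})

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])

#' @rdname frameSpacing
#' @export
setMethod("frameSpacing", "Trajectory", function(x) x@frameSpacing)

#' @rdname frameCoords
#' @export
setMethod("frameCoords", "Trajectory", function(x, i) {
  if (i < 1L || i > nFrames(x)) stop("frame index out of range: ", i)
  matrix(x@coords[i, , ], ncol = 3L)
})

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "Trajectory", function(x)
  seq_len(nFrames(x)) * x@frameSpacing)

#' @rdname meanRmsf
#' @export
setMethod("meanRmsf", "RmsfProfile", function(x) mean(x@rmsf))

#' @rdname totalSasa
#' @export
setMethod("totalSasa", "SasaProfile", function(x) sum(x@sasa))

#' @rdname energyVector
#' @export
setMethod("energyVector", "EnergyComponents", function(x)
  c(internal = x@internal, electrostatic = x@electrostatic, vdw = x@vdw,
    gb_polar = x@gbPolar, nonpolar = x@nonpolar, gbsol = x@gbsol,
    gbtot = x@gbtot))

#' @rdname energyVector
#' @export
setMethod("energyVector", "EnergySummary", function(x) x@means)

#' Coerce result objects to data frames
#'
#' @param x An [RmsdSeries-class], [RmsfProfile-class] or
#'   [SasaProfile-class].
#' @param row.names,optional Passed through (unused).
#' @param ... Unused.
#' @return A `data.frame` representation.
#' @name as.data.frame-methods
NULL

#' @rdname as.data.frame-methods
#' @export
as.data.frame.RmsdSeries <- function(x, row.names = NULL,
                                     optional = FALSE, ...)
  data.frame(time_ps = x@times, rmsd_A = x@values)

#' @rdname as.data.frame-methods
#' @export
as.data.frame.RmsfProfile <- function(x, row.names = NULL,
                                      optional = FALSE, ...)
  cbind(x@residues, data.frame(rmsf_A = x@rmsf))

#' @rdname as.data.frame-methods
#' @export
as.data.frame.SasaProfile <- function(x, row.names = NULL,
                                      optional = FALSE, ...)
  cbind(x@residues, data.frame(sasa_A2 = x@sasa))

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  key <- paste(a$chain, a$resseq, a$icode, sep = "|")
  cat(sprintf("StructureModel: %d atoms, %d residues, %d chain(s)\n",
              nrow(a), length(unique(key)), length(unique(a$chain))))
  for (ch in unique(a$chain))
    cat(sprintf("  chain %s: %d atoms [%s]\n", ch, sum(a$chain == ch),
                object@chainRoles[[ch]]))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf(
    "Trajectory: %d frames x %d atoms, %.3g ps/frame (total %.4g ps)\n",
    nFrames(object), nAtoms(object), object@frameSpacing,
    nFrames(object) * object@frameSpacing))
})

setMethod("show", "ForceFieldTable", function(object) {
  cat(sprintf(
    "ForceFieldTable: %d atoms, %d bonds, %d angles, %d dihedrals\n",
    nrow(object@atoms), nrow(object@bonds), nrow(object@angles),
    nrow(object@dihedrals)))
})

setMethod("show", "Selection", function(object) {
  cat(sprintf("Selection '%s': %d atoms\n", object@name,
              length(object@indices)))
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd = %.4f A\n", object@rmsd))
})

setMethod("show", "RmsdSeries", function(object) {
  cat(sprintf(
    "RmsdSeries vs %s: %d frames, mean %.3f A, max %.3f A\n",
    object@referenceLabel, length(object@values),
    mean(object@values), max(object@values)))
})

setMethod("show", "RmsfProfile", function(object) {
  cat(sprintf("RmsfProfile '%s': %d residues, mean RMSF %.3f A\n",
              object@label, length(object@rmsf), meanRmsf(object)))
})

setMethod("show", "SasaProfile", function(object) {
  cat(sprintf("SasaProfile '%s': %d residues, total %.1f A^2\n",
              object@label, length(object@sasa), totalSasa(object)))
})

setMethod("show", "EnergyComponents", function(object) {
  v <- energyVector(object)
  cat("EnergyComponents (kcal/mol):\n")
  for (nm in names(v)) cat(sprintf("  %-13s %12.4f\n", nm, v[[nm]]))
})

setMethod("show", "EnergySummary", function(object) {
  cat(sprintf("EnergySummary '%s' over %d snapshots (kcal/mol):\n",
              object@label, object@nSnapshots))
  for (nm in names(object@means))
    cat(sprintf("  %-13s %12.2f (%.2f)\n", nm, object@means[[nm]],
                object@sds[[nm]]))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d+%d residues, %d bridge(s), %d frames @ %.3g ps, seed %d\n",
    object@nResLigand, object@nResReceptor, nrow(object@bridges),
    object@nFrames, object@frameSpacing, object@seed))
  if (object@shiftFrame > 0)
    cat(sprintf("  shift event at frame %d (%d residues)\n",
                object@shiftFrame, length(object@shiftResidues)))
  if (nrow(object@occluders))
    cat(sprintf("  %d occluder site(s), %d sphere(s) total\n",
                nrow(object@occluders), sum(object@occluders$n_spheres)))
})
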