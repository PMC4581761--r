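#' @include AllClasses.R AllGenerics.R superposition.R
NULL

#' Per-residue RMSF profile of a trajectory window
#'
#' Fluctuations are measured about the window-mean structure: frames are
#' superposed onto an initial reference (the first window frame), the
#' mean structure is formed, frames are re-superposed onto that mean and
#' the mean recomputed (two iterations), and the RMSF of each selected
#' atom is the root-mean-squared deviation from the final mean. With a
#' C-alpha selection this yields the conventional per-residue profile.
#'
#' @param traj A [Trajectory-class].
#' @param selection [Selection-class] of reporter atoms (typically
#'   `"calpha"`), one per residue.
#' @param window Integer vector of frame indices, or `NULL` for all
#'   frames. Must contain at least 2 frames.
#' @param label System name stored in the profile.
#' @return An [RmsfProfile-class].
#' @export
rmsfProfile <- function(traj, selection, window = NULL, label = "system") {
  idx <- selection@indices
  if (max(idx) > nAtoms(traj))
    stop("selection exceeds trajectory topology", call. = FALSE)
  if (is.null(window)) window <- seq_len(nFrames(traj))
  if (length(window) < 2L)
    stop("insufficient frames: RMSF needs a window of at least 2 frames",
         call. = FALSE)
  sel_frames <- lapply(window, function(f)
    frameCoords(traj, f)[idx, , drop = FALSE])
  ref <- sel_frames[[1L]]
  for (iter in 1:2) {
    fitted <- lapply(sel_frames, function(xyz)
      applySuperposition(kabschSuperpose(xyz, ref), xyz))
    ref <- Reduce(`+`, fitted) / length(fitted)
  }
  sq <- Reduce(`+`, lapply(fitted, function(xyz)
    rowSums((xyz - ref)^2))) / length(fitted)
  rmsf <- sqrt(sq)
  new("RmsfProfile", residues = .residue_table(traj@topology, idx),
      rmsf = rmsf, label = label)
}

.match_residues <- function(a, b, what) {
  if (nrow(a@residues) != nrow(b@residues) ||
      !all(a@residues$chain == b@residues$chain &
           a@residues$resseq == b@residues$resseq &
           a@residues$icode == b@residues$icode))
    stop("residue lists differ between the two ", what,
         " profiles; alignment is required", call. = FALSE)
}

#' Glycoform difference of two RMSF profiles
#'
#' Per-residue `delta = system - baseline`; residues whose absolute
#' difference exceeds `threshold` (default 0.50 Angstrom) are flagged as
#' highly fluctuating.
#'
#' @param system,baseline [RmsfProfile-class] objects over identical
#'   residue lists.
#' @param threshold Flagging threshold, Angstrom.
#' @return `data.frame(chain, resseq, icode, delta_A, flagged)` with the
#'   threshold stored as attribute `"threshold"`.
#' @export
rmsfDifference <- function(system, baseline, threshold = 0.50) {
  .match_residues(system, baseline, "RMSF")
  delta <- system@rmsf - baseline@rmsf
  out <- cbind(system@residues,
               data.frame(delta_A = delta,
                          flagged = abs(delta) > threshold))
  attr(out, "threshold") <- threshold
  out
}

#' Bound-versus-free RMSF comparison
#'
#' As [rmsfDifference()] with the receptor-binding convention: the
#' difference is `bound - free` and the default flagging threshold is
#' 1.0 Angstrom, so negative flagged deltas mark regions rigidified by
#' binding.
#'
#' @param bound,free [RmsfProfile-class] objects over identical residue
#'   lists.
#' @param threshold Flagging threshold, Angstrom.
#' @return As [rmsfDifference()].
#' @export
boundVsFreeComparison <- function(bound, free, threshold = 1.0)
  rmsfDifference(bound, free, threshold = threshold)

.BAND_EDGES <- c(1, 2, 3, 4, 5)
.BAND_NAMES <- c("blue", "cyan", "green", "yellow", "brown", "red")

#' Flexibility colour bands from an RMSF profile
#'
#' Residues are banded on a fixed sliding scale (right-closed
#' intervals, Angstrom): `<=1` blue (least flexible), `(1,2]` cyan,
#' `(2,3]` green, `(3,4]` yellow, `(4,5]` brown, `>5` red (highly
#' flexible). Band assignment is a pure function of the RMSF value.
#'
#' @param profile An [RmsfProfile-class].
#' @return `data.frame(chain, resseq, icode, rmsf_A, band)`.
#' @export
flexibilityBands <- function(profile) {
  if (!length(profile@rmsf)) stop("empty profile", call. = FALSE)
  band <- .BAND_NAMES[findInterval(profile@rmsf, .BAND_EDGES,
                                   left.open = TRUE) + 1L]
  cbind(profile@residues,
        data.frame(rmsf_A = profile@rmsf, band = band,
                   stringsAsFactors = FALSE))
}
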