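#' @include AllClasses.R AllGenerics.R structure-io.R
NULL

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the weighted
#' RMSD between two matched point sets. Reflections are excluded, so the
#' result is always a physical rigid motion.
#'
#' @param mobile Numeric `n x 3` matrix to be fitted.
#' @param reference Numeric `n x 3` matrix to fit onto.
#' @param weights Optional non-negative per-point weights (default
#'   uniform).
#' @return A [SuperpositionResult-class]. The fitted coordinates of
#'   point `x` are `rotation %*% x + translation`.
#' @examples
#' ref <- matrix(rnorm(12), 4, 3)
#' fit <- kabschSuperpose(ref + 5, ref)
#' fit@rmsd   # ~0: a pure translation is removed exactly
#' @export
kabschSuperpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference))
    stop("mobile and reference differ in point count", call. = FALSE)
  if (n < 3L)
    stop("degenerate geometry: superposition needs at least 3 points",
         call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with positive sum", call. = FALSE)
  w <- weights / sum(weights)
  mbar <- colSums(mobile * w)
  rbar <- colSums(reference * w)
  mc <- sweep(mobile, 2L, mbar)
  rc <- sweep(reference, 2L, rbar)
  H <- crossprod(mc * w, rc)                  # 3x3 weighted covariance
  if (qr(H)$rank < 2L)
    stop("degenerate geometry: rank-deficient covariance (collinear points?)",
         call. = FALSE)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- mc %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - rc)^2)))
  new("SuperpositionResult", rotation = R,
      translation = as.numeric(rbar - R %*% mbar), rmsd = rmsd)
}

#' Apply a superposition result to coordinates
#'
#' @param fit A [SuperpositionResult-class].
#' @param xyz Numeric `n x 3` coordinate matrix.
#' @return Transformed `n x 3` matrix.
#' @export
applySuperposition <- function(fit, xyz)
  sweep(as.matrix(xyz) %*% t(fit@rotation), 2L, fit@translation, "+")

#' RMSD time series of a trajectory against a reference
#'
#' Each frame's selected atoms are optimally superposed onto the
#' reference selection before the deviation is measured, so any rigid
#' motion applied uniformly to a frame leaves the series unchanged.
#'
#' @param traj A [Trajectory-class].
#' @param selection A [Selection-class] valid in both the trajectory
#'   topology and the reference.
#' @param reference A [StructureModel-class], or `NULL` to use the first
#'   frame (the default reference convention).
#' @param referenceLabel Label stored in the result.
#' @return An [RmsdSeries-class].
#' @export
rmsdSeries <- function(traj, selection, reference = NULL,
                       referenceLabel = NULL) {
  idx <- selection@indices
  if (max(idx) > nAtoms(traj))
    stop("selection exceeds trajectory topology", call. = FALSE)
  if (is.null(reference)) {
    ref_xyz <- frameCoords(traj, 1L)[idx, , drop = FALSE]
    if (is.null(referenceLabel)) referenceLabel <- "first_frame"
  } else {
    if (max(idx) > nAtoms(reference))
      stop("selection exceeds reference structure", call. = FALSE)
    ref_xyz <- coords(reference)[idx, , drop = FALSE]
    if (is.null(referenceLabel)) referenceLabel <- "external_structure"
  }
  vals <- vapply(seq_len(nFrames(traj)), function(f) {
    kabschSuperpose(frameCoords(traj, f)[idx, , drop = FALSE],
                    ref_xyz)@rmsd
  }, numeric(1))
  new("RmsdSeries", times = frameTimes(traj), values = vals,
      referenceLabel = referenceLabel)
}

#' Classify residues by settled backbone shift and interface contact
#'
#' Each analysed residue gets its backbone displacement between the
#' time-averaged post-superposition structure and the reference (a
#' settled shift, not a per-frame maximum), a shifted flag
#' (`shift > shiftThreshold`), an interface flag (any heavy atom within
#' `contactCutoff` of the partner selection in the reference), and a
#' class label: `contact`, `shifted`, `contact+shifted` or `neither`.
#'
#' @param traj A [Trajectory-class].
#' @param reference Reference [StructureModel-class] (or `NULL` for the
#'   first frame).
#' @param selection [Selection-class] of analysed atoms (the hormone
#'   side); residues are classified from its backbone atoms.
#' @param partnerSelection [Selection-class] of the binding partner's
#'   heavy atoms; must be disjoint from `selection`.
#' @param shiftThreshold Settled-shift threshold, Angstrom (default 1.5).
#' @param contactCutoff Heavy-atom contact cutoff, Angstrom (default 4.5).
#' @param superposeSelection Optional [Selection-class] used for the
#'   per-frame superposition (default: `selection`).
#' @return `data.frame(chain, resseq, icode, shift_A, is_shifted,
#'   is_interface, class)` with one row per analysed residue.
#' @export
classifyResidueShifts <- function(traj, reference, selection,
                                  partnerSelection,
                                  shiftThreshold = 1.5,
                                  contactCutoff = 4.5,
                                  superposeSelection = NULL) {
  if (shiftThreshold <= 0) stop("shiftThreshold must be > 0",
                                call. = FALSE)
  if (contactCutoff <= 0) stop("contactCutoff must be > 0",
                               call. = FALSE)
  if (length(intersect(selection@indices, partnerSelection@indices)))
    stop("analysed and partner selections must be disjoint",
         call. = FALSE)
  topo <- traj@topology
  if (is.null(reference)) {
    reference <- topo
    coords(reference) <- frameCoords(traj, 1L)
  }
  sup <- if (is.null(superposeSelection)) selection else superposeSelection
  sidx <- sup@indices
  ref_xyz <- coords(reference)
  # time-averaged coordinates after per-frame superposition
  acc <- matrix(0, nAtoms(traj), 3L)
  for (f in seq_len(nFrames(traj))) {
    xyz <- frameCoords(traj, f)
    fit <- kabschSuperpose(xyz[sidx, , drop = FALSE],
                           ref_xyz[sidx, , drop = FALSE])
    acc <- acc + applySuperposition(fit, xyz)
  }
  mean_xyz <- acc / nFrames(traj)

  a <- topo@atoms
  sel_atoms <- selection@indices
  res_key_all <- .residue_key(a)
  res_tab <- .residue_table(topo, sel_atoms)
  res_keys <- paste(res_tab$chain, res_tab$resseq, res_tab$icode,
                    sep = "|")
  part_idx <- partnerSelection@indices
  part_heavy <- part_idx[toupper(a$element[part_idx]) != "H"]
  part_xyz <- ref_xyz[part_heavy, , drop = FALSE]

  shift <- numeric(length(res_keys))
  interface <- logical(length(res_keys))
  for (r in seq_along(res_keys)) {
    ridx <- which(res_key_all == res_keys[r])
    bb <- ridx[a$name[ridx] %in% .BACKBONE_NAMES]
    if (!length(bb)) bb <- ridx
    disp <- sqrt(rowSums((mean_xyz[bb, , drop = FALSE] -
                          ref_xyz[bb, , drop = FALSE])^2))
    shift[r] <- max(disp)
    heavy <- ridx[toupper(a$element[ridx]) != "H"]
    if (length(part_heavy)) {
      dmin <- min(vapply(heavy, function(i)
        min(sqrt(colSums((t(part_xyz) - ref_xyz[i, ])^2))), numeric(1)))
      interface[r] <- dmin < contactCutoff
    }
  }
  shifted <- shift > shiftThreshold
  cls <- ifelse(interface & shifted, "contact+shifted",
         ifelse(interface, "contact",
         ifelse(shifted, "shifted", "neither")))
  cbind(res_tab, data.frame(shift_A = shift, is_shifted = shifted,
                            is_interface = interface, class = cls,
                            stringsAsFactors = FALSE))
}

#' Locate an abrupt conformational shift in an RMSD series
#'
#' Two-segment least-squares change-point: the split minimizing the
#' summed within-segment squared deviation from the segment means. The
#' returned index is the first frame of the post-shift regime.
#'
#' @param series An [RmsdSeries-class] or numeric vector.
#' @return Integer frame index of the first post-shift frame.
#' @export
detectShiftFrame <- function(series) {
  v <- if (is(series, "RmsdSeries")) series@values else as.numeric(series)
  n <- length(v)
  if (n < 3L) stop("series too short for change-point detection",
                   call. = FALSE)
  # prefix sums give O(n) evaluation of both segment SSEs
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  k <- seq_len(n - 1L)
  sse_left <- cs2[k] - cs[k]^2 / k
  nr <- n - k
  sr <- cs[n] - cs[k]
  sse_right <- (cs2[n] - cs2[k]) - sr^2 / nr
  which.min(sse_left + sse_right) + 1L
}
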