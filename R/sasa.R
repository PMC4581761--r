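#' @include AllClasses.R AllGenerics.R structure-io.R
NULL

#' Default per-element van der Waals radii (Angstrom)
#'
#' Bondi-style values used by the Shrake-Rupley engine; element `"X"` is
#' the pseudo-glycan occluder sphere of the synthetic generator.
#'
#' @return Named numeric vector of radii.
#' @export
defaultRadii <- function()
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, X = 3.00)

#' Deterministic quasi-uniform sphere points (golden spiral)
#'
#' @param n Number of points.
#' @return `n x 3` matrix of unit vectors. The construction is
#'   deterministic, so SASA results are reproducible bit for bit.
#' @export
goldenSpiralPoints <- function(n) {
  i <- seq_len(n) - 1L
  z <- 1 - 2 * (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# per-atom Shrake-Rupley areas; atoms with radius NA are skipped (area 0)
# but still never act as occluders
.sasa_atoms <- function(xyz, radii, probe, nPoints) {
  n <- nrow(xyz)
  pts <- goldenSpiralPoints(nPoints)
  ext <- radii + probe
  out <- numeric(n)
  # squared-distance matrix for neighbour detection
  sq <- rowSums(xyz^2)
  d2 <- outer(sq, sq, "+") - 2 * xyz %*% t(xyz)
  for (i in seq_len(n)) {
    cutoff2 <- (ext[i] + ext)^2
    nb <- which(d2[i, ] < cutoff2 & seq_len(n) != i)
    if (!length(nb)) {
      out[i] <- 4 * pi * ext[i]^2
      next
    }
    p <- sweep(pts * ext[i], 2L, xyz[i, ], "+")
    buried <- rep(FALSE, nPoints)
    for (j in nb) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
             (p[, 3] - xyz[j, 3])^2
      buried <- buried | dj2 < ext[j]^2
      if (all(buried)) break
    }
    out[i] <- 4 * pi * ext[i]^2 * sum(!buried) / nPoints
  }
  out
}

.atom_radii <- function(a, radii) {
  el <- toupper(a$element)
  r <- radii[el]
  if (anyNA(r))
    stop("no radius for element(s): ",
         paste(unique(el[is.na(r)]), collapse = ", "), call. = FALSE)
  unname(r)
}

#' Shrake-Rupley solvent-accessible surface area of one structure
#'
#' Per atom, the fraction of quasi-uniform test points on the expanded
#' sphere (radius `r_atom + probe`) that fall inside no neighbouring
#' expanded sphere, scaled by the sphere area. Hydrogens are excluded by
#' default; non-protein atoms (e.g. pseudo-glycan occluders) bury
#' protein surface but their own area is not assigned to any protein
#' residue. The per-residue profile sums all heavy atoms of each protein
#' residue, side chains included.
#'
#' @param model A [StructureModel-class].
#' @param radii Named per-element radii, Angstrom (default
#'   [defaultRadii()]).
#' @param probe Probe radius, Angstrom (default 1.4).
#' @param nPoints Test points per sphere (default 960).
#' @param includeHydrogens Keep hydrogens as spheres (default FALSE).
#' @param label Profile label.
#' @return A [SasaProfile-class] over the protein residues.
#' @export
sasaStructure <- function(model, radii = defaultRadii(), probe = 1.4,
                          nPoints = 960L, includeHydrogens = FALSE,
                          label = "structure") {
  a <- model@atoms
  keep <- if (includeHydrogens) rep(TRUE, nrow(a))
          else toupper(a$element) != "H"
  sub <- a[keep, , drop = FALSE]
  r <- .atom_radii(sub, radii)
  atom_sasa <- .sasa_atoms(unname(as.matrix(sub[, c("x", "y", "z")])),
                           r, probe, nPoints)
  is_protein <- sub$resname %in% .AMINO_RESNAMES
  res_tab <- .residue_table(model, which(keep)[is_protein])
  key_sub <- .residue_key(sub)[is_protein]
  keys <- paste(res_tab$chain, res_tab$resseq, res_tab$icode, sep = "|")
  per_res <- vapply(keys, function(k)
    sum(atom_sasa[is_protein][key_sub == k]), numeric(1))
  new("SasaProfile", residues = res_tab, sasa = unname(per_res),
      label = label)
}

#' Trajectory-averaged per-residue SASA
#'
#' Frames are sampled after an equilibration skip (default: the first
#' 12.5\% of frames, the 5-of-40 ns convention) with an optional stride,
#' and the per-residue SASA is averaged over the sampled frames.
#'
#' @param traj A [Trajectory-class].
#' @param skipFraction Fraction of initial frames discarded, in
#'   `[0, 1)`; default 0.125.
#' @param stride Frame stride within the analysis window (default 1).
#' @param ... Passed to [sasaStructure()] (`radii`, `probe`, `nPoints`,
#'   `includeHydrogens`).
#' @param label Profile label.
#' @return A [SasaProfile-class] of window means.
#' @export
sasaTrajectory <- function(traj, skipFraction = 0.125, stride = 1L, ...,
                           label = "trajectory") {
  if (skipFraction >= 1)
    stop("skipFraction must be < 1 (nothing left to analyse)",
         call. = FALSE)
  if (skipFraction < 0) stop("skipFraction must be >= 0", call. = FALSE)
  n <- nFrames(traj)
  start <- floor(skipFraction * n) + 1L
  frames <- seq(start, n, by = stride)
  topo <- traj@topology
  acc <- NULL
  for (f in frames) {
    m <- topo
    coords(m) <- frameCoords(traj, f)
    prof <- sasaStructure(m, ..., label = label)
    acc <- if (is.null(acc)) prof@sasa else acc + prof@sasa
  }
  new("SasaProfile", residues = prof@residues,
      sasa = acc / length(frames), label = label)
}

#' Per-residue SASA difference between two systems
#'
#' `delta = system - baseline` per residue; residues with
#' `|delta| > cutoff` (strict; default 40 Angstrom^2) are highlighted as
#' substantially occluded or exposed.
#'
#' @param system,baseline [SasaProfile-class] objects over identical
#'   residue lists.
#' @param cutoff Highlight cutoff, Angstrom^2.
#' @return `data.frame(chain, resseq, icode, delta_A2, highlighted)`
#'   with the cutoff stored as attribute `"cutoff"`.
#' @export
sasaDifference <- function(system, baseline, cutoff = 40) {
  if (nrow(system@residues) != nrow(baseline@residues) ||
      !all(system@residues$chain == baseline@residues$chain &
           system@residues$resseq == baseline@residues$resseq &
           system@residues$icode == baseline@residues$icode))
    stop("residue lists differ between the two SASA profiles",
         call. = FALSE)
  delta <- system@sasa - baseline@sasa
  out <- cbind(system@residues,
               data.frame(delta_A2 = delta,
                          highlighted = abs(delta) > cutoff))
  attr(out, "cutoff") <- cutoff
  out
}
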