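#' @include AllClasses.R AllGenerics.R structure-io.R
NULL

.CATION_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                      HIS = c("ND1", "NE2"))
.ANION_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

.charged_residues <- function(a, chains, tables) {
  out <- list()
  for (resname in names(tables)) {
    sel <- a$chain %in% chains & a$resname == resname &
      a$name %in% tables[[resname]]
    if (!any(sel)) next
    sub <- a[sel, , drop = FALSE]
    key <- paste(sub$chain, sub$resseq, sub$icode, sep = "|")
    for (k in unique(key)) {
      rows <- which(key == k)
      out[[length(out) + 1L]] <- list(
        chain = sub$chain[rows[1L]], resseq = sub$resseq[rows[1L]],
        icode = sub$icode[rows[1L]], resname = resname,
        atoms = sub$name[rows],
        idx = which(sel)[rows])
    }
  }
  out
}

#' Enumerate interface salt bridges in a reference structure
#'
#' A bridge is reported when the minimum N-O distance between a cationic
#' side chain (Lys NZ; Arg NE/NH1/NH2; His ND1/NE2 only if
#' `includeHistidine = TRUE`) on one side of the interface and an
#' anionic side chain (Asp OD1/OD2; Glu OE1/OE2) on the other is below
#' `seedCutoff`. Results are ordered by the ligand-side residue
#' (chain, then residue number); like-charged appositions are never
#' reported.
#'
#' @param model A [StructureModel-class] with chain roles assigned.
#' @param ligandChains Character vector of ligand chain ids (default:
#'   chains whose role starts with `ligand`).
#' @param receptorChains Character vector of receptor chain ids
#'   (default: chains with role `receptor`).
#' @param seedCutoff Detection cutoff on the reference N-O distance,
#'   Angstrom (default 4.0).
#' @param includeHistidine Count histidine as a cation (default FALSE).
#' @return `data.frame` with one row per bridge: cation and anion chain /
#'   residue number / residue name, comma-separated charged atom names,
#'   `ligand_side` (`"cation"` or `"anion"`), and the reference minimum
#'   N-O distance `min_distance_A`.
#' @export
findSaltBridges <- function(model, ligandChains = NULL,
                            receptorChains = NULL, seedCutoff = 4.0,
                            includeHistidine = FALSE) {
  roles <- model@chainRoles
  if (is.null(ligandChains))
    ligandChains <- names(roles)[startsWith(roles, "ligand")]
  if (is.null(receptorChains))
    receptorChains <- names(roles)[roles == "receptor"]
  if (!length(ligandChains) || !length(receptorChains))
    stop("both interface sides need at least one chain", call. = FALSE)
  a <- model@atoms
  cat_tab <- .CATION_ATOMS[if (includeHistidine) 1:3 else 1:2]
  xyz <- coords(model)
  sides <- list(ligand = ligandChains, receptor = receptorChains)
  rows <- list()
  for (lig_side in c("cation", "anion")) {
    cat_chains <- if (lig_side == "cation") ligandChains else receptorChains
    ani_chains <- if (lig_side == "cation") receptorChains else ligandChains
    cats <- .charged_residues(a, cat_chains, cat_tab)
    anis <- .charged_residues(a, ani_chains, .ANION_ATOMS)
    for (ct in cats) for (an in anis) {
      d <- min(sqrt(outer(rowSums(xyz[ct$idx, , drop = FALSE]^2),
                          rowSums(xyz[an$idx, , drop = FALSE]^2), "+") -
                    2 * xyz[ct$idx, , drop = FALSE] %*%
                      t(xyz[an$idx, , drop = FALSE])))
      if (d < seedCutoff)
        rows[[length(rows) + 1L]] <- data.frame(
          cation_chain = ct$chain, cation_resseq = ct$resseq,
          cation_icode = ct$icode, cation_resname = ct$resname,
          cation_atoms = paste(ct$atoms, collapse = ","),
          anion_chain = an$chain, anion_resseq = an$resseq,
          anion_icode = an$icode, anion_resname = an$resname,
          anion_atoms = paste(an$atoms, collapse = ","),
          ligand_side = lig_side, min_distance_A = d,
          stringsAsFactors = FALSE)
    }
  }
  lig_cat <- vapply(sides$ligand, function(ch) any(
    a$chain == ch & a$resname %in% names(.CATION_ATOMS)), logical(1))
  lig_ani <- vapply(sides$ligand, function(ch) any(
    a$chain == ch & a$resname %in% names(.ANION_ATOMS)), logical(1))
  rec_cat <- any(a$chain %in% sides$receptor &
                 a$resname %in% names(.CATION_ATOMS))
  rec_ani <- any(a$chain %in% sides$receptor &
                 a$resname %in% names(.ANION_ATOMS))
  if (!(any(lig_cat) || any(lig_ani)) || !(rec_cat || rec_ani))
    warning("no charged residues on one side of the interface")
  if (!length(rows))
    return(data.frame(cation_chain = character(0),
                      cation_resseq = integer(0),
                      cation_icode = character(0),
                      cation_resname = character(0),
                      cation_atoms = character(0),
                      anion_chain = character(0),
                      anion_resseq = integer(0),
                      anion_icode = character(0),
                      anion_resname = character(0),
                      anion_atoms = character(0),
                      ligand_side = character(0),
                      min_distance_A = numeric(0)))
  out <- do.call(rbind, rows)
  lig_chain <- ifelse(out$ligand_side == "cation", out$cation_chain,
                      out$anion_chain)
  lig_res <- ifelse(out$ligand_side == "cation", out$cation_resseq,
                    out$anion_resseq)
  out <- out[order(lig_chain, lig_res), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.bridge_atom_indices <- function(topology, pair) {
  a <- topology@atoms
  find <- function(chain, resseq, icode, names_csv) {
    nms <- strsplit(names_csv, ",", fixed = TRUE)[[1L]]
    idx <- which(a$chain == chain & a$resseq == resseq &
                 a$icode == icode & a$name %in% nms)
    missing <- setdiff(nms, a$name[idx])
    if (length(missing))
      stop("atom(s) missing from topology for residue ", chain, ":",
           resseq, ": ", paste(missing, collapse = ", "), call. = FALSE)
    idx
  }
  list(cation = find(pair$cation_chain, pair$cation_resseq,
                     pair$cation_icode, pair$cation_atoms),
       anion = find(pair$anion_chain, pair$anion_resseq,
                    pair$anion_icode, pair$anion_atoms))
}

#' Strided N-O distance series for one salt bridge
#'
#' Samples frames `stride, 2*stride, ...` and reports, per sampled
#' frame, the minimum distance over all cation-nitrogen by anion-oxygen
#' atom pairs of the bridge.
#'
#' @param traj A [Trajectory-class].
#' @param pair One row of the table returned by [findSaltBridges()].
#' @param stride Sampling stride in frames (>= 1). With the original
#'   2 fs integration step the protocol's "every 1000th time step"
#'   corresponds to one sample per 2 ps, i.e.
#'   `stride = max(1, ceiling(2 / frameSpacing(traj)))`.
#' @return Numeric vector of minimum N-O distances, Angstrom.
#' @export
bridgeDistanceSeries <- function(traj, pair, stride = 1L) {
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  pair <- as.list(pair)
  idx <- .bridge_atom_indices(traj@topology, pair)
  frames <- seq(stride, nFrames(traj), by = stride)
  vapply(frames, function(f) {
    xyz <- frameCoords(traj, f)
    cn <- xyz[idx$cation, , drop = FALSE]
    ao <- xyz[idx$anion, , drop = FALSE]
    min(sqrt(outer(rowSums(cn^2), rowSums(ao^2), "+") -
             2 * cn %*% t(ao)))
  }, numeric(1))
}

#' Persistence statistics of a salt-bridge distance series
#'
#' @param series Numeric vector of sampled minimum N-O distances,
#'   Angstrom (non-empty).
#' @param cutoff Occupancy cutoff, Angstrom (default 3.5); occupancy
#'   counts samples with distance strictly below the cutoff.
#' @return `data.frame(median_A, occupancy, occupancy_pct, n_samples)`:
#'   the sample median (even length: mean of the central pair), the
#'   occupancy fraction in `[0, 1]`, the same as a percentage rounded to
#'   1 decimal for tabulation, and the sample count.
#' @export
bridgeStatistics <- function(series, cutoff = 3.5) {
  if (!length(series)) stop("empty distance series", call. = FALSE)
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  occ <- mean(series < cutoff)
  data.frame(median_A = stats::median(series), occupancy = occ,
             occupancy_pct = round(100 * occ, 1L),
             n_samples = length(series))
}

#' Default sampling stride for the bridge-distance protocol
#'
#' @param traj A [Trajectory-class].
#' @param samplePs Target sampling period, ps (default 2, the "every
#'   1000th 2-fs step" convention).
#' @return Integer stride, at least 1.
#' @export
defaultBridgeStride <- function(traj, samplePs = 2)
  max(1L, as.integer(ceiling(samplePs / frameSpacing(traj))))
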