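#' @include AllClasses.R AllGenerics.R structure-io.R
NULL

#' Construct a synthetic-complex specification
#'
#' Defaults describe a 20+20-residue two-chain complex sampled for 400
#' frames at 100 ps/frame (a 40-ns-equivalent run) with a 0.5-Angstrom
#' background fluctuation amplitude and slightly mobile termini --
#' magnitudes chosen to mimic the modest RMSF level of a stable bound
#' hormone-receptor complex.
#'
#' @param nResLigand,nResReceptor Residues per chain.
#' @param bridges `data.frame(ligand_res, receptor_res, occupancy,
#'   closed_distance, open_distance, cation, anion)`; may have zero
#'   rows.
#' @param sigmaProfile Per-residue jitter sigma, Angstrom (ligand then
#'   receptor); default 0.5 with 0.9 at the four chain termini.
#' @param tipSigma Jitter sigma for charged bridge-tip atoms, Angstrom.
#' @param shiftFrame Frame from which the conformational-shift
#'   displacement applies (0 disables the event).
#' @param shiftResidues Ligand residue numbers displaced by the event.
#' @param shiftDisplacement Length-3 displacement, Angstrom.
#' @param occluders `data.frame(site_res, n_spheres)` of pseudo-glycan
#'   spheres on ligand residues.
#' @param bridgePersistence State-retention probability of the two-state
#'   bridge process (0 gives i.i.d. states at the target occupancy).
#' @param nFrames,frameSpacing Trajectory length and spacing (ps).
#' @param seed RNG seed (fixed seed implies bit-identical output).
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nResLigand = 20L, nResReceptor = 20L,
                          bridges = defaultBridgeTable(),
                          sigmaProfile = NULL, tipSigma = 0.05,
                          shiftFrame = 0L, shiftResidues = integer(0),
                          shiftDisplacement = numeric(0),
                          occluders = data.frame(site_res = integer(0),
                                                 n_spheres = integer(0)),
                          bridgePersistence = 0,
                          nFrames = 400L, frameSpacing = 100,
                          seed = 1L) {
  if (is.null(sigmaProfile)) {
    sigmaProfile <- rep(0.5, nResLigand + nResReceptor)
    sigmaProfile[c(1L, nResLigand, nResLigand + 1L,
                   nResLigand + nResReceptor)] <- 0.9
  }
  new("SyntheticSpec", nResLigand = as.integer(nResLigand),
      nResReceptor = as.integer(nResReceptor), bridges = bridges,
      sigmaProfile = sigmaProfile, tipSigma = tipSigma,
      shiftFrame = as.integer(shiftFrame),
      shiftResidues = as.integer(shiftResidues),
      shiftDisplacement = as.numeric(shiftDisplacement),
      occluders = occluders, bridgePersistence = bridgePersistence,
      nFrames = as.integer(nFrames), frameSpacing = frameSpacing,
      seed = as.integer(seed))
}

#' Default planted-bridge table
#'
#' Four interface salt bridges with persistence targets spanning the
#' range seen across glycoforms of a hormone-receptor complex (from
#' nearly always closed to barely majority-closed).
#'
#' @return The bridge `data.frame` accepted by [syntheticSpec()].
#' @export
defaultBridgeTable <- function()
  data.frame(ligand_res = c(4L, 8L, 12L, 16L),
             receptor_res = c(4L, 8L, 12L, 16L),
             occupancy = c(0.998, 0.97, 0.90, 0.62),
             closed_distance = 2.8, open_distance = 6.0,
             cation = c("LYS", "LYS", "ARG", "LYS"),
             anion = c("ASP", "ASP", "GLU", "ASP"),
             stringsAsFactors = FALSE)

# geometry constants of the toy complex (Angstrom)
.CA_STEP <- 3.8       # backbone spacing along x
.CHAIN_GAP <- 9.0     # distance between the two CA lines (y)
.ANION_REACH <- 3.1   # anion tip offset from the receptor CA line

.toy_residue_atoms <- function(chain, resseq, resname, ca, side_sign,
                               tip_atoms = NULL) {
  # backbone in the z=0 plane; side chain out of plane to avoid
  # degenerate geometry
  rows <- list(
    list(name = "N", element = "N",
         xyz = ca + c(-1.2, 0.9 * side_sign, 0)),
    list(name = "CA", element = "C", xyz = ca),
    list(name = "C", element = "C",
         xyz = ca + c(1.2, 0.9 * side_sign, 0)),
    list(name = "O", element = "O",
         xyz = ca + c(1.4, 0.9 * side_sign, 1.3)))
  if (is.null(tip_atoms)) {
    rows[[5L]] <- list(name = "CB", element = "C",
                       xyz = ca + c(0, -0.8 * side_sign, -1.2))
  } else {
    rows <- c(rows, tip_atoms)
  }
  do.call(rbind, lapply(rows, function(r)
    data.frame(name = r$name, element = r$element, resname = resname,
               chain = chain, resseq = resseq, icode = "",
               x = r$xyz[1], y = r$xyz[2], z = r$xyz[3],
               stringsAsFactors = FALSE)))
}

.cation_tip_atoms <- function(type, tip) {
  # tip = position of the nitrogen closest to the anion (closed state)
  if (type == "LYS")
    return(list(list(name = "NZ", element = "N", xyz = tip)))
  list(list(name = "NH1", element = "N", xyz = tip),
       list(name = "NH2", element = "N", xyz = tip + c(1.0, 0.2, 0.9)),
       list(name = "NE", element = "N", xyz = tip + c(-0.6, -1.0, -0.5)))
}

.anion_tip_atoms <- function(type, tip) {
  nms <- if (type == "ASP") c("OD1", "OD2") else c("OE1", "OE2")
  list(list(name = nms[1L], element = "O", xyz = tip),
       list(name = nms[2L], element = "O", xyz = tip + c(1.0, 0.1, -0.6)))
}

.TIP_NAMES <- c("NZ", "NE", "NH1", "NH2", "OD1", "OD2", "OE1", "OE2")

.toy_ff_params <- function(atoms) {
  # neutral backbone charge set; tips carry the formal charges
  charge <- numeric(nrow(atoms))
  charge[atoms$name == "N"] <- -0.45
  charge[atoms$name == "CA"] <- 0.25
  charge[atoms$name == "C"] <- 0.50
  charge[atoms$name == "O"] <- -0.50
  charge[atoms$name == "CB"] <- 0.20
  charge[atoms$name == "NZ"] <- 1.0
  charge[atoms$name %in% c("NH1", "NH2")] <- 0.5
  charge[atoms$name == "NE"] <- 0
  charge[atoms$name %in% c("OD1", "OD2", "OE1", "OE2")] <- -0.5
  el <- toupper(atoms$element)
  lj_sigma <- c(C = 3.40, N = 3.25, O = 2.96, X = 3.00)[el]
  lj_epsilon <- c(C = 0.109, N = 0.170, O = 0.210, X = 0.100)[el]
  gb_radius <- c(C = 1.70, N = 1.55, O = 1.50, X = 2.50)[el]
  gb_scale <- c(C = 0.72, N = 0.79, O = 0.85, X = 0.80)[el]
  data.frame(charge = charge, lj_sigma = unname(lj_sigma),
             lj_epsilon = unname(lj_epsilon),
             gb_radius = unname(gb_radius), gb_scale = unname(gb_scale))
}

.toy_bonded_terms <- function(atoms) {
  xyz <- unname(as.matrix(atoms[, c("x", "y", "z")]))
  dist <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  bonds <- list(); angles <- list(); dihedrals <- list()
  key <- paste(atoms$chain, atoms$resseq, sep = "|")
  prot <- atoms$resname %in% .AMINO_RESNAMES
  for (ch in unique(atoms$chain[prot])) {
    res <- unique(atoms$resseq[prot & atoms$chain == ch])
    idx_of <- function(rs, nm) which(atoms$chain == ch &
                                     atoms$resseq == rs &
                                     atoms$name == nm)
    prevC <- integer(0)
    for (rs in res) {
      iN <- idx_of(rs, "N"); iCA <- idx_of(rs, "CA")
      iC <- idx_of(rs, "C"); iO <- idx_of(rs, "O")
      add_bond <- function(i, j)
        bonds[[length(bonds) + 1L]] <<- c(i, j, 300, dist(i, j))
      add_bond(iN, iCA); add_bond(iCA, iC); add_bond(iC, iO)
      if (length(prevC)) {
        add_bond(prevC, iN)
        # backbone torsion across the peptide link
        prevCA <- which(atoms$chain == ch &
                        atoms$resseq == rs - 1L & atoms$name == "CA")
        if (length(prevCA))
          dihedrals[[length(dihedrals) + 1L]] <-
            c(prevCA, prevC, iN, iCA, 0.5, 2, 0)
      }
      angles[[length(angles) + 1L]] <-
        c(iN, iCA, iC, 50,
          acos(sum((xyz[iN, ] - xyz[iCA, ]) * (xyz[iC, ] - xyz[iCA, ])) /
               (dist(iN, iCA) * dist(iC, iCA))))
      side <- which(atoms$chain == ch & atoms$resseq == rs &
                    atoms$name %in% c("CB", .TIP_NAMES))
      for (s in side) add_bond(iCA, s)
      prevC <- iC
    }
  }
  as_df <- function(lst, nms) {
    if (!length(lst)) {
      out <- as.data.frame(matrix(numeric(0), ncol = length(nms)))
      names(out) <- nms
      return(out)
    }
    out <- as.data.frame(do.call(rbind, lst))
    names(out) <- nms
    out
  }
  b <- as_df(bonds, c("i", "j", "kb", "r0"))
  g <- as_df(angles, c("i", "j", "k", "ka", "theta0"))
  d <- as_df(dihedrals, c("i", "j", "k", "l", "barrier", "periodicity",
                          "phase"))
  for (cl in c("i", "j")) b[[cl]] <- as.integer(b[[cl]])
  for (cl in c("i", "j", "k")) g[[cl]] <- as.integer(g[[cl]])
  for (cl in c("i", "j", "k", "l")) d[[cl]] <- as.integer(d[[cl]])
  d$periodicity <- as.integer(d$periodicity)
  list(bonds = b, angles = g, dihedrals = d)
}

#' Build a toy two-chain complex with planted salt bridges
#'
#' Ligand chain `A` (role `ligand_alpha`) and receptor chain `B` (role
#' `receptor`) run as parallel simplified backbones 9 Angstrom apart.
#' Ordinary residues are alanine-like (backbone + CB); at each planted
#' bridge the ligand residue becomes Lys or Arg with its charged
#' nitrogen tip placed so the minimum N-O distance to the receptor-side
#' Asp/Glu oxygens equals `closed_distance` in the reference. Optional
#' pseudo-glycan occluder spheres (inert element `X`, LJ-only, zero
#' charge) are attached to ligand residues pointing away from the
#' interface. Construction is deterministic.
#'
#' @param spec A [SyntheticSpec-class].
#' @return `list(model = StructureModel, ff = ForceFieldTable)`.
#' @export
buildToyComplex <- function(spec) {
  validObject(spec)
  br <- spec@bridges
  lig_bridge <- stats::setNames(br$cation, br$ligand_res)
  rec_bridge <- stats::setNames(br$anion, br$receptor_res)
  parts <- list()
  # anion tips first: the cation tip position is derived from them
  anion_tip <- function(q) c(.CA_STEP * q, .CHAIN_GAP - .ANION_REACH, 0)
  for (i in seq_len(spec@nResLigand)) {
    ca <- c(.CA_STEP * i, 0, 0)
    tip <- NULL
    resname <- "ALA"
    b <- which(br$ligand_res == i)
    if (length(b)) {
      b <- b[1L]
      resname <- br$cation[b]
      t_anion <- anion_tip(br$receptor_res[b])
      tip_pos <- t_anion - c(0, br$closed_distance[b], 0)
      tip <- .cation_tip_atoms(resname, tip_pos)
    }
    parts[[length(parts) + 1L]] <-
      .toy_residue_atoms("A", i, resname, ca, side_sign = 1, tip)
  }
  occ <- spec@occluders
  if (nrow(occ)) {
    for (s in seq_len(nrow(occ))) {
      rs <- occ$site_res[s]
      ca <- c(.CA_STEP * rs, 0, 0)
      # spheres flank the side chain in z (pairs), then stack outward
      offsets <- list(c(0, -3.0, 1.6), c(0, -3.0, -1.6),
                      c(0.6, -6.2, 1.4), c(0.6, -6.2, -1.4))
      for (k in seq_len(min(occ$n_spheres[s], 4L))) {
        pos <- ca + offsets[[k]]
        parts[[length(parts) + 1L]] <- data.frame(
          name = paste0("X", k), element = "X", resname = "OCX",
          chain = "A", resseq = 900L + rs, icode = "",
          x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE)
      }
    }
  }
  for (i in seq_len(spec@nResReceptor)) {
    ca <- c(.CA_STEP * i, .CHAIN_GAP, 0)
    tip <- NULL
    resname <- "ALA"
    b <- which(br$receptor_res == i)
    if (length(b)) {
      b <- b[1L]
      resname <- br$anion[b]
      tip <- .anion_tip_atoms(resname, anion_tip(i))
    }
    parts[[length(parts) + 1L]] <-
      .toy_residue_atoms("B", i, resname, ca, side_sign = -1, tip)
  }
  atoms <- do.call(rbind, parts)
  atoms$serial <- seq_len(nrow(atoms))
  atoms <- atoms[, .ATOM_COLUMNS]
  model <- structureModel(atoms, c(A = "ligand_alpha", B = "receptor"))
  bonded <- .toy_bonded_terms(atoms)
  ff <- new("ForceFieldTable", atoms = .toy_ff_params(atoms),
            bonds = bonded$bonds, angles = bonded$angles,
            dihedrals = bonded$dihedrals)
  list(model = model, ff = ff)
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Sample a synthetic trajectory with known ground truth
#'
#' Frames are the reference plus independent Gaussian displacements per
#' atom (sigma from the per-residue profile; charged bridge-tip atoms
#' use the reduced `tipSigma`). A shift event adds its displacement to
#' the event residues from `shiftFrame` onward. Each planted bridge
#' follows a two-state process whose stationary closed fraction equals
#' the target occupancy (with `bridgePersistence = 0` the states are
#' i.i.d.); in the open state the cation tip swings away so the minimum
#' N-O distance equals `open_distance`. Identical spec + seed yields
#' bit-identical frames.
#'
#' @param model The [StructureModel-class] from [buildToyComplex()].
#' @param spec The matching [SyntheticSpec-class].
#' @return A [Trajectory-class]. The realized per-frame bridge states
#'   are attached as attribute `"bridgeStates"` (frames x bridges
#'   logical matrix, `TRUE` = closed) on the returned object's
#'   `@coords` -- ground truth for recovery tests.
#' @export
sampleTrajectory <- function(model, spec) {
  validObject(spec)
  a <- model@atoms
  n <- nrow(a)
  nf <- spec@nFrames
  ref <- coords(model)
  # per-atom sigma from the residue profile (occluders follow their
  # host site residue; tips get the reduced sigma)
  res_index <- ifelse(a$chain == "A",
                      ifelse(a$resseq > 900L, a$resseq - 900L, a$resseq),
                      spec@nResLigand + a$resseq)
  sigma <- spec@sigmaProfile[res_index]
  is_tip <- a$name %in% .TIP_NAMES &
    a$resname %in% c("LYS", "ARG", "ASP", "GLU")
  sigma[is_tip] <- spec@tipSigma
  # occluder blobs are bulky and sluggish: damped jitter also keeps
  # their LJ repulsion against the host side chain well-behaved
  sigma[a$resname == "OCX"] <- pmin(sigma[a$resname == "OCX"], 0.2)
  br <- spec@bridges
  .with_seed(spec@seed, {
    arr <- array(stats::rnorm(nf * n * 3L), dim = c(nf, n, 3L))
    for (k in 1:3) arr[, , k] <- sweep(arr[, , k], 2L, sigma, "*")
    for (k in 1:3) arr[, , k] <- sweep(arr[, , k], 2L, ref[, k], "+")
    if (spec@shiftFrame > 0L) {
      moved <- which(a$chain == "A" & a$resseq %in% spec@shiftResidues)
      fr <- spec@shiftFrame:nf
      for (k in 1:3)
        arr[fr, moved, k] <- arr[fr, moved, k] + spec@shiftDisplacement[k]
    }
    states <- matrix(TRUE, nf, max(1L, nrow(br)))
    if (nrow(br)) {
      phi <- spec@bridgePersistence
      for (b in seq_len(nrow(br))) {
        p <- br$occupancy[b]
        draws <- stats::runif(nf) < p
        if (phi > 0) {
          keep <- stats::runif(nf) < phi
          s <- logical(nf)
          s[1L] <- draws[1L]
          for (f in 2:nf) s[f] <- if (keep[f]) s[f - 1L] else draws[f]
        } else s <- draws
        states[, b] <- s
        tip_idx <- which(a$chain == "A" &
                         a$resseq == br$ligand_res[b] &
                         a$name %in% .TIP_NAMES)
        open_frames <- which(!s)
        if (length(open_frames)) {
          dy <- br$open_distance[b] - br$closed_distance[b]
          arr[open_frames, tip_idx, 2L] <-
            arr[open_frames, tip_idx, 2L] - dy
        }
      }
    }
    traj <- new("Trajectory", topology = model, coords = arr,
                frameSpacing = spec@frameSpacing)
    attr(traj@coords, "bridgeStates") <- if (nrow(br))
      states[, seq_len(nrow(br)), drop = FALSE] else NULL
    traj
  })
}

#' Write a five-system toy glycoform suite
#'
#' Emits five toy systems sharing one complex geometry and bridge set,
#' differing only in pseudo-glycan occluder load -- none (the
#' deglycosylated analog), two then four sites of small (1-sphere)
#' glycans, and two then four sites of large (4-sphere) glycans -- with
#' the large 2-site analog additionally carrying an abrupt
#' conformational-shift event early in its run. Each system is written
#' as PDB structure, compact-frame trajectory, parameter file and spec
#' YAML, plus a ready-to-run pipeline `config.yaml`.
#'
#' @param outdir Writable output directory (created if absent).
#' @param nFrames,frameSpacing Trajectory length and spacing (ps);
#'   defaults give a 40-ns-equivalent run.
#' @param seed Base seed; system `k` uses `seed + k - 1`.
#' @return Invisibly, a list with `systems` (per-system label, spec and
#'   file paths) and `configPath`.
#' @export
toyGlycoformSuite <- function(outdir, nFrames = 400L, frameSpacing = 100,
                              seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sites2 <- c(6L, 14L)
  sites4 <- c(6L, 10L, 14L, 18L)
  defs <- list(
    dgFSH      = list(sites = integer(0), spheres = 0L, shift = FALSE),
    FSH15_NAG  = list(sites = sites2, spheres = 1L, shift = FALSE),
    FSH24_NAG  = list(sites = sites4, spheres = 1L, shift = FALSE),
    FSH15_TAG  = list(sites = sites2, spheres = 4L, shift = TRUE),
    FSH24_TAG  = list(sites = sites4, spheres = 4L, shift = FALSE))
  systems <- list()
  for (k in seq_along(defs)) {
    label <- names(defs)[k]
    d <- defs[[k]]
    occ <- if (length(d$sites))
      data.frame(site_res = d$sites, n_spheres = d$spheres)
    else data.frame(site_res = integer(0), n_spheres = integer(0))
    spec <- syntheticSpec(
      occluders = occ, nFrames = nFrames, frameSpacing = frameSpacing,
      shiftFrame = if (d$shift) as.integer(round(0.175 * nFrames)) else 0L,
      shiftResidues = if (d$shift) 1:3 else integer(0),
      shiftDisplacement = if (d$shift) c(0, 0, 3) else numeric(0),
      seed = seed + k - 1L)
    sys <- buildToyComplex(spec)
    traj <- sampleTrajectory(sys$model, spec)
    paths <- list(
      structure = file.path(outdir, paste0(label, ".pdb")),
      trajectory = file.path(outdir, paste0(label, ".traj")),
      parameters = file.path(outdir, paste0(label, ".ff")),
      spec = file.path(outdir, paste0(label, ".yaml")))
    writePDB(sys$model, paths$structure)
    writeFrames(traj, paths$trajectory, comment = label)
    writeForceField(sys$ff, sys$model, paths$parameters)
    writeSyntheticSpec(spec, paths$spec)
    systems[[label]] <- list(label = label, spec = spec, paths = paths)
  }
  config <- list(
    baseline = "dgFSH",
    seed = seed,
    thresholds = list(shift_A = 1.5, rmsf_diff_A = 0.5,
                      bridge_cutoff_A = 3.5, sasa_diff_A2 = 40,
                      contact_A = 4.5),
    window = list(skip_fraction = 0.125, stride = 1L),
    energy = list(gb_model = "HCT", snapshot_interval_ps = 1000,
                  sasa_points = 240L),
    frame_spacing_ps = frameSpacing,
    systems = lapply(systems, function(s) list(
      label = s$label, structure = s$paths$structure,
      trajectory = s$paths$trajectory, parameters = s$paths$parameters,
      chain_roles = list(A = "ligand_alpha", B = "receptor"))))
  configPath <- file.path(outdir, "config.yaml")
  yaml::write_yaml(config, configPath)
  invisible(list(systems = systems, configPath = configPath))
}

#' Write / read a SyntheticSpec as YAML
#'
#' @param spec A [SyntheticSpec-class].
#' @param path File path.
#' @return `path` invisibly ([writeSyntheticSpec()]); a
#'   [SyntheticSpec-class] ([readSyntheticSpec()]).
#' @export
writeSyntheticSpec <- function(spec, path) {
  yaml::write_yaml(list(
    n_res_ligand = spec@nResLigand, n_res_receptor = spec@nResReceptor,
    bridges = if (nrow(spec@bridges)) as.list(spec@bridges) else NULL,
    sigma_profile = spec@sigmaProfile, tip_sigma = spec@tipSigma,
    shift_frame = spec@shiftFrame,
    shift_residues = spec@shiftResidues,
    shift_displacement = spec@shiftDisplacement,
    occluders = if (nrow(spec@occluders)) as.list(spec@occluders)
                else NULL,
    bridge_persistence = spec@bridgePersistence,
    n_frames = spec@nFrames, frame_spacing = spec@frameSpacing,
    seed = spec@seed), path)
  invisible(path)
}

#' @rdname writeSyntheticSpec
#' @export
readSyntheticSpec <- function(path) {
  y <- yaml::read_yaml(path)
  as_df <- function(x, proto) {
    if (is.null(x)) return(proto)
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  syntheticSpec(
    nResLigand = y$n_res_ligand, nResReceptor = y$n_res_receptor,
    bridges = as_df(y$bridges,
                    defaultBridgeTable()[0, ]),
    sigmaProfile = y$sigma_profile, tipSigma = y$tip_sigma,
    shiftFrame = y$shift_frame,
    shiftResidues = if (is.null(y$shift_residues)) integer(0)
                    else y$shift_residues,
    shiftDisplacement = if (is.null(y$shift_displacement)) numeric(0)
                        else y$shift_displacement,
    occluders = as_df(y$occluders,
                      data.frame(site_res = integer(0),
                                 n_spheres = integer(0))),
    bridgePersistence = y$bridge_persistence,
    nFrames = y$n_frames, frameSpacing = y$frame_spacing, seed = y$seed)
}
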