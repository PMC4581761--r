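#' @include AllClasses.R AllGenerics.R sasa.R
NULL

#' Construct an MM-GBSA model configuration
#'
#' @param interiorDielectric Solute dielectric, default 1.0.
#' @param solventDielectric Solvent dielectric, default 80.0.
#' @param gamma Nonpolar surface coefficient, kcal/(mol A^2), default
#'   0.00542.
#' @param beta Nonpolar intercept, kcal/mol, default 0.92.
#' @param coulombConstant kcal A / (mol e^2), fixed convention 332.0636.
#' @param gbModel `"HCT"` or `"OBC2"`.
#' @param gbOffset Intrinsic-radius offset, Angstrom, default 0.09.
#' @param bornRadiusFloor Clamp for degenerate effective radii, Angstrom.
#' @param scaleEE14,scaleLJ14 1-4 nonbonded scaling factors (defaults
#'   1/1.2 and 1/2, the usual additive-force-field convention).
#' @param includeEntropy Must be `FALSE`: the protocol omits the
#'   conformational-entropy term, and requesting it is an error.
#' @return An [EnergyModelConfig-class].
#' @export
energyModelConfig <- function(interiorDielectric = 1.0,
                              solventDielectric = 80.0,
                              gamma = 0.00542, beta = 0.92,
                              coulombConstant = 332.0636,
                              gbModel = c("HCT", "OBC2"),
                              gbOffset = 0.09, bornRadiusFloor = 0.1,
                              scaleEE14 = 1 / 1.2, scaleLJ14 = 0.5,
                              includeEntropy = FALSE) {
  if (isTRUE(includeEntropy))
    stop("the conformational-entropy term is not part of this model; ",
         "includeEntropy must be FALSE", call. = FALSE)
  new("EnergyModelConfig", interiorDielectric = interiorDielectric,
      solventDielectric = solventDielectric, gamma = gamma, beta = beta,
      coulombConstant = coulombConstant, gbModel = match.arg(gbModel),
      gbOffset = gbOffset, bornRadiusFloor = bornRadiusFloor,
      scaleEE14 = scaleEE14, scaleLJ14 = scaleLJ14)
}

#' Construct an energy-component ledger
#'
#' @param internal,electrostatic,vdw,gbPolar,nonpolar Component
#'   energies, kcal/mol. `gbsol` and `gbtot` are derived so the ledger
#'   identities hold exactly.
#' @return An [EnergyComponents-class].
#' @export
energyComponents <- function(internal, electrostatic, vdw, gbPolar,
                             nonpolar) {
  gbsol <- gbPolar + nonpolar
  new("EnergyComponents", internal = internal,
      electrostatic = electrostatic, vdw = vdw, gbPolar = gbPolar,
      nonpolar = nonpolar, gbsol = gbsol,
      gbtot = internal + electrostatic + vdw + gbsol)
}

.dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("degenerate dihedral: three collinear atoms", call. = FALSE)
  m1 <- cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

#' Bonded (internal) molecular-mechanics energy
#'
#' `sum kb (r - r0)^2 + sum ka (theta - theta0)^2 +
#'  sum barrier (1 + cos(n phi - phase))`; harmonic constants carry the
#' full force constant (no 1/2 factor), the torsion term is the plain
#' cosine series. Angles use a guarded arccos; a dihedral with three
#' collinear atoms is an error.
#'
#' @param xyz `n x 3` coordinate matrix, Angstrom.
#' @param ff A [ForceFieldTable-class].
#' @return Energy in kcal/mol.
#' @export
bondedEnergy <- function(xyz, ff) {
  xyz <- as.matrix(xyz)
  e <- 0
  b <- ff@bonds
  if (nrow(b)) {
    r <- sqrt(rowSums((xyz[b$i, , drop = FALSE] -
                       xyz[b$j, , drop = FALSE])^2))
    e <- e + sum(b$kb * (r - b$r0)^2)
  }
  g <- ff@angles
  if (nrow(g)) {
    v1 <- xyz[g$i, , drop = FALSE] - xyz[g$j, , drop = FALSE]
    v2 <- xyz[g$k, , drop = FALSE] - xyz[g$j, , drop = FALSE]
    cosang <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    theta <- acos(pmin(1, pmax(-1, cosang)))
    e <- e + sum(g$ka * (theta - g$theta0)^2)
  }
  d <- ff@dihedrals
  if (nrow(d)) {
    for (t in seq_len(nrow(d))) {
      phi <- .dihedral_angle(xyz[d$i[t], ], xyz[d$j[t], ],
                             xyz[d$k[t], ], xyz[d$l[t], ])
      e <- e + d$barrier[t] * (1 + cos(d$periodicity[t] * phi -
                                       d$phase[t]))
    }
  }
  e
}

# pair classification from the bond graph: 1-2 and 1-3 excluded,
# 1-4 scaled. Returns n x n matrices of logical masks.
.pair_masks <- function(n, bonds) {
  A <- matrix(FALSE, n, n)
  if (nrow(bonds)) {
    A[cbind(bonds$i, bonds$j)] <- TRUE
    A[cbind(bonds$j, bonds$i)] <- TRUE
  }
  Ai <- A * 1
  A2 <- (Ai %*% Ai) > 0
  A3 <- (Ai %*% Ai %*% Ai) > 0
  diag(A2) <- diag(A3) <- FALSE
  excl <- A | (A2 & !A)
  one4 <- A3 & !excl
  list(excluded = excl, scaled14 = one4)
}

#' Gas-phase nonbonded energies (Coulomb and Lennard-Jones)
#'
#' No cutoff (gas phase). Pairs separated by one or two bonds are
#' excluded; 1-4 pairs are scaled by the configured factors.
#' Lennard-Jones uses 12-6 form with Lorentz-Berthelot combining, so a
#' pair at `r = 2^(1/6) sigma` sits at `-epsilon`.
#'
#' @param xyz `n x 3` coordinate matrix, Angstrom.
#' @param ff A [ForceFieldTable-class].
#' @param config An [EnergyModelConfig-class].
#' @return `c(electrostatic = ..., vdw = ...)` in kcal/mol.
#' @export
nonbondedEnergy <- function(xyz, ff, config = energyModelConfig()) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  p <- ff@atoms
  if (n != nrow(p)) stop("coordinate/parameter atom count mismatch",
                         call. = FALSE)
  if (n < 2L) return(c(electrostatic = 0, vdw = 0))
  sq <- rowSums(xyz^2)
  d2 <- outer(sq, sq, "+") - 2 * xyz %*% t(xyz)
  d2[d2 < 0] <- 0
  masks <- .pair_masks(n, ff@bonds)
  upper <- upper.tri(d2)
  use <- upper & !masks$excluded
  if (any(d2[use] == 0))
    stop("singularity: coincident atoms in a nonbonded pair",
         call. = FALSE)
  scale <- matrix(1, n, n)
  scale_lj <- matrix(1, n, n)
  scale[masks$scaled14] <- config@scaleEE14
  scale_lj[masks$scaled14] <- config@scaleLJ14
  r <- sqrt(d2)
  qq <- outer(p$charge, p$charge)
  ele <- config@coulombConstant * sum((qq * scale / r)[use])
  sig <- outer(p$lj_sigma, p$lj_sigma, "+") / 2
  eps <- sqrt(outer(p$lj_epsilon, p$lj_epsilon))
  sr6 <- (sig / r)^6
  vdw <- sum((4 * eps * (sr6^2 - sr6) * scale_lj)[use])
  c(electrostatic = ele, vdw = vdw)
}

#' Effective Born radii (HCT or OBC-II)
#'
#' Intrinsic radii are offset-reduced (`rho = gb_radius - gbOffset`) and
#' descreened with the standard pairwise integral using the per-atom
#' scale factors. Under `"HCT"` the inverse radius is `1/rho - I`; under
#' `"OBC2"` the descreening sum is rescaled through the
#' tanh(a psi - b psi^2 + c psi^3) form with a = 1.0, b = 0.8,
#' c = 4.85. A non-positive result is clamped to `bornRadiusFloor` with
#' a warning.
#'
#' @param xyz `n x 3` coordinate matrix, Angstrom.
#' @param ff A [ForceFieldTable-class].
#' @param config An [EnergyModelConfig-class].
#' @return Numeric vector of effective Born radii, Angstrom.
#' @export
effectiveBornRadii <- function(xyz, ff, config = energyModelConfig()) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  rho <- ff@atoms$gb_radius - config@gbOffset
  if (any(rho <= 0))
    stop("gb_radius must exceed the offset ", config@gbOffset,
         call. = FALSE)
  sr_all <- ff@atoms$gb_scale * rho
  I <- numeric(n)
  if (n > 1L) {
    sq <- rowSums(xyz^2)
    d <- sqrt(pmax(outer(sq, sq, "+") - 2 * xyz %*% t(xyz), 0))
    for (i in seq_len(n)) {
      r <- d[i, -i]
      sr <- sr_all[-i]
      ri <- rho[i]
      active <- ri < r + sr
      if (!any(active)) next
      r <- r[active]; sr <- sr[active]
      L <- pmax(ri, abs(r - sr))
      U <- r + sr
      term <- 1 / L - 1 / U + 0.25 * (1 / U^2 - 1 / L^2) *
        (r - sr^2 / r) + 0.5 * log(L / U) / r
      engulf <- ri < (sr - r)
      term[engulf] <- term[engulf] + 2 * (1 / ri - 1 / L[engulf])
      I[i] <- 0.5 * sum(term)
    }
  }
  inv <- if (config@gbModel == "HCT") {
    1 / rho - I
  } else {
    psi <- I * rho
    1 / rho - tanh(psi - 0.8 * psi^2 + 4.85 * psi^3) / ff@atoms$gb_radius
  }
  R <- 1 / inv
  bad <- !is.finite(R) | R <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive effective Born radius value(s) ",
            "clamped to the floor of ", config@bornRadiusFloor, " A")
    R[bad] <- config@bornRadiusFloor
  }
  R
}

#' Generalized-Born polar solvation energy
#'
#' Pairwise GB with
#' `f_GB = sqrt(r^2 + Ri Rj exp(-r^2 / (4 Ri Rj)))`, self terms
#' included (`f_GB = Ri` at `i = j`), and prefactor
#' `-1/2 ke (1/eps_in - 1/eps_out)`. In the single-ion limit this
#' reduces to the Born equation; for two distant ions it approaches the
#' sum of the isolated Born energies plus the dielectric-screened
#' Coulomb interaction.
#'
#' @param xyz `n x 3` coordinate matrix, Angstrom.
#' @param ff A [ForceFieldTable-class].
#' @param config An [EnergyModelConfig-class].
#' @return Energy in kcal/mol.
#' @export
gbPolarEnergy <- function(xyz, ff, config = energyModelConfig()) {
  xyz <- as.matrix(xyz)
  q <- ff@atoms$charge
  if (all(q == 0)) return(0)
  R <- effectiveBornRadii(xyz, ff, config)
  n <- nrow(xyz)
  sq <- rowSums(xyz^2)
  d2 <- pmax(outer(sq, sq, "+") - 2 * xyz %*% t(xyz), 0)
  RR <- outer(R, R)
  fgb <- sqrt(d2 + RR * exp(-d2 / (4 * RR)))
  pref <- -0.5 * config@coulombConstant *
    (1 / config@interiorDielectric - 1 / config@solventDielectric)
  pref * sum(outer(q, q) / fgb)
}

#' Nonpolar (surface-area) solvation energy
#'
#' `gamma * SASA + beta`, exactly linear in the total
#' solvent-accessible surface area.
#'
#' @param sasaTotal Total SASA, Angstrom^2 (>= 0).
#' @param config An [EnergyModelConfig-class].
#' @return Energy in kcal/mol.
#' @export
nonpolarEnergy <- function(sasaTotal, config = energyModelConfig()) {
  if (sasaTotal < 0) stop("SASA must be >= 0", call. = FALSE)
  config@gamma * sasaTotal + config@beta
}

# restrict model + parameters to an atom index subset; bonded terms not
# fully inside the subset are dropped (they vanish in binding
# differences anyway under the single-trajectory approximation)
.subset_system <- function(model, ff, indices) {
  indices <- sort(indices)
  map <- integer(nAtoms(model))
  map[indices] <- seq_along(indices)
  keep_bonded <- function(df, cols) {
    if (!nrow(df)) return(df)
    inside <- rowSums(matrix(map[as.matrix(df[cols])] == 0,
                             nrow = nrow(df))) == 0
    df <- df[inside, , drop = FALSE]
    for (cl in cols) df[[cl]] <- map[df[[cl]]]
    df
  }
  ff2 <- new("ForceFieldTable",
             atoms = ff@atoms[indices, , drop = FALSE],
             bonds = keep_bonded(ff@bonds, c("i", "j")),
             angles = keep_bonded(ff@angles, c("i", "j", "k")),
             dihedrals = keep_bonded(ff@dihedrals, c("i", "j", "k", "l")))
  m2 <- structureModel(model@atoms[indices, , drop = FALSE],
                       model@chainRoles)
  list(model = m2, ff = ff2)
}

# total molecular SASA (all heavy atoms) for the nonpolar term
.total_molecular_sasa <- function(atoms, xyz, radii, probe, nPoints) {
  heavy <- toupper(atoms$element) != "H"
  sub <- atoms[heavy, , drop = FALSE]
  sum(.sasa_atoms(xyz[heavy, , drop = FALSE], .atom_radii(sub, radii),
                  probe, nPoints))
}

#' Full MM-GBSA component ledger for one snapshot
#'
#' Composes the bonded, nonbonded, GB polar and SASA-nonpolar kernels
#' into an [EnergyComponents-class] whose ledger identities hold
#' exactly by construction.
#'
#' @param model A [StructureModel-class] (supplies elements for SASA).
#' @param ff The matching [ForceFieldTable-class].
#' @param config An [EnergyModelConfig-class].
#' @param selection Optional [Selection-class]; energies are computed
#'   for that subsystem only.
#' @param xyz Optional `n x 3` coordinates overriding the model's (full
#'   topology indexing; e.g. one trajectory frame).
#' @param radii,probe,nPoints SASA engine settings (see
#'   [sasaStructure()]).
#' @return An [EnergyComponents-class].
#' @export
snapshotEnergy <- function(model, ff, config = energyModelConfig(),
                           selection = NULL, xyz = NULL,
                           radii = defaultRadii(), probe = 1.4,
                           nPoints = 960L) {
  if (is.null(xyz)) xyz <- coords(model)
  if (!is.null(selection)) {
    sys <- .subset_system(model, ff, selection@indices)
    xyz <- xyz[selection@indices, , drop = FALSE]
    model <- sys$model
    ff <- sys$ff
  }
  internal <- bondedEnergy(xyz, ff)
  nb <- nonbondedEnergy(xyz, ff, config)
  gb <- gbPolarEnergy(xyz, ff, config)
  sasa <- .total_molecular_sasa(model@atoms, xyz, radii, probe, nPoints)
  np <- nonpolarEnergy(sasa, config)
  energyComponents(internal, nb[["electrostatic"]], nb[["vdw"]], gb, np)
}

.summarize_components <- function(mat, label) {
  # mat: nSnapshots x 7 matrix with .ENERGY_NAMES columns
  means <- colMeans(mat)
  # re-derive the ledger sums from the component means so the mean
  # identities hold exactly (they are linear; this only removes
  # floating-point summation-order noise)
  means[6L] <- means[4L] + means[5L]
  means[7L] <- means[1L] + means[2L] + means[3L] + means[6L]
  sds <- apply(mat, 2L, stats::sd)
  if (nrow(mat) == 1L) sds[] <- 0
  new("EnergySummary", means = stats::setNames(means, .ENERGY_NAMES),
      sds = stats::setNames(sds, .ENERGY_NAMES),
      nSnapshots = nrow(mat), label = label)
}

#' Snapshot-averaged MM-GBSA summary for a trajectory
#'
#' Snapshots are taken every `snapshotIntervalPs` of simulated time
#' (frames `s, 2s, ...` with `s = interval / frameSpacing`), following
#' the 1-ns-apart convention that yields 40 snapshots from a 40-ns run.
#' In `"absolute"` mode the whole system's component ledger is averaged.
#' In `"binding"` mode the single-trajectory approximation is used:
#' ligand (chain roles `ligand_*`) and receptor (role `receptor`)
#' coordinates are extracted from the complex frames and the summary of
#' `complex - receptor - ligand` is returned along with the three parts;
#' intra-molecular bonded terms cancel exactly in the difference.
#'
#' @param traj A [Trajectory-class] whose topology has chain roles.
#' @param ff The matching [ForceFieldTable-class].
#' @param config An [EnergyModelConfig-class].
#' @param snapshotIntervalPs Time between snapshots, ps (>= frame
#'   spacing).
#' @param mode `"absolute"` or `"binding"`.
#' @param label System name.
#' @param ... SASA engine settings passed to [snapshotEnergy()].
#' @return In absolute mode an [EnergySummary-class]; in binding mode a
#'   list with elements `complex`, `receptor`, `ligand`, `delta`.
#' @export
mmgbsaSummary <- function(traj, ff, config = energyModelConfig(),
                          snapshotIntervalPs = 1000,
                          mode = c("absolute", "binding"),
                          label = "system", ...) {
  mode <- match.arg(mode)
  sp <- frameSpacing(traj)
  if (snapshotIntervalPs < sp)
    stop("snapshot interval must be >= the frame spacing", call. = FALSE)
  step <- as.integer(round(snapshotIntervalPs / sp))
  frames <- seq(step, nFrames(traj), by = step)
  if (!length(frames)) stop("zero snapshots in trajectory", call. = FALSE)
  topo <- traj@topology
  if (mode == "absolute") {
    mat <- t(vapply(frames, function(f)
      energyVector(snapshotEnergy(topo, ff, config,
                                  xyz = frameCoords(traj, f), ...)),
      numeric(7L)))
    return(.summarize_components(mat, label))
  }
  roles <- topo@chainRoles
  lig_chains <- names(roles)[startsWith(roles, "ligand")]
  rec_chains <- names(roles)[roles == "receptor"]
  if (!length(lig_chains) || !length(rec_chains))
    stop("binding mode needs ligand_* and receptor chain roles",
         call. = FALSE)
  a <- topo@atoms
  sel_lig <- new("Selection", name = "ligand",
                 indices = which(a$chain %in% lig_chains))
  sel_rec <- new("Selection", name = "receptor",
                 indices = which(a$chain %in% rec_chains))
  comp <- rec <- lig <- matrix(0, length(frames), 7L)
  for (k in seq_along(frames)) {
    xyz <- frameCoords(traj, frames[k])
    comp[k, ] <- energyVector(snapshotEnergy(topo, ff, config,
                                             xyz = xyz, ...))
    rec[k, ] <- energyVector(snapshotEnergy(topo, ff, config,
                                            selection = sel_rec,
                                            xyz = xyz, ...))
    lig[k, ] <- energyVector(snapshotEnergy(topo, ff, config,
                                            selection = sel_lig,
                                            xyz = xyz, ...))
  }
  colnames(comp) <- colnames(rec) <- colnames(lig) <- .ENERGY_NAMES
  list(complex = .summarize_components(comp, paste0(label, ":complex")),
       receptor = .summarize_components(rec, paste0(label, ":receptor")),
       ligand = .summarize_components(lig, paste0(label, ":ligand")),
       delta = .summarize_components(comp - rec - lig,
                                     paste0(label, ":delta")))
}
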