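test_that("bonded terms reproduce hand arithmetic and cosine extrema", {
  # one bond stretched by 0.1 A with kb = 100 -> 1.0 kcal/mol
  xyz <- rbind(c(0, 0, 0), c(1.6, 0, 0))
  ff <- makeFF(c(0, 0), bonds = data.frame(i = 1L, j = 2L, kb = 100,
                                           r0 = 1.5))
  expect_equal(bondedEnergy(xyz, ff), 1.0, tolerance = 1e-12)
  # at r = r0 the contribution vanishes
  expect_equal(bondedEnergy(rbind(c(0, 0, 0), c(1.5, 0, 0)), ff), 0)

  # single dihedral, periodicity 1, phase 0: 0 at phi = pi, 2V at phi = 0
  dihed <- function(phi) {
    xyz <- rbind(c(1, 0, -1), c(0, 0, 0), c(0, 0, 1),
                 c(cos(phi), sin(phi), 2))
    ff <- makeFF(rep(0, 4),
                 dihedrals = data.frame(i = 1L, j = 2L, k = 3L, l = 4L,
                                        barrier = 3, periodicity = 1L,
                                        phase = 0))
    bondedEnergy(xyz, ff)
  }
  expect_equal(dihed(pi), 0, tolerance = 1e-9)
  expect_equal(dihed(0), 6, tolerance = 1e-9)

  # collinear dihedral triple errors
  bad <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2), c(1, 0, 3))
  ffb <- makeFF(rep(0, 4),
                dihedrals = data.frame(i = 1L, j = 2L, k = 3L, l = 4L,
                                       barrier = 1, periodicity = 1L,
                                       phase = 0))
  expect_error(bondedEnergy(bad, ffb), "degenerate dihedral")
})

test_that("nonbonded terms: Coulomb constant, LJ minimum, charge zeroing, singularity", {
  cfg <- energyModelConfig()
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0))
  ff <- makeFF(c(1, 1), lj_epsilon = 0)
  nb <- nonbondedEnergy(xyz, ff, cfg)
  expect_equal(nb[["electrostatic"]], 332.0636, tolerance = 1e-9)

  # LJ pair at its minimum sits at -epsilon
  sig <- 3.2; eps <- 0.25
  xyz2 <- rbind(c(0, 0, 0), c(2^(1 / 6) * sig, 0, 0))
  ff2 <- makeFF(c(0, 0), lj_sigma = sig, lj_epsilon = eps)
  expect_equal(nonbondedEnergy(xyz2, ff2, cfg)[["vdw"]], -eps,
               tolerance = 1e-12)

  # zeroing one charge kills electrostatics but not vdw
  ff3 <- makeFF(c(1, 0), lj_sigma = sig, lj_epsilon = eps)
  nb3 <- nonbondedEnergy(xyz2, ff3, cfg)
  expect_equal(nb3[["electrostatic"]], 0)
  expect_equal(nb3[["vdw"]], -eps, tolerance = 1e-12)

  expect_error(nonbondedEnergy(rbind(c(0, 0, 0), c(0, 0, 0)), ff, cfg),
               "singularity")
})

test_that("exclusions drop 1-2/1-3 pairs and scale 1-4 pairs", {
  # linear 4-atom chain with unit charges
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(3.0, 0, 0), c(4.5, 0, 0))
  bonds <- data.frame(i = 1:3, j = 2:4, kb = 0, r0 = 1.5)
  ff <- makeFF(rep(1, 4), lj_epsilon = 0, bonds = bonds)
  cfg <- energyModelConfig()
  # only the single 1-4 pair (atoms 1-4, r = 4.5) survives, scaled
  expect_equal(nonbondedEnergy(xyz, ff, cfg)[["electrostatic"]],
               cfg@scaleEE14 * 332.0636 / 4.5, tolerance = 1e-9)
})

test_that("GB energy: Born single-ion limit, zero charges, distant-ion separability", {
  cfg <- energyModelConfig()
  # effective Born radius 2.0 A after the 0.09 A offset
  ff1 <- makeFF(1, gb_radius = 2.0 + cfg@gbOffset)
  born <- -(332.0636 / 2) * (1 - 1 / 80) / 2.0
  expect_equal(gbPolarEnergy(matrix(0, 1, 3), ff1, cfg), born,
               tolerance = 1e-3 * abs(born))

  expect_equal(gbPolarEnergy(matrix(rnorm(9), 3, 3), makeFF(rep(0, 3)),
                             cfg), 0)

  # two ions 400 A apart: energies separate to within 0.1%
  ff2 <- makeFF(c(1, -1), gb_radius = 2.0 + cfg@gbOffset)
  xyz2 <- rbind(c(0, 0, 0), c(400, 0, 0))
  e2 <- gbPolarEnergy(xyz2, ff2, cfg)
  screened <- -332.0636 * (1 - 1 / 80) * (1 * -1) / 400
  expect_equal(e2, 2 * born + screened, tolerance = 1e-3)
})

test_that("GB energy is rigid-motion invariant and monotone in solvent dielectric", {
  sys <- buildToyComplex(syntheticSpec(nFrames = 2L))
  xyz <- coords(sys$model)
  cfg <- energyModelConfig()
  e0 <- gbPolarEnergy(xyz, sys$ff, cfg)
  moved <- xyz %*% t(randomRotation(4)) + 7
  expect_equal(gbPolarEnergy(moved, sys$ff, cfg), e0, tolerance = 1e-8)

  es <- vapply(c(2, 10, 80), function(eo)
    gbPolarEnergy(xyz, sys$ff, energyModelConfig(solventDielectric = eo)),
    numeric(1))
  expect_true(all(diff(es) < 0))

  # OBC2 variant runs and is also negative for this charged system
  expect_lt(gbPolarEnergy(xyz, sys$ff,
                          energyModelConfig(gbModel = "OBC2")), 0)
})

test_that("nonpolar term is exactly linear with intercept beta", {
  expect_equal(nonpolarEnergy(0), 0.92)
  expect_equal(nonpolarEnergy(1000), 6.34, tolerance = 1e-12)
  set.seed(3)
  for (s in runif(5, 0, 5000))
    expect_equal(nonpolarEnergy(2 * s) - 0.92,
                 2 * (nonpolarEnergy(s) - 0.92), tolerance = 1e-9)
  expect_error(nonpolarEnergy(-1), "SASA")
})

test_that("entropy is rejected by the model configuration", {
  expect_error(energyModelConfig(includeEntropy = TRUE), "entropy")
})

test_that("snapshot ledger composes the kernels and matches the naive O(n^2) oracle", {
  sys <- buildToyComplex(syntheticSpec(
    nResLigand = 8L, nResReceptor = 8L, sigmaProfile = rep(0.4, 16),
    bridges = data.frame(ligand_res = 4L, receptor_res = 4L,
                         occupancy = 1, closed_distance = 2.8,
                         open_distance = 6.0, cation = "LYS",
                         anion = "ASP", stringsAsFactors = FALSE),
    nFrames = 2L))
  expect_lte(nAtoms(sys$model), 100L)
  cfg <- energyModelConfig()
  xyz <- coords(sys$model)
  ec <- snapshotEnergy(sys$model, sys$ff, cfg, nPoints = 240L)
  v <- energyVector(ec)
  # ledger identities hold exactly
  expect_equal(v[["gbsol"]], v[["gb_polar"]] + v[["nonpolar"]],
               tolerance = 1e-12)
  expect_equal(v[["gbtot"]], sum(v[c("internal", "electrostatic", "vdw",
                                     "gbsol")]), tolerance = 1e-12)
  # composition equals independent kernel calls
  nb <- nonbondedEnergy(xyz, sys$ff, cfg)
  expect_identical(v[["internal"]], bondedEnergy(xyz, sys$ff))
  expect_identical(v[["electrostatic"]], nb[["electrostatic"]])
  expect_identical(v[["vdw"]], nb[["vdw"]])
  expect_identical(v[["gb_polar"]], gbPolarEnergy(xyz, sys$ff, cfg))
  # naive loop oracle agreement to 1e-10
  nv <- naiveNonbonded(xyz, sys$ff, cfg)
  expect_equal(v[["electrostatic"]], nv[["electrostatic"]],
               tolerance = 1e-10)
  expect_equal(v[["vdw"]], nv[["vdw"]], tolerance = 1e-10)
  expect_equal(v[["internal"]], naiveBonded(xyz, sys$ff),
               tolerance = 1e-10)
})

test_that("all-zero charges with gamma = beta = 0 reduce the total to internal + vdw", {
  sys <- buildToyComplex(syntheticSpec(nFrames = 2L, nResLigand = 6L,
                                       nResReceptor = 6L,
                                       sigmaProfile = rep(0.4, 12),
                                       bridges = defaultBridgeTable()[0, ]))
  ff0 <- sys$ff
  ff0@atoms$charge <- 0
  cfg0 <- energyModelConfig(gamma = 0, beta = 0)
  v <- energyVector(snapshotEnergy(sys$model, ff0, cfg0, nPoints = 96L))
  expect_equal(v[["gbtot"]], v[["internal"]] + v[["vdw"]],
               tolerance = 1e-12)
  expect_equal(v[["electrostatic"]], 0)
  expect_equal(v[["gb_polar"]], 0)
})

test_that("snapshot protocol counts and binding-mode cancellations behave", {
  spec <- syntheticSpec(nResLigand = 6L, nResReceptor = 6L,
                        sigmaProfile = rep(0.3, 12),
                        bridges = defaultBridgeTable()[0, ],
                        nFrames = 80L, frameSpacing = 100, seed = 12L)
  sys <- buildToyComplex(spec)
  tr <- sampleTrajectory(sys$model, spec)
  cfg <- energyModelConfig()
  # 80 frames x 100 ps = 8 ns; 1-ns snapshots -> 8
  es <- mmgbsaSummary(tr, sys$ff, cfg, snapshotIntervalPs = 1000,
                      nPoints = 96L)
  expect_equal(es@nSnapshots, 8L)
  expect_error(mmgbsaSummary(tr, sys$ff, cfg, snapshotIntervalPs = 10),
               "frame spacing")

  # static trajectory: all component sds are exactly zero
  tr0 <- trajectory(sys$model,
                    replicate(4, coords(sys$model), simplify = FALSE),
                    500)
  es0 <- mmgbsaSummary(tr0, sys$ff, cfg, snapshotIntervalPs = 500,
                       nPoints = 96L)
  expect_equal(unname(es0@sds), rep(0, 7))

  # binding mode with well-separated, uncharged chains: delta internal
  # is exactly zero and delta vdw vanishes
  a <- atomData(sys$model)
  a$y[a$chain == "B"] <- a$y[a$chain == "B"] + 99
  far <- structureModel(a, chainRoles(sys$model))
  ff0 <- sys$ff
  ff0@atoms$charge <- 0
  trf <- trajectory(far, replicate(2, coords(far), simplify = FALSE),
                    1000)
  bs <- mmgbsaSummary(trf, ff0, cfg, snapshotIntervalPs = 1000,
                      mode = "binding", nPoints = 96L)
  expect_equal(bs$delta@means[["internal"]], 0, tolerance = 1e-12)
  expect_equal(bs$delta@means[["vdw"]], 0, tolerance = 1e-4)
  expect_equal(bs$delta@means[["electrostatic"]], 0, tolerance = 1e-12)
})
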