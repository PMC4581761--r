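test_that("planted bridges are found exactly; far or like-charged pairs are not", {
  spec <- syntheticSpec(nFrames = 2L)
  m <- buildToyComplex(spec)$model
  br <- findSaltBridges(m)
  expect_equal(nrow(br), 4L)
  expect_equal(br$cation_resseq, c(4L, 8L, 12L, 16L))
  expect_equal(br$cation_resname, c("LYS", "LYS", "ARG", "LYS"))
  expect_equal(br$anion_resname, c("ASP", "ASP", "GLU", "ASP"))
  expect_equal(br$min_distance_A, rep(2.8, 4), tolerance = 1e-9)

  # zero planted bridges -> empty with a warning (no charged residues)
  m0 <- buildToyComplex(syntheticSpec(
    nFrames = 2L, bridges = defaultBridgeTable()[0, ]))$model
  expect_warning(br0 <- findSaltBridges(m0), "no charged residues")
  expect_equal(nrow(br0), 0L)

  # chains pulled 30 A apart: nothing within the seed cutoff
  a <- atomData(m)
  a$y[a$chain == "B"] <- a$y[a$chain == "B"] + 30
  expect_equal(nrow(findSaltBridges(structureModel(
    a, chainRoles(m)))), 0L)
})

test_that("cation-cation appositions are never reported", {
  # receptor-side LYS directly across from a ligand LYS
  spec <- syntheticSpec(nFrames = 2L)
  m <- buildToyComplex(spec)$model
  a <- atomData(m)
  # mutate the receptor-side bridge partners into lysines carrying NZ
  a$resname[a$chain == "B" & a$resname %in% c("ASP", "GLU")] <- "LYS"
  a$name[a$name %in% c("OD1", "OE1")] <- "NZ"
  a <- a[!a$name %in% c("OD2", "OE2"), ]
  a$serial <- seq_len(nrow(a))
  m2 <- structureModel(a, chainRoles(m))
  br <- findSaltBridges(m2)   # cations face cations: nothing to report
  expect_equal(nrow(br), 0L)
})

test_that("distance series uses the minimum rule and the requested stride", {
  spec <- syntheticSpec(nFrames = 100L, seed = 6L, sigmaProfile = rep(0, 40),
                        tipSigma = 0,
                        bridges = within(defaultBridgeTable(),
                                         occupancy <- 1))
  sys <- buildToyComplex(spec)
  tr <- sampleTrajectory(sys$model, spec)
  br <- findSaltBridges(sys$model)
  ser <- bridgeDistanceSeries(tr, br[1, ], stride = 10L)
  expect_length(ser, 10L)
  expect_equal(ser, rep(2.8, 10), tolerance = 1e-9)

  # Arg bridge: several N-O pairs, minimum taken
  ser_arg <- bridgeDistanceSeries(tr, br[br$cation_resname == "ARG", ],
                                  stride = 50L)
  expect_equal(ser_arg, rep(2.8, 2), tolerance = 1e-9)

  # missing side-chain atom in topology
  bad <- br[1, ]
  bad$cation_atoms <- "NZ,NXX"
  expect_error(bridgeDistanceSeries(tr, bad), "missing from topology")
  expect_error(bridgeDistanceSeries(tr, br[1, ], stride = 0L),
               "stride")
})

test_that("bridge statistics: median convention, strict cutoff, occupancy bounds", {
  st <- bridgeStatistics(rep(2.8, 50))
  expect_equal(st$median_A, 2.8)
  expect_equal(st$occupancy_pct, 100.0)

  alt <- rep(c(3.0, 4.0), 500)
  st2 <- bridgeStatistics(alt)
  expect_equal(st2$median_A, 3.5)
  expect_equal(st2$occupancy_pct, 50.0)
  expect_equal(st2$n_samples, 1000L)

  # a sample exactly at the cutoff does not count as closed
  expect_equal(bridgeStatistics(c(3.5, 3.5))$occupancy, 0)

  expect_error(bridgeStatistics(numeric(0)), "empty")

  # occupancy non-increasing as the cutoff shrinks; median invariant
  set.seed(1)
  ser <- runif(400, 2, 5)
  occs <- vapply(c(4.5, 3.5, 2.5), function(cf)
    bridgeStatistics(ser, cutoff = cf)$occupancy, numeric(1))
  expect_true(all(diff(occs) <= 0))
  meds <- vapply(c(4.5, 3.5, 2.5), function(cf)
    bridgeStatistics(ser, cutoff = cf)$median_A, numeric(1))
  expect_equal(meds, rep(meds[1], 3))
})

test_that("two-state sampling recovers the planted stationary occupancy", {
  spec <- syntheticSpec(nResLigand = 10L, nResReceptor = 10L,
                        sigmaProfile = rep(0.5, 20),
                        nFrames = 20000L, seed = 99L,
                        bridges = data.frame(
                          ligand_res = 8L, receptor_res = 8L,
                          occupancy = 0.62, closed_distance = 2.8,
                          open_distance = 6.0, cation = "LYS",
                          anion = "ASP", stringsAsFactors = FALSE))
  sys <- buildToyComplex(spec)
  tr <- sampleTrajectory(sys$model, spec)
  br <- findSaltBridges(sys$model)
  ser <- bridgeDistanceSeries(tr, br[1, ], stride = 1L)
  st <- bridgeStatistics(ser)
  # 99% binomial interval at n = 20000, p = 0.62 is +/- 0.88 pct points
  expect_lt(abs(st$occupancy_pct - 62.0), 1.5)
  # measured states equal the generator's realized states
  states <- attr(tr@coords, "bridgeStates")[, 1]
  expect_equal(mean(ser < 3.5), mean(states), tolerance = 1e-3)
})

test_that("persistent two-state chains converge to the stationary fraction with chain length", {
  errs <- vapply(c(500L, 4000L, 20000L), function(nf) {
    spec <- syntheticSpec(nResLigand = 10L, nResReceptor = 10L,
                          sigmaProfile = rep(0.5, 20),
                          nFrames = nf, seed = 123L,
                          bridgePersistence = 0.5,
                          bridges = data.frame(
                            ligand_res = 4L, receptor_res = 4L,
                            occupancy = 0.75, closed_distance = 2.8,
                            open_distance = 6.0, cation = "LYS",
                            anion = "ASP", stringsAsFactors = FALSE))
    sys <- buildToyComplex(spec)
    tr <- sampleTrajectory(sys$model, spec)
    br <- findSaltBridges(sys$model)
    st <- bridgeStatistics(bridgeDistanceSeries(tr, br[1, ]))
    abs(st$occupancy - 0.75)
  }, numeric(1))
  expect_lt(errs[3], 0.02)
  expect_lt(errs[3], errs[1] + 0.02)
})

test_that("default stride mirrors the 2-ps sampling convention", {
  m <- makeModel(diag(3))
  expect_equal(defaultBridgeStride(trajectory(
    m, list(coords(m)), spacingPs = 0.5)), 4L)
  expect_equal(defaultBridgeStride(trajectory(
    m, list(coords(m)), spacingPs = 100)), 1L)
})
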