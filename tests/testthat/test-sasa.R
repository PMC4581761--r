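test_that("single sphere matches the analytic area and the point count controls the error", {
  m <- makeModel(matrix(0, 1, 3))
  analytic <- 4 * pi * (1.70 + 1.4)^2
  got <- totalSasa(sasaStructure(m, nPoints = 960L))
  expect_equal(got, analytic, tolerance = 0.01)

  # two identical atoms 50 A apart: exact additivity
  m2 <- makeModel(rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_equal(totalSasa(sasaStructure(m2)), 2 * got, tolerance = 1e-9)

  # two touching spheres: still decreasing error vs the analytic
  # two-sphere union area (spherical-cap closed form)
  d <- 2.5
  re <- 1.70 + 1.4
  cap <- 2 * pi * re * (re - d / 2)      # buried cap area per sphere
  union_area <- 2 * (4 * pi * re^2 - cap)
  m3 <- makeModel(rbind(c(0, 0, 0), c(d, 0, 0)))
  errs2 <- vapply(c(96L, 960L, 9600L), function(np)
    abs(totalSasa(sasaStructure(m3, nPoints = np)) - union_area),
    numeric(1))
  expect_true(all(diff(errs2) < 0))
  expect_lt(errs2[2] / union_area, 0.01)
})

test_that("a caged atom has zero accessible area and occlusion is monotone", {
  # carbon at origin surrounded by an octahedral cage of tight neighbors
  cage <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0), c(0, -2, 0),
                c(0, 0, 2), c(0, 0, -2),
                c(1.2, 1.2, 1.2), c(-1.2, 1.2, 1.2), c(1.2, -1.2, 1.2),
                c(1.2, 1.2, -1.2), c(-1.2, -1.2, 1.2),
                c(-1.2, 1.2, -1.2), c(1.2, -1.2, -1.2),
                c(-1.2, -1.2, -1.2))
  m <- makeModel(rbind(c(0, 0, 0), cage))
  prof <- sasaStructure(m)
  expect_equal(prof@sasa[1], 0, tolerance = 1e-9)

  # adding neighbors never increases a given atom's SASA
  area_of_first <- function(nbr) {
    mm <- makeModel(rbind(c(0, 0, 0), nbr))
    sasaStructure(mm)@sasa[1]
  }
  areas <- vapply(list(cage[1, , drop = FALSE], cage[1:3, ],
                       cage[1:6, ], cage),
                  area_of_first, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("SASA is invariant under rigid motions", {
  # globular fixture: 40 atoms in an 8 A ball
  set.seed(20)
  blob <- matrix(rnorm(120, sd = 4), 40, 3)
  m <- makeModel(blob)
  base <- sasaStructure(m)@sasa
  for (s in 1:3) {
    xyz <- blob %*% t(randomRotation(s)) +
      matrix(rep(c(3 * s, -s, s), each = 40), ncol = 3)
    m2 <- m
    coords(m2) <- xyz
    moved <- sasaStructure(m2)@sasa
    expect_equal(sum(moved), sum(base), tolerance = 5e-3)
    expect_equal(moved, base, tolerance = 0.03)
  }
  # the planar toy complex is the worst case for a fixed point set;
  # totals still agree at the 2% level
  tm <- buildToyComplex(syntheticSpec(nFrames = 2L))$model
  tb <- totalSasa(sasaStructure(tm))
  tmr <- tm
  coords(tmr) <- coords(tm) %*% t(randomRotation(7)) + 5
  expect_equal(totalSasa(sasaStructure(tmr)), tb, tolerance = 0.02)
})

test_that("SASA agrees with an independent Shrake-Rupley implementation", {
  # 50-atom fixture; reference total computed once with the biotite
  # structure library (probe 1.4 A, identical element radii, 1000
  # points): 1122.268 A^2
  m <- buildToyComplex(syntheticSpec(nFrames = 2L))$model
  a <- atomData(m)[1:50, ]
  a$x <- round(a$x, 3); a$y <- round(a$y, 3); a$z <- round(a$z, 3)
  fix <- structureModel(a)
  expect_equal(totalSasa(sasaStructure(fix)), 1122.268,
               tolerance = 0.02)
})

test_that("missing element radius is a named error", {
  m <- makeModel(matrix(0, 1, 3), element = "ZZ")
  expect_error(sasaStructure(m), "no radius for element.*ZZ")
})

test_that("trajectory SASA windows and averages correctly", {
  m <- buildToyComplex(syntheticSpec(nFrames = 2L))$model
  xyz <- coords(m)
  static <- trajectory(m, list(xyz, xyz, xyz), 100)
  expect_equal(sasaTrajectory(static, skipFraction = 0)@sasa,
               sasaStructure(m)@sasa, tolerance = 1e-9)
  expect_error(sasaTrajectory(static, skipFraction = 1), "skipFraction")

  # skip 0.5 on 10 frames averages frames 6..10 only: plant a
  # distinguishable first half
  shifted <- xyz                         # pull the chains apart:
  bsel <- atomData(m)$chain == "B"       # more exposed interface
  shifted[bsel, 2] <- shifted[bsel, 2] + 100
  frames <- c(replicate(5, shifted, simplify = FALSE),
              replicate(5, xyz, simplify = FALSE))
  tr <- trajectory(m, frames, 100)
  expect_equal(sasaTrajectory(tr, skipFraction = 0.5)@sasa,
               sasaStructure(m)@sasa, tolerance = 1e-9)

  # duty-cycle average: 40% open frames, 60% closed
  frames2 <- c(replicate(4, shifted, simplify = FALSE),
               replicate(6, xyz, simplify = FALSE))
  tr2 <- trajectory(m, frames2, 100)
  open_prof <- local({m2 <- m; coords(m2) <- shifted
                      sasaStructure(m2)@sasa})
  expect_equal(sasaTrajectory(tr2, skipFraction = 0)@sasa,
               0.4 * open_prof + 0.6 * sasaStructure(m)@sasa,
               tolerance = 1e-9)
})

test_that("glycan occlusion highlights exactly the planted residues; boundary is strict", {
  base <- sasaStructure(buildToyComplex(syntheticSpec(nFrames = 2L))$model)
  occl <- sasaStructure(buildToyComplex(syntheticSpec(
    nFrames = 2L,
    occluders = data.frame(site_res = c(6L, 14L),
                           n_spheres = 4L)))$model)
  d <- sasaDifference(occl, base)
  expect_equal(d$resseq[d$highlighted], c(6L, 14L))
  expect_true(all(d$delta_A2[d$highlighted] < -40))

  # identity: all deltas zero
  d0 <- sasaDifference(base, base)
  expect_equal(d0$delta_A2, rep(0, 40))

  # a delta of exactly the cutoff is not highlighted
  resd <- data.frame(chain = "A", resseq = 1:2, icode = "")
  lo <- new("SasaProfile", residues = resd, sasa = c(100, 60),
            label = "lo")
  hi <- new("SasaProfile", residues = resd, sasa = c(140, 100),
            label = "hi")
  expect_false(any(sasaDifference(hi, lo)$highlighted))
  hi2 <- new("SasaProfile", residues = resd, sasa = c(140.5, 100),
             label = "hi2")
  expect_equal(sum(sasaDifference(hi2, lo)$highlighted), 1L)
})
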