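test_that("Kabsch removes exact rigid motions and rejects degenerate input", {
  set.seed(11)
  ref <- matrix(rnorm(12), 4, 3)
  fit0 <- kabschSuperpose(ref, ref)
  expect_equal(fit0@rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0@rotation, diag(3), tolerance = 1e-9)

  fit1 <- kabschSuperpose(ref + rep(c(5, 0, 0), each = 4), ref)
  expect_equal(fit1@rmsd, 0, tolerance = 1e-10)
  expect_equal(fit1@translation, c(-5, 0, 0), tolerance = 1e-9)

  expect_error(kabschSuperpose(ref[1:2, ], ref[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabschSuperpose(line, line), "degenerate|rank")
})

test_that("Kabsch matches a brute-force 1-degree rotation grid for z-axis motion", {
  set.seed(37)
  ref <- matrix(rnorm(18), 6, 3)
  th <- 37 * pi / 180
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  mobile <- ref %*% t(Rz) + matrix(rnorm(18, sd = 0.1), 6, 3)
  kab <- kabschSuperpose(mobile, ref)@rmsd
  grid <- gridRotationRmsd(mobile, ref)
  expect_lte(kab, grid + 1e-12)        # optimum can only improve on the grid
  expect_lt(abs(kab - grid) / grid, 0.10)
})

test_that("Kabsch optimum beats 1000 random proper rotations and is symmetric", {
  set.seed(5)
  a <- matrix(rnorm(24), 8, 3)
  b <- a %*% t(randomRotation(17)) + matrix(rnorm(24, sd = 0.3), 8, 3)
  best <- kabschSuperpose(a, b)@rmsd
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  for (s in 1:1000) {
    r <- sqrt(mean(rowSums((ac %*% t(randomRotation(s + 1000)) - bc)^2)))
    expect_gte(r, best - 1e-9)
  }
  expect_equal(kabschSuperpose(b, a)@rmsd, best, tolerance = 1e-9)
})

test_that("weighted Kabsch equals the direct centered-rotated RMSD", {
  set.seed(2)
  a <- matrix(rnorm(21), 7, 3)
  b <- matrix(rnorm(21), 7, 3)
  w <- runif(7)
  fit <- kabschSuperpose(a, b, weights = w)
  wn <- w / sum(w)
  ac <- sweep(a, 2, colSums(a * wn))
  bc <- sweep(b, 2, colSums(b * wn))
  direct <- sqrt(sum(wn * rowSums((ac %*% t(fit@rotation) - bc)^2)))
  expect_equal(fit@rmsd, direct, tolerance = 1e-10)
})

test_that("Kabsch agrees with bio3d least-squares fitting", {
  skip_if_not_installed("bio3d")
  set.seed(9)
  a <- matrix(rnorm(30), 10, 3)
  b <- a %*% t(randomRotation(3)) + matrix(rnorm(30, sd = 0.2), 10, 3)
  ours <- kabschSuperpose(a, b)@rmsd
  inds <- bio3d::atom2xyz(1:10)
  fitted <- bio3d::fit.xyz(fixed = as.numeric(t(b)),
                           mobile = as.numeric(t(a)),
                           fixed.inds = inds, mobile.inds = inds)
  theirs <- sqrt(mean(rowSums(
    (matrix(fitted, ncol = 3, byrow = TRUE) - b)^2)))
  expect_equal(ours, theirs, tolerance = 1e-6)
})

test_that("RMSD series is zero for static or rigidly rotated frames", {
  m <- buildToyComplex(syntheticSpec(nFrames = 2L))$model
  sel <- makeSelection(m, "backbone")
  xyz <- coords(m)
  frames <- list(xyz, xyz %*% t(randomRotation(1)) + 3,
                 xyz %*% t(randomRotation(2)) - 1)
  tr <- trajectory(m, frames, 100)
  rs <- rmsdSeries(tr, sel)
  expect_equal(rs@values, rep(0, 3), tolerance = 1e-9)
  expect_equal(rs@times, c(100, 200, 300))
})

test_that("a planted step displacement produces a sustained RMSD increase at the event frame", {
  spec <- syntheticSpec(nFrames = 120L, seed = 21L, shiftFrame = 40L,
                        shiftResidues = 1:3,
                        shiftDisplacement = c(0, 0, 3))
  sys <- buildToyComplex(spec)
  tr <- sampleTrajectory(sys$model, spec)
  sel <- makeSelection(sys$model, "backbone and chain A")
  rs <- rmsdSeries(tr, sel, reference = sys$model)
  pre <- mean(rs@values[1:39])
  post <- mean(rs@values[40:120])
  expect_gt(post, pre + 0.3)
  expect_lte(abs(detectShiftFrame(rs) - 40L), 2L)
})

test_that("residue shift classification flags exactly the displaced residues", {
  spec <- syntheticSpec(nFrames = 60L, seed = 13L, shiftFrame = 1L,
                        shiftResidues = 10:12,
                        shiftDisplacement = c(0, 0, 3))
  sys <- buildToyComplex(spec)
  tr <- sampleTrajectory(sys$model, spec)
  sel <- makeSelection(sys$model, "backbone and chain A")
  part <- makeSelection(sys$model, "heavy and chain B")
  cls <- classifyResidueShifts(tr, sys$model, sel, part)
  expect_equal(cls$resseq[cls$is_shifted], 10:12)
  # interface residues are the planted bridge ligand residues
  expect_equal(sort(cls$resseq[cls$is_interface]), c(4L, 8L, 12L, 16L))
  expect_true(all(cls$class[cls$resseq == 12] == "contact+shifted"))
  expect_true(all(cls$class[cls$resseq == 4] == "contact"))
  expect_true(all(cls$class[cls$resseq == 10] == "shifted"))

  # static trajectory: nothing shifted
  tr0 <- trajectory(sys$model, list(coords(sys$model), coords(sys$model),
                                    coords(sys$model)), 100)
  cls0 <- classifyResidueShifts(tr0, sys$model, sel, part)
  expect_false(any(cls0$is_shifted))
  expect_error(classifyResidueShifts(tr0, sys$model, sel, part,
                                     shiftThreshold = 0),
               "shiftThreshold")
})

test_that("no interface residues when chains are far apart; shifted fraction monotone in threshold", {
  m <- buildToyComplex(syntheticSpec(nFrames = 2L,
                                     bridges = defaultBridgeTable()[0, ]))$model
  a <- atomData(m)
  a[a$chain == "B", c("y")] <- a$y[a$chain == "B"] + 30
  far <- structureModel(a, chainRoles(m))
  sel <- makeSelection(far, "backbone and chain A")
  part <- makeSelection(far, "heavy and chain B")
  tr <- trajectory(far, list(coords(far), coords(far)), 100)
  cls <- classifyResidueShifts(tr, far, sel, part)
  expect_false(any(cls$is_interface))

  spec <- syntheticSpec(nFrames = 40L, seed = 31L)
  sys <- buildToyComplex(spec)
  tr2 <- sampleTrajectory(sys$model, spec)
  sel2 <- makeSelection(sys$model, "backbone and chain A")
  part2 <- makeSelection(sys$model, "heavy and chain B")
  fracs <- vapply(c(0.2, 0.5, 1.0, 1.5), function(th)
    mean(classifyResidueShifts(tr2, sys$model, sel2, part2,
                               shiftThreshold = th)$is_shifted),
    numeric(1))
  expect_true(all(diff(fracs) <= 1e-12))
})
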