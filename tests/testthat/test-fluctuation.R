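test_that("rmsf-to-B conversion matches the displacement relation", {
  # independent evaluation of the constant: pi^2 = 9.8696044, x8/3 = 26.31894507
  expect_equal(rmsfToBfactor(1.0), 26.31894507, tolerance = 1e-8)
  expect_equal(rmsfToBfactor(0), 0)
  expect_equal(rmsfToBfactor(0.5), 6.57973627, tolerance = 1e-7)
  expect_error(rmsfToBfactor(-0.1), "domain error")
  # strictly increasing on a grid
  grid <- seq(0, 5, length.out = 1000)
  expect_true(all(diff(rmsfToBfactor(grid)) > 0))
})

test_that("identical frames give zero rmsf and two displaced frames give the midpoint deviation", {
  h <- makeIdealHelix(8)
  still <- CoarseEnsemble(rep(list(h), 10))
  pr <- computeRMSF(still, windowFraction = 1, superpose = FALSE)
  expect_equal(max(rmsfValues(pr)), 0)

  # residue 4 moves 2 A between the two frames: each frame is 1 A from the
  # mean, so rmsf = 1 exactly; all other residues stay at 0
  ca2 <- caCoords(h); ca2[4, 1] <- ca2[4, 1] + 2
  h2 <- CoarseModel(resno = residueIndices(h), resid = residueNames(h),
                    ca = ca2, cb = cbCoords(h), o = oCoords(h))
  pr2 <- computeRMSF(CoarseEnsemble(list(h, h2)), windowFraction = 1,
                     superpose = FALSE)
  r <- unname(rmsfValues(pr2))
  expect_equal(r[4], 1.0, tolerance = 1e-12)
  expect_equal(r[-4], rep(0, 7))
  expect_equal(unname(bfactorValues(pr2)[4]), 8 * pi^2 / 3, tolerance = 1e-9)
})

test_that("rmsf recovers the planted noise amplitude (sqrt(3) sigma)", {
  n <- 10
  sigma <- seq(0.2, 2.0, length.out = n)
  spec <- fixtureSpec(n, sigma, nFrames = 2000, seed = 42)
  ens <- perturbEnsemble(makeIdealHelix(n), spec)
  pr <- computeRMSF(ens, windowFraction = 1, superpose = FALSE)
  ratio <- unname(rmsfValues(pr)) / (sqrt(3) * sigma)
  expect_true(all(abs(ratio - 1) < 0.05))
})

test_that("superposition removes pure rigid-body motion", {
  spec <- fixtureSpec(12, 0, nFrames = 40, seed = 9)
  ens <- perturbEnsemble(makeIdealHelix(12), spec, rigidMotions = TRUE)
  pr <- computeRMSF(ens, windowFraction = 1, superpose = TRUE)
  expect_lt(max(rmsfValues(pr)), 0.05)
  # without superposition the same ensemble looks hugely flexible
  raw <- computeRMSF(ens, windowFraction = 1, superpose = FALSE)
  expect_gt(min(rmsfValues(raw)), 1)
})

test_that("the window is the trailing fraction of frames and needs >= 2 frames", {
  h <- makeIdealHelix(6)
  ca_far <- caCoords(h) + 100
  noisy <- CoarseModel(resno = residueIndices(h), resid = residueNames(h),
                       ca = ca_far, cb = cbCoords(h), o = oCoords(h))
  # 8 early junk frames, then 4 identical frames: a 0.25 window sees only
  # the still tail, so rmsf is 0 there
  ens <- CoarseEnsemble(c(rep(list(noisy), 8), rep(list(h), 4)))
  pr <- computeRMSF(ens, windowFraction = 0.25, superpose = FALSE)
  expect_equal(max(rmsfValues(pr)), 0)
  expect_identical(pr@window, c(10L, 12L))
  expect_error(computeRMSF(CoarseEnsemble(list(h)), windowFraction = 1),
               ">= 2 frames")
  expect_error(computeRMSF(ens, windowFraction = 0), "windowFraction")
})

test_that("trimming removes exactly the residues with rmsf strictly over the cutoff", {
  h <- makeIdealHelix(4)
  prof <- new("FluctuationProfile", resno = 1:4,
              rmsf = c(0.5, 1.6, 1.5, 2.0),
              bfactor = rmsfToBfactor(c(0.5, 1.6, 1.5, 2.0)),
              window = c(1L, 2L))
  out <- trimByRMSF(h, prof, cutoff = 1.5)
  expect_identical(removedResidues(out$report), c(2L, 4L))  # 1.5 is kept
  expect_identical(keptResidues(out$report), c(1L, 3L))
  expect_equal(fractionRemoved(out$report), 0.5)
  expect_identical(residueIndices(out$model), c(1L, 3L))    # numbering kept

  # nothing over the cutoff -> nothing removed
  prof1 <- new("FluctuationProfile", resno = 1:4, rmsf = rep(1, 4),
               bfactor = rmsfToBfactor(rep(1, 4)), window = c(1L, 2L))
  out1 <- trimByRMSF(h, prof1, cutoff = 1.5)
  expect_equal(fractionRemoved(out1$report), 0)
  expect_identical(out1$model, h)

  # cutoff 0 with positive rmsf empties the model, flagged by a warning
  expect_warning(out0 <- trimByRMSF(h, prof1, cutoff = 0), "empty")
  expect_equal(nResidues(out0$model), 0L)
  expect_equal(fractionRemoved(out0$report), 1)

  # roster mismatch
  expect_error(trimByRMSF(makeIdealHelix(6), prof), "consistency error")
})

test_that("trimming is idempotent", {
  n <- 12
  sigma <- seq(0.2, 1.6, length.out = n)
  ens <- perturbEnsemble(makeIdealHelix(n), fixtureSpec(n, sigma, 300, seed = 5))
  pr <- computeRMSF(ens, windowFraction = 1, superpose = FALSE)
  once <- trimByRMSF(makeIdealHelix(n), pr)
  expect_gt(length(removedResidues(once$report)), 0)
  twice <- trimByRMSF(once$model, pr)
  expect_equal(length(removedResidues(twice$report)), 0L)
  expect_identical(residueIndices(twice$model), residueIndices(once$model))
})

test_that("trimmed residues stratify by secondary-structure class", {
  rep5 <- new("TrimReport", cutoff = 1.5, removed = c(2L, 4L),
              kept = c(1L, 3L, 5L), fractionRemoved = 0.4)
  fr <- stratifyTrimmed(rep5, c("H", "C", "H", "U", "E"))
  expect_equal(fr, c(H = 0, E = 0, C = 0.5, U = 0.5))
  expect_equal(sum(fr), 1)

  none <- new("TrimReport", cutoff = 1.5, removed = integer(0),
              kept = 1:5, fractionRemoved = 0)
  expect_equal(sum(stratifyTrimmed(none, rep("H", 5))), 0)

  allH <- new("TrimReport", cutoff = 1.5, removed = 1:3, kept = integer(0),
              fractionRemoved = 1)
  expect_equal(stratifyTrimmed(allH, rep("H", 3))[["H"]], 1)

  expect_error(stratifyTrimmed(rep5, c("H", "C", "X", "U", "E")), "domain error")
  expect_error(stratifyTrimmed(rep5, c("H", "C")), "one label per roster")
})
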