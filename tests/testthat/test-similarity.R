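test_that("all metrics return exact identity on self-comparison", {
  h <- makeIdealHelix(12)
  expect_equal(qw(h, h), 1.0)
  expect_equal(gdtTS(h, h), 1.0)
  expect_equal(qTemplate(h, h, fullAlignment(h)), 1.0)
  fit <- kabschSuperpose(caCoords(h), caCoords(h))
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
})

test_that("metrics are invariant under rigid-body motion (50 random motions)", {
  set.seed(101)
  a <- makeIdealHelix(15)
  spec <- fixtureSpec(15, 0.5, nFrames = 1, seed = 2)
  b <- getFrame(perturbEnsemble(a, spec), 1)
  q0 <- qw(a, b)
  g0 <- gdtTS(a, b)
  c0 <- contactPairs(contactMap(b))
  for (k in 1:50) {
    rt <- random_rigid()
    bT <- transform_model(b, rt$R, rt$t)
    expect_equal(qw(a, bT), q0, tolerance = 1e-9)
    expect_equal(gdtTS(a, bT), g0, tolerance = 1e-9)
    expect_equal(kabschSuperpose(caCoords(bT), caCoords(b))$rmsd, 0,
                 tolerance = 1e-9)
    expect_identical(contactPairs(contactMap(bT)), c0)
  }
})

test_that("Qw matches a hand-enumerated sum on the 5-residue collinear toy", {
  # chain on the x axis at 3.8 A spacing; second copy has residue 5 pushed
  # +1 A along the axis. Qualifying pairs (|i-j| >= 3): (1,4), (1,5), (2,5).
  a <- ca_model(cbind(3.8 * (0:4), 0, 0))
  xb <- 3.8 * (0:4); xb[5] <- xb[5] + 1
  b <- ca_model(cbind(xb, 0, 0))
  # (1,4): distances equal -> 1; (1,5): diff 1, sigma = (1+4)^0.15;
  # (2,5): diff 1, sigma = (1+3)^0.15
  oracle <- (1 + exp(-1 / (2 * 5^0.3)) + exp(-1 / (2 * 4^0.3))) / 3
  expect_equal(qw(a, b), oracle, tolerance = 1e-6)
})

test_that("Qw is symmetric and errors on degenerate input", {
  set.seed(7)
  for (k in 1:5) {
    a <- ca_model(matrix(rnorm(30, sd = 5), 10))
    b <- ca_model(matrix(rnorm(30, sd = 5), 10))
    expect_equal(qw(a, b), qw(b, a), tolerance = 1e-12)
  }
  small <- ca_model(matrix(rnorm(9), 3))
  expect_error(qw(small, small), ">= 4 residues")
})

test_that("Q_template matches hand enumeration over the aligned region", {
  # 6 residues, alignment covering 1-4 only: the single qualifying pair is
  # (1,4), sep 3, template distance 11.4 A, model distance 12.4 A.
  tmpl <- ca_model(cbind(3.8 * (0:5), 0, 0))
  xm <- 3.8 * (0:5); xm[4] <- xm[4] + 1
  model <- ca_model(cbind(xm, 0, 0))
  al <- AlignmentMap(1:4, 1:4)
  oracle <- exp(-1 / (2 * 4^0.3))
  expect_equal(qTemplate(model, tmpl, al), oracle, tolerance = 1e-6)
})

test_that("template pairs closer than 2 A are excluded from sum and normalization", {
  # template: d(1,4) = 1.9 A (excluded); pairs (1,5) and (2,5) remain, and
  # the model shifts residue 5 by +1 A so both remaining diffs are 1 A.
  tx <- c(0, 0.9, 2.0, 1.9, 12.0)
  mx <- c(0, 0.9, 2.0, 1.9, 13.0)
  tmpl <- ca_model(cbind(tx, 0, 0))
  model <- ca_model(cbind(mx, 0, 0))
  oracle <- (exp(-1 / (2 * 5^0.3)) + exp(-1 / (2 * 4^0.3))) / 2
  expect_equal(qTemplate(model, tmpl), oracle, tolerance = 1e-6)
  # with every pair under 2 A in the template nothing qualifies
  tiny <- ca_model(cbind(c(0, 0.3, 0.6, 0.9), 0, 0))
  expect_error(qTemplate(tiny, tiny), "no aligned pairs")
})

test_that("Q_template with a full identity alignment reduces to Qw", {
  a <- makeIdealHelix(14)
  b <- getFrame(perturbEnsemble(a, fixtureSpec(14, 0.4, 1, seed = 8)), 1)
  # all helix template distances at |i-j| >= 3 exceed 2 A, so the pair sets
  # coincide and the two implementations must agree
  expect_equal(qTemplate(a, b, fullAlignment(a)), qw(a, b), tolerance = 1e-12)
})

test_that("Kabsch rmsd matches a brute-force rotation-search oracle", {
  # independent oracle: minimize rmsd over rotations parameterised as
  # axis-angle vectors, many random starts, Nelder-Mead refinement
  brute_rmsd <- function(P, Q) {
    Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
    obj <- function(v) {
      ang <- sqrt(sum(v^2))
      R <- if (ang < 1e-12) diag(3) else axis_rotation(v, ang)
      sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
    }
    best <- Inf
    for (s in 1:40) {
      v0 <- rnorm(3, sd = 1.5)
      fit <- optim(v0, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-14))
      best <- min(best, fit$value)
    }
    best
  }
  set.seed(33)
  P <- matrix(c(0, 0, 0, 3, 0, 0, 0, 2, 0, 1, 1, 4), 4, 3, byrow = TRUE)
  for (k in 1:3) {
    rt <- random_rigid()
    Q <- sweep(P %*% t(rt$R), 2, rt$t, "+") + matrix(rnorm(12, sd = 0.3), 4)
    expect_equal(kabschSuperpose(P, Q)$rmsd, brute_rmsd(P, Q),
                 tolerance = 1e-4)
  }
})

test_that("Kabsch agrees with the bio3d superposition on random pairs", {
  set.seed(12)
  for (k in 1:5) {
    P <- matrix(rnorm(30, sd = 4), 10)
    Q <- matrix(rnorm(30, sd = 4), 10)
    ours <- kabschSuperpose(P, Q)$rmsd
    ref <- bio3d::rmsd(as.vector(t(P)), as.vector(t(Q)), fit = TRUE)
    expect_equal(ours, ref, tolerance = 1e-3)
  }
})

test_that("superposed rmsd never exceeds the raw rmsd", {
  set.seed(21)
  for (k in 1:20) {
    P <- matrix(rnorm(24, sd = 3), 8)
    Q <- matrix(rnorm(24, sd = 3), 8)
    raw <- sqrt(mean(rowSums((P - Q)^2)))
    expect_lte(kabschSuperpose(P, Q)$rmsd, raw + 1e-12)
  }
})

test_that("Kabsch input contract: matched lengths, >= 3 points", {
  P <- matrix(rnorm(12), 4)
  expect_error(kabschSuperpose(P, P[1:3, ]), "differ in length")
  expect_error(kabschSuperpose(P[1:2, ], P[1:2, ]), ">= 3 points")
})

test_that("GDT-TS counts threshold fractions exactly", {
  ref <- ca_model(cbind(c(0, 10, 20, 30), 0, 0))
  dev <- c(0.5, 1.5, 3.0, 9.0)
  mod <- ca_model(cbind(c(0, 10, 20, 30), dev, 0))
  # fixed frame: (1/4 + 2/4 + 3/4 + 3/4) / 4
  expect_equal(gdtTS(mod, ref, presuperpose = FALSE), 0.5625)
  far <- ca_model(cbind(c(0, 10, 20, 30), 50, 0))
  expect_equal(gdtTS(far, ref, presuperpose = FALSE), 0)
})

test_that("Qw decays monotonically with noise amplitude (in expectation)", {
  base <- makeIdealHelix(20)
  amps <- c(0.1, 0.4, 0.8, 1.6)
  mean_q <- vapply(amps, function(a) {
    mean(vapply(1:20, function(s) {
      noisy <- getFrame(perturbEnsemble(base, fixtureSpec(20, a, 1, seed = s)), 1)
      qw(base, noisy)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_q) < 0))
})

test_that("contact maps respect the distance boundary and separation rule", {
  place <- function(d) ca_model(cbind(c(0, 30, 60, 90, d), 0, 0),
                                resno = 1:5)
  # residues 1 and 5 are sequence-separated by 4; vary their distance
  expect_true(any(contactPairs(contactMap(place(9.4)))[, 1] == 1))
  expect_true(any(contactPairs(contactMap(place(9.5)))[, 1] == 1))
  expect_false(any(nContacts(contactMap(place(9.6))) > 0 &
                   contactPairs(contactMap(place(9.6)))[, 1] == 1))
  # (i, i+2) never counts under minSeqSep = 3 however close
  close2 <- ca_model(cbind(c(0, 50, 1, 100), 0, 0))
  cp <- contactPairs(contactMap(close2))
  expect_false(any(cp[, 1] == 1 & cp[, 2] == 3))
})

test_that("helix contact count equals exhaustive pair enumeration", {
  h <- makeIdealHelix(20)
  ca <- caCoords(h)
  # brute-force double loop, plain arithmetic
  hits <- 0L
  expected_pairs <- NULL
  for (i in 1:19) for (j in (i + 1):20) {
    if (j - i >= 3 && sqrt(sum((ca[i, ] - ca[j, ])^2)) <= 9.5) {
      hits <- hits + 1L
      expected_pairs <- rbind(expected_pairs, c(i, j))
    }
  }
  cm <- contactMap(h)
  expect_equal(nContacts(cm), hits)
  expect_equal(contactPairs(cm), expected_pairs)
  expect_gt(hits, 0)  # i,i+4 helical contacts exist under the 9.5 A cutoff
})

test_that("contact overlap statistics follow set arithmetic", {
  mk <- function(pairs) new("ContactMap", nResidues = 10L,
                            contacts = pairs, cutoff = 9.5, minSeqSep = 3L)
  a <- mk(rbind(c(1L, 5L), c(2L, 6L)))
  b <- mk(rbind(c(2L, 6L), c(3L, 7L)))
  expect_equal(contactOverlap(a, a), c(precision = 1, recall = 1, jaccard = 1))
  expect_equal(contactOverlap(a, b),
               c(precision = 0.5, recall = 0.5, jaccard = 1 / 3))
  disjoint <- mk(rbind(c(4L, 8L)))
  expect_equal(unname(contactOverlap(a, disjoint)), c(0, 0, 0))
  empty <- mk(matrix(integer(0), 0, 2))
  expect_warning(res <- contactOverlap(empty, a), "undefined")
  expect_true(is.na(res[["precision"]]))
  wrong <- new("ContactMap", nResidues = 10L, contacts = rbind(c(1L, 5L)),
               cutoff = 8, minSeqSep = 3L)
  expect_error(contactOverlap(a, wrong), "different parameters")
})
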