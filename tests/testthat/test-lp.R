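## LP assembly, the interior-point solver, slack recovery.

test_that("assembly counts rows and variables: 2 rows per (voxel, map) pair
           plus one cap row per OAR voxel", {
  g <- lineGrid(1)
  d <- mkInfluence(matrix(1, 1, 1), g)
  rx <- mkRx(g, 1, 70)
  p <- assembleLP(d, rx, lpConfig())
  expect_equal(nrow(p@rowInfo), 2L)
  expect_equal(p@nApertures + 2L, 3L)   # omega + x + y
  ## k stacked maps on one voxel give 2k rows
  rx2 <- mkRx(g, 1, 70)
  rx2@maps <- c(rx2@maps, rx2@maps)
  p2 <- assembleLP(d, rx2, lpConfig())
  expect_equal(nrow(p2@rowInfo), 4L)
  ## row sparsity equals the influence row support
  g3 <- lineGrid(3)
  D <- matrix(c(1, 0, 0.5, 0, 2, 0), 3, 2)
  p3 <- assembleLP(mkInfluence(D, g3), mkRx(g3, rep(1, 3), rep(70, 3)),
                   lpConfig())
  ceil <- p3@rowInfo$type == "ceiling"
  expect_equal(as.matrix(p3@G[ceil, ] != 0), D != 0,
               ignore_attr = TRUE)
})

test_that("forced single-voxel problem returns the exact weight with zero
           objective", {
  g <- lineGrid(1)
  d <- mkInfluence(matrix(1, 1, 1), g)
  sol <- solveLP(assembleLP(d, mkRx(g, 1, 70), lpConfig()), d)
  expect_equal(sol@status, "optimal")
  expect_equal(weights(sol), 70, tolerance = 1e-7)
  expect_lt(objectiveValue(sol), 1e-6)
})

test_that("two voxels sharing one unit aperture with prescriptions 70 and
           82 yield the brute-force objective 12", {
  g <- lineGrid(2)
  d <- mkInfluence(matrix(1, 2, 1), g)
  rx <- mkRx(g, c(1, 1), c(70, 82))
  prob <- assembleLP(d, rx, lpConfig(pTmax = 1, pTmin = 1))
  sol <- solveLP(prob, d)
  expect_equal(objectiveValue(sol), bruteForceLP(prob@G, prob@rhs,
                                                 prob@penalty),
               tolerance = 1e-6)
  expect_equal(objectiveValue(sol), 12, tolerance = 1e-6)
})

test_that("solver matches exhaustive vertex enumeration on 100 random tiny
           instances and slack recovery agrees at the optimum", {
  set.seed(123)
  for (t in 1:100) {
    M <- sample(1:3, 1); nv <- sample(1:5, 1)
    D <- matrix(round(runif(nv * M, 0.05, 1), 2), nv, M)
    lo <- round(runif(nv, 50, 70), 1)
    hi <- lo + round(runif(nv, 0, 8), 1)
    g <- lineGrid(nv)
    rx <- mkRx(g, rep(1, nv), (lo + hi) / 2, dmin = lo, dmax = hi)
    d <- mkInfluence(D, g)
    cfg <- lpConfig(pTmax = 1, pTmin = 1)
    prob <- assembleLP(d, rx, cfg)
    sol <- solveLP(prob, d)
    bf <- bruteForceLP(prob@G, prob@rhs, prob@penalty)
    expect_lt(abs(objectiveValue(sol) - bf) / max(1, abs(bf)), 1e-4)
    rs <- recoverSlacks(weights(sol), d, rx, cfg)
    expect_lt(abs(attr(rs, "objective") - objectiveValue(sol)) /
              max(1, objectiveValue(sol)), 1e-6)
  }
})

test_that("slack recovery reproduces hand arithmetic: dose 75 against a
           70 Gy ceiling with a 1.03 similarity factor leaves x = 2.9", {
  g <- lineGrid(1)
  d <- mkInfluence(matrix(1, 1, 1), g)
  rx <- mkRx(g, 1, 70, delta = c(0.97, 1.03))
  rs <- recoverSlacks(75, d, rx, lpConfig())
  x <- rs$slack[rs$type == "ceiling"]
  y <- rs$slack[rs$type == "floor"]
  expect_equal(x, 75 - 70 * 1.03)
  expect_equal(y, 0)
  ## dose inside the band leaves all slacks zero
  rs0 <- recoverSlacks(71, d, rx, lpConfig())
  expect_true(all(rs0$slack == 0))
})

test_that("a prescription constructed from a known weighting is certified
           with near-zero objective", {
  set.seed(7)
  n <- 40; M <- 6
  D <- matrix(runif(n * M), n, M); D[D < 0.4] <- 0
  wstar <- runif(M, 10, 80)
  dose <- as.numeric(D %*% wstar)
  g <- lineGrid(n)
  d <- mkInfluence(D, g)
  rx <- mkRx(g, rep(1, n), dose)
  sol <- solveLP(assembleLP(d, rx, lpConfig()), d)
  expect_lt(objectiveValue(sol), 1e-6)
})

test_that("raising the OAR penalty never increases the optimal OAR
           overdose", {
  set.seed(9)
  n <- 12; M <- 4
  D <- matrix(runif(n * M, 0.2, 1), n, M)
  g <- lineGrid(n)
  tmask <- c(rep(1, 8), rep(0, 4))
  omask <- 1 - tmask
  oar <- oarConstraint("o", imageVolume(array(omask, g@shape), g, "mask"),
                       cap = 30)
  rx <- mkRx(g, tmask, 70 * tmask, oars = list(oar))
  d <- mkInfluence(D, g)
  oarOver <- vapply(c(0.1, 0.5, 2, 10), function(pw) {
    sol <- solveLP(assembleLP(d, rx, lpConfig(pOARmax = pw)), d)
    rs <- recoverSlacks(weights(sol), d, rx, lpConfig(pOARmax = pw))
    sum(rs$slack[rs$type == "oar"])
  }, numeric(1))
  expect_true(all(diff(oarOver) <= 1e-6))
})

test_that("solving the same problem twice is deterministic in objective and
           dose", {
  set.seed(5)
  n <- 20; M <- 5
  D <- matrix(runif(n * M, 0, 1), n, M)
  g <- lineGrid(n)
  rx <- mkRx(g, rep(1, n), runif(n, 68, 84))
  d <- mkInfluence(D, g)
  s1 <- solveLP(assembleLP(d, rx, lpConfig()), d)
  s2 <- solveLP(assembleLP(d, rx, lpConfig()), d)
  expect_identical(objectiveValue(s1), objectiveValue(s2))
  expect_identical(voxelData(s1@dose), voxelData(s2@dose))
})

test_that("apertures with no influence on constrained voxels get zero
           weight instead of breaking the solve", {
  g <- lineGrid(2)
  ## second aperture only hits the unconstrained voxel
  d <- mkInfluence(matrix(c(1, 1, 0, 0.5), 2, 2), g)
  rx <- mkRx(g, c(1, 0), c(70, 0))
  sol <- solveLP(assembleLP(d, rx, lpConfig()), d)
  expect_equal(weights(sol)[2], 0)
  expect_equal(weights(sol)[1], 70, tolerance = 1e-6)
})
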