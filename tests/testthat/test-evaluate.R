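## Quality-index evaluation: Q map, QVH, QF, tolerance fractions, DVH, CI,
## isodose masks.

mkMapDose <- function(n = 30, seed = 3) {
  set.seed(seed)
  g <- lineGrid(n)
  rxDose <- runif(n, 70, 82)
  map <- new("PrescriptionMap", grid = g, mask = array(1, g@shape),
             dose = array(rxDose, g@shape), doseMin = array(rxDose, g@shape),
             doseMax = array(rxDose, g@shape), deltaMin = 0.97,
             deltaMax = 1.03, label = "dpbn")
  list(g = g, map = map, rxDose = rxDose)
}

test_that("the quality index is the planned/prescribed ratio, NA off
           target", {
  f <- mkMapDose()
  dose <- imageVolume(array(f$rxDose * 1.02, f$g@shape), f$g, "dose-Gy")
  q <- qMap(dose, f$map)
  expect_equal(as.numeric(voxelData(q)), rep(1.02, 30))
  ## off-target voxels are masked out
  f$map@mask[5] <- 0
  q2 <- qMap(dose, f$map)
  expect_true(is.na(voxelData(q2)[5]))
  ## prescribing the dose itself gives Q identically 1 and QF 0
  qq <- qMap(imageVolume(array(f$rxDose, f$g@shape), f$g, "dose-Gy"), f$map)
  expect_equal(qf(qq), 0)
})

test_that("QF of a uniformly scaled prescription equals 100|alpha - 1| and
           matches the direct mean-absolute oracle on random doses", {
  f <- mkMapDose()
  for (alpha in c(0.95, 1.0, 1.02, 1.3)) {
    dose <- imageVolume(array(alpha * f$rxDose, f$g@shape), f$g, "dose-Gy")
    expect_equal(qf(qMap(dose, f$map)), 100 * abs(alpha - 1),
                 tolerance = 1e-9)
  }
  set.seed(11)
  dv <- f$rxDose * runif(30, 0.9, 1.1)
  q <- qMap(imageVolume(array(dv, f$g@shape), f$g, "dose-Gy"), f$map)
  expect_equal(qf(q), 100 * mean(abs(dv / f$rxDose - 1)))
})

test_that("tolerance fractions use strict inequalities and are nested over
           3/4/5%", {
  f <- mkMapDose()
  exact <- imageVolume(array(f$rxDose * 1.05, f$g@shape), f$g, "dose-Gy")
  q <- qMap(exact, f$map)
  expect_equal(fractionWithin(q, tol = 0.05), 0)  # boundary excluded
  set.seed(12)
  dv <- f$rxDose * (1 + rnorm(30, 0, 0.03))
  q2 <- qMap(imageVolume(array(dv, f$g@shape), f$g, "dose-Gy"), f$map)
  w3 <- fractionWithin(q2, tol = 0.03)
  w4 <- fractionWithin(q2, tol = 0.04)
  w5 <- fractionWithin(q2, tol = 0.05)
  expect_lte(w3, w4); expect_lte(w4, w5)
  expect_equal(w3, 100 * mean(abs(dv / f$rxDose - 1) < 0.03))
})

test_that("QVH starts at 100%, is monotone non-increasing, and matches a
           sorted-array oracle; two-value Q gives a 50% plateau", {
  f <- mkMapDose()
  set.seed(13)
  qv <- runif(30, 0.9, 1.1)
  q <- imageVolume(array(qv, f$g@shape), f$g, "q-index")
  h <- qvh(q, binWidth = 0.01)
  expect_equal(h$pct[1], 100)
  expect_true(all(diff(h$pct) <= 1e-9))
  for (i in seq_len(nrow(h)))
    expect_equal(h$pct[i], 100 * mean(qv >= h$q[i]))
  two <- imageVolume(array(rep(c(0.9, 1.1), 15), f$g@shape), f$g, "q-index")
  h2 <- qvh(two, binWidth = 0.01)
  expect_equal(h2$pct[h2$q > 0.9 + 1e-9 & h2$q <= 1.1],
               rep(50, sum(h2$q > 0.9 + 1e-9 & h2$q <= 1.1)))
})

test_that("DVH is the cumulative dose coverage and demands a non-empty
           mask", {
  g <- lineGrid(40)
  dose <- imageVolume(array(55, g@shape), g, "dose-Gy")
  mask <- imageVolume(array(1, g@shape), g, "mask")
  h <- dvh(dose, mask, binWidth = 1)
  expect_true(all(h$pct[h$dose <= 55] == 100))
  expect_true(all(h$pct[h$dose > 55] == 0))
  set.seed(14)
  dv <- runif(40, 0, 80)
  h2 <- dvh(imageVolume(array(dv, g@shape), g, "dose-Gy"), mask,
            binWidth = 0.5)
  for (i in sample(nrow(h2), 10))
    expect_equal(h2$pct[i], 100 * mean(dv >= h2$dose[i]))
  expect_error(dvh(dose, imageVolume(array(0, g@shape), g, "mask")),
               "empty")
})

test_that("the conformity index reads coverage of the per-voxel 95%
           isodose: full, none, and a half-covered slab", {
  f <- mkMapDose()
  full <- imageVolume(array(f$rxDose, f$g@shape), f$g, "dose-Gy")
  expect_equal(conformityIndex(full, f$map), 100)
  none <- imageVolume(array(0, f$g@shape), f$g, "dose-Gy")
  expect_equal(conformityIndex(none, f$map), 0)
  half <- f$rxDose
  half[1:15] <- half[1:15] * 0.9   # below the 95% reference
  hd <- imageVolume(array(half, f$g@shape), f$g, "dose-Gy")
  expect_equal(conformityIndex(hd, f$map), 50)
})

test_that("isodose masks nest with level and respect the 70 Gy reference", {
  g <- lineGrid(50)
  set.seed(15)
  dose <- imageVolume(array(runif(50, 0, 90), g@shape), g, "dose-Gy")
  m100 <- isodoseMask(dose, 100)
  m80 <- isodoseMask(dose, 80)
  m110 <- isodoseMask(dose, 110)
  expect_true(all(voxelData(m100) <= voxelData(m80)))
  expect_true(all(voxelData(m110) <= voxelData(m100)))
  expect_equal(voxelData(m100), (voxelData(dose) >= 70) * 1)
  expect_true(all(voxelData(isodoseMask(dose, 200)) == 0))
  ## adding dose never lowers coverage
  f <- mkMapDose()
  d1 <- imageVolume(array(f$rxDose * 0.9, f$g@shape), f$g, "dose-Gy")
  d2 <- imageVolume(voxelData(d1) + 5, f$g, "dose-Gy")
  expect_gte(conformityIndex(d2, f$map), conformityIndex(d1, f$map))
})

test_that("qualityReport bundles the pieces with nested tolerance fractions
           and CI within [0, 100]", {
  f <- mkMapDose()
  set.seed(16)
  dose <- imageVolume(array(f$rxDose * (1 + rnorm(30, 0, 0.02)),
                            f$g@shape), f$g, "dose-Gy")
  rep <- qualityReport(dose, f$map)
  expect_s4_class(rep, "QualityReport")
  expect_equal(unname(rep@within[1] <= rep@within[3]), TRUE)
  expect_true(all(rep@ci >= 0 & rep@ci <= 100))
  expect_equal(rep@qf, qf(qMap(dose, f$map)))
})
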