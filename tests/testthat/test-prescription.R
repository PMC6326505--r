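## Segmentation and SUV-to-dose prescription maps.

test_that("threshold segmentation recovers a uniform sphere and counts
           disjoint lesions", {
  suv <- sphereSUV(radius = 6, level = 10)
  seg <- segmentSUV(suv, 0.5)
  expect_equal(voxelData(seg@mask), (voxelData(suv) >= 5) * 1)
  expect_equal(seg@nComponents, 1L)
  g <- gridCovering(c(-20, -20, -10), c(20, 20, 10), c(2, 2, 2))
  two <- makeActivityTruth(list(
    lesionSpec("A", "sphere", c(-10, 0, 0), 5, activity = 10),
    lesionSpec("B", "sphere", c(12, 0, 0), 4, activity = 8)), g)
  expect_equal(segmentSUV(two, 0.4)@nComponents, 2L)
  expect_error(segmentSUV(imageVolume(0, g, "suv"), 0.4), "empty")
})

test_that("components below the voxel floor are removed, matching a
           breadth-first-search labelling oracle", {
  g <- gridCovering(c(-20, -20, -6), c(20, 20, 6), c(2, 2, 2))
  suv <- makeActivityTruth(list(
    lesionSpec("big", "sphere", c(-10, 0, 0), 6, activity = 10),
    lesionSpec("tiny", "sphere", c(12, 0, 0), 2.2, activity = 10)), g)
  segAll <- segmentSUV(suv, 0.5)
  oracle <- bfsComponents(voxelData(suv) >= 5)
  expect_equal(segAll@nComponents, max(oracle))
  expect_equal(segAll@labels > 0, oracle > 0)
  sizes <- tabulate(oracle[oracle > 0])
  floorVox <- as.integer(min(sizes) + 1L)
  segBig <- segmentSUV(suv, 0.5, minComponentVoxels = floorVox)
  expect_equal(segBig@nComponents, sum(sizes >= floorVox))
  expect_equal(sum(voxelData(segBig@mask)), sum(sizes[sizes >= floorVox]))
})

test_that("the by-numbers map hits 70 Gy at the minimum-SUV voxel, 82 Gy at
           the maximum, 76 Gy at the midpoint, and is affine in SUV", {
  suv <- sphereSUV(radius = 8, level = 10)
  v <- voxelData(suv)
  ## make the lesion heterogeneous: linear gradient inside
  v[v > 0] <- 4 + seq(0, 6, length.out = sum(v > 0))
  suv <- imageVolume(v, suv@grid, "suv")
  mask <- (v > 0) * 1
  map <- dpbnMap(suv, mask)
  on <- mask > 0
  expect_equal(map@dose[on][which.min(v[on])], 70)
  expect_equal(map@dose[on][which.max(v[on])], 82)
  mid <- which.min(abs(v[on] - 7))   # midpoint SUV of the 4..10 range
  expect_equal(map@dose[on][mid], 76, tolerance = 1e-3)
  expect_equal(cor(map@dose[on], v[on]), 1)
  ## constant SUV collapses to the low endpoint
  flat <- dpbnMap(imageVolume((v > 0) * 5, suv@grid, "suv"), mask)
  expect_true(all(flat@dose[on] == 70))
  expect_error(dpbnMap(suv, mask, dLow = 80, dHigh = 70), "dHigh")
  expect_error(dpbnMap(suv, array(0, dim(v)), 70, 82), "empty")
})

test_that("the by-contour map is piecewise constant on nested subvolumes
           and quantizes the by-numbers map", {
  suv <- sphereSUV(radius = 8, level = 10)
  v <- voxelData(suv)
  v[v > 0] <- 4 + seq(0, 6, length.out = sum(v > 0))
  suv <- imageVolume(v, suv@grid, "suv")
  mask <- (v > 0) * 1
  fr <- c(0.5, 0.7, 0.9)
  dp <- dpbcMap(suv, mask, levelFractions = fr)
  expect_length(dp@levels, 3L)
  b1 <- dp@levels$BTV1 > 0; b2 <- dp@levels$BTV2 > 0; b3 <- dp@levels$BTV3 > 0
  expect_true(all(b2 <= b1) && all(b3 <= b2))  # nested by construction
  on <- mask > 0
  expect_lte(length(unique(dp@dose[on])), 3L)
  ## per-voxel oracle: innermost-level dose equals the by-numbers dose of
  ## that level's threshold SUV
  dn <- dpbnMap(suv, mask)
  rng <- range(v[on])
  lvl <- function(s) 70 + (min(max(s, rng[1]), rng[2]) - rng[1]) /
    diff(rng) * 12
  expected <- ifelse(b3[on], lvl(0.9 * max(v)),
              ifelse(b2[on], lvl(0.7 * max(v)), lvl(0.5 * max(v))))
  expect_equal(dp@dose[on], expected, tolerance = 1e-9)
  ## a single level at a tiny fraction reproduces a uniform prescription
  uni <- dpbcMap(suv, mask, levelFractions = min(v[on]) / max(v) - 1e-9)
  expect_equal(length(unique(uni@dose[on])), 1L)
  expect_error(dpbcMap(suv, mask, levelFractions = c(0.5, 0.7),
                       levelDoses = c(80, 75)), "ascend")
})

test_that("stacking maps never loosens any single map's feasible band and
           counts constraints by mask algebra", {
  suv <- sphereSUV(radius = 8, level = 10)
  v <- voxelData(suv)
  v[v > 0] <- 4 + seq(0, 6, length.out = sum(v > 0))
  suv <- imageVolume(v, suv@grid, "suv")
  mask <- (v > 0) * 1
  dn <- dpbnMap(suv, mask)
  dc <- dpbcMap(suv, mask, levelFractions = c(0.5, 0.7, 0.9))
  dg <- gridCovering(c(-16, -16, -16), c(16, 16, 16), c(4, 4, 4))
  rx <- combineRobust(list(dn, dc), list(), dg)
  m1 <- rx@maps[[1]]@mask > 0; m2 <- rx@maps[[2]]@mask > 0
  expect_equal(rx@nT, sum(m1 | m2))
  expect_equal(sum(m1 & m2),
               sum((rx@maps[[1]]@mask > 0) & (rx@maps[[2]]@mask > 0)))
  ## stacked feasible interval is contained in each map's interval
  both <- m1 & m2
  lo <- pmax(rx@maps[[1]]@doseMin[both] * rx@maps[[1]]@deltaMin,
             rx@maps[[2]]@doseMin[both] * rx@maps[[2]]@deltaMin)
  hi1 <- rx@maps[[1]]@doseMax[both] * rx@maps[[1]]@deltaMax
  hi2 <- rx@maps[[2]]@doseMax[both] * rx@maps[[2]]@deltaMax
  expect_true(all(lo >= rx@maps[[1]]@doseMin[both] *
                        rx@maps[[1]]@deltaMin - 1e-12))
  expect_true(all(pmin(hi1, hi2) <= hi1 + 1e-12))
})

test_that("OAR voxels overlapping the target are released from the cap
           (target priority)", {
  suv <- sphereSUV(radius = 8, level = 10)
  mask <- (voxelData(suv) > 0) * 1
  map <- dpbnMap(suv, mask)
  ## an OAR that half-overlaps the target
  oarMask <- array(0, dim(mask))
  oarMask[1:8, , ] <- 1
  oar <- oarConstraint("organ", imageVolume(oarMask, suv@grid, "mask"), 45)
  rx <- combineRobust(list(map), list(oar), suv@grid)
  ov <- rx@oars[[1]]@mask@values
  expect_equal(sum(ov * rx@unionMask), 0)
  expect_equal(rx@n, rx@nT + sum(ov))
})
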