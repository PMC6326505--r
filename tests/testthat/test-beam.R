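## Ray-traced projections, aperture generation, pencil-beam influence.

test_that("face-on projection of a cube has the cube's cross-section and an
           empty mask projects to zero with a warning", {
  g <- gridCovering(c(-30, -30, -30), c(30, 30, 30), c(2, 2, 2))
  cube <- array(0, g@shape)
  cube[abs(axisCoords(g, 1)) <= 10,
       abs(axisCoords(g, 2)) <= 10,
       abs(axisCoords(g, 3)) <= 10] <- 1
  vol <- imageVolume(cube, g, "mask")
  p <- projectStructure(vol, beamGeometry(0))
  area <- sum(p@values > 0) * p@du * p@dv
  expect_lt(abs(area - 22^2) / 22^2, 0.25)  # one-pixel-ring slack
  expect_warning(pe <- projectStructure(imageVolume(array(0, g@shape), g,
                                                    "mask"),
                                        beamGeometry(0)), "empty")
  expect_true(all(pe@values == 0))
})

test_that("a sphere projects to a disc of area pi r^2 within one pixel ring
           and opposing beams see the same silhouette", {
  g <- gridCovering(c(-40, -40, -40), c(40, 40, 40), c(2, 2, 2))
  sph <- lesionMask(lesionSpec("s", "sphere", c(0, 0, 0), 15,
                               activity = 1), g)
  p <- projectStructure(sph, beamGeometry(30))
  area <- sum(p@values > 0) * p@du * p@dv
  ring <- 2 * pi * 15 * (p@du + p@dv)
  expect_lt(abs(area - pi * 15^2), ring)
  p180 <- projectStructure(sph, beamGeometry(210))
  expect_equal(sum(p@values), sum(p180@values), tolerance = 1e-9)
})

test_that("nested prescription bands generate nested apertures (interval
           containment per leaf row)", {
  suv <- sphereSUV(radius = 10, level = 10, half = 24)
  v <- voxelData(suv)
  v[v > 0] <- 4 + 6 * seq(0, 1, length.out = sum(v > 0))
  suv <- imageVolume(v, suv@grid, "suv")
  map <- dpbnMap(suv, (v > 0) * 1)
  aps <- biomapApertures(map, list(beamGeometry(0)), nBands = 3L,
                         rules = list(erodeMm = numeric(0),
                                      dilateConformalMm = numeric(0)))
  prov <- vapply(aps, function(a) a@provenance, character(1))
  b2 <- aps[[which(prov == "band2")]]
  b3 <- aps[[which(prov == "band3")]]
  for (r in seq_along(b3@leafV)) {
    if (is.na(b3@intervals[r, 1])) next
    expect_false(is.na(b2@intervals[r, 1]))
    expect_gte(b3@intervals[r, 1], b2@intervals[r, 1] - 1e-9)
    expect_lte(b3@intervals[r, 2], b2@intervals[r, 2] + 1e-9)
  }
})

test_that("pencil-beam depth dose follows exp(-mu d) in water and is flat in
           air", {
  g <- gridCovering(c(-59, -59, -39), c(59, 59, 39), c(2, 2, 2))
  sphMask <- lesionMask(lesionSpec("s", "sphere", c(0, 0, 0), 15,
                                   activity = 1), g)
  ap <- biomapApertures(dpbnMap(imageVolume(voxelData(sphMask) * 5 + 1e-3,
                                            g, "suv"), sphMask),
                        list(beamGeometry(0)), nBands = 1L,
                        rules = list(erodeMm = numeric(0),
                                     dilateConformalMm = numeric(0)))[[1]]
  water <- imageVolume(array(1, g@shape), g, "ct-density")
  col <- pencilBeamColumn(ap, water, g)
  arr <- array(col, g@shape)
  cx <- which.min(abs(axisCoords(g, 1)))
  cz <- which.min(abs(axisCoords(g, 3)))
  prof <- arr[cx, , cz]
  ys <- axisCoords(g, 2)
  sel <- which(prof > 0.05 * max(prof) & abs(ys) < 30)
  fit <- stats::lm(log(prof[sel]) ~ ys[sel])
  expect_equal(unname(coef(fit)[2]), 0.005, tolerance = 1e-3)
  air <- imageVolume(array(0, g@shape), g, "ct-density")
  colAir <- pencilBeamColumn(ap, air, g)
  profAir <- array(colAir, g@shape)[cx, , cz]
  selAir <- which(profAir > 0.5 * max(profAir))
  expect_lt(diff(range(profAir[selAir])) / max(profAir), 1e-6)
  ## linearity in the output factor
  col2 <- pencilBeamColumn(ap, water, g,
                           kernel = pencilBeamKernel(outputFactor = 2))
  expect_equal(col2, 2 * col, tolerance = 1e-12)
})

test_that("the influence matrix is non-negative, one column per aperture,
           and unit weights match a dense superposition oracle", {
  g <- gridCovering(c(-30, -30, -20), c(30, 30, 20), c(4, 4, 4))
  suv <- makeActivityTruth(list(lesionSpec("L", "sphere", c(0, 0, 0), 10,
                                           activity = 8)), g)
  map <- dpbnMap(suv, (voxelData(suv) > 0) * 1)
  ct <- imageVolume(array(1, g@shape), g, "ct-density")
  beams <- beamSet(3L)
  aps <- biomapApertures(map, beams, nBands = 2L,
                         rules = list(erodeMm = 2,
                                      dilateConformalMm = numeric(0)))
  d <- buildInfluenceMatrix(aps, ct, g)
  expect_s4_class(d, "DoseInfluenceMatrix")
  expect_equal(ncol(d@matrix), length(d@apertures))
  expect_true(min(d@matrix) >= 0 && all(is.finite(d@matrix@x)))
  w <- rep(1, ncol(d@matrix))
  direct <- Reduce(`+`, lapply(seq_along(d@apertures), function(j)
    pencilBeamColumn(d@apertures[[j]], ct, g)))
  viaMatrix <- as.numeric(d@matrix %*% w)
  expect_equal(viaMatrix, direct, tolerance = 1e-10)
  ## single aperture gives M = 1
  d1 <- buildInfluenceMatrix(aps[1], ct, g)
  expect_equal(ncol(d1@matrix), 1L)
})

test_that("dose is linear in the weights: scaling and superposition are
           exact", {
  g <- lineGrid(6)
  set.seed(4)
  D <- matrix(runif(18), 6, 3)
  d <- mkInfluence(D, g)
  w1 <- c(1, 2, 3); w2 <- c(0.5, 0, 4)
  expect_equal(voxelData(computeDose(d, w1 + w2)),
               voxelData(computeDose(d, w1)) +
               voxelData(computeDose(d, w2)))
  expect_equal(voxelData(computeDose(d, 2 * w1)),
               2 * voxelData(computeDose(d, w1)))
  expect_true(all(voxelData(computeDose(d, c(0, 0, 0))) == 0))
  expect_error(computeDose(d, c(1, 2)), "mismatch")
})
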