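## Digital phantoms and reconstruction emulation.

test_that("makeCT paints air outside the outline and tissue inside, and
           rejects lesions outside the body", {
  g <- gridCovering(c(-40, -40, -10), c(40, 40, 10), c(2, 2, 2))
  outline <- bodyOutline(semiAxes = c(30, 25))
  ct <- makeCT(list(), outline, g)
  w <- expand.grid(x = axisCoords(g, 1), y = axisCoords(g, 2),
                   z = axisCoords(g, 3))
  inside <- (w$x / 30)^2 + (w$y / 25)^2 <= 1
  expect_equal(as.numeric(voxelData(ct)), as.numeric(inside))
  expect_equal(sum(voxelData(ct) > 0), sum(inside))  # point-in-shape oracle
  expect_error(makeCT(list(lesionSpec("far", "sphere", c(38, 0, 0), 5,
                                      activity = 1)), outline, g),
               "outside the body")
})

test_that("activity truth paints levels with nested override and rejects
           non-nested overlap", {
  g <- gridCovering(c(-20, -20, -20), c(20, 20, 20), c(1, 1, 1))
  host <- lesionSpec("V3", "cylinder", c(0, 0, 0), c(8, 20), activity = 2)
  core <- lesionSpec("V2", "sphere", c(0, 0, 2), 4, activity = 10,
                     inside = "V3")
  suv <- makeActivityTruth(list(host, core), g)
  lv <- sort(unique(as.numeric(voxelData(suv))))
  expect_equal(lv, c(0, 2, 10))  # two distinct uptake levels plus background
  expect_equal(max(voxelData(makeActivityTruth(list(), g))), 0)
  bad <- lesionSpec("B", "sphere", c(3, 0, 0), 4, activity = 5)
  expect_error(makeActivityTruth(list(host, bad), g), "overlap")
  ## a 0.3 ml sphere recovers its volume within one voxel shell
  les <- lesionSpec("V1", "sphere", c(0, 0, 0), 4.153, activity = 10)
  vol <- measureVolume(lesionMask(les, g))
  shell <- 4 * pi * 4.153^2 * max(g@spacing) / 1000
  expect_lt(abs(vol - 0.3), shell)
})

test_that("reconstruction emulation is the identity without blur, noise or
           regridding", {
  suv <- sphereSUV()
  p0 <- new("ReconstructionProtocol", name = "null",
            voxelSize = suv@grid@spacing, gridPixels = 32L, psfFwhm = 0,
            postFilterFwhm = 0, noiseCV = 0)
  out <- emulateReconstruction(suv, p0, targetGrid = suv@grid)
  expect_equal(voxelData(out), voxelData(suv))
})

test_that("wider blur depresses the peak of a small lesion (partial volume
           effect, monotone in fwhm)", {
  suv <- sphereSUV(radius = 5)
  peaks <- vapply(c(0, 3, 6, 9), function(f) {
    p <- new("ReconstructionProtocol", name = "b", voxelSize =
             suv@grid@spacing, gridPixels = 32L, psfFwhm = 0,
             postFilterFwhm = f, noiseCV = 0)
    max(voxelData(emulateReconstruction(suv, p, targetGrid = suv@grid)))
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("noiseless blur conserves total activity to within 1%", {
  ## a lesion well inside the field, large enough that the coarse
  ## protocol grids quadrature its profile accurately
  suv <- sphereSUV(radius = 9, half = 26)
  for (proto in list(earlProtocol(noiseCV = 0),
                     biographProtocol(noiseCV = 0))) {
    out <- emulateReconstruction(suv, proto)
    ratio <- (sum(voxelData(out)) * voxelVolume(out)) /
             (sum(voxelData(suv)) * voxelVolume(suv))
    expect_gt(ratio, 0.99)
    expect_lt(ratio, 1.01)
  }
})

test_that("emulation with a fixed seed is bit-reproducible and does not
           disturb the caller's RNG stream", {
  suv <- sphereSUV()
  a <- emulateReconstruction(suv, biographProtocol(), seed = 7L)
  set.seed(99)
  before <- runif(1)
  b <- emulateReconstruction(suv, biographProtocol(), seed = 7L)
  set.seed(99)
  expect_identical(voxelData(a), voxelData(b))
  expect_identical(before, runif(1))
})

test_that("the two protocol emulations of one truth are not related by a
           scale factor: thresholded volumes differ by more than 5%", {
  ## the tube phantom's small lesions maximize the partial-volume
  ## difference between the two resolutions
  ph <- tubePhantom()
  truth <- makeActivityTruth(ph$lesions, ph$grid)
  vE <- measureVolume(segmentSUV(emulateReconstruction(truth,
    earlProtocol(), seed = 1L), 0.4)@mask)
  vB <- measureVolume(segmentSUV(emulateReconstruction(truth,
    biographProtocol(), seed = 2L), 0.4)@mask)
  expect_gt(abs(vE - vB) / vB, 0.05)
})

test_that("a YAML phantom spec round-trips into the same truth volume as
           the in-code constructors", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "grid:    {lower: [-20, -20, -10], upper: [20, 20, 10], spacing: [2, 2, 2]}",
    "outline: {center: [0, 0], semiAxes: [18, 18]}",
    "lesions:",
    "  - {name: A, shape: sphere, center: [-6, 0, 0], size: 5, activity: 10}",
    "  - {name: B, shape: cylinder, center: [8, 4, 0], size: [4, 10], activity: 6}"),
    f)
  ph <- readPhantomSpec(f)
  ref <- list(
    lesionSpec("A", "sphere", c(-6, 0, 0), 5, activity = 10),
    lesionSpec("B", "cylinder", c(8, 4, 0), c(4, 10), activity = 6))
  g <- gridCovering(c(-20, -20, -10), c(20, 20, 10), c(2, 2, 2))
  expect_equal(voxelData(makeActivityTruth(ph$lesions, ph$grid)),
               voxelData(makeActivityTruth(ref, g)))
  expect_error(readPhantomSpec({
    f2 <- tempfile(fileext = ".yaml"); writeLines("lesions: []", f2); f2
  }), "grid")
})

test_that("follow-up synthesis applies per-lesion factors and zero
           regions", {
  g <- gridCovering(c(-20, -20, -10), c(20, 20, 10), c(2, 2, 2))
  les <- list(lesionSpec("A", "sphere", c(-8, 0, 0), 5, activity = 10),
              lesionSpec("B", "sphere", c(10, 0, 0), 5, activity = 6))
  base <- makeActivityTruth(les, g)
  same <- followUpSUV(base, les, responseModel(factors = c(A = 1, B = 1)))
  expect_equal(voxelData(same), voxelData(base))
  mB <- voxelData(lesionMask(les[[2]], g)) > 0
  half <- followUpSUV(base, les, responseModel(factors = c(B = 0.5)))
  expect_equal(mean(voxelData(half)[mB]), 0.5 * mean(voxelData(base)[mB]))
  gone <- followUpSUV(base, les, responseModel(factors = c(A = 0)))
  mA <- voxelData(lesionMask(les[[1]], g)) > 0
  expect_true(all(voxelData(gone)[mA] == 0))
  expect_error(responseModel(factors = c(A = -0.5)), "factors")
})
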