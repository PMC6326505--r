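## Digital phantoms: ground-truth activity and density volumes, emulated
## PET reconstructions, and virtual follow-up SUV maps.

#' Create a lesion specification
#'
#' @param name identifier (used by response models and nesting).
#' @param shape \code{"sphere"}, \code{"ellipsoid"} or \code{"cylinder"}.
#' @param center world centre, mm.
#' @param size sphere: radius; ellipsoid: three semi-axes; cylinder:
#'   c(radius, height) with the axis along z.  All mm.
#' @param activity SUV level (> 0).
#' @param inside optional name of the host lesion this one is nested in.
#' @return a [LesionSpec-class].
#' @examples
#' lesionSpec("V1", "sphere", c(0, 40, 0), 4.153, activity = 10)
#' @export
lesionSpec <- function(name, shape, center, size, activity,
                       inside = NA_character_) {
  new("LesionSpec", name = name, shape = shape, center = as.numeric(center),
      size = as.numeric(size), activity = activity, inside = inside)
}

#' Nominal volume of a lesion shape in ml
#' @param lesion a [LesionSpec-class].
#' @export
lesionVolumeMl <- function(lesion) {
  s <- lesion@size
  mm3 <- switch(lesion@shape,
    sphere    = 4 / 3 * pi * s[1L]^3,
    ellipsoid = 4 / 3 * pi * prod(s),
    cylinder  = pi * s[1L]^2 * s[2L])
  mm3 / 1000
}

## logical array: voxel centres inside the lesion shape
.rasterize_lesion <- function(lesion, grid) {
  w <- .grid_coords(grid)
  c0 <- lesion@center; s <- lesion@size
  inside <- switch(lesion@shape,
    sphere = (w[, 1L] - c0[1L])^2 + (w[, 2L] - c0[2L])^2 +
             (w[, 3L] - c0[3L])^2 <= s[1L]^2,
    ellipsoid = ((w[, 1L] - c0[1L]) / s[1L])^2 +
                ((w[, 2L] - c0[2L]) / s[2L])^2 +
                ((w[, 3L] - c0[3L]) / s[3L])^2 <= 1,
    cylinder = (w[, 1L] - c0[1L])^2 + (w[, 2L] - c0[2L])^2 <= s[1L]^2 &
               abs(w[, 3L] - c0[3L]) <= s[2L] / 2)
  array(inside, dim = grid@shape)
}

#' Binary mask of a lesion on a grid
#'
#' @param lesion a [LesionSpec-class].
#' @param grid a [GridSpec-class].
#' @return a mask [ImageVolume-class].
#' @export
lesionMask <- function(lesion, grid) {
  imageVolume(.rasterize_lesion(lesion, grid) * 1, grid, "mask")
}

#' Body outline specification
#'
#' An elliptic cylinder of tissue (relative density 1) spanning the full z
#' range of the grid, with an optional bone rod (relative density 1.6).
#'
#' @param center in-plane centre (x, y), mm.
#' @param semiAxes in-plane semi-axes (mm).
#' @param bone optional list(center = c(x, y), radius) for a bone cylinder.
#' @return a list used by [makeCT()].
#' @export
bodyOutline <- function(center = c(0, 0), semiAxes = c(80, 70), bone = NULL) {
  list(center = center, semiAxes = semiAxes, bone = bone)
}

.rasterize_body <- function(outline, grid) {
  w <- .grid_coords(grid)
  inside <- ((w[, 1L] - outline$center[1L]) / outline$semiAxes[1L])^2 +
            ((w[, 2L] - outline$center[2L]) / outline$semiAxes[2L])^2 <= 1
  array(inside, dim = grid@shape)
}

#' Build a CT-like relative density volume
#'
#' Air outside the body outline (density 0), tissue inside (density 1),
#' optional bone (1.6).  Lesions must lie inside the outline; they do not
#' alter density unless given a \code{density} attribute.
#'
#' @param lesions list of [LesionSpec-class] (used only for the
#'   inside-outline check).
#' @param outline a [bodyOutline()].
#' @param grid target [GridSpec-class].
#' @return a \code{"ct-density"} [ImageVolume-class].
#' @export
makeCT <- function(lesions, outline, grid) {
  body <- .rasterize_body(outline, grid)
  dens <- array(0, dim = grid@shape)
  dens[body] <- 1
  if (!is.null(outline$bone)) {
    w <- .grid_coords(grid)
    b <- outline$bone
    inb <- (w[, 1L] - b$center[1L])^2 + (w[, 2L] - b$center[2L])^2 <=
           b$radius^2
    dens[array(inb, dim = grid@shape)] <- 1.6
  }
  for (les in lesions) {
    m <- .rasterize_lesion(les, grid)
    if (any(m & !body))
      stop("configuration error: lesion '", les@name,
           "' extends outside the body outline")
  }
  imageVolume(dens, grid, "ct-density")
}

#' Build the ground-truth activity (SUV) volume
#'
#' Paints each lesion's activity level onto a configurable background
#' (default 0, mirroring a phantom without background uptake).  Nested
#' lesions override their hosts; overlapping non-nested lesions are a
#' configuration error.
#'
#' @param lesions list of [LesionSpec-class].
#' @param grid target [GridSpec-class].
#' @param background background SUV (default 0).
#' @return an \code{"suv"} [ImageVolume-class].
#' @export
makeActivityTruth <- function(lesions, grid, background = 0) {
  suv <- array(background, dim = grid@shape)
  masks <- lapply(lesions, .rasterize_lesion, grid = grid)
  names(masks) <- vapply(lesions, function(l) l@name, character(1))
  nm <- names(masks)
  for (a in seq_along(lesions)) for (b in seq_along(lesions)) {
    if (a >= b) next
    la <- lesions[[a]]; lb <- lesions[[b]]
    nested <- identical(la@inside, lb@name) || identical(lb@inside, la@name)
    if (!nested && any(masks[[a]] & masks[[b]]))
      stop("configuration error: lesions '", la@name, "' and '", lb@name,
           "' overlap but are not nested")
  }
  for (les in lesions) {
    if (!is.na(les@inside)) {
      host <- masks[[les@inside]]
      if (is.null(host)) stop("unknown host lesion: ", les@inside)
      if (any(masks[[les@name]] & !host))
        stop("configuration error: nested lesion '", les@name,
             "' is not contained in '", les@inside, "'")
    }
  }
  ## hosts first, nested cores afterwards so they override
  ord <- order(!is.na(vapply(lesions, function(l) l@inside, character(1))))
  for (les in lesions[ord]) suv[masks[[les@name]]] <- les@activity
  imageVolume(suv, grid, "suv")
}

## ---------------------------------------------------------------------------
## Reconstruction emulation
## ---------------------------------------------------------------------------

#' Reconstruction protocol constructors
#'
#' \code{earlProtocol()} emulates an OSEM3D reconstruction tuned for EARL
#' harmonization: 3.2 x 3.2 x 5 mm voxels on a nominal 256 x 256 grid with
#' a 6 mm post-processing Gaussian filter.  \code{biographProtocol()}
#' emulates a point-spread-function reconstruction at the scanner's highest
#' available resolution: 1.6 x 1.6 x 1.5 mm voxels on a nominal 512 x 512
#' grid with a 3 mm filter.  The intrinsic psf fwhm defaults encode that
#' resolution modelling recovers part of the scanner blur (2 mm) while the
#' harmonized protocol does not (4.5 mm).
#'
#' @param noiseCV multiplicative voxel-noise coefficient of variation.
#' @param psfFwhm intrinsic resolution fwhm in mm.
#' @return a [ReconstructionProtocol-class].
#' @export
earlProtocol <- function(noiseCV = 0.05, psfFwhm = 4.5) {
  new("ReconstructionProtocol", name = "EARL",
      voxelSize = c(3.2, 3.2, 5), gridPixels = 256L,
      psfFwhm = psfFwhm, postFilterFwhm = 6, noiseCV = noiseCV)
}

#' @rdname earlProtocol
#' @export
biographProtocol <- function(noiseCV = 0.05, psfFwhm = 2) {
  new("ReconstructionProtocol", name = "BIOGRAPH",
      voxelSize = c(1.6, 1.6, 1.5), gridPixels = 512L,
      psfFwhm = psfFwhm, postFilterFwhm = 3, noiseCV = noiseCV)
}

## separable Gaussian blur in world units (zero boundary, integral-
## conserving away from the edges); fwhm per axis in mm
.gaussian_blur <- function(arr, spacing, fwhm) {
  if (all(fwhm <= 0)) return(arr)
  d <- dim(arr)
  for (ax in 1:3) {
    sigma <- fwhm[ax] / (2 * sqrt(2 * log(2))) / spacing[ax]  # in voxels
    if (sigma <= 0) next
    r <- max(1L, ceiling(4 * sigma))
    k <- exp(-0.5 * ((-r:r) / sigma)^2)
    k <- k / sum(k)
    n <- d[ax]
    ## banded convolution matrix with zero boundary
    B <- matrix(0, n, n)
    for (off in -r:r) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1L & j <= n
      B[cbind(i[ok], j[ok])] <- k[off + r + 1L]
    }
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(arr, perm), nrow = n)
    m <- B %*% m
    arr <- aperm(array(m, dim = d[perm]), order(perm))
  }
  arr
}

## run expr with a fixed RNG state, restoring the caller's state after
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Emulate a PET reconstruction of a ground-truth activity map
#'
#' The reconstruction chain is emulated as (1) a Gaussian resolution blur of
#' fwhm \code{sqrt(psfFwhm^2 + postFilterFwhm^2)} applied in world units on
#' the truth grid, (2) a linear resample onto the protocol's voxel grid
#' covering the truth field of view, and (3) multiplicative Gaussian voxel
#' noise at the protocol's coefficient of variation.  The noiseless chain
#' conserves total activity (world integral) to within 1% for structures
#' away from the field edge; the blur reproduces the partial volume effect
#' that depresses the apparent peak uptake of small lesions.
#'
#' @param truth an \code{"suv"} [ImageVolume-class].
#' @param protocol a [ReconstructionProtocol-class].
#' @param seed integer seed for the noise (reproducible); NULL uses the
#'   current RNG state.
#' @param targetGrid optional explicit reconstruction [GridSpec-class];
#'   default covers the truth extent at the protocol voxel size.
#' @return an \code{"suv"} [ImageVolume-class] on the protocol grid.
#' @export
emulateReconstruction <- function(truth, protocol, seed = NULL,
                                  targetGrid = NULL) {
  validObject(protocol)
  fwhm <- sqrt(protocol@psfFwhm^2 + protocol@postFilterFwhm^2)
  blurred <- .gaussian_blur(truth@values, truth@grid@spacing,
                            rep(fwhm, 3))
  bvol <- imageVolume(pmax(blurred, 0), truth@grid, "suv")
  if (is.null(targetGrid)) {
    ext <- gridExtent(truth@grid)
    targetGrid <- gridCovering(ext["lower", ], ext["upper", ],
                               protocol@voxelSize)
  }
  same_grid <- identical(as.integer(targetGrid@shape),
                         as.integer(truth@grid@shape)) &&
    all(abs(targetGrid@spacing - truth@grid@spacing) < 1e-12) &&
    all(abs(targetGrid@origin - truth@grid@origin) < 1e-12)
  recon <- if (same_grid) bvol else resampleVolume(bvol, targetGrid, "linear")
  if (protocol@noiseCV > 0) {
    noise <- .with_seed(seed,
      stats::rnorm(prod(targetGrid@shape), mean = 1, sd = protocol@noiseCV))
    recon@values[] <- pmax(recon@values * noise, 0)
  }
  recon
}

#' Response model constructor
#'
#' @param factors named numeric vector of per-lesion multiplicative activity
#'   changes (>= 0).
#' @param zeroRegions list of [LesionSpec-class] shapes whose voxels drop to
#'   background activity.
#' @return a [ResponseModel-class].
#' @export
responseModel <- function(factors = numeric(0), zeroRegions = list()) {
  new("ResponseModel", factors = factors, zeroRegions = zeroRegions)
}

#' Synthesize a virtual follow-up SUV map
#'
#' Applies a metabolic response to a baseline SUV map: each named lesion's
#' voxels are scaled by its factor and zero-response regions are reset to
#' the background level.  The grid is unchanged (no morphological changes
#' are modelled).
#'
#' @param baseline baseline \code{"suv"} [ImageVolume-class].
#' @param lesions the lesion list that defines named regions (masks are
#'   rasterized on the baseline grid).
#' @param response a [ResponseModel-class].
#' @param background background SUV used for zeroed regions (default 0).
#' @return an \code{"suv"} [ImageVolume-class] on the baseline grid.
#' @export
followUpSUV <- function(baseline, lesions, response, background = 0) {
  validObject(response)
  out <- baseline@values
  for (nm in names(response@factors)) {
    les <- Filter(function(l) l@name == nm, lesions)
    if (!length(les)) stop("response names unknown lesion: ", nm)
    m <- .rasterize_lesion(les[[1L]], baseline@grid)
    f <- response@factors[[nm]]
    out[m] <- background + f * (out[m] - background)
  }
  for (reg in response@zeroRegions) {
    m <- .rasterize_lesion(reg, baseline@grid)
    out[m] <- background
  }
  imageVolume(pmax(out, 0), baseline@grid, "suv")
}

## ---------------------------------------------------------------------------
## Default phantoms (the study conditions)
## ---------------------------------------------------------------------------

#' Tube phantom for the co-registration study
#'
#' Mirrors the anthropomorphic-phantom setup used for interpolation-chain
#' testing: a small 0.3 ml tube (V1) in the larynx area, and a second 0.3 ml
#' tube (V2) nested inside a 2.0 ml vial (V3) in the oral cavity to mimic a
#' lesion with heterogeneous uptake.  Activity concentrations follow the
#' filled activities (0.116 MBq in 0.3 ml vs 0.1 MBq in 2 ml), expressed in
#' SUV-like units with zero background.
#'
#' @return list with elements \code{lesions}, \code{outline} and the truth
#'   grid \code{grid} (1.52 x 1.52 x 1.5 mm, CT resolution).
#' @export
tubePhantom <- function() {
  ## concentrations: V1 = V2 = 0.116/0.3 = 0.387 MBq/ml, V3 = 0.05 MBq/ml;
  ## scaled so the hot tubes sit at SUV 10
  hot <- 10
  bg_vial <- hot * (0.1 / 2) / (0.116 / 0.3)
  lesions <- list(
    lesionSpec("V1", "sphere", c(-20, 35, 0), 4.153, activity = hot),
    lesionSpec("V3", "cylinder", c(25, -20, 0), c(5.6, 20.3),
               activity = bg_vial),
    lesionSpec("V2", "sphere", c(25, -20, 2), 4.153, activity = hot,
               inside = "V3"))
  grid <- gridCovering(c(-60, -60, -30), c(60, 60, 30), c(1.52, 1.52, 1.5))
  list(lesions = lesions,
       outline = bodyOutline(center = c(0, 0), semiAxes = c(58, 58)),
       grid = grid)
}

#' Head-and-neck-like planning phantom
#'
#' The default planning scenario: a biological target composed of three
#' separate lesions with distinct uptake levels (the largest carrying a hot
#' core, i.e. heterogeneous SUV), a spinal-cord-like organ at risk, and an
#' elliptic tissue outline.  The ground-truth grid is isotropic 1.5 mm.
#'
#' @return list with elements \code{lesions} (targets), \code{core} name of
#'   the nested hot core, \code{oar} (a [LesionSpec-class]-shaped cord
#'   region), \code{outline}, and \code{grid}.
#' @export
hnPhantom <- function() {
  lesions <- list(
    lesionSpec("L1", "sphere", c(-30, -10, -10), 9.8, activity = 8),
    lesionSpec("L1core", "sphere", c(-28, -8, -10), 5, activity = 12,
               inside = "L1"),
    lesionSpec("L2", "sphere", c(26, 14, 8), 7.8, activity = 6),
    lesionSpec("L3", "ellipsoid", c(8, -38, 16), c(6, 6, 9), activity = 10))
  oar <- lesionSpec("cord", "cylinder", c(0, 48, 0), c(10, 88),
                    activity = 1)   # activity unused; shape carrier only
  grid <- gridCovering(c(-66, -66, -45), c(66, 66, 45), c(1.5, 1.5, 1.5))
  list(lesions = lesions, core = "L1core", oar = oar,
       outline = bodyOutline(center = c(0, 0), semiAxes = c(68, 68)),
       grid = grid)
}
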