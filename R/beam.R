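## Beam geometry, ray-traced Boolean projections, MLC aperture generation,
## and the pencil-beam dose-influence engine.

#' Beam geometry constructor
#'
#' @param gantry gantry angle in degrees (rotation about the longitudinal z
#'   axis; 0 = beam travelling along -y).
#' @param isocenter world isocentre, mm.
#' @param sad source-axis distance, mm (used by the divergent projection
#'   mode).
#' @param pixelSize fluence-plane pixel size along the leaf-travel axis, mm.
#' @param leafWidth MLC leaf width along z, mm.
#' @return a [BeamGeometry-class].
#' @export
beamGeometry <- function(gantry, isocenter = c(0, 0, 0), sad = 1000,
                         pixelSize = 2, leafWidth = 5) {
  new("BeamGeometry", gantry = gantry, isocenter = as.numeric(isocenter),
      sad = sad, pixelSize = pixelSize, leafWidth = leafWidth)
}

#' Equispaced coplanar beam set
#'
#' @param n number of beams (default 7).
#' @param isocenter shared isocentre, mm.
#' @param ... passed to [beamGeometry()].
#' @return list of [BeamGeometry-class].
#' @export
beamSet <- function(n = 7L, isocenter = c(0, 0, 0), ...) {
  lapply(seq(0, 360, length.out = n + 1L)[seq_len(n)], beamGeometry,
         isocenter = isocenter, ...)
}

## beam unit axes: direction of travel, leaf-travel axis u, leaf-stack axis v
.beam_axes <- function(beam) {
  g <- beam@gantry * pi / 180
  list(dir = c(sin(g), -cos(g), 0),
       u = c(cos(g), sin(g), 0),
       v = c(0, 0, 1))
}

setMethod("show", "BeamGeometry", function(object) {
  cat(sprintf("BeamGeometry: gantry %.1f deg, iso (%s) mm, SAD %.0f mm\n",
              object@gantry, paste(format(object@isocenter), collapse = ", "),
              object@sad))
})

## fluence-plane raster shared by all structures of one (beam, grid) pair:
## u at beam pixelSize, v at leafWidth, covering the grid corners
.plane_raster <- function(beam, grid) {
  ax <- .beam_axes(beam)
  ext <- gridExtent(grid)
  corners <- as.matrix(expand.grid(ext[, 1L], ext[, 2L], ext[, 3L]))
  rel <- sweep(corners, 2L, beam@isocenter)
  u <- rel %*% ax$dir * 0 + rel %*% ax$u   # keep shapes aligned
  v <- rel %*% ax$v
  du <- beam@pixelSize; dv <- beam@leafWidth
  u0 <- floor(min(u) / du) * du - du
  v0 <- floor(min(v) / dv) * dv - dv
  nu <- ceiling((max(u) - u0) / du) + 2L
  nv <- ceiling((max(v) - v0) / dv) + 2L
  list(u0 = u0, v0 = v0, du = du, dv = dv, nu = as.integer(nu),
       nv = as.integer(nv))
}

#' Ray-traced projection of a volume onto a beam's fluence plane
#'
#' Computes parallel-ray line integrals of the volume along the beam
#' direction, rasterized on the fluence plane (pixel pitch: the beam's
#' fluence pixel size along the leaf-travel axis u, the leaf width along the
#' stacking axis v).  With \code{divergent = TRUE} voxel coordinates are
#' scaled to the isocentre plane by sad / (sad + depth) before binning.
#' Projections of masks are the Boolean building blocks of aperture
#' generation.
#'
#' @param vol an [ImageVolume-class] (any kind; typically a mask).
#' @param beam a [BeamGeometry-class].
#' @param divergent logical; default FALSE (parallel rays).
#' @return a [ProjectionMap-class]; values are line integrals in
#'   value x mm units.
#' @export
projectStructure <- function(vol, beam, divergent = FALSE) {
  ax <- .beam_axes(beam)
  pl <- .plane_raster(beam, vol@grid)
  w <- .grid_coords(vol@grid)
  rel <- sweep(w, 2L, beam@isocenter)
  u <- as.numeric(rel %*% ax$u)
  v <- as.numeric(rel %*% ax$v)
  if (divergent) {
    t <- as.numeric(rel %*% ax$dir)
    sc <- beam@sad / (beam@sad + t)
    u <- u * sc; v <- v * sc
  }
  vals <- as.numeric(vol@values)
  nzi <- which(vals != 0)
  proj <- matrix(0, pl$nu, pl$nv)
  if (length(nzi)) {
    ui <- pmin.int(pmax.int(floor((u[nzi] - pl$u0) / pl$du + 0.5) + 1L, 1L),
                   pl$nu)
    vi <- pmin.int(pmax.int(floor((v[nzi] - pl$v0) / pl$dv + 0.5) + 1L, 1L),
                   pl$nv)
    wgt <- vals[nzi] * voxelVolume(vol@grid) / (pl$du * pl$dv)
    acc <- rowsum(wgt, group = ui + (vi - 1L) * pl$nu)
    proj[as.integer(rownames(acc))] <- acc[, 1L]
  } else {
    warning("beam misses the structure entirely: empty projection")
  }
  new("ProjectionMap", beam = beam, values = proj, u0 = pl$u0, v0 = pl$v0,
      du = pl$du, dv = pl$dv)
}

## geometry fingerprint of an aperture (beam + leaf intervals to 0.1 mm);
## used to deduplicate pools during adaptive replanning
.aperture_key <- function(ap) {
  iv <- round(ap@intervals, 1)
  paste(ap@beam@gantry, paste(ap@beam@isocenter, collapse = ","),
        paste(ifelse(is.na(iv), "x", iv), collapse = "|"), sep = "@")
}

## binary 2-D dilation/erosion with a rectangle of world half-widths
## (r mm in u, r mm in v), expressed in pixels of the plane raster
.morph2 <- function(open, pl, rMm, dilate = TRUE) {
  if (rMm <= 0) return(open)
  ru <- max(0L, round(rMm / pl$du))
  rv <- max(0L, round(rMm / pl$dv))
  out <- if (dilate) open else !open
  acc <- out
  nr <- nrow(open); nc <- ncol(open)
  shift2 <- function(a, dx, dy) {
    o <- matrix(FALSE, nr, nc)
    xs <- max(1, 1 + dx):min(nr, nr + dx)
    ys <- max(1, 1 + dy):min(nc, nc + dy)
    o[xs, ys] <- a[xs - dx, ys - dy]
    o
  }
  for (dx in -ru:ru) for (dy in -rv:rv) {
    if (dx == 0 && dy == 0) next
    acc <- acc | shift2(out, dx, dy)
  }
  if (dilate) acc else !acc
}

## per-leaf-row open intervals (convex hull of open pixels per row);
## NA rows = closed
.intervals_from_open <- function(open, pl) {
  nv <- ncol(open)
  iv <- matrix(NA_real_, nv, 2L)
  ucent <- pl$u0 + (seq_len(nrow(open)) - 1L) * pl$du
  for (r in seq_len(nv)) {
    idx <- which(open[, r])
    if (!length(idx)) next
    iv[r, ] <- c(ucent[min(idx)] - pl$du / 2, ucent[max(idx)] + pl$du / 2)
  }
  iv
}

.aperture_from_open <- function(open, pl, beam, provenance, erodeMm = 0,
                                dilateMm = 0) {
  if (dilateMm > 0) open <- .morph2(open, pl, dilateMm, dilate = TRUE)
  if (erodeMm > 0) open <- .morph2(open, pl, erodeMm, dilate = FALSE)
  iv <- .intervals_from_open(open, pl)
  if (all(is.na(iv[, 1L]))) return(NULL)
  leafV <- pl$v0 + (seq_len(ncol(open)) - 1L) * pl$dv
  new("Aperture", beam = beam, intervals = iv, leafV = leafV,
      provenance = provenance)
}

#' Generate MLC apertures from prescription-band projections
#'
#' The aperture generator works on image information only: the prescribed-
#' dose map is quantized into nested dose bands (voxels at or above each of
#' \code{nBands} equally spaced dose thresholds), each band is ray-traced
#' onto every beam's fluence plane, organ-at-risk projections are optionally
#' subtracted (Boolean minus), and each projection row is collapsed to one
#' open leaf interval (the convex hull of its open pixels).  Per beam this
#' yields one conformal whole-target aperture (optionally dilated and eroded
#' copies) and one aperture per band (plus eroded copies), so a plan's
#' aperture count is
#' \code{nBeams x (1 + nErode + nDilate + (nBands - 1) x (1 + nErode))}.
#' Bands are nested by construction, so higher-band apertures are contained
#' in lower-band ones row by row.  Apertures whose opening closes completely
#' (e.g. after OAR blocking) are dropped with a message.
#'
#' @param rx a [RobustPrescription-class] or single [PrescriptionMap-class].
#' @param beams list of [BeamGeometry-class].
#' @param nBands number of dose bands (default 4).
#' @param rules list: \code{blockOAR} (subtract OAR projections from every
#'   opening; default FALSE), \code{erodeMm} (symmetric interval erosions to
#'   add as extra apertures; default c(2, 4, 6)), \code{dilateConformalMm}
#'   (dilated conformal copies covering the penumbra at the target edge;
#'   default c(3, 6)).
#' @param tag provenance prefix (e.g. the adaptive phase).
#' @return list of [Aperture-class].
#' @export
biomapApertures <- function(rx, beams, nBands = 4L,
                            rules = list(), tag = "") {
  rules <- utils::modifyList(list(blockOAR = FALSE, erodeMm = c(2, 4, 6),
                                  dilateConformalMm = c(3, 6)), rules)
  if (is(rx, "PrescriptionMap"))
    rx <- new("RobustPrescription", grid = rx@grid, maps = list(rx),
              oars = list(), unionMask = rx@mask,
              nT = as.integer(sum(rx@mask > 0)),
              n = as.integer(sum(rx@mask > 0)))
  grid <- rx@grid
  un <- rx@unionMask
  if (!any(un > 0)) stop("empty prescription: no target voxels")
  ## combined prescribed dose over the union target (max over maps)
  dose <- Reduce(pmax, lapply(rx@maps, slot, "dose"))
  don <- dose[un > 0]
  rng <- range(don)
  thr <- rng[1L] + (seq_len(nBands) - 1L) / nBands * (rng[2L] - rng[1L])
  pre <- if (nzchar(tag)) paste0(tag, "/") else ""
  out <- list()
  for (beam in beams) {
    pl <- .plane_raster(beam, grid)
    projOpen <- function(maskArr) {
      p <- projectStructure(imageVolume(maskArr * 1, grid, "mask"), beam)
      p@values > 0
    }
    oarOpen <- NULL
    if (isTRUE(rules$blockOAR) && length(rx@oars)) {
      oarOpen <- Reduce(`|`, lapply(rx@oars, function(o)
        projOpen(o@mask@values)))
    }
    addAp <- function(open, provenance, erode = 0, dilate = 0) {
      if (!is.null(oarOpen)) open <- open & !oarOpen
      ap <- .aperture_from_open(open, pl, beam, provenance, erodeMm = erode,
                                dilateMm = dilate)
      if (is.null(ap)) {
        message("dropping fully closed aperture: ", provenance,
                " (gantry ", beam@gantry, ")")
      } else out[[length(out) + 1L]] <<- ap
    }
    confOpen <- projOpen(un)
    addAp(confOpen, paste0(pre, "conformal"))
    for (dl in rules$dilateConformalMm)
      if (dl > 0) addAp(confOpen, paste0(pre, "conformal+", dl), dilate = dl)
    for (e in rules$erodeMm)
      addAp(confOpen, paste0(pre, "conformal-", e), erode = e)
    if (nBands > 1L) for (k in 2:nBands) {
      band <- array(dose >= thr[k] & un > 0, dim = grid@shape)
      if (!any(band)) next
      bandOpen <- projOpen(band)
      addAp(bandOpen, paste0(pre, "band", k))
      for (e in rules$erodeMm)
        addAp(bandOpen, paste0(pre, "band", k, "-", e), erode = e)
    }
  }
  out
}

## ---------------------------------------------------------------------------
## Pencil-beam dose engine
## ---------------------------------------------------------------------------

#' Pencil-beam kernel parameters
#'
#' A three-parameter kernel standing in for full transport: primary
#' attenuation \code{mu} (1/mm) applied to the density-weighted
#' (radiological) depth, a Gaussian lateral spread \code{sigma} (mm) that
#' models the penumbra, and a global \code{outputFactor} (Gy per unit weight
#' at zero depth under an open field).  Defaults give clinically shaped
#' depth and penumbra curves at megavoltage scale.
#'
#' @param mu linear attenuation per mm of unit-density tissue.
#' @param sigma lateral Gaussian spread, mm.
#' @param outputFactor dose scale, Gy per unit aperture weight.
#' @return a list used by the influence engine.
#' @export
pencilBeamKernel <- function(mu = 0.005, sigma = 4, outputFactor = 1) {
  stopifnot(mu >= 0, sigma > 0, outputFactor > 0)
  list(mu = mu, sigma = sigma, outputFactor = outputFactor)
}

## trilinear sampler on an axis-aligned lattice given by (origin, spacing,
## shape); points outside take 0
.interp3 <- function(vals, origin, spacing, shape, pts) {
  d <- as.integer(shape)
  fx <- (pts[, 1L] - origin[1L]) / spacing[1L] + 1
  fy <- (pts[, 2L] - origin[2L]) / spacing[2L] + 1
  fz <- (pts[, 3L] - origin[3L]) / spacing[3L] + 1
  x0 <- floor(fx); y0 <- floor(fy); z0 <- floor(fz)
  tx <- fx - x0; ty <- fy - y0; tz <- fz - z0
  acc <- numeric(nrow(pts))
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
    wgt <- (if (ox) tx else 1 - tx) * (if (oy) ty else 1 - ty) *
           (if (oz) tz else 1 - tz)
    nz <- which(wgt > 0)
    if (!length(nz)) next
    acc[nz] <- acc[nz] + wgt[nz] *
      .gather(vals, d, as.integer(x0[nz]) + ox, as.integer(y0[nz]) + oy,
              as.integer(z0[nz]) + oz)
  }
  acc
}

## per-beam precomputation shared by all apertures of that beam:
## radiological depth and fluence-plane coordinates of every dose voxel
.beam_context <- function(beam, ct, doseGrid, kernel, step = 2) {
  ax <- .beam_axes(beam)
  ext <- gridExtent(ct@grid)
  corners <- as.matrix(expand.grid(ext[, 1L], ext[, 2L], ext[, 3L]))
  rel <- sweep(corners, 2L, beam@isocenter)
  cu <- rel %*% ax$u; ct_ <- rel %*% ax$dir; cv <- rel %*% ax$v
  ## beam-aligned lattice (u, t, v)
  sp <- c(beam@pixelSize, step, step)
  o <- c(min(cu) - sp[1L], min(ct_) - sp[2L], min(cv) - sp[3L])
  hi <- c(max(cu) + sp[1L], max(ct_) + sp[2L], max(cv) + sp[3L])
  sh <- pmax(2L, as.integer(ceiling((hi - o) / sp)) + 1L)
  iu <- o[1L] + (seq_len(sh[1L]) - 1L) * sp[1L]
  it <- o[2L] + (seq_len(sh[2L]) - 1L) * sp[2L]
  iv <- o[3L] + (seq_len(sh[3L]) - 1L) * sp[3L]
  pts <- cbind(rep(iu, times = sh[2L] * sh[3L]),
               rep(rep(it, each = sh[1L]), times = sh[3L]),
               rep(iv, each = sh[1L] * sh[2L]))
  world <- sweep(pts[, 1L] %o% ax$u + pts[, 2L] %o% ax$dir +
                 pts[, 3L] %o% ax$v, 2L, -beam@isocenter)
  dens <- .interp3(ct@values, ct@grid@origin, ct@grid@spacing,
                   ct@grid@shape, world)
  dens <- array(dens, dim = sh)
  ## cumulative density-weighted path length along t (beam travel)
  depth <- aperm(apply(dens, c(1L, 3L), cumsum), c(2L, 1L, 3L)) * sp[2L]
  ## dose-voxel coordinates in the beam frame
  wd <- .grid_coords(doseGrid)
  reld <- sweep(wd, 2L, beam@isocenter)
  du <- as.numeric(reld %*% ax$u)
  dt <- as.numeric(reld %*% ax$dir)
  dv <- as.numeric(reld %*% ax$v)
  vdepth <- .interp3(depth, o, sp, sh, cbind(du, dt, dv))
  list(beam = beam, u = du, v = dv, depth = vdepth,
       attn = exp(-kernel$mu * vdepth))
}

## blurred open-fluence lookup for one aperture: raster the leaf intervals
## on a fine (u, v) plane, blur with the lateral Gaussian, then sample at
## the dose-voxel plane coordinates
.aperture_fluence <- function(aperture, kernel, u, v) {
  iv <- aperture@intervals
  open_rows <- which(!is.na(iv[, 1L]))
  if (!length(open_rows)) return(numeric(length(u)))
  px <- min(aperture@beam@pixelSize, kernel$sigma / 2)
  pad <- 4 * kernel$sigma
  u0 <- min(iv[open_rows, 1L]) - pad
  u1 <- max(iv[open_rows, 2L]) + pad
  lw <- aperture@beam@leafWidth
  v0 <- min(aperture@leafV[open_rows]) - lw / 2 - pad
  v1 <- max(aperture@leafV[open_rows]) + lw / 2 + pad
  nu <- as.integer(ceiling((u1 - u0) / px)) + 1L
  nv <- as.integer(ceiling((v1 - v0) / px)) + 1L
  uc <- u0 + (seq_len(nu) - 1L) * px
  vc <- v0 + (seq_len(nv) - 1L) * px
  F <- matrix(0, nu, nv)
  for (r in open_rows) {
    rows_v <- which(vc >= aperture@leafV[r] - lw / 2 &
                    vc < aperture@leafV[r] + lw / 2)
    if (!length(rows_v)) next
    cols_u <- which(uc >= iv[r, 1L] & uc <= iv[r, 2L])
    F[cols_u, rows_v] <- 1
  }
  ## separable Gaussian blur (sigma in mm -> pixels)
  s <- kernel$sigma / px
  r <- max(1L, ceiling(4 * s))
  k <- exp(-0.5 * ((-r:r) / s)^2); k <- k / sum(k)
  F <- apply(F, 2L, function(col) stats::filter(c(numeric(r), col,
             numeric(r)), k, sides = 2L)[(r + 1L):(r + length(col))])
  F <- t(apply(F, 1L, function(row) stats::filter(c(numeric(r), row,
             numeric(r)), k, sides = 2L)[(r + 1L):(r + length(row))]))
  F[is.na(F)] <- 0
  ## bilinear sample at the voxel plane coordinates
  .interp3(array(F, dim = c(nu, nv, 1L)), c(u0, v0, 0), c(px, px, 1),
           c(nu, nv, 1L), cbind(u, v, 0))
}

#' Dose column of one aperture (pencil-beam engine)
#'
#' Dose per unit weight at every dose-grid voxel for one aperture: the
#' aperture opening is rasterized and blurred with the lateral Gaussian,
#' sampled at each voxel's fluence-plane coordinates, and attenuated with
#' \code{exp(-mu x radiological depth)} where the radiological depth is the
#' density-weighted path length from the patient surface to the voxel along
#' the beam.  Entries below 1e-6 of the column maximum are truncated to
#' keep the column sparse.
#'
#' @param aperture an [Aperture-class].
#' @param ct a \code{"ct-density"} [ImageVolume-class] covering the dose
#'   grid.
#' @param doseGrid dose [GridSpec-class].
#' @param kernel a [pencilBeamKernel()].
#' @param context optional precomputed beam context (internal reuse).
#' @return sparse numeric column (\code{Matrix::sparseVector}-like dense
#'   numeric with zeros; assembled sparse by [buildInfluenceMatrix()]).
#' @export
pencilBeamColumn <- function(aperture, ct, doseGrid,
                             kernel = pencilBeamKernel(), context = NULL) {
  if (is.null(context))
    context <- .beam_context(aperture@beam, ct, doseGrid, kernel)
  fl <- .aperture_fluence(aperture, kernel, context$u, context$v)
  col <- kernel$outputFactor * context$attn * fl
  mx <- max(col)
  if (mx > 0) col[col < 1e-6 * mx] <- 0
  col
}

#' Build the sparse dose-influence matrix
#'
#' Computes the pencil-beam dose column of every aperture and assembles the
#' aperture-by-voxel influence matrix d_ij.  Apertures whose column is
#' entirely zero (the beam misses the dose grid) are removed with a message
#' and the column indices compacted.
#'
#' @param apertureList list of [Aperture-class].
#' @param ct CT density [ImageVolume-class].
#' @param doseGrid dose [GridSpec-class].
#' @param kernel a [pencilBeamKernel()].
#' @return a [DoseInfluenceMatrix-class].
#' @export
buildInfluenceMatrix <- function(apertureList, ct, doseGrid,
                                 kernel = pencilBeamKernel()) {
  if (!length(apertureList)) stop("at least one aperture is required")
  key <- vapply(apertureList, function(a)
    paste(a@beam@gantry, paste(a@beam@isocenter, collapse = ","), sep = "@"),
    character(1))
  cols <- vector("list", length(apertureList))
  for (k in unique(key)) {
    idx <- which(key == k)
    ctx <- .beam_context(apertureList[[idx[1L]]]@beam, ct, doseGrid, kernel)
    for (i in idx)
      cols[[i]] <- pencilBeamColumn(apertureList[[i]], ct, doseGrid, kernel,
                                    context = ctx)
  }
  keep <- vapply(cols, function(x) any(x > 0), logical(1))
  if (!all(keep)) {
    message("removed ", sum(!keep), " aperture(s) with empty dose columns")
    cols <- cols[keep]
    apertureList <- apertureList[keep]
  }
  if (!length(cols)) stop("all aperture columns are empty")
  nv <- prod(doseGrid@shape)
  ii <- unlist(lapply(cols, function(x) which(x > 0)))
  jj <- rep(seq_along(cols), times = vapply(cols, function(x) sum(x > 0),
                                            integer(1)))
  xx <- unlist(lapply(cols, function(x) x[x > 0]))
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nv, length(cols)))
  new("DoseInfluenceMatrix", matrix = m, grid = doseGrid,
      apertures = apertureList)
}

#' @export
setMethod("apertures", "DoseInfluenceMatrix", function(x) x@apertures)

setMethod("show", "DoseInfluenceMatrix", function(object) {
  cat(sprintf(
    "DoseInfluenceMatrix: %d voxels x %d apertures, %.2f%% non-zero\n",
    nrow(object@matrix), ncol(object@matrix),
    100 * length(object@matrix@x) / prod(dim(object@matrix))))
})

setMethod("show", "Aperture", function(object) {
  open <- sum(!is.na(object@intervals[, 1L]))
  cat(sprintf("Aperture [%s]: gantry %.1f deg, %d open leaf pair(s)\n",
              object@provenance, object@beam@gantry, open))
})
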