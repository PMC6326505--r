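## Voxel-grid data model: constructors, accessors, world mapping, resampling.

#' Create a grid specification
#'
#' @param shape voxels per axis, 3 integers.
#' @param spacing mm per axis, 3 positive reals.
#' @param origin world coordinate (mm) of the centre of voxel (0, 0, 0).
#' @return a [GridSpec-class].
#' @examples
#' g <- gridSpecNew(c(64, 64, 32), c(2, 2, 3))
#' @export
gridSpecNew <- function(shape, spacing, origin = c(0, 0, 0)) {
  new("GridSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Create an image volume
#'
#' @param values numeric array conforming to the grid shape (a scalar is
#'   recycled).
#' @param grid a [GridSpec-class].
#' @param kind volume kind; see [ImageVolume-class].
#' @return an [ImageVolume-class].
#' @export
imageVolume <- function(values, grid, kind) {
  if (length(values) == 1L)
    values <- array(values, dim = grid@shape)
  if (is.null(dim(values)))
    stop("values must be a 3-D array")
  if (!identical(as.integer(dim(values)), as.integer(grid@shape)))
    stop("values array does not conform to grid shape")
  new("ImageVolume", grid = grid, values = array(as.numeric(values),
      dim = grid@shape), kind = kind)
}

#' @describeIn gridSpecNew grid of an image volume
#' @param x an object with a grid.
#' @export
setMethod("gridSpec", "ImageVolume", function(x) x@grid)

#' @export
setMethod("gridSpec", "PrescriptionMap", function(x) x@grid)

#' @export
setMethod("gridSpec", "RobustPrescription", function(x) x@grid)

#' @export
setMethod("gridSpec", "DoseInfluenceMatrix", function(x) x@grid)

#' @export
setMethod("voxelData", "ImageVolume", function(x) x@values)

#' @export
setMethod("volumeKind", "ImageVolume", function(x) x@kind)

#' Voxel volume in mm^3
#' @param x a [GridSpec-class] or [ImageVolume-class].
#' @export
setMethod("voxelVolume", "GridSpec", function(x) prod(x@spacing))

#' @export
setMethod("voxelVolume", "ImageVolume", function(x) prod(x@grid@spacing))

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %s voxels, %s mm spacing, origin (%s) mm\n",
              paste(object@shape, collapse = "x"),
              paste(format(object@spacing), collapse = "x"),
              paste(format(object@origin), collapse = ", ")))
})

setMethod("show", "ImageVolume", function(object) {
  v <- object@values
  cat(sprintf("ImageVolume <%s>: %s voxels @ %s mm, range [%.4g, %.4g]\n",
              object@kind, paste(object@grid@shape, collapse = "x"),
              paste(format(object@grid@spacing), collapse = "x"),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
})

#' World coordinates of all voxel centres
#'
#' Returns the world coordinate of every voxel centre along one axis, in
#' array order, or the full coordinate arrays.
#'
#' @param grid a [GridSpec-class].
#' @param axis 1, 2 or 3.
#' @return numeric vector of length \code{shape[axis]}.
#' @export
axisCoords <- function(grid, axis) {
  grid@origin[axis] + (seq_len(grid@shape[axis]) - 1) * grid@spacing[axis]
}

## world coords (n x 3) of every voxel centre, array order
.grid_coords <- function(grid) {
  cbind(rep(axisCoords(grid, 1L), times = prod(grid@shape[2:3])),
        rep(rep(axisCoords(grid, 2L), each = grid@shape[1L]),
            times = grid@shape[3L]),
        rep(axisCoords(grid, 3L), each = prod(grid@shape[1:2])))
}

#' Physical extent of a grid
#'
#' Lower and upper world coordinates of the voxel-centre bounding box.
#'
#' @param grid a [GridSpec-class].
#' @return 2 x 3 matrix (rows: lower, upper).
#' @export
gridExtent <- function(grid) {
  lo <- grid@origin
  hi <- grid@origin + (grid@shape - 1L) * grid@spacing
  rbind(lower = lo, upper = hi)
}

#' Build a grid covering a world-space box
#'
#' @param lower,upper world corners in mm.
#' @param spacing voxel size in mm.
#' @return a [GridSpec-class] whose voxel-centre lattice covers the box.
#' @export
gridCovering <- function(lower, upper, spacing) {
  shape <- pmax(1L, as.integer(ceiling((upper - lower) / spacing)) + 1L)
  gridSpecNew(shape, spacing, origin = lower)
}

## ---------------------------------------------------------------------------
## Resampling
## ---------------------------------------------------------------------------

## mirror (whole-sample symmetric) index reflection into 1..n
.mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  i <- (i - 1L) %% p
  i <- ifelse(i >= n, p - i, i)
  i + 1L
}

## cubic B-spline prefilter along one axis: solve the tridiagonal system
## (1/6, 4/6, 1/6) with mirror boundary for every line at once
.bspline_prefilter_axis <- function(arr, axis) {
  d <- dim(arr)
  n <- d[axis]
  if (n == 1L) return(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = n)
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- 4 / 6
  A[cbind(2:n, 1:(n - 1))] <- 1 / 6
  A[cbind(1:(n - 1), 2:n)] <- 1 / 6
  ## mirror boundary: the off-grid neighbour of row 1 is sample 2
  A[1L, 2L] <- A[1L, 2L] + 1 / 6
  A[n, n - 1L] <- A[n, n - 1L] + 1 / 6
  m <- solve(A, m)
  aperm(array(m, dim = d[perm]), order(perm))
}

## cubic B-spline kernel on |t| <= 2
.bspline3 <- function(t) {
  at <- abs(t)
  ifelse(at < 1, (4 - 6 * at^2 + 3 * at^3) / 6,
         ifelse(at < 2, (2 - at)^3 / 6, 0))
}

## gather values at (possibly out-of-range) integer indices, 0 outside
.gather <- function(vals, d, ii, jj, kk) {
  ok <- ii >= 1L & ii <= d[1L] & jj >= 1L & jj <= d[2L] & kk >= 1L & kk <= d[3L]
  out <- numeric(length(ii))
  idx <- ii[ok] + (jj[ok] - 1L) * d[1L] + (kk[ok] - 1L) * (d[1L] * d[2L])
  out[ok] <- vals[idx]
  out
}

#' Resample a volume onto another grid
#'
#' Samples the source volume at the world coordinates of the target grid's
#' voxel centres.  Three interpolation methods are available:
#' \code{"nearest"} (nearest neighbour), \code{"linear"} (trilinear) and
#' \code{"cubic-spline"} (tricubic B-spline with tridiagonal prefilter and
#' mirror boundary; exactly interpolating at the source nodes).  Points
#' outside the source voxel-centre extent take the fill value 0.
#'
#' Mask volumes resampled with a smoothing method come back fractional; the
#' result is re-labelled kind \code{"suv"}-agnostic only when needed - here
#' the output keeps the input kind except that non-nearest resampling of a
#' mask returns kind \code{"dose-Gy"}-free fractional values as kind
#' \code{"suv"} would be wrong, so fractional mask output is returned with
#' kind \code{"q-index"} (unconstrained).  Use \code{"nearest"} to keep
#' binary masks binary.
#'
#' @param vol source [ImageVolume-class].
#' @param target target [GridSpec-class].
#' @param method \code{"linear"}, \code{"nearest"} or \code{"cubic-spline"}.
#' @return an [ImageVolume-class] on \code{target}.
#' @examples
#' g <- gridSpecNew(c(8, 8, 8), c(2, 2, 2))
#' v <- imageVolume(array(runif(512), c(8, 8, 8)), g, "suv")
#' identicalBack <- resampleVolume(v, g, "cubic-spline")
#' max(abs(voxelData(identicalBack) - voxelData(v))) < 1e-9
#' @export
resampleVolume <- function(vol, target,
                           method = c("linear", "nearest", "cubic-spline")) {
  method <- match.arg(method)
  src <- vol@grid
  ext_s <- gridExtent(src); ext_t <- gridExtent(target)
  if (any(ext_t["lower", ] > ext_s["upper", ]) ||
      any(ext_t["upper", ] < ext_s["lower", ]))
    stop("physical extents of source and target grids do not overlap")
  d <- as.integer(src@shape)
  ## continuous 1-based source index of each target voxel centre
  w <- .grid_coords(target)
  fx <- (w[, 1L] - src@origin[1L]) / src@spacing[1L] + 1
  fy <- (w[, 2L] - src@origin[2L]) / src@spacing[2L] + 1
  fz <- (w[, 3L] - src@origin[3L]) / src@spacing[3L] + 1
  eps <- 1e-9
  inside <- fx >= 1 - eps & fx <= d[1L] + eps &
            fy >= 1 - eps & fy <= d[2L] + eps &
            fz >= 1 - eps & fz <= d[3L] + eps
  out <- numeric(length(fx))
  vals <- vol@values
  if (method == "nearest") {
    ii <- pmin.int(pmax.int(round(fx), 1L), d[1L])
    jj <- pmin.int(pmax.int(round(fy), 1L), d[2L])
    kk <- pmin.int(pmax.int(round(fz), 1L), d[3L])
    out[inside] <- .gather(vals, d, ii, jj, kk)[inside]
  } else if (method == "linear") {
    x0 <- floor(fx); y0 <- floor(fy); z0 <- floor(fz)
    tx <- fx - x0; ty <- fy - y0; tz <- fz - z0
    acc <- numeric(length(fx))
    for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
      wgt <- (if (ox) tx else 1 - tx) * (if (oy) ty else 1 - ty) *
             (if (oz) tz else 1 - tz)
      nz <- wgt > 0
      if (!any(nz)) next
      acc[nz] <- acc[nz] + wgt[nz] *
        .gather(vals, d, as.integer(x0[nz]) + ox, as.integer(y0[nz]) + oy,
                as.integer(z0[nz]) + oz)
    }
    out[inside] <- acc[inside]
  } else {
    coef <- vals
    for (ax in 1:3) coef <- .bspline_prefilter_axis(coef, ax)
    x0 <- floor(fx); y0 <- floor(fy); z0 <- floor(fz)
    acc <- numeric(length(fx))
    for (ox in -1:2) for (oy in -1:2) for (oz in -1:2) {
      wgt <- .bspline3(fx - (x0 + ox)) * .bspline3(fy - (y0 + oy)) *
             .bspline3(fz - (z0 + oz))
      nz <- which(wgt > 0)
      if (!length(nz)) next
      ii <- .mirror_index(as.integer(x0[nz]) + ox, d[1L])
      jj <- .mirror_index(as.integer(y0[nz]) + oy, d[2L])
      kk <- .mirror_index(as.integer(z0[nz]) + oz, d[3L])
      idx <- ii + (jj - 1L) * d[1L] + (kk - 1L) * (d[1L] * d[2L])
      acc[nz] <- acc[nz] + wgt[nz] * coef[idx]
    }
    out[inside] <- acc[inside]
  }
  kind <- vol@kind
  if (kind == "mask" && method != "nearest")
    kind <- "q-index"   # fractional occupancy, unconstrained values
  if (kind %in% c("suv", "dose-Gy", "ct-density"))
    out[out < 0] <- 0   # clip interpolation undershoot for physical fields
  imageVolume(array(out, dim = target@shape), target, kind)
}

#' Measure the volume of a binary mask
#'
#' @param x a mask [ImageVolume-class].
#' @return volume in millilitres: (number of 1-voxels) x (voxel volume in
#'   mm^3) / 1000.
#' @examples
#' g <- gridSpecNew(c(10, 10, 10), c(1, 1, 1))
#' m <- imageVolume(array(1, c(10, 10, 10)), g, "mask")
#' measureVolume(m)  # 1 ml
#' @export
setMethod("measureVolume", "ImageVolume", function(x) {
  if (x@kind != "mask") stop("measureVolume expects a mask volume")
  sum(x@values) * voxelVolume(x) / 1000
})
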