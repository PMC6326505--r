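## Plan-quality evaluation: quality-index maps and histograms, quality
## factor, tolerance fractions, DVH, conformity index, isodose masks.

.mask_values <- function(mask) {
  if (is(mask, "ImageVolume")) mask@values else mask
}

#' Quality-index map
#'
#' Q_i = planned dose / prescribed dose per target voxel; 1 is ideal.
#' Off-target voxels are NA.
#'
#' @param dose planned dose [ImageVolume-class].
#' @param rx a [PrescriptionMap-class] on the same grid.
#' @return a \code{"q-index"} [ImageVolume-class].
#' @export
qMap <- function(dose, rx) {
  if (!identical(as.integer(dose@grid@shape), as.integer(rx@grid@shape)))
    stop("dose and prescription must share a grid")
  on <- rx@mask > 0
  if (any(rx@dose[on] <= 0))
    stop("zero prescribed dose on a target voxel")
  q <- array(NA_real_, dim = dose@grid@shape)
  q[on] <- dose@values[on] / rx@dose[on]
  imageVolume(q, dose@grid, "q-index")
}

#' Quality-volume histogram
#'
#' Cumulative fraction of target voxels with Q at or above each bin edge;
#' the curve starts at 100% and is monotone non-increasing.
#'
#' @param q a \code{"q-index"} [ImageVolume-class] (NA off target) or array.
#' @param mask target mask; default: all non-NA q voxels.
#' @param binWidth histogram bin width in Q units (default 0.01).
#' @return data.frame with columns \code{q} and \code{pct}.
#' @export
qvh <- function(q, mask = NULL, binWidth = 0.01) {
  qv <- if (is(q, "ImageVolume")) q@values else q
  sel <- if (is.null(mask)) !is.na(qv) else .mask_values(mask) > 0
  vals <- qv[sel]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("empty mask: no Q values to histogram")
  edges <- seq(0, max(vals) + binWidth, by = binWidth)
  pct <- vapply(edges, function(e) 100 * mean(vals >= e), numeric(1))
  data.frame(q = edges, pct = pct)
}

#' Quality factor
#'
#' QF = 100 x mean |Q - 1| over target voxels, in percent.
#'
#' @inheritParams qvh
#' @return percent.
#' @export
qf <- function(q, mask = NULL) {
  qv <- if (is(q, "ImageVolume")) q@values else q
  sel <- if (is.null(mask)) !is.na(qv) else .mask_values(mask) > 0
  vals <- qv[sel]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("empty mask")
  100 * mean(abs(vals - 1))
}

#' Fraction of target voxels within a Q tolerance
#'
#' Percent of target voxels with 1 - tol < Q < 1 + tol (strict
#' inequalities).
#'
#' @inheritParams qvh
#' @param tol tolerance around 1 (e.g. 0.03, 0.04, 0.05).
#' @return percent.
#' @export
fractionWithin <- function(q, mask = NULL, tol = 0.05) {
  qv <- if (is(q, "ImageVolume")) q@values else q
  sel <- if (is.null(mask)) !is.na(qv) else .mask_values(mask) > 0
  vals <- qv[sel]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("empty mask")
  100 * mean(vals > 1 - tol & vals < 1 + tol)
}

#' Cumulative dose-volume histogram
#'
#' V(d) = percent of structure voxels receiving at least dose d.
#'
#' @param dose dose [ImageVolume-class].
#' @param mask structure mask.
#' @param binWidth dose bin width in Gy (default 0.1).
#' @return data.frame with columns \code{dose} and \code{pct}.
#' @export
dvh <- function(dose, mask, binWidth = 0.1) {
  m <- .mask_values(mask) > 0
  if (!any(m)) stop("empty mask")
  vals <- dose@values[m]
  edges <- seq(0, max(vals) + binWidth, by = binWidth)
  data.frame(dose = edges,
             pct = vapply(edges, function(e) 100 * mean(vals >= e),
                          numeric(1)))
}

#' Conformity index
#'
#' Fraction (percent) of the structure covered by the reference isodose,
#' applied per voxel: a voxel counts as covered when its dose reaches
#' \code{refFraction} of its own prescribed dose (95% by default).  The
#' coverage reading keeps CI within [0, 100] for heterogeneous
#' prescriptions.
#'
#' @param dose planned dose [ImageVolume-class].
#' @param rx a [PrescriptionMap-class] providing the per-voxel prescription.
#' @param mask structure mask (default: the map's target).  Voxels without
#'   a prescribed dose use the map's minimum prescription as reference.
#' @param refFraction reference isodose fraction (default 0.95).
#' @return percent in [0, 100].
#' @export
conformityIndex <- function(dose, rx, mask = NULL, refFraction = 0.95) {
  m <- if (is.null(mask)) rx@mask > 0 else .mask_values(mask) > 0
  if (!any(m)) stop("empty structure mask")
  ref <- rx@dose
  base <- min(rx@dose[rx@mask > 0])
  ref[ref <= 0] <- base
  100 * mean(dose@values[m] >= refFraction * ref[m])
}

#' Isodose mask
#'
#' Voxels receiving at least \code{levelPercent} of the reference dose
#' (by convention the minimum prescription value, 70 Gy by default).
#'
#' @param dose dose [ImageVolume-class].
#' @param levelPercent isodose level in percent.
#' @param referenceDose reference dose in Gy.
#' @return a mask [ImageVolume-class].
#' @export
isodoseMask <- function(dose, levelPercent, referenceDose = 70) {
  imageVolume((dose@values >= levelPercent / 100 * referenceDose) * 1,
              dose@grid, "mask")
}

#' Full plan-quality report
#'
#' Computes the Q map, QVH, QF, the 3/4/5% tolerance fractions, per-
#' structure DVHs and conformity indices in one pass.
#'
#' @param dose planned dose [ImageVolume-class].
#' @param rx [PrescriptionMap-class] the plan is evaluated against.
#' @param structures named list of masks for DVH/CI evaluation (defaults to
#'   the target plus the map's BTV levels, if any).
#' @param qvhBinWidth,dvhBinWidth histogram bin widths.
#' @return a [QualityReport-class].
#' @export
qualityReport <- function(dose, rx, structures = NULL, qvhBinWidth = 0.01,
                          dvhBinWidth = 0.1) {
  q <- qMap(dose, rx)
  if (is.null(structures)) {
    structures <- c(list(target = rx@mask), rx@levels)
  }
  within <- c(`3%` = fractionWithin(q, tol = 0.03),
              `4%` = fractionWithin(q, tol = 0.04),
              `5%` = fractionWithin(q, tol = 0.05))
  dvhs <- lapply(structures, function(m) dvh(dose, m, dvhBinWidth))
  cis <- vapply(structures, function(m)
    conformityIndex(dose, rx, mask = m), numeric(1))
  new("QualityReport", qMap = q, qvh = qvh(q, binWidth = qvhBinWidth),
      qf = qf(q), within = within, dvh = dvhs, ci = cis)
}

#' @export
setMethod("qualityFactor", "QualityReport", function(x) x@qf)

setMethod("show", "QualityReport", function(object) {
  cat("QualityReport\n")
  cat(sprintf("  QF: %.2f%%\n", object@qf))
  cat(sprintf("  Q within 3/4/5%%: %.1f%% / %.1f%% / %.1f%%\n",
              object@within[1L], object@within[2L], object@within[3L]))
  if (length(object@ci))
    cat(sprintf("  CI: %s\n", paste(sprintf("%s %.1f%%", names(object@ci),
                                            object@ci), collapse = ", ")))
})
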