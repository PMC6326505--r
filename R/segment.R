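## Threshold segmentation of SUV maps with 26-connectivity components.

## 3-D connected-component labelling, 26-connectivity, by iterative
## minimum-label propagation (converges in O(component diameter) sweeps).
.label_components_26 <- function(fg) {
  d <- dim(fg)
  lab <- array(0, dim = d)
  lab[fg] <- which(fg)
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offsets <- offsets[!(offsets$dx == 0 & offsets$dy == 0 & offsets$dz == 0), ]
  shift3 <- function(a, dx, dy, dz) {
    out <- array(0, dim = d)
    xs <- max(1, 1 + dx):min(d[1L], d[1L] + dx)
    ys <- max(1, 1 + dy):min(d[2L], d[2L] + dy)
    zs <- max(1, 1 + dz):min(d[3L], d[3L] + dz)
    out[xs, ys, zs] <- a[xs - dx, ys - dy, zs - dz]
    out
  }
  repeat {
    newlab <- lab
    for (r in seq_len(nrow(offsets))) {
      s <- shift3(lab, offsets$dx[r], offsets$dy[r], offsets$dz[r])
      upd <- fg & s > 0 & (newlab == 0 | s < newlab)
      newlab[upd] <- s[upd]
    }
    if (identical(newlab, lab)) break
    lab <- newlab
  }
  ## compact labels to 1..k
  u <- sort(unique(lab[lab > 0]))
  relab <- array(0L, dim = d)
  relab[lab > 0] <- match(lab[lab > 0], u)
  relab
}

#' Segment a biological target from an SUV map
#'
#' Thresholds the SUV map at a fraction of its maximum and removes connected
#' components (26-connectivity) smaller than a voxel-count floor.  This is a
#' deliberately simple stand-in for semi-automatic PET segmentation
#' algorithms; the threshold fraction is the only tuning parameter.
#'
#' @param suv an \code{"suv"} [ImageVolume-class].
#' @param thresholdFraction fraction of the maximum SUV in (0, 1); default
#'   0.4 (the common 40%-of-max PET rule).
#' @param minComponentVoxels components smaller than this are discarded.
#' @return a [SegmentationResult-class].
#' @examples
#' ph <- tubePhantom()
#' suv <- makeActivityTruth(ph$lesions, ph$grid)
#' seg <- segmentSUV(suv, 0.5)
#' seg@nComponents
#' @export
segmentSUV <- function(suv, thresholdFraction = 0.4, minComponentVoxels = 1L) {
  if (thresholdFraction <= 0 || thresholdFraction >= 1)
    stop("thresholdFraction must lie in (0, 1)")
  mx <- max(suv@values)
  if (mx <= 0)
    stop(structure(class = c("paintboxEmptySegmentation", "error",
                             "condition"),
                   list(message = "SUV map is identically zero: empty segmentation",
                        call = sys.call())))
  thr <- thresholdFraction * mx
  fg <- suv@values >= thr
  lab <- .label_components_26(fg)
  if (minComponentVoxels > 1L && any(lab > 0)) {
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < minComponentVoxels)
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
      keep <- sort(unique(lab[lab > 0]))
      lab[lab > 0] <- match(lab[lab > 0], keep)
    }
  }
  mask <- imageVolume((lab > 0) * 1, suv@grid, "mask")
  new("SegmentationResult", mask = mask, threshold = thr,
      nComponents = as.integer(max(lab)), labels = lab)
}

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf(
    "SegmentationResult: %d component(s), threshold %.3g, volume %.3g ml\n",
    object@nComponents, object@threshold, measureVolume(object@mask)))
})
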