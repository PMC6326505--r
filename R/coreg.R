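## Interpolation-chain study: how resampling PET -> CT -> dose grid
## distorts segmented volumes of known lesions.

## measured volume (ml) of one lesion on an SUV volume: threshold at
## `fraction` of the lesion's observed peak (max SUV within `peakRadius`
## mm of its centre - the usual adaptive-threshold PET rule, robust to the
## partial-volume depression of small objects) and keep the 26-connected
## component containing (or nearest to) the lesion centre
.measure_lesion <- function(suv, level, center, fraction = 0.5,
                            peakRadius = 8) {
  w <- .grid_coords(suv@grid)
  near <- (w[, 1L] - center[1L])^2 + (w[, 2L] - center[2L])^2 +
          (w[, 3L] - center[3L])^2 <= peakRadius^2
  peak <- if (any(near)) max(suv@values[near]) else max(suv@values)
  peak <- min(peak, level)   # never above the nominal fill level
  if (peak <= 0) return(0)
  fg <- suv@values >= fraction * peak
  if (!any(fg)) return(0)
  lab <- .label_components_26(fg)
  g <- suv@grid
  ci <- pmin(pmax(round((center - g@origin) / g@spacing) + 1, 1), g@shape)
  l0 <- lab[ci[1L], ci[2L], ci[3L]]
  if (l0 == 0) {
    ## nearest foreground voxel to the centre
    idx <- which(lab > 0)
    co <- .grid_coords(g)[idx, , drop = FALSE]
    d2 <- (co[, 1L] - center[1L])^2 + (co[, 2L] - center[2L])^2 +
          (co[, 3L] - center[3L])^2
    l0 <- lab[idx[which.min(d2)]]
  }
  sum(lab == l0) * voxelVolume(g) / 1000
}

#' Interpolation-chain co-registration study
#'
#' Quantifies how the two-stage resampling chain (PET grid to CT grid for
#' image fusion, then CT grid to the dose-calculation grid) distorts the
#' apparent volume of known lesions, for every combination of first- and
#' second-stage interpolation method.  For each first-stage method the SUV
#' map is resampled to the CT grid and each lesion is segmented (threshold
#' at half its observed peak uptake, capped at the nominal fill level;
#' connected component at its centre) and
#' measured; the CT-grid map is then resampled to the dose grid with each
#' second-stage method and measured again.  A nested host/insert pair is
#' additionally reported as a combined volume (segmented at the host's
#' level).
#'
#' @param lesions list of [LesionSpec-class] with known volumes (the truth).
#' @param suv the reconstructed SUV map on the PET grid.
#' @param ctGrid,doseGrid the CT and dose-calculation [GridSpec-class]s.
#' @param methods interpolation methods to cross (default all three).
#' @param fraction segmentation threshold as a fraction of each lesion's
#'   activity level (default 0.5).
#' @param measureFn measurement override, signature
#'   \code{function(suvVolume, level, center)} returning ml; default the
#'   threshold-component rule above.
#' @return a deviation table (data.frame) with one row per (stage, method
#'   combination, lesion): columns \code{stage} ("PET->CT" or "CT->dose"),
#'   \code{method1}, \code{method2} (NA for first-stage rows),
#'   \code{lesion}, \code{measured_ml}, \code{truth_ml},
#'   \code{deviation_pct} = 100 x (measured - truth) / truth.  An empty
#'   segmentation is reported as -100%, not an error.
#' @export
coregistrationStudy <- function(lesions, suv, ctGrid, doseGrid,
                                methods = c("linear", "nearest",
                                            "cubic-spline"),
                                fraction = 0.5, measureFn = NULL) {
  if (is.null(measureFn))
    measureFn <- function(vol, level, center)
      .measure_lesion(vol, level, center, fraction = fraction)
  ## lesion bookkeeping: individual truths plus combined host+insert rows
  nms <- vapply(lesions, function(l) l@name, character(1))
  rows <- list()
  measureAll <- function(vol, stage, m1, m2) {
    for (l in lesions) {
      ml <- measureFn(vol, l@activity, l@center)
      ## an insert nested in a host is measured at its own (higher) level;
      ## subtract it from the host's component volume
      nested_in_me <- lesions[vapply(lesions, function(x)
        identical(x@inside, l@name), logical(1))]
      truth <- lesionVolumeMl(l)
      if (length(nested_in_me)) {
        ## host alone: component at host level minus the insert volume
        comb <- ml
        insert <- nested_in_me[[1L]]
        mlIns <- measureFn(vol, insert@activity, insert@center)
        rows[[length(rows) + 1L]] <<- data.frame(stage = stage,
          method1 = m1, method2 = m2, lesion = l@name,
          measured_ml = comb - mlIns, truth_ml = truth,
          deviation_pct = 100 * ((comb - mlIns) - truth) / truth)
        rows[[length(rows) + 1L]] <<- data.frame(stage = stage,
          method1 = m1, method2 = m2,
          lesion = paste0(insert@name, "+", l@name),
          measured_ml = comb, truth_ml = truth + lesionVolumeMl(insert),
          deviation_pct = 100 * (comb - (truth + lesionVolumeMl(insert))) /
            (truth + lesionVolumeMl(insert)))
      } else {
        rows[[length(rows) + 1L]] <<- data.frame(stage = stage,
          method1 = m1, method2 = m2, lesion = l@name,
          measured_ml = ml, truth_ml = truth,
          deviation_pct = 100 * (ml - truth) / truth)
      }
    }
  }
  for (m1 in methods) {
    onCT <- resampleVolume(suv, ctGrid, m1)
    measureAll(onCT, "PET->CT", m1, NA_character_)
    for (m2 in methods) {
      onDose <- resampleVolume(onCT, doseGrid, m2)
      measureAll(onDose, "CT->dose", m1, m2)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a deviation table as CSV
#'
#' @param table a deviation table from [coregistrationStudy()].
#' @param path destination CSV.
#' @export
writeDeviationTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
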