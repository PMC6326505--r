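## Adaptive replanning and voxel-wise dose accumulation across phases.

#' Treatment phase constructor
#'
#' @param fractions c(first, last) fraction numbers.
#' @param rx the [RobustPrescription-class] the phase plan satisfies.
#' @param plan the [LPSolution-class] (planned as total-course dose).
#' @param newApertures apertures generated specifically for this phase.
#' @param influence the [DoseInfluenceMatrix-class] behind the plan.
#' @return a [TreatmentPhase-class].
#' @export
treatmentPhase <- function(fractions, rx, plan, newApertures = NA_integer_,
                           influence = NULL) {
  new("TreatmentPhase", fractions = as.integer(fractions), rx = rx,
      plan = plan, newApertures = as.integer(newApertures),
      influence = influence)
}

setMethod("show", "TreatmentPhase", function(object) {
  cat(sprintf(
    "TreatmentPhase: fractions %d-%d, OF = %.4g, %d apertures (%s new)\n",
    object@fractions[1L], object@fractions[2L], object@plan@objective,
    length(object@plan@weights),
    ifelse(is.na(object@newApertures), "?", object@newApertures)))
})

#' Replan against an updated prescription
#'
#' Adaptive replanning reuses the prior phase's aperture pool and adds only
#' the few new geometries that the image-driven aperture generator derives
#' from the updated prescription map; the LP is then re-solved over the
#' full pool.  Because apertures are generated from image information
#' alone, a change in the follow-up SUV map translates directly into a
#' small set of new apertures rather than a full replanning from scratch.
#'
#' @param prior the prior [TreatmentPhase-class].
#' @param newRx the updated [RobustPrescription-class] (same dose grid).
#' @param ct CT density volume (for the new influence columns).
#' @param beams beam set used for the new apertures.
#' @param fractions c(first, last) fraction numbers of the new phase.
#' @param cfg an [LPConfig-class].
#' @param kernel a [pencilBeamKernel()].
#' @param nBands,rules forwarded to [biomapApertures()].
#' @param tag provenance prefix for the new apertures (default "adapt").
#' @return a [TreatmentPhase-class] whose plan uses the combined pool;
#'   \code{@newApertures} counts the added geometries.
#' @export
replan <- function(prior, newRx, ct, beams, fractions, cfg = lpConfig(),
                   kernel = pencilBeamKernel(), nBands = 4L, rules = list(),
                   tag = "adapt") {
  if (!any(newRx@unionMask > 0)) stop("new prescription is empty")
  newAps <- biomapApertures(newRx, beams, nBands = nBands, rules = rules,
                            tag = tag)
  oldAps <- priorApertures(prior)
  ## only genuinely new geometries enter the pool: apertures identical to a
  ## prior one (same beam, same leaf intervals) are redundant columns
  oldKeys <- vapply(oldAps, .aperture_key, character(1))
  newAps <- newAps[!(vapply(newAps, .aperture_key, character(1)) %in%
                     oldKeys)]
  allAps <- c(oldAps, newAps)
  d <- buildInfluenceMatrix(allAps, ct, newRx@grid, kernel)
  prob <- assembleLP(d, newRx, cfg)
  ## prior weights (padded with zeros for the new columns) are a feasible
  ## warm start: replanning over a superset pool can never end up worse
  warm <- c(prior@plan@weights,
            numeric(length(d@apertures) - length(oldAps)))
  sol <- solveLP(prob, d, warmWeights = warm)
  treatmentPhase(fractions, newRx, sol, newApertures = length(newAps),
                 influence = d)
}

#' Apertures of a phase's plan
#' @param phase a [TreatmentPhase-class].
#' @export
priorApertures <- function(phase) {
  if (!is.null(phase@influence)) return(phase@influence@apertures)
  stop("phase carries no influence matrix; pass apertures explicitly")
}

#' Accumulate phase doses over a treatment course
#'
#' Total dose per voxel is the fraction-weighted sum of the phase plans'
#' total-course doses: phase p delivering f_p of the total fractions
#' contributes (f_p / total) x its planned dose.  Because no morphological
#' change is modelled, accumulation is direct voxel-by-voxel addition on
#' the shared dose grid - no deformable registration is involved.  The
#' total is evaluated against the fraction-weighted per-voxel prescription
#' (over voxels prescribed in every phase).
#'
#' @param phases list of [TreatmentPhase-class] whose fraction ranges
#'   partition 1..totalFractions.
#' @param totalFractions total number of fractions (default 30).
#' @return list with \code{dose} (the accumulated [ImageVolume-class]),
#'   \code{report} (a [QualityReport-class] against the blended
#'   prescription) and \code{weights} (the fraction shares).
#' @export
accumulatePhases <- function(phases, totalFractions = 30L) {
  if (!length(phases)) stop("no phases")
  covered <- integer(0)
  for (ph in phases) {
    rng <- ph@fractions[1L]:ph@fractions[2L]
    if (length(intersect(covered, rng)))
      stop("overlapping fraction ranges")
    covered <- c(covered, rng)
  }
  if (!setequal(covered, seq_len(totalFractions)))
    stop("fraction ranges must partition 1..totalFractions")
  wts <- vapply(phases, function(ph)
    (ph@fractions[2L] - ph@fractions[1L] + 1L) / totalFractions, numeric(1))
  grid <- phases[[1L]]@rx@grid
  total <- array(0, dim = grid@shape)
  rxTotal <- array(0, dim = grid@shape)
  inAll <- array(TRUE, dim = grid@shape)
  for (i in seq_along(phases)) {
    ph <- phases[[i]]
    total <- total + wts[i] * ph@plan@dose@values
    map <- ph@rx@maps[[1L]]
    rxTotal <- rxTotal + wts[i] * map@dose
    inAll <- inAll & map@mask > 0
  }
  doseVol <- imageVolume(total, grid, "dose-Gy")
  blended <- new("PrescriptionMap", grid = grid, mask = inAll * 1,
                 dose = rxTotal * inAll, doseMin = rxTotal * inAll,
                 doseMax = rxTotal * inAll,
                 deltaMin = phases[[1L]]@rx@maps[[1L]]@deltaMin,
                 deltaMax = phases[[1L]]@rx@maps[[1L]]@deltaMax,
                 label = phases[[1L]]@rx@maps[[1L]]@label)
  list(dose = doseVol, report = qualityReport(doseVol, blended),
       weights = wts)
}
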