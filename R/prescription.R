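## SUV-driven dose prescriptions: by numbers, by contour, and robust stacks.

#' Linear dose-painting-by-numbers prescription map
#'
#' Maps SUV to prescribed dose linearly over the target mask using min-max
#' normalization: the minimum-SUV target voxel receives \code{dLow}, the
#' maximum-SUV voxel \code{dHigh}, and every other voxel interpolates
#' linearly in SUV.  Defaults follow a 70 Gy baseline prescription with
#' escalation up to 82 Gy inside the SUV heterogeneity.  If the SUV is
#' constant over the mask every voxel receives \code{dLow}.
#'
#' The per-voxel floor and ceiling both equal the prescribed dose; the
#' multiplicative similarity factors (defaults 0.97 / 1.03) provide the
#' robust band the optimizer works within.
#'
#' @param suv an \code{"suv"} [ImageVolume-class].
#' @param mask target mask ([ImageVolume-class] or 0/1 array on the same
#'   grid).
#' @param dLow,dHigh dose endpoints in Gy, \code{dHigh >= dLow > 0}.
#' @param delta similarity factors \code{c(deltaMin, deltaMax)}.
#' @param protocol name of the reconstruction protocol behind the SUV map.
#' @return a [PrescriptionMap-class] labelled \code{"dpbn"}.
#' @export
dpbnMap <- function(suv, mask, dLow = 70, dHigh = 82, delta = c(0.97, 1.03),
                    protocol = "unspecified") {
  if (dLow <= 0 || dHigh < dLow)
    stop("need dHigh >= dLow > 0")
  m <- if (is(mask, "ImageVolume")) mask@values else mask
  if (!any(m > 0)) stop("target mask is empty")
  s <- suv@values[m > 0]
  rng <- range(s)
  dose <- array(0, dim = suv@grid@shape)
  if (rng[2L] > rng[1L]) {
    dose[m > 0] <- dLow + (s - rng[1L]) / (rng[2L] - rng[1L]) * (dHigh - dLow)
  } else {
    dose[m > 0] <- dLow
  }
  new("PrescriptionMap", grid = suv@grid, mask = (m > 0) * 1, dose = dose,
      doseMin = dose, doseMax = dose, deltaMin = delta[1L],
      deltaMax = delta[2L], label = "dpbn", protocol = protocol)
}

#' Dose-painting-by-contour prescription map
#'
#' Thresholds nested biological target subvolumes BTV_k = voxels with SUV >=
#' fraction_k x max SUV (within the target mask) and prescribes each voxel
#' the uniform dose of the innermost subvolume containing it; target voxels
#' below the lowest fraction receive the first level dose.  By default the
#' level doses are the by-numbers doses at each threshold SUV, which makes
#' by-contour, by-numbers and hybrid plans directly comparable.
#'
#' @param suv an \code{"suv"} [ImageVolume-class].
#' @param mask target mask.
#' @param levelFractions ascending fractions of max SUV in (0, 1].
#' @param levelDoses ascending doses (Gy), one per level; default derived
#'   from the [dpbnMap()] linear relation with \code{dLow}/\code{dHigh}.
#' @param dLow,dHigh endpoints used when \code{levelDoses} is NULL.
#' @param delta similarity factors \code{c(deltaMin, deltaMax)}.
#' @param protocol protocol name.
#' @return a [PrescriptionMap-class] labelled \code{"dpbc"}; the nested BTV
#'   masks are kept in \code{@levels} (named BTV1, BTV2, ...).
#' @export
dpbcMap <- function(suv, mask, levelFractions = c(0.4, 0.6, 0.8),
                    levelDoses = NULL, dLow = 70, dHigh = 82,
                    delta = c(0.97, 1.03), protocol = "unspecified") {
  if (is.unsorted(levelFractions, strictly = TRUE) ||
      any(levelFractions <= 0) || any(levelFractions > 1))
    stop("levelFractions must be strictly ascending within (0, 1]")
  m <- if (is(mask, "ImageVolume")) mask@values else mask
  if (!any(m > 0)) stop("target mask is empty")
  s_on <- suv@values[m > 0]
  rng <- range(s_on)
  mx <- max(suv@values)
  if (is.null(levelDoses)) {
    thrSUV <- levelFractions * mx
    if (rng[2L] > rng[1L]) {
      levelDoses <- dLow + (pmin(pmax(thrSUV, rng[1L]), rng[2L]) - rng[1L]) /
        (rng[2L] - rng[1L]) * (dHigh - dLow)
    } else levelDoses <- rep(dLow, length(levelFractions))
  }
  if (length(levelDoses) != length(levelFractions))
    stop("levelFractions and levelDoses must have the same length")
  if (is.unsorted(levelDoses))
    stop("configuration error: level doses must ascend with fractions")
  dose <- array(0, dim = suv@grid@shape)
  dose[m > 0] <- levelDoses[1L]
  levels <- list()
  for (k in seq_along(levelFractions)) {
    btv <- (suv@values >= levelFractions[k] * mx & m > 0) * 1
    levels[[paste0("BTV", k)]] <- btv
    dose[btv > 0] <- levelDoses[k]
  }
  new("PrescriptionMap", grid = suv@grid, mask = (m > 0) * 1, dose = dose,
      doseMin = dose, doseMax = dose, deltaMin = delta[1L],
      deltaMax = delta[2L], label = "dpbc", protocol = protocol,
      levels = levels)
}

#' @export
setMethod("targetMask", "PrescriptionMap", function(x)
  imageVolume(x@mask, x@grid, "mask"))

#' @export
setMethod("prescribedDose", "PrescriptionMap", function(x)
  imageVolume(x@dose, x@grid, "dose-Gy"))

setMethod("show", "PrescriptionMap", function(object) {
  on <- object@mask > 0
  cat(sprintf(
    "PrescriptionMap [%s, %s]: %d target voxels, D in [%.1f, %.1f] Gy, delta %.2f/%.2f\n",
    object@label, object@protocol, sum(on),
    if (any(on)) min(object@dose[on]) else NA,
    if (any(on)) max(object@dose[on]) else NA,
    object@deltaMin, object@deltaMax))
  if (length(object@levels))
    cat(sprintf("  levels: %s\n", paste(sprintf("%s (%d vox)",
      names(object@levels), vapply(object@levels, function(m) sum(m > 0),
      integer(1))), collapse = ", ")))
})

#' Organ-at-risk constraint constructor
#'
#' @param name structure name.
#' @param mask a mask [ImageVolume-class].
#' @param cap maximum dose in Gy.
#' @return an [OARConstraint-class].
#' @export
oarConstraint <- function(name, mask, cap) {
  new("OARConstraint", name = name, mask = mask, cap = cap)
}

## resample a prescription map to the dose grid (nearest-neighbour: the
## co-registration study selects nearest for image data -> dose grid)
.resample_map <- function(map, doseGrid, method = "nearest") {
  msk <- resampleVolume(imageVolume(map@mask, map@grid, "mask"), doseGrid,
                        method)
  mv <- (msk@values > 0.5) * 1
  rs <- function(a) resampleVolume(imageVolume(a, map@grid, "dose-Gy"),
                                   doseGrid, method)@values * (mv > 0)
  levels <- lapply(map@levels, function(l)
    (resampleVolume(imageVolume(l, map@grid, "mask"), doseGrid,
                    method)@values > 0.5) * 1)
  new("PrescriptionMap", grid = doseGrid, mask = mv, dose = rs(map@dose),
      doseMin = rs(map@doseMin), doseMax = rs(map@doseMax),
      deltaMin = map@deltaMin, deltaMax = map@deltaMax, label = map@label,
      protocol = map@protocol, levels = levels)
}

#' Assemble a robust multi-map prescription on the dose grid
#'
#' Resamples every prescription map (and OAR mask) to the dose-calculation
#' grid and stacks the constraint sets: a voxel covered by k maps' targets
#' carries all k floor/ceiling pairs simultaneously, which is what lets one
#' plan satisfy several prescriptions (two reconstruction protocols, or
#' by-numbers plus by-contour) at the voxel level.  OAR voxels that overlap
#' the union target are released from the OAR cap (target priority).
#'
#' @param maps list of [PrescriptionMap-class] (any grids).
#' @param oars list of [OARConstraint-class].
#' @param doseGrid the dose-calculation [GridSpec-class].
#' @param method interpolation used to move maps onto the dose grid;
#'   nearest-neighbour by default.
#' @return a [RobustPrescription-class].
#' @export
combineRobust <- function(maps, oars = list(), doseGrid,
                          method = "nearest") {
  if (!length(maps)) stop("at least one prescription map is required")
  rmaps <- lapply(maps, .resample_map, doseGrid = doseGrid, method = method)
  un <- Reduce(`+`, lapply(rmaps, slot, "mask"))
  un <- (un > 0) * 1
  if (!any(un > 0)) stop("empty union target on the dose grid")
  roars <- lapply(oars, function(o) {
    mv <- resampleVolume(o@mask, doseGrid, "nearest")@values
    mv[un > 0] <- 0   # target priority
    oarConstraint(o@name, imageVolume(mv, doseGrid, "mask"), o@cap)
  })
  roars <- Filter(function(o) any(o@mask@values > 0), roars)
  nOar <- if (length(roars))
    sum(Reduce(`|`, lapply(roars, function(o) o@mask@values > 0))) else 0L
  new("RobustPrescription", grid = doseGrid, maps = rmaps, oars = roars,
      unionMask = un, nT = as.integer(sum(un)),
      n = as.integer(sum(un) + nOar))
}

#' @export
setMethod("targetMask", "RobustPrescription", function(x)
  imageVolume(x@unionMask, x@grid, "mask"))

setMethod("show", "RobustPrescription", function(object) {
  cat(sprintf(
    "RobustPrescription: %d map(s), %d OAR(s), N_T = %d, N = %d on %s grid\n",
    length(object@maps), length(object@oars), object@nT, object@n,
    paste(object@grid@shape, collapse = "x")))
})
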