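## High-level planning drivers: from phantom truth to an evaluated plan.
## These wire the modules together under the package's default study
## conditions and are what the command-line interface and the worked
## examples call.

#' Default dose-calculation grid for the planning phantom
#'
#' Isotropic 3 mm voxels covering the head-and-neck phantom field of view.
#'
#' @param spacing voxel size in mm (default 3 mm isotropic).
#' @return a [GridSpec-class].
#' @export
defaultDoseGrid <- function(spacing = c(3, 3, 3)) {
  gridCovering(c(-66, -66, -45), c(66, 66, 45), spacing)
}

#' Plan a dose-painting treatment for a prescription
#'
#' Generates image-driven apertures for the prescription, builds the
#' pencil-beam influence matrix, assembles and solves the voxel-wise LP,
#' and evaluates the plan against each prescription map.
#'
#' @param rx a [RobustPrescription-class] on the dose grid.
#' @param ct CT density [ImageVolume-class].
#' @param beams beam set (default 7 equispaced coplanar beams).
#' @param cfg an [LPConfig-class].
#' @param kernel a [pencilBeamKernel()].
#' @param nBands,rules forwarded to [biomapApertures()].
#' @param fractions fraction range the plan covers (default the whole
#'   course, \code{c(1, 30)}).
#' @return a list: \code{phase} ([TreatmentPhase-class]), \code{reports}
#'   (one [QualityReport-class] per prescription map), \code{apertures}
#'   (count).
#' @export
planRobust <- function(rx, ct, beams = beamSet(7L), cfg = lpConfig(),
                       kernel = pencilBeamKernel(), nBands = 4L,
                       rules = list(), fractions = c(1L, 30L)) {
  aps <- biomapApertures(rx, beams, nBands = nBands, rules = rules)
  d <- buildInfluenceMatrix(aps, ct, rx@grid, kernel)
  prob <- assembleLP(d, rx, cfg)
  sol <- solveLP(prob, d)
  reports <- lapply(rx@maps, function(map) qualityReport(sol@dose, map))
  names(reports) <- vapply(seq_along(rx@maps), function(i) {
    m <- rx@maps[[i]]
    if (m@protocol != "unspecified") m@protocol else paste0(m@label, i)
  }, character(1))
  list(phase = treatmentPhase(fractions, rx, sol,
                              newApertures = length(d@apertures),
                              influence = d),
       reports = reports, apertures = length(d@apertures))
}

#' Run the default head-and-neck planning scenario
#'
#' The package's reference experiment: generate the three-lesion phantom,
#' emulate the high-resolution reconstruction, fuse the SUV map onto the CT
#' grid with cubic-spline interpolation (the chain the co-registration
#' study selects; the prescription later moves to the dose grid with
#' nearest-neighbour), segment the biological target at 40% of the maximum
#' SUV, build the linear 70-82 Gy by-numbers prescription, and optimize a
#' 7-beam plan.
#'
#' @param seed RNG seed for the reconstruction noise.
#' @param protocol a [ReconstructionProtocol-class] (default
#'   [biographProtocol()]).
#' @param doseGrid dose grid (default [defaultDoseGrid()]).
#' @param nBeams number of beams.
#' @param thresholdFraction segmentation threshold fraction.
#' @param dLow,dHigh prescription endpoints in Gy.
#' @param cfg LP configuration.
#' @param ... forwarded to [planRobust()].
#' @return as [planRobust()], plus \code{rx}, \code{ct}, \code{suv},
#'   \code{phantom}.
#' @export
planDefaultHN <- function(seed = 1L, protocol = biographProtocol(),
                          doseGrid = defaultDoseGrid(), nBeams = 7L,
                          thresholdFraction = 0.4, dLow = 70, dHigh = 82,
                          cfg = lpConfig(), ...) {
  ph <- hnPhantom()
  truth <- makeActivityTruth(ph$lesions, ph$grid)
  ct <- makeCT(ph$lesions, ph$outline, ph$grid)
  suv <- emulateReconstruction(truth, protocol, seed = seed)
  ## PET/CT fusion: cubic spline onto the CT grid (co-registration choice)
  suv <- resampleVolume(suv, ph$grid, "cubic-spline")
  seg <- segmentSUV(suv, thresholdFraction)
  map <- dpbnMap(suv, seg@mask, dLow = dLow, dHigh = dHigh,
                 protocol = protocol@name)
  oar <- oarConstraint("cord", lesionMask(ph$oar, ph$grid), cap = 50)
  rx <- combineRobust(list(map), list(oar), doseGrid)
  ctDose <- resampleVolume(ct, doseGrid, "linear")
  res <- planRobust(rx, ctDose, beams = beamSet(nBeams), cfg = cfg, ...)
  c(res, list(rx = rx, ct = ctDose, suv = suv, phantom = ph, seg = seg))
}

#' Run the robust two-protocol scenario
#'
#' One phantom truth reconstructed under both emulated protocols; each
#' reconstruction yields its own by-numbers prescription map and one plan
#' is optimized against the stacked pair, then evaluated against each map
#' separately.
#'
#' @inheritParams planDefaultHN
#' @return as [planRobust()] plus the two maps.
#' @export
planRobustTwoProtocol <- function(seed = 1L, doseGrid = defaultDoseGrid(),
                                  nBeams = 7L, thresholdFraction = 0.4,
                                  dLow = 70, dHigh = 82, cfg = lpConfig(),
                                  ...) {
  ph <- hnPhantom()
  truth <- makeActivityTruth(ph$lesions, ph$grid)
  ct <- makeCT(ph$lesions, ph$outline, ph$grid)
  suvE <- emulateReconstruction(truth, earlProtocol(), seed = seed)
  suvB <- emulateReconstruction(truth, biographProtocol(), seed = seed + 1L)
  ## PET/CT fusion stage: cubic spline onto the CT grid for both protocols
  suvE <- resampleVolume(suvE, ph$grid, "cubic-spline")
  suvB <- resampleVolume(suvB, ph$grid, "cubic-spline")
  mapE <- dpbnMap(suvE, segmentSUV(suvE, thresholdFraction)@mask,
                  dLow = dLow, dHigh = dHigh, protocol = "EARL")
  mapB <- dpbnMap(suvB, segmentSUV(suvB, thresholdFraction)@mask,
                  dLow = dLow, dHigh = dHigh, protocol = "BIOGRAPH")
  oar <- oarConstraint("cord", lesionMask(ph$oar, ph$grid), cap = 50)
  rx <- combineRobust(list(mapE, mapB), list(oar), doseGrid)
  ctDose <- resampleVolume(ct, doseGrid, "linear")
  res <- planRobust(rx, ctDose, beams = beamSet(nBeams), cfg = cfg, ...)
  c(res, list(rx = rx, ct = ctDose, maps = list(EARL = mapE,
                                                BIOGRAPH = mapB)))
}
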