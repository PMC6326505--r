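#' @import methods
#' @importFrom Matrix Matrix sparseMatrix crossprod colSums rowSums t
NULL

## ---------------------------------------------------------------------------
## Grid and image containers
## ---------------------------------------------------------------------------

#' Voxel grid specification
#'
#' A \code{GridSpec} describes a regular 3-D voxel lattice in world (scanner)
#' coordinates: the number of voxels per axis, the voxel spacing in mm, and
#' the world position (mm) of the centre of the first voxel.  Voxel indices
#' are 0-based in the world mapping: the centre of voxel index
#' \code{(i, j, k)} sits at \code{origin + c(i, j, k) * spacing}.  Axis order
#' is (x, y, z) with z the longitudinal (cranio-caudal) axis.
#'
#' @slot shape integer(3), voxels per axis (all >= 1).
#' @slot spacing numeric(3), mm per voxel along each axis (all > 0).
#' @slot origin numeric(3), world coordinate (mm) of the centre of voxel
#'   (0, 0, 0).
#'
#' @seealso [gridSpec()], [ImageVolume-class]
#' @export
setClass("GridSpec",
  representation(shape = "integer", spacing = "numeric", origin = "numeric"),
  prototype(shape = c(1L, 1L, 1L), spacing = c(1, 1, 1), origin = c(0, 0, 0))
)

setValidity("GridSpec", function(object) {
  if (length(object@shape) != 3L || length(object@spacing) != 3L ||
      length(object@origin) != 3L)
    return("shape, spacing and origin must each have length 3")
  if (any(is.na(object@shape)) || any(object@shape < 1L))
    return("all shape entries must be >= 1")
  if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
    return("all spacing entries must be > 0")
  if (any(!is.finite(object@origin)))
    return("origin must be finite")
  TRUE
})

.volume_kinds <- c("ct-density", "suv", "dose-Gy", "mask", "q-index")

#' Scalar image volume on a voxel grid
#'
#' The central data container: a 3-D scalar field (CT relative density, SUV,
#' dose in Gy, a binary mask, or a quality-index map) together with its
#' [GridSpec-class].  Validity enforces kind-specific constraints: masks are
#' strictly 0/1, dose and SUV values are non-negative, q-index maps may hold
#' \code{NA} outside the target.
#'
#' @slot grid a [GridSpec-class].
#' @slot values numeric array conforming to \code{shape(grid)}.
#' @slot kind one of \code{"ct-density"}, \code{"suv"}, \code{"dose-Gy"},
#'   \code{"mask"}, \code{"q-index"}.
#'
#' @seealso [imageVolume()], [resampleVolume()], [readVolume()]
#' @export
setClass("ImageVolume",
  representation(grid = "GridSpec", values = "array", kind = "character")
)

setValidity("ImageVolume", function(object) {
  if (!identical(dim(object@values), as.integer(object@grid@shape)))
    return("values array does not conform to grid shape")
  if (length(object@kind) != 1L || !(object@kind %in% .volume_kinds))
    return(sprintf("kind must be one of: %s",
                   paste(.volume_kinds, collapse = ", ")))
  v <- object@values
  if (object@kind == "mask") {
    if (anyNA(v) || !all(v == 0 | v == 1))
      return("mask volumes may contain only 0/1 values")
  } else if (object@kind %in% c("suv", "dose-Gy", "ct-density")) {
    if (anyNA(v) || any(v < 0))
      return(sprintf("%s volumes must be non-negative and free of NA",
                     object@kind))
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Phantom specification
## ---------------------------------------------------------------------------

#' Lesion specification for digital phantoms
#'
#' Describes one active lesion (a tube or tumour subvolume): its shape in
#' world coordinates and its activity level in SUV units.  A lesion may be
#' declared nested inside a host lesion (by name), in which case its voxels
#' override the host's activity - this is how a heterogeneous-uptake lesion
#' (a hot core inside a larger active volume) is modelled.
#'
#' @slot name character scalar identifier.
#' @slot shape one of \code{"sphere"}, \code{"ellipsoid"}, \code{"cylinder"}.
#' @slot center numeric(3), world mm.
#' @slot size shape dimensions in mm: sphere \code{c(radius)}, ellipsoid
#'   \code{c(rx, ry, rz)} (semi-axes), cylinder \code{c(radius, height)}
#'   (axis along z).
#' @slot activity SUV level (> 0).
#' @slot inside name of the host lesion, or \code{NA_character_}.
#' @export
setClass("LesionSpec",
  representation(name = "character", shape = "character", center = "numeric",
                 size = "numeric", activity = "numeric", inside = "character"),
  prototype(inside = NA_character_)
)

setValidity("LesionSpec", function(object) {
  if (!(object@shape %in% c("sphere", "ellipsoid", "cylinder")))
    return("shape must be sphere, ellipsoid or cylinder")
  need <- c(sphere = 1L, ellipsoid = 3L, cylinder = 2L)[[object@shape]]
  if (length(object@size) != need)
    return(sprintf("%s needs %d size entries", object@shape, need))
  if (any(object@size <= 0)) return("all dimensions must be positive")
  if (length(object@center) != 3L) return("center must have length 3")
  if (length(object@activity) != 1L || object@activity <= 0)
    return("activity must be a positive scalar")
  TRUE
})

#' PET reconstruction protocol (emulated)
#'
#' Parameters of one image reconstruction protocol, emulated as a resolution
#' blur (intrinsic point-spread function combined with the post-processing
#' Gaussian filter), a resample onto the protocol's voxel grid, and
#' multiplicative voxel noise.  See [earlProtocol()] and
#' [biographProtocol()] for the two study protocols.
#'
#' @slot name protocol label.
#' @slot voxelSize numeric(3), reconstruction voxel size in mm.
#' @slot gridPixels in-plane matrix size of the nominal reconstruction grid
#'   (pixels per axial slice); kept as metadata, the emulated grid covers the
#'   phantom field of view at \code{voxelSize}.
#' @slot psfFwhm intrinsic resolution fwhm, mm (>= 0).
#' @slot postFilterFwhm post-processing Gaussian filter fwhm, mm (>= 0).
#' @slot noiseCV coefficient of variation of multiplicative voxel noise
#'   (>= 0).
#' @export
setClass("ReconstructionProtocol",
  representation(name = "character", voxelSize = "numeric",
                 gridPixels = "integer", psfFwhm = "numeric",
                 postFilterFwhm = "numeric", noiseCV = "numeric")
)

setValidity("ReconstructionProtocol", function(object) {
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive values")
  if (object@psfFwhm < 0 || object@postFilterFwhm < 0)
    return("fwhm values must be >= 0")
  if (object@noiseCV < 0) return("noiseCV must be >= 0")
  TRUE
})

#' Metabolic response model for follow-up imaging
#'
#' Per-lesion multiplicative activity changes applied to a baseline SUV map
#' to synthesize a virtual follow-up scan, plus optional regions where
#' activity drops to background entirely (lesion sub-volumes that stopped
#' showing metabolic activity).
#'
#' @slot factors named numeric vector of multiplicative changes (>= 0), one
#'   per lesion name; lesions not named keep factor 1.
#' @slot zeroRegions list of [LesionSpec-class]-like shapes whose voxels are
#'   reset to background.
#' @export
setClass("ResponseModel",
  representation(factors = "numeric", zeroRegions = "list"),
  prototype(factors = numeric(0), zeroRegions = list())
)

setValidity("ResponseModel", function(object) {
  if (length(object@factors) && any(object@factors < 0))
    return("response factors must be >= 0")
  if (length(object@factors) && is.null(names(object@factors)))
    return("factors must be named by lesion")
  TRUE
})

## ---------------------------------------------------------------------------
## Prescription
## ---------------------------------------------------------------------------

#' Segmentation result
#'
#' @slot mask binary [ImageVolume-class] of the segmented target.
#' @slot threshold absolute SUV threshold that was applied.
#' @slot nComponents number of connected components retained
#'   (26-connectivity).
#' @slot labels integer array of component labels (0 = background).
#' @export
setClass("SegmentationResult",
  representation(mask = "ImageVolume", threshold = "numeric",
                 nComponents = "integer", labels = "array")
)

#' Voxel-wise dose prescription map
#'
#' Holds the per-voxel prescribed dose over a target mask together with the
#' floor/ceiling pair used as LP constraints and the multiplicative
#' similarity factors that widen the feasible band.  For a
#' dose-painting-by-numbers map floor = ceiling = the prescribed dose and
#' the similarity factors supply all the slack; for a by-contour map the
#' dose is piecewise constant on nested threshold subvolumes (BTV shells),
#' which are retained in \code{levels} for volume-based evaluation.
#'
#' @slot grid [GridSpec-class] the map lives on.
#' @slot mask binary array: target voxels.
#' @slot dose numeric array, prescribed dose D_i in Gy (0 off-target).
#' @slot doseMin,doseMax per-voxel floor/ceiling in Gy.
#' @slot deltaMin,deltaMax similarity factors in (0, 2); floors enter the LP
#'   as doseMin * deltaMin, ceilings as doseMax * deltaMax.
#' @slot label \code{"dpbn"} or \code{"dpbc"}.
#' @slot protocol name of the reconstruction protocol the SUV map came from.
#' @slot levels named list of binary arrays (nested BTV masks, by-contour
#'   maps only).
#' @export
setClass("PrescriptionMap",
  representation(grid = "GridSpec", mask = "array", dose = "array",
                 doseMin = "array", doseMax = "array",
                 deltaMin = "numeric", deltaMax = "numeric",
                 label = "character", protocol = "character",
                 levels = "list"),
  prototype(levels = list(), protocol = "unspecified")
)

setValidity("PrescriptionMap", function(object) {
  sh <- as.integer(object@grid@shape)
  for (nm in c("mask", "dose", "doseMin", "doseMax"))
    if (!identical(dim(slot(object, nm)), sh))
      return(sprintf("%s does not conform to the grid", nm))
  if (!all(object@mask %in% c(0, 1))) return("mask must be 0/1")
  on <- object@mask > 0
  if (any(on)) {
    if (any(object@doseMin[on] > object@dose[on] + 1e-9) ||
        any(object@dose[on] > object@doseMax[on] + 1e-9))
      return("doseMin <= dose <= doseMax must hold on target voxels")
  }
  if (object@deltaMin <= 0 || object@deltaMin >= 2 ||
      object@deltaMax <= 0 || object@deltaMax >= 2)
    return("similarity factors must lie in (0, 2)")
  if (!(object@label %in% c("dpbn", "dpbc")))
    return("label must be 'dpbn' or 'dpbc'")
  TRUE
})

#' Organ-at-risk dose cap
#'
#' @slot name structure name.
#' @slot mask binary [ImageVolume-class].
#' @slot cap maximum allowed dose D_OAR,max in Gy (> 0); toxicity-driven.
#' @export
setClass("OARConstraint",
  representation(name = "character", mask = "ImageVolume", cap = "numeric")
)

setValidity("OARConstraint", function(object) {
  if (length(object@cap) != 1L || object@cap <= 0)
    return("cap must be a positive scalar")
  if (object@mask@kind != "mask") return("mask volume must have kind 'mask'")
  TRUE
})

#' Robust multi-map prescription on the dose grid
#'
#' The stacked constraint set the optimizer works against: one or more
#' prescription maps, all resampled to the dose-calculation grid, plus
#' organ-at-risk caps.  A voxel belonging to k maps' targets carries k
#' (floor, ceiling) pairs, all enforced simultaneously - this is what makes
#' a single plan robust to several prescriptions (two reconstruction
#' protocols, or by-numbers plus by-contour).
#'
#' @slot grid the dose-calculation [GridSpec-class].
#' @slot maps list of [PrescriptionMap-class], already on \code{grid}.
#' @slot oars list of [OARConstraint-class], masks on \code{grid}, target
#'   voxels removed (target priority).
#' @slot unionMask binary array: union of all map targets.
#' @slot nT integer, union-of-targets voxel count.
#' @slot n integer, total constrained voxel count (targets + OAR voxels).
#' @export
setClass("RobustPrescription",
  representation(grid = "GridSpec", maps = "list", oars = "list",
                 unionMask = "array", nT = "integer", n = "integer")
)

setValidity("RobustPrescription", function(object) {
  if (!length(object@maps)) return("at least one prescription map required")
  sh <- as.integer(object@grid@shape)
  for (m in object@maps)
    if (!identical(as.integer(m@grid@shape), sh))
      return("all maps must live on the dose grid")
  if (object@n < object@nT) return("n must be >= nT")
  if (object@nT != sum(object@unionMask > 0))
    return("nT inconsistent with unionMask")
  TRUE
})

## ---------------------------------------------------------------------------
## Beam model
## ---------------------------------------------------------------------------

#' Beam geometry
#'
#' One treatment beam: a gantry angle (rotation about the longitudinal z
#' axis), an isocentre, and the fluence-plane discretization.  The default
#' engine uses parallel rays; the source-axis distance is kept for the
#' optional divergent mode.
#'
#' @slot gantry gantry angle in degrees; 0 points the beam along -y
#'   (anterior-posterior), angles increase clockwise seen from the feet.
#' @slot isocenter numeric(3), world mm.
#' @slot sad source-axis distance, mm (> 0).
#' @slot pixelSize fluence-plane pixel size, mm (> 0), along the leaf-travel
#'   axis.
#' @slot leafWidth MLC leaf width, mm, along the leaf-stacking axis (z).
#' @export
setClass("BeamGeometry",
  representation(gantry = "numeric", isocenter = "numeric", sad = "numeric",
                 pixelSize = "numeric", leafWidth = "numeric")
)

setValidity("BeamGeometry", function(object) {
  if (object@sad <= 0) return("source-axis distance must be > 0")
  if (object@pixelSize <= 0) return("pixel size must be > 0")
  if (object@leafWidth <= 0) return("leaf width must be > 0")
  if (length(object@isocenter) != 3L) return("isocenter must have length 3")
  TRUE
})

#' Ray-traced projection of a structure on the fluence plane
#'
#' @slot beam the [BeamGeometry-class] that produced it.
#' @slot values matrix of line integrals (rows: leaf-travel axis u, columns:
#'   leaf-stacking axis v).
#' @slot u0,v0 plane coordinates (mm) of the centre of pixel (1, 1).
#' @slot du,dv pixel pitch (mm) along u and v.
#' @export
setClass("ProjectionMap",
  representation(beam = "BeamGeometry", values = "matrix",
                 u0 = "numeric", v0 = "numeric", du = "numeric",
                 dv = "numeric")
)

#' Deliverable MLC aperture
#'
#' One multileaf-collimator shape for one beam: an open interval per leaf
#' pair on the fluence plane, plus a provenance tag recording which
#' prescription band (and which adaptive phase) generated it.
#'
#' @slot beam [BeamGeometry-class].
#' @slot intervals numeric matrix (leaf pairs x 2) of left/right edges in mm
#'   on the u axis; NA rows are closed pairs.
#' @slot leafV numeric vector of leaf-row centre coordinates (mm, v axis).
#' @slot provenance character tag, e.g. \code{"band2"} or
#'   \code{"phase2/conformal"}.
#' @export
setClass("Aperture",
  representation(beam = "BeamGeometry", intervals = "matrix",
                 leafV = "numeric", provenance = "character")
)

setValidity("Aperture", function(object) {
  iv <- object@intervals
  if (ncol(iv) != 2L) return("intervals must have two columns")
  if (nrow(iv) != length(object@leafV))
    return("one leaf-row coordinate per interval row required")
  open <- !is.na(iv[, 1L])
  if (any(is.na(iv[open, 2L])))
    return("half-open interval rows are not allowed")
  if (any(iv[open, 1L] > iv[open, 2L]))
    return("left edge must not exceed right edge")
  TRUE
})

#' Sparse aperture-by-voxel dose-influence matrix
#'
#' Entry (i, j) is the dose in Gy deposited in dose-grid voxel i by aperture
#' j at unit weight.  Columns are stored sparse; the voxel index runs in
#' array order over the dose grid.
#'
#' @slot matrix a \code{dgCMatrix} (voxels x apertures), entries >= 0.
#' @slot grid the dose [GridSpec-class].
#' @slot apertures list of the [Aperture-class] objects behind the columns.
#' @export
setClass("DoseInfluenceMatrix",
  representation(matrix = "Matrix", grid = "GridSpec", apertures = "list")
)

setValidity("DoseInfluenceMatrix", function(object) {
  if (nrow(object@matrix) != prod(object@grid@shape))
    return("matrix rows must equal the dose-grid voxel count")
  if (ncol(object@matrix) != length(object@apertures))
    return("one aperture per column required")
  cs <- Matrix::colSums(object@matrix != 0)
  if (any(cs == 0)) return("every aperture column must be non-zero somewhere")
  if (min(object@matrix) < 0) return("influence entries must be >= 0")
  TRUE
})

## ---------------------------------------------------------------------------
## LP optimizer
## ---------------------------------------------------------------------------

#' LP penalty and solver configuration
#'
#' @slot pTmax target overdose penalty (>= 0).
#' @slot pTmin target underdose penalty (>= 0).
#' @slot pOARmax organ-at-risk overdose penalty (>= 0).
#' @slot tol interior-point convergence tolerance (relative duality gap and
#'   residuals).
#' @slot maxIter iteration cap.
#' @slot wMax optional upper bound on aperture weights (NA = unbounded).
#' @export
setClass("LPConfig",
  representation(pTmax = "numeric", pTmin = "numeric", pOARmax = "numeric",
                 tol = "numeric", maxIter = "integer", wMax = "numeric"),
  prototype(pTmax = 1, pTmin = 1, pOARmax = 0.5, tol = 1e-9,
            maxIter = 200L, wMax = NA_real_)
)

setValidity("LPConfig", function(object) {
  p <- c(object@pTmax, object@pTmin, object@pOARmax)
  if (any(p < 0)) return("penalties must be >= 0")
  if (all(p == 0)) return("at least one penalty must be > 0")
  if (object@tol <= 0) return("tol must be > 0")
  TRUE
})

#' Assembled voxel-wise LP
#'
#' The inequality system of the aperture-weight optimization in row form.
#' Each row couples the dose rows of the influence matrix with one penalized
#' slack: target ceilings (dose - x <= Dmax*deltaMax), target floors
#' (dose + y >= Dmin*deltaMin) and OAR caps (dose - x <= Dcap).  All
#' variables (weights and slacks) are bounded below by zero.
#'
#' @slot G sparse matrix (rows x apertures): signed dose rows (+d for
#'   ceilings/caps, -d for floors).
#' @slot rhs numeric right-hand sides (signed to match G).
#' @slot penalty numeric per-row slack penalty.
#' @slot rowInfo data.frame with columns voxel (dose-grid linear index), map
#'   (map index or NA for OAR rows), type ("ceiling", "floor", "oar"),
#'   structure (OAR name or NA).
#' @slot nApertures number of weight variables M.
#' @slot grid dose [GridSpec-class].
#' @slot config the [LPConfig-class] used at assembly.
#' @export
setClass("LPProblem",
  representation(G = "Matrix", rhs = "numeric", penalty = "numeric",
                 rowInfo = "data.frame", nApertures = "integer",
                 grid = "GridSpec", config = "LPConfig")
)

#' LP solution
#'
#' @slot weights aperture weights omega_j (>= 0).
#' @slot overdose per-row overdose slack x (target ceilings and OAR caps).
#' @slot underdose per-row underdose slack y (target floors).
#' @slot objective objective value OF = pTmax*sum(x_T) + pTmin*sum(y_T) +
#'   pOARmax*sum(x_OAR), recomputed analytically from the weights.
#' @slot status \code{"optimal"} or \code{"max-iterations"}.
#' @slot iterations interior-point iterations used.
#' @slot gap final relative duality gap.
#' @slot dose planned dose [ImageVolume-class] on the dose grid.
#' @slot problem the [LPProblem-class] solved.
#' @export
setClass("LPSolution",
  representation(weights = "numeric", overdose = "numeric",
                 underdose = "numeric", objective = "numeric",
                 status = "character", iterations = "integer",
                 gap = "numeric", dose = "ImageVolume", problem = "LPProblem")
)

## ---------------------------------------------------------------------------
## Evaluation / adaptive
## ---------------------------------------------------------------------------

#' Plan-quality report
#'
#' @slot qMap quality-index [ImageVolume-class] (NA off target).
#' @slot qvh data.frame (q, pct): cumulative percent of target voxels with
#'   Q >= q.
#' @slot qf quality factor in percent: 100 * mean |Q - 1| over the target.
#' @slot within named numeric: percent of target voxels with Q strictly
#'   inside 1 +/- 3%, 4%, 5%.
#' @slot dvh named list of data.frames (dose, pct) per structure.
#' @slot ci named numeric, conformity index percent per structure.
#' @export
setClass("QualityReport",
  representation(qMap = "ImageVolume", qvh = "data.frame", qf = "numeric",
                 within = "numeric", dvh = "list", ci = "numeric"),
  prototype(dvh = list(), ci = numeric(0))
)

setValidity("QualityReport", function(object) {
  if (object@qf < 0) return("QF must be >= 0")
  w <- object@within
  if (length(w) == 3L && !(w[1L] <= w[2L] + 1e-9 && w[2L] <= w[3L] + 1e-9))
    return("tolerance fractions must be nested (3% <= 4% <= 5%)")
  if (length(object@ci) && any(object@ci < -1e-9 | object@ci > 100 + 1e-9))
    return("CI must lie in [0, 100]")
  if (nrow(object@qvh) > 1L && any(diff(object@qvh$pct) > 1e-9))
    return("QVH must be monotone non-increasing")
  TRUE
})

#' One phase of an (adaptive) treatment course
#'
#' @slot fractions integer(2): first and last fraction numbers delivered
#'   with this plan.
#' @slot rx the [RobustPrescription-class] the phase was optimized against.
#' @slot plan the [LPSolution-class] (planned as total-course dose).
#' @slot newApertures number of apertures generated for this phase (as
#'   opposed to reused from the prior phase).
#' @slot influence the [DoseInfluenceMatrix-class] behind the plan (kept so
#'   adaptive replanning can reuse the aperture pool).
#' @export
setClass("TreatmentPhase",
  representation(fractions = "integer", rx = "RobustPrescription",
                 plan = "LPSolution", newApertures = "integer",
                 influence = "ANY"),
  prototype(influence = NULL)
)

setValidity("TreatmentPhase", function(object) {
  f <- object@fractions
  if (length(f) != 2L || f[1L] > f[2L] || f[1L] < 1L)
    return("fractions must be c(first, last) with 1 <= first <= last")
  TRUE
})
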