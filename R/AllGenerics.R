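## Generics shared across the package.

#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @export
setGeneric("volumeKind", function(x) standardGeneric("volumeKind"))

#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @export
setGeneric("measureVolume", function(x) standardGeneric("measureVolume"))

#' @export
setGeneric("targetMask", function(x) standardGeneric("targetMask"))

#' @export
setGeneric("prescribedDose", function(x) standardGeneric("prescribedDose"))

#' @export
setGeneric("apertures", function(x) standardGeneric("apertures"))

#' @export
setGeneric("weights", function(object, ...) standardGeneric("weights"))

#' @export
setGeneric("plannedDose", function(x) standardGeneric("plannedDose"))

#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @export
setGeneric("qualityFactor", function(x) standardGeneric("qualityFactor"))
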