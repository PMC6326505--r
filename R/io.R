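## Volume I/O: NIfTI-1 (via RNifti) and a native serialized container.

.kind_from_string <- function(kind) {
  if (is.null(kind) || is.na(kind) || !nzchar(kind)) "suv" else kind
}

#' Read an image volume
#'
#' Two on-disk representations are supported: NIfTI-1 (\code{.nii} /
#' \code{.nii.gz}; grid metadata taken from the qform affine, which must be
#' axis-aligned) and the package's native container (an \code{.rds} holding
#' the [ImageVolume-class] itself, bit-exact on round trip).  The volume
#' kind is stored in the NIfTI \code{intent_name} field when writing; a file
#' without one is read back as \code{"suv"} unless \code{kind} is given.
#'
#' @param path file to read.
#' @param format \code{"nifti"} or \code{"container"}; default guessed from
#'   the extension.
#' @param kind override the volume kind recorded in the file.
#' @return an [ImageVolume-class].
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, format = c("auto", "nifti", "container"),
                       kind = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "container"
              else "nifti"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "container") {
    vol <- readRDS(path)
    if (!is(vol, "ImageVolume")) stop("container does not hold an ImageVolume")
    if (!is.null(kind)) vol@kind <- kind
    validObject(vol)
    return(vol)
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file: ",
                                           conditionMessage(e)))
  hdr <- RNifti::niftiHeader(img)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("metadata error: non-positive voxel spacing in NIfTI header")
  xf <- RNifti::xform(img)
  ## axis-aligned grids only: off-diagonal rotation terms must vanish
  rot <- abs(xf[1:3, 1:3]); diag(rot) <- 0
  if (any(rot > 1e-6 * max(sp)))
    stop("metadata error: oblique NIfTI orientations are not supported")
  orig <- xf[1:3, 4L]
  ## xform scales carry the RAS sign convention; spacing stays positive and
  ## a flipped axis is folded into the origin by construction of our writer.
  a <- as.array(img)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  if (length(dim(a)) != 3L) stop("only 3-D volumes are supported")
  k <- if (!is.null(kind)) kind else .kind_from_string(hdr$intent_name)
  grid <- gridSpecNew(dim(a), sp, orig)
  imageVolume(a, grid, k)
}

#' Write an image volume
#'
#' @param vol an [ImageVolume-class].
#' @param path destination file.
#' @param format \code{"nifti"} or \code{"container"}; default guessed from
#'   the extension.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path, format = c("auto", "nifti", "container")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "container"
              else "nifti"
  if (format == "container") {
    saveRDS(vol, path)
    return(invisible(path))
  }
  img <- RNifti::asNifti(vol@values)
  RNifti::pixdim(img) <- vol@grid@spacing
  aff <- rbind(cbind(diag(vol@grid@spacing), vol@grid@origin), c(0, 0, 0, 1))
  attr(aff, "code") <- 2L
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  img <- RNifti::asNifti(img, list(intent_name = vol@kind))
  RNifti::writeNifti(img, path)
  invisible(path)
}
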