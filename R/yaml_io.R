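## YAML phantom / prescription configuration.

#' Read a phantom specification from YAML
#'
#' The YAML layout mirrors the constructors: a \code{grid} block
#' (\code{lower}, \code{upper}, \code{spacing} in mm), an \code{outline}
#' block (\code{center}, \code{semiAxes}), and a list of \code{lesions},
#' each with \code{name}, \code{shape}, \code{center}, \code{size},
#' \code{activity} and optionally \code{inside}.
#'
#' ```yaml
#' grid:    {lower: [-60, -60, -30], upper: [60, 60, 30], spacing: [1.5, 1.5, 1.5]}
#' outline: {center: [0, 0], semiAxes: [58, 58]}
#' lesions:
#'   - {name: V1, shape: sphere, center: [-20, 35, 0], size: 4.153, activity: 10}
#'   - {name: V3, shape: cylinder, center: [25, -20, 0], size: [5.6, 20.3], activity: 1.3}
#'   - {name: V2, shape: sphere, center: [25, -20, 2], size: 4.153, activity: 10, inside: V3}
#' ```
#'
#' @param path YAML file.
#' @return a list with \code{lesions}, \code{outline}, \code{grid}, in the
#'   same shape as [tubePhantom()] / [hnPhantom()].
#' @export
readPhantomSpec <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$grid) || is.null(y$lesions))
    stop("phantom spec needs 'grid' and 'lesions' blocks")
  grid <- gridCovering(as.numeric(y$grid$lower), as.numeric(y$grid$upper),
                       as.numeric(y$grid$spacing))
  lesions <- lapply(y$lesions, function(l)
    lesionSpec(l$name, l$shape, as.numeric(l$center), as.numeric(l$size),
               activity = l$activity,
               inside = if (is.null(l$inside)) NA_character_ else l$inside))
  outline <- if (is.null(y$outline)) NULL else
    bodyOutline(center = as.numeric(y$outline$center),
                semiAxes = as.numeric(y$outline$semiAxes),
                bone = y$outline$bone)
  list(lesions = lesions, outline = outline, grid = grid)
}
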