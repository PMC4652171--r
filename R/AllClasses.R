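#' DiffusionVolume: a 3D diffusion-weighted intensity grid
#'
#' Holds the voxel intensities (arbitrary units) of a diffusion-weighted MRI
#' volume together with voxel spacing and origin in mm, plus optional ground
#' truth carried by synthetic phantoms (brain mask, lesion mask, planted
#' territory label). Physical position of voxel (i,j,k) (1-based) is
#' \code{origin + (c(i,j,k)-1) * spacing}, i.e. voxel centres on a regular
#' grid; all downstream geometry works in mm.
#'
#' @slot values 3D numeric array of intensities (a.u.).
#' @slot spacing Numeric length-3, mm per voxel along each axis (> 0).
#' @slot origin Numeric length-3, mm position of voxel (1,1,1).
#' @slot orientation Character length-3 axis labels; canonical order is
#'   right/anterior/superior.
#' @slot brainMask,lesionMask Logical arrays congruent with \code{values},
#'   or 0-length logical when absent.
#' @slot territory Planted lesion territory label or \code{"none"}.
#' @export
setClass("DiffusionVolume",
  representation(values = "array", spacing = "numeric", origin = "numeric",
                 orientation = "character", brainMask = "array",
                 lesionMask = "array", territory = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@values)) != 3L || prod(dim(object@values)) == 0)
      msg <- c(msg, "values must be a non-empty 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 strictly positive values")
    if (length(object@origin) != 3L)
      msg <- c(msg, "origin must have length 3")
    for (nm in c("brainMask", "lesionMask")) {
      m <- slot(object, nm)
      if (length(m) && !identical(dim(m), dim(object@values)))
        msg <- c(msg, paste(nm, "must be congruent with values"))
    }
    if (is.null(msg)) TRUE else msg
  })

#' Construct a DiffusionVolume
#'
#' @param values 3D numeric array of intensities (a.u.).
#' @param spacing Voxel spacing in mm (length 3).
#' @param origin Position of the first voxel centre in mm (length 3).
#' @param orientation Axis labels, default right/anterior/superior.
#' @param brainMask,lesionMask Optional logical ground-truth masks.
#' @param territory Optional planted territory label.
#' @return A \linkS4class{DiffusionVolume}.
#' @export
DiffusionVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                            orientation = c("R", "A", "S"),
                            brainMask = NULL, lesionMask = NULL,
                            territory = "none") {
  empty <- array(logical(0), dim = c(0L, 0L, 0L))
  new("DiffusionVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = orientation,
      brainMask = if (is.null(brainMask)) empty else brainMask,
      lesionMask = if (is.null(lesionMask)) empty else lesionMask,
      territory = territory)
}

#' ProjectionGeometry: spherical projection frame and map raster size
#'
#' The projection centre is the anatomical origin of the radial projection
#' (on patients: the ventral surface of the lower mesencephalon between the
#' cerebral peduncles; on phantoms: a configuration input, by default the
#' brain centroid). The polar axis points superior, the reference axis
#' (longitude zero) anterior; longitude increases toward the right side, so
#' the left hemisphere lands on the left half of the map.
#'
#' @slot center Numeric length-3, mm.
#' @slot radius Sphere radius r in mm (> 0). Rasterisation normalises by r,
#'   so r only sets the physical scale of map coordinates.
#' @slot polarAxis,referenceAxis Unit vectors in the canonical frame.
#' @slot mapShape Integer length-2, map raster (width, height) in pixels.
#' @export
setClass("ProjectionGeometry",
  representation(center = "numeric", radius = "numeric",
                 polarAxis = "numeric", referenceAxis = "numeric",
                 mapShape = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@center) != 3L) msg <- c(msg, "center must have length 3")
    if (length(object@radius) != 1L || object@radius <= 0)
      msg <- c(msg, "radius must be a single positive number")
    if (abs(sqrt(sum(object@polarAxis^2)) - 1) > 1e-6)
      msg <- c(msg, "polarAxis must be a unit vector")
    if (length(object@mapShape) != 2L || any(object@mapShape < 2L))
      msg <- c(msg, "mapShape must be two integers >= 2")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a ProjectionGeometry
#'
#' @param center Projection centre in mm.
#' @param radius Sphere radius in mm.
#' @param polarAxis Direction mapped to latitude +90 degrees (superior).
#' @param referenceAxis Direction of longitude zero (anterior).
#' @param mapShape Map raster (width, height); default 960 x 240 pixels.
#'   The 4:1 aspect matches the 8r x 4r footprint of the projection
#'   formulas; the resolution is chosen so that on a default phantom about
#'   40% of occupied pixels collect more than one voxel, the multiplicity
#'   regime the method is designed for.
#' @return A \linkS4class{ProjectionGeometry}.
#' @export
ProjectionGeometry <- function(center, radius, polarAxis = c(0, 0, 1),
                               referenceAxis = c(0, 1, 0),
                               mapShape = c(960L, 240L)) {
  new("ProjectionGeometry", center = as.numeric(center),
      radius = as.numeric(radius), polarAxis = .unit(as.numeric(polarAxis)),
      referenceAxis = .unit(as.numeric(referenceAxis)),
      mapShape = as.integer(mapShape))
}

#' ProjectedMap: a 2D Mollweide-projected intensity raster
#'
#' Map matrices are stored height x width; row 1 is the superior pole
#' (latitude +90 degrees), column 1 the left edge of the map. Pixel values
#' are the maximum intensity over all voxels projecting into the pixel, so
#' that hyperintense stroke signal is never obscured by healthy tissue.
#'
#' @slot values Numeric matrix (a.u.), \code{NA} outside \code{inside}.
#' @slot inside Logical matrix: pixels receiving at least one voxel.
#' @slot multiplicity Integer matrix of per-pixel contributor counts.
#' @slot geometry The \linkS4class{ProjectionGeometry} used.
#' @export
setClass("ProjectedMap",
  representation(values = "matrix", inside = "matrix",
                 multiplicity = "matrix", geometry = "ProjectionGeometry"),
  validity = function(object) {
    msg <- NULL
    dm <- dim(object@values)
    if (!identical(dm, dim(object@inside)) ||
        !identical(dm, dim(object@multiplicity)))
      msg <- c(msg, "values, inside and multiplicity must share dimensions")
    if (!identical(dm, c(object@geometry@mapShape[2L],
                         object@geometry@mapShape[1L])))
      msg <- c(msg, "matrix dimensions must equal rev(mapShape)")
    if (any((object@multiplicity >= 1L) != object@inside))
      msg <- c(msg, "multiplicity must be >= 1 exactly on inside pixels")
    if (any(object@inside & is.na(object@values)))
      msg <- c(msg, "values must be defined on all inside pixels")
    if (is.null(msg)) TRUE else msg
  })

#' DiffusionReference: per-pixel healthy diffusion levels
#'
#' Per-map-pixel mean and standard deviation (population divisor n) of
#' healthy diffusion values, plus the sigma level k used for flagging:
#' a patient pixel is stroke-indicating when its value exceeds
#' mean + k * SD at that pixel.
#'
#' @slot mean,sd Numeric matrices (a.u.), \code{NA} where no healthy map
#'   covered the pixel.
#' @slot nContributors Integer matrix of contributing healthy maps per pixel.
#' @slot sigmaLevel The flagging threshold k (> 0), default 2.
#' @slot geometry Shared \linkS4class{ProjectionGeometry}.
#' @export
setClass("DiffusionReference",
  representation(mean = "matrix", sd = "matrix", nContributors = "matrix",
                 sigmaLevel = "numeric", geometry = "ProjectionGeometry"),
  validity = function(object) {
    msg <- NULL
    dm <- dim(object@mean)
    if (!identical(dm, dim(object@sd)) ||
        !identical(dm, dim(object@nContributors)))
      msg <- c(msg, "mean, sd and nContributors must share dimensions")
    if (object@sigmaLevel <= 0) msg <- c(msg, "sigmaLevel must be > 0")
    if (any(object@sd < 0, na.rm = TRUE)) msg <- c(msg, "sd must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' TerritoryAtlas: five binary territory masks on the map raster
#'
#' One binary raster per artery territory, built by merging the projected
#' stroke footprints of single-territory cases; overlap between territories
#' is permitted. Provenance records which case identifiers contributed, so
#' atlas cases can be excluded from evaluation.
#'
#' @slot masks Named list of logical matrices, names \code{territoryNames()}.
#' @slot provenance Named list of contributing case identifiers.
#' @slot mapShape Integer (width, height) of the shared raster.
#' @export
setClass("TerritoryAtlas",
  representation(masks = "list", provenance = "list", mapShape = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!identical(sort(names(object@masks)), sort(.TERRITORIES)))
      msg <- c(msg, "masks must be named after the five territories")
    dm <- c(object@mapShape[2L], object@mapShape[1L])
    for (nm in names(object@masks)) {
      m <- object@masks[[nm]]
      if (!is.logical(m) || !identical(dim(m), dm))
        msg <- c(msg, paste("mask", nm, "must be logical and congruent"))
      else if (!any(m)) msg <- c(msg, paste("territory mask", nm, "is empty"))
    }
    if (is.null(msg)) TRUE else msg
  })
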