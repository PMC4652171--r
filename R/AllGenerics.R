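#' Accessors for strokemap S4 objects
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{intensities} returns the voxel array of a volume, \code{voxelSpacing}
#' and \code{voxelOrigin} its mm geometry, \code{brainMask}/\code{lesionMask}
#' the ground-truth masks carried by phantoms (or \code{NULL}),
#' \code{trueTerritory} the planted territory label. For maps,
#' \code{mapValues}, \code{insideMask} and \code{multiplicity} return the
#' three raster layers and \code{geometry} the projection geometry. For
#' references, \code{refMean}/\code{refSd}/\code{refN} return the per-pixel
#' statistics and \code{sigmaLevel} the flagging threshold k;
#' \code{territoryMask} extracts one atlas mask.
#'
#' @param x An object of the respective class.
#' @param territory A territory name for \code{territoryMask}.
#' @return The slot contents documented above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))
#' @rdname accessors
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))
#' @rdname accessors
#' @export
setGeneric("lesionMask", function(x) standardGeneric("lesionMask"))
#' @rdname accessors
#' @export
setGeneric("trueTerritory", function(x) standardGeneric("trueTerritory"))
#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setGeneric("insideMask", function(x) standardGeneric("insideMask"))
#' @rdname accessors
#' @export
setGeneric("multiplicity", function(x) standardGeneric("multiplicity"))
#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setGeneric("refMean", function(x) standardGeneric("refMean"))
#' @rdname accessors
#' @export
setGeneric("refSd", function(x) standardGeneric("refSd"))
#' @rdname accessors
#' @export
setGeneric("refN", function(x) standardGeneric("refN"))
#' @rdname accessors
#' @export
setGeneric("sigmaLevel", function(x) standardGeneric("sigmaLevel"))
#' @rdname accessors
#' @export
setGeneric("territoryMask", function(x, territory)
  standardGeneric("territoryMask"))

#' @rdname accessors
#' @export
setMethod("intensities", "DiffusionVolume", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "DiffusionVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelOrigin", "DiffusionVolume", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("brainMask", "DiffusionVolume",
          function(x) if (length(x@brainMask)) x@brainMask else NULL)
#' @rdname accessors
#' @export
setMethod("lesionMask", "DiffusionVolume",
          function(x) if (length(x@lesionMask)) x@lesionMask else NULL)
#' @rdname accessors
#' @export
setMethod("trueTerritory", "DiffusionVolume", function(x) x@territory)

#' @rdname accessors
#' @export
setMethod("mapValues", "ProjectedMap", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("insideMask", "ProjectedMap", function(x) x@inside)
#' @rdname accessors
#' @export
setMethod("multiplicity", "ProjectedMap", function(x) x@multiplicity)
#' @rdname accessors
#' @export
setMethod("geometry", "ProjectedMap", function(x) x@geometry)
#' @rdname accessors
#' @export
setMethod("geometry", "DiffusionReference", function(x) x@geometry)

#' @rdname accessors
#' @export
setMethod("refMean", "DiffusionReference", function(x) x@mean)
#' @rdname accessors
#' @export
setMethod("refSd", "DiffusionReference", function(x) x@sd)
#' @rdname accessors
#' @export
setMethod("refN", "DiffusionReference", function(x) x@nContributors)
#' @rdname accessors
#' @export
setMethod("sigmaLevel", "DiffusionReference", function(x) x@sigmaLevel)

#' @rdname accessors
#' @export
setMethod("territoryMask", "TerritoryAtlas", function(x, territory) {
  if (!territory %in% .TERRITORIES)
    stop("unknown territory name: ", territory)
  x@masks[[territory]]
})

setMethod("show", "DiffusionVolume", function(object) {
  d <- dim(object@values)
  cat("DiffusionVolume:", paste(d, collapse = " x "), "voxels,",
      paste(format(object@spacing, digits = 3), collapse = " x "), "mm\n")
  if (length(object@brainMask))
    cat("  brain mask:", sum(object@brainMask), "voxels\n")
  if (length(object@lesionMask) && sum(object@lesionMask) > 0)
    cat("  lesion:", sum(object@lesionMask), "voxels, territory",
        object@territory, "\n")
  invisible(NULL)
})

setMethod("show", "ProjectedMap", function(object) {
  cat("ProjectedMap:", object@geometry@mapShape[1L], "x",
      object@geometry@mapShape[2L], "pixels (w x h),",
      sum(object@inside), "inside\n")
  invisible(NULL)
})

setMethod("show", "DiffusionReference", function(object) {
  cat("DiffusionReference: defined on", sum(object@nContributors >= 1L),
      "pixels, sigma level", object@sigmaLevel, "\n")
  invisible(NULL)
})

setMethod("show", "TerritoryAtlas", function(object) {
  cat("TerritoryAtlas on", object@mapShape[1L], "x", object@mapShape[2L],
      "map:\n")
  for (nm in .TERRITORIES)
    cat(sprintf("  %-7s %6d pixels (%d cases)\n", nm,
                sum(object@masks[[nm]]),
                length(object@provenance[[nm]] %||% character(0))))
  invisible(NULL)
})
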