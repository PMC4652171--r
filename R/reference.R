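# Healthy diffusion-level reference (per-pixel mean and SD over healthy
# maps), contralateral hemisphere mirroring, sigma-level flagging of
# stroke-indicating pixels, sigma-level selection by the stroke-per-brain
# comparison, and the territory atlas built from single-territory cases.

.checkSameRaster <- function(a, b, what = "rasters") {
  if (!identical(dim(a), dim(b)))
    stop("geometry mismatch: ", what, " have different shapes")
  invisible(TRUE)
}

#' Build the healthy diffusion-level reference
#'
#' Per-pixel mean and standard deviation (population divisor n) of the
#' diffusion values of healthy maps. Pixels covered by no map are undefined
#' and are never flagged downstream.
#'
#' @param maps List of at least two \linkS4class{ProjectedMap}s sharing one
#'   raster geometry (typically mirrored healthy hemispheres, see
#'   \code{\link{mirrorHealthyHemisphere}}).
#' @param sigmaLevel Flagging threshold k in SDs (default 2).
#' @return A \linkS4class{DiffusionReference}.
#' @export
buildDiffusionReference <- function(maps, sigmaLevel = 2) {
  stopifnot(length(maps) >= 2, sigmaLevel > 0)
  dm <- dim(maps[[1]]@values)
  for (m in maps) .checkSameRaster(maps[[1]]@values, m@values, "maps")
  n <- matrix(0L, dm[1], dm[2])
  sumv <- matrix(0, dm[1], dm[2])
  sumsq <- matrix(0, dm[1], dm[2])
  for (m in maps) {
    v <- m@values
    v[!m@inside] <- 0
    n <- n + m@inside
    sumv <- sumv + v
    sumsq <- sumsq + v^2
  }
  mu <- sumv / n
  mu[n == 0L] <- NA_real_
  sdv <- sqrt(pmax(sumsq / n - mu^2, 0))
  sdv[n == 0L] <- NA_real_
  new("DiffusionReference", mean = mu, sd = sdv,
      nContributors = matrix(as.integer(n), dm[1], dm[2]),
      sigmaLevel = sigmaLevel, geometry = maps[[1]]@geometry)
}

#' Replace the stroke-side half of a map by the mirror of the healthy half
#'
#' The map is mirrored about its vertical midline (longitude sign flip); the
#' affected hemisphere's pixels are replaced by the mirrored healthy
#' hemisphere, yielding an all-healthy map for reference building. On a
#' left/right-symmetric map this is the identity.
#'
#' @param map A \linkS4class{ProjectedMap}.
#' @param strokeSide \code{"left"} or \code{"right"}: which hemisphere holds
#'   the stroke.
#' @return A \linkS4class{ProjectedMap} with the affected half replaced.
#' @export
mirrorHealthyHemisphere <- function(map, strokeSide = c("left", "right")) {
  strokeSide <- match.arg(strokeSide)
  W <- ncol(map@values)
  half <- floor(W / 2)
  cols <- if (strokeSide == "left") seq_len(half)
          else (W - half + 1L):W
  mirror <- function(M) {
    out <- M
    flipped <- M[, W:1, drop = FALSE]
    out[, cols] <- flipped[, cols]
    out
  }
  new("ProjectedMap", values = mirror(map@values),
      inside = mirror(map@inside),
      multiplicity = mirror(map@multiplicity), geometry = map@geometry)
}

#' Flag stroke-indicating pixels
#'
#' A pixel is stroke-indicating when its value exceeds the healthy reference
#' mean by more than k SDs at that pixel (one-sided upper flagging: acute
#' stroke is hyperintense on diffusion imaging; a two-sided mode is
#' available). Pixels undefined in the reference are never flagged.
#'
#' @param map A \linkS4class{ProjectedMap}.
#' @param ref A \linkS4class{DiffusionReference} on the same raster.
#' @param twoSided Also flag pixels below mean - k SD.
#' @return Logical matrix (stroke mask), \code{TRUE} only on inside pixels.
#' @export
flagStrokePixels <- function(map, ref, twoSided = FALSE) {
  .checkSameRaster(map@values, ref@mean, "map and reference")
  k <- ref@sigmaLevel
  up <- map@values > ref@mean + k * ref@sd
  flag <- if (twoSided) up | (map@values < ref@mean - k * ref@sd) else up
  flag[is.na(flag)] <- FALSE
  flag & map@inside & (ref@nContributors >= 1L)
}

#' 2D stroke-per-brain area fraction of a flagged map
#'
#' @param stroke Logical stroke mask from \code{\link{flagStrokePixels}}.
#' @param map The \linkS4class{ProjectedMap} it came from.
#' @param ref Optional \linkS4class{DiffusionReference}; when given, only
#'   reference-defined pixels enter the area denominator.
#' @return Flagged pixels / inside pixels, in [0, 1].
#' @export
mapStrokeFraction <- function(stroke, map, ref = NULL) {
  inside <- map@inside
  if (!is.null(ref)) inside <- inside & (ref@nContributors >= 1L)
  denom <- sum(inside)
  if (denom == 0) stop("no inside pixels")
  sum(stroke & inside) / denom
}

#' Choose the sigma level by the stroke-per-brain comparison
#'
#' For each candidate k, flags every cohort map at that level and averages
#' the discrepancy between the 3D stroke-per-brain volume ratio and the 2D
#' flagged-area fraction (\code{\link{spbDifference}}); returns the k with
#' the smallest mean discrepancy. Too low a k over-flags healthy noise, too
#' high a k under-represents the lesion; ties break toward the smaller k.
#'
#' @param maps List of patient \linkS4class{ProjectedMap}s.
#' @param p3d Numeric vector of per-case 3D stroke-per-brain ratios
#'   (\code{\link{strokeBrainRatio3D}}).
#' @param ref A \linkS4class{DiffusionReference} (its own sigma level is
#'   ignored).
#' @param ks At least two candidate sigma levels.
#' @param mode Discrepancy mode, see \code{\link{spbDifference}}.
#' @return List with the selected \code{k} and the per-k
#'   \code{meanDifference}.
#' @export
chooseSigmaLevel <- function(maps, p3d, ref, ks = c(1, 2, 3),
                             mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(length(maps) >= 1, length(maps) == length(p3d),
            length(ks) >= 2)
  ks <- sort(ks)
  perK <- vapply(ks, function(k) {
    refk <- ref
    refk@sigmaLevel <- k
    mean(vapply(seq_along(maps), function(i) {
      flag <- flagStrokePixels(maps[[i]], refk)
      spbDifference(p3d[i], mapStrokeFraction(flag, maps[[i]], refk),
                    mode = mode)
    }, 0))
  }, 0)
  list(k = ks[which.min(perK)], meanDifference = setNames(perK, ks))
}

#' Build the stroke-territory atlas from single-territory cases
#'
#' Each territory's mask is the union of the projected stroke masks of the
#' cases with a distinct diagnosis in only that territory; provenance records
#' the contributing case identifiers so those cases can be excluded from
#' later evaluation.
#'
#' @param strokeMasks List of logical stroke masks on one raster.
#' @param labels Character vector: the single territory of each case.
#' @param ids Case identifiers (default \code{names(strokeMasks)} or
#'   generated).
#' @param mapShape Raster (width, height); inferred from the masks when
#'   omitted.
#' @return A \linkS4class{TerritoryAtlas}.
#' @export
buildTerritoryAtlas <- function(strokeMasks, labels, ids = NULL,
                                mapShape = NULL) {
  stopifnot(length(strokeMasks) == length(labels), length(labels) >= 1)
  bad <- setdiff(unique(labels), .TERRITORIES)
  if (length(bad)) stop("unknown territory label: ", paste(bad, collapse = ", "))
  missing <- setdiff(.TERRITORIES, labels)
  if (length(missing))
    stop("no atlas case for territory: ", paste(missing, collapse = ", "))
  ids <- ids %||% names(strokeMasks) %||%
    sprintf("atlas_%02d", seq_along(strokeMasks))
  dm <- dim(strokeMasks[[1]])
  for (m in strokeMasks) .checkSameRaster(strokeMasks[[1]], m, "stroke masks")
  masks <- lapply(.TERRITORIES, function(t)
    Reduce(`|`, strokeMasks[labels == t]))
  names(masks) <- .TERRITORIES
  prov <- lapply(.TERRITORIES, function(t) ids[labels == t])
  names(prov) <- .TERRITORIES
  new("TerritoryAtlas", masks = masks, provenance = prov,
      mapShape = as.integer(mapShape %||% c(dm[2], dm[1])))
}
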