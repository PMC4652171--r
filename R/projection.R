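# Radial projection of brain voxels onto a sphere and flattening to a 2D map.
# The flattening uses the closed-form map
#   x = 8 r lambda cos(theta) / pi ,  y = 2 r sin(theta)
# applied verbatim; it spans an 8r-wide, 4r-tall footprint (4:1 aspect). The
# canonical Mollweide projection (2:1, transcendental auxiliary angle) is
# available behind a flag for comparison but is not the default.

.projectionFrame <- function(geom) {
  p <- geom@polarAxis
  a <- geom@referenceAxis
  e1 <- a - sum(a * p) * p
  if (sqrt(sum(e1^2)) < 1e-8)
    stop("referenceAxis must not be parallel to polarAxis")
  e1 <- .unit(e1)
  list(p = p, e1 = e1, e2 = .cross3(e1, p))
}

#' Spherical coordinates of positions relative to the projection centre
#'
#' Purely radial mapping: every position maps to the direction of
#' (position - centre), so all points on one ray share (lambda, theta).
#' Latitude theta is +pi/2 along the polar axis; longitude lambda is 0 on
#' the reference (anterior) meridian and increases toward the right side.
#' At the poles lambda is canonicalised to 0.
#'
#' @param pos Numeric length-3 position or n x 3 matrix, in mm.
#' @param geometry A \linkS4class{ProjectionGeometry}.
#' @return Matrix with columns \code{lambda} (radians, [-pi, pi]),
#'   \code{theta} (radians, [-pi/2, pi/2]) and \code{rho} (mm).
#' @export
toSpherical <- function(pos, geometry) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3)
  d <- sweep(pos, 2, geometry@center)
  rho <- sqrt(rowSums(d^2))
  if (any(rho == 0))
    stop("position coincides with the projection centre: direction undefined")
  f <- .projectionFrame(geometry)
  z <- pmin(1, pmax(-1, as.vector(d %*% f$p) / rho))
  theta <- asin(z)
  lambda <- atan2(as.vector(d %*% f$e2), as.vector(d %*% f$e1))
  lambda[abs(abs(theta) - pi / 2) < 1e-12] <- 0
  cbind(lambda = lambda, theta = theta, rho = rho)
}

#' Forward map from spherical to planar map coordinates
#'
#' Implements \code{x = 8 r lambda cos(theta) / pi},
#' \code{y = 2 r sin(theta)}. With \code{canonical = TRUE} the classical
#' equal-area Mollweide formulas (auxiliary angle solved by Newton
#' iteration, 2:1 aspect) are used instead.
#'
#' @param lambda Longitude(s), radians in [-pi, pi].
#' @param theta Latitude(s), radians in [-pi/2, pi/2].
#' @param r Sphere radius (same unit as the output coordinates).
#' @param canonical Use the classical Mollweide formulas.
#' @return Matrix with columns \code{x} and \code{y}.
#' @export
mollweideForward <- function(lambda, theta, r = 1, canonical = FALSE) {
  if (!canonical)
    return(cbind(x = 8 * r * lambda * cos(theta) / pi,
                 y = 2 * r * sin(theta)))
  # canonical: solve 2a + sin(2a) = pi sin(theta)
  a <- theta
  for (i in 1:25) {
    da <- -(2 * a + sin(2 * a) - pi * sin(theta)) / (2 + 2 * cos(2 * a))
    da[!is.finite(da)] <- 0
    a <- a + da
    if (max(abs(da)) < 1e-12) break
  }
  cbind(x = 2 * sqrt(2) * r * lambda * cos(a) / pi,
        y = sqrt(2) * r * sin(a))
}

# map (x, y) in the 8r x 4r footprint to (row, col) pixel indices;
# row 1 = top = y of +2r (superior pole), col 1 = x of -8r (map left)
.rasterize <- function(xy, r, mapShape) {
  W <- mapShape[1L]; H <- mapShape[2L]
  col <- pmin(W, pmax(1L, 1L + floor((xy[, 1] / r + 8) / 16 * W)))
  row <- pmin(H, pmax(1L, 1L + floor((2 - xy[, 2] / r) / 4 * H)))
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Project a volume's brain voxels onto a 2D map
#'
#' Every brain voxel is projected radially from the centre and rasterised
#' into exactly one map pixel; a pixel's value is the maximum over its
#' contributors, so hyperintense stroke voxels are never lost behind healthy
#' tissue, and the contributor count is recorded per pixel. The default
#' geometry centres the sphere on the brain-mask centroid with radius equal
#' to the largest centre-to-voxel distance (a sphere around the brain
#' surface); a voxel exactly at the centre maps to the map origin.
#'
#' @param vol A \linkS4class{DiffusionVolume}.
#' @param mask Logical voxel mask of what to project; defaults to the
#'   volume's brain mask.
#' @param geometry Optional \linkS4class{ProjectionGeometry}.
#' @param canonical Use the canonical Mollweide variant (see
#'   \code{\link{mollweideForward}}).
#' @return A \linkS4class{ProjectedMap}.
#' @export
projectVolume <- function(vol, mask = NULL, geometry = NULL,
                          canonical = FALSE) {
  mask <- mask %||% brainMask(vol)
  if (is.null(mask)) stop("no mask given and the volume carries none")
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask: nothing to project")
  ai <- arrayInd(idx, dim(mask))
  pos <- sweep(t(t(ai - 1L) * vol@spacing), 2, vol@origin, "+")
  if (is.null(geometry)) {
    ctr <- colMeans(pos)
    rho <- sqrt(rowSums(sweep(pos, 2, ctr)^2))
    geometry <- ProjectionGeometry(center = ctr, radius = max(rho))
  }
  d <- sweep(pos, 2, geometry@center)
  rho <- sqrt(rowSums(d^2))
  f <- .projectionFrame(geometry)
  safe <- pmax(rho, 1e-12)
  z <- pmin(1, pmax(-1, as.vector(d %*% f$p) / safe))
  theta <- asin(z)
  lambda <- atan2(as.vector(d %*% f$e2), as.vector(d %*% f$e1))
  lambda[abs(abs(theta) - pi / 2) < 1e-12] <- 0
  theta[rho == 0] <- 0
  lambda[rho == 0] <- 0
  xy <- mollweideForward(lambda, theta, geometry@radius,
                         canonical = canonical)
  rc <- .rasterize(xy, geometry@radius, geometry@mapShape)
  H <- geometry@mapShape[2L]; W <- geometry@mapShape[1L]
  pix <- rc[, "row"] + (rc[, "col"] - 1L) * H
  vals <- vol@values[idx]
  ord <- order(pix, vals)
  keep <- c(diff(pix[ord]) != 0L, TRUE)
  vmat <- matrix(NA_real_, H, W)
  vmat[pix[ord][keep]] <- vals[ord][keep]
  mult <- matrix(tabulate(pix, nbins = H * W), H, W)
  new("ProjectedMap", values = vmat, inside = mult >= 1L,
      multiplicity = mult, geometry = geometry)
}

#' Histogram of per-pixel contributor counts
#'
#' How many voxels each inside map pixel represents; the total mass over
#' multiplicities equals the number of inside pixels, and the
#' multiplicity-weighted sum equals the number of projected voxels.
#'
#' @param map A \linkS4class{ProjectedMap}.
#' @return An \code{"IntensityHistogram"} over contributor counts.
#' @export
multiplicityHistogram <- function(map) {
  stopifnot(is(map, "ProjectedMap"))
  buildHistogram(as.numeric(map@multiplicity[map@inside]), binWidth = 1,
                 origin = 0.5)
}
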