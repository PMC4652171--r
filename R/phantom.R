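# Synthetic brain phantoms: ellipsoidal brain in a noisy background with an
# optional planted lesion confined to one artery-territory sector. Intensity
# regimes mimic clinical diffusion-weighted histograms: a background peak
# around 20 a.u., a broad healthy-brain peak around 180 a.u. and a sparse
# hyperintense stroke tail around 300 a.u.

# Territory sectors as angular wedges in the projection's own spherical
# coordinates (degrees; |longitude| x latitude, half-open on the upper
# longitude/latitude bound except at the domain edge). Bilateral by design;
# lesions are planted in the left-hemisphere half of a wedge.
.WEDGES <- list(
  ACA    = c(lmin =   0, lmax =  45, tmin =  15, tmax =  90),
  supMCA = c(lmin =  45, lmax = 135, tmin =  15, tmax =  90),
  infMCA = c(lmin =  30, lmax = 135, tmin = -25, tmax =  15),
  PCA    = c(lmin = 135, lmax = 180, tmin = -25, tmax =  90),
  PICA   = c(lmin =  60, lmax = 180, tmin = -90, tmax = -25)
)

#' Territory wedge boundaries
#'
#' The five artery-territory sectors used by the phantom generator, as fixed
#' angular wedges (degrees) in the projection's spherical coordinates:
#' absolute longitude from the anterior meridian, latitude from the equator
#' (positive superior). ACA sits anterior-superior at the midline, the MCA
#' divisions laterally (superior and inferior bands), PCA posterior and PICA
#' inferior-posterior; ACA and PICA are disjoint by construction.
#'
#' @return A data.frame with one row per territory and the wedge bounds.
#' @export
territoryWedges <- function() {
  data.frame(territory = names(.WEDGES),
             absLambdaMin = vapply(.WEDGES, `[[`, 0, "lmin"),
             absLambdaMax = vapply(.WEDGES, `[[`, 0, "lmax"),
             thetaMin = vapply(.WEDGES, `[[`, 0, "tmin"),
             thetaMax = vapply(.WEDGES, `[[`, 0, "tmax"),
             row.names = NULL)
}

#' Specification of a synthetic brain phantom
#'
#' Defaults encode the study conditions the package is evaluated under: a
#' 96^3 grid at 2 mm isotropic spacing, a 70 x 85 x 60 mm semi-axis brain
#' ellipsoid, background / brain / stroke intensity levels of 20 / 180 / 300
#' a.u. with Gaussian noise of SD 10 a.u., and a lesion occupying 4.3% of the
#' brain volume (the clinical mean stroke burden).
#'
#' @param gridShape Voxels per axis (length 3).
#' @param voxelSpacing mm per voxel (length 3, > 0).
#' @param brainSemiAxes Ellipsoid semi-axes in mm (length 3).
#' @param backgroundLevel,brainLevel,strokeLevel Mean intensities (a.u.);
#'   must be strictly increasing.
#' @param noiseSD Noise standard deviation (a.u., > 0).
#' @param noiseModel \code{"gaussian"} (default; appropriate at the
#'   signal-to-noise levels emulated here) or \code{"rician"} (magnitude of a
#'   complex Gaussian signal).
#' @param gradientAmplitude Amplitude (a.u.) of a smooth linear intensity
#'   gradient across the brain in a random (seed-determined) direction,
#'   emulating regional diffusion-level differences and scanner bias
#'   fields; 0 (default) disables it. The gradient shifts brain and lesion
#'   levels together, so lesion contrast is relative to the local level.
#' @param lesionProfile \code{"uniform"} (default): every lesion voxel sits
#'   at \code{strokeLevel}; \code{"graded"}: full contrast in the lesion
#'   core decaying toward the rim (floored at 30% contrast), emulating the
#'   graded severity of real infarcts.
#' @param lesionTerritory One of \code{territoryNames()} or \code{"none"}.
#' @param lesionFraction Target lesion / brain volume ratio in [0, 0.3];
#'   \code{NA} lets \code{makeCohort} draw per-case fractions.
#' @param seed Integer seed; the phantom is a pure function of spec + seed.
#' @return A classed list of class \code{"PhantomSpec"}.
#' @export
phantomSpec <- function(gridShape = c(96L, 96L, 96L),
                        voxelSpacing = c(2, 2, 2),
                        brainSemiAxes = c(70, 85, 60),
                        backgroundLevel = 20, brainLevel = 180,
                        strokeLevel = 300, noiseSD = 10,
                        gradientAmplitude = 0,
                        noiseModel = c("gaussian", "rician"),
                        lesionProfile = c("uniform", "graded"),
                        lesionTerritory = "none",
                        lesionFraction = 0.043, seed = 1L) {
  noiseModel <- match.arg(noiseModel)
  lesionProfile <- match.arg(lesionProfile)
  spec <- list(gridShape = as.integer(gridShape),
               voxelSpacing = as.numeric(voxelSpacing),
               brainSemiAxes = as.numeric(brainSemiAxes),
               backgroundLevel = backgroundLevel, brainLevel = brainLevel,
               strokeLevel = strokeLevel, noiseSD = noiseSD,
               gradientAmplitude = gradientAmplitude,
               noiseModel = noiseModel, lesionProfile = lesionProfile,
               lesionTerritory = lesionTerritory,
               lesionFraction = lesionFraction, seed = as.integer(seed))
  class(spec) <- "PhantomSpec"
  validatePhantomSpec(spec)
  spec
}

validatePhantomSpec <- function(spec) {
  stopifnot(length(spec$gridShape) == 3L, all(spec$gridShape >= 8L),
            length(spec$voxelSpacing) == 3L, all(spec$voxelSpacing > 0),
            all(spec$brainSemiAxes > 0), spec$noiseSD > 0,
            spec$gradientAmplitude >= 0)
  if (!(spec$backgroundLevel < spec$brainLevel &&
        spec$brainLevel < spec$strokeLevel))
    stop("intensity levels must satisfy background < brain < stroke")
  if (!spec$lesionTerritory %in% c("none", .TERRITORIES))
    stop("unknown lesion territory: ", spec$lesionTerritory)
  if (!is.na(spec$lesionFraction) &&
      (spec$lesionFraction < 0 || spec$lesionFraction > 0.3))
    stop("lesionFraction must be in [0, 0.3]")
  invisible(spec)
}

# voxel-centre coordinates (mm) along each axis, origin at 0
.axisCoords <- function(gridShape, spacing)
  lapply(1:3, function(i) (seq_len(gridShape[i]) - 1) * spacing[i])

.gridCenter <- function(gridShape, spacing) (gridShape - 1) / 2 * spacing

# ellipsoid brain mask centred on the grid centre
.brainEllipsoid <- function(gridShape, spacing, semiAxes) {
  ctr <- .gridCenter(gridShape, spacing)
  ax <- .axisCoords(gridShape, spacing)
  tx <- ((ax[[1]] - ctr[1]) / semiAxes[1])^2
  ty <- ((ax[[2]] - ctr[2]) / semiAxes[2])^2
  tz <- ((ax[[3]] - ctr[3]) / semiAxes[3])^2
  outer(outer(tx, ty, "+"), tz, "+") <= 1
}

# spherical angles of every voxel relative to a centre (canonical frame:
# polar axis +z superior, longitude zero +y anterior, longitude increasing
# toward +x right). Returns list(lambda, theta, rho) of arrays.
.voxelAngles <- function(gridShape, spacing, center) {
  ax <- .axisCoords(gridShape, spacing)
  dx <- ax[[1]] - center[1]; dy <- ax[[2]] - center[2]
  dz <- ax[[3]] - center[3]
  X <- array(dx, gridShape)
  Y <- aperm(array(dy, gridShape[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(dz, gridShape[c(3, 1, 2)]), c(2, 3, 1))
  rho <- sqrt(X^2 + Y^2 + Z^2)
  theta <- asin(pmin(1, pmax(-1, ifelse(rho > 0, Z / rho, 0))))
  lambda <- atan2(X, Y)
  lambda[abs(abs(theta) - pi / 2) < 1e-12] <- 0
  list(lambda = lambda, theta = theta, rho = rho)
}

.wedgeMembership <- function(territory, lambda, theta) {
  w <- .WEDGES[[territory]]
  al <- abs(lambda) * 180 / pi
  th <- theta * 180 / pi
  inL <- al >= w[["lmin"]] &
    (if (w[["lmax"]] >= 180) al <= 180 else al < w[["lmax"]])
  inT <- th >= w[["tmin"]] &
    (if (w[["tmax"]] >= 90) th <= 90 else th < w[["tmax"]])
  inL & inT
}

#' Angular territory sector as a 3D voxel region
#'
#' Returns the fixed angular wedge (see \code{\link{territoryWedges}}) of a
#' territory as a logical voxel array, relative to a projection centre.
#' Deterministic: identical inputs give identical regions.
#'
#' @param territory One of \code{territoryNames()}.
#' @param gridShape,voxelSpacing Grid definition (voxels, mm).
#' @param center Projection centre in mm; default the grid centre.
#' @param leftOnly Restrict to the left hemisphere (longitude < 0), where
#'   phantom lesions are planted.
#' @return Logical array of shape \code{gridShape}.
#' @export
territorySector <- function(territory, gridShape, voxelSpacing,
                            center = NULL, leftOnly = FALSE) {
  if (!territory %in% .TERRITORIES)
    stop("unknown territory name: ", territory)
  gridShape <- as.integer(gridShape)
  center <- center %||% .gridCenter(gridShape, voxelSpacing)
  ang <- .voxelAngles(gridShape, voxelSpacing, center)
  m <- .wedgeMembership(territory, ang$lambda, ang$theta)
  if (leftOnly) m <- m & (ang$lambda < 0)
  m
}

#' Generate a synthetic brain phantom volume
#'
#' Voxels outside the brain ellipsoid are noise around the background level,
#' brain voxels around the brain level, and lesion voxels around the stroke
#' level; intensities are clipped at 0. The lesion is a single compact blob:
#' the requested number of voxels nearest to a randomly chosen seed point
#' inside the left-hemisphere half of the territory wedge. Ground-truth brain
#' and lesion masks and the planted territory label travel with the volume.
#'
#' @param spec A \code{\link{phantomSpec}}.
#' @return A \linkS4class{DiffusionVolume} with ground truth attached.
#' @export
makeBrainPhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  validatePhantomSpec(spec)
  if (spec$lesionTerritory != "none" && is.na(spec$lesionFraction))
    stop("lesionFraction must be set when a lesion territory is requested")
  withSeed(spec$seed, {
    dm <- spec$gridShape
    n <- prod(dm)
    brain <- .brainEllipsoid(dm, spec$voxelSpacing, spec$brainSemiAxes)
    signal <- array(spec$backgroundLevel, dm)
    signal[brain] <- spec$brainLevel
    field <- NULL
    if (spec$gradientAmplitude > 0) {
      gdir <- .unit(rnorm(3))
      ctr <- .gridCenter(dm, spec$voxelSpacing)
      ax <- .axisCoords(dm, spec$voxelSpacing)
      px <- (ax[[1]] - ctr[1]) * gdir[1]
      py <- (ax[[2]] - ctr[2]) * gdir[2]
      pz <- (ax[[3]] - ctr[3]) * gdir[3]
      field <- outer(outer(px, py, "+"), pz, "+") *
        (spec$gradientAmplitude / max(spec$brainSemiAxes))
      signal[brain] <- signal[brain] + field[brain]
    }
    lesion <- array(FALSE, dm)
    if (spec$lesionTerritory != "none" && spec$lesionFraction > 0) {
      region <- territorySector(spec$lesionTerritory, dm, spec$voxelSpacing,
                                leftOnly = TRUE) & brain
      k <- round(spec$lesionFraction * sum(brain))
      if (k > sum(region))
        stop("unsatisfiable lesion request: fraction ",
             spec$lesionFraction, " exceeds the capacity of territory ",
             spec$lesionTerritory)
      if (k > 0) {
        ri <- which(region)
        ai <- arrayInd(ri, dm)
        pos <- t(t(ai - 1) * spec$voxelSpacing)
        ctr <- .gridCenter(dm, spec$voxelSpacing)
        rho <- sqrt(rowSums(sweep(pos, 2, ctr)^2))
        cand <- which(rho >= 0.5 * max(rho))
        seedRow <- cand[sample.int(length(cand), 1L)]
        d2 <- rowSums(sweep(pos, 2, pos[seedRow, ])^2)
        sel <- order(d2)[seq_len(k)]
        lesion[ri[sel]] <- TRUE
        contrast <- spec$strokeLevel - spec$brainLevel
        w <- if (spec$lesionProfile == "graded" && k > 1) {
          dmax <- sqrt(max(d2[sel]))
          pmax(0.3, 1.2 * (1 - d2[sel] / dmax^2))
        } else rep(1, k)
        signal[ri[sel]] <- spec$brainLevel + contrast * w
        if (!is.null(field))
          signal[ri[sel]] <- signal[ri[sel]] + field[ri[sel]]
      }
    }
    vals <- if (spec$noiseModel == "gaussian") {
      signal + spec$noiseSD * array(rnorm(n), dm)
    } else {
      sqrt((signal + spec$noiseSD * array(rnorm(n), dm))^2 +
             (spec$noiseSD * array(rnorm(n), dm))^2)
    }
    vals[vals < 0] <- 0
    DiffusionVolume(values = vals, spacing = spec$voxelSpacing,
                    brainMask = brain, lesionMask = lesion,
                    territory = spec$lesionTerritory)
  })
}

#' Generate a labelled phantom cohort
#'
#' Samples a lesion territory per case from \code{mix}, draws per-case lesion
#' fractions (log-normal around the clinical median burden of 2.3%, clipped
#' to [0.008, 0.04] so every territory wedge can accommodate the lesion)
#' unless the template fixes one, and assigns each case its own seed derived
#' from the cohort seed. With \code{outDir} set, volumes are written as NIfTI
#' and the manifest records their paths.
#'
#' @param n Number of cases (>= 1).
#' @param mix Named territory proportions summing to 1; default uniform over
#'   the five territories.
#' @param template A \code{\link{phantomSpec}} used for all non-lesion
#'   parameters; its \code{lesionFraction} (if not \code{NA}) fixes the
#'   fraction for every case.
#' @param seed Cohort seed; fixes labels, fractions and per-case seeds.
#' @param outDir Optional directory to write NIfTI volumes into.
#' @param keepVolumes Keep generated volumes in the return value (set to
#'   \code{FALSE} for large cohorts and regenerate from \code{specs}).
#' @return List with \code{manifest} (id, territory, lesionFraction, path,
#'   seed), \code{specs} (per-case \code{PhantomSpec}s) and \code{volumes}.
#' @export
makeCohort <- function(n, mix = NULL, template = phantomSpec(),
                       seed = 1L, outDir = NULL, keepVolumes = TRUE) {
  if (n < 1) stop("n must be >= 1")
  mix <- mix %||% setNames(rep(1 / 5, 5), .TERRITORIES)
  if (is.null(names(mix)) || !all(names(mix) %in% .TERRITORIES))
    stop("mix must be named with territory names")
  if (abs(sum(mix) - 1) > 1e-6) stop("mix proportions must sum to 1")
  withSeed(seed, {
    terr <- sample(names(mix), n, replace = TRUE, prob = mix)
    frac <- if (is.na(template$lesionFraction)) {
      pmin(0.04, pmax(0.008, rlnorm(n, log(0.023), 0.6)))
    } else rep(template$lesionFraction, n)
    caseSeeds <- sample.int(.Machine$integer.max - 1L, n)
  })
  ids <- sprintf("case_%03d", seq_len(n))
  specs <- lapply(seq_len(n), function(i) {
    s <- template
    s$lesionTerritory <- terr[i]
    s$lesionFraction <- frac[i]
    s$seed <- caseSeeds[i]
    s
  })
  paths <- rep(NA_character_, n)
  volumes <- if (keepVolumes || !is.null(outDir)) vector("list", n) else NULL
  for (i in seq_len(n)) {
    if (keepVolumes || !is.null(outDir)) {
      vol <- makeBrainPhantom(specs[[i]])
      if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        paths[i] <- file.path(outDir, paste0(ids[i], ".nii.gz"))
        saveVolume(vol, paths[i])
      }
      if (keepVolumes) volumes[[i]] <- vol
    }
  }
  manifest <- data.frame(id = ids, territory = terr, lesionFraction = frac,
                         path = paths, seed = caseSeeds,
                         stringsAsFactors = FALSE)
  if (!is.null(outDir))
    utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                     row.names = FALSE)
  list(manifest = manifest, specs = specs,
       volumes = if (keepVolumes) volumes else NULL)
}
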