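# End-to-end phantom study: simulate a cohort, segment and project every
# case, build the healthy diffusion reference from mirrored hemispheres,
# build the territory atlas from dedicated widespread-lesion cases (excluded
# from evaluation), flag and classify, then cross-validate and independently
# validate the territory recognition.

#' Configuration of a full phantom study
#'
#' Defaults mirror the clinical study layout: 14 atlas cases, 91
#' cross-validation cases, 20 independent hold-out cases, a healthy
#' reference built from 50 hemispheres, sigma level 2, 10 folds and 5%-step
#' cut-off grids.
#'
#' @param nAtlas Cases used to build the territory atlas (>= 5, one per
#'   territory at minimum); excluded from evaluation.
#' @param nCV Cross-validation cohort size.
#' @param nHoldout Independent validation cohort size (0 disables).
#' @param mix Territory proportions for evaluation cases; default uniform.
#' @param template \code{\link{phantomSpec}} template; its
#'   \code{lesionFraction = NA} default lets each case draw its own burden.
#' @param mapShape Map raster (width, height).
#' @param binWidth,smoothWindow Histogram parameters for segmentation.
#' @param sigmaLevel Flagging threshold k.
#' @param chooseSigma Select k from \code{sigmaCandidates} by the
#'   stroke-per-brain comparison instead of using \code{sigmaLevel}.
#' @param sigmaCandidates Candidate sigma levels.
#' @param nReferenceMaps Healthy hemispheres entering the reference.
#' @param atlasLesionScale Atlas-case lesion size as a fraction of each
#'   territory's capacity (widespread lesions give good atlas coverage).
#' @param nFolds,areaGrid,bulkGrid,plrCompat Validation parameters.
#' @param seed Master seed; all randomness in the run derives from it.
#' @param outDir Optional output directory for CSV/JSON artifacts.
#' @return List of class \code{"StudyConfig"}.
#' @export
studyConfig <- function(nAtlas = 14, nCV = 91, nHoldout = 20, mix = NULL,
                        template = phantomSpec(lesionFraction = NA),
                        mapShape = c(960L, 240L), binWidth = 1,
                        smoothWindow = 5, sigmaLevel = 2,
                        chooseSigma = FALSE, sigmaCandidates = c(1, 2, 3),
                        nReferenceMaps = 50, atlasLesionScale = 0.7,
                        nFolds = 10, areaGrid = seq(0, 1, by = 0.05),
                        bulkGrid = seq(0, 1, by = 0.05), plrCompat = TRUE,
                        seed = 1L, outDir = NULL) {
  stopifnot(nAtlas >= 5, nCV >= nFolds, nHoldout >= 0)
  structure(as.list(environment()), class = "StudyConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

# deterministic per-territory lesion capacity (fraction of brain volume
# available in the left half of each wedge)
.territoryCapacity <- function(template) {
  brain <- .brainEllipsoid(template$gridShape, template$voxelSpacing,
                           template$brainSemiAxes)
  vapply(.TERRITORIES, function(t)
    sum(territorySector(t, template$gridShape, template$voxelSpacing,
                        leftOnly = TRUE) & brain) / sum(brain), 0)
}

#' Run the full phantom study end to end
#'
#' Executes simulate, segment, project, build-reference, flag, build-atlas,
#' classify, cross-validate and (optionally) independent-validate with all
#' parameters and seeds recorded; the result is a pure function of the
#' configuration. Atlas cases are generated separately from the evaluation
#' cohort and the run refuses to proceed if any identifier appears in both.
#'
#' @param config A \code{\link{studyConfig}}.
#' @return List of class \code{"StudyReport"}: cohort partition, per-case
#'   thresholds and stroke burdens, sigma selection (when requested), the
#'   cross-validation \code{"ValidationReport"}, the independent validation,
#'   the atlas and reference summaries, and the configuration.
#' @export
runFullStudy <- function(config = studyConfig()) {
  stopifnot(inherits(config, "StudyConfig"))
  tpl <- config$template
  seeds <- withSeed(config$seed,
                    sample.int(.Machine$integer.max - 1L, 4L))
  mix <- config$mix %||% setNames(rep(1 / 5, 5), .TERRITORIES)

  # shared projection geometry: all phantoms share one brain shape, so the
  # common map frame is fixed once from the noise-free ellipsoid
  geom <- .stage("geometry", {
    brain0 <- .brainEllipsoid(tpl$gridShape, tpl$voxelSpacing,
                              tpl$brainSemiAxes)
    idx <- which(brain0)
    pos <- t(t(arrayInd(idx, dim(brain0)) - 1L) * tpl$voxelSpacing)
    ctr <- .gridCenter(tpl$gridShape, tpl$voxelSpacing)
    ProjectionGeometry(center = ctr,
                       radius = max(sqrt(rowSums(sweep(pos, 2, ctr)^2))),
                       mapShape = config$mapShape)
  })

  # cohort plan
  nEval <- config$nCV + config$nHoldout
  plan <- .stage("simulate", {
    capacity <- .territoryCapacity(tpl)
    atlasTerr <- rep(.TERRITORIES, length.out = config$nAtlas)
    atlasFrac <- pmin(0.3, config$atlasLesionScale * capacity[atlasTerr])
    ev <- withSeed(seeds[1L], {
      terr <- sample(names(mix), nEval, replace = TRUE, prob = mix)
      frac <- if (is.na(tpl$lesionFraction))
        pmin(0.04, pmax(0.008, rlnorm(nEval, log(0.023), 0.6)))
      else rep(tpl$lesionFraction, nEval)
      caseSeeds <- sample.int(.Machine$integer.max - 1L,
                              nEval + config$nAtlas)
      list(terr = terr, frac = frac, caseSeeds = caseSeeds)
    })
    list(ids = c(sprintf("atlas_%02d", seq_len(config$nAtlas)),
                 sprintf("case_%03d", seq_len(nEval))),
         terr = c(atlasTerr, ev$terr),
         frac = c(atlasFrac, ev$frac),
         seeds = ev$caseSeeds,
         role = c(rep("atlas", config$nAtlas),
                  rep("cv", config$nCV), rep("holdout", config$nHoldout)))
  })
  if (length(intersect(plan$ids[plan$role == "atlas"],
                       plan$ids[plan$role != "atlas"])))
    stop("atlas cases may not re-enter the evaluation cohort")

  nAll <- length(plan$ids)
  maps <- vector("list", nAll)
  p3d <- numeric(nAll)
  thr <- vector("list", nAll)
  .stage("segment/project", {
    for (i in seq_len(nAll)) {
      s <- tpl
      s$lesionTerritory <- plan$terr[i]
      s$lesionFraction <- plan$frac[i]
      s$seed <- plan$seeds[i]
      vol <- makeBrainPhantom(s)
      seg <- segmentVolume(vol, config$binWidth, config$smoothWindow)
      p3d[i] <- strokeBrainRatio3D(vol, seg$thresholds)
      thr[[i]] <- seg$thresholds[c("backgroundCutoff", "brainMode",
                                    "strokeCutoff")]
      maps[[i]] <- projectVolume(vol, seg$brainMask, geom)
    }
  })

  evalIdx <- which(plan$role != "atlas")
  ref <- .stage("build-reference", {
    nRef <- min(config$nReferenceMaps, length(evalIdx))
    healthy <- lapply(evalIdx[seq_len(nRef)], function(i)
      mirrorHealthyHemisphere(maps[[i]], strokeSide = "left"))
    buildDiffusionReference(healthy, sigmaLevel = config$sigmaLevel)
  })

  sigmaSel <- NULL
  if (config$chooseSigma) {
    sigmaSel <- .stage("choose-sigma",
      chooseSigmaLevel(maps[evalIdx], p3d[evalIdx], ref,
                       ks = config$sigmaCandidates))
    ref@sigmaLevel <- sigmaSel$k
  }

  strokes <- .stage("flag", lapply(maps, flagStrokePixels, ref = ref))

  atlasIdx <- which(plan$role == "atlas")
  atlas <- .stage("build-atlas",
    buildTerritoryAtlas(strokes[atlasIdx], plan$terr[atlasIdx],
                        ids = plan$ids[atlasIdx]))

  features <- .stage("classify",
    lapply(strokes[evalIdx], caseFeatures, atlas = atlas))
  truths <- lapply(plan$terr[evalIdx], identity)
  evalIds <- plan$ids[evalIdx]
  evalRole <- plan$role[evalIdx]
  cvIdx <- which(evalRole == "cv")
  hoIdx <- which(evalRole == "holdout")

  cv <- .stage("cross-validate",
    crossValidate(features[cvIdx], truths[cvIdx], evalIds[cvIdx],
                  nFolds = config$nFolds, seed = seeds[2L],
                  areaGrid = config$areaGrid, bulkGrid = config$bulkGrid,
                  plrCompat = config$plrCompat))

  indep <- if (config$nHoldout > 0) {
    .stage("independent-validate",
      independentValidate(features[cvIdx], truths[cvIdx], evalIds[cvIdx],
                          features[hoIdx], truths[hoIdx], evalIds[hoIdx],
                          areaGrid = config$areaGrid,
                          bulkGrid = config$bulkGrid,
                          plrCompat = config$plrCompat))
  } else NULL

  report <- structure(list(
    partition = list(atlas = plan$ids[atlasIdx], cv = evalIds[cvIdx],
                     holdout = evalIds[hoIdx]),
    cases = data.frame(id = plan$ids, role = plan$role,
                       territory = plan$terr, lesionFraction = plan$frac,
                       p3d = p3d,
                       backgroundCutoff = vapply(thr, `[[`, 0,
                                                 "backgroundCutoff"),
                       brainMode = vapply(thr, `[[`, 0, "brainMode"),
                       strokeCutoff = vapply(thr, `[[`, 0, "strokeCutoff"),
                       stringsAsFactors = FALSE),
    sigmaLevel = ref@sigmaLevel, sigmaSelection = sigmaSel,
    geometry = geom, atlas = atlas, reference = ref,
    crossValidation = cv, independent = indep,
    config = config, seed = config$seed), class = "StudyReport")
  if (!is.null(config$outDir)) .writeStudyReport(report, config$outDir)
  report
}

#' @export
print.StudyReport <- function(x, ...) {
  cat("StudyReport:", length(x$partition$atlas), "atlas /",
      length(x$partition$cv), "CV /", length(x$partition$holdout),
      "hold-out cases, sigma level", x$sigmaLevel, "\n")
  cat(sprintf("cross-validated mean sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$crossValidation$mean["sensitivity"],
              100 * x$crossValidation$mean["specificity"]))
  if (!is.null(x$independent))
    cat(sprintf("independent validation sensitivity %.1f%%, specificity %.1f%%\n",
                100 * x$independent$stats$sensitivity,
                100 * x$independent$stats$specificity))
  invisible(x)
}

.writeStudyReport <- function(report, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$crossValidation$perFold,
                   file.path(outDir, "cross_validation.csv"),
                   row.names = FALSE)
  utils::write.csv(report$cases, file.path(outDir, "cases.csv"),
                   row.names = FALSE)
  summary <- list(
    seed = report$seed, sigmaLevel = report$sigmaLevel,
    partition = report$partition,
    cvMean = as.list(report$crossValidation$mean),
    cvSD = as.list(report$crossValidation$sd),
    independent = if (!is.null(report$independent))
      c(unclass(report$independent$stats)[.statCols],
        list(counts = as.list(report$independent$counts))))
  jsonlite::write_json(summary, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}
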