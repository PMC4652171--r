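# Diagnostic-accuracy statistics, Youden-index cut-off optimisation,
# leave-p-out (outer) cross-validation and independent validation.

#' Contingency counts
#'
#' @param TP,FP,TN,FN Non-negative integer counts.
#' @return Named integer vector \code{c(TP, FP, TN, FN)}.
#' @export
contingencyCounts <- function(TP, FP, TN, FN) {
  x <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  if (sum(x) == 0) stop("all counts are zero")
  x
}

#' Diagnostic-accuracy statistics from contingency counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), predictive values
#' PPV = TP/(TP+FP), NPV = TN/(TN+FN), likelihood ratios
#' PLR = sensitivity/(1-specificity), NLR = (1-sensitivity)/specificity,
#' and the Youden index Y = sensitivity + specificity - 1.
#'
#' @param counts Named counts as from \code{\link{contingencyCounts}}.
#' @param plrCompat At perfect specificity the PLR is undefined
#'   (\code{NA}); with \code{plrCompat = TRUE} it is reported as 0 instead,
#'   the convention used in the clinical result tables this package
#'   reproduces.
#' @return List of class \code{"DiagnosticStats"} with the seven statistics
#'   and the counts. Errors when a truth margin (TP+FN or TN+FP) is empty.
#' @export
diagnosticStats <- function(counts, plrCompat = FALSE) {
  TP <- unname(counts["TP"]); FP <- unname(counts["FP"])
  TN <- unname(counts["TN"]); FN <- unname(counts["FN"])
  if (anyNA(c(TP, FP, TN, FN))) stop("counts must be named TP, FP, TN, FN")
  if (TP + FN == 0 || TN + FP == 0)
    stop("undefined statistic: empty truth margin")
  sens <- TP / (TP + FN)
  spec <- TN / (TN + FP)
  structure(list(
    sensitivity = sens, specificity = spec,
    ppv = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
    npv = if (TN + FN > 0) TN / (TN + FN) else NA_real_,
    plr = if (spec < 1) sens / (1 - spec)
          else if (plrCompat) 0 else NA_real_,
    nlr = if (spec > 0) (1 - sens) / spec else Inf,
    youden = sens + spec - 1,
    counts = c(TP = TP, FP = FP, TN = TN, FN = FN)),
    class = "DiagnosticStats")
}

#' @export
print.DiagnosticStats <- function(x, ...) {
  cat(sprintf(
    "sensitivity %.1f%%  specificity %.1f%%  PPV %.3f  NPV %.3f  PLR %.3f  NLR %.3f\n",
    100 * x$sensitivity, 100 * x$specificity, x$ppv, x$npv, x$plr, x$nlr))
  cat(sprintf("counts: TP %d  FP %d  TN %d  FN %d\n",
              x$counts["TP"], x$counts["FP"], x$counts["TN"], x$counts["FN"]))
  invisible(x)
}

#' Youden index
#'
#' @param counts Contingency counts with both truth margins non-empty.
#' @return Y = sensitivity + specificity - 1, in [-1, 1].
#' @export
youdenIndex <- function(counts) {
  st <- diagnosticStats(counts, plrCompat = TRUE)
  st$youden
}

.statCols <- c("sensitivity", "specificity", "ppv", "npv", "plr", "nlr",
               "youden")

#' Optimise per-territory cut-offs by maximising the Youden index
#'
#' Grid search over (area, bulk) cut-off pairs for each territory,
#' maximising the Youden index of the pooled decisions over the training
#' cases. Ties break toward the largest area cut-off, then the largest bulk
#' cut-off (the most conservative rule). Territories absent from the
#' training truth cannot be optimised: a warning is raised and the grid
#' maxima are used. The full per-territory grid trace (an ROC-style table)
#' is returned alongside the chosen configuration.
#'
#' @param features List of per-case feature sets from
#'   \code{\link{caseFeatures}}.
#' @param truths List of per-case true territory label vectors.
#' @param areaGrid,bulkGrid Candidate cut-offs; default 0 to 1 in 5% steps.
#' @return List with \code{cutoffs} (a \code{"CutoffConfig"}) and
#'   \code{roc} (per-territory data.frames of area, bulk, sensitivity,
#'   specificity and Youden index).
#' @export
optimizeCutoffs <- function(features, truths,
                            areaGrid = seq(0, 1, by = 0.05),
                            bulkGrid = seq(0, 1, by = 0.05)) {
  stopifnot(length(features) == length(truths), length(features) >= 1,
            length(areaGrid) >= 1, length(bulkGrid) >= 1)
  n <- length(features)
  covM <- t(vapply(features, function(f) f$coverage[.TERRITORIES],
                   numeric(5)))
  blkM <- t(vapply(features, function(f) f$bulk[.TERRITORIES], numeric(5)))
  area <- bulk <- setNames(numeric(5), .TERRITORIES)
  roc <- list()
  grid <- expand.grid(area = areaGrid, bulk = bulkGrid,
                      KEEP.OUT.ATTRS = FALSE)
  for (t in .TERRITORIES) {
    y <- vapply(truths, function(l) t %in% l, TRUE)
    if (!any(y)) {
      warning("territory ", t, " absent from training truth; ",
              "using grid maxima")
      area[t] <- max(areaGrid)
      bulk[t] <- max(bulkGrid)
      next
    }
    nPos <- sum(y); nNeg <- sum(!y)
    sens <- spec <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      pos <- covM[, t] > grid$area[g] |
        (grid$bulk[g] > 0 & blkM[, t] > grid$bulk[g])
      sens[g] <- sum(pos & y) / nPos
      spec[g] <- if (nNeg > 0) sum(!pos & !y) / nNeg else 1
    }
    yj <- sens + spec - 1
    best <- which(yj == max(yj))
    best <- best[order(-grid$area[best], -grid$bulk[best])][1L]
    area[t] <- grid$area[best]
    bulk[t] <- grid$bulk[best]
    roc[[t]] <- data.frame(area = grid$area, bulk = grid$bulk,
                           sensitivity = sens, specificity = spec,
                           youden = yj)
  }
  list(cutoffs = cutoffConfig(area, bulk), roc = roc)
}

# pooled outcome counts of a case subset under a cutoff configuration
.pooledCounts <- function(features, truths, cutoffs) {
  outcomes <- lapply(seq_along(features), function(i)
    diagnosisAgainstTruth(.applyCutoffs(features[[i]], cutoffs)$positive,
                          truths[[i]]))
  countOutcomes(outcomes)
}

#' Leave-p-out (outer) cross-validation of the territory classifier
#'
#' The cohort is randomly partitioned (seeded uniform shuffle, then
#' contiguous near-equal chunks; the remainder cases go to the first folds)
#' into \code{nFolds} subgroups. In each round the cut-offs are optimised on
#' the other folds and evaluated on the held-out fold; per-fold statistics
#' are averaged, with SDs using the population divisor n over folds.
#'
#' @param features,truths Per-case feature sets and true label vectors.
#' @param ids Unique case identifiers (audited so that no held-out case is
#'   seen during its fold's optimisation).
#' @param nFolds Number of validation folds (default 10).
#' @param seed Seed for the fold shuffle; recorded in the report.
#' @param areaGrid,bulkGrid Cut-off grids, see \code{\link{optimizeCutoffs}}.
#' @param plrCompat See \code{\link{diagnosticStats}}.
#' @return List of class \code{"ValidationReport"}: \code{perFold}
#'   data.frame (statistics and counts per fold), \code{mean} and \code{sd}
#'   rows over folds, \code{folds} (id to fold assignment), per-fold
#'   \code{cutoffs}, and the \code{seed}.
#' @export
crossValidate <- function(features, truths, ids = NULL, nFolds = 10,
                          seed = 1L, areaGrid = seq(0, 1, by = 0.05),
                          bulkGrid = seq(0, 1, by = 0.05),
                          plrCompat = TRUE) {
  n <- length(features)
  stopifnot(length(truths) == n)
  if (n < nFolds) stop("fewer cases than folds")
  ids <- ids %||% sprintf("case_%03d", seq_len(n))
  if (anyDuplicated(ids)) stop("case identifiers must be unique")
  perm <- withSeed(seed, sample.int(n))
  sizes <- rep(n %/% nFolds, nFolds)
  rem <- n %% nFolds
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  foldOf <- integer(n)
  foldOf[perm] <- rep(seq_len(nFolds), times = sizes)
  rows <- vector("list", nFolds)
  cutoffs <- vector("list", nFolds)
  for (k in seq_len(nFolds)) {
    test <- which(foldOf == k)
    train <- which(foldOf != k)
    if (length(intersect(ids[test], ids[train])))
      stop("fold audit failed: held-out case present in training set")
    opt <- optimizeCutoffs(features[train], truths[train],
                           areaGrid, bulkGrid)
    cutoffs[[k]] <- opt$cutoffs
    cnt <- .pooledCounts(features[test], truths[test], opt$cutoffs)
    st <- diagnosticStats(cnt, plrCompat = plrCompat)
    rows[[k]] <- data.frame(fold = k, n = length(test),
                            as.data.frame(unclass(st)[.statCols]),
                            TP = cnt["TP"], FP = cnt["FP"],
                            TN = cnt["TN"], FN = cnt["FN"],
                            row.names = NULL)
  }
  perFold <- do.call(rbind, rows)
  structure(list(
    perFold = perFold,
    mean = vapply(perFold[.statCols], mean, 0),
    sd = vapply(perFold[.statCols], .popSD, 0),
    folds = data.frame(id = ids, fold = foldOf, stringsAsFactors = FALSE),
    cutoffs = cutoffs, seed = seed),
    class = "ValidationReport")
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat("Cross-validation over", nrow(x$perFold), "folds (seed", x$seed, "):\n")
  print(cbind(round(x$perFold[c("fold", "n")], 0),
              round(x$perFold[.statCols], 3)), row.names = FALSE)
  cat(sprintf("mean sensitivity %.1f%%, specificity %.1f%%  (SD %.1f%% / %.1f%%)\n",
              100 * x$mean["sensitivity"], 100 * x$mean["specificity"],
              100 * x$sd["sensitivity"], 100 * x$sd["specificity"]))
  invisible(x)
}

#' Independent validation on a held-out set
#'
#' Optimises the cut-offs on the full training cohort and evaluates the
#' pooled patient-by-territory decisions on a disjoint hold-out set.
#'
#' @param trainFeatures,trainTruths,trainIds Training cohort.
#' @param holdFeatures,holdTruths,holdIds Hold-out cohort; identifiers must
#'   not overlap the training identifiers.
#' @param areaGrid,bulkGrid,plrCompat As in \code{\link{crossValidate}}.
#' @return List with \code{stats} (a \code{"DiagnosticStats"}),
#'   \code{counts} and the optimised \code{cutoffs}.
#' @export
independentValidate <- function(trainFeatures, trainTruths, trainIds,
                                holdFeatures, holdTruths, holdIds,
                                areaGrid = seq(0, 1, by = 0.05),
                                bulkGrid = seq(0, 1, by = 0.05),
                                plrCompat = TRUE) {
  if (length(holdFeatures) == 0) stop("empty hold-out set")
  if (length(intersect(trainIds, holdIds)))
    stop("hold-out cases overlap the training set")
  opt <- optimizeCutoffs(trainFeatures, trainTruths, areaGrid, bulkGrid)
  cnt <- .pooledCounts(holdFeatures, holdTruths, opt$cutoffs)
  list(stats = diagnosticStats(cnt, plrCompat = plrCompat), counts = cnt,
       cutoffs = opt$cutoffs)
}

#' Stroke-per-brain discrepancy between volume and map
#'
#' Compares the 3D stroke-per-brain volume ratio with the 2D flagged-area
#' fraction of the projected map. The default relative mode reports
#' \code{100 * |p3d - p2d| / p3d} (percent of the 3D ratio); the absolute
#' mode reports \code{100 * |p3d - p2d|} (percentage points).
#'
#' @param p3d 3D stroke-per-brain ratio (fraction).
#' @param p2d 2D flagged-area fraction (see \code{\link{mapStrokeFraction}}).
#' @param mode \code{"relative"} (default) or \code{"absolute"}.
#' @return Discrepancy in percent.
#' @export
spbDifference <- function(p3d, p2d, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  if (mode == "relative") {
    if (p3d == 0) stop("relative discrepancy undefined for p3d = 0")
    100 * abs(p3d - p2d) / p3d
  } else {
    100 * abs(p3d - p2d)
  }
}
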