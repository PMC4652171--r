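# Two-criterion territory classifier. A territory is stroke-positive when
# (1) a large fraction of its atlas area is covered by stroke-indicating
# pixels, or (2) a large bulk of all stroke-indicating pixels falls into it.
# Cut-offs are compared with strict inequality; a bulk cut-off of exactly 0
# disables criterion 2 for that territory (a literal 0% threshold would fire
# on any single scattered pixel).

#' Per-territory cut-off configuration
#'
#' @param area Named fractions in [0, 1]: how much of a territory's area
#'   must be covered by stroke pixels (criterion 1).
#' @param bulk Named fractions in [0, 1]: how much of all stroke pixels must
#'   convene in the territory (criterion 2); 0 disables the criterion.
#' @return List of class \code{"CutoffConfig"}.
#' @export
cutoffConfig <- function(area, bulk) {
  area <- area[.TERRITORIES]
  bulk <- bulk[.TERRITORIES]
  if (any(is.na(area)) || any(is.na(bulk)))
    stop("area and bulk must be named for all five territories")
  if (any(area < 0 | area > 1 | bulk < 0 | bulk > 1))
    stop("all cut-offs must lie in [0, 1]")
  structure(list(area = area, bulk = bulk), class = "CutoffConfig")
}

#' Published per-territory cut-offs
#'
#' The cut-off configuration reported for the clinical cohort (modal values
#' across the cross-validation rounds): area cut-offs of 20/10/5/10/30% for
#' ACA/supMCA/infMCA/PCA/PICA, bulk cut-offs of 90% (PCA) and 50% (PICA),
#' with criterion 2 unused for the other territories.
#'
#' @return A \code{"CutoffConfig"}.
#' @export
defaultCutoffs <- function() {
  cutoffConfig(
    area = c(ACA = 0.20, supMCA = 0.10, infMCA = 0.05, PCA = 0.10,
             PICA = 0.30),
    bulk = c(ACA = 0, supMCA = 0, infMCA = 0, PCA = 0.90, PICA = 0.50))
}

#' Coverage and bulk features of a stroke mask
#'
#' For each territory t: \code{coverage(t)} = flagged pixels inside the
#' territory mask / territory mask area; \code{bulk(t)} = flagged pixels
#' inside the territory / all flagged pixels (0 when no pixel is flagged).
#'
#' @param stroke Logical stroke mask.
#' @param atlas A \linkS4class{TerritoryAtlas} on the same raster.
#' @return List with named numeric vectors \code{coverage} and \code{bulk}.
#' @export
caseFeatures <- function(stroke, atlas) {
  .checkSameRaster(stroke, atlas@masks[[1]], "stroke mask and atlas")
  total <- sum(stroke)
  inter <- vapply(.TERRITORIES,
                  function(t) sum(stroke & atlas@masks[[t]]), 0)
  areas <- vapply(.TERRITORIES, function(t) sum(atlas@masks[[t]]), 0)
  list(coverage = inter / areas,
       bulk = if (total == 0) setNames(rep(0, 5), .TERRITORIES)
              else inter / total)
}

# decision rule on precomputed features
.applyCutoffs <- function(features, cutoffs) {
  byArea <- features$coverage > cutoffs$area
  byBulk <- cutoffs$bulk > 0 & features$bulk > cutoffs$bulk
  list(positive = byArea | byBulk, byArea = byArea, byBulk = byBulk)
}

#' Classify a stroke mask into territory diagnoses
#'
#' @param stroke Logical stroke mask from \code{\link{flagStrokePixels}}.
#' @param atlas A \linkS4class{TerritoryAtlas}.
#' @param cutoffs A \code{"CutoffConfig"}; default the published values.
#' @return Data.frame of class \code{"TerritoryDiagnosis"} with one row per
#'   territory: \code{coverage}, \code{bulk}, logical \code{positive} and
#'   the firing \code{criterion} (\code{"area"}, \code{"bulk"},
#'   \code{"both"} or \code{"none"}). An empty stroke mask yields five
#'   negative calls.
#' @export
classifyTerritories <- function(stroke, atlas, cutoffs = defaultCutoffs()) {
  ft <- caseFeatures(stroke, atlas)
  dec <- .applyCutoffs(ft, cutoffs)
  data.frame(territory = .TERRITORIES, coverage = unname(ft$coverage),
             bulk = unname(ft$bulk), positive = unname(dec$positive),
             criterion = ifelse(dec$byArea & dec$byBulk, "both",
                         ifelse(dec$byArea, "area",
                         ifelse(dec$byBulk, "bulk", "none"))),
             row.names = .TERRITORIES, stringsAsFactors = FALSE)
}

#' Compare a diagnosis with the recorded truth
#'
#' Per territory: TP when called positive and truly affected, FP when
#' positive and unaffected, TN negative and unaffected, FN negative and
#' affected — so each patient contributes exactly five outcomes.
#'
#' @param diagnosis A \code{"TerritoryDiagnosis"} data.frame or a named
#'   logical vector of positive calls.
#' @param trueLabels Character vector of truly affected territories (subset
#'   of \code{territoryNames()}).
#' @return Named character vector over territories with values
#'   \code{"TP"}, \code{"FP"}, \code{"TN"}, \code{"FN"}.
#' @export
diagnosisAgainstTruth <- function(diagnosis, trueLabels) {
  bad <- setdiff(trueLabels, .TERRITORIES)
  if (length(bad)) stop("unknown territory label: ", paste(bad, collapse = ", "))
  pos <- if (is.data.frame(diagnosis))
    setNames(diagnosis$positive, rownames(diagnosis))[.TERRITORIES]
  else diagnosis[.TERRITORIES]
  truth <- .TERRITORIES %in% trueLabels
  setNames(ifelse(pos & truth, "TP",
           ifelse(pos & !truth, "FP",
           ifelse(truth, "FN", "TN"))), .TERRITORIES)
}

#' Tally outcome labels into contingency counts
#'
#' @param outcomes Character vector(s) of \code{"TP"/"FP"/"TN"/"FN"}.
#' @return Named integer vector \code{c(TP, FP, TN, FN)}.
#' @export
countOutcomes <- function(outcomes) {
  outcomes <- unlist(outcomes, use.names = FALSE)
  vapply(c(TP = "TP", FP = "FP", TN = "TN", FN = "FN"),
         function(k) sum(outcomes == k), 0L)
}
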