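# Intensity-histogram segmentation of a diffusion volume into background,
# healthy brain and stroke-affected tissue. The background/brain cut-off is
# the minimum of the dip between the two dominant histogram peaks; the
# brain/stroke cut-off reflects that minimum across the healthy-brain peak
# maximum (the healthy distribution is symmetric, the stroke tail skews it
# to the right).

#' Build an intensity histogram
#'
#' @param x A \linkS4class{DiffusionVolume} or numeric vector.
#' @param binWidth Bin width in a.u. (> 0); default 1 a.u., suited to data in
#'   the 0-400 a.u. regime.
#' @param origin Lower edge alignment: bin edges are placed at integer
#'   multiples of \code{binWidth} plus \code{origin}.
#' @return An object of class \code{"IntensityHistogram"}: list with
#'   \code{edges}, \code{counts}, \code{mids}, \code{binWidth}. Counts
#'   conserve the total number of values.
#' @export
buildHistogram <- function(x, binWidth = 1, origin = 0) {
  v <- if (is(x, "DiffusionVolume")) as.vector(x@values) else as.numeric(x)
  stopifnot(length(v) > 0, binWidth > 0)
  lo <- floor((min(v) - origin) / binWidth) * binWidth + origin
  nb <- max(1L, ceiling((max(v) - lo) / binWidth + 1e-9))
  edges <- lo + (0:nb) * binWidth
  idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = nb)
  structure(list(edges = edges, counts = counts,
                 mids = (edges[-1] + edges[-(nb + 1)]) / 2,
                 binWidth = binWidth),
            class = "IntensityHistogram")
}

#' @export
print.IntensityHistogram <- function(x, ...) {
  cat("IntensityHistogram:", length(x$counts), "bins of width", x$binWidth,
      "over [", x$edges[1], ",", x$edges[length(x$edges)], "],",
      sum(x$counts), "values\n")
  invisible(x)
}

# moving-average smoothing with partial windows at the edges
.smoothCounts <- function(counts, window = 5) {
  n <- length(counts)
  if (window <= 1 || n < 3) return(as.numeric(counts))
  half <- floor(window / 2)
  cs <- cumsum(c(0, counts))
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# start indices of local-maximum plateaus (first bin of a plateau, so ties
# break toward the lowest intensity)
.localMaxima <- function(s) {
  r <- rle(s)
  k <- length(r$values)
  if (k == 1L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  left <- c(-Inf, r$values[-k])
  right <- c(r$values[-1], -Inf)
  starts[r$values > left & r$values > right]
}

# the two dominant, genuinely separated peaks of a smoothed histogram:
# the global maximum plus the highest other local maximum that is at least
# minPeakRatio of it and whose connecting valley drops below valleyRatio of
# the lower peak. NULL when unimodal (noise bumps in the tails never
# qualify as a second mode).
.twoMainPeaks <- function(s, valleyRatio = 0.5, minPeakRatio = 0.05) {
  peaks <- .localMaxima(s)
  if (length(peaks) < 2L) return(NULL)
  peaks <- peaks[order(-s[peaks], peaks)]
  p1 <- peaks[1L]
  peaks <- peaks[s[peaks] >= minPeakRatio * s[p1]]
  if (length(peaks) < 2L) return(NULL)
  for (p2 in peaks[-1L]) {
    lo <- min(p1, p2); hi <- max(p1, p2)
    if (hi - lo < 2L) next
    valley <- min(s[(lo + 1L):(hi - 1L)])
    if (valley < valleyRatio * min(s[p1], s[p2])) return(sort(c(p1, p2)))
  }
  NULL
}

#' Background/brain cut-off from the histogram dip
#'
#' Finds the two dominant peaks of the smoothed histogram (background and
#' healthy brain) and returns the intensity of the minimum of the dip
#' strictly between them. When several bins tie at the minimum (an empty
#' valley between well-separated populations), the central tied bin is
#' taken: the midpoint of a flat dip is its minimum for all practical
#' purposes and keeps the reflected stroke cut-off from drifting upward.
#'
#' @param hist An \code{"IntensityHistogram"}.
#' @param window Moving-average smoothing window in bins (default 5; raw
#'   counts are too noisy for extremum detection).
#' @return Cut-off intensity in a.u.
#' @export
backgroundCutoff <- function(hist, window = 5) {
  s <- .smoothCounts(hist$counts, window)
  pk <- .twoMainPeaks(s)
  if (is.null(pk))
    stop("no background/brain separation: histogram appears unimodal")
  seg <- (pk[1] + 1L):(pk[2] - 1L)
  ties <- seg[s[seg] == min(s[seg])]
  dip <- ties[ceiling(length(ties) / 2)]
  hist$mids[dip]
}

#' Brain/stroke cut-off by reflection across the brain peak
#'
#' The healthy-brain peak maximum is located above the background cut-off;
#' the cut-off between healthy brain and stroke is the dip minimum reflected
#' across it: \code{2 * brainMode - backgroundCutoff}. The returned value
#' carries the located \code{brainMode} as an attribute.
#'
#' @param hist An \code{"IntensityHistogram"}.
#' @param backgroundCutoff Background/brain cut-off in a.u. (the dip-minimum
#'   intensity, see \code{\link{backgroundCutoff}}).
#' @param window Smoothing window in bins.
#' @return Cut-off intensity in a.u. with attribute \code{brainMode}.
#' @export
strokeCutoff <- function(hist, backgroundCutoff, window = 5) {
  s <- .smoothCounts(hist$counts, window)
  above <- which(hist$mids > backgroundCutoff)
  if (length(above) == 0L || all(s[above] == 0))
    stop("no brain peak above the background cut-off")
  modeIdx <- above[which.max(s[above])]
  if (modeIdx >= length(s))
    stop("brain peak lies at the histogram edge")
  mode <- hist$mids[modeIdx]
  out <- 2 * mode - backgroundCutoff
  attr(out, "brainMode") <- mode
  out
}

#' All segmentation thresholds of a volume
#'
#' @param x A \linkS4class{DiffusionVolume}, numeric vector or
#'   \code{"IntensityHistogram"}.
#' @param binWidth,window Histogram bin width (a.u.) and smoothing window
#'   (bins).
#' @return List of class \code{"SegmentationThresholds"} with
#'   \code{backgroundCutoff}, \code{brainMode}, \code{strokeCutoff} and the
#'   histogram; always \code{backgroundCutoff < brainMode < strokeCutoff}.
#' @export
segmentationThresholds <- function(x, binWidth = 1, window = 5) {
  hist <- if (inherits(x, "IntensityHistogram")) x
          else buildHistogram(x, binWidth)
  bg <- backgroundCutoff(hist, window)
  sc <- strokeCutoff(hist, bg, window)
  out <- list(backgroundCutoff = bg, brainMode = attr(sc, "brainMode"),
              strokeCutoff = as.numeric(sc), histogram = hist)
  if (!(out$backgroundCutoff < out$brainMode &&
        out$brainMode < out$strokeCutoff))
    stop("inconsistent thresholds: need background < brain mode < stroke")
  class(out) <- "SegmentationThresholds"
  out
}

#' @export
print.SegmentationThresholds <- function(x, ...) {
  cat(sprintf(
    "SegmentationThresholds: background < %.1f a.u., brain mode %.1f, stroke > %.1f\n",
    x$backgroundCutoff, x$brainMode, x$strokeCutoff))
  invisible(x)
}

#' Kolmogorov-Smirnov check for Gaussian intensities
#'
#' One-sample KS test of a sample against a Gaussian with the sample's own
#' mean and SD. Because the parameters are estimated from the data the test
#' is conservative. The check is advisory: the segmentation assumes an
#' approximately Gaussian histogram, and this quantifies how reasonable that
#' is at the signal-to-noise level at hand; it never blocks the pipeline.
#'
#' @param x Numeric sample (>= 20 values, non-degenerate).
#' @param alpha Flagging level (default 0.05).
#' @return List with \code{statistic}, \code{p.value} and logical
#'   \code{reject}.
#' @export
gaussianityCheck <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  if (length(x) < 20) stop("need at least 20 values")
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("degenerate (zero-variance) sample")
  kt <- suppressWarnings(ks.test(x, "pnorm", mean(x), s))
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       reject = kt$p.value < alpha)
}

#' 3D stroke-per-brain volume ratio
#'
#' @param vol A \linkS4class{DiffusionVolume}.
#' @param thresholds A \code{"SegmentationThresholds"}.
#' @return Fraction of above-background voxels that lie above the stroke
#'   cut-off, in [0, 1].
#' @export
strokeBrainRatio3D <- function(vol, thresholds) {
  v <- as.vector(vol@values)
  nBrain <- sum(v > thresholds$backgroundCutoff)
  if (nBrain == 0) stop("empty brain: no voxels above the background cut-off")
  sum(v > thresholds$strokeCutoff) / nBrain
}

#' Segment a volume into brain and stroke masks
#'
#' @param vol A \linkS4class{DiffusionVolume}.
#' @param binWidth,window Passed to \code{\link{segmentationThresholds}}.
#' @return List with \code{thresholds}, logical \code{brainMask}
#'   (above-background voxels) and \code{strokeMask3D} (above-stroke-cut-off
#'   voxels).
#' @export
segmentVolume <- function(vol, binWidth = 1, window = 5) {
  th <- segmentationThresholds(vol, binWidth, window)
  list(thresholds = th,
       brainMask = vol@values > th$backgroundCutoff,
       strokeMask3D = vol@values > th$strokeCutoff)
}
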