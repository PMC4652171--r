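test_that("diagnostic statistics follow the standard definitions", {
  st <- diagnosticStats(contingencyCounts(11, 4, 28, 2))
  expect_equal(st$sensitivity, 11 / 13)
  expect_equal(st$specificity, 28 / 32)
  expect_equal(st$ppv, 11 / 15)
  expect_equal(st$npv, 28 / 30)
  expect_equal(st$plr, (11 / 13) / (1 - 28 / 32))
  expect_equal(st$nlr, (1 - 11 / 13) / (28 / 32))
  expect_equal(st$youden, st$sensitivity + st$specificity - 1)

  perfect <- diagnosticStats(contingencyCounts(7, 0, 7, 0), plrCompat = TRUE)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$youden, 1)
  expect_equal(perfect$plr, 0)     # compatibility convention
  expect_true(is.na(diagnosticStats(contingencyCounts(7, 0, 7, 0))$plr))

  expect_error(diagnosticStats(contingencyCounts(0, 3, 5, 0)), "margin")
  expect_error(contingencyCounts(-1, 0, 2, 0), "non-negative")
})

test_that("the Youden index is centred at zero for chance decisions", {
  expect_equal(youdenIndex(contingencyCounts(5, 0, 9, 0)), 1)
  expect_equal(youdenIndex(contingencyCounts(11, 4, 28, 2)),
               0.721, tolerance = 5e-4)
  set.seed(19)
  nPos <- 8L; nNeg <- 32L; p <- 0.3
  y <- vapply(seq_len(1e4), function(i) {
    tp <- rbinom(1, nPos, p); fp <- rbinom(1, nNeg, p)
    tp / nPos + (nNeg - fp) / nNeg - 1
  }, 0)
  expect_lt(abs(mean(y)), 0.01)
})

test_that("cut-off optimisation maximises Youden with conservative ties", {
  mkFeat <- function(cov) list(
    coverage = setNames(rep(cov, 5), territoryNames()),
    bulk = setNames(rep(0, 5), territoryNames()))
  # positives at 30% coverage, negatives at 2%: perfectly separable
  features <- c(lapply(1:6, function(i) mkFeat(0.30)),
                lapply(1:6, function(i) mkFeat(0.02)))
  truths <- c(lapply(1:6, function(i) territoryNames()),
              lapply(1:6, function(i) character(0)))
  opt <- optimizeCutoffs(features, truths)
  expect_true(all(opt$cutoffs$area >= 0.05 & opt$cutoffs$area < 0.30))
  expect_equal(max(opt$roc$PICA$youden), 1)
  # conservative tie-break: the largest separating area cut-off
  expect_equal(unname(opt$cutoffs$area["ACA"]), 0.25)

  single <- optimizeCutoffs(features, truths, areaGrid = 0.15,
                            bulkGrid = 0.4)
  expect_equal(unname(single$cutoffs$area), rep(0.15, 5))
  expect_equal(unname(single$cutoffs$bulk), rep(0.4, 5))

  w <- capture_warnings(optimizeCutoffs(features[7:12], truths[7:12]))
  expect_true(any(grepl("absent from training truth", w)))
})

test_that("cross-validation partitions 91 cases into nine 9s and one 10", {
  terr <- rep(territoryNames(), length.out = 91)
  set.seed(5)
  features <- lapply(seq_len(91), function(i) {
    cov <- setNames(rep(0.01, 5), territoryNames())
    cov[terr[i]] <- runif(1, 0.2, 0.4)
    list(coverage = cov, bulk = setNames(rep(0.1, 5), territoryNames()))
  })
  truths <- as.list(terr)
  cv <- crossValidate(features, truths, nFolds = 10, seed = 3)
  sizes <- sort(table(cv$folds$fold))
  expect_equal(unname(as.integer(sizes)), c(rep(9L, 9), 10L))
  expect_equal(nrow(cv$folds), 91)
  expect_true(all(table(cv$folds$id) == 1))     # each case in one fold
  counts <- cv$perFold[, c("TP", "FP", "TN", "FN")]
  expect_equal(unname(rowSums(counts)), 5 * cv$perFold$n)  # 5 per case

  cv2 <- crossValidate(features, truths, nFolds = 10, seed = 3)
  expect_identical(cv$perFold, cv2$perFold)     # seeded determinism

  expect_error(crossValidate(features[1:5], truths[1:5], nFolds = 10),
               "fewer cases")
})

test_that("fold means and SDs reproduce the published aggregate rows", {
  tab <- publishedTable()
  cvRows <- tab[tab$group != "independent", ]
  sens <- cvRows$TP / (cvRows$TP + cvRows$FN)
  spec <- cvRows$TN / (cvRows$TN + cvRows$FP)
  popSD <- function(x) sqrt(mean((x - mean(x))^2))
  expect_equal(round(100 * mean(sens), 1), 80.6)
  expect_equal(round(100 * popSD(sens), 1), 7.8)
  expect_equal(round(100 * mean(spec), 1), 87.3)
  expect_equal(round(100 * popSD(spec), 1), 6.8)
  # the sample SD would NOT reproduce the published rows
  expect_gt(round(100 * sd(sens), 1), 7.8)
})

test_that("independent validation guards against case leakage", {
  mkFeat <- function(cov) list(
    coverage = setNames(c(cov, 0, 0, 0, 0), territoryNames()),
    bulk = setNames(rep(0, 5), territoryNames()))
  train <- lapply(c(0.3, 0.3, 0.02, 0.02), mkFeat)
  truthsT <- list("ACA", "ACA", character(0), character(0))
  hold <- lapply(c(0.35, 0.01), mkFeat)
  truthsH <- list("ACA", character(0))
  res <- suppressWarnings(
    independentValidate(train, truthsT, c("a", "b", "c", "d"),
                        hold, truthsH, c("e", "f")))
  expect_equal(sum(res$counts), 10)             # 2 cases x 5 territories
  expect_equal(unname(res$counts["TP"]), 1L)

  expect_error(independentValidate(train, truthsT, c("a", "b", "c", "d"),
                                   hold, truthsH, c("a", "f")),
               "overlap")
  expect_error(independentValidate(train, truthsT, c("a", "b", "c", "d"),
                                   list(), list(), character(0)),
               "empty")
})

test_that("stroke-per-brain discrepancies are reported in percent", {
  expect_equal(spbDifference(0.04, 0.05), 25)
  expect_equal(spbDifference(0.04, 0.04), 0)
  expect_equal(spbDifference(0.04, 0.05, mode = "absolute"), 1)
  expect_error(spbDifference(0, 0.05), "undefined")
})
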