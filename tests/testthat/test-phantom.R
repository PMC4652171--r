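test_that("phantom generation is deterministic and honours the spec", {
  v1 <- smallPhantom("PICA", 0.03, seed = 11)
  v2 <- smallPhantom("PICA", 0.03, seed = 11)
  expect_identical(intensities(v1), intensities(v2))
  expect_identical(lesionMask(v1), lesionMask(v2))

  v3 <- smallPhantom("none")
  expect_equal(sum(lesionMask(v3)), 0)
  expect_identical(trueTerritory(v3), "none")

  expect_error(smallPhantom("PICA", 0.25), "unsatisfiable")
  expect_error(phantomSpec(backgroundLevel = 200), "background < brain")
  expect_error(phantomSpec(lesionTerritory = "SCA"), "unknown")
  expect_error(phantomSpec(lesionFraction = 0.5), "0.3")
})

test_that("default intensity regimes give a tri-modal histogram", {
  v <- makeBrainPhantom(phantomSpec(gridShape = c(64L, 64L, 64L),
                                    voxelSpacing = c(3, 3, 3),
                                    lesionTerritory = "infMCA",
                                    lesionFraction = 0.05, seed = 3))
  h <- buildHistogram(v, binWidth = 1)
  s <- strokemap:::.smoothCounts(h$counts, 5)
  peaks <- h$mids[strokemap:::.localMaxima(s)]
  expect_true(any(abs(peaks - 20) <= 10))
  expect_true(any(abs(peaks - 180) <= 10))
  expect_true(any(abs(peaks - 300) <= 10))

  # ground-truth populations have disjoint interquartile ranges
  vals <- intensities(v)
  bg <- vals[!brainMask(v)]
  br <- vals[brainMask(v) & !lesionMask(v)]
  st <- vals[lesionMask(v)]
  expect_lt(quantile(bg, 0.75), quantile(br, 0.25))
  expect_lt(quantile(br, 0.75), quantile(st, 0.25))
})

test_that("territory sectors are fixed, disjoint where required, and wide", {
  gs <- c(48L, 48L, 48L)
  sp <- c(4, 4, 4)
  secs <- lapply(territoryNames(), territorySector, gridShape = gs,
                 voxelSpacing = sp)
  names(secs) <- territoryNames()

  expect_identical(secs$ACA,
                   territorySector("ACA", gs, sp))       # deterministic
  expect_equal(sum(secs$ACA & secs$PICA), 0)             # disjoint wedges
  for (a in 1:4) for (b in (a + 1):5)
    expect_false(identical(secs[[a]], secs[[b]]))
  expect_error(territorySector("SCA", gs, sp), "unknown")

  # union of sectors covers >= 80% of the brain surface
  brain <- strokemap:::.brainEllipsoid(gs, sp, c(70, 85, 60))
  core <- brain
  n <- gs[1]
  core[2:(n - 1), , ] <- core[2:(n - 1), , ] & brain[1:(n - 2), , ] &
    brain[3:n, , ]
  core[, 2:(n - 1), ] <- core[, 2:(n - 1), ] & brain[, 1:(n - 2), ] &
    brain[, 3:n, ]
  core[, , 2:(n - 1)] <- core[, , 2:(n - 1)] & brain[, , 1:(n - 2)] &
    brain[, , 3:n]
  surface <- brain & !core
  union <- Reduce(`|`, secs)
  expect_gte(sum(union & surface) / sum(surface), 0.80)
})

test_that("planted lesions stay inside their territory sector", {
  for (terr in territoryNames()) {
    v <- smallPhantom(terr, 0.02, seed = 5)
    sec <- territorySector(terr, c(48L, 48L, 48L), c(4, 4, 4))
    expect_gte(sum(lesionMask(v) & sec) / sum(lesionMask(v)), 0.95)
  }
})

test_that("cohorts are labelled, reproducible and validated", {
  co <- makeCohort(10, mix = c(PICA = 1), template = smallSpec(),
                   seed = 4, keepVolumes = FALSE)
  expect_equal(nrow(co$manifest), 10)
  expect_true(all(co$manifest$territory == "PICA"))
  expect_false(anyDuplicated(co$manifest$id) > 0)

  co2 <- makeCohort(50, template = smallSpec(lesionFraction = NA), seed = 9,
                    keepVolumes = FALSE)
  co3 <- makeCohort(50, template = smallSpec(lesionFraction = NA), seed = 9,
                    keepVolumes = FALSE)
  expect_identical(co2$manifest, co3$manifest)
  expect_true(all(table(co2$manifest$territory) > 0))
  expect_true(all(co2$manifest$lesionFraction >= 0.008 &
                    co2$manifest$lesionFraction <= 0.04))

  expect_error(makeCohort(0), ">= 1")
  expect_error(makeCohort(5, mix = c(PICA = 0.5, ACA = 0.4)), "sum to 1")
})

test_that("graded profile and bias field shape intensities as documented", {
  v <- smallPhantom("PCA", 0.05, seed = 8, lesionProfile = "graded",
                    strokeLevel = 300)
  les <- intensities(v)[lesionMask(v)]
  # graded rim: lesion spans from ~30% contrast up to full contrast
  expect_lt(min(les), 240)
  expect_gt(max(les), 280)

  vg <- smallPhantom("none", seed = 8, gradientAmplitude = 30)
  v0 <- smallPhantom("none", seed = 8)
  sdg <- sd(intensities(vg)[brainMask(vg)])
  sd0 <- sd(intensities(v0)[brainMask(v0)])
  expect_gt(sdg, sd0 + 3)  # field adds spatial spread to the brain levels
})
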