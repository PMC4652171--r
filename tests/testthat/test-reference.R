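test_that("the diffusion reference averages per pixel with population SD", {
  a <- rasterMap(matrix(100, 4, 8))
  b <- rasterMap(matrix(200, 4, 8))
  ref <- buildDiffusionReference(list(a, b))
  expect_true(all(refMean(ref) == 150))
  expect_true(all(refSd(ref) == 50))           # divisor n, not n - 1
  expect_true(all(refN(ref) == 2L))

  same <- buildDiffusionReference(list(a, a, a))
  expect_true(all(refSd(same) == 0))

  expect_error(buildDiffusionReference(list(a)), "length")
  expect_error(buildDiffusionReference(list(a, rasterMap(matrix(1, 2, 2)))),
               "geometry mismatch")
})

test_that("reference means recover the generating brain level", {
  maps <- lapply(1:12, function(s) projectVolume(smallPhantom(seed = s)))
  ref <- buildDiffusionReference(maps)
  mid <- refMean(ref)[refN(ref) == 12L]
  # max-aggregated pixels sit slightly above the 180 a.u. brain level
  expect_gt(mean(mid), 178)
  expect_lt(mean(mid), 200)
})

test_that("hemisphere mirroring removes the affected side", {
  sym <- rasterMap(matrix(rep(c(1, 2, 3, 3, 2, 1), each = 4), 4, 6))
  out <- mirrorHealthyHemisphere(sym, "left")
  expect_equal(mapValues(out), mapValues(sym))  # symmetric map: identity

  v <- smallPhantom("infMCA", 0.04, seed = 23, strokeLevel = 400)
  m <- projectVolume(v, brainMask(v), smallGeometry(v))
  mm <- mirrorHealthyHemisphere(m, "left")
  expect_gt(max(mapValues(m), na.rm = TRUE), 350)    # lesion visible before
  expect_lt(max(mapValues(mm), na.rm = TRUE), 300)   # and gone after
})

test_that("flagging is one-sided, bounded to defined pixels, monotone", {
  mu <- matrix(100, 5, 10)
  ref <- buildDiffusionReference(lapply(1:4, function(i)
    rasterMap(mu + rnorm(50, 0, 0))), sigmaLevel = 2)
  ref@sd <- matrix(10, 5, 10)

  flat <- rasterMap(mu)
  expect_equal(sum(flagStrokePixels(flat, ref)), 0)  # equal to mean: empty

  one <- mu; one[3, 4] <- 100 + 3 * 10
  fl <- flagStrokePixels(rasterMap(one), ref)
  expect_equal(which(fl), which(one > 100))          # exactly that pixel

  # anti-monotone in k, monotone in intensity
  refLow <- ref; refLow@sigmaLevel <- 1
  refHigh <- ref; refHigh@sigmaLevel <- 3
  noisy <- rasterMap(mu + matrix(rnorm(50, 0, 15), 5, 10))
  f1 <- flagStrokePixels(noisy, refLow)
  f2 <- flagStrokePixels(noisy, ref)
  f3 <- flagStrokePixels(noisy, refHigh)
  expect_true(all(f2 <= f1) && all(f3 <= f2))
  brighter <- rasterMap(mapValues(noisy) + 5)
  expect_true(all(flagStrokePixels(noisy, ref) <=
                    flagStrokePixels(brighter, ref)))

  expect_error(flagStrokePixels(rasterMap(matrix(0, 2, 2)), ref),
               "geometry mismatch")
})

test_that("healthy maps are flagged at roughly the k = 2 tail rate", {
  maps <- lapply(1:21, function(s) projectVolume(smallPhantom(seed = 100 + s)))
  ref <- buildDiffusionReference(maps[1:20], sigmaLevel = 2)
  fl <- flagStrokePixels(maps[[21]], ref)
  rate <- sum(fl) / sum(insideMask(maps[[21]]) & refN(ref) >= 1L)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.05)
})

test_that("the territory atlas is the union of its cases", {
  base <- matrix(FALSE, 6, 12)
  mk <- function(cells) { m <- base; m[cells] <- TRUE; m }
  masks <- list(mk(1:3), mk(10:12), mk(20:22), mk(30:32), mk(40:42),
                mk(44:46))
  labels <- c(territoryNames(), "PICA")
  atlas <- buildTerritoryAtlas(masks, labels,
                               ids = sprintf("c%d", 1:6))
  expect_equal(territoryMask(atlas, "ACA"), masks[[1]])
  expect_equal(territoryMask(atlas, "PICA"), masks[[5]] | masks[[6]])
  expect_true(all(territoryMask(atlas, "PICA") >= masks[[5]]))  # union grows
  expect_equal(atlas@provenance$PICA, c("c5", "c6"))

  expect_error(buildTerritoryAtlas(masks[1:4], labels[1:4]),
               "no atlas case for territory: PICA")
  expect_error(buildTerritoryAtlas(masks, c(labels[-6], "SCA")), "unknown")
})

test_that("a 14-case phantom atlas recovers the generating wedges", {
  # widespread single-territory lesions (70% of each wedge's capacity);
  # atlas masks merge the cases' true lesion footprints, so the recovered
  # territories must overlap the wedge footprints they were drawn from
  tpl <- smallSpec()
  brain <- strokemap:::.brainEllipsoid(tpl$gridShape, tpl$voxelSpacing,
                                       tpl$brainSemiAxes)
  caps <- vapply(territoryNames(), function(t)
    sum(territorySector(t, tpl$gridShape, tpl$voxelSpacing,
                        leftOnly = TRUE) & brain) / sum(brain), 0)
  terr14 <- rep(territoryNames(), length.out = 14)
  geom <- NULL
  cases <- list()
  for (i in seq_len(14)) {
    t <- terr14[i]
    v <- smallPhantom(t, round(0.7 * caps[[t]], 3), seed = 300 + i)
    if (is.null(geom)) geom <- geometry(projectVolume(v))
    cases[[i]] <- insideMask(projectVolume(v, lesionMask(v), geom))
  }
  atlas <- buildTerritoryAtlas(cases, terr14)
  v0 <- smallPhantom(seed = 1)
  for (t in territoryNames()) {
    wedge <- territorySector(t, tpl$gridShape, tpl$voxelSpacing,
                             leftOnly = TRUE)
    foot <- insideMask(projectVolume(v0, wedge & brainMask(v0), geom))
    expect_gte(diceCoefficient(territoryMask(atlas, t), foot), 0.6)
  }
})

test_that("sigma-level selection minimises the stroke-per-brain mismatch", {
  # direct construction: one pixel fraction matches p3d exactly at k = 2
  mu <- matrix(100, 10, 20)
  ref <- buildDiffusionReference(list(rasterMap(mu), rasterMap(mu)))
  ref@sd <- matrix(10, 10, 20)
  pat <- mu
  pat[1, 1:10] <- 125              # 10 of 200 pixels at mu + 2.5 sd
  pat[2, 1:5] <- 115               # 5 more at mu + 1.5 sd: k = 1 over-flags
  sel <- chooseSigmaLevel(list(rasterMap(pat)), p3d = 10 / 200, ref,
                          ks = c(1, 2, 3))
  expect_equal(sel$k, 2)
  expect_equal(unname(sel$meanDifference["2"]), 0)

  # all-tied candidates: the smaller k wins
  selTie <- chooseSigmaLevel(list(rasterMap(mu)), p3d = 0.05, ref,
                             ks = c(2, 3))
  expect_equal(selTie$k, 2)
})
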