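geomAt <- function(center = c(0, 0, 0), r = 1, mapShape = c(24L, 6L))
  ProjectionGeometry(center = center, radius = r, mapShape = mapShape)

test_that("the planar map formulas are applied exactly as stated", {
  expect_equal(unname(mollweideForward(0, 0, 1)), cbind(0, 0))
  expect_equal(unname(mollweideForward(pi / 8, 0, 1)), cbind(1, 0))
  expect_equal(unname(mollweideForward(0.73, pi / 2, 1)), cbind(0, 2))
  expect_equal(unname(mollweideForward(pi, 0, 2)), cbind(16, 0))
  # bounds forced by the formulas
  lam <- runif(100, -pi, pi); th <- runif(100, -pi / 2, pi / 2)
  xy <- mollweideForward(lam, th, 3)
  expect_true(all(abs(xy[, "x"]) <= 24 + 1e-9))
  expect_true(all(abs(xy[, "y"]) <= 6 + 1e-9))
  # canonical equal-area variant behind the flag
  can <- mollweideForward(c(0, 0.4), c(pi / 2, 0), 1, canonical = TRUE)
  expect_equal(unname(can[1, "y"]), sqrt(2), tolerance = 1e-9)
  expect_equal(unname(can[2, "x"]), 2 * sqrt(2) * 0.4 / pi,
               tolerance = 1e-9)
})

test_that("spherical coordinates implement a purely radial mapping", {
  g <- geomAt()
  polar <- toSpherical(c(0, 0, 5), g)
  expect_equal(unname(polar[, "theta"]), pi / 2)
  expect_equal(unname(polar[, "lambda"]), 0)          # pole convention
  eq <- toSpherical(c(0, 7, 0), g)
  expect_equal(unname(eq[, c("lambda", "theta")]), c(0, 0))
  expect_equal(unname(eq[, "rho"]), 7)
  right <- toSpherical(c(3, 0, 0), g)
  expect_equal(unname(right[, "lambda"]), pi / 2)     # right side: positive lambda

  a <- toSpherical(c(2, 5, -1) * 2, g)
  b <- toSpherical(c(2, 5, -1) * 10, g)
  expect_equal(a[, c("lambda", "theta")], b[, c("lambda", "theta")])

  expect_error(toSpherical(c(0, 0, 0), g), "centre")
})

test_that("projection aggregates by maximum and records multiplicity", {
  arr <- array(0, c(9, 9, 9))
  mask <- array(FALSE, c(9, 9, 9))
  # two voxels on the +y ray from the centre voxel (5,5,5); centre at mm (4,4,4)
  arr[5, 7, 5] <- 5; arr[5, 9, 5] <- 9
  mask[5, 7, 5] <- TRUE; mask[5, 9, 5] <- TRUE
  vol <- DiffusionVolume(arr, spacing = c(1, 1, 1))
  g <- geomAt(center = c(4, 4, 4), r = 5)
  m <- projectVolume(vol, mask, g)
  expect_equal(sum(insideMask(m)), 1)         # one shared pixel
  expect_equal(mapValues(m)[insideMask(m)], 9)  # max rule
  expect_equal(multiplicity(m)[insideMask(m)], 2L)

  mask1 <- array(FALSE, c(9, 9, 9)); mask1[5, 9, 5] <- TRUE
  m1 <- projectVolume(vol, mask1, g)
  expect_equal(sum(insideMask(m1)), 1)
  expect_equal(multiplicity(m1)[insideMask(m1)], 1L)
  h1 <- multiplicityHistogram(m1)
  expect_equal(sum(h1$counts), 1)
  expect_equal(h1$mids[h1$counts > 0], 1)

  expect_error(projectVolume(vol, array(FALSE, c(9, 9, 9)), g), "empty")
})

test_that("projection conserves voxels and is monotone in intensity", {
  v <- smallPhantom("infMCA", 0.03, seed = 13)
  m <- projectVolume(v, brainMask(v), smallGeometry(v))
  expect_equal(sum(multiplicity(m)), sum(brainMask(v)))  # conservation
  expect_equal(sum(multiplicityHistogram(m)$counts), sum(insideMask(m)))
  expect_gte(max(multiplicity(m)), 2)

  # raising one voxel never lowers any pixel
  idx <- which(brainMask(v))[123]
  arr <- intensities(v)
  arr[idx] <- arr[idx] + 500
  v2 <- DiffusionVolume(arr, spacing = voxelSpacing(v))
  m2 <- projectVolume(v2, brainMask(v), smallGeometry(v))
  expect_true(all(mapValues(m2) >= mapValues(m), na.rm = TRUE))

  # radial invariance: same direction, different depth, same pixel
  g <- geomAt(center = c(4, 4, 4), r = 8, mapShape = c(48L, 12L))
  arr0 <- array(0, c(9, 9, 9)); arr0[7, 7, 7] <- 1
  maskA <- array(FALSE, c(9, 9, 9)); maskA[7, 7, 7] <- TRUE
  maskB <- array(FALSE, c(9, 9, 9)); maskB[6, 6, 6] <- TRUE
  pa <- which(insideMask(projectVolume(DiffusionVolume(arr0), maskA, g)))
  pb <- which(insideMask(projectVolume(DiffusionVolume(arr0), maskB, g)))
  expect_equal(pa, pb)
})

test_that("left brain hemisphere lands on the left half of the map", {
  v <- smallPhantom("supMCA", 0.03, seed = 17, strokeLevel = 400)
  m <- projectVolume(v, brainMask(v), smallGeometry(v))
  vals <- mapValues(m)
  W <- ncol(vals)
  hot <- which(vals > 300, arr.ind = TRUE)
  expect_gt(nrow(hot), 0)
  expect_true(all(hot[, 2] <= ceiling(W / 2)))  # lesions are planted left
})
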