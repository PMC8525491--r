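# Registration, reslicing and slab extraction.

test_that("reslice round trips are lossless along every axis", {
  set.seed(61)
  g <- VolumeGeometry(20, 18, 24)
  arr <- array(runif(24 * 20 * 18), dim = c(24, 20, 18))
  vol <- new("OCTVolume", intensities = arr, geometry = g,
             metadata = list())
  # B-scan stack reconstructs the volume bit-exactly
  back <- array(0, dim(arr))
  for (y in 1:18) back[, , y] <- reslice(vol, "bscan", y)
  expect_identical(back, arr)
  # C-scan: slow x fast orientation, and stacking round-trips
  cs <- reslice(vol, "cscan", 5)
  expect_equal(dim(cs), c(18L, 20L))
  back2 <- array(0, dim(arr))
  for (z in 1:24) back2[z, , ] <- t(reslice(vol, "cscan", z))
  expect_identical(back2, arr)
  back3 <- array(0, dim(arr))
  for (x in 1:20) back3[, x, ] <- reslice(vol, "ascan-line", x)
  expect_identical(back3, arr)
  expect_error(reslice(vol, "bscan", 19), "out of bounds")
  expect_error(reslice(vol, "cscan", 0), "out of bounds")
})

test_that("two identical B-scans with a known shift register exactly", {
  set.seed(62)
  g <- VolumeGeometry(32, 16, 48)
  b1 <- matrix(runif(48 * 32), 48, 32)
  arr <- array(0, dim = c(48, 32, 16))
  for (y in 1:16) arr[, , y] <- b1
  # the second scan is shifted by (3, -2) voxels
  arr[, , 2] <- enfaceOCTA:::circShift2D(b1, 3, -2)
  vol <- new("OCTVolume", intensities = arr, geometry = g,
             metadata = list())
  reg <- registerBscans(vol)
  expect_equal(reg$offsets$dz_vox[2], -3)
  expect_equal(reg$offsets$dx_vox[2], 2)
  expect_equal(reg$volume@intensities[, , 2], b1)
})

test_that("registration recovers injected jitter and is idempotent", {
  g <- VolumeGeometry(96, 160, 320)
  sc <- simulateScene(g, "control", 0, seed = 5)
  vol <- renderVolume(sc, 1, NoiseModel(motionJitterUm = c(4, 3), seed = 5))
  app <- vol@metadata$appliedOffsets
  expect_gte(max(abs(app)), 3)  # the walk actually moved
  reg <- registerBscans(vol)
  est <- as.matrix(reg$offsets[, c("dz_vox", "dx_vox")])
  err <- abs(est - (-app))
  expect_gte(mean(apply(err, 1, max) <= 1), 0.95)
  # re-registering the registered volume finds (almost) nothing
  reg2 <- registerBscans(reg$volume)
  expect_lte(max(abs(as.matrix(reg2$offsets[, c("dz_vox", "dx_vox")]))), 1)
})

test_that("zero-jitter volumes register to zero and flat scans are flagged", {
  fx <- controlFixture()
  reg <- registerBscans(fx$volume)
  expect_lte(max(abs(as.matrix(reg$offsets[, c("dz_vox", "dx_vox")]))), 1)
  # featureless B-scan: flagged, offset zero
  g <- VolumeGeometry(24, 16, 32)
  arr <- array(0.5, dim = c(32, 24, 16))
  vol <- new("OCTVolume", intensities = arr, geometry = g,
             metadata = list())
  reg2 <- registerBscans(vol)
  expect_true(all(reg2$offsets$flagged[-1]))
  expect_true(all(reg2$offsets$dz_vox == 0))
})

test_that("slab extraction flattens per column with no lateral mixing", {
  fx <- controlFixture()
  g <- fx$geom
  # encode the column id in the voxel values: a slab must preserve it
  colId <- array(rep(seq_len(g@nFast * g@nSlow), each = g@nAxial),
                 dim = c(g@nAxial, g@nFast, g@nSlow))
  slab <- extractSlab(colId, fx$surfaces, "ILM", 0, 60)
  expect_equal(dim(slab@voxels)[1], round(60 / g@dzUm))
  want <- matrix(seq_len(g@nFast * g@nSlow), g@nFast, g@nSlow)
  for (b in seq_len(dim(slab@voxels)[1]))
    expect_equal(slab@voxels[b, , ], want)
  expect_error(extractSlab(colId, fx$surfaces, "ILM", 0, 0), "thicknessUm")
  expect_warning(extractSlab(colId, fx$surfaces, "RPE", 400, 60),
                 "clipped")
})

test_that("an ILM slab captures the superficial plexus, not the choroid", {
  fx <- controlFixture()
  m <- fx$masks
  inner <- extractSlab(m$SVP * 1, fx$surfaces, "ILM", 0, 60)
  expect_gte(sum(inner@voxels > 0) / sum(m$SVP), 0.99)
  chor <- extractSlab(m$choroid * 1, fx$surfaces, "ILM", 0, 60)
  expect_lte(sum(chor@voxels > 0) / sum(m$choroid), 0.01)
})

test_that("the lesion-centered B-scan is found from orthographic landmarks", {
  fx <- cnvFixture()
  ctr <- fx$scene@lesionSpecs[[1]]@centerUm
  yTrue <- round(ctr[2] / fx$geom@dxUm + 0.5)
  yc <- findLesionBscan(fx$volume, fx$surfaces, ctr)
  expect_lte(abs(yc - yTrue), 2)
})
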