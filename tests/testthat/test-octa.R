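# Angiography core: enhancement, segmentation, shadow rejection and depth
# projection.

test_that("a 5 um capillary is enhanced well above background", {
  g <- VolumeGeometry(96, 96, 64)
  ph <- tubePhantom(g, diameterUm = 5, seed = 9)
  vn <- enhanceVessels(ph$volume)
  s <- vesselScores(vn)
  expect_gte(mean(s[ph$mask]) / mean(s[!ph$mask]), 3)
  expect_gt(length(vn@iteratorLog), 0)
})

test_that("two capillaries 10 um apart resolve as distinct ridges", {
  g <- VolumeGeometry(96, 96, 64)
  ph <- tubePhantom(g, diameterUm = 5, nTubes = 2, centerSepUm = 15,
                    seed = 9)
  s <- vesselScores(enhanceVessels(ph$volume, scalesUm = c(5, 10)))
  zc <- round(g@nAxial / 2)
  prof <- rowMeans(apply(s[(zc - 2):(zc + 2), , ], c(2, 3), max))
  ctr <- g@nFast / 2
  sep <- 15 / g@dxUm / 2
  pkL <- which.max(prof[1:ctr])
  pkR <- ctr + which.max(prof[(ctr + 1):g@nFast])
  gapMin <- min(prof[pkL:pkR])
  # two maxima near the true centers with a clear valley between
  expect_lt(abs(pkL - (ctr - sep)), 3)
  expect_lt(abs(pkR - (ctr + sep)), 3)
  expect_lt(gapMin, 0.5 * min(prof[pkL], prof[pkR]))
})

test_that("degenerate volumes give zero scores and empty masks", {
  g <- VolumeGeometry(32, 32, 64)
  flat <- new("OCTVolume", intensities = array(0, c(64, 32, 32)),
              geometry = g, metadata = list())
  expect_warning(vn <- enhanceVessels(flat), "constant")
  expect_true(all(vn@scores == 0))
  ang <- segmentAngiogram(vn)
  expect_equal(sum(ang@mask), 0L)
})

test_that("enhancement is invariant to a constant intensity shift", {
  g <- VolumeGeometry(64, 64, 48)
  ph <- tubePhantom(g, diameterUm = 10, seed = 19)
  v1 <- vesselScores(enhanceVessels(ph$volume))
  shifted <- new("OCTVolume",
                 intensities = ph$volume@intensities + 0.5,
                 geometry = g, metadata = ph$volume@metadata)
  v2 <- vesselScores(enhanceVessels(shifted))
  expect_lt(sqrt(mean((v1 - v2)^2)) / max(sqrt(mean(v1^2)), 1e-9), 0.01)
})

test_that("raising the high threshold never grows the mask", {
  g <- VolumeGeometry(64, 64, 48)
  ph <- tubePhantom(g, diameterUm = 10, seed = 19)
  vn <- enhanceVessels(ph$volume)
  m1 <- segmentAngiogram(vn, hystFractions = c(0.3, 0.15))@mask
  m2 <- segmentAngiogram(vn, hystFractions = c(0.5, 0.15))@mask
  m3 <- segmentAngiogram(vn, hystFractions = c(0.7, 0.15))@mask
  expect_true(all(m2 <= m1))
  expect_true(all(m3 <= m2))
  # equal high/low reduces to a single threshold
  mEq <- segmentAngiogram(vn, hystFractions = c(0.4, 0.4))@mask
  mHi <- segmentAngiogram(vn, hystFractions = c(0.4, 0.4),
                          minVoxels = 1L)@mask
  expect_true(all(mEq <= mHi))
})

test_that("shadow rejection never adds voxels and spares the SVP band", {
  fx <- octaFixture()
  pre <- fx$angiogram@mask
  post <- fx$rejected@mask
  expect_true(all(post <= pre))
  g <- fx$fx$geom
  zUm <- (seq_len(g@nAxial) - 0.5) * g@dzUm
  inBand <- outer(zUm, as.numeric(fx$fx$surfaces@surfaces$ILM),
                  function(z, i) z >= i & z <= i + 40)
  dim(inBand) <- dim(pre)
  expect_identical(post[inBand], pre[inBand])
  expect_error(suppressProjectionArtifacts(fx$angiogram, fx$vness, NULL),
               "surfaces")
})

test_that("plexus segmentation reaches the target overlap on controls", {
  fx <- octaFixture()
  d <- fx$dice
  expect_gte(d[["SVP"]], 0.7)
  expect_gte(d[["IVP"]], 0.6)
  expect_gte(d[["DVP"]], 0.6)
})

test_that("decorrelation tails are removed, true deep vessels kept", {
  # single superficial vessel casting a rendered tail into the deep band
  fx <- controlFixture()
  sc <- fx$scene
  sc@vesselCenterlines$SVP <- sc@vesselCenterlines$SVP[1]
  sc@vesselCenterlines$IVP <- list()
  vol <- renderVolume(sc, 1, NoiseModel(seed = 2))
  surf <- segmentSurfaces(vol)
  tails <- projectionTailMask(sc)
  dvp <- plexusMasksAt(sc, 0, "DVP")$DVP
  vn <- enhanceVessels(vol, surf)
  ang <- segmentAngiogram(vn)
  ang2 <- suppressProjectionArtifacts(ang, vn, surf)
  pre <- ang@mask
  post <- ang2@mask
  tailIn <- sum(pre & tails)
  expect_gt(tailIn, 100)
  expect_gte(1 - sum(post & tails) / tailIn, 0.8)
  dvpIn <- sum(pre & dvp)
  expect_lte(1 - sum(post & dvp) / dvpIn, 0.05)
  # an angiogram with an empty superficial band passes through unchanged
  vn0 <- new("VesselnessVolume", scores = vn@scores * 0,
             geometry = vn@geometry, iteratorLog = vn@iteratorLog)
  ang3 <- suppressProjectionArtifacts(ang, vn0, surf)
  expect_identical(ang3@mask, ang@mask)
})

test_that("depth projections match exhaustive per-column scans", {
  set.seed(71)
  arr <- array(runif(16 * 12 * 10), dim = c(16, 12, 10))
  pr <- depthProject(arr, mode = "max_intensity", dzUm = 1.9)
  want <- apply(arr, c(2, 3), max)
  expect_equal(matrix(pr@image, 12, 10), want, tolerance = 1e-12)
  # empty input: background image
  pr0 <- depthProject(arr * 0, mode = "depth_color", dzUm = 1.9)
  expect_true(all(pr0@image == 0))
})

test_that("depth-coded hues decode to the true vessel depth", {
  # one flat vessel at a known constant depth
  g <- VolumeGeometry(48, 48, 32)
  mask <- array(FALSE, dim = c(32, 48, 48))
  mask[17:19, 20:28, ] <- TRUE
  ang <- new("Angiogram", mask = mask, geometry = g, provenance = list())
  pr <- depthProject(ang, bandUm = c(0, 60), mode = "depth_color")
  dec <- decodeProjectionDepth(pr)
  trueDepth <- (17 - 0.5) * g@dzUm  # topmost (brightest-first) voxel
  fg <- !is.na(dec)
  expect_gt(sum(fg), 0)
  expect_lte(max(abs(dec[fg] - trueDepth)), g@dzUm)
})
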