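# Retinal surface segmentation accuracy and validity behaviour.

test_that("segmented surfaces are accurate and depth-ordered on controls", {
  fx <- controlFixture()
  surf <- fx$surfaces
  for (s in c("ILM", "RPE")) {
    err <- abs(surf@surfaces[[s]] - fx$scene@surfaces[[s]])
    expect_lte(unname(quantile(err, 0.95)), 5.7)
  }
  nm <- c("ILM", "ONLtop", "ELM", "ISOS", "RPE")
  for (i in seq_len(length(nm) - 1L))
    expect_true(all(surf@surfaces[[nm[i]]] < surf@surfaces[[nm[i + 1L]]]))
  expect_gte(mean(surf@validity), 0.98)
})

test_that("a noiseless volume is segmented to within one voxel", {
  g <- smallGeom()
  sc <- simulateScene(g, "control", 0, seed = 13)
  vol <- renderVolume(sc, 1, NoiseModel(speckleContrast = 0,
                                        backgroundLevel = 0,
                                        projectionTail = 0, seed = 13))
  surf <- segmentSurfaces(vol)
  for (s in c("ILM", "RPE")) {
    err <- abs(surf@surfaces[[s]] - sc@surfaces[[s]])
    expect_lte(stats::median(err), g@dzUm)
    expect_lte(unname(quantile(err, 0.95)), 2 * g@dzUm)
  }
})

test_that("a flat volume raises a segmentation failure", {
  g <- VolumeGeometry(16, 16, 64)
  vol <- new("OCTVolume", intensities = array(0.3, c(64, 16, 16)),
             geometry = g, metadata = list())
  expect_error(segmentSurfaces(vol), "no detectable retina")
})

test_that("the validity mask is false inside an RPE rupture", {
  fx <- cnvFixture()
  g <- fx$geom
  ctr <- fx$scene@lesionSpecs[[1]]@centerUm
  r2d <- enfaceOCTA:::lesionRadiusMap(g, ctr)
  rr <- fx$scene@params$ruptureRadiusUm * fx$scene@dimScale
  core <- r2d <= 0.7 * rr
  outside <- r2d > 3 * rr
  expect_gte(mean(!fx$surfaces@validity[core]), 0.5)
  expect_lte(mean(!fx$surfaces@validity[outside]), 0.05)
})
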