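# Lesion morphometry on B-scans.

test_that("a control B-scan yields a flagged all-zero measurement", {
  fx <- controlFixture()
  m <- measureLesion(reslice(fx$volume, "bscan", 64), fx$surfaces,
                     fx$geom@nFast * fx$geom@dxUm / 2, 64)
  expect_true(m$flagged)
  expect_true(all(m[1, c("onl_um", "rpe_um", "height_um", "pr_um")] == 0))
})

test_that("CNV morphometry recovers the simulated dome height", {
  fx <- cnvFixture()
  spec <- fx$scene@lesionSpecs[[1]]
  ctr <- spec@centerUm
  yc <- findLesionBscan(fx$volume, fx$surfaces, ctr)
  m <- measureLesion(reslice(fx$volume, "bscan", yc), fx$surfaces,
                     ctr[1], yc)
  truth <- enfaceOCTA:::lesionDimsAt(spec, 1)
  expect_false(m$flagged)
  expect_lte(abs(m$height_um - truth[["height_um"]]), 3 * fx$geom@dzUm)
  # the ruptured RPE is read as a disruption at least as wide as the core
  expect_gt(m$rpe_um, 2 * fx$scene@params$ruptureRadiusUm *
              fx$scene@dimScale * 0.8)
})

test_that("the sub-RPE slab shows the rupture void on CNV day 1", {
  fx <- cnvFixture()
  slab <- extractSlab(fx$volume, fx$surfaces, "RPE", offsetUm = 8,
                      thicknessUm = 50)
  chorMap <- apply(slab@voxels, c(2, 3), mean)
  g <- fx$geom
  ctr <- fx$scene@lesionSpecs[[1]]@centerUm
  r2d <- enfaceOCTA:::lesionRadiusMap(g, ctr)
  rr <- fx$scene@params$ruptureRadiusUm * fx$scene@dimScale
  core <- r2d <= 0.7 * rr
  surround <- r2d > 3 * rr
  expect_lt(mean(chorMap[core]), 0.5 * mean(chorMap[surround]))
})

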