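# Synthetic scene and volume generator: determinism, calibration against
# the packaged dimension table, dispersion recovery, mask invariants and
# the non-perfusion schedule.

test_that("scenes and volumes are deterministic in (params, seed)", {
  g <- smallGeom()
  s1 <- simulateScene(g, "control", 0, seed = 7)
  s2 <- simulateScene(g, "control", 0, seed = 7)
  expect_identical(s1@surfaces, s2@surfaces)
  expect_identical(s1@vesselCenterlines, s2@vesselCenterlines)
  nm <- NoiseModel(motionJitterUm = c(3, 3), seed = 9)
  v1 <- renderVolume(s1, 1, nm)
  v2 <- renderVolume(s2, 1, nm)
  expect_identical(v1@intensities, v2@intensities)
  expect_identical(v1@metadata$appliedOffsets, v2@metadata$appliedOffsets)
  # a different seed changes the realization
  v3 <- renderVolume(s1, 1, NoiseModel(motionJitterUm = c(3, 3), seed = 10))
  expect_false(identical(v1@intensities, v3@intensities))
})

test_that("dispersion-off dimensions equal the reference means exactly", {
  g <- VolumeGeometry(1600, 1600, 256)  # scene-level only, nothing rendered
  tab <- lesionDimensionTable("cnv")
  sc <- simulateScene(g, "cnv", 1, seed = 7, dispersion = FALSE)
  expect_equal(unname(sc@lesionSpecs[[1]]@trueDims[, "height_um"]),
               tab$height_um, tolerance = 1e-12)
  expect_equal(unname(sc@lesionSpecs[[1]]@trueDims[, "onl_um"]),
               tab$onl_um, tolerance = 1e-12)
  # acute day-1 ONL width, every lesion identical with dispersion off
  ga <- VolumeGeometry(1024, 1024, 256)
  sa <- simulateScene(ga, "acute", 4, seed = 3, dispersion = FALSE)
  onl1 <- vapply(sa@lesionSpecs, function(s) s@trueDims[1, "onl_um"],
                 numeric(1))
  expect_true(all(onl1 == 128.31))
})

test_that("timecourse tables carry the ground truth per lesion and day", {
  g <- VolumeGeometry(1600, 1600, 256)
  tc <- simulateTimecourse("cnv", 1, g, seed = 5, dispersion = FALSE,
                           render = FALSE)
  expect_equal(tc$table$height_um,
               c(170.38, 204.83, 246.35, 197.74, 178.06), tolerance = 1e-12)
  expect_equal(tc$table$day, c(1, 3, 7, 14, 21))
  # control: empty table
  tcc <- simulateTimecourse("control", 0, smallGeom(), seed = 5,
                            render = FALSE)
  expect_equal(nrow(tcc$table), 0L)
})

test_that("lesion-to-lesion lognormal dispersion recovers the requested CV", {
  # 200 lesions via 50 independent 4-lesion scenes (lesion geometry scaled
  # down; the CV structure is scale-free)
  g <- VolumeGeometry(192, 192, 256)
  vals <- lapply(1:50, function(i) {
    sc <- simulateScene(g, "acute", 4, seed = 1000L + i, dimScale = 0.1)
    t(vapply(sc@lesionSpecs, function(s) s@trueDims[1, ], numeric(4)))
  })
  vals <- do.call(rbind, vals)
  tab <- lesionDimensionTable("acute")
  want <- unlist(tab[1, c("onl_cv", "rpe_cv", "height_cv", "pr_cv")])
  got <- apply(vals, 2, function(v) sd(v) / mean(v))
  expect_true(all(abs(got - want) / want < 0.15))
})

test_that("plexus masks are disjoint and confined to their layers", {
  fx <- controlFixture()
  m <- fx$masks
  expect_equal(sum((m$SVP + m$IVP + m$DVP + m$choroid) > 1), 0L)
  g <- fx$geom
  zUm <- (seq_len(g@nAxial) - 0.5) * g@dzUm
  D <- outer(zUm, as.numeric(fx$scene@surfaces$ILM), "-")
  dim(D) <- dim(m$SVP)
  rpeD <- 190  # RPE center below the ILM in the layer model
  for (pl in c("SVP", "IVP", "DVP")) {
    expect_true(all(D[m[[pl]]] > 0))
    expect_true(all(D[m[[pl]]] < rpeD))
  }
  expect_true(all(D[m$choroid] > rpeD + 5))
})

test_that("rendered vessels are hyperreflective relative to tissue", {
  fx <- controlFixture()
  vol <- fx$volume@intensities
  m <- fx$masks
  inside <- m$SVP | m$IVP | m$DVP | m$choroid
  expect_gt(mean(vol[inside]), 2 * mean(vol[!inside]))
})

test_that("the CNV schedule removes deep vessels only with tall lesions", {
  # default schedule keys on the condition's mean height >= 200 um:
  # days 3 and 7 only
  g <- VolumeGeometry(288, 288, 256)
  sc <- simulateScene(g, "cnv", 1, seed = 6, dispersion = FALSE,
                      dimScale = 0.35)
  sched <- sc@lesionSpecs[[1]]@nonperfusionSchedule
  expect_equal(sched > 0, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  # acute lesions never schedule removal
  ga <- VolumeGeometry(256, 256, 256)
  sa <- simulateScene(ga, "acute", 1, seed = 6, dimScale = 0.5)
  expect_true(all(sa@lesionSpecs[[1]]@nonperfusionSchedule == 0))
  # removal is confined to the lesion cylinder and hits the scheduled
  # fraction of in-cylinder voxels
  m0 <- plexusMasksAt(sc, 0, "DVP")$DVP
  m3 <- plexusMasksAt(sc, 3, "DVP")$DVP
  removed <- m0 & !m3
  expect_gt(sum(removed), 0)
  r2d <- enfaceOCTA:::lesionRadiusMap(g, sc@lesionSpecs[[1]]@centerUm)
  R <- enfaceOCTA:::lesionDimsAt(sc@lesionSpecs[[1]], 3)[["onl_um"]] / 2
  rRep <- rep(r2d, each = g@nAxial)
  expect_true(all(rRep[removed] <= R + 1e-9))
  inCyl <- m0 & (rRep <= R)
  expect_equal(sum(removed) / sum(inCyl), 0.8, tolerance = 0.05)
  # acute masks never change over time
  ma0 <- plexusMasksAt(sa, 0, "DVP")$DVP
  ma7 <- plexusMasksAt(sa, 7, "DVP")$DVP
  expect_identical(ma0, ma7)
})

test_that("placement and geometry errors are raised", {
  expect_error(simulateScene(smallGeom(), "cnv", 1, seed = 1),
               "too small")
  expect_error(simulateScene(smallGeom(), "control", 2, seed = 1),
               "zero lesions")
  expect_error(simulateScene(VolumeGeometry(96, 96, 64), "control", 0,
                             seed = 1),
               "axial extent")
  expect_error(renderVolume(cnvFixture()$scene, 2), "grid")
})

test_that("zero-jitter renders record all-zero offsets", {
  fx <- controlFixture()
  expect_true(all(fx$volume@metadata$appliedOffsets == 0L))
})
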