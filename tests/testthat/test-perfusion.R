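# Vessel density, non-perfusion interval detection, lesion classification
# and laser dose accounting.

test_that("vessel density is an exact voxel fraction", {
  vox <- array(1, dim = c(8, 16, 16))
  slab <- new("Slab", referenceSurface = "ILM", offsetUm = 0,
              thicknessUm = 15, voxels = vox,
              geometry = VolumeGeometry(16, 16, 64), clipped = FALSE)
  expect_equal(vesselDensity(slab), 1)
  slab@voxels[] <- 0
  expect_equal(vesselDensity(slab), 0)
  # half-masked: exact 0.5 verified by exhaustive count
  slab@voxels[, 1:8, ] <- 1
  expect_equal(vesselDensity(slab), sum(slab@voxels > 0) /
                 length(slab@voxels))
  expect_equal(vesselDensity(slab), 0.5)
})

test_that("density is stable under ROI translation on homogeneous slabs", {
  set.seed(31)
  vox <- array(runif(8 * 64 * 64) < 0.2, dim = c(8, 64, 64))
  slab <- new("Slab", referenceSurface = "ILM", offsetUm = 0,
              thicknessUm = 15, voxels = vox,
              geometry = VolumeGeometry(64, 64, 64), clipped = FALSE)
  base <- vesselDensity(slab)
  for (i in 1:10) {
    roi <- list(cxUm = runif(1, 25, 65), cyUm = runif(1, 25, 65),
                radiusUm = 20)
    expect_lt(abs(vesselDensity(slab, roi) - base), 0.02 + 0.02)
  }
})

test_that("non-perfusion intervals and reperfusion match the schedule", {
  # deep plexus removed days 1-7, restored from day 14
  d <- data.frame(day = c(1, 3, 7, 14, 21),
                  density = c(0.04, 0.03, 0.05, 0.19, 0.20))
  tc <- detectNonperfusion(d, baseline = 0.20)
  expect_equal(nrow(tc@intervals), 1L)
  expect_equal(tc@intervals$start_day, 1)
  expect_equal(tc@intervals$end_day, 7)
  expect_equal(unname(tc@reperfusionDay), 14)
  # intact capillary bed: no intervals
  d2 <- data.frame(day = c(1, 3, 7, 14, 21),
                   density = c(0.19, 0.21, 0.20, 0.18, 0.20))
  tc2 <- detectNonperfusion(d2, baseline = 0.20)
  expect_equal(nrow(tc2@intervals), 0L)
  expect_true(is.na(tc2@reperfusionDay))
  # constant density exactly at baseline: never below the drop threshold
  d3 <- data.frame(day = c(1, 3), density = c(0.2, 0.2))
  expect_equal(nrow(detectNonperfusion(d3, 0.2)@intervals), 0L)
  expect_error(detectNonperfusion(d3, 0), "baseline")
})

test_that("lowering the drop fraction never lengthens intervals", {
  set.seed(41)
  for (i in 1:20) {
    d <- data.frame(day = c(1, 3, 7, 14, 21), density = runif(5, 0, 0.3))
    flagged <- function(fr)
      sum(detectNonperfusion(d, 0.25, fr)@densities$nonperfused)
    expect_lte(flagged(0.3), flagged(0.5))
    expect_lte(flagged(0.5), flagged(0.7))
  }
})

test_that("classification follows the evidence rule exactly", {
  cls <- function(r, v, h, n)
    classifyLesion(list(rpeRupture = r, choroidVoid = v, maxHeightUm = h,
                        dvpNonperfusion = n))@label
  # ruptured, void, tall, non-perfused: the full CNV phenotype
  expect_equal(cls(TRUE, TRUE, 246, TRUE), "cnv")
  # photoreceptor-confined lesion, no vascular involvement
  expect_equal(cls(FALSE, FALSE, 125, FALSE), "acute")
  # tall but perfused with intact RPE: the residual branch
  expect_equal(cls(FALSE, FALSE, 210, FALSE), "indeterminate")
  # tall + deep non-perfusion qualifies without rupture
  expect_equal(cls(FALSE, FALSE, 210, TRUE), "cnv")
  # short but non-perfused: not clean acute, not CNV
  expect_equal(cls(FALSE, FALSE, 120, TRUE), "indeterminate")
  expect_error(classifyLesion(list(rpeRupture = TRUE)), "missing")
})

test_that("classification is a pure function of evidence", {
  set.seed(51)
  ev <- lapply(1:12, function(i)
    list(rpeRupture = runif(1) < 0.5, choroidVoid = runif(1) < 0.5,
         maxHeightUm = runif(1, 80, 300), dvpNonperfusion = runif(1) < 0.5))
  labs <- vapply(ev, function(e) classifyLesion(e)@label, character(1))
  perm <- sample(12)
  labs2 <- vapply(ev[perm], function(e) classifyLesion(e)@label,
                  character(1))
  expect_identical(labs2, labs[perm])
})

test_that("pulse energy is power times duration", {
  e <- pulseEnergy(46, 200)
  expect_equal(unname(e["joules"]), 0.0092, tolerance = 1e-12)
  expect_equal(unname(e["rounded"]), 0.009)
  expect_equal(unname(pulseEnergy(0, 500)["joules"]), 0)
  expect_equal(unname(pulseEnergy(180, 70)["joules"]), 0.0126,
               tolerance = 1e-12)
  expect_error(pulseEnergy(-1, 10), "non-negative")
})
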