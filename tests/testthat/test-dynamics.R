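# Longitudinal dynamics: percent change, interval differences, steady-state
# onset and group statistics. Expected values are recomputed independently
# in the tests by direct spreadsheet-style arithmetic on the packaged
# reference table.

tab <- lesionDimensionTable()
acute <- tab[tab$condition == "acute", ]
cnv <- tab[tab$condition == "cnv", ]

test_that("percent change and interval differences match direct arithmetic", {
  tr <- percentChangeTrace(acute$onl_um, "onl_um", days = acute$day)
  # independent recomputation
  m0 <- acute$onl_um[1]
  expect_equal(tr@percentChange, 100 * (acute$onl_um - m0) / m0,
               tolerance = 1e-12)
  expect_equal(tr@firstDiff, 100 * diff(acute$onl_um) / m0,
               tolerance = 1e-12)
  expect_equal(tr@secondDiff, diff(100 * diff(acute$onl_um) / m0),
               tolerance = 1e-12)
  # day-3 percent change of the acute ONL trace
  expect_equal(tr@percentChange[2], 100 * (110.90 - 128.31) / 128.31,
               tolerance = 1e-10)
  # first interval of the acute RPE trace, percent of baseline
  trR <- percentChangeTrace(acute$rpe_um, "rpe_um", days = acute$day)
  expect_equal(trR@firstDiff[1], 100 * (196.09 - 136.59) / 136.59,
               tolerance = 1e-10)
  expect_equal(round(trR@firstDiff[1], 2), 43.56)
})

test_that("dynamics arithmetic matches an independent recomputation per row", {
  for (cond in list(acute, cnv)) {
    for (d in c("onl_um", "rpe_um", "height_um", "pr_um")) {
      tr <- percentChangeTrace(cond[[d]], d, days = cond$day)
      v <- cond[[d]]
      expect_lt(max(abs(tr@percentChange - 100 * (v - v[1]) / v[1])),
                1e-10 * max(abs(v)))
      expect_lt(max(abs(tr@firstDiff - 100 * diff(v) / v[1])), 1e-10)
    }
  }
})

test_that("steady-state onset reproduces the reported lesion behaviour", {
  # acute photoreceptor protrusion settles at day 7
  trPr <- percentChangeTrace(acute$pr_um, "pr_um", days = acute$day)
  expect_equal(detectSteadyState(trPr)$steadyOnset, 7)
  # subsequent intervals are within the 5% threshold (2.7%, 3.6%)
  expect_true(all(abs(trPr@firstDiff[3:4]) <= 5))
  # acute height is stable from day 7 as well
  trH <- percentChangeTrace(acute$height_um, "height_um", days = acute$day)
  expect_equal(trH@steadyOnset, 7)
  # no CNV dimension converges through day 21
  for (d in c("onl_um", "rpe_um", "height_um", "pr_um")) {
    tr <- percentChangeTrace(cnv[[d]], d, days = cnv$day)
    expect_true(is.na(detectSteadyState(tr)$steadyOnset))
  }
})

test_that("steady-state edge cases behave", {
  # constant series: steady from the first timepoint, all derivatives zero
  tr <- percentChangeTrace(rep(100, 5), days = c(1, 3, 7, 14, 21))
  expect_true(all(tr@percentChange == 0))
  expect_true(all(tr@firstDiff == 0))
  expect_equal(tr@steadyOnset, 1)
  # monotone series with all changes above threshold: none
  tr2 <- percentChangeTrace(c(100, 120, 144, 170, 200),
                            days = c(1, 3, 7, 14, 21))
  expect_true(is.na(tr2@steadyOnset))
  # phases: early through day 3, transition to 7, late from 7
  expect_equal(unname(detectSteadyState(tr)$phaseLabels),
               c("early", "early", "late", "late", "late"))
  expect_error(percentChangeTrace(c(0, 5), days = c(1, 3)), "baseline")
  expect_error(percentChangeTrace(c(5, 7), days = c(3, 1)), "increasing")
  expect_error(detectSteadyState(percentChangeTrace(c(5, 7),
                                                    days = c(1, 3))),
               "three")
})

test_that("dynamics are invariant under rescaling of the measurements", {
  set.seed(11)
  for (i in 1:10) {
    v <- runif(5, 50, 400)
    k <- runif(1, 0.1, 10)
    a <- percentChangeTrace(v, days = c(1, 3, 7, 14, 21))
    b <- percentChangeTrace(k * v, days = c(1, 3, 7, 14, 21))
    expect_equal(a@percentChange, b@percentChange, tolerance = 1e-9)
    expect_equal(a@firstDiff, b@firstDiff, tolerance = 1e-9)
    expect_identical(is.na(a@steadyOnset), is.na(b@steadyOnset))
    if (!is.na(a@steadyOnset)) expect_equal(a@steadyOnset, b@steadyOnset)
  }
})

test_that("group statistics pool printed CV cells", {
  gs <- groupStatistics(tab, "acute")
  # oracle: plain mean of the 20 printed CV cells
  cvCols <- c("onl_cv", "rpe_cv", "height_cv", "pr_cv")
  expect_equal(gs@pooledCv, mean(unlist(acute[, cvCols])), tolerance = 1e-12)
  gs2 <- groupStatistics(tab, "cnv")
  expect_equal(gs2@pooledCv, mean(unlist(cnv[, cvCols])), tolerance = 1e-12)
  expect_equal(nrow(gs@cells), 20L)
})

test_that("group statistics on raw lesion tables use the population sd", {
  set.seed(21)
  raw <- do.call(rbind, lapply(1:12, function(i)
    data.frame(lesion_id = i, day = c(1, 3),
               onl_um = rnorm(2, 120, 15), rpe_um = rnorm(2, 140, 20),
               height_um = rnorm(2, 120, 8), pr_um = rnorm(2, 130, 10))))
  gs <- groupStatistics(raw)
  cell <- gs@cells[gs@cells$dimension == "onl_um" & gs@cells$day == 1, ]
  x <- raw$onl_um[raw$day == 1]
  expect_equal(cell$mean, mean(x), tolerance = 1e-12)
  expect_equal(cell$sd, sqrt(mean((x - mean(x))^2)), tolerance = 1e-12)
  expect_equal(cell$cv, cell$sd / cell$mean, tolerance = 1e-12)
  # identical lesions: all CVs zero
  same <- do.call(rbind, lapply(1:3, function(i)
    data.frame(lesion_id = i, day = 1, onl_um = 100, rpe_um = 100,
               height_um = 100, pr_um = 100)))
  expect_true(all(groupStatistics(same)@cells$cv == 0))
  # zero-mean cells are excluded with a warning
  zero <- do.call(rbind, lapply(1:3, function(i)
    data.frame(lesion_id = i, day = 1, onl_um = 0, rpe_um = 100,
               height_um = 100, pr_um = 100)))
  expect_warning(gz <- groupStatistics(zero), "excluded")
  expect_equal(nrow(gz@excluded), 1L)
})
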