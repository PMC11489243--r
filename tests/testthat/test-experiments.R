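test_that("sweeps are reproducible from the master seed and ledger their child seeds", {
  s1 <- precisionSweep(jValues = c(0.4, 1), replicates = 3L, seed = 17L)
  s2 <- precisionSweep(jValues = c(0.4, 1), replicates = 3L, seed = 17L)
  expect_identical(perPoint(s1), perPoint(s2))
  expect_identical(sweepDetails(s1), sweepDetails(s2))
  # any detail row is independently re-derivable from its own seed
  row <- sweepDetails(s1)[4, ]
  res <- runConversion(row$j, defaultParams, defaultConfig, seed = row$seed)
  expect_equal(mean(glomerularValues(res)), row$fieldMean)
  expect_equal(sd(glomerularValues(res)), row$withinSD)

  # a degenerate grid point yields zero spread
  s0 <- precisionSweep(jValues = c(jDegenerate, 1), replicates = 2L, seed = 2L)
  expect_identical(perPoint(s0)$sdWithin[1], 0)
})

test_that("precision loss grows with activity density on a coarse grid", {
  ps <- precisionSweep(jValues = c(0.4, 1.0, 1.6), replicates = 30L, seed = 23L)
  sds <- perPoint(ps)$sdWithin
  expect_true(all(diff(sds) > 0))
})

test_that("accuracy sweeps give linear grand means and widening field-mean spread", {
  as1 <- accuracySweep(jValues = c(0.4, 1.2, 2.0), nFields = 40L,
                       replicates = 3L, seed = 29L)
  pp <- perPoint(as1)
  expect_true(all(diff(pp$sdOfMeans) > 0))
  fit <- sweepLinearity(as1)
  expect_gte(fit$r.squared, 0.99)
  # unbiased averaging makes the slope the dendritic mean per percent active:
  # n(1%) * p_dendrite = 1750 * 0.00342/3 per 1% of activity
  expect_equal(fit$slope, 1750 * 0.00342 / 3, tolerance = 0.02)
  expect_error(accuracySweep(jValues = 1, nFields = 1L, seed = 1L), "nFields")
})

test_that("group-size benefits diminish consistently with 1/sqrt(size) contraction", {
  gs <- groupSizeSweep(sizes = c(2L, 6L, 12L), j = 1, replicates = 40L, seed = 37L)
  pp <- perPoint(gs)
  expect_true(all(diff(pp$sdWithin) < 0))
  expect_lt(pp$sdWithin[2] - pp$sdWithin[3],   # 6 -> 12 gains less
            pp$sdWithin[1] - pp$sdWithin[2])   # than 2 -> 6
  ratio <- pp$sdGroupPooled / pp$sdInputPooled
  expect_equal(ratio, 1 / sqrt(c(2, 6, 12)), tolerance = 0.15)
  expect_error(groupSizeSweep(sizes = c(2L, 90L), seed = 1L), "sizes|group sizes")
})

test_that("near-total group size equalises the ensemble almost completely", {
  gs <- groupSizeSweep(sizes = c(6L, 89L), j = 1, replicates = 10L, seed = 41L)
  pp <- perPoint(gs)
  # sampling 89 of the other 89 dendrites reproduces their mean exactly;
  # residual group-mean spread only reflects each focal dendrite's exclusion
  expect_lt(pp$sdGroupPooled[2], 0.05 * pp$sdInputPooled[2])
  expect_lt(pp$sdWithin[2], 0.2 * pp$sdWithin[1])
})

test_that("repeated runs track the input mean and their spread is set by activity", {
  rr <- repeatedRuns(1, nRuns = 60L, params = defaultParams,
                     config = defaultConfig, seed = 43L)
  tab <- runTable(rr)
  expect_identical(nrow(tab), 60L)
  # group-mean series is an unbiased tracker of the dendritic series
  dif <- tab$groupMeanMean - tab$dendriticMean
  expect_lt(abs(mean(dif)), 4 * sd(dif) / sqrt(nrow(tab)))
  # somatic means equal group-mean means exactly (disjoint partition of all)
  expect_equal(tab$somaticMean, tab$groupMeanMean, tolerance = 1e-12)
  # output means co-vary with input means run to run (unbiased averaging)
  expect_gt(cor(tab$dendriticMean, tab$glomerularMean), 0.5)

  # spread of the output series across runs is governed by activity density
  hi <- runTable(repeatedRuns(2, nRuns = 40L, seed = 47L))$glomerularMean
  lo <- runTable(repeatedRuns(0.4, nRuns = 40L, seed = 47L))$glomerularMean
  expect_gt(sd(hi), sd(lo))

  # degenerate density: all series identically zero
  z <- runTable(repeatedRuns(jDegenerate, nRuns = 5L, seed = 3L))
  expect_identical(z$dendriticMean, numeric(5))
  expect_identical(z$groupMeanMean, numeric(5))
  expect_identical(z$glomerularMean, numeric(5))
})
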