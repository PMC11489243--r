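test_that("constant inputs propagate unchanged through every averaging stage", {
  withr::with_seed(1L, {
    x <- rep(3.5, 90)
    g <- gapJunctionEqualise(x, defaultConfig)
    expect_equal(g, rep(3.5, 90))
    s <- somaticIntegration(g, defaultConfig)
    expect_equal(as.numeric(s), rep(3.5, 30))
    o <- glomerularOutput(s, defaultConfig)
    expect_equal(o, rep(3.5, 700))
  })
})

test_that("gap-junction equalisation averages a snapshot of surrounding dendrites", {
  # one dendrite holds 6, the rest 0: every sample of 6 contains it 0 or 1
  # times, so every group mean is 0 or 1
  withr::with_seed(7L, {
    x <- c(6, rep(0, 89))
    g <- gapJunctionEqualise(x, defaultConfig)
    expect_true(all(g %in% c(0, 1)))
    # focal dendrite excluded: index 1 can never sample itself
    expect_identical(g[1], 0)
  })

  # variance contraction ~ 1/sqrt(groupSize), pooled over replicate runs
  withr::with_seed(11L, {
    ratios <- replicate(300, {
      x <- rbinom(90, 1750, 0.00114)
      var(gapJunctionEqualise(x, defaultConfig)) / var(x)
    })
    expect_equal(sqrt(mean(ratios)), 1 / sqrt(6), tolerance = 0.15)
  })

  # a finite neighbourhood window keeps influence local
  withr::with_seed(3L, {
    cfgW <- EnsembleConfig(neighbourhoodWindow = 6)
    x <- c(90, rep(0, 89))
    g <- gapJunctionEqualise(x, cfgW)
    expect_true(all(g[8:90] == 0))   # indices beyond the window never see it
    expect_true(any(g[1:7] > 0))
  })

  expect_error(gapJunctionEqualise(rep(1, 10), defaultConfig), "dendrite")
  # a group cannot span the whole dendrite population
  expect_error(EnsembleConfig(gapGroupSize = 90L), "gapGroupSize")
})

test_that("somatic integration averages a recorded random partition", {
  withr::with_seed(5L, {
    v <- as.numeric(1:90)
    s <- somaticIntegration(v, defaultConfig)
    part <- attr(s, "partition")
    expect_identical(dim(part), c(3L, 30L))
    expect_setequal(as.integer(part), 1:90)       # disjoint triples cover all
    # independent recomputation over the recorded partition
    expect_equal(as.numeric(s),
                 apply(part, 2, function(ix) mean(v[ix])))
  })
  # identical seed, identical partition and output
  s1 <- withr::with_seed(8L, somaticIntegration(as.numeric(1:90), defaultConfig))
  s2 <- withr::with_seed(8L, somaticIntegration(as.numeric(1:90), defaultConfig))
  expect_identical(s1, s2)
  expect_error(somaticIntegration(1:80, defaultConfig), "divisible")
})

test_that("glomerular sampling is unbiased and exact at full-population convergence", {
  withr::with_seed(2L, {
    som <- rnorm(30, 5, 1)
    # convergence = all somata: every glomerulus averages the whole population
    cfgFull <- EnsembleConfig(convergenceMin = 30L, convergenceMax = 30L)
    expect_equal(glomerularOutput(som, cfgFull), rep(mean(som), 700))
    # unbiasedness at default convergence, many glomeruli
    o <- glomerularOutput(som, defaultConfig, nGlomeruli = 1e4)
    se <- sd(o) / sqrt(1e4)
    expect_lt(abs(mean(o) - mean(som)), 3 * se)
  })
  expect_error(glomerularOutput(rnorm(10), defaultConfig), "convergenceMax")
})

test_that("a full conversion is deterministic and contained stage by stage", {
  r1 <- runConversion(1, defaultParams, defaultConfig, seed = 101L)
  r2 <- runConversion(1, defaultParams, defaultConfig, seed = 101L)
  expect_identical(dendriticInputs(r1), dendriticInputs(r2))
  expect_identical(groupMeans(r1), groupMeans(r2))
  expect_identical(somaticValues(r1), somaticValues(r2))
  expect_identical(glomerularValues(r1), glomerularValues(r2))
  expect_identical(somaticPartition(r1), somaticPartition(r2))

  for (j in c(0.4, 1, 2)) {
    r <- runConversion(j, defaultParams, defaultConfig, seed = 7L)
    expect_gte(min(groupMeans(r)), min(dendriticInputs(r)))
    expect_lte(max(groupMeans(r)), max(dendriticInputs(r)))
    expect_gte(min(somaticValues(r)), min(groupMeans(r)) - 1e-12)
    expect_lte(max(somaticValues(r)), max(groupMeans(r)) + 1e-12)
    expect_gte(min(glomerularValues(r)), min(somaticValues(r)) - 1e-12)
    expect_lte(max(glomerularValues(r)), max(somaticValues(r)) + 1e-12)
  }

  # the caller's RNG stream is not consumed
  withr::with_seed(99L, {
    before <- runif(1)
    withr::with_seed(99L, {
      invisible(runConversion(1, seed = 55L))
      expect_identical(runif(1), before)
    })
  })
})

test_that("a density with no active fibres propagates zeros through all stages", {
  r <- runConversion(jDegenerate, defaultParams, defaultConfig, seed = 4L)
  expect_identical(dendriticInputs(r), integer(90))
  expect_identical(groupMeans(r), numeric(90))
  expect_identical(as.numeric(somaticValues(r)), numeric(30))
  expect_identical(glomerularValues(r), numeric(700))
  expect_identical(stageSummary(r)$sd, numeric(4))
})

test_that("averaging contracts the spread at the grouped and glomerular stages", {
  wins2 <- wins4 <- 0L
  for (s in childSeeds(31L, 200L)) {
    r <- runConversion(1, defaultParams, defaultConfig, seed = s)
    sm <- stageSummary(r)
    wins2 <- wins2 + (sm$sd[2] < sm$sd[1])
    wins4 <- wins4 + (sm$sd[4] < sm$sd[3])
  }
  expect_gte(wins2, 198L)
  expect_gte(wins4, 198L)
})
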