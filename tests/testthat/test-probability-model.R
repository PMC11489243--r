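test_that("input-count pmf matches independent evaluations and closed forms", {
  # degenerate density: zero contacts certain
  expect_identical(pmfActiveInputs(defaultParams, j = 0, k = 0, "dendrite"), 1)
  expect_identical(pmfActiveInputs(defaultParams, j = 0, k = 3, "cell"), 0)

  # direct power-form evaluation: P(0 contacts on one dendrite | 700 active)
  expect_equal(pmfActiveInputs(defaultParams, j = 0.4, k = 0, "dendrite"),
               (1 - 0.00342 / 3)^700, tolerance = 1e-12)
  expect_equal(pmfActiveInputs(defaultParams, j = 0.4, k = 0, "dendrite"),
               0.4500, tolerance = 1e-4)

  # log-gamma route against stats::dbinom across scopes and densities
  for (j in c(0.4, 1, 2)) {
    n <- activeFibreCount(defaultParams, j)
    for (sc in c("cell", "dendrite")) {
      p <- 0.00342 / ifelse(sc == "dendrite", 3, 1)
      got <- pmfActiveInputs(defaultParams, j, 0:25, sc)
      expect_equal(got, dbinom(0:25, n, p), tolerance = 1e-9)
    }
  }

  # closed-form mean at j = 2 for a whole cell: n * p = 3500 * 0.00342
  pm <- pmfActiveInputs(defaultParams, j = 2, k = 0:3500, "cell")
  expect_equal(sum(0:3500 * pm), 3500 * 0.00342, tolerance = 1e-9)

  # domain errors and the k > n convention
  expect_error(pmfActiveInputs(defaultParams, j = -1, k = 0, "cell"), "j")
  expect_error(pmfActiveInputs(defaultParams, j = 1, k = -2, "cell"), "k")
  expect_identical(pmfActiveInputs(defaultParams, j = 0.4, k = 701, "dendrite"), 0)
})

test_that("active fibre counts are the rounded fraction of the population", {
  expect_identical(activeFibreCount(defaultParams, c(0.4, 0.6, 0.8)),
                   c(700L, 1050L, 1400L))
  expect_identical(activeFibreCount(defaultParams, 0), 0L)
  # non-integer products round to the nearest integer trial count
  expect_identical(activeFibreCount(defaultParams, 0.123), 215L)
  expect_error(activeFibreCount(defaultParams, -0.1), "j")
})

test_that("distributions normalise, truncate for display only, and widen with activity", {
  maxKCell <- numeric(0)
  for (j in jGridDefault()) {
    for (sc in c("cell", "dendrite")) {
      d <- buildDistribution(defaultParams, j, sc)
      expect_equal(sum(pmfValues(d)), 1, tolerance = 1e-12)
      expect_true(all(pmfValues(d) >= 0 & pmfValues(d) <= 1))
      tp <- truncatedPmf(d)
      expect_true(all(tp > 0.001))
      # the truncated view never changes the underlying mass
      expect_identical(unname(tp), unname(pmfValues(d)[names(tp)]))
    }
    maxKCell <- c(maxKCell, max(as.integer(names(
      truncatedPmf(buildDistribution(defaultParams, j, "cell"))))))
  }
  # monotone spread: the displayed k range is non-decreasing in j
  expect_true(all(diff(maxKCell) >= 0))
  expect_gt(maxKCell[length(maxKCell)], maxKCell[1])

  d1 <- buildDistribution(defaultParams, 1, "cell")
  expect_equal(sum(as.integer(names(pmfValues(d1))) * pmfValues(d1)),
               1750 * 0.00342, tolerance = 1e-9)
  expect_error(buildDistribution(defaultParams, 0, "cell"), "> 0")
  expect_error(buildDistribution(defaultParams, -1, "cell"), "> 0")
})

test_that("sampling is reproducible and consistent with binomial moments", {
  d <- buildDistribution(defaultParams, 0.4, "dendrite")
  x1 <- sampleInputCounts(d, 1e5, seed = 42L)
  x2 <- sampleInputCounts(d, 1e5, seed = 42L)
  expect_identical(x1, x2)

  n <- 700; p <- 0.00342 / 3
  seMean <- sqrt(n * p * (1 - p) / 1e5)
  expect_lt(abs(mean(x1) - n * p), 4 * seMean)
  seVar <- n * p * (1 - p) * sqrt(2 / (1e5 - 1))
  expect_lt(abs(var(x1) - n * p * (1 - p)), 4 * seVar)

  # degenerate distribution yields all-zero draws
  d0 <- buildDistribution(defaultParams, jDegenerate, "dendrite")
  expect_identical(nActive(d0), 0L)
  expect_identical(sampleInputCounts(d0, 50, seed = 1L), integer(50))
  expect_error(sampleInputCounts(list(), 10), "ActiveInputDistribution")
})

test_that("probability table pairs cell and dendrite rows over the density grid", {
  tab <- probabilityTable(defaultParams)
  expect_named(tab, c("j", "scope", "k", "probability"))
  expect_setequal(unique(tab$j), jGridDefault())
  expect_true(all(tab$probability > 0.001))
  for (j in jGridDefault())
    expect_setequal(unique(tab$scope[tab$j == j]), c("cell", "dendrite"))
  # a cell pools three dendrites, so its displayed range reaches further
  kCell <- max(tab$k[tab$scope == "cell" & tab$j == 2])
  kDend <- max(tab$k[tab$scope == "dendrite" & tab$j == 2])
  expect_gt(kCell, kDend)
})
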