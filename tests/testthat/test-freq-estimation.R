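test_that("read-strain log-likelihood follows the match/mismatch error model", {
  panel <- distinctPairPanel(5)
  row <- alleleMatrix(panel)[1, ]
  calls3 <- data.frame(site = 1:3, allele = c(0L, 0L, 0L))
  expect_equal(readStrainLoglik(calls3, row, 0.01), 3 * log(0.99))
  expect_equal(readStrainLoglik(calls3, row, 0), 0)
  mixed <- data.frame(site = 1:2, allele = c(0L, 1L))
  expect_equal(readStrainLoglik(mixed, row, 0.03), log(0.97) + log(0.01))
  # e = 0 mismatch is a representable -Inf
  expect_identical(readStrainLoglik(mixed, row, 0), -Inf)
  expect_error(readStrainLoglik(data.frame(site = 9, allele = 0L), row, 0.01),
               "out of range")
  expect_error(readStrainLoglik(calls3, row, 0.8), "0.75")
})

test_that("EM on a single-strain panel is the degenerate mixture", {
  panel <- toyPanel(matrix(c(0L, 1L, 0L), nrow = 1))
  s <- sampleFromReads(rbind(c(0, 1, NA), c(0, NA, 0), c(NA, 1, 0)))
  est <- emEstimate(s, panel, errorRate = 0.01)
  expect_equal(unname(frequencies(est)), 1)
  direct <- sum(c(readStrainLoglik(data.frame(site = 1:2, allele = c(0L, 1L)),
                                   alleleMatrix(panel)[1, ], 0.01),
                  readStrainLoglik(data.frame(site = c(1, 3), allele = c(0L, 0L)),
                                   alleleMatrix(panel)[1, ], 0.01),
                  readStrainLoglik(data.frame(site = 2:3, allele = c(1L, 0L)),
                                   alleleMatrix(panel)[1, ], 0.01)))
  expect_equal(est@loglik, direct)
})

test_that("with e = 0 and fully distinct strains EM reaches the exact
           hard-assignment fixed point", {
  panel <- distinctPairPanel(6)
  reads <- rbind(matrix(0L, 10, 6), matrix(1L, 30, 6))
  s <- sampleFromReads(reads)
  est <- emEstimate(s, panel, errorRate = 0)
  expect_equal(unname(frequencies(est)), c(0.25, 0.75))
  # coincides with the lattice at resolution 0.05
  or <- gridOracle(s, panel, errorRate = 0, resolution = 0.05)
  expect_equal(unname(or$frequencies), c(0.25, 0.75))
})

test_that("grid oracle handles the degenerate single-strain case", {
  panel <- toyPanel(matrix(c(0L, 1L), nrow = 1))
  s <- sampleFromReads(rbind(c(0, 1), c(0, NA)))
  or <- gridOracle(s, panel, errorRate = 0.01)
  expect_equal(unname(or$frequencies), 1)
  est <- emEstimate(s, panel, errorRate = 0.01)
  expect_equal(or$loglik, est@loglik)
  expect_error(gridOracle(s, toyPanel(matrix(0:1, 4, 2)), 0.01),
               "at most 3 strains")
})

test_that("EM matches the simplex-grid oracle on a 3-strain mixture", {
  set.seed(21)
  cfg <- simulationConfig(nStrains = 3, nSites = 80, seed = 21)
  panel <- simulatePanel(cfg)
  truth <- c(strain01 = 0.6, strain02 = 0.3, strain03 = 0.1)
  s <- simulateReads(truth, panel, 200, 3, 0.02, seed = 22)
  est <- emEstimate(s, panel, errorRate = 0.02)
  or <- gridOracle(s, panel, errorRate = 0.02, resolution = 0.01)
  expect_gte(est@loglik, or$loglik - 1e-6)
  expect_lt(max(abs(frequencies(est) - or$frequencies)), 0.02)
})

test_that("EM log-likelihood dominates the grid oracle over seeded instances,
           monotonically and on the simplex", {
  for (seed in 1:20) {
    set.seed(seed)
    nS <- sample(2:3, 1)
    cfg <- simulationConfig(nStrains = nS, nSites = 40,
                            pairwiseDiffProb = 0.5, seed = seed)
    panel <- simulatePanel(cfg)
    f <- rexp(nS); f <- f / sum(f); names(f) <- strainIds(panel)
    s <- simulateReads(f, panel, sample(30:200, 1), 3, 0.02, seed = seed + 100)
    est <- emEstimate(s, panel, errorRate = 0.02, tol = 1e-10)
    or <- gridOracle(s, panel, errorRate = 0.02, resolution = 0.05)
    expect_gte(est@loglik, or$loglik - 1e-10)
    # invariants on every fit: monotone trace, frequencies on the simplex
    expect_true(all(diff(est@loglikTrace) >= -1e-7))
    expect_lt(abs(sum(frequencies(est)) - 1), 1e-9)
    expect_true(all(frequencies(est) >= 0))
  }
})

test_that("permuting panel strain order permutes the estimate identically", {
  set.seed(33)
  cfg <- simulationConfig(nStrains = 3, nSites = 50, seed = 33)
  panel <- simulatePanel(cfg)
  truth <- c(strain01 = 0.5, strain02 = 0.35, strain03 = 0.15)
  s <- simulateReads(truth, panel, 150, 3, 0.01, seed = 34)
  est <- emEstimate(s, panel, errorRate = 0.01)
  perm <- c(3L, 1L, 2L)
  panelP <- strainPanel(strainIds(panel)[perm], siteInfo(panel),
                        alleleMatrix(panel)[perm, ])
  estP <- emEstimate(s, panelP, errorRate = 0.01)
  expect_equal(frequencies(estP)[names(frequencies(est))],
               frequencies(est))
})

test_that("uninformative reads are excluded, and an empty sample errors", {
  panel <- distinctPairPanel(4)
  # read 3 matches neither strain anywhere: zero likelihood when e = 0
  reads <- rbind(c(0, 0, 0, 0), c(1, 1, 1, 1), c(0, 1, 0, 1))
  s <- sampleFromReads(reads)
  expect_message(est <- emEstimate(s, panel, errorRate = 0),
                 "excluded 1 read")
  expect_equal(est@nReadsUsed, 2L)
  expect_equal(unname(frequencies(est)), c(0.5, 0.5))
  allBad <- sampleFromReads(rbind(c(0, 1, 0, 1)))
  expect_error(suppressMessages(emEstimate(allBad, panel, errorRate = 0)),
               "no usable reads")
})

test_that("bootstrap intervals: degenerate cases", {
  panel <- distinctPairPanel(5)
  s <- sampleFromReads(rbind(matrix(0L, 4, 5), matrix(1L, 6, 5)))
  ci1 <- bootstrapCI(s, panel, errorRate = 0.01, nBoot = 1, seed = 9)
  ests <- attr(ci1, "estimates")
  expect_equal(ci1$lower, unname(ests[1, ]))
  expect_equal(ci1$upper, unname(ests[1, ]))
  one <- toyPanel(matrix(c(0L, 1L), nrow = 1))
  s1 <- sampleFromReads(rbind(c(0, 1), c(0, 1)))
  ci <- bootstrapCI(s1, one, errorRate = 0.01, nBoot = 5, seed = 2)
  expect_equal(ci$lower, 1)
  expect_equal(ci$upper, 1)
})

test_that("bootstrap intervals cover a balanced two-strain truth", {
  panel <- distinctPairPanel(8)
  truth <- c(S1 = 0.5, S2 = 0.5)
  covered <- 0L
  nRep <- 50
  for (i in seq_len(nRep)) {
    s <- simulateReads(truth, panel, 500, 3, 0.02,
                       sampleId = "cov", seed = 1000 + i)
    ci <- bootstrapCI(s, panel, errorRate = 0.02, nBoot = 200,
                      seed = 2000 + i)
    if (ci$lower[1] <= 0.5 && ci$upper[1] >= 0.5) covered <- covered + 1L
  }
  expect_gte(covered / nRep, 0.9)
})
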