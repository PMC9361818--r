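test_that("panel simulation is deterministic and hits its Hamming targets", {
  cfg <- simulationConfig(nStrains = 5, nSites = 300, seed = 3)
  p1 <- simulatePanel(cfg)
  p2 <- simulatePanel(cfg)
  expect_identical(alleleMatrix(p1), alleleMatrix(p2))
  # two strains, difference probability 1 -> every site differs
  cfg2 <- simulationConfig(nStrains = 2, nSites = 100, pairwiseDiffProb = 1,
                           seed = 4)
  d <- validatePanel(simulatePanel(cfg2), minPairwiseSnps = 1)$distances
  expect_equal(unname(d[1, 2]), 100L)
  # mean pairwise distance within 3 SD of the binomial expectation
  cfg3 <- simulationConfig(nStrains = 10, nSites = 1000,
                           pairwiseDiffProb = 0.5, seed = 5)
  D <- suppressWarnings(validatePanel(simulatePanel(cfg3))$distances)
  off <- D[upper.tri(D)]
  expect_lt(abs(mean(off) - 500), 3 * sqrt(1000 * 0.25))
})

test_that("inoculum simulation: jitter, normalisation, replicate estimates", {
  cfg <- simulationConfig(nStrains = 68, inoculumJitterSd = 0, seed = 6)
  ino <- simulateInoculum(cfg, "C68")
  expect_equal(unname(ino$q), rep(1 / 68, 68))
  pairCfg <- simulationConfig(nStrains = 4, seed = 7)
  ip <- simulateInoculum(pairCfg, "P12")
  expect_length(ip$q, 2)
  expect_equal(sum(ip$q), 1)
  expect_error(simulateInoculum(pairCfg, "C99"), "unknown community")
  # jittered initial frequencies have a realistic near-equal spread
  cfgJ <- simulationConfig(nStrains = 68, inoculumJitterSd = 0.25, seed = 8)
  r <- range(simulateInoculum(cfgJ, "C68")$q) / (1 / 68)
  expect_gt(r[1], 0.3)
  expect_lt(r[2], 3)
})

test_that("nodule pools: multinomial selection tilt, dominance, drift", {
  ino <- c(a = 0.5, b = 0.3, c = 0.2)
  # neutral selection, huge pool: frequencies converge to the inoculum
  pool <- simulateNodulePool(ino, c(a = 0, b = 0, c = 0), 1e6, seed = 11)
  expect_lt(max(abs(pool - ino)), 0.003)
  expect_equal(sum(pool), 1)
  # an overwhelming selection coefficient takes every nodule
  dom <- simulateNodulePool(ino, c(a = 0, b = 50, c = 0), 500, seed = 12)
  expect_equal(unname(dom["b"]), 1)
  # single nodule: degenerate one-strain pool
  one <- simulateNodulePool(ino, c(a = 0, b = 0, c = 0), 1, seed = 13)
  expect_equal(sort(unname(one)), c(0, 0, 1))
  # drift scales with pool size: fewer nodules, noisier replicate pools
  reps <- function(n) vapply(1:40, function(i)
    simulateNodulePool(ino, c(a = 0, b = 0, c = 0), n)[["a"]], 0)
  set.seed(14)
  expect_gt(var(reps(100)), var(reps(500)))
})

test_that("read simulation: exact copies at e = 0, forced mismatch at e = 1", {
  panel <- distinctPairPanel(20)
  s0 <- simulateReads(c(S1 = 1), panel, 50, 4, errorRate = 0, seed = 21)
  al <- alleleMatrix(panel)
  expect_true(all(s0@calls$allele == al[1, s0@calls$site]))
  s1 <- simulateReads(c(S1 = 1), panel, 50, 4, errorRate = 1, seed = 22)
  expect_true(all(s1@calls$allele != al[1, s1@calls$site]))
  expect_error(simulateReads(c(S1 = 1), panel, 5, 21, 0, seed = 1),
               "exceeds panel sites")
})

test_that("read source fractions follow the pool frequencies", {
  panel <- distinctPairPanel(50)
  s <- simulateReads(c(S1 = 0.7, S2 = 0.3), panel, 1e4, 3, errorRate = 0,
                     seed = 31)
  al <- alleleMatrix(panel)
  # with fully distinct strains and e = 0 each read is uniquely consistent
  # with its source strain
  firstCall <- s@calls[!duplicated(s@calls$read), ]
  fracS1 <- mean(firstCall$allele == al[1, firstCall$site])
  expect_lt(abs(fracS1 - 0.7), 3 * sqrt(0.7 * 0.3 / 1e4))
})

test_that("the default factorial design has the study's shape", {
  cfg <- simulationConfig(seed = 41)
  ex <- simulateExperiment(cfg, sequencing = FALSE)
  md <- ex$metadata
  c68 <- md[md$community == "C68", ]
  # 4 N x D cells x 2 hosts x 6 reps = 48 full-community samples
  expect_equal(nrow(c68), 48L)
  expect_true(all(table(c68$host, c68$density, c68$nitrogen) == 6L))
  expect_equal(sum(md$community == "C8"), 10L)   # 2 hosts x 5 reps
  expect_equal(sum(md$community == "C3"), 10L)
  expect_equal(sum(grepl("^P", md$community)), 24L)  # 3 pairs x 2 x 4
  # nodule counts respect the host-specific ranges
  expect_true(all(md$nNodules[md$host == "A17"] >= 300 &
                    md$nNodules[md$host == "A17"] <= 500))
  expect_true(all(md$nNodules[md$host == "R108"] >= 100 &
                    md$nNodules[md$host == "R108"] <= 200))
  # every truth frequency vector is a distribution
  sums <- vapply(ex$truth$pools, sum, 0)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("a null experiment (no selection, no jitter, huge pools) gives
           fitness near zero everywhere", {
  cfg <- simulationConfig(nStrains = 10, nSites = 50,
                          inoculumJitterSd = 0,
                          selectionSd = c(A17 = 0, R108 = 0),
                          densityMultiplier = c(A17 = 1, R108 = 1),
                          nitrogenMultiplier = c(A17 = 1, R108 = 1),
                          noduleRange = list(A17 = c(1e6, 1e6),
                                             R108 = c(1e6, 1e6)),
                          seed = 51)
  ex <- simulateExperiment(cfg, sequencing = FALSE)
  comm <- initialCommunity("C10", ex$truth$inocula$C10)
  fullIds <- ex$metadata$sample_id[ex$metadata$community == "C10"]
  for (sid in fullIds[1:8]) {
    fit <- strainFitness(ex$truth$pools[[sid]], comm)
    expect_lt(max(abs(fit)), 0.05)
  }
})

test_that("experiment output files are byte-identical across re-runs", {
  cfg <- simulationConfig(nStrains = 6, nSites = 40, readsPerSample = 100,
                          noduleRange = list(A17 = c(50L, 80L),
                                             R108 = c(30L, 50L)),
                          seed = 61)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeExperiment(simulateExperiment(cfg), d1)
  writeExperiment(simulateExperiment(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("checksum of", f))
  }
})
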