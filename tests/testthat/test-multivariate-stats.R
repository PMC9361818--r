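makeBalancedMeta <- function(reps = 3) {
  expand.grid(host = c("A17", "R108"), density = c("low", "high"),
              nitrogen = c("N-", "N+"), rep = seq_len(reps),
              stringsAsFactors = FALSE)[, 1:3]
}

test_that("an exact single-factor response yields proportion 1 and zero
           residual", {
  md <- data.frame(host = rep(c("A17", "R108"), each = 4))
  Y <- cbind(a = ifelse(md$host == "A17", 1, -1) * 2,
             b = ifelse(md$host == "A17", -0.5, 0.5))
  d <- designMatrix(md, ~ host)
  fit <- rdaFit(Y, d)
  expect_equal(fit$table$propVar[1], 1)
  expect_equal(fit$table$propVar[2], 0, tolerance = 1e-12)
  expect_equal(fit$table$df, c(1L, 6L))
})

test_that("a response orthogonalised against the design has zero model
           variance", {
  set.seed(5)
  md <- makeBalancedMeta(2)
  X <- stats::model.matrix(~ host * density, md)
  Y <- matrix(rnorm(nrow(md) * 4), ncol = 4)
  Y <- stats::resid(stats::lm(Y ~ X))  # orthogonal to every model column
  d <- designMatrix(md, ~ host * density)
  fit <- suppressWarnings(rdaFit(Y, d))
  expect_lt(sum(fit$table$propVar[-nrow(fit$table)]), 1e-9)
})

test_that("sequential term SS match an independent projection-matrix oracle", {
  set.seed(12)
  for (i in 1:5) {
    md <- data.frame(host = rep(c("A17", "R108"), 6),
                     density = sample(c("low", "high"), 12, replace = TRUE),
                     nitrogen = sample(c("N-", "N+"), 12, replace = TRUE))
    Y <- matrix(rnorm(60), 12, 5)
    d <- designMatrix(md, ~ host + density + nitrogen + host:density)
    fit <- rdaFit(Y, d)
    ssOracle <- projectionSSOracle(Y, d$X, d$assign)
    ssTotal <- sum(scale(Y)^2)
    expect_equal(fit$table$propVar[1:4], ssOracle / ssTotal,
                 tolerance = 1e-9)
    # bookkeeping invariants
    expect_equal(sum(fit$table$propVar), 1, tolerance = 1e-9)
    expect_equal(sum(fit$table$df), 11L)
  }
})

test_that("variance partition and pseudo-F agree with vegan's RDA", {
  skip_if_not_installed("vegan")
  set.seed(31)
  md <- makeBalancedMeta(2)
  Y <- matrix(rnorm(nrow(md) * 6), ncol = 6)
  d <- designMatrix(md, ~ host * density * nitrogen)
  fit <- rdaFit(Y, d)
  v <- vegan::rda(Y ~ host * density * nitrogen, data = md, scale = TRUE)
  av <- anova(v, by = "terms", permutations = 99)
  expect_equal(fit$table$propVar, av$Variance / sum(av$Variance),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$table$F[-nrow(fit$table)],
               av$F[-length(av$F)], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$adjR2, vegan::RsquareAdj(v)$adj.r.squared,
               tolerance = 1e-10)
})

test_that("rank-deficient designs error naming the aliased term", {
  md <- data.frame(host = rep(c("A17", "R108"), 4))
  md$copy <- md$host  # perfectly aliased factor
  Y <- matrix(rnorm(16), 8, 2)
  expect_error(rdaFit(Y, designMatrix(md, ~ host + copy)), "copy")
})

test_that("a perfectly separated response attains the minimum permutation p", {
  set.seed(8)
  md <- data.frame(host = rep(c("A17", "R108"), each = 8))
  Y <- cbind(ifelse(md$host == "A17", 3, -3) + rnorm(16, 0, 0.01),
             ifelse(md$host == "A17", -2, 2) + rnorm(16, 0, 0.01))
  res <- permutationTest(Y, designMatrix(md, ~ host), nPerm = 999, seed = 3)
  expect_equal(res$table$P[1], 0.001)
})

test_that("permutation p-values are invariant to response column scaling", {
  set.seed(44)
  md <- makeBalancedMeta(2)
  Y <- matrix(rnorm(nrow(md) * 3), ncol = 3)
  d <- designMatrix(md, ~ host * density)
  p1 <- permutationTest(Y, d, nPerm = 99, seed = 7)$table$P
  p2 <- permutationTest(sweep(Y, 2, c(10, 0.1, 3), `*`), d,
                        nPerm = 99, seed = 7)$table$P
  expect_equal(p1, p2)
})

test_that("anovaTerms: balanced orthogonal design isolates the planted main
           effect", {
  md <- makeBalancedMeta(3)
  y <- ifelse(md$host == "A17", 1, 0)  # pure host effect, no noise
  tab <- suppressWarnings(anovaTerms(y, designMatrix(md, ~ host + density)))
  expect_equal(tab$SS[tab$term == "density"], 0, tolerance = 1e-12)
  expect_equal(tab$SS[tab$term == "host"], sum((y - mean(y))^2))
  # constant response: SS zero, statistics undefined
  w <- capture_warnings(tab0 <- anovaTerms(rep(2, nrow(md)),
                                           designMatrix(md, ~ host)))
  expect_true(any(grepl("constant response", w)))
  expect_equal(tab0$SS, rep(0, nrow(tab0)), tolerance = 1e-12)
  expect_true(all(is.na(tab0$F)))
})

test_that("anovaTerms sequential SS equal the projection oracle on scaled y", {
  set.seed(61)
  md <- makeBalancedMeta(2)
  y <- rnorm(nrow(md))
  d <- designMatrix(md, ~ host + density + nitrogen)
  tab <- anovaTerms(as.numeric(scale(y)), d)
  ssOracle <- projectionSSOracle(matrix(y, ncol = 1), d$X, d$assign)
  expect_equal(tab$SS[1:3], ssOracle, tolerance = 1e-9)
})

test_that("per-host submodels: symmetry, single host, and host-specific
           density effects", {
  set.seed(77)
  md <- data.frame(host = rep(c("A17", "R108"), each = 8),
                   density = rep(c("low", "high"), 8),
                   nitrogen = rep(rep(c("N-", "N+"), each = 2), 4))
  Yhalf <- matrix(rnorm(8 * 3), 8, 3)
  Y <- rbind(Yhalf, Yhalf)  # identical responses in both hosts
  sub <- perHostSubmodels(Y, md, nPerm = 49, seed = 5)
  expect_named(sub, c("A17", "R108"))
  expect_equal(sub$A17$table$propVar, sub$R108$table$propVar)
  # single-host input -> one submodel
  one <- perHostSubmodels(Y[1:8, ], md[1:8, ], nPerm = 49, seed = 5)
  expect_named(one, "A17")
  # planted density effect in A17 only
  Y2 <- matrix(rnorm(16 * 4, sd = 0.3), 16, 4)
  Y2[md$host == "A17", ] <- Y2[md$host == "A17", ] +
    outer(ifelse(md$density[md$host == "A17"] == "high", 2, -2), rep(1, 4))
  sub2 <- perHostSubmodels(Y2, md, nPerm = 49, seed = 5)
  dProp <- function(r) r$table$propVar[r$table$term == "density"]
  expect_gt(dProp(sub2$A17), dProp(sub2$R108))
})
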