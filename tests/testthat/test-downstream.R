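test_that("log-rank test matches the risk-set formula and handles symmetry", {
  # identical event patterns in both groups: statistic 0, p = 1
  tab <- data.frame(time = rep(c(1, 2, 3), 2), event = rep(c(1, 1, 0), 2),
                    group = rep(c("A", "B"), each = 3))
  lr <- logrankTest(tab)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p.value, 1, tolerance = 1e-12)

  # brute-force oracle on random small tables (with ties)
  set.seed(41)
  for (i in 1:40) {
    n <- sample(6:8, 1)
    tb <- data.frame(time = sample(1:5, n, replace = TRUE),
                     event = rbinom(n, 1, 0.8),
                     group = sample(rep(c("A", "B"), length.out = n)))
    if (sum(tb$event) == 0 || length(unique(tb$group)) < 2) next
    expect_equal(logrankTest(tb)$statistic,
                 bfLogrank2(tb$time, tb$event, tb$group),
                 tolerance = 1e-10)
  }
  expect_error(logrankTest(data.frame(time = 1:4, event = 0,
                                      group = rep(c("A", "B"), 2))),
               "no events")
})

test_that("Kaplan-Meier estimates equal the brute-force product limit", {
  # no events: constant 1
  tab <- data.frame(time = 1:5, event = 0, group = "A")
  expect_true(all(kmCurve(tab)$surv == 1))

  # all events at distinct times: steps k/n
  tab2 <- data.frame(time = c(2, 5, 7, 9), event = 1, group = "A")
  expect_equal(kmCurve(tab2)$surv, c(3, 2, 1, 0) / 4)

  set.seed(43)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    tb <- data.frame(time = sample(1:6, n, replace = TRUE),
                     event = rbinom(n, 1, 0.7), group = "A")
    km <- kmCurve(tb)
    oracle <- bfKM(tb$time, tb$event)
    expect_equal(km$surv[match(oracle$time, km$time)], oracle$surv,
                 tolerance = 1e-12)
  }
  expect_error(kmCurve(tab, group = "missing"), "empty")
})

test_that("one-sided Mann-Whitney p equals enumeration for small tie-free inputs", {
  expect_equal(mannWhitneyOneSided(c(4, 5, 6), c(1, 2, 3))$p.value, 0.05)
  set.seed(47)
  for (i in 1:30) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    v <- sample(1000, nx + ny)  # distinct -> tie-free
    x <- v[1:nx]; y <- v[-(1:nx)]
    expect_equal(mannWhitneyOneSided(x, y)$p.value,
                 bfMannWhitneyGreater(x, y), tolerance = 1e-12)
  }
  # identical samples at larger n: p near 1/2 under the null
  set.seed(48)
  v <- rnorm(40)
  p <- mannWhitneyOneSided(v + rnorm(40, sd = 1e-9), v)$p.value
  expect_gt(p, 0.4); expect_lt(p, 0.6)
  # exact and approximate branches agree on tie-free n = 12
  x <- c(1, 4, 7, 10, 13, 16); y <- c(2, 5, 8, 11, 14, 17)
  pe <- mannWhitneyOneSided(x, y)$p.value
  pa <- suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                            exact = FALSE)$p.value)
  expect_lt(abs(pe - pa), 0.01)
  expect_error(mannWhitneyOneSided(numeric(0), 1:3), "nonempty")
})

test_that("BH adjustment is the step-up procedure with its invariances", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.3), 0.3)
  set.seed(51)
  p <- runif(25)
  o <- sample(25)
  expect_equal(bhAdjust(p)[o], bhAdjust(p[o]))
  expect_true(all(bhAdjust(p) >= p))
  expect_true(all(bhAdjust(p) <= 1))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("q-value thresholding controls the false discovery rate", {
  set.seed(53)
  fdr <- vapply(1:200, function(r) {
    p <- c(runif(90), rbeta(10, 0.05, 1))  # 90 nulls, 10 signals
    disc <- which(bhAdjust(p) <= 0.1)
    if (!length(disc)) return(0)
    mean(disc <= 90)
  }, numeric(1))
  expect_lte(mean(fdr), 0.1 + 0.02)
})

test_that("gene-set enrichment shares the hypergeometric kernel", {
  u <- paste0("g", 1:20)
  full <- genesetEnrichment(u[1:10], u[1:10], u)
  expect_equal(full$p.value, 1 / choose(20, 10), tolerance = 1e-10)
  expect_equal(full$p.value, 5.4123e-6, tolerance = 1e-3)
  expect_equal(full$overlap, 10L)
  disj <- genesetEnrichment(u[1:5], u[6:10], u)
  expect_equal(disj$p.value, 1)
  expect_equal(genesetEnrichment(u[1:6], u[4:12], u)$p.value,
               hypergeometricOverlapTest(3, 6, 9, 20))
  expect_error(genesetEnrichment(u[1:3], "zz", u), "subsets")
})

test_that("marker-overlap odds ratios use the Haldane-corrected sample OR", {
  u <- paste0("g", 1:30)
  # table (11=10, a-only=2, b-only=3, neither=15)
  a <- u[1:12]; b <- u[c(1:10, 13:15)]
  res <- markerOverlapOddsRatio(a, b, u)
  expect_equal(res$OR, (10 * 15) / (2 * 3))
  expect_lt(res$p.value, 1e-3)
  # identical sets: zero off-diagonal cells trigger the 0.5 correction
  same <- markerOverlapOddsRatio(u[1:8], u[1:8], u)
  expect_equal(same$OR, (8.5 * 22.5) / (0.5 * 0.5))
  expect_lt(same$p.value, 1e-6)
  # independent random sets: OR near 1 on average
  set.seed(59)
  ors <- vapply(1:200, function(r) {
    big <- paste0("h", 1:200)
    markerOverlapOddsRatio(sample(big, 50), sample(big, 50), big)$OR
  }, numeric(1))
  expect_gt(mean(log(ors)), -0.3)
  expect_lt(mean(log(ors)), 0.3)
})

test_that("ligand-receptor edges are directional and require joint significance", {
  set.seed(61)
  n <- 60; lab <- rep(1:3, each = 20)
  X <- matrix(rlnorm(5 * n, 0, 0.3), 5, n,
              dimnames = list(c("L1", "R1", "G1", "G2", "G3"),
                              paste0("s", 1:n)))
  X["L1", lab == 1] <- X["L1", lab == 1] + 10
  X["R1", lab == 2] <- X["R1", lab == 2] + 10
  st <- list(CT = stats::setNames(lab, colnames(X)))
  edges <- ligandReceptorEnrichment(list(CT = X), st,
                                    data.frame(ligand = "L1",
                                               receptor = "R1"))
  expect_equal(nrow(edges), 1L)
  expect_identical(edges$source_state, "CT_S01")
  expect_identical(edges$target_state, "CT_S02")
  # swapping the columns reverses the direction
  rev <- ligandReceptorEnrichment(list(CT = X), st,
                                  data.frame(ligand = "R1",
                                             receptor = "L1"))
  expect_identical(rev$source_state, "CT_S02")
  expect_identical(rev$target_state, "CT_S01")
  # absent genes are skipped, not fatal
  expect_message(
    none <- ligandReceptorEnrichment(list(CT = X), st,
                                     data.frame(ligand = "nope",
                                                receptor = "R1")),
    "skipped")
  expect_equal(nrow(none), 0L)
})

test_that("median split dichotomises around the median", {
  x <- stats::setNames(c(1, 2, 3, 10, 11, 12), paste0("s", 1:6))
  g <- medianSplit(x)
  expect_identical(unname(g), rep(c("low", "high"), each = 3))
})
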