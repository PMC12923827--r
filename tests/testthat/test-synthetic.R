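test_that("zero-noise profiles are an exact low-rank product with planted structure", {
  gp <- generateStateProfiles(200, 60, 3, 0, 20, seed = 7)
  X <- exprValues(gp$expr)
  expect_equal(qr(X)$rank, 3L)
  expect_identical(X, gp$W %*% gp$H)
  expect_true(all(X >= 0))
  # every sample's planted dominant coefficient has at least a 2-fold margin
  for (j in seq_len(ncol(gp$H))) {
    s <- gp$labels[j]
    expect_gte(gp$H[s, j], 2 * max(gp$H[-s, j]))
  }
  # labels are the argmax of H
  expect_equal(unname(gp$labels), unname(apply(gp$H, 2L, which.max)))
})

test_that("profile generation is seed-deterministic and guards its inputs", {
  a <- generateStateProfiles(200, 60, 3, 0.1, 20, seed = 7)
  b <- generateStateProfiles(200, 60, 3, 0.1, 20, seed = 7)
  expect_identical(exprValues(a$expr), exprValues(b$expr))
  expect_identical(a$labels, b$labels)
  c <- generateStateProfiles(200, 60, 3, 0.1, 20, seed = 8)
  expect_false(identical(exprValues(a$expr), exprValues(c$expr)))

  expect_error(generateStateProfiles(0, 60, 3, 0.1, 20), "nGenes")
  expect_error(generateStateProfiles(200, 60, 3, -0.1, 20), "noiseSd")
  expect_error(generateStateProfiles(50, 60, 3, 0.1, 20), "markerBlock")
  expect_error(generateStateProfiles(200, 5, 3, 0.1, 20), "3 \\* kStates")
  expect_error(generateStateProfiles(200, 60, 1, 0.1, 20), "kStates")
})

test_that("cohort generation enforces a disjoint ecotype partition and valid sizes", {
  es <- ecoSpecs(2)
  expect_error(generateCohort(es$celltypes, list(es$ecotypes[[1]],
                                                 es$ecotypes[[1]]),
                              50, 0, seed = 1), "disjoint")
  expect_error(generateCohort(es$celltypes,
                              list(c("Nope_S01", es$ecotypes[[2]])),
                              50, 0, seed = 1), "unknown states")
  expect_error(generateCohort(es$celltypes, es$ecotypes, 0, 0, seed = 1),
               "nSamples")
  expect_error(generateCohort(es$celltypes, es$ecotypes, 50, 0, seed = 1,
                              coocProb = 0.4), "coocProb")
})

test_that("cohort fractions are simplex rows and identifiers are consistent", {
  es <- ecoSpecs(2)
  coh <- generateCohort(es$celltypes, es$ecotypes, 80, 0.1, seed = 3)
  expect_equal(unname(rowSums(coh@fractions)), rep(1, 80), tolerance = 1e-9)
  samples <- rownames(coh@fractions)
  for (ct in names(coh@expression))
    expect_identical(colnames(exprValues(coh@expression[[ct]])), samples)
  expect_identical(names(coh@truth$sampleEcotype), samples)
})

test_that("perfect co-occurrence gives within-ecotype Jaccard exactly 1", {
  es <- ecoSpecs(2)
  coh <- generateCohort(es$celltypes, es$ecotypes, 100, 0, seed = 5,
                        coocProb = 1.0)
  # binary matrix straight from planted labels: state support = samples
  # where the state is dominant
  labs <- coh@truth$stateLabels
  for (e in 1:2) {
    members <- es$ecotypes[[e]]
    sup <- lapply(members, function(st) {
      ct <- sub("_S[0-9]+$", "", st)
      s <- as.integer(sub("^.*_S", "", st))
      which(labs[[ct]] == s)
    })
    for (i in 1:3) for (j in (i + 1):4)
      expect_equal(length(intersect(sup[[i]], sup[[j]])) /
                   length(union(sup[[i]], sup[[j]])), 1)
  }
})

test_that("survival tables follow the exponential event/censoring construction", {
  asg <- stats::setNames(rep(c("A", "B"), each = 30), sprintf("s%02d", 1:60))
  tab <- generateSurvivalTable(asg, c(A = 0.1, B = 1), 0.02, 100, seed = 3)
  expect_identical(tab, generateSurvivalTable(asg, c(A = 0.1, B = 1),
                                              0.02, 100, seed = 3))
  expect_true(all(tab$time > 0))
  expect_true(all(tab$time <= 100))
  expect_true(all(tab$event %in% c(0, 1)))
  expect_identical(tab$group, unname(asg))

  expect_error(generateSurvivalTable(asg, c(A = 0.1), 0.02, 100),
               "unknown ecotype")
  expect_error(generateSurvivalTable(asg, c(A = 0.1, B = 1), 0.02, 0),
               "positive")
  expect_error(generateSurvivalTable(asg, c(A = -1, B = 1), 0.02, 100),
               "positive")
})

test_that("single-cell fixtures have fixed depth, annotations and seed determinism", {
  gp <- generateStateProfiles(100, 20, 2, 0, 20, seed = 2, cellType = "T")
  truth <- list(basis = list(T = gp$W))
  sc <- generateSingleCellFixture(truth, cellsPerState = 6, depth = 500,
                                  seed = 9)
  expect_equal(ncol(sc$counts), 12L)
  expect_equal(unname(colSums(sc$counts)), rep(500, 12))
  expect_identical(sc$annotation$cell_type, rep("T", 12))
  expect_identical(sc$annotation$true_state, rep(c("S01", "S02"), each = 6))
  sc2 <- generateSingleCellFixture(truth, 6, 500, seed = 9)
  expect_identical(sc$counts, sc2$counts)

  expect_error(generateSingleCellFixture(truth, 1, 500), "cellsPerState")
  expect_error(generateSingleCellFixture(truth, 6, 0), "depth")
})

test_that("spatial fixtures sit on the simplex and regenerate identically", {
  es <- ecoSpecs(2)
  coh <- generateCohort(es$celltypes, es$ecotypes, 30, 0, seed = 4)
  sp <- generateSpatialFixture(coh@truth, nSpots = 25, seed = 6)
  expect_equal(unname(rowSums(sp$fractions)), rep(1, 25), tolerance = 1e-9)
  expect_true(all(sp$expr >= 0))
  sp2 <- generateSpatialFixture(coh@truth, nSpots = 25, seed = 6)
  expect_identical(sp$expr, sp2$expr)
  expect_error(generateSpatialFixture(coh@truth, 3), "nSpots")
})

test_that("noise weakly degrades average state-label recovery", {
  acc <- function(noise) {
    vals <- vapply(1:20, function(s) {
      gp <- generateStateProfiles(100, 45, 3, noise, 15, seed = 100 + s)
      fit <- EcoStates:::nmfFit(exprValues(gp$expr), 3, seed = 200 + s)
      lab <- max.col(t(fit$H), ties.method = "first")
      tab <- table(lab, gp$labels)
      sum(apply(tab, 1L, max)) / 45
    }, numeric(1))
    mean(vals)
  }
  a0 <- acc(0); a1 <- acc(0.8); a2 <- acc(2.5)
  expect_gte(a0, a1 - 1e-9)
  expect_gte(a1, a2 - 1e-9)
  expect_lt(a2, a0)  # the trend is real, not flat
})
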