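test_that("cell scoring ranks the true state's markers first", {
  genes <- paste0("g", 1:40)
  counts <- matrix(0L, 40, 3, dimnames = list(genes, paste0("c", 1:3)))
  markers <- list(T_S01 = genes[1:5], T_S02 = genes[6:10])
  counts[1:5, 1] <- 50L            # cell 1 expresses only S01 markers
  counts[6:10, 2] <- 50L           # cell 2 only S02 markers
  ann <- data.frame(barcode = paste0("c", 1:3), cell_type = "T")
  sc <- scoreCellsAgainstStates(counts, ann, markers, seed = 1)
  expect_equal(colnames(sc)[apply(sc[1:2, ], 1L, which.max)],
               c("T_S01", "T_S02"))
  expect_equal(unname(sc[3, ]), c(0, 0))   # all-zero cell scores 0

  # cells of a different cell type are not scored against the state
  ann2 <- data.frame(barcode = paste0("c", 1:3),
                     cell_type = c("T", "B", "B"))
  sc2 <- scoreCellsAgainstStates(counts, ann2, markers, seed = 1)
  expect_true(all(is.na(sc2[2:3, ])))

  # a state with too few usable markers is excluded with a warning
  mk3 <- list(T_S01 = genes[1:5], T_S02 = c("zz1", "zz2", "zz3"))
  expect_warning(sc3 <- scoreCellsAgainstStates(counts, ann, mk3, seed = 1),
                 "excluded")
  expect_true(all(is.na(sc3[, "T_S02"])))
})

test_that("single-cell argmax recovery is near-perfect on planted fixtures", {
  es <- ecoSpecs(2)
  coh <- generateCohort(es$celltypes, es$ecotypes, 30, 0, seed = 21)
  markers <- plantedMarkers(coh@truth)
  sc <- generateSingleCellFixture(coh@truth, cellsPerState = 50,
                                  depth = 2000, seed = 3)
  scores <- scoreCellsAgainstStates(sc$counts, sc$annotation, markers,
                                    seed = 4)
  pred <- colnames(scores)[apply(scores, 1L, function(r)
    which.max(replace(r, is.na(r), -Inf)))]
  truth <- paste0(sc$annotation$cell_type, "_", sc$annotation$true_state)
  expect_gte(mean(pred == truth), 0.95)
})

test_that("permutation z is reproducible and near-null for random markers", {
  set.seed(5)
  counts <- matrix(rpois(200 * 100, 3), 200, 100,
                   dimnames = list(paste0("g", 1:200), paste0("c", 1:100)))
  mk <- paste0("g", sample(200, 10))
  z1 <- permutationZ(counts, mk, nPerm = 200, seed = 9)
  expect_identical(z1, permutationZ(counts, mk, nPerm = 200, seed = 9))
  expect_error(permutationZ(counts, mk, nPerm = 50, seed = 9), "nPerm")
  expect_error(permutationZ(counts, c("g1", "g2"), nPerm = 200), "3 marker")

  # null calibration: random marker sets give approximately standard
  # normal z-scores
  zs <- vapply(1:120, function(r) {
    mkr <- paste0("g", sample(200, 10))
    permutationZ(counts, mkr, nPerm = 100, seed = 1000 + r)
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.3)
  expect_gt(stats::sd(zs), 0.7)
  expect_lt(stats::sd(zs), 1.3)
  expect_gte(mean(abs(zs) <= 3), 0.98)
})

test_that("Stouffer combination matches its closed form and invariances", {
  expect_identical(stoufferMetaZ(c(1, 1, 1, 1)), 2)
  expect_identical(stoufferMetaZ(3.7), 3.7)
  expect_identical(stoufferMetaZ(c(2, -2)), 0)
  expect_error(stoufferMetaZ(numeric(0)), "no z-scores")
  set.seed(2)
  z <- rnorm(7)
  expect_equal(stoufferMetaZ(z), stoufferMetaZ(sample(z)))
  expect_equal(stoufferMetaZ(3 * z), 3 * stoufferMetaZ(z))
  expect_warning(v <- stoufferMetaZ(c(1, NA, 1)), "dropped")
  expect_equal(v, 2 / sqrt(2))
})

test_that("spatial state recovery is one-hot times the cell-type fraction", {
  genes <- paste0("g", 1:30)
  markers <- list(A_S01 = genes[1:5], A_S02 = genes[6:10],
                  B_S01 = genes[11:15], B_S02 = genes[16:20])
  # pure spot: 100% cell type A in state S01
  expr <- matrix(0, 30, 2, dimnames = list(genes, c("sp1", "sp2")))
  expr[1:5, 1] <- 10
  expr[1:5, 2] <- 6; expr[16:20, 2] <- 4   # mixed spot
  fr <- rbind(sp1 = c(A = 1, B = 0), sp2 = c(A = 0.6, B = 0.4))
  sa <- recoverStatesSpatial(expr, fr, markers, seed = 2)
  expect_equal(unname(sa["sp1", "A_S01"]), 1)
  expect_equal(sum(sa["sp1", ]), 1)
  expect_equal(unname(sa["sp2", c("A_S01", "B_S02")]), c(0.6, 0.4))
  expect_equal(unname(rowSums(sa)), c(1, 1))  # one-hot x simplex
})

test_that("spatial ecotype maps scale their 99th percentile to exactly 1", {
  part <- c(A_S01 = 1L, B_S01 = 1L, A_S02 = 2L, B_S02 = 2L)
  # single spot, single ecotype value scales to its own percentile
  sa1 <- matrix(c(0.5, 0.5, 0, 0), 1,
                dimnames = list("sp1", names(part)))
  em1 <- recoverEcotypesSpatial(sa1, part)
  expect_equal(unname(em1$ecotypeAbundance[1, "E1"]), 1)

  set.seed(8)
  sa <- matrix(runif(50 * 4), 50, 4,
               dimnames = list(paste0("sp", 1:50), names(part)))
  em <- recoverEcotypesSpatial(sa, part)
  expect_equal(unname(stats::quantile(em$ecotypeAbundance, 0.99, type = 1)),
               1, tolerance = 1e-9)
  expect_true(all(em$ecotypeAbundance <= 1 & em$ecotypeAbundance >= 0))
  expect_error(recoverEcotypesSpatial(sa * 0, part), "all-zero")
})

test_that("planted spatial fixtures are recovered spot by spot", {
  es <- ecoSpecs(2)
  coh <- generateCohort(es$celltypes, es$ecotypes, 30, 0, seed = 4)
  markers <- plantedMarkers(coh@truth)
  sp <- generateSpatialFixture(coh@truth, nSpots = 80, seed = 6)
  sa <- recoverStatesSpatial(sp$expr, sp$fractions, markers, seed = 7)
  em <- recoverEcotypesSpatial(sa, coh@truth$ecotypePartition, sp$coords)
  dom <- max.col(em$ecotypeAbundance)
  expect_gte(mean(dom == sp$spotEcotype), 0.9)
})
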