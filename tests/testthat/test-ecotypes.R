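# Hand-built state models over an explicit shared sample set.
mkModelH <- function(H, cellType, samples) {
  k <- nrow(H)
  colnames(H) <- samples
  rownames(H) <- sprintf("S%02d", seq_len(k))
  W <- matrix(1, 4, k, dimnames = list(paste0("g", 1:4), rownames(H)))
  new("StateModel", cellType = cellType, rank = as.integer(k),
      basis = W, coefficients = H, markers = list(),
      sampleStates = stats::setNames(max.col(t(H), ties.method = "first"),
                                     samples),
      afi = numeric(), retained = logical())
}

test_that("the binary matrix one-hot encodes dominant states per cell type", {
  s <- paste0("p", 1:3)
  m <- mkModelH(rbind(c(1, 1, 0.1), c(0.1, 0.2, 1)), "A", s)
  A <- buildBinaryMatrix(list(m))
  expect_identical(unname(A@A), rbind(c(1L, 1L, 0L), c(0L, 0L, 1L)))

  m2 <- mkModelH(rbind(c(0.1, 1, 1), c(1, 0.2, 0.1)), "B", s)
  A2 <- buildBinaryMatrix(list(m, m2))
  expect_equal(unname(colSums(A2@A)), rep(2, 3))  # one 1 per cell type

  m3 <- mkModelH(rbind(c(1, 0), c(0, 1)), "C", c("q1", "q2"))
  expect_error(buildBinaryMatrix(list(m, m3)), "no samples shared")
})

test_that("removing a sample leaves other columns of A unchanged", {
  s <- paste0("p", 1:6)
  set.seed(9)
  H1 <- matrix(runif(18), 3, 6); H2 <- matrix(runif(12), 2, 6)
  mA <- mkModelH(H1, "A", s); mB <- mkModelH(H2, "B", s)
  full <- buildBinaryMatrix(list(mA, mB))@A
  mA2 <- mkModelH(H1[, -4], "A", s[-4]); mB2 <- mkModelH(H2[, -4], "B", s[-4])
  red <- suppressMessages(buildBinaryMatrix(list(mA2, mB2))@A)
  expect_identical(full[, s[-4]], red)
})

test_that("hypergeometric overlap p-values match exhaustive enumeration", {
  expect_equal(hypergeometricOverlapTest(10, 10, 10, 20),
               1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(hypergeometricOverlapTest(0, 5, 5, 100), 1.0)
  expect_equal(hypergeometricOverlapTest(3, 5, 6, 30), bfHyper(3, 5, 6, 30),
               tolerance = 1e-12)
  expect_error(hypergeometricOverlapTest(6, 5, 6, 30), "inconsistent")
  expect_error(hypergeometricOverlapTest(3, 35, 6, 30), "inconsistent")

  set.seed(17)
  for (i in 1:40) {
    N <- sample(5:30, 1)
    ni <- sample.int(N, 1); nj <- sample.int(N, 1)
    ov <- sample.int(min(ni, nj) + 1L, 1) - 1L
    expect_equal(hypergeometricOverlapTest(ov, ni, nj, N),
                 bfHyper(ov, ni, nj, N), tolerance = 1e-12)
  }
})

test_that("Jaccard co-occurrence equals brute-force set arithmetic", {
  A <- rbind(s1 = c(1, 1, 1, 0, 0), s2 = c(0, 1, 1, 1, 0))
  J <- jaccardCooccurrence(A, gate = FALSE)@J
  expect_equal(J["s1", "s2"], 0.5)   # {1,2,3} vs {2,3,4}
  expect_equal(unname(diag(J)), c(1, 1))
  A2 <- rbind(s1 = c(1, 0, 1), s2 = c(1, 0, 1))
  expect_equal(jaccardCooccurrence(A2, gate = FALSE)@J["s1", "s2"], 1)

  set.seed(23)
  for (i in 1:15) {
    A3 <- matrix(rbinom(8 * 30, 1, 0.4), 8, 30,
                 dimnames = list(paste0("st", 1:8), NULL))
    jm <- suppressWarnings(jaccardCooccurrence(A3, gate = FALSE))
    for (a in 1:7) for (b in (a + 1):8)
      expect_equal(jm@J[a, b], bfJaccard(A3[a, ], A3[b, ]))
  }
})

test_that("independent supports are overwhelmingly gated to zero", {
  set.seed(31)
  A <- matrix(rbinom(12 * 200, 1, 0.3), 12, 200,
              dimnames = list(paste0("st", 1:12), NULL))
  jm <- jaccardCooccurrence(A, alpha = 0.05)
  off <- jm@J[upper.tri(jm@J)]
  expect_gte(mean(off == 0), 0.95)
})

test_that("state clustering finds blocks, drops small clusters, renumbers by size", {
  # two perfect blocks of 4 and 5 states
  J <- diag(1, 9)
  J[1:4, 1:4] <- 1; J[5:9, 5:9] <- 1
  dimnames(J) <- list(paste0("st", 1:9), paste0("st", 1:9))
  eco <- clusterStatesIntoEcotypes(J)
  expect_equal(nEcotypes(eco), 2L)
  part <- ecotypePartition(eco)
  expect_equal(unname(part[paste0("st", 5:9)]), rep(1L, 5))  # largest is E1
  expect_equal(unname(part[paste0("st", 1:4)]), rep(2L, 4))

  # one block of 5 plus 3 isolated states: isolated clusters dropped
  J2 <- diag(1, 8)
  J2[1:5, 1:5] <- 1
  dimnames(J2) <- list(paste0("st", 1:8), paste0("st", 1:8))
  eco2 <- clusterStatesIntoEcotypes(J2)
  expect_equal(nEcotypes(eco2), 1L)
  expect_identical(names(ecotypePartition(eco2)), paste0("st", 1:5))
  expect_equal(length(eco2@rawPartition), 8L)

  # nothing survives the size filter
  J3 <- diag(1, 6)
  J3[1:3, 1:3] <- 1; J3[4:6, 4:6] <- 1
  dimnames(J3) <- list(paste0("st", 1:6), paste0("st", 1:6))
  expect_error(clusterStatesIntoEcotypes(J3), "minimum ecotype size|no ecotypes")
})

test_that("ecotype abundance averages member states and renormalises rows", {
  sa <- rbind(a1 = c(0.4, 0.1), a2 = c(0.2, 0.1),
              b1 = c(0.15, 0.0), b2 = c(0.05, 0.2))
  colnames(sa) <- c("s1", "s2")
  part <- c(a1 = 1L, a2 = 1L, b1 = 2L, b2 = 2L)
  ab <- computeEcotypeAbundance(sa, part)
  # sample s1: means (0.3, 0.1) -> normalised (0.75, 0.25)
  expect_equal(unname(ab["s1", ]), c(0.75, 0.25))
  expect_equal(unname(rowSums(ab)), c(1, 1), tolerance = 1e-9)

  saz <- sa; saz[, 2] <- 0
  expect_warning(abz <- computeEcotypeAbundance(saz, part), "all-zero")
  expect_equal(unname(abz["s2", ]), c(0.5, 0.5))
})

test_that("sample assignment follows the q-value and allocation rules", {
  states <- c(sprintf("a%d", 1:4), sprintf("b%d", 1:4))
  part <- stats::setNames(rep(1:2, each = 4L), states)
  # sample s1 strongly ecotype 1; s2 uniform (no evidence)
  sa <- cbind(s1 = c(0.9, 0.8, 0.85, 0.88, 0.01, 0.02, 0.01, 0.015),
              s2 = rep(0.25, 8))
  rownames(sa) <- states
  A <- matrix(0L, 8, 2, dimnames = list(states, c("s1", "s2")))
  A["a1", "s1"] <- 1L; A["b1", "s2"] <- 1L
  res <- assignSamplesToEcotypes(sa, part, A)
  expect_identical(unname(res$assignment["s1"]), "E1")
  expect_true(is.na(res$assignment["s2"]))   # all q-values at 1
  expect_true(all(res$q["s2", ] > 0.25))

  expect_error(assignSamplesToEcotypes(sa, stats::setNames(rep(1L, 8), states), A),
               "2 ecotypes")
})

test_that("the planted two-ecotype cohort is recovered perfectly at zero noise", {
  pp <- cachedPipeline(2, 0)
  expect_equal(nEcotypes(pp$eco$model), 2L)
  expect_equal(pp$ari, 1.0)
  expect_gte(pp$accAssigned, 0.9)
  # abundance rows on the simplex
  expect_equal(unname(rowSums(ecotypeAbundance(pp$eco$model))),
               rep(1, 300), tolerance = 1e-9)
})
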