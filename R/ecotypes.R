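#' Build the binary dominant-state assignment matrix
#'
#' Stacks the retained states of all cell types into the 0/1 matrix A
#' with states as rows and samples as columns: A[i, j] = 1 iff state i is
#' the dominant state of sample j within state i's cell type. Samples are
#' restricted to the intersection across cell types; dropped samples are
#' reported via a message.
#'
#' @param models list of filtered [StateModel-class] objects, one per
#'   cell type.
#' @return A [BinaryAssignmentMatrix-class].
#' @export
buildBinaryMatrix <- function(models) {
  stopifnot(length(models) >= 1L,
            all(vapply(models, is, logical(1), "StateModel")))
  sampleSets <- lapply(models, function(m) names(sampleStates(m)))
  common <- Reduce(intersect, sampleSets)
  if (length(common) == 0L)
    stop("no samples shared across all cell types")
  dropped <- length(unique(unlist(sampleSets))) - length(common)
  if (dropped > 0L)
    message(dropped, " sample(s) not shared across cell types were dropped")
  rows <- list(); cts <- character()
  for (m in models) {
    keep <- if (length(m@retained)) which(m@retained) else seq_len(m@rank)
    st <- sampleStates(m)[common]
    for (s in keep) {
      rows[[qualifiedStateNames(cellType(m), stateNames(m@rank)[s])]] <-
        as.integer(st == s)
      cts <- c(cts, cellType(m))
    }
  }
  A <- do.call(rbind, rows)
  colnames(A) <- common
  new("BinaryAssignmentMatrix", A = A, stateCellType = cts)
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing at least \code{nOverlap} common samples
#' between two states supported by \code{nI} and \code{nJ} samples out of
#' \code{N}, under random draws without replacement. Also used as the
#' gene-set enrichment kernel.
#'
#' @param nOverlap observed overlap size.
#' @param nI,nJ support sizes of the two sets.
#' @param N universe size.
#' @return Upper-tail p-value.
#' @examples
#' hypergeometricOverlapTest(10, 10, 10, 20)  # 1 / choose(20, 10)
#' @export
hypergeometricOverlapTest <- function(nOverlap, nI, nJ, N) {
  nOverlap <- assertCount(nOverlap, "nOverlap", min = 0L)
  nI <- assertCount(nI, "nI", min = 0L)
  nJ <- assertCount(nJ, "nJ", min = 0L)
  N <- assertCount(N, "N", min = 1L)
  if (nOverlap > min(nI, nJ) || nI > N || nJ > N)
    stop("inconsistent counts for the hypergeometric test")
  stats::phyper(nOverlap - 1L, nI, N - nI, nJ, lower.tail = FALSE)
}

#' Jaccard co-occurrence matrix with hypergeometric gating
#'
#' Computes the pairwise Jaccard index between the sample supports of all
#' states in the binary assignment matrix, tests each pairwise overlap
#' with the upper-tail hypergeometric test, BH-adjusts the p-values over
#' the strict upper triangle, and (when \code{gate} is TRUE) zeroes
#' Jaccard entries whose q-value exceeds \code{alpha} so that only
#' significant co-occurrence feeds the ecotype clustering. The diagonal
#' is kept at 1.
#'
#' @param A a [BinaryAssignmentMatrix-class] or plain 0/1 state-by-sample
#'   matrix with rownames.
#' @param alpha significance level for the gate (default 0.05).
#' @param gate zero out non-significant entries (default TRUE).
#' @return A [JaccardMatrix-class].
#' @export
jaccardCooccurrence <- function(A, alpha = 0.05, gate = TRUE) {
  if (is(A, "BinaryAssignmentMatrix")) A <- A@A
  stopifnot(is.matrix(A), all(A %in% c(0, 1)))
  ns <- nrow(A)
  if (ns < 2L) stop("at least 2 states are required")
  N <- ncol(A)
  supports <- apply(A, 1L, function(r) which(r == 1L), simplify = FALSE)
  sizes <- lengths(supports)
  if (any(sizes == 0L))
    warning("state(s) with empty sample support: ",
            paste(rownames(A)[sizes == 0L], collapse = ", "))
  J <- diag(1, ns); p <- matrix(0, ns, ns)
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    ov <- length(intersect(supports[[i]], supports[[j]]))
    un <- length(union(supports[[i]], supports[[j]]))
    J[i, j] <- J[j, i] <- if (un == 0L) 0 else ov / un
    p[i, j] <- p[j, i] <- hypergeometricOverlapTest(ov, sizes[i], sizes[j], N)
  }
  q <- matrix(0, ns, ns)
  ut <- upper.tri(q)
  q[ut] <- stats::p.adjust(p[ut], method = "BH")
  q <- q + t(q)
  if (gate) {
    off <- !diag(TRUE, ns)
    J[off & q > alpha] <- 0
  }
  dn <- list(rownames(A), rownames(A))
  dimnames(J) <- dimnames(p) <- dimnames(q) <- dn
  new("JaccardMatrix", J = J, p = p, q = q, alpha = alpha)
}

#' Cluster states into ecotypes
#'
#' Performs average-linkage hierarchical clustering on the distance
#' 1 - Jaccard, chooses the number of clusters in \code{2..kMax} that
#' maximises the mean silhouette width over the same distance, removes
#' clusters with 3 or fewer member states, and renumbers the surviving
#' ecotypes by decreasing size (E1 is the largest).
#'
#' @param J a [JaccardMatrix-class] or a symmetric state-by-state matrix.
#' @param kMax upper bound of the cluster-number search (default
#'   \code{min(20, nStates - 1)}).
#' @param minSize minimum member count for an ecotype to be kept
#'   (default 4; clusters at or below \code{minSize - 1} are removed).
#' @return An [EcotypeModel-class] with \code{partition},
#'   \code{rawPartition} and \code{nEcotypes} populated (abundance and
#'   assignment are filled by the downstream steps).
#' @export
clusterStatesIntoEcotypes <- function(J, kMax = NULL, minSize = 4L) {
  if (is(J, "JaccardMatrix")) J <- J@J
  stopifnot(is.matrix(J), isSymmetric(unname(J), tol = 1e-8))
  ns <- nrow(J)
  if (ns < 5L)
    stop("at least 5 states are required to discover ecotypes")
  if (is.null(kMax)) kMax <- min(20L, ns - 1L)
  kMax <- min(assertCount(kMax, "kMax", min = 2L), ns - 1L)
  d <- stats::as.dist(1 - J)
  hc <- stats::hclust(d, method = "average")
  ks <- 2:kMax
  sil <- vapply(ks, function(k) {
    cl <- stats::cutree(hc, k = k)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1))
  kBest <- ks[which.max(sil)]
  raw <- stats::cutree(hc, k = kBest)
  names(raw) <- rownames(J)
  sizes <- table(raw)
  keepIds <- as.integer(names(sizes)[sizes >= minSize])
  if (length(keepIds) == 0L)
    stop("all clusters fell below the minimum ecotype size; no ecotypes")
  # renumber survivors by decreasing size for stable labels
  keepIds <- keepIds[order(-sizes[as.character(keepIds)], keepIds)]
  partition <- integer(0)
  for (newId in seq_along(keepIds)) {
    members <- names(raw)[raw == keepIds[newId]]
    partition[members] <- newId
  }
  new("EcotypeModel", partition = partition, rawPartition = raw,
      nEcotypes = length(keepIds),
      abundance = matrix(numeric(0), 0, 0),
      assignment = character(0), assignmentQ = matrix(numeric(0), 0, 0))
}

#' Stack per-cell-type state abundances into one matrix
#'
#' Normalises each cell type's coefficient columns to sum to 1 (relative
#' state abundance within the cell type, making cell types comparable)
#' and stacks the retained states of all models over the shared samples.
#'
#' @param models list of filtered [StateModel-class] objects.
#' @return State-by-sample numeric matrix with qualified
#'   "<cellType>_S<k>" rownames.
#' @export
stateAbundance <- function(models) {
  common <- Reduce(intersect,
                   lapply(models, function(m) names(sampleStates(m))))
  if (length(common) == 0L) stop("no samples shared across all cell types")
  rows <- list()
  for (m in models) {
    H <- stateCoefficients(m)[, common, drop = FALSE]
    cs <- colSums(H)
    cs[cs == 0] <- 1
    H <- sweep(H, 2L, cs, "/")
    keep <- if (length(m@retained)) which(m@retained) else seq_len(m@rank)
    for (s in keep)
      rows[[qualifiedStateNames(cellType(m), stateNames(m@rank)[s])]] <-
        H[s, ]
  }
  out <- do.call(rbind, rows)
  colnames(out) <- common
  out
}

#' Per-sample ecotype abundance
#'
#' For each sample, the abundance of an ecotype is the mean abundance of
#' its member states; the resulting values are then normalised to sum to
#' 1 across ecotypes within the sample. Samples with all-zero raw
#' abundance get a uniform row with a warning.
#'
#' @param stateAbund state-by-sample abundance matrix (e.g. from
#'   [stateAbundance()]), rownames matching \code{names(partition)}.
#' @param partition named integer vector, state -> ecotype id (e.g.
#'   \code{ecotypePartition(model)}).
#' @return Sample-by-ecotype matrix with rows summing to 1, columns
#'   "E1", "E2", ...
#' @export
computeEcotypeAbundance <- function(stateAbund, partition) {
  stopifnot(is.matrix(stateAbund), length(partition) > 0L)
  if (!all(names(partition) %in% rownames(stateAbund)))
    stop("partition names missing from the state abundance matrix")
  ids <- sort(unique(partition))
  raw <- vapply(ids, function(e) {
    colMeans(stateAbund[names(partition)[partition == e], , drop = FALSE])
  }, numeric(ncol(stateAbund)))
  raw <- matrix(raw, ncol = length(ids),
                dimnames = list(colnames(stateAbund), paste0("E", ids)))
  rs <- rowSums(raw)
  if (any(rs == 0)) {
    warning(sum(rs == 0), " sample(s) with all-zero ecotype abundance; ",
            "set to uniform")
    raw[rs == 0, ] <- 1 / ncol(raw)
    rs[rs == 0] <- 1
  }
  raw / rs
}

#' Assign samples to ecotypes
#'
#' For each sample and ecotype, a two-sided Welch t-test compares the
#' abundances of the ecotype's member states against the abundances of
#' all states belonging to other ecotypes; p-values are BH-adjusted
#' across ecotypes within the sample. An ecotype is eligible when its
#' q-value is at most \code{qCut} and the sample is allocated to at least
#' one of its member states in the binary matrix A; the sample is
#' assigned to the eligible ecotype with the highest abundance, otherwise
#' left unassigned (\code{NA}).
#'
#' @param stateAbund state-by-sample abundance matrix.
#' @param partition named integer vector, state -> ecotype id.
#' @param A a [BinaryAssignmentMatrix-class] (or 0/1 matrix) with the
#'   same state rownames.
#' @param qCut q-value eligibility threshold (default 0.25).
#' @param abundance optional precomputed sample-by-ecotype abundance;
#'   computed from \code{stateAbund} when NULL.
#' @return List with \code{assignment} (named character, NA =
#'   unassigned), \code{q} (sample-by-ecotype q-value matrix) and
#'   \code{abundance}.
#' @export
assignSamplesToEcotypes <- function(stateAbund, partition, A, qCut = 0.25,
                                    abundance = NULL) {
  if (is(A, "BinaryAssignmentMatrix")) A <- A@A
  ids <- sort(unique(partition))
  if (length(ids) < 2L)
    stop("at least 2 ecotypes are required for assignment")
  memberSets <- lapply(ids, function(e) names(partition)[partition == e])
  if (any(lengths(memberSets) < 2L))
    stop("ecotype with fewer than 2 member states reached assignment; ",
         "size filtering was not applied upstream")
  if (is.null(abundance))
    abundance <- computeEcotypeAbundance(stateAbund, partition)
  samples <- colnames(stateAbund)
  allStates <- names(partition)
  pmat <- matrix(NA_real_, length(samples), length(ids),
                 dimnames = list(samples, paste0("E", ids)))
  for (j in seq_along(samples)) {
    v <- stateAbund[allStates, samples[j]]
    for (e in seq_along(ids)) {
      x <- v[memberSets[[e]]]
      y <- v[setdiff(allStates, memberSets[[e]])]
      pmat[j, e] <- tryCatch(stats::t.test(x, y)$p.value,
                             error = function(err)
                               if (abs(mean(x) - mean(y)) < 1e-12) 1 else 0)
    }
  }
  qmat <- t(apply(pmat, 1L, stats::p.adjust, method = "BH"))
  dimnames(qmat) <- dimnames(pmat)
  assignment <- stats::setNames(rep(NA_character_, length(samples)), samples)
  for (j in seq_along(samples)) {
    eligible <- which(qmat[j, ] <= qCut & vapply(memberSets, function(ms)
      any(A[ms, samples[j]] == 1), logical(1)))
    if (length(eligible))
      assignment[j] <- colnames(abundance)[
        eligible[which.max(abundance[samples[j], eligible])]]
  }
  list(assignment = assignment, q = qmat, abundance = abundance)
}

#' Discover ecotypes from fitted state models
#'
#' The full ecotype-discovery stage: build the binary dominant-state
#' matrix, compute the significance-gated Jaccard co-occurrence matrix,
#' cluster states into ecotypes, estimate per-sample ecotype abundance,
#' and assign samples to ecotypes.
#'
#' @param models list of filtered [StateModel-class] objects.
#' @param alpha Jaccard significance gate (default 0.05).
#' @param qCut assignment q-value threshold (default 0.25).
#' @param kMax,minSize see [clusterStatesIntoEcotypes()].
#' @return List with \code{model} (the completed [EcotypeModel-class]),
#'   \code{A} (the [BinaryAssignmentMatrix-class]), \code{jaccard}
#'   (the [JaccardMatrix-class]) and \code{stateAbundance}.
#' @export
discoverEcotypes <- function(models, alpha = 0.05, qCut = 0.25,
                             kMax = NULL, minSize = 4L) {
  A <- buildBinaryMatrix(models)
  jac <- jaccardCooccurrence(A, alpha = alpha)
  eco <- clusterStatesIntoEcotypes(jac, kMax = kMax, minSize = minSize)
  sa <- stateAbundance(models)
  asg <- assignSamplesToEcotypes(sa, eco@partition, A, qCut = qCut)
  eco@abundance <- asg$abundance
  eco@assignment <- asg$assignment
  eco@assignmentQ <- asg$q
  validObject(eco)
  list(model = eco, A = A, jaccard = jac, stateAbundance = sa)
}
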