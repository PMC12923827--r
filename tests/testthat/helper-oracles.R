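## Independent brute-force oracles. These deliberately avoid the code
## paths (and the stats/survival functions) used by the implementation:
## everything here is direct enumeration or naive traversal.

# Upper-tail hypergeometric by explicit enumeration of the pmf.
bfHyper <- function(nOverlap, nI, nJ, N) {
  xs <- nOverlap:min(nI, nJ)
  if (length(xs) == 0L) return(0)
  sum(vapply(xs, function(x)
    choose(nI, x) * choose(N - nI, nJ - x), numeric(1))) / choose(N, nJ)
}

# Jaccard index by direct set arithmetic on two 0/1 rows.
bfJaccard <- function(a, b) {
  ia <- which(a == 1); ib <- which(b == 1)
  u <- length(union(ia, ib))
  if (u == 0L) 0 else length(intersect(ia, ib)) / u
}

# One-sided ("greater") Mann-Whitney p by enumerating all assignments of
# the pooled tie-free values to the x positions.
bfMannWhitneyGreater <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  uStat <- function(xs, ys) sum(outer(xs, ys, ">"))
  uObs <- uStat(x, y)
  idx <- utils::combn(length(pooled), nx)
  us <- apply(idx, 2L, function(i) uStat(pooled[i], pooled[-i]))
  mean(us >= uObs)
}

# Kaplan-Meier product-limit estimate at each observed time, by direct
# product over risk sets.
bfKM <- function(time, event) {
  ut <- sort(unique(time))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    n <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  data.frame(time = ut, surv = surv)
}

# Two-group log-rank statistic: sum over event times of (O - E) and the
# hypergeometric variance, then (sum(O - E))^2 / sum(V).
bfLogrank2 <- function(time, event, group) {
  g <- sort(unique(group))
  stopifnot(length(g) == 2L)
  ut <- sort(unique(time[event == 1]))
  O1 <- E1 <- V1 <- 0
  for (t in ut) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & group == g[1L])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g[1L])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V1 <- V1 + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V1
}

# Cophenetic correlation by a naive O(n^3) average-linkage (UPGMA)
# implementation: cluster distances are means of the original pairwise
# distances over all member pairs; the cophenetic distance of a pair is
# the merge height at which they first share a cluster.
bfCophenetic <- function(consensus) {
  d <- 1 - consensus
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  cd <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      dm <- mean(d[clusters[[i]], clusters[[j]]])
      if (dm < bestD) { bestD <- dm; best <- c(i, j) }
    }
    for (a in clusters[[best[1L]]]) for (b in clusters[[best[2L]]]) {
      cd[a, b] <- cd[b, a] <- bestD
    }
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  lower <- lower.tri(d)
  stats::cor(d[lower], cd[lower])
}

# All permutations of 1..n (n small), for Hungarian-style matching by
# exhaustive search.
allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Best mean correlation between rows of recovered H and planted H over
# all state permutations; returns the matched mean correlation.
matchedRowCor <- function(Hrec, Hplant) {
  k <- nrow(Hrec)
  cc <- stats::cor(t(Hrec), t(Hplant))
  perms <- allPerms(k)
  best <- -Inf
  for (r in seq_len(nrow(perms))) {
    v <- mean(cc[cbind(seq_len(k), perms[r, ])])
    if (v > best) best <- v
  }
  best
}

# Adjusted Rand index between two labelings (direct contingency form).
bfARI <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2)); bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- ai * bj / n2
  (sumij - exp_) / ((ai + bj) / 2 - exp_)
}
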