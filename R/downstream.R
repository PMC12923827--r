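## Downstream statistics: survival stratified by state or ecotype,
## ligand-receptor enrichment between states, marker-overlap odds ratios,
## gene-set enrichment, and shared multiple-testing machinery.

.checkSurvivalTable <- function(table) {
  stopifnot(all(c("time", "event", "group") %in% colnames(table)))
  if (any(table$time <= 0)) stop("survival times must be positive")
  if (!all(table$event %in% c(0, 1))) stop("'event' must be 0/1")
  table
}

#' Log-rank test across groups
#'
#' The standard log-rank test over pooled event times; the statistic is
#' chi-squared with (number of groups - 1) degrees of freedom. For two
#' groups it equals the classical sum of (observed - expected)^2 /
#' variance over the risk sets.
#'
#' @param table data.frame with columns \code{time} (positive),
#'   \code{event} (0/1) and \code{group} (at least 2 levels, at least 1
#'   event overall).
#' @return List with \code{statistic}, \code{df} and \code{p.value}.
#' @export
logrankTest <- function(table) {
  table <- .checkSurvivalTable(table)
  if (length(unique(table$group)) < 2L)
    stop("at least 2 groups are required")
  if (sum(table$event) == 0L) stop("no events; log-rank test undefined")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = table)
  df <- length(fit$n) - 1L
  list(statistic = unname(fit$chisq), df = df,
       p.value = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Kaplan-Meier survival curve for one group
#'
#' The product-limit estimator: a non-increasing step function starting
#' at 1, evaluated at the group's observed times.
#'
#' @param table survival data.frame (see [logrankTest()]).
#' @param group the group label to estimate (NULL for the whole table).
#' @return data.frame with columns \code{time}, \code{n.risk},
#'   \code{n.event}, \code{surv}.
#' @export
kmCurve <- function(table, group = NULL) {
  table <- .checkSurvivalTable(table)
  if (!is.null(group)) {
    table <- table[table$group == group, , drop = FALSE]
    if (nrow(table) == 0L) stop("group '", group, "' is empty")
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = table)
  data.frame(time = fit$time, n.risk = fit$n.risk, n.event = fit$n.event,
             surv = fit$surv)
}

#' One-sided Mann-Whitney U test
#'
#' Exact p-value by enumeration of orderings when the combined sample
#' size is at most 12 and there are no ties; otherwise the normal
#' approximation with midranks and tie-corrected variance.
#'
#' @param x,y nonempty numeric samples.
#' @param alternative "greater" (x tends larger than y) or "less".
#' @return List with \code{U} (the statistic for \code{x}) and
#'   \code{p.value}.
#' @examples
#' mannWhitneyOneSided(c(4, 5, 6), c(1, 2, 3))$p.value  # 1/20
#' @export
mannWhitneyOneSided <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 12L && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = exact, correct = !exact))
  list(U = unname(wt$statistic), p.value = wt$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; q-values never fall below
#' their p-values and are capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return The adjusted q-values in the input order.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Ligand-receptor enrichment between cellular states
#'
#' For every state and every ligand/receptor gene, a one-sided
#' Mann-Whitney test asks whether the gene is overexpressed in the
#' samples of that state relative to all other samples of the same cell
#' type; p-values are BH-adjusted jointly over all (gene, state) tests.
#' A directed edge source -> target is emitted when the ligand is
#' significant (q <= \code{qCut}) in the source state and the receptor
#' is significant in the target state.
#'
#' @param profiles named list, cell type -> gene-by-sample expression
#'   matrix.
#' @param states named list, cell type -> named vector of per-sample
#'   dominant state labels (e.g. \code{sampleStates} of a
#'   [StateModel-class]).
#' @param pairs data.frame with columns \code{ligand} and
#'   \code{receptor}; pairs with either gene absent from every profile
#'   are skipped with a message.
#' @param qCut edge significance threshold (default 0.05).
#' @param minSamples minimum samples per state to test (default 3).
#' @return data.frame of edges with columns source_state, target_state,
#'   ligand, receptor, q_ligand, q_receptor.
#' @export
ligandReceptorEnrichment <- function(profiles, states, pairs,
                                     qCut = 0.05, minSamples = 3L) {
  stopifnot(all(c("ligand", "receptor") %in% colnames(pairs)),
            identical(names(profiles), names(states)))
  genesNeeded <- unique(c(pairs$ligand, pairs$receptor))
  tests <- list()
  for (ct in names(profiles)) {
    X <- profiles[[ct]]
    lab <- states[[ct]][colnames(X)]
    genes <- intersect(genesNeeded, rownames(X))
    for (s in sort(unique(lab))) {
      inState <- lab == s
      if (sum(inState) < minSamples || sum(!inState) < minSamples) next
      for (g in genes) {
        p <- mannWhitneyOneSided(X[g, inState], X[g, !inState],
                                 "greater")$p.value
        tests[[length(tests) + 1L]] <- data.frame(
          state = qualifiedStateNames(ct, sprintf("S%02d", s)),
          gene = g, p = p)
      }
    }
  }
  if (length(tests) == 0L) stop("no testable (gene, state) combinations")
  tests <- do.call(rbind, tests)
  tests$q <- bhAdjust(tests$p)
  qOf <- function(gene, state) {
    hit <- tests$q[tests$gene == gene & tests$state == state]
    if (length(hit)) hit else NA_real_
  }
  skipped <- 0L
  edges <- list()
  allStates <- unique(tests$state)
  for (r in seq_len(nrow(pairs))) {
    lig <- pairs$ligand[r]; rec <- pairs$receptor[r]
    if (!lig %in% tests$gene || !rec %in% tests$gene) {
      skipped <- skipped + 1L
      next
    }
    for (src in allStates) for (tgt in allStates) {
      ql <- qOf(lig, src); qr <- qOf(rec, tgt)
      if (!is.na(ql) && !is.na(qr) && ql <= qCut && qr <= qCut)
        edges[[length(edges) + 1L]] <- data.frame(
          source_state = src, target_state = tgt, ligand = lig,
          receptor = rec, q_ligand = ql, q_receptor = qr)
    }
  }
  if (skipped > 0L)
    message(skipped, " ligand-receptor pair(s) skipped (gene not profiled)")
  if (length(edges) == 0L)
    return(data.frame(source_state = character(), target_state = character(),
                      ligand = character(), receptor = character(),
                      q_ligand = numeric(), q_receptor = numeric()))
  do.call(rbind, edges)
}

#' Hypergeometric gene-set enrichment
#'
#' Tests whether a marker set is enriched in a pathway within a gene
#' universe, using the upper-tail hypergeometric test (the same kernel
#' as [hypergeometricOverlapTest()]).
#'
#' @param markers,pathway gene sets (subsets of \code{universe}).
#' @param universe the gene universe.
#' @return List with \code{p.value} and \code{overlap}.
#' @export
genesetEnrichment <- function(markers, pathway, universe) {
  if (length(universe) == 0L) stop("empty gene universe")
  markers <- unique(markers); pathway <- unique(pathway)
  universe <- unique(universe)
  if (!all(markers %in% universe) || !all(pathway %in% universe))
    stop("'markers' and 'pathway' must be subsets of 'universe'")
  ov <- length(intersect(markers, pathway))
  list(p.value = hypergeometricOverlapTest(ov, length(markers),
                                           length(pathway),
                                           length(universe)),
       overlap = ov)
}

#' Marker-overlap odds ratio with one-sided Fisher test
#'
#' Cross-tabulates two gene sets over a universe and reports the sample
#' odds ratio (with the Haldane 0.5 continuity correction when any cell
#' is zero) and the one-sided ("greater") Fisher exact p-value.
#'
#' @param setA,setB gene sets (subsets of \code{universe}).
#' @param universe the gene universe.
#' @return List with \code{OR}, \code{p.value} and \code{table} (the
#'   2x2 contingency table).
#' @export
markerOverlapOddsRatio <- function(setA, setB, universe) {
  if (length(universe) == 0L) stop("empty gene universe")
  universe <- unique(universe)
  setA <- unique(setA); setB <- unique(setB)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("both sets must be subsets of the universe")
  inA <- universe %in% setA
  inB <- universe %in% setB
  n11 <- sum(inA & inB); n10 <- sum(inA & !inB)
  n01 <- sum(!inA & inB); n00 <- sum(!inA & !inB)
  tab <- matrix(c(n11, n01, n10, n00), 2L, 2L,
                dimnames = list(inA = c("yes", "no"),
                                inB = c("yes", "no")))
  cells <- c(n11, n10, n01, n00)
  if (any(cells == 0L)) cells <- cells + 0.5
  OR <- (cells[1L] * cells[4L]) / (cells[2L] * cells[3L])
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(OR = OR, p.value = p, table = tab)
}

#' Median split of a continuous variable into high/low groups
#'
#' Dichotomises a continuous per-sample score at its median for survival
#' stratification; values above the median are "high".
#'
#' @param x named numeric vector.
#' @return Named character vector of "high"/"low" labels.
#' @export
medianSplit <- function(x) {
  stats::setNames(ifelse(x > stats::median(x), "high", "low"), names(x))
}
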