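## Readers and writers for the standard formats touched by the pipeline
## (TSV/CSV expression matrices, MTX triplets, GMT gene sets, YAML run
## configuration) plus the per-stage output writers. All tables are
## tab-separated with header rows; identifiers are opaque strings.

#' Read a gene-by-sample expression matrix
#'
#' Reads TSV/CSV (genes as row labels in the first column) or an MTX
#' triplet (matrix.mtx with features.tsv and barcodes.tsv sidecars in
#' the same directory). Duplicate gene rows are collapsed by taking the
#' per-sample maximum; negative values are rejected with the offending
#' row and column named.
#'
#' @param path file path (for \code{mtx}: the matrix.mtx file or its
#'   directory).
#' @param dialect "tsv", "csv" or "mtx".
#' @param cellType cell-type name attached to the result.
#' @return A [CellTypeExpression-class].
#' @export
readExpressionMatrix <- function(path, dialect = c("tsv", "csv", "mtx"),
                                 cellType = "CellType") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "mtx") {
    dir <- if (dir.exists(path)) path else dirname(path)
    mtx <- if (dir.exists(path)) file.path(path, "matrix.mtx") else path
    feat <- file.path(dir, "features.tsv")
    bc <- file.path(dir, "barcodes.tsv")
    if (!file.exists(feat) || !file.exists(bc))
      stop("MTX dialect requires features.tsv and barcodes.tsv sidecars")
    m <- as.matrix(Matrix::readMM(mtx))
    rownames(m) <- readLines(feat)
    colnames(m) <- readLines(bc)
  } else {
    sep <- if (dialect == "tsv") "\t" else ","
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, row.names = NULL,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("malformed header in ", path)
    genes <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric expression values in ", path)
    rownames(m) <- genes
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop(sprintf("negative value at gene '%s', sample '%s'",
                 rownames(m)[neg[1L, 1L]], colnames(m)[neg[1L, 2L]]))
  if (anyDuplicated(rownames(m))) {
    # duplicates collapse to the per-sample maximum
    m <- do.call(rbind, lapply(split.data.frame(m, rownames(m)), function(b)
      apply(b, 2L, max)))
  }
  CellTypeExpression(cellType, m)
}

#' Write a gene-by-sample matrix as TSV
#'
#' @param x a [CellTypeExpression-class] or matrix with dimnames.
#' @param path output file.
#' @param label header name of the identifier column.
#' @export
writeExpressionMatrix <- function(x, path, label = "gene") {
  if (is(x, "CellTypeExpression")) x <- exprValues(x)
  df <- data.frame(rownames(x), x, check.names = FALSE)
  colnames(df)[1L] <- label
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write gene sets in GMT format
#'
#' One line per set: name, description ("NA"), then the genes, all
#' tab-separated. Round-trips losslessly through [readGmt()].
#'
#' @param sets named list of character vectors; names must be unique and
#'   no name or gene may contain a tab.
#' @param path output file.
#' @export
writeGmt <- function(sets, path) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("set names must be present and unique")
  all <- c(names(sets), unlist(sets))
  if (any(grepl("\t", all)))
    stop("tab characters are not allowed in set or gene names")
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "NA", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (name, description, genes per line).
#' @return Named list of character vectors.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[`, character(1), 1L))
}

#' Default run configuration
#'
#' The pipeline's tunable parameters with their conventional defaults:
#' rank range 2-20, 100 NMF runs, cophenetic target 0.97, minimum 10
#' marker genes, AFI cutoff 1, Jaccard significance 0.05, ecotype
#' assignment q-value cutoff 0.25, minimum ecotype size 4, 1000
#' permutations.
#'
#' @param ... overrides of the defaults (unknown names are rejected).
#' @return A named list of parameters (class "RunConfig").
#' @export
runConfig <- function(...) {
  cfg <- list(seed = 1L, kMin = 2L, kMax = 20L, nmfRuns = 100L,
              copheneticTarget = 0.97, minMarkers = 10L, afiCut = 1.0,
              jaccardAlpha = 0.05, ecotypeQCut = 0.25,
              minEcotypeSize = 4L, perms = 1000L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "RunConfig")
}

#' Write the resolved configuration and run log alongside outputs
#'
#' Every output directory carries the resolved configuration (YAML) and
#' a log with package version, seed and per-stage timings, so that any
#' run can be reproduced exactly.
#'
#' @param dir output directory.
#' @param config a [runConfig()] list.
#' @param timings optional named numeric vector of per-stage seconds.
#' @export
writeRunLog <- function(dir, config, timings = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  lines <- c(paste0("package: EcoStates ",
                    as.character(utils::packageVersion("EcoStates"))),
             paste0("seed: ", config$seed))
  if (!is.null(timings))
    lines <- c(lines, sprintf("stage %s: %.3f s", names(timings), timings))
  writeLines(lines, file.path(dir, "run.log"))
  invisible(dir)
}

#' Write state-discovery outputs for one cell type
#'
#' Writes basis.tsv, coefficients.tsv, markers.gmt, states.tsv (sample,
#' state) and qc.tsv (per-rank cophenetic coefficients and per-state
#' AFI/retention) into a per-cell-type directory.
#'
#' @param dir output directory (created if needed).
#' @param model a fitted [StateModel-class].
#' @param cophenetics named numeric vector of per-rank cophenetic
#'   coefficients (optional).
#' @export
writeStateOutputs <- function(dir, model, cophenetics = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpressionMatrix(stateBasis(model), file.path(dir, "basis.tsv"))
  writeExpressionMatrix(stateCoefficients(model),
                        file.path(dir, "coefficients.tsv"), label = "state")
  writeGmt(stateMarkers(model), file.path(dir, "markers.gmt"))
  st <- sampleStates(model)
  utils::write.table(
    data.frame(sample = names(st), state = stateNames(model@rank)[st]),
    file.path(dir, "states.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  qc <- data.frame(metric = character(), name = character(),
                   value = numeric())
  if (!is.null(cophenetics))
    qc <- rbind(qc, data.frame(metric = "cophenetic",
                               name = names(cophenetics),
                               value = as.numeric(cophenetics)))
  qc <- rbind(qc,
              data.frame(metric = "afi", name = names(stateAFI(model)),
                         value = as.numeric(stateAFI(model))),
              data.frame(metric = "retained",
                         name = names(retainedStates(model)),
                         value = as.numeric(retainedStates(model))))
  utils::write.table(qc, file.path(dir, "qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write ecotype-discovery outputs
#'
#' Writes ecotypes.tsv (state, cell_type, ecotype), abundance.tsv,
#' assignment.tsv (sample, ecotype, min q) and jaccard.tsv.
#'
#' @param dir output directory.
#' @param eco result list from [discoverEcotypes()].
#' @export
writeEcotypeOutputs <- function(dir, eco) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- eco$model
  part <- ecotypePartition(model)
  utils::write.table(
    data.frame(state = names(part),
               cell_type = sub("_S[0-9]+$", "", names(part)),
               ecotype = paste0("E", part)),
    file.path(dir, "ecotypes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  ab <- ecotypeAbundance(model)
  writeExpressionMatrix(t(ab), file.path(dir, "abundance.tsv"),
                        label = "ecotype")
  asg <- ecotypeAssignment(model)
  qmin <- apply(model@assignmentQ, 1L, min)
  utils::write.table(
    data.frame(sample = names(asg),
               ecotype = ifelse(is.na(asg), "unassigned", asg),
               q = qmin[names(asg)]),
    file.path(dir, "assignment.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeExpressionMatrix(eco$jaccard@J, file.path(dir, "jaccard.tsv"),
                        label = "state")
  invisible(dir)
}

#' Write a synthetic cohort to disk
#'
#' Expression as one gene-by-sample TSV per cell type, fractions and
#' clinical tables as TSV, and the planted truth (labels, partition) as
#' TSVs, all under one directory.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ct in names(cohort@expression))
    writeExpressionMatrix(cohort@expression[[ct]],
                          file.path(dir, paste0("expr_", ct, ".tsv")))
  fr <- data.frame(sample_id = rownames(cohort@fractions),
                   cohort@fractions, check.names = FALSE)
  utils::write.table(fr, file.path(dir, "fractions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (nrow(cohort@clinical))
    utils::write.table(cohort@clinical, file.path(dir, "clinical.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- cohort@truth
  utils::write.table(
    data.frame(sample_id = names(tr$sampleEcotype),
               ecotype = tr$sampleEcotype),
    file.path(dir, "truth_sample_ecotype.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(state = names(tr$ecotypePartition),
               ecotype = tr$ecotypePartition),
    file.path(dir, "truth_partition.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' Simulate a cohort from a YAML scenario file
#'
#' The scenario fully specifies a cohort: cell types and their state
#' counts, ecotype member lists, sample count, noise, co-occurrence
#' probability and optional survival parameters. See the vignette for
#' the schema.
#'
#' @param scenario path to a YAML file or an equivalent named list.
#' @param seed master seed (overrides any seed in the scenario).
#' @return A [SyntheticCohort-class].
#' @export
simulateScenario <- function(scenario, seed = NULL) {
  if (is.character(scenario)) scenario <- yaml::read_yaml(scenario)
  if (is.null(seed)) seed <- scenario$seed
  if (is.null(seed)) seed <- 1L
  hazards <- scenario$hazards
  if (!is.null(hazards)) hazards <- unlist(hazards)
  generateCohort(
    celltypeSpecs = unlist(scenario$celltypes),
    ecotypeSpec = scenario$ecotypes,
    nSamples = scenario$n_samples,
    noiseSd = if (is.null(scenario$noise_sd)) 0.1 else scenario$noise_sd,
    seed = seed,
    coocProb = if (is.null(scenario$cooc_prob)) 0.9 else scenario$cooc_prob,
    nGenes = if (is.null(scenario$n_genes)) 150L else scenario$n_genes,
    markerBlock = if (is.null(scenario$marker_block)) 20L
                  else scenario$marker_block,
    hazards = hazards,
    censorRate = if (is.null(scenario$censor_rate)) 0.02
                 else scenario$censor_rate,
    horizon = if (is.null(scenario$horizon)) 100 else scenario$horizon)
}
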