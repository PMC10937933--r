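## End-to-end orchestration: annotate -> featurize -> label -> train ->
## rank -> report, from a single declarative config with one master seed.

#' Build a pipeline run configuration
#'
#' All randomness flows from \code{seed} through named substreams (folds,
#' SMOTE, permutations, simulation), so stages can be re-run independently
#' and a rerun with the same config is byte-identical.
#'
#' @param task \code{"nucleotide"} or \code{"amino-acid"}.
#' @param structures Character vector of structure file paths (PDB/mmCIF),
#'   or NULL for a simulation-only run.
#' @param sites Named list (by structure accession) of site specs: each a
#'   list with \code{chain} and \code{instances} (path to an instance TSV
#'   or a list of offset vectors). Used to label nucleotides.
#' @param simulate NULL, or a list of \code{\link{simulateFeatureTable}}
#'   arguments for a fixtures-only run.
#' @param identities Append identity one-hot blocks (structure runs only).
#' @param contact \code{contactConfig()}.
#' @param calling \code{crosslinkCallConfig()}.
#' @param cvK Cross-validation folds.
#' @param rf \code{rfConfig()}; defaults to the task's tuned values.
#' @param smote \code{smoteConfig()} (seed filled from the master seed).
#' @param permutations Label permutations for robustness ranking.
#' @param bootstrap Bootstrap models for the AUC confidence interval.
#' @param plots Emit SVG plots.
#' @param seed Master seed.
#' @return Config list for \code{\link{runPipeline}}.
#' @export
runConfig <- function(task = "nucleotide", structures = NULL, sites = NULL,
                      simulate = NULL, identities = FALSE,
                      contact = contactConfig(),
                      calling = crosslinkCallConfig(),
                      cvK = 10, rf = NULL, smote = NULL,
                      permutations = 200, bootstrap = 0, plots = TRUE,
                      seed = 1) {
  if (is.null(rf)) rf <- rfConfig(task = if (task == "nucleotide")
    "nucleotide" else "amino-acid")
  if (is.null(smote)) smote <- smoteConfig(seed = seed * 1000 + 2)
  list(task = task, structures = structures, sites = sites,
       simulate = simulate, identities = identities, contact = contact,
       calling = calling, cvK = cvK, rf = rf, smote = smote,
       permutations = permutations, bootstrap = bootstrap, plots = plots,
       seed = seed, schema = .SCHEMA_VERSION)
}

#' @keywords internal
.logStage <- function(stage, ...) {
  message(sprintf("[xlink3d] %s: %s", stage, sprintf(...)))
}

#' Run the full pipeline
#'
#' Stages: load or simulate inputs; annotate structures and tabulate
#' features; label residues from crosslink evidence; train the SMOTE-
#' balanced random forest under stratified cross-validation; rank features
#' by Gini importance, direction sign and permutation robustness; write a
#' report bundle (feature table, labels, ROC result, importance records,
#' plots, resolved config with hash) into \code{outDir}. Identical config
#' and seed give identical output bytes.
#'
#' @param config Output of \code{\link{runConfig}}.
#' @param outDir Output directory (created).
#' @return Invisible list with the in-memory results (\code{dataset},
#'   \code{roc}, \code{importance}, \code{files}).
#' @export
runPipeline <- function(config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  ## stage 1: assemble the labeled dataset
  if (!is.null(config$simulate)) {
    .logStage("input", "simulated feature table")
    simArgs <- config$simulate
    if (is.null(simArgs$seed)) simArgs$seed <- seed * 1000 + 1
    sim <- do.call(simulateFeatureTable, simArgs)
    x <- sim$x
    y <- sim$y
    featTable <- data.frame(label = ifelse(y == 1, "crosslinked",
                                           "non-crosslinked"),
                            as.data.frame(x), check.names = FALSE)
  } else {
    if (is.null(config$structures) || !length(config$structures))
      stop("stage input: no structures and no simulation spec")
    rows <- list()
    structuresRead <- list()
    for (p in config$structures) {
      s <- tryCatch(readStructure(p),
                    error = function(e) stop("stage input (", p, "): ",
                                             conditionMessage(e)))
      structuresRead[[s@accession]] <- s
      ann <- annotateInterface(s, config$contact)
      tab <- featurizeStructure(s, ann, task = config$task,
                                contactingOnly = TRUE,
                                config = config$contact)
      .logStage("featurize", "%s: %d contacting residues", s@accession,
                nrow(tab))
      ## labels from instance tables (nucleotide task)
      tab$label <- "non-crosslinked"
      spec <- config$sites[[s@accession]]
      if (!is.null(spec)) {
        offs <- spec$instances
        if (is.character(offs)) offs <- readInstanceTable(offs)
        res <- residueTable(s, kind = "ribonucleotide")
        res <- res[res$chain == spec$chain, , drop = FALSE]
        fr <- positionCrosslinkFrequency(offs, nrow(res))
        called <- callCrosslinkedPositions(fr, config = config$calling)
        xlKeys <- res$key[called$label == "crosslinked"]
        tab$label[tab$key %in% xlKeys] <- "crosslinked"
      }
      rows[[length(rows) + 1]] <- tab
    }
    featTable <- do.call(rbind, rows)
    if (isTRUE(config$identities))
      featTable <- encodeIdentities(featTable, structuresRead)
    featCols <- setdiff(names(featTable), c(.META_COLS, "label"))
    x <- as.matrix(featTable[, featCols, drop = FALSE])
    y <- as.integer(featTable$label == "crosslinked")
  }
  if (length(unique(y)) < 2)
    stop("stage label: need both crosslinked and non-crosslinked rows")

  ## stage 2: classification
  .logStage("train", "%d rows, %d features, %d positives", nrow(x),
            ncol(x), sum(y))
  roc <- crossvalAUC(x, y, method = "rf",
                     cv = cvConfig(k = config$cvK, seed = seed * 1000 + 3),
                     smote = config$smote, params = config$rf,
                     bootstrap = config$bootstrap)
  .logStage("train", "AUC %.3f", roc$auc)

  ## stage 3: importance ranking
  ## importance is ranked on the original rows (no SMOTE): interpolated
  ## synthetic points perturb impurity-based rankings
  imp <- importanceReport(x, y, params = config$rf,
                          N = config$permutations, seed = seed * 1000 + 4)

  ## stage 4: report bundle
  cfgFile <- file.path(outDir, "config.json")
  jsonlite::write_json(config[setdiff(names(config), "sites")], cfgFile,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  cfgHash <- unname(tools::md5sum(cfgFile))
  featFile <- file.path(outDir, "features.tsv")
  attr(featTable, "version") <- config$schema
  attr(featTable, "task") <- config$task
  exportFeatureTable(featTable, featFile)
  impFile <- file.path(outDir, "importance.tsv")
  utils::write.table(cbind(imp, configHash = cfgHash), impFile,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rocFile <- file.path(outDir, "roc.json")
  jsonlite::write_json(
    list(schema = config$schema, configHash = cfgHash, auc = roc$auc,
         ciLower = roc$ciLower, ciUpper = roc$ciUpper,
         foldScores = roc$foldScores),
    rocFile, auto_unbox = TRUE, digits = NA, na = "null")
  files <- c(cfgFile, featFile, impFile, rocFile)
  if (isTRUE(config$plots)) {
    rocPlot <- file.path(outDir, "roc.svg")
    plotROC(y, roc$predictions, rocPlot)
    impPlot <- file.path(outDir, "importance.svg")
    plotImportance(imp, impPlot)
    files <- c(files, rocPlot, impPlot)
  }
  .logStage("report", "bundle written to %s", outDir)
  invisible(list(dataset = list(x = x, y = y), roc = roc,
                 importance = imp, files = files))
}

#' ROC curve plot (SVG)
#'
#' @param y Binary labels.
#' @param score Predicted scores.
#' @param file Output SVG path.
#' @return \code{file}, invisibly.
#' @export
plotROC <- function(y, score, file) {
  r <- pROC::roc(response = y, predictor = score, levels = c("0", "1"),
                 direction = "<", quiet = TRUE)
  grDevices::svg(file, width = 5, height = 5)
  on.exit(grDevices::dev.off())
  graphics::plot(1 - r$specificities, r$sensitivities, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC AUC = %.3f", as.numeric(pROC::auc(r))))
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(file)
}

#' Importance scatter: Gini decrease vs permutation robustness (SVG)
#'
#' X axis: mean Gini decrease, signed by the elastic-net direction
#' (undetermined directions plotted at their unsigned value in grey);
#' y axis: permutation robustness R_s.
#'
#' @param importance Output of \code{\link{importanceReport}}.
#' @param file Output SVG path.
#' @param topLabels Number of top features to label.
#' @return \code{file}, invisibly.
#' @export
plotImportance <- function(importance, file, topLabels = 10) {
  sgn <- ifelse(is.na(importance$sign), 1,
                ifelse(importance$sign == "-", -1, 1))
  xv <- importance$meanGiniDecrease * sgn
  grDevices::svg(file, width = 6, height = 5)
  on.exit(grDevices::dev.off())
  graphics::plot(xv, importance$Rs,
                 col = ifelse(is.na(importance$sign), "grey40", "black"),
                 pch = 16, cex = 0.6,
                 xlab = "Signed mean Gini decrease",
                 ylab = expression(R[s]))
  top <- order(importance$trueRank)[seq_len(min(topLabels,
                                                nrow(importance)))]
  graphics::text(xv[top], importance$Rs[top],
                 labels = importance$feature[top], pos = 3, cex = 0.55)
  invisible(file)
}
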