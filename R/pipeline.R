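## End-to-end pipeline: input -> normalization -> z-score calls -> group
## statistics -> clinical summaries, with a machine-readable run report.

.write_df <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    path
}

#' Run the full panel analysis pipeline
#'
#' Reads a cohort (an RCC directory with a \code{samples.tsv} sidecar, a
#' count-matrix TSV plus metadata sidecar, or an in-memory
#' \code{\linkS4class{PanelCohort}}), normalizes it, computes patient
#' z-scores and calls, patients-versus-controls comparisons per detectable
#' gene and, when clinical metadata is available, correlations and
#' stratified contrasts plus the clinical cohort summary. All results are
#' written under \code{outDir} together with a JSON run report (config
#' snapshot, stage timings, detectable and reference genes, warnings, and
#' an md5 manifest of every output file).
#'
#' @param input RCC directory, count-matrix TSV path, or
#'   \code{\linkS4class{PanelCohort}}.
#' @param metadata sample-group sidecar TSV (required with a count-matrix
#'   input).
#' @param clinical optional clinical table path or \code{data.frame}.
#' @param config a \code{\link{panelConfig}} list or YAML/JSON path.
#' @param outDir output directory (created if needed).
#' @return Invisibly, the run report list.
#' @export
runPipeline <- function(input, metadata = NULL, clinical = NULL,
                        config = panelConfig(), outDir) {
    t0 <- proc.time()[["elapsed"]]
    timings <- c()
    warn_log <- character(0)
    note <- function(stage, start)
        timings[[stage]] <<- round(proc.time()[["elapsed"]] - start, 3)
    collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
        warn_log <<- c(warn_log, conditionMessage(w))
        invokeRestart("muffleWarning")
    })
    if (is.character(config)) config <- loadPanelConfig(config)

    s <- proc.time()[["elapsed"]]
    cohort <- if (is(input, "PanelCohort")) input
        else if (dir.exists(input)) readRCCDirectory(input)
        else {
            if (is.null(metadata))
                stop("pipeline stage 'input': count-matrix input needs a metadata sidecar")
            readCountMatrix(input, metadata)
        }
    if (!any(sampleGroups(cohort) == "control"))
        stop("pipeline stage 'input': no control group")
    if (!any(sampleGroups(cohort) == "patient"))
        stop("pipeline stage 'input': no patient group")
    input_checksums <- if (is.character(input) && dir.exists(input))
        as.list(tools::md5sum(sort(list.files(input, full.names = TRUE))))
    else if (is.character(input)) as.list(tools::md5sum(input))
    else list()
    note("input", s)

    clin <- NULL
    if (!is.null(clinical))
        clin <- if (is.data.frame(clinical)) clinical
                else readClinicalTable(clinical)

    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    outputs <- character(0)

    s <- proc.time()[["elapsed"]]
    norm <- collect(normalizeCohort(cohort, config))
    note("normalization", s)
    outputs <- c(outputs,
        .write_df(data.frame(gene = rownames(norm),
                             code_class = rowData(norm)$CodeClass,
                             detectable = rowData(norm)$Detectable,
                             format(as.data.frame(normalizedCounts(norm)),
                                    trim = TRUE, digits = 10),
                             check.names = FALSE),
                  file.path(outDir, "normalized_counts.tsv")))
    pv <- provenance(norm)
    gn <- pv$geNorm
    jsonlite::write_json(list(
        background = pv$background,
        positive_factors = as.list(pv$positiveFactors),
        content_factors = as.list(pv$contentFactors),
        genorm = list(m_values = as.list(mValues(gn)),
                      exclusion_order = exclusionOrder(gn),
                      v_curve = as.list(vCurve(gn)),
                      n_selected = gn@nSelected,
                      reference_genes = referenceGenes(gn)),
        detectable_genes = detectableGenes(norm),
        config = pv$config),
        file.path(outDir, "normalization_provenance.json"),
        auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, file.path(outDir, "normalization_provenance.json"))

    s <- proc.time()[["elapsed"]]
    ztab <- collect(computeZScores(norm, threshold = config$zscore_threshold,
                                   logScale = config$zscore_log_scale))
    zpaths <- writeZScoreTable(ztab, file.path(outDir, "zscores.tsv"))
    outputs <- c(outputs, zpaths)
    calls <- summarizeCalls(ztab)
    jsonlite::write_json(list(
        patients_flagged = calls$flagged_patients,
        n_flagged = calls$n_flagged,
        fraction = calls$fraction_flagged,
        multi_gene_patients = calls$multi_gene_patients,
        per_gene_calls = calls$per_gene),
        file.path(outDir, "call_summary.json"), auto_unbox = TRUE,
        digits = NA, dataframe = "rows")
    outputs <- c(outputs, file.path(outDir, "call_summary.json"))
    note("zscores", s)

    s <- proc.time()[["elapsed"]]
    cmp <- collect(compareExpressionAllGenes(norm,
        alphaNormality = config$stats_alpha_normality,
        varEqual = config$stats_var_equal))
    outputs <- c(outputs, .write_df(cmp, file.path(outDir,
                                                   "group_comparisons.tsv")))
    if (!is.null(clin)) {
        cors <- collect(correlateExpressionClinical(norm, clin,
            alphaNormality = config$stats_alpha_normality))
        outputs <- c(outputs, .write_df(cors,
            file.path(outDir, "clinical_correlations.tsv")))
        for (strat in c("onset_age_25", "bmi_class")) {
            res <- suppressMessages(collect(stratifiedComparison(norm, clin,
                stratifier = strat,
                alphaNormality = config$stats_alpha_normality,
                varEqual = config$stats_var_equal)))
            if (nrow(res))
                outputs <- c(outputs, .write_df(res,
                    file.path(outDir, paste0("stratified_", strat, ".tsv"))))
            else warn_log <- c(warn_log, attr(res, "skipped"))
        }
        patients <- clin[clin$group %in% "patient" |
                         clin$case_id %in% names(sampleGroups(cohort))[
                             sampleGroups(cohort) == "patient"], , drop = FALSE]
        cs <- cohortSummary(patients)
        jsonlite::write_json(cs, file.path(outDir, "cohort_summary.json"),
                             auto_unbox = TRUE, digits = NA,
                             dataframe = "rows")
        outputs <- c(outputs, file.path(outDir, "cohort_summary.json"))
    }
    note("statistics", s)

    report <- list(
        config = config,
        input_checksums = input_checksums,
        n_samples = ncol(cohort),
        n_controls = sum(sampleGroups(cohort) == "control"),
        n_patients = sum(sampleGroups(cohort) == "patient"),
        detectable_genes = detectableGenes(norm),
        reference_genes = referenceGenes(pv$geNorm),
        warnings = warn_log,
        stage_seconds = as.list(timings),
        total_seconds = round(proc.time()[["elapsed"]] - t0, 3),
        manifest = as.list(tools::md5sum(sort(unique(outputs)))))
    jsonlite::write_json(report, file.path(outDir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(report)
}
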