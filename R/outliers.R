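## Control-referenced z-score outlier calls: z = (x - mu) / sigma with mu and
## sigma taken from the control samples' normalized counts, calls at |z| >= 2
## (inclusive), detectable endogenous genes only.

#' Control-cohort z-score reference
#'
#' Per-gene mean and sample standard deviation (n - 1) of the control
#' samples' normalized counts, for detectable endogenous genes.
#'
#' @param norm a \code{\linkS4class{NormalizedPanel}} with at least 2
#'   control samples.
#' @param logScale compute the reference on log2 values (off by default; the
#'   z formula operates on normalized counts directly).
#' @return A \code{\linkS4class{ControlReference}}.
#' @export
controlReference <- function(norm, logScale = FALSE) {
    stopifnot(is(norm, "NormalizedPanel"))
    ctrl <- sampleGroups(norm) == "control"
    if (sum(ctrl) < 2L)
        stop("at least 2 control samples required")
    genes <- detectableGenes(norm)
    if (length(genes) == 0L)
        stop("no detectable endogenous genes")
    x <- normalizedCounts(norm)[genes, ctrl, drop = FALSE]
    if (logScale) x <- log2(x)
    mu <- rowMeans(x)
    sigma <- apply(x, 1L, sd)
    zero_sd <- names(sigma)[sigma == 0]
    if (length(zero_sd))
        stop(sprintf("control SD is zero for gene(s) %s; z-scores undefined",
                     paste(zero_sd, collapse = ", ")))
    new("ControlReference", mu = mu, sigma = sigma,
        nControls = sum(ctrl))
}

#' Patient z-scores against the control reference
#'
#' z = (x - mu) / sigma per patient and detectable gene; calls are
#' \code{high} at z >= threshold and \code{low} at z <= -threshold
#' (inclusive).
#'
#' @param norm a \code{\linkS4class{NormalizedPanel}}.
#' @param ref a \code{\linkS4class{ControlReference}} (computed from
#'   \code{norm}'s controls when omitted).
#' @param samples which columns to score: \code{"patient"} (default),
#'   \code{"control"} (self-standardization check) or \code{"all"}.
#' @param threshold absolute z call cutoff (default 2).
#' @param logScale score log2 values (must match the reference).
#' @return A \code{\linkS4class{ZScoreTable}} (genes x scored samples).
#' @export
computeZScores <- function(norm, ref = controlReference(norm, logScale),
                           samples = c("patient", "control", "all"),
                           threshold = 2, logScale = FALSE) {
    samples <- match.arg(samples)
    keep <- switch(samples,
        patient = sampleGroups(norm) == "patient",
        control = sampleGroups(norm) == "control",
        all = rep(TRUE, ncol(norm)))
    genes <- names(ref@mu)
    x <- normalizedCounts(norm)[genes, keep, drop = FALSE]
    if (logScale) x <- log2(x)
    z <- (x - ref@mu) / ref@sigma
    ZScoreTable(z, threshold = threshold)
}

#' Summarize expression calls across a cohort
#'
#' Per-patient counts of non-normal calls, the number and fraction of
#' patients with at least one call, the patients with calls in more than
#' one gene, and per-gene lists of low/high patients.
#'
#' @param table a \code{\linkS4class{ZScoreTable}}.
#' @return List with elements \code{per_patient} (named integer),
#'   \code{n_flagged}, \code{fraction_flagged}, \code{multi_gene_patients},
#'   \code{n_multi_gene}, and \code{per_gene} (data.frame: gene, low, high
#'   as comma-separated patient lists).
#' @export
summarizeCalls <- function(table) {
    stopifnot(is(table, "ZScoreTable"))
    calls <- zCalls(table)
    if (length(calls) == 0L)
        stop("empty z-score table")
    per_patient <- colSums(calls != "normal")
    flagged <- names(per_patient)[per_patient >= 1L]
    multi <- names(per_patient)[per_patient > 1L]
    per_gene <- data.frame(
        gene = rownames(calls),
        low = apply(calls, 1L, function(r)
            paste(colnames(calls)[r == "low"], collapse = ",")),
        high = apply(calls, 1L, function(r)
            paste(colnames(calls)[r == "high"], collapse = ",")),
        row.names = NULL)
    list(per_patient = per_patient,
         n_flagged = length(flagged),
         fraction_flagged = length(flagged) / ncol(calls),
         flagged_patients = flagged,
         multi_gene_patients = multi,
         n_multi_gene = length(multi),
         per_gene = per_gene)
}

#' Export / import the z-score table as TSV
#'
#' Writes two tab-separated tables with genes as rows (alphabetical) and
#' patients as columns (cohort order preserved): the z values at
#' \code{path}, and the call layer at \code{path} with its extension
#' replaced by \code{_calls.tsv}. \code{readZScoreTable} reconstructs the
#' \code{\linkS4class{ZScoreTable}} from the z file (calls re-derived at the
#' stored threshold).
#'
#' @param table a \code{\linkS4class{ZScoreTable}}.
#' @param path output TSV path for the z matrix.
#' @param threshold call threshold used when re-reading.
#' @return \code{writeZScoreTable} invisibly returns the two paths written.
#' @export
writeZScoreTable <- function(table, path) {
    stopifnot(is(table, "ZScoreTable"))
    ord <- order(rownames(table@z))
    z <- table@z[ord, , drop = FALSE]
    calls <- table@calls[ord, , drop = FALSE]
    write_mat <- function(m, p) {
        header <- paste(c("gene", colnames(m)), collapse = "\t")
        rows <- paste(rownames(m), apply(m, 1L, paste, collapse = "\t"),
                      sep = "\t")
        writeLines(c(header, rows), p)
    }
    calls_path <- paste0(tools::file_path_sans_ext(path), "_calls.tsv")
    write_mat(format(z, trim = TRUE, digits = 15), path)
    write_mat(calls, calls_path)
    invisible(c(path, calls_path))
}

#' @rdname writeZScoreTable
#' @export
readZScoreTable <- function(path, threshold = 2) {
    df <- utils::read.delim(path, check.names = FALSE)
    z <- as.matrix(df[, -1L, drop = FALSE])
    rownames(z) <- df[[1L]]
    ZScoreTable(z, threshold = threshold)
}
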