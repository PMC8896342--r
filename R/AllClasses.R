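#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData assayNames
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom stats sd
NULL

## Probe code classes of the nCounter platform handled by this package.
.PROBE_CLASSES <- c("Endogenous", "Positive", "Negative", "Housekeeping")
.SAMPLE_GROUPS <- c("control", "patient")

#' Genes of the targeted MODY expression panel
#'
#' The 19 MODY-associated genes quantified by the panel, and the 8 candidate
#' housekeeping (reference) genes included for content normalization.
#'
#' @return Character vector of gene symbols.
#' @export
#' @examples
#' modyPanelGenes()
#' housekeepingCandidates()
modyPanelGenes <- function() {
    c("ABCC8", "APPL1", "BLK", "CEL", "GCK", "GLIS3", "HADH", "HNF1A",
      "HNF1B", "HNF4A", "IER3IP1", "INS", "KCNJ11", "KLF11", "NEUROD1",
      "PAX4", "PDX1", "PLAGL1", "UCP2")
}

#' @rdname modyPanelGenes
#' @export
housekeepingCandidates <- function() {
    c("ABCF1", "ALAS1", "EEF1G", "G6PD", "GAPDH", "GUSB", "HPRT1", "TBP")
}

## ---------------------------------------------------------------------------
## RCCSample
## ---------------------------------------------------------------------------

#' Single-sample RCC record
#'
#' One nCounter-style sample: its probe table (code class, probe name,
#' accession, molecule count) plus the verbatim non-count sections of the RCC
#' file, preserved so that \code{\link{writeRCC}} can round-trip a file
#' exactly.
#'
#' @slot sampleID Sample identifier (from the Sample_Attributes ID field).
#' @slot group \code{"control"}, \code{"patient"}, or \code{NA} when the file
#'   carries no cohort assignment (groups normally come from a metadata
#'   sidecar; see \code{\link{assembleCohort}}).
#' @slot probes \code{data.frame} with columns \code{CodeClass}, \code{Name},
#'   \code{Accession}, \code{Count}, in file order.
#' @slot sections Named list of character vectors: the body lines of each RCC
#'   section in file order. The \code{Code_Summary} entry is a placeholder;
#'   its content is always regenerated from \code{probes}.
#'
#' @export
setClass("RCCSample",
    slots = c(sampleID = "character", group = "character",
              probes = "data.frame", sections = "list"))

.validRCCSample <- function(object) {
    msg <- character()
    p <- object@probes
    need <- c("CodeClass", "Name", "Accession", "Count")
    if (!all(need %in% names(p)))
        return(sprintf("probes must have columns %s", paste(need, collapse = ", ")))
    if (nrow(p) == 0L)
        msg <- c(msg, "sample contains no probes")
    if (!all(p$CodeClass %in% .PROBE_CLASSES))
        msg <- c(msg, sprintf("unsupported CodeClass: %s",
            paste(unique(setdiff(p$CodeClass, .PROBE_CLASSES)), collapse = ", ")))
    if (any(!nzchar(p$Name)))
        msg <- c(msg, "empty probe name")
    if (anyDuplicated(paste(p$CodeClass, p$Name, sep = ":")))
        msg <- c(msg, "duplicated (CodeClass, Name) pair within sample")
    if (any(is.na(p$Count)) || any(p$Count < 0) || any(p$Count != round(p$Count)))
        msg <- c(msg, "counts must be non-negative integers")
    if (sum(p$CodeClass == "Negative") < 1L)
        msg <- c(msg, "at least one Negative probe required")
    if (sum(p$CodeClass == "Positive") < 1L)
        msg <- c(msg, "at least one Positive probe required")
    if (!is.na(object@group) && !object@group %in% .SAMPLE_GROUPS)
        msg <- c(msg, sprintf("group must be one of %s",
                              paste(.SAMPLE_GROUPS, collapse = "/")))
    if (length(msg)) msg else TRUE
}
setValidity("RCCSample", .validRCCSample)

#' @describeIn RCCSample-class Construct an \code{RCCSample} from a probe
#'   table.
#' @param sampleID sample identifier.
#' @param probes probe \code{data.frame} (CodeClass, Name, Accession, Count).
#' @param group optional cohort group (\code{"control"} or \code{"patient"}).
#' @param sections optional named list of verbatim RCC section bodies.
#' @export
RCCSample <- function(sampleID, probes, group = NA_character_,
                      sections = list()) {
    probes$CodeClass <- as.character(probes$CodeClass)
    probes$Name <- as.character(probes$Name)
    probes$Accession <- as.character(probes$Accession)
    probes$Count <- as.integer(probes$Count)
    rownames(probes) <- NULL
    new("RCCSample", sampleID = as.character(sampleID),
        group = as.character(group), probes = probes, sections = sections)
}

setMethod("show", "RCCSample", function(object) {
    cat(sprintf("RCCSample '%s' (%s): %d probes (%s)\n",
        object@sampleID,
        ifelse(is.na(object@group), "group unset", object@group),
        nrow(object@probes),
        paste(sprintf("%d %s", table(factor(object@probes$CodeClass,
                                            .PROBE_CLASSES)),
                      .PROBE_CLASSES), collapse = ", ")))
})

## ---------------------------------------------------------------------------
## PanelCohort
## ---------------------------------------------------------------------------

#' Cohort of panel samples as a SummarizedExperiment
#'
#' A \code{PanelCohort} holds the raw probe-count matrix of a cohort
#' (probes x samples) with the probe code class and accession in
#' \code{rowData} and the cohort group (\code{control}/\code{patient}) in
#' \code{colData$Group}. Samples are ordered controls first, then patients.
#'
#' @export
setClass("PanelCohort", contains = "SummarizedExperiment")

.validPanelCohort <- function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        return("assay 'counts' is required")
    m <- assay(object, "counts")
    rd <- rowData(object)
    if (!all(c("CodeClass", "Accession") %in% names(rd)))
        msg <- c(msg, "rowData must contain CodeClass and Accession")
    else if (!all(rd$CodeClass %in% .PROBE_CLASSES))
        msg <- c(msg, sprintf("unsupported CodeClass: %s",
            paste(unique(setdiff(rd$CodeClass, .PROBE_CLASSES)), collapse = ", ")))
    if (!"Group" %in% names(colData(object)))
        msg <- c(msg, "colData must contain Group")
    else if (!all(colData(object)$Group %in% .SAMPLE_GROUPS))
        msg <- c(msg, "Group values must be 'control' or 'patient'")
    if (is.null(rownames(object)) || any(!nzchar(rownames(object))))
        msg <- c(msg, "probe names (rownames) required")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "unique sample identifiers (colnames) required")
    if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
        msg <- c(msg, "counts must be non-negative integers")
    if ("CodeClass" %in% names(rd) &&
        anyDuplicated(paste(rd$CodeClass, rownames(object), sep = ":")))
        msg <- c(msg, "duplicated (CodeClass, Name) probe")
    if (length(msg)) msg else TRUE
}
setValidity("PanelCohort", .validPanelCohort)

#' @describeIn PanelCohort-class Construct a \code{PanelCohort} from a count
#'   matrix.
#' @param counts integer matrix, probes x samples, with probe names as
#'   rownames and sample identifiers as colnames.
#' @param codeClass character vector (one of Endogenous, Positive, Negative,
#'   Housekeeping) per probe.
#' @param group character vector (\code{"control"}/\code{"patient"}) per
#'   sample.
#' @param accession optional transcript accession per probe.
#' @export
PanelCohort <- function(counts, codeClass, group,
                        accession = rep("", nrow(counts))) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    ord <- order(match(group, .SAMPLE_GROUPS))   # controls first, stable
    se <- SummarizedExperiment(
        assays = SimpleList(counts = counts[, ord, drop = FALSE]),
        rowData = DataFrame(CodeClass = as.character(codeClass),
                            Accession = as.character(accession)),
        colData = DataFrame(Group = as.character(group)[ord],
                            row.names = colnames(counts)[ord]))
    new("PanelCohort", se)
}

setMethod("show", "PanelCohort", function(object) {
    cat(sprintf("PanelCohort: %d probes x %d samples (%d controls, %d patients)\n",
        nrow(object), ncol(object),
        sum(colData(object)$Group == "control"),
        sum(colData(object)$Group == "patient")))
    cat("  probe classes:",
        paste(sprintf("%d %s", table(factor(rowData(object)$CodeClass,
                                            .PROBE_CLASSES)),
                      .PROBE_CLASSES), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## GeNormResult
## ---------------------------------------------------------------------------

#' geNorm reference-gene stability result
#'
#' Result of ranking candidate housekeeping genes by the geNorm expression
#' stability measure M (mean standard deviation of pairwise log2 ratios with
#' all other candidates) and of the pairwise-variation analysis that selects
#' the optimal number of reference genes.
#'
#' @slot mValues Named numeric: the M value of every candidate, computed
#'   directly on the full candidate set.
#' @slot exclusionOrder Character: genes removed during stepwise exclusion,
#'   least stable first (length \code{n - 2}).
#' @slot stabilityRank Character: all candidates from most to least stable
#'   (the final, un-rankable pair ordered lexicographically).
#' @slot vCurve Named numeric: pairwise variations V(n, n+1) for
#'   n = 2 .. (number of candidates - 1).
#' @slot nSelected Integer: smallest n with V(n, n+1) below the cutoff, or
#'   the full candidate count when the curve never drops below it.
#' @slot vCutoff Numeric: pairwise-variation cutoff used (default 0.15).
#' @slot referenceGenes Character: the \code{nSelected} most stable genes.
#'
#' @export
setClass("GeNormResult",
    slots = c(mValues = "numeric", exclusionOrder = "character",
              stabilityRank = "character", vCurve = "numeric",
              nSelected = "integer", vCutoff = "numeric",
              referenceGenes = "character"))

setMethod("show", "GeNormResult", function(object) {
    cat(sprintf("GeNormResult: %d candidates, %d selected (V cutoff %.2f)\n",
        length(object@mValues), object@nSelected, object@vCutoff))
    cat("  reference genes:", paste(object@referenceGenes, collapse = ", "), "\n")
    cat("  exclusion order (least stable first):",
        paste(object@exclusionOrder, collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## NormalizedPanel
## ---------------------------------------------------------------------------

#' Normalized panel cohort
#'
#' A \code{PanelCohort} carrying, in addition to raw counts, the fully
#' normalized expression matrix (assay \code{"normalized"}), the per-gene
#' detectability flag (\code{rowData()$Detectable}, defined for Endogenous
#' probes), and the complete normalization provenance
#' (\code{provenance(x)}): background thresholds, positive-control and
#' content factors, and the \code{\linkS4class{GeNormResult}}.
#'
#' @export
setClass("NormalizedPanel", contains = "PanelCohort")

.validNormalizedPanel <- function(object) {
    msg <- character()
    if (!"normalized" %in% assayNames(object))
        msg <- c(msg, "assay 'normalized' is required")
    else if (any(assay(object, "normalized") < 0))
        msg <- c(msg, "normalized values must be non-negative")
    if (!"Detectable" %in% names(rowData(object)))
        msg <- c(msg, "rowData must contain Detectable")
    pv <- metadata(object)$provenance
    if (is.null(pv) || !all(c("background", "positiveFactors", "geNorm",
                              "contentFactors", "config") %in% names(pv)))
        msg <- c(msg, "metadata()$provenance incomplete")
    else {
        if (any(pv$positiveFactors <= 0) || any(pv$contentFactors <= 0))
            msg <- c(msg, "normalization factors must be strictly positive")
    }
    if (length(msg)) msg else TRUE
}
setValidity("NormalizedPanel", .validNormalizedPanel)

setMethod("show", "NormalizedPanel", function(object) {
    callNextMethod()
    det <- detectableGenes(object)
    cat(sprintf("  detectable endogenous genes: %d of %d (%s)\n",
        length(det), sum(rowData(object)$CodeClass == "Endogenous"),
        paste(det, collapse = ", ")))
    cat("  reference genes:",
        paste(geNormResult(object)@referenceGenes, collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## ControlReference and ZScoreTable
## ---------------------------------------------------------------------------

#' Control-cohort reference for z-scoring
#'
#' Per-gene mean and standard deviation (sample SD, n - 1 denominator) of
#' the normalized counts of the control samples, for detectable genes only.
#'
#' @slot mu,sigma Named numerics over detectable genes.
#' @slot nControls Number of control samples used.
#' @export
setClass("ControlReference",
    slots = c(mu = "numeric", sigma = "numeric", nControls = "integer"))

setMethod("show", "ControlReference", function(object) {
    cat(sprintf("ControlReference over %d controls, %d genes\n",
        object@nControls, length(object@mu)))
})

#' Patient z-score table with expression calls
#'
#' Z-scores of patients' normalized counts against the control reference,
#' z = (x - mu) / sigma, with the categorical call \code{low} (z <= -2),
#' \code{high} (z >= 2) or \code{normal} per (gene, patient) cell.
#'
#' @slot z Numeric matrix, detectable genes x patients.
#' @slot calls Character matrix of the same shape.
#' @slot threshold Absolute z cutoff used for calls (default 2).
#' @export
setClass("ZScoreTable",
    slots = c(z = "matrix", calls = "matrix", threshold = "numeric"))

.validZScoreTable <- function(object) {
    msg <- character()
    if (!identical(dim(object@z), dim(object@calls)))
        msg <- c(msg, "z and calls must have identical shape")
    if (!all(object@calls %in% c("low", "normal", "high")))
        msg <- c(msg, "calls must be low/normal/high")
    expect <- .callFromZ(object@z, object@threshold)
    if (!identical(as.vector(object@calls), as.vector(expect)))
        msg <- c(msg, "calls inconsistent with z at the stated threshold")
    if (length(msg)) msg else TRUE
}
setValidity("ZScoreTable", .validZScoreTable)

.callFromZ <- function(z, threshold = 2) {
    out <- ifelse(z >= threshold, "high", ifelse(z <= -threshold, "low", "normal"))
    if (is.matrix(z)) dimnames(out) <- dimnames(z)
    out
}

#' @describeIn ZScoreTable-class Construct a \code{ZScoreTable} from a z
#'   matrix (genes x patients); calls are derived at the threshold.
#' @param z numeric matrix of z-scores, genes as rows, patients as columns.
#' @param threshold absolute z cutoff for calls.
#' @export
ZScoreTable <- function(z, threshold = 2) {
    z <- as.matrix(z)
    new("ZScoreTable", z = z, calls = .callFromZ(z, threshold),
        threshold = threshold)
}

setMethod("show", "ZScoreTable", function(object) {
    n_extreme <- sum(object@calls != "normal")
    cat(sprintf("ZScoreTable: %d genes x %d patients, %d calls at |z| >= %g\n",
        nrow(object@z), ncol(object@z), n_extreme, object@threshold))
})
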