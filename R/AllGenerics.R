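#' @importFrom BiocGenerics counts
NULL

#' Accessors for panel cohort objects
#'
#' \code{counts} returns the raw count matrix; \code{normalizedCounts} the
#' fully normalized matrix; \code{probeClasses} the per-probe code class;
#' \code{sampleGroups} the per-sample cohort group; \code{detectableGenes}
#' the endogenous genes whose counts rise above the negative-control
#' background; \code{provenance} the normalization provenance list;
#' \code{geNormResult} the stored \code{\linkS4class{GeNormResult}}.
#'
#' @param object a \code{\linkS4class{PanelCohort}} or
#'   \code{\linkS4class{NormalizedPanel}}.
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
setMethod("counts", "PanelCohort", function(object) assay(object, "counts"))

#' @rdname panel-accessors
#' @export
setGeneric("normalizedCounts", function(object) standardGeneric("normalizedCounts"))

#' @rdname panel-accessors
#' @export
setMethod("normalizedCounts", "NormalizedPanel",
          function(object) assay(object, "normalized"))

#' @rdname panel-accessors
#' @export
setGeneric("probeClasses", function(object) standardGeneric("probeClasses"))

#' @rdname panel-accessors
#' @export
setMethod("probeClasses", "PanelCohort", function(object) {
    stats::setNames(rowData(object)$CodeClass, rownames(object))
})

#' @rdname panel-accessors
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))

#' @rdname panel-accessors
#' @export
setMethod("sampleGroups", "PanelCohort", function(object) {
    stats::setNames(colData(object)$Group, colnames(object))
})

#' @rdname panel-accessors
#' @export
setGeneric("detectableGenes", function(object) standardGeneric("detectableGenes"))

#' @rdname panel-accessors
#' @export
setMethod("detectableGenes", "NormalizedPanel", function(object) {
    rd <- rowData(object)
    rownames(object)[rd$CodeClass == "Endogenous" & rd$Detectable %in% TRUE]
})

#' @rdname panel-accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname panel-accessors
#' @export
setMethod("provenance", "NormalizedPanel",
          function(object) metadata(object)$provenance)

#' @rdname panel-accessors
#' @export
setGeneric("geNormResult", function(object) standardGeneric("geNormResult"))

#' @rdname panel-accessors
#' @export
setMethod("geNormResult", "NormalizedPanel",
          function(object) metadata(object)$provenance$geNorm)

#' Accessors for GeNormResult and ZScoreTable
#'
#' @param object a \code{\linkS4class{GeNormResult}} or
#'   \code{\linkS4class{ZScoreTable}}.
#' @name result-accessors
NULL

#' @rdname result-accessors
#' @export
setGeneric("mValues", function(object) standardGeneric("mValues"))
#' @rdname result-accessors
#' @export
setMethod("mValues", "GeNormResult", function(object) object@mValues)

#' @rdname result-accessors
#' @export
setGeneric("exclusionOrder", function(object) standardGeneric("exclusionOrder"))
#' @rdname result-accessors
#' @export
setMethod("exclusionOrder", "GeNormResult", function(object) object@exclusionOrder)

#' @rdname result-accessors
#' @export
setGeneric("vCurve", function(object) standardGeneric("vCurve"))
#' @rdname result-accessors
#' @export
setMethod("vCurve", "GeNormResult", function(object) object@vCurve)

#' @rdname result-accessors
#' @export
setGeneric("referenceGenes", function(object) standardGeneric("referenceGenes"))
#' @rdname result-accessors
#' @export
setMethod("referenceGenes", "GeNormResult", function(object) object@referenceGenes)

#' @rdname result-accessors
#' @export
setGeneric("zScores", function(object) standardGeneric("zScores"))
#' @rdname result-accessors
#' @export
setMethod("zScores", "ZScoreTable", function(object) object@z)

#' @rdname result-accessors
#' @export
setGeneric("zCalls", function(object) standardGeneric("zCalls"))
#' @rdname result-accessors
#' @export
setMethod("zCalls", "ZScoreTable", function(object) object@calls)
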