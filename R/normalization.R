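## Three-stage normalization of a panel cohort:
##   1. negative-control background thresholding (mean + k*SD per sample),
##      driving a detectability mask over the endogenous genes;
##   2. positive-control technical normalization, correcting per-lane
##      hybridization efficiency;
##   3. content normalization by the geometric mean of geNorm-selected
##      reference genes, correcting RNA input amount.
## Background counts are never subtracted: the threshold gates detectability,
## and below-threshold values of genes entering log-ratio computations are
## floored at the sample threshold to protect geometric means.

.geomean <- function(x) exp(mean(log(x)))

#' Default pipeline configuration
#'
#' Tunable parameters of the normalization and calling pipeline, with their
#' defaults: background threshold multiplier \code{background_k_sd} (mean +
#' k SD of the negative probes, k = 2), detectability fraction
#' \code{detect_min_fraction} (a gene must exceed its sample's threshold in
#' at least this fraction of all samples, 0.5), geNorm pairwise-variation
#' cutoff \code{genorm_v_cutoff} (0.15, the algorithm's canonical
#' recommendation) and minimum reference count \code{genorm_min_genes} (2),
#' the z-score call threshold \code{zscore_threshold} (2) and log-scale
#' toggle \code{zscore_log_scale} (off: z is computed on normalized counts
#' directly), and the statistics gates \code{stats_alpha_normality}
#' (Shapiro-Wilk level 0.05) and \code{stats_var_equal} (Student rather than
#' Welch t).
#'
#' @param ... overrides of the defaults listed above.
#' @return Named list of configuration values.
#' @export
#' @examples
#' panelConfig(detect_min_fraction = 0.75)
panelConfig <- function(...) {
    cfg <- list(background_k_sd = 2, detect_min_fraction = 0.5,
                genorm_v_cutoff = 0.15, genorm_min_genes = 2L,
                zscore_threshold = 2, zscore_log_scale = FALSE,
                stats_alpha_normality = 0.05, stats_var_equal = TRUE)
    dots <- list(...)
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
        stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
    cfg[names(dots)] <- dots
    cfg
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path a YAML (\code{.yml}/\code{.yaml}) or JSON file whose keys are
#'   a subset of \code{\link{panelConfig}}'s.
#' @return Named configuration list.
#' @export
loadPanelConfig <- function(path) {
    vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
        yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
    do.call(panelConfig, as.list(vals))
}

#' Negative-control background threshold
#'
#' The background threshold of one sample: mean + k standard deviations
#' (sample SD, n - 1) of its negative-control probe counts.
#'
#' @param negCounts numeric vector of negative-probe counts of one sample
#'   (at least 2).
#' @param kSD standard-deviation multiplier (default 2).
#' @return Threshold in counts.
#' @export
#' @examples
#' backgroundThreshold(c(10, 12, 14, 12, 12))  # 12 + 2 * 1.414
backgroundThreshold <- function(negCounts, kSD = 2) {
    if (length(negCounts) < 2L)
        stop("at least 2 negative probes required (SD undefined)")
    s <- sd(negCounts)
    if (s == 0)
        warning("zero variance among negative probes; threshold equals their mean")
    mean(negCounts) + kSD * s
}

#' Per-sample background thresholds of a cohort
#'
#' @param cohort a \code{\linkS4class{PanelCohort}}.
#' @param kSD standard-deviation multiplier.
#' @return Named numeric vector, one threshold per sample.
#' @export
backgroundThresholds <- function(cohort, kSD = 2) {
    neg <- counts(cohort)[rowData(cohort)$CodeClass == "Negative", , drop = FALSE]
    if (nrow(neg) < 2L)
        stop("at least 2 negative probes required (SD undefined)")
    apply(neg, 2L, backgroundThreshold, kSD = kSD)
}

#' Endogenous-gene detectability mask
#'
#' An endogenous gene is detectable when its raw count strictly exceeds its
#' sample's background threshold in at least \code{minFraction} of all
#' samples. Non-detectable genes are excluded from z-scores and group
#' statistics downstream.
#'
#' @param cohort a \code{\linkS4class{PanelCohort}}.
#' @param thresholds named per-sample thresholds, as from
#'   \code{\link{backgroundThresholds}}.
#' @param minFraction minimum fraction of samples above threshold (0.5).
#' @return Named logical vector over the endogenous genes.
#' @export
detectabilityMask <- function(cohort, thresholds = backgroundThresholds(cohort),
                              minFraction = 0.5) {
    endo <- counts(cohort)[rowData(cohort)$CodeClass == "Endogenous", ,
                           drop = FALSE]
    thresholds <- thresholds[colnames(endo)]
    above <- sweep(endo, 2L, thresholds, FUN = ">")
    rowMeans(above) >= minFraction
}

#' Positive-control normalization factors
#'
#' Corrects per-lane hybridization efficiency. With \eqn{G_s} the geometric
#' mean of sample s's positive-control counts, the factor is
#' \eqn{f_s = \bar{G} / G_s} (arithmetic mean of the geometric means over
#' samples); all counts of sample s are multiplied by \eqn{f_s}.
#'
#' @param cohort a \code{\linkS4class{PanelCohort}} with at least 2 positive
#'   probes per sample, all counts positive.
#' @return Named numeric vector of factors, one per sample.
#' @export
positiveFactors <- function(cohort) {
    pos <- counts(cohort)[rowData(cohort)$CodeClass == "Positive", ,
                          drop = FALSE]
    if (nrow(pos) < 2L)
        stop("at least 2 positive probes required")
    if (any(pos == 0))
        stop(sprintf("zero positive-control count in sample(s): %s",
             paste(colnames(pos)[colSums(pos == 0) > 0], collapse = ", ")))
    g <- apply(pos, 2L, .geomean)
    mean(g) / g
}

#' geNorm reference-gene ranking and selection
#'
#' Ranks candidate reference genes by the geNorm stability measure and picks
#' the optimal number by pairwise variation. For candidates j, k the
#' pairwise variation \eqn{V_{jk}} is the standard deviation over samples of
#' \eqn{\log_2(x_j / x_k)}; the stability \eqn{M_j} is the mean of
#' \eqn{V_{jk}} over all other candidates. The least stable gene (highest M,
#' ties broken lexicographically by name) is removed and M recomputed until
#' two genes remain. The pairwise variation V(n, n+1) is the SD over samples
#' of \eqn{\log_2(NF_n / NF_{n+1})}, where \eqn{NF_n} is the per-sample
#' geometric mean of the n most stable genes; the selected number of
#' reference genes is the smallest n with V(n, n+1) below \code{vCutoff},
#' or all candidates if the curve never drops below it.
#'
#' @param hkMatrix numeric matrix, housekeeping genes x samples, positive
#'   values (typically positive-control-normalized counts), at least 3
#'   genes.
#' @param vCutoff pairwise-variation cutoff (default 0.15).
#' @param minGenes minimum number of reference genes (default 2).
#' @return A \code{\linkS4class{GeNormResult}}.
#' @export
geNormRank <- function(hkMatrix, vCutoff = 0.15, minGenes = 2L) {
    hkMatrix <- as.matrix(hkMatrix)
    if (nrow(hkMatrix) < 3L)
        stop("geNorm requires at least 3 candidate housekeeping genes")
    if (any(hkMatrix <= 0))
        stop("geNorm requires strictly positive values (zero count present)")
    if (is.null(rownames(hkMatrix)))
        rownames(hkMatrix) <- paste0("HK", seq_len(nrow(hkMatrix)))
    lg <- log2(hkMatrix)

    m_of <- function(lgm) {
        genes <- rownames(lgm)
        vapply(genes, function(j) {
            others <- setdiff(genes, j)
            mean(vapply(others, function(k)
                sd(lgm[j, ] - lgm[k, ]), numeric(1)))
        }, numeric(1))
    }

    m_full <- m_of(lg)
    remaining <- lg
    excluded <- character(0)
    while (nrow(remaining) > 2L) {
        m <- m_of(remaining)
        worst <- names(m)[order(-m, names(m))][1L]
        excluded <- c(excluded, worst)
        remaining <- remaining[setdiff(rownames(remaining), worst), , drop = FALSE]
    }
    final_pair <- sort(rownames(remaining))
    rank <- c(final_pair, rev(excluded))   # most to least stable

    n_hk <- nrow(lg)
    v <- numeric(0)
    for (n in 2:(n_hk - 1L)) {
        nf_n  <- colMeans(lg[rank[seq_len(n)], , drop = FALSE])
        nf_n1 <- colMeans(lg[rank[seq_len(n + 1L)], , drop = FALSE])
        v <- c(v, sd(nf_n - nf_n1))
    }
    names(v) <- sprintf("V%d.%d", 2:(n_hk - 1L), 3:n_hk)

    ok <- which(v < vCutoff & (2:(n_hk - 1L)) >= minGenes)
    n_selected <- if (length(ok)) (2:(n_hk - 1L))[ok[1L]] else n_hk
    n_selected <- max(n_selected, minGenes)

    new("GeNormResult", mValues = m_full, exclusionOrder = excluded,
        stabilityRank = rank, vCurve = v, nSelected = as.integer(n_selected),
        vCutoff = vCutoff, referenceGenes = rank[seq_len(n_selected)])
}

#' Content (RNA input) normalization factors
#'
#' With \eqn{H_s} the geometric mean of sample s's reference-gene values,
#' the factor is \eqn{\bar{H} / H_s}, applied multiplicatively to all genes.
#' After application, the per-sample geometric means of the reference genes
#' are equal across samples.
#'
#' @param values numeric matrix, genes x samples (positive-control
#'   normalized), containing the reference genes as rows.
#' @param referenceGenes character vector of selected reference genes.
#' @return Named numeric vector of factors, one per sample.
#' @export
contentFactors <- function(values, referenceGenes) {
    missing_ref <- setdiff(referenceGenes, rownames(values))
    if (length(missing_ref))
        stop(sprintf("reference gene(s) absent from matrix: %s",
                     paste(missing_ref, collapse = ", ")))
    ref <- values[referenceGenes, , drop = FALSE]
    if (any(ref <= 0))
        stop("zero reference-gene value; content factors undefined")
    h <- apply(ref, 2L, .geomean)
    mean(h) / h
}

#' Full cohort normalization
#'
#' Chains the pipeline stages: per-sample background thresholds,
#' endogenous-gene detectability, positive-control factors, geNorm
#' reference-gene selection on the housekeeping candidates, and content
#' factors. Background counts are not subtracted; after positive-control
#' scaling, values of housekeeping and detectable endogenous genes that fall
#' below the (equally scaled) sample threshold are floored at it before any
#' log-ratio computation. Full provenance is recorded in the result.
#'
#' @param cohort a \code{\linkS4class{PanelCohort}} containing all four
#'   probe classes.
#' @param config a \code{\link{panelConfig}} list.
#' @return A \code{\linkS4class{NormalizedPanel}}.
#' @export
normalizeCohort <- function(cohort, config = panelConfig()) {
    stopifnot(is(cohort, "PanelCohort"))
    cls <- rowData(cohort)$CodeClass
    for (needed in .PROBE_CLASSES)
        if (!needed %in% cls)
            stop(sprintf("normalization stage 'input': no %s probes in cohort",
                         needed))
    bg <- withCallingHandlers(
        backgroundThresholds(cohort, kSD = config$background_k_sd),
        error = function(e) stop(sprintf("normalization stage 'background': %s",
                                         conditionMessage(e)), call. = FALSE))
    mask <- detectabilityMask(cohort, bg,
                              minFraction = config$detect_min_fraction)
    pf <- tryCatch(positiveFactors(cohort),
        error = function(e) stop(sprintf("normalization stage 'positive': %s",
                                         conditionMessage(e)), call. = FALSE))
    values <- sweep(counts(cohort) + 0.0, 2L, pf, `*`)

    ## floor below-threshold values of genes used in log-ratio computations
    floor_at <- bg * pf
    floor_rows <- rownames(cohort)[cls == "Housekeeping" |
        (cls == "Endogenous" & rownames(cohort) %in% names(mask)[mask])]
    values[floor_rows, ] <- pmax(values[floor_rows, , drop = FALSE],
                                 matrix(floor_at, nrow = length(floor_rows),
                                        ncol = ncol(values), byrow = TRUE))

    hk <- values[cls == "Housekeeping", , drop = FALSE]
    gn <- tryCatch(
        geNormRank(hk, vCutoff = config$genorm_v_cutoff,
                   minGenes = config$genorm_min_genes),
        error = function(e) stop(sprintf("normalization stage 'genorm': %s",
                                         conditionMessage(e)), call. = FALSE))
    cf <- tryCatch(contentFactors(values, referenceGenes(gn)),
        error = function(e) stop(sprintf("normalization stage 'content': %s",
                                         conditionMessage(e)), call. = FALSE))
    values <- sweep(values, 2L, cf, `*`)

    rd <- rowData(cohort)
    rd$Detectable <- ifelse(rd$CodeClass == "Endogenous",
                            unname(mask[rownames(cohort)]), NA)
    se <- SummarizedExperiment(
        assays = SimpleList(counts = counts(cohort), normalized = values),
        rowData = rd, colData = colData(cohort),
        metadata = list(provenance = list(
            background = list(thresholds = bg, k_sd = config$background_k_sd),
            positiveFactors = pf, geNorm = gn, contentFactors = cf,
            config = config)))
    new("NormalizedPanel", se)
}
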