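## Shared fixture builders and independent oracles.

suppressPackageStartupMessages({
    library(SummarizedExperiment)
})

## A small valid cohort built directly from a count matrix.
makeCohort <- function(counts, codeClass, group, accession = NULL) {
    if (is.null(accession)) accession <- rep("", nrow(counts))
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("S%d", seq_len(ncol(counts)))
    PanelCohort(counts, codeClass = codeClass, group = group,
                accession = accession)
}

## Random valid cohort for round-trip property tests.
randomCohort <- function(nEndo = 5, nSamples = 4, seed = 1) {
    set.seed(seed)
    genes <- c(sprintf("POS_%s", LETTERS[1:3]), sprintf("NEG_%s", LETTERS[1:3]),
               sprintf("HK%d", 1:3), sprintf("GENE%d", seq_len(nEndo)))
    cls <- rep(c("Positive", "Negative", "Housekeeping", "Endogenous"),
               c(3, 3, 3, nEndo))
    n <- length(genes)
    m <- matrix(rpois(n * nSamples, lambda = 200), nrow = n,
                dimnames = list(genes,
                                sprintf("S%d", seq_len(nSamples))))
    grp <- rep(c("control", "patient"), length.out = nSamples)
    makeCohort(m, cls, grp, accession = sprintf("NM_%06d", seq_len(n)))
}

## A NormalizedPanel with prescribed normalized values, bypassing the
## normalization stages: used to unit-test the z-score layer in isolation.
makeNormalizedPanel <- function(values, group,
                                detectable = rep(TRUE, nrow(values))) {
    values <- as.matrix(values)
    raw <- round(values)
    storage.mode(raw) <- "integer"
    gn <- new("GeNormResult", mValues = c(HKa = 0.1, HKb = 0.1),
              exclusionOrder = character(0), stabilityRank = c("HKa", "HKb"),
              vCurve = numeric(0), nSelected = 2L, vCutoff = 0.15,
              referenceGenes = c("HKa", "HKb"))
    se <- SummarizedExperiment(
        assays = S4Vectors::SimpleList(counts = raw, normalized = values),
        rowData = S4Vectors::DataFrame(
            CodeClass = rep("Endogenous", nrow(values)),
            Accession = rep("", nrow(values)),
            Detectable = detectable),
        colData = S4Vectors::DataFrame(Group = group,
                                       row.names = colnames(values)),
        metadata = list(provenance = list(
            background = list(thresholds = numeric(0), k_sd = 2),
            positiveFactors = rep(1, ncol(values)),
            geNorm = gn, contentFactors = rep(1, ncol(values)),
            config = panelConfig())))
    new("NormalizedPanel", se)
}

## ---------------------------------------------------------------------------
## Independent geNorm oracle: literal double-loop evaluation of the M
## definition, stepwise exclusion, and the pairwise-variation curve.
## ---------------------------------------------------------------------------

oracleM <- function(mat) {
    lg <- log2(mat)
    genes <- rownames(mat)
    m <- numeric(length(genes))
    names(m) <- genes
    for (j in genes) {
        vs <- c()
        for (k in genes) {
            if (k == j) next
            ratios <- c()
            for (s in seq_len(ncol(mat)))
                ratios <- c(ratios, lg[j, s] - lg[k, s])
            vs <- c(vs, sd(ratios))
        }
        m[j] <- sum(vs) / length(vs)
    }
    m
}

oracleExclusion <- function(mat) {
    out <- character(0)
    cur <- mat
    while (nrow(cur) > 2) {
        m <- oracleM(cur)
        worst_val <- max(m)
        cand <- sort(names(m)[m == worst_val])[1]
        out <- c(out, cand)
        cur <- cur[rownames(cur) != cand, , drop = FALSE]
    }
    out
}

oracleVCurve <- function(mat, rank) {
    lg <- log2(mat)
    n_hk <- nrow(mat)
    v <- c()
    for (n in 2:(n_hk - 1)) {
        nf_a <- nf_b <- numeric(ncol(mat))
        for (s in seq_len(ncol(mat))) {
            nf_a[s] <- mean(lg[rank[1:n], s])
            nf_b[s] <- mean(lg[rank[1:(n + 1)], s])
        }
        v <- c(v, sd(nf_a - nf_b))
    }
    v
}

## Independent gate oracle for the two-group test choice.
oracleTestChoice <- function(x, y, alpha = 0.05) {
    normal <- function(v) length(unique(v)) > 1 &&
        stats::shapiro.test(v)$p.value >= alpha
    if (normal(x) && normal(y)) "t_test" else "mann_whitney"
}

clinicalFixturePath <- function() {
    system.file("extdata", "mody_cohort_clinical.tsv", package = "MODYexpress")
}

reportedCallsPath <- function() {
    system.file("extdata", "reported_zscore_calls.tsv", package = "MODYexpress")
}
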