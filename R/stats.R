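## Normality-gated inference: Shapiro-Wilk per group decides between the
## unpaired Student t-test and the Mann-Whitney U-test; Pearson vs Spearman
## for correlations with clinical variables; stratified contrasts by age at
## onset (cutoff 25 years) and WHO BMI class.

#' @importFrom stats shapiro.test t.test wilcox.test cor.test setNames
NULL

.passes_normality <- function(v, alpha) {
    ## constant vectors cannot be tested and are treated as non-normal
    if (length(unique(v)) < 2L) return(FALSE)
    shapiro.test(v)$p.value >= alpha
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk is applied to each group at \code{alphaNormality}; when both
#' groups pass, an unpaired two-sided Student t-test (equal variances by
#' default) compares means, otherwise a two-sided Mann-Whitney U-test
#' compares distributions (exact for small untied samples, normal
#' approximation with tie correction otherwise). Direction is reported when
#' p < 0.05.
#'
#' @param x,y numeric vectors, each of length >= 3.
#' @param alphaNormality Shapiro-Wilk level for the gate (default 0.05).
#' @param varEqual use Student's pooled-variance t (default); \code{FALSE}
#'   gives Welch.
#' @param labels group labels for the direction field.
#' @return One-row \code{data.frame}: \code{test_used}, \code{statistic},
#'   \code{p_value}, \code{direction}, \code{n1}, \code{n2}.
#' @export
#' @examples
#' compareGroups(rnorm(8), rnorm(19, mean = 3))
compareGroups <- function(x, y, alphaNormality = 0.05, varEqual = TRUE,
                          labels = c("group1", "group2")) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 3L || length(y) < 3L)
        stop("each group must have at least 3 observations")
    gate <- .passes_normality(x, alphaNormality) &&
            .passes_normality(y, alphaNormality)
    if (gate) {
        fit <- t.test(x, y, var.equal = varEqual)
        test_used <- "t_test"
        higher <- mean(x) > mean(y)
    } else {
        fit <- suppressWarnings(wilcox.test(x, y))
        test_used <- "mann_whitney"
        higher <- median(x) > median(y)
    }
    p <- fit$p.value
    direction <- if (p < 0.05 && mean(x) != mean(y))
        ifelse(higher, paste0(labels[1L], "_higher"), paste0(labels[2L], "_higher"))
    else "none"
    data.frame(test_used = test_used,
               statistic = unname(fit$statistic),
               p_value = p, direction = direction,
               n1 = length(x), n2 = length(y))
}

#' Patients-versus-controls comparison for every detectable gene
#'
#' Applies \code{\link{compareGroups}} to the normalized counts of each
#' detectable endogenous gene, patients versus controls, with no
#' multiple-testing adjustment.
#'
#' @param norm a \code{\linkS4class{NormalizedPanel}}.
#' @param alphaNormality Shapiro-Wilk gate level.
#' @param varEqual Student (TRUE) or Welch (FALSE) t-test variant.
#' @return \code{data.frame}, one row per detectable gene, with the
#'   \code{\link{compareGroups}} columns; direction labels are
#'   \code{patients_higher} / \code{controls_higher}.
#' @export
compareExpressionAllGenes <- function(norm, alphaNormality = 0.05,
                                      varEqual = TRUE) {
    genes <- detectableGenes(norm)
    grp <- sampleGroups(norm)
    vals <- normalizedCounts(norm)
    out <- do.call(rbind, lapply(genes, function(g) {
        res <- compareGroups(vals[g, grp == "patient"],
                             vals[g, grp == "control"],
                             alphaNormality = alphaNormality,
                             varEqual = varEqual,
                             labels = c("patients", "controls"))
        cbind(gene = g, res)
    }))
    rownames(out) <- NULL
    out
}

#' Correlation of gene expression with clinical variables
#'
#' For each detectable gene and clinical variable, correlates patients'
#' normalized counts with the variable over pairwise-complete observations.
#' Pearson's coefficient is used when both variables pass the Shapiro-Wilk
#' gate, Spearman's rank correlation otherwise. Pairs with fewer than 4
#' complete observations are skipped with a recorded reason.
#'
#' @param norm a \code{\linkS4class{NormalizedPanel}}.
#' @param clinical clinical \code{data.frame} with \code{case_id} matching
#'   patient sample identifiers.
#' @param variables clinical columns to correlate.
#' @param alphaNormality Shapiro-Wilk gate level.
#' @return \code{data.frame}: gene, variable, method, n, coefficient,
#'   p_value (NA rows carry the skip reason in \code{note}).
#' @export
correlateExpressionClinical <- function(norm, clinical,
        variables = c("fasting_glucose_mg_dl", "hba1c_pct", "c_peptide_ng_ml"),
        alphaNormality = 0.05) {
    genes <- detectableGenes(norm)
    grp <- sampleGroups(norm)
    patients <- names(grp)[grp == "patient"]
    vals <- normalizedCounts(norm)[, patients, drop = FALSE]
    clin <- clinical[match(patients, clinical$case_id), , drop = FALSE]
    rows <- list()
    for (g in genes) for (v in variables) {
        if (!v %in% names(clin)) next
        e <- vals[g, ]
        c_v <- clin[[v]]
        ok <- !is.na(e) & !is.na(c_v)
        if (sum(ok) < 4L) {
            rows[[length(rows) + 1L]] <- data.frame(
                gene = g, variable = v, method = NA_character_,
                n = sum(ok), coefficient = NA_real_, p_value = NA_real_,
                note = "skipped: fewer than 4 complete pairs")
            next
        }
        gate <- .passes_normality(e[ok], alphaNormality) &&
                .passes_normality(c_v[ok], alphaNormality)
        method <- if (gate) "pearson" else "spearman"
        fit <- suppressWarnings(cor.test(e[ok], c_v[ok], method = method))
        rows[[length(rows) + 1L]] <- data.frame(
            gene = g, variable = v, method = method, n = sum(ok),
            coefficient = unname(fit$estimate), p_value = fit$p.value,
            note = "")
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Stratified within-patient comparisons
#'
#' Splits the patients by age at diabetes onset (young onset at or below 25
#' years versus later onset) or by WHO BMI class (obese versus normal
#' weight; overweight patients are counted but not part of the contrast)
#' and applies \code{\link{compareGroups}} per detectable gene. Strata with
#' fewer than 3 patients skip the contrast with a message.
#'
#' @param norm a \code{\linkS4class{NormalizedPanel}}.
#' @param clinical clinical \code{data.frame} with \code{case_id},
#'   \code{onset_age_years}, \code{bmi_kg_m2}.
#' @param stratifier \code{"onset_age_25"} or \code{"bmi_class"}.
#' @param alphaNormality Shapiro-Wilk gate level.
#' @param varEqual t-test variant.
#' @return \code{data.frame} of per-gene comparisons (zero rows when a
#'   stratum is too small; the skip reason is in \code{attr(., "skipped")}).
#' @export
stratifiedComparison <- function(norm, clinical,
                                 stratifier = c("onset_age_25", "bmi_class"),
                                 alphaNormality = 0.05, varEqual = TRUE) {
    stratifier <- match.arg(stratifier)
    grp <- sampleGroups(norm)
    patients <- names(grp)[grp == "patient"]
    clin <- clinical[match(patients, clinical$case_id), , drop = FALSE]
    if (stratifier == "onset_age_25") {
        a <- patients[!is.na(clin$onset_age_years) & clin$onset_age_years <= 25]
        b <- patients[!is.na(clin$onset_age_years) & clin$onset_age_years > 25]
        labels <- c("onset_le_25", "onset_gt_25")
    } else {
        cls <- bmiClass(clin$bmi_kg_m2)
        a <- patients[!is.na(cls) & cls == "obese"]
        b <- patients[!is.na(cls) & cls == "normal"]
        labels <- c("obese", "normal_weight")
    }
    if (length(a) < 3L || length(b) < 3L) {
        reason <- sprintf("stratum too small for '%s': %s n=%d, %s n=%d",
                          stratifier, labels[1L], length(a),
                          labels[2L], length(b))
        message(reason)
        out <- data.frame()
        attr(out, "skipped") <- reason
        return(out)
    }
    vals <- normalizedCounts(norm)
    out <- do.call(rbind, lapply(detectableGenes(norm), function(g) {
        cbind(gene = g, stratifier = stratifier,
              compareGroups(vals[g, a], vals[g, b],
                            alphaNormality = alphaNormality,
                            varEqual = varEqual, labels = labels))
    }))
    rownames(out) <- NULL
    out
}
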