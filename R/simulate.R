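## Seeded synthetic-cohort generator with planted ground truth.
##
## The generator emulates the statistical structure a targeted
## hybridization-counting panel assumes: a shared positive-control titration
## scaled by per-sample lane efficiency, low Poisson-level negative probes,
## housekeeping candidates of varying stability, endogenous genes that are
## either expressed in blood or stuck at background, and patient cells with
## planted extreme expression. Counts are log-normal multiplicative noise on
## top of a Poisson-like technical floor, rounded to integers.

#' @importFrom stats rnorm rpois runif median
NULL

#' Synthetic cohort generator configuration
#'
#' Defaults mirror the study design the pipeline targets: 8 controls and 19
#' patients, the 19-gene MODY panel with 12 genes undetectable in blood
#' (leaving the 7 blood-expressed genes APPL1, BLK, GLIS3, HADH, IER3IP1,
#' PLAGL1, UCP2), 8 candidate housekeeping genes of which 3 (EEF1G, G6PD,
#' HPRT1) carry extra instability, a 6-point 4-fold positive-control
#' titration, 8 negative probes at a Poisson background of mean 10, lane
#' efficiencies log2-normal with SD 0.3, and 20\% biological CV.
#'
#' @param nControls,nPatients cohort arm sizes.
#' @param endogenousGenes,housekeepingGenes panel composition.
#' @param undetectableGenes endogenous genes planted at background only.
#' @param unstableHK housekeeping genes receiving extra per-sample jitter.
#' @param nPositive,nNegative numbers of control probes.
#' @param titrationTop top positive-control level in counts; successive
#'   probes fall 4-fold.
#' @param lambdaBG Poisson mean of background counts.
#' @param laneEffSdLog2 SD (log2) of per-sample lane efficiency.
#' @param biologicalCV biological coefficient of variation of expressed
#'   genes.
#' @param positiveCV technical CV of positive-control counts.
#' @param unstableSdLog2 extra per-sample jitter SD (log2) of unstable
#'   housekeeping genes.
#' @param outlierCells \code{data.frame(patient, gene, log2fc)} of planted
#'   extreme-expression cells (empty by default).
#' @param baselineExpression optional named baseline counts for expressed
#'   genes; a deterministic log-spaced grid when omitted.
#' @param strataShiftGene,strataShiftBy,strataShiftLog2FC optional planted
#'   stratum contrast: multiply \code{strataShiftGene} by
#'   \code{2^strataShiftLog2FC} in patients of the young-onset stratum
#'   (\code{strataShiftBy = "onset"}) or the obese stratum (\code{"bmi"}).
#' @param seed integer random seed; the generator is fully deterministic
#'   given the configuration.
#' @return Named configuration list of class \code{simConfig}.
#' @export
simConfig <- function(nControls = 8L, nPatients = 19L,
                      endogenousGenes = modyPanelGenes(),
                      housekeepingGenes = housekeepingCandidates(),
                      undetectableGenes = setdiff(modyPanelGenes(),
                          c("APPL1", "BLK", "GLIS3", "HADH", "IER3IP1",
                            "PLAGL1", "UCP2")),
                      unstableHK = c("EEF1G", "G6PD", "HPRT1"),
                      nPositive = 6L, nNegative = 8L,
                      titrationTop = 25600,
                      lambdaBG = 10, laneEffSdLog2 = 0.3,
                      biologicalCV = 0.2, positiveCV = 0.05,
                      unstableSdLog2 = 0.5,
                      outlierCells = NULL,
                      baselineExpression = NULL,
                      strataShiftGene = NULL,
                      strataShiftBy = c("onset", "bmi"),
                      strataShiftLog2FC = 0,
                      seed = 1L) {
    strataShiftBy <- match.arg(strataShiftBy)
    cfg <- as.list(environment())
    if (!all(cfg$undetectableGenes %in% cfg$endogenousGenes))
        stop("undetectableGenes must be a subset of endogenousGenes")
    if (length(cfg$undetectableGenes) >= length(cfg$endogenousGenes))
        stop("at least one endogenous gene must remain detectable")
    if (!all(cfg$unstableHK %in% cfg$housekeepingGenes))
        stop("unstableHK must be a subset of housekeepingGenes")
    if (cfg$nControls < 2L || cfg$nPatients < 1L)
        stop("need at least 2 controls and 1 patient")
    if (cfg$nPositive < 2L || cfg$nNegative < 2L)
        stop("need at least 2 positive and 2 negative probes")
    if (cfg$titrationTop <= 0 ||
        any(c(cfg$lambdaBG, cfg$laneEffSdLog2, cfg$biologicalCV,
              cfg$positiveCV, cfg$unstableSdLog2) < 0))
        stop("noise and count parameters must be non-negative")
    if (!is.null(cfg$outlierCells)) {
        oc <- cfg$outlierCells
        if (!all(c("patient", "gene", "log2fc") %in% names(oc)))
            stop("outlierCells needs columns patient, gene, log2fc")
        det <- setdiff(cfg$endogenousGenes, cfg$undetectableGenes)
        if (!all(oc$gene %in% det))
            stop("outlier genes must be detectable endogenous genes")
    }
    class(cfg) <- c("simConfig", "list")
    cfg
}

.with_seed <- function(seed, code) {
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    code
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws a complete cohort under \code{config}: per-sample lane efficiencies
#' \eqn{e_s = 2^{N(0, \sigma^2)}}; negative probes Poisson(\code{lambdaBG});
#' positive probes \eqn{e_s \times} titration level with log-normal
#' technical noise; expressed genes \eqn{e_s \times baseline_g \times
#' 2^{N(0, \log_2(1 + CV)^2)}}, with extra jitter on unstable housekeeping
#' genes; undetectable genes Poisson(\code{lambdaBG}); planted outlier cells
#' multiply the mean by \eqn{2^{fc}}. Clinical records are drawn with onset
#' ages straddling the 25-year cutoff and BMI values spanning the WHO
#' classes so stratified contrasts can be planted.
#'
#' @param config a \code{\link{simConfig}}.
#' @return List with elements \code{cohort}
#'   (\code{\linkS4class{PanelCohort}}), \code{clinical}
#'   (\code{data.frame}) and \code{truth} (planted ground truth: lane
#'   efficiencies, undetectable genes, unstable housekeeping genes, outlier
#'   cells, baseline expression).
#' @export
#' @examples
#' sim <- simulateCohort(simConfig(seed = 7))
#' sim$cohort
simulateCohort <- function(config = simConfig()) {
    stopifnot(inherits(config, "simConfig"))
    .with_seed(config$seed, {
        n <- config$nControls + config$nPatients
        ids <- c(sprintf("C%d", seq_len(config$nControls)),
                 sprintf("M%d", seq_len(config$nPatients)))
        grp <- rep(c("control", "patient"),
                   c(config$nControls, config$nPatients))
        e <- 2^rnorm(n, 0, config$laneEffSdLog2)
        names(e) <- ids

        detectable <- setdiff(config$endogenousGenes, config$undetectableGenes)
        base <- config$baselineExpression
        if (is.null(base)) {
            base <- c(
                setNames(round(exp(seq(log(100), log(3000),
                                       length.out = length(detectable)))),
                         sort(detectable)),
                setNames(round(exp(seq(log(200), log(8000),
                                       length.out = length(config$housekeepingGenes)))),
                         sort(config$housekeepingGenes)))
        }
        sd_bio <- log2(1 + config$biologicalCV)
        sd_pos <- sqrt(log(1 + config$positiveCV^2))

        expressed <- function(gene, extra_sd = 0) {
            mu <- rep(base[[gene]], n) * e
            jitter <- 2^rnorm(n, 0, sqrt(sd_bio^2 + extra_sd^2))
            mu * jitter
        }

        rows <- list(); classes <- character(0); names_ <- character(0)
        for (i in seq_len(config$nPositive)) {
            level <- config$titrationTop / 4^(i - 1L)
            rows[[length(rows) + 1L]] <-
                level * e * exp(rnorm(n, -sd_pos^2 / 2, sd_pos))
            classes <- c(classes, "Positive")
            names_ <- c(names_, sprintf("POS_%s", LETTERS[i]))
        }
        for (i in seq_len(config$nNegative)) {
            rows[[length(rows) + 1L]] <- rpois(n, config$lambdaBG)
            classes <- c(classes, "Negative")
            names_ <- c(names_, sprintf("NEG_%s", LETTERS[i]))
        }
        for (g in config$housekeepingGenes) {
            extra <- if (g %in% config$unstableHK) config$unstableSdLog2 else 0
            rows[[length(rows) + 1L]] <- expressed(g, extra)
            classes <- c(classes, "Housekeeping")
            names_ <- c(names_, g)
        }

        ## clinical records first drawn here would disturb count RNG order;
        ## draw counts fully, then clinical, keeping one deterministic stream
        endo_rows <- list()
        for (g in config$endogenousGenes) {
            endo_rows[[g]] <- if (g %in% config$undetectableGenes)
                rpois(n, config$lambdaBG)
            else expressed(g)
        }

        clinical <- .simulateClinical(ids, grp)

        ## planted stratum shift
        if (!is.null(config$strataShiftGene) && config$strataShiftLog2FC != 0) {
            g <- config$strataShiftGene
            if (!g %in% names(endo_rows))
                stop("strataShiftGene must be an endogenous gene")
            pat <- ids[grp == "patient"]
            clin_p <- clinical[match(pat, clinical$case_id), ]
            in_stratum <- if (config$strataShiftBy == "onset")
                clin_p$onset_age_years <= 25
            else bmiClass(clin_p$bmi_kg_m2) == "obese"
            idx <- match(pat[in_stratum %in% TRUE], ids)
            endo_rows[[g]][idx] <- endo_rows[[g]][idx] * 2^config$strataShiftLog2FC
        }

        ## planted outlier cells
        if (!is.null(config$outlierCells)) {
            oc <- config$outlierCells
            for (k in seq_len(nrow(oc))) {
                j <- match(oc$patient[k], ids)
                if (is.na(j)) stop(sprintf("unknown outlier patient '%s'",
                                           oc$patient[k]))
                endo_rows[[oc$gene[k]]][j] <-
                    endo_rows[[oc$gene[k]]][j] * 2^oc$log2fc[k]
            }
        }
        for (g in config$endogenousGenes) {
            rows[[length(rows) + 1L]] <- endo_rows[[g]]
            classes <- c(classes, "Endogenous")
            names_ <- c(names_, g)
        }

        m <- do.call(rbind, rows)
        m <- round(m)
        storage.mode(m) <- "integer"
        dimnames(m) <- list(names_, ids)
        cohort <- PanelCohort(m, codeClass = classes, group = grp)

        truth <- list(
            laneEfficiency = e,
            undetectable = config$undetectableGenes,
            detectable = detectable,
            unstableHK = config$unstableHK,
            outlierCells = config$outlierCells,
            baselineExpression = base,
            seed = config$seed)
        list(cohort = cohort, clinical = clinical, truth = truth)
    })
}

## Synthetic clinical records: adult enrolment ages, onset ages straddling
## the 25-year cutoff, BMI spanning normal/overweight/obese, HbA1c around
## the 7% target, glucose and C-peptide around their reference ranges.
.simulateClinical <- function(ids, grp) {
    n <- length(ids)
    is_pat <- grp == "patient"
    age <- as.integer(round(runif(n, 24, 80)))
    onset <- ifelse(is_pat,
                    pmax(5L, age - as.integer(round(runif(n, 5, 30)))),
                    NA_integer_)
    onset <- pmin(onset, age)
    bmi <- round(runif(n, 19, 41), 1)
    hba1c <- ifelse(is_pat, round(rnorm(n, 7.3, 1.1), 1), NA_real_)
    hba1c[!is.na(hba1c) & hba1c < 4.5] <- 4.5
    glucose <- round(ifelse(is_pat, rnorm(n, 130, 25), rnorm(n, 92, 5)))
    cpep <- ifelse(is_pat, round(exp(rnorm(n, log(0.9), 0.5)), 2), NA_real_)
    tx <- matrix(runif(n * 5) < 0.25, nrow = n,
                 dimnames = list(NULL, .THERAPY_COLS))
    tx[is_pat & rowSums(tx) == 0L, "insulin"] <- TRUE   # treated patients
    tx[!is_pat, ] <- FALSE
    data.frame(case_id = ids, group = grp,
               age_years = age, sex = sample(c("M", "F"), n, replace = TRUE),
               onset_age_years = onset,
               family_history_dm_n = as.integer(rpois(n, 2) * is_pat),
               bmi_kg_m2 = bmi,
               hba1c_pct = hba1c,
               fasting_glucose_mg_dl = glucose,
               c_peptide_ng_ml = cpep,
               secondary_complications = is_pat & runif(n) < 0.2,
               insulin = tx[, 1L], metformin = tx[, 2L], dpp4i = tx[, 3L],
               sglt2i = tx[, 4L], glp1ra = tx[, 5L])
}

#' Write a synthetic cohort as a fixture bundle
#'
#' Writes one RCC file per sample, a \code{samples.tsv} group sidecar, a
#' \code{clinical.tsv} metadata table and a \code{truth.json} ground-truth
#' record under \code{dir}; the bundle is re-readable with
#' \code{\link{readRCCDirectory}} and \code{\link{readClinicalTable}}.
#'
#' @param sim result of \code{\link{simulateCohort}}.
#' @param dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return Invisibly, the paths written.
#' @export
writeFixtureBundle <- function(sim, dir, overwrite = FALSE) {
    if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
        stop(sprintf("directory '%s' exists and is not empty (use overwrite = TRUE)",
                     dir))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cohort <- sim$cohort
    m <- counts(cohort)
    rd <- rowData(cohort)
    paths <- character(0)
    for (j in seq_len(ncol(m))) {
        s <- RCCSample(colnames(m)[j],
                       data.frame(CodeClass = rd$CodeClass,
                                  Name = rownames(m),
                                  Accession = rd$Accession,
                                  Count = m[, j]),
                       group = colData(cohort)$Group[j])
        p <- file.path(dir, paste0(colnames(m)[j], ".RCC"))
        writeRCC(s, p)
        paths <- c(paths, p)
    }
    meta_path <- file.path(dir, "samples.tsv")
    writeLines(c("sample_id\tgroup",
                 paste(colnames(m), colData(cohort)$Group, sep = "\t")),
               meta_path)
    clin_path <- file.path(dir, "clinical.tsv")
    df <- sim$clinical
    df$secondary_complications <- ifelse(df$secondary_complications, "Yes", "No")
    for (col in .THERAPY_COLS) df[[col]] <- ifelse(df[[col]], "Yes", "No")
    utils::write.table(df, clin_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    truth_path <- file.path(dir, "truth.json")
    truth <- sim$truth
    ## named vectors must serialize as JSON objects, not nameless arrays
    truth$laneEfficiency <- as.list(truth$laneEfficiency)
    truth$baselineExpression <- as.list(truth$baselineExpression)
    if (!is.null(truth$outlierCells))
        truth$outlierCells <- as.data.frame(truth$outlierCells)
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    invisible(c(paths, meta_path, clin_path, truth_path))
}
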