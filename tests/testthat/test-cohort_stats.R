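test_that("identical groups yield a null comparison", {
    res <- compareGroups(c(1, 2, 3), c(1, 2, 3))
    expect_equal(res$direction, "none")
    if (res$test_used == "t_test") expect_equal(res$statistic, 0)
    expect_gte(res$p_value, 0.99)
    expect_error(compareGroups(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("a planted large shift is detected with the right direction", {
    set.seed(101)
    x <- rnorm(8, mean = 0)
    y <- rnorm(19, mean = 5)   # 5 SD shift
    res <- compareGroups(x, y, labels = c("controls", "patients"))
    expect_lt(res$p_value, 0.05)
    expect_equal(res$direction, "patients_higher")
    res_rev <- compareGroups(y, x, labels = c("patients", "controls"))
    expect_equal(res_rev$direction, "patients_higher")
})

test_that("the normality gate agrees with an independent oracle", {
    for (seed in 1:200) {
        set.seed(seed)
        gen <- sample(c("normal", "lognormal", "uniform", "exponential"), 2,
                      replace = TRUE)
        draw <- function(kind, n) switch(kind,
            normal = rnorm(n), lognormal = rlnorm(n, sdlog = 1.2),
            uniform = runif(n), exponential = rexp(n))
        x <- draw(gen[1], sample(5:20, 1))
        y <- draw(gen[2], sample(5:20, 1))
        res <- compareGroups(x, y)
        expect_equal(res$test_used, oracleTestChoice(x, y))
    }
})

test_that("the Mann-Whitney branch is invariant under monotone transforms", {
    set.seed(55)
    x <- rlnorm(10, sdlog = 1.5)
    y <- rlnorm(12, sdlog = 1.5, meanlog = 1)
    res <- compareGroups(x, y)
    expect_equal(res$test_used, "mann_whitney")
    for (f in list(function(v) v^3, exp, function(v) 5 * v + 2)) {
        res_t <- compareGroups(f(x), f(y))
        if (res_t$test_used == "mann_whitney")
            expect_equal(res_t$p_value, res$p_value, tolerance = 1e-12)
        expect_equal(res_t$statistic, res$statistic)  # U depends on ranks only
    }
})

test_that("per-gene group comparison flags a planted patient shift", {
    sim <- simulateCohort(simConfig(seed = 31))
    cohort <- sim$cohort
    m <- counts(cohort)
    pat <- sampleGroups(cohort) == "patient"
    m["HADH", pat] <- as.integer(round(m["HADH", pat] * 0.4))  # down in patients
    shifted <- makeCohort(m, as.character(rowData(cohort)$CodeClass),
                          unname(sampleGroups(cohort)))
    res <- compareExpressionAllGenes(normalizeCohort(shifted))
    expect_equal(nrow(res), 7)
    hadh <- res[res$gene == "HADH", ]
    expect_lt(hadh$p_value, 0.05)
    expect_equal(hadh$direction, "controls_higher")
})

test_that("correlation layer: identities, gating and missing-data handling", {
    set.seed(77)
    vals <- matrix(exp(rnorm(7 * 27, log(300), 0.3)), nrow = 7,
                   dimnames = list(c("APPL1", "BLK", "GLIS3", "HADH",
                                     "IER3IP1", "PLAGL1", "UCP2"),
                                   c(paste0("C", 1:8), paste0("M", 1:19))))
    ## make one gene exactly linear in HbA1c and one monotone nonlinear
    hba1c <- seq(5, 10, length.out = 19)
    vals["GLIS3", 9:27] <- 10 * hba1c + 3
    vals["UCP2", 9:27] <- exp(hba1c)
    norm <- makeNormalizedPanel(vals, rep(c("control", "patient"), c(8, 19)))
    clin <- data.frame(case_id = paste0("M", 1:19), hba1c_pct = hba1c,
                       fasting_glucose_mg_dl = c(rep(NA, 17), 100, 120),
                       c_peptide_ng_ml = rnorm(19, 1.5, 0.3))
    res <- correlateExpressionClinical(norm, clin)
    g <- res[res$gene == "GLIS3" & res$variable == "hba1c_pct", ]
    expect_equal(g$coefficient, 1, tolerance = 1e-12)
    u <- res[res$gene == "UCP2" & res$variable == "hba1c_pct", ]
    expect_equal(u$method, "spearman")
    expect_equal(u$coefficient, 1, tolerance = 1e-12)
    skipped <- res[res$variable == "fasting_glucose_mg_dl", ]
    expect_true(all(grepl("skipped", skipped$note)))
    expect_true(all(abs(res$coefficient[!is.na(res$coefficient)]) <= 1))
})

test_that("under independence the mean correlation is near zero", {
    set.seed(991)
    coefs <- replicate(300, {
        e <- exp(rnorm(19, log(300), 0.3))
        v <- rnorm(19)
        suppressWarnings(cor(rank(e), rank(v)))
    })
    expect_lt(abs(mean(coefs)), 0.05)
})

test_that("stratified contrasts recover a planted early-onset shift", {
    cfg <- simConfig(seed = 47, strataShiftGene = "GLIS3",
                     strataShiftBy = "onset", strataShiftLog2FC = 2)
    sim <- simulateCohort(cfg)
    norm <- normalizeCohort(sim$cohort)
    res <- stratifiedComparison(norm, sim$clinical, "onset_age_25")
    g <- res[res$gene == "GLIS3", ]
    expect_lt(g$p_value, 0.05)
    expect_equal(g$direction, "onset_le_25_higher")
})

test_that("too-small strata are skipped with a message, not an error", {
    sim <- simulateCohort(simConfig(seed = 5))
    norm <- normalizeCohort(sim$cohort)
    clin <- sim$clinical
    clin$onset_age_years[clin$group == "patient"] <- 40  # one stratum empty
    expect_message(res <- stratifiedComparison(norm, clin, "onset_age_25"),
                   "too small")
    expect_equal(nrow(res), 0)
    expect_error(stratifiedComparison(norm, clin, "height"), "arg")
})
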