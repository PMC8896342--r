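test_that("background threshold is mean + k SD of the negative probes", {
    expect_equal(backgroundThreshold(c(10, 12, 14, 12, 12)), 12 + 2 * sqrt(2),
                 tolerance = 1e-12)
    expect_equal(suppressWarnings(backgroundThreshold(c(0, 0, 0, 0))), 0)
    expect_warning(expect_equal(backgroundThreshold(c(7, 7, 7)), 7),
                   "zero variance")
    expect_error(backgroundThreshold(5), "at least 2")
})

test_that("detectability requires strict exceedance in enough samples", {
    m <- rbind(POS_A = c(100L, 100L), POS_B = c(25L, 25L),
               NEG_A = c(10L, 10L), NEG_B = c(12L, 12L), NEG_C = c(14L, 14L),
               HK1 = c(500L, 500L), HK2 = c(600L, 600L), HK3 = c(700L, 700L),
               GENE_HI = c(300L, 300L),
               GENE_AT = c(16L, 16L),     # threshold 12 + 2*2 = 16 exactly
               GENE_LO = c(5L, 5L))
    cohort <- makeCohort(m, c("Positive", "Positive", "Negative", "Negative",
                              "Negative", "Housekeeping", "Housekeeping",
                              "Housekeeping", "Endogenous", "Endogenous",
                              "Endogenous"),
                         c("control", "patient"))
    thr <- backgroundThresholds(cohort)
    expect_equal(unname(thr), c(16, 16))
    mask <- detectabilityMask(cohort, thr)
    expect_true(mask[["GENE_HI"]])
    expect_false(mask[["GENE_AT"]])   # at threshold is not above it
    expect_false(mask[["GENE_LO"]])
})

test_that("positive factors: identity, closed form, and zero-count error", {
    base <- rbind(POS_A = c(4000, 4000), POS_B = c(1000, 1000),
                  NEG_A = c(10, 10), NEG_B = c(12, 12),
                  HK1 = c(500, 500), HK2 = c(600, 600), HK3 = c(700, 700),
                  G1 = c(300, 300))
    cls <- c("Positive", "Positive", "Negative", "Negative",
             "Housekeeping", "Housekeeping", "Housekeeping", "Endogenous")
    ident <- makeCohort(base, cls, c("control", "patient"))
    expect_equal(unname(positiveFactors(ident)), c(1, 1))

    doubled <- base; doubled[1:2, 2] <- base[1:2, 2] * 2
    cohort <- makeCohort(doubled, cls, c("control", "patient"))
    ## B's positives are 2x A's: G_A = g, G_B = 2g, mean = 1.5g
    expect_equal(unname(positiveFactors(cohort)), c(1.5, 0.75))

    zeroed <- base; zeroed[1, 1] <- 0
    expect_error(positiveFactors(makeCohort(zeroed, cls,
        c("control", "patient"))), "zero positive-control count")
})

test_that("proportional genes have zero pairwise variation and equal M", {
    samples <- 2^seq(0, 3, length.out = 6)
    mat <- rbind(A = 100 * samples, B = 7 * samples, C = c(50, 80, 20, 90, 30, 60))
    gn <- geNormRank(mat)
    ## A and B are exactly proportional: their mutual V is 0, so both M
    ## values equal V(A,C) = V(B,C) / (n-1) contributions identically
    expect_equal(mValues(gn)[["A"]], mValues(gn)[["B"]], tolerance = 1e-12)
    expect_equal(exclusionOrder(gn), "C")
    lgr <- log2(mat["A", ] / mat["B", ])
    expect_equal(sd(lgr), 0, tolerance = 1e-12)
})

test_that("geNorm matches the brute-force oracle on random small matrices", {
    for (seed in 1:40) {
        set.seed(seed)
        n_g <- sample(3:6, 1)
        n_s <- sample(4:8, 1)
        mat <- matrix(exp(rnorm(n_g * n_s, log(500), 0.6)), nrow = n_g,
                      dimnames = list(paste0("HK", seq_len(n_g)), NULL))
        gn <- geNormRank(mat)
        expect_equal(mValues(gn), oracleM(mat), tolerance = 1e-10)
        expect_equal(exclusionOrder(gn), oracleExclusion(mat))
        expect_equal(unname(vCurve(gn)),
                     oracleVCurve(mat, gn@stabilityRank), tolerance = 1e-10)
        expect_true(all(mValues(gn) >= 0))
        expect_length(exclusionOrder(gn), n_g - 2)
        expect_length(vCurve(gn), n_g - 2)
    }
})

test_that("geNorm input contracts: minimum genes and positive values", {
    mat <- matrix(runif(8, 1, 10), nrow = 2)
    expect_error(geNormRank(mat), "at least 3")
    mat3 <- matrix(c(0, runif(11, 1, 10)), nrow = 3)
    expect_error(geNormRank(mat3), "positive")
})

test_that("content factors equalize reference geometric means across samples", {
    vals <- rbind(HK1 = c(500, 250, 500), HK2 = c(600, 300, 600),
                  G1 = c(100, 100, 100))
    cf <- contentFactors(vals, c("HK1", "HK2"))
    ## sample 2's references are uniformly halved: H = (h, h/2, h),
    ## mean(H) = 5h/6, factors = (5/6, 5/3, 5/6); ratio f2/f1 = 2
    expect_equal(unname(cf), c(5 / 6, 5 / 3, 5 / 6))
    scaled <- sweep(vals, 2, cf, `*`)
    gm <- apply(scaled[c("HK1", "HK2"), ], 2, function(x) exp(mean(log(x))))
    expect_equal(unname(gm), rep(gm[[1]], 3), tolerance = 1e-12)
    expect_error(contentFactors(vals, c("HK1", "HK9")), "HK9")
    vals0 <- vals; vals0["HK1", 1] <- 0
    expect_error(contentFactors(vals0, c("HK1", "HK2")), "zero reference")
})

test_that("factor computations are invariant to gene and sample ordering", {
    cohort <- randomCohort(nEndo = 5, nSamples = 6, seed = 11)
    pf <- positiveFactors(cohort)
    shuffled <- cohort[sample(nrow(cohort)), sample(ncol(cohort))]
    pf2 <- positiveFactors(shuffled)
    expect_equal(pf2[names(pf)], pf)

    vals <- matrix(runif(18, 50, 500), nrow = 3,
                   dimnames = list(c("HK1", "HK2", "HK3"), paste0("S", 1:6)))
    cf <- contentFactors(vals, c("HK1", "HK3"))
    cf2 <- contentFactors(vals[c(3, 1, 2), c(4, 2, 6, 1, 3, 5)], c("HK1", "HK3"))
    expect_equal(cf2[names(cf)], cf)
})

test_that("normalizeCohort is the identity on uniform cohorts and homogeneous", {
    one <- c(POS_A = 4000, POS_B = 1000, POS_C = 250,
             NEG_A = 10, NEG_B = 12, NEG_C = 14,
             HK1 = 500, HK2 = 600, HK3 = 700,
             G1 = 300, G2 = 5)
    m <- matrix(rep(one, 4), ncol = 4,
                dimnames = list(names(one), paste0("S", 1:4)))
    cls <- c(rep("Positive", 3), rep("Negative", 3), rep("Housekeeping", 3),
             "Endogenous", "Endogenous")
    cohort <- makeCohort(m, cls, c("control", "control", "patient", "patient"))
    norm <- normalizeCohort(cohort)
    expect_equal(detectableGenes(norm), "G1")
    expect_equal(normalizedCounts(norm)["G1", ], counts(cohort)["G1", ] + 0.0)
    expect_true(all(provenance(norm)$positiveFactors == 1))
    expect_true(all(provenance(norm)$contentFactors == 1))

    ## scaling every sample by the same constant scales normalized values
    cohort10 <- makeCohort(m * 10L, cls,
                           c("control", "control", "patient", "patient"))
    norm10 <- normalizeCohort(cohort10)
    expect_equal(normalizedCounts(norm10)["G1", ],
                 10 * normalizedCounts(norm)["G1", ], tolerance = 1e-12)
})

test_that("normalization reduces per-gene control variability on noisy cohorts", {
    sim <- simulateCohort(simConfig(seed = 21))
    norm <- normalizeCohort(sim$cohort)
    ctrl <- sampleGroups(norm) == "control"
    genes <- detectableGenes(norm)
    cv <- function(m) apply(m, 1, function(x) sd(x) / mean(x))
    cv_before <- cv(counts(norm)[genes, ctrl])
    cv_after <- cv(normalizedCounts(norm)[genes, ctrl])
    expect_lt(median(cv_after), median(cv_before))
    expect_true(all(normalizedCounts(norm) >= 0))
    expect_true(all(provenance(norm)$positiveFactors > 0))
    expect_true(all(provenance(norm)$contentFactors > 0))
})

test_that("stage failures name the failing stage", {
    cohort <- randomCohort(seed = 5)
    no_hk <- cohort[rowData(cohort)$CodeClass != "Housekeeping", ]
    expect_error(normalizeCohort(no_hk), "stage 'input'")
    m <- counts(cohort)
    m[rowData(cohort)$CodeClass == "Positive", 1][1] <- 0L
    broken <- makeCohort(m, as.character(rowData(cohort)$CodeClass),
                         unname(sampleGroups(cohort)))
    expect_error(normalizeCohort(broken), "stage 'positive'")
})
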