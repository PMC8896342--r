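test_that("a minimal RCC file parses into its probe rows in file order", {
    f <- tempfile(fileext = ".RCC")
    writeLines(c("<Header>", "FileVersion,1.7", "</Header>",
                 "<Sample_Attributes>", "ID,S1", "</Sample_Attributes>",
                 "<Lane_Attributes>", "ID,1", "</Lane_Attributes>",
                 "<Code_Summary>", "CodeClass,Name,Accession,Count",
                 "Negative,NEG_A,,12", "Positive,POS_A,,5032",
                 "Endogenous,HADH,NM_005327,210", "</Code_Summary>"), f)
    s <- readRCC(f)
    expect_s4_class(s, "RCCSample")
    expect_equal(s@sampleID, "S1")
    expect_equal(s@probes$Name, c("NEG_A", "POS_A", "HADH"))
    expect_equal(s@probes$Count, c(12L, 5032L, 210L))
    expect_equal(s@probes$Accession, c("", "", "NM_005327"))
})

test_that("RCC read/write round-trips byte-for-byte", {
    f <- tempfile(fileext = ".RCC")
    s <- RCCSample("S9", data.frame(
        CodeClass = c("Negative", "Negative", "Positive", "Positive",
                      "Housekeeping", "Endogenous"),
        Name = c("NEG_A", "NEG_B", "POS_A", "POS_B", "GAPDH", "GCK"),
        Accession = c("", "", "", "", "NM_002046", ""),
        Count = c(8L, 11L, 4000L, 1000L, 950L, 100L)))
    writeRCC(s, f)
    f2 <- tempfile(fileext = ".RCC")
    writeRCC(readRCC(f), f2)
    expect_identical(readBin(f, "raw", file.size(f)),
                     readBin(f2, "raw", file.size(f2)))
    ## empty accession emits an empty CSV field
    expect_true(any(grepl("^Endogenous,GCK,,100$", readLines(f))))
})

test_that("malformed RCC content is rejected with informative errors", {
    f <- tempfile(fileext = ".RCC")
    writeLines(c("<Header>", "FileVersion,1.7", "</Header>"), f)
    expect_error(readRCC(f), "Code_Summary")
    writeLines(c("<Code_Summary>", "CodeClass,Name,Accession,Count",
                 "Negative,NEG_A,,-3", "</Code_Summary>"), f)
    expect_error(readRCC(f), "non-integer or negative Count '-3'")
    writeLines(c("<Code_Summary>", "CodeClass,Name,Accession,Count",
                 "SpikeIn,ERCC_1,,50", "</Code_Summary>"), f)
    expect_error(readRCC(f), "SpikeIn")
    s <- RCCSample("S1", data.frame(CodeClass = c("Negative", "Positive"),
                                    Name = c("NEG_A", "POS_A"),
                                    Accession = c("", ""),
                                    Count = c(1L, 2L)))
    s@probes <- s@probes[0, ]
    expect_error(writeRCC(s, tempfile()), "no probes")
})

test_that("assembleCohort orders controls first and validates probe sets", {
    probes <- function(count_shift = 0L) data.frame(
        CodeClass = c("Negative", "Negative", "Positive", "Positive",
                      "Housekeeping", "Endogenous"),
        Name = c("NEG_A", "NEG_B", "POS_A", "POS_B", "GAPDH", "GCK"),
        Accession = "", Count = c(8L, 11L, 4000L, 1000L, 950L, 100L) + count_shift)
    ss <- list(RCCSample("P1", probes(1L), group = "patient"),
               RCCSample("C1", probes(2L), group = "control"),
               RCCSample("P2", probes(3L), group = "patient"),
               RCCSample("C2", probes(4L), group = "control"))
    cohort <- assembleCohort(ss)
    expect_equal(colnames(cohort), c("C1", "C2", "P1", "P2"))
    expect_equal(unname(sampleGroups(cohort)),
                 c("control", "control", "patient", "patient"))
    expect_equal(unname(counts(cohort)["GCK", ]), c(102L, 104L, 101L, 103L))

    ## probe-set mismatch names the offending probe
    bad <- probes(); bad$Name[6] <- "GCKX"
    expect_error(assembleCohort(c(ss[1:2], list(RCCSample("P9", bad,
        group = "patient")))), "GCK")
    ## duplicate ids rejected
    expect_error(assembleCohort(list(ss[[1]], ss[[1]])), "duplicate sample_id")
    expect_error(assembleCohort(ss[1]), "at least 2 samples")
})

test_that("assembleCohort is permutation-stable in sample order", {
    cohort <- randomCohort(nEndo = 6, nSamples = 5, seed = 42)
    samples <- lapply(colnames(cohort), function(id)
        RCCSample(id, data.frame(CodeClass = rowData(cohort)$CodeClass,
                                 Name = rownames(cohort),
                                 Accession = rowData(cohort)$Accession,
                                 Count = counts(cohort)[, id]),
                  group = sampleGroups(cohort)[[id]]))
    a <- assembleCohort(samples)
    set.seed(7)
    b <- assembleCohort(sample(samples))
    expect_setequal(colnames(a), colnames(b))
    expect_identical(counts(a)[, colnames(a)], counts(b)[, colnames(a)])
    expect_identical(sampleGroups(a)[colnames(a)], sampleGroups(b)[colnames(a)])
})

test_that("count-matrix TSV round-trips a cohort losslessly", {
    for (seed in c(2, 9)) {
        cohort <- randomCohort(nEndo = 4, nSamples = 3, seed = seed)
        f <- tempfile(fileext = ".tsv"); meta <- tempfile(fileext = ".tsv")
        writeCountMatrix(cohort, f, meta)
        back <- readCountMatrix(f, meta)
        expect_identical(counts(back), counts(cohort))
        expect_equal(rownames(back), rownames(cohort))  # probe order kept
        expect_equal(as.character(rowData(back)$CodeClass),
                     as.character(rowData(cohort)$CodeClass))
        expect_equal(as.character(rowData(back)$Accession),
                     as.character(rowData(cohort)$Accession))
        expect_identical(sampleGroups(back), sampleGroups(cohort))
    }
})

test_that("count-matrix errors: ragged rows and missing sidecar entries", {
    cohort <- randomCohort(seed = 3)
    f <- tempfile(fileext = ".tsv"); meta <- tempfile(fileext = ".tsv")
    writeCountMatrix(cohort, f, meta)
    lines <- readLines(f)
    lines[3] <- paste(lines[3], "extra", sep = "\t")
    writeLines(lines, f)
    expect_error(readCountMatrix(f, meta), "ragged row at line 3")

    writeCountMatrix(cohort, f, meta)
    m <- utils::read.delim(meta)
    writeLines(c("sample_id\tgroup",
                 paste(m$sample_id[-1], m$group[-1], sep = "\t")), meta)
    expect_error(readCountMatrix(f, meta), m$sample_id[1])
})
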