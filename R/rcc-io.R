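## RCC sample-file and count-matrix input/output.
##
## The RCC dialect handled here is the common nCounter text layout: sections
## delimited by <Name> ... </Name> tags, CSV bodies, and a Code_Summary
## section with columns CodeClass,Name,Accession,Count. Unknown sections and
## header keys are preserved verbatim so reading and writing round-trip.

.DEFAULT_SECTIONS <- function(sampleID) {
    list(Header = c("FileVersion,1.7", "SoftwareVersion,4.0.0.3"),
         Sample_Attributes = c(paste0("ID,", sampleID), "Owner,", "Comments,",
                               "Date,20200101", "GeneRLF,panel_rlf",
                               "SystemAPF,n6_vDV1"),
         Lane_Attributes = c("ID,1", "FovCount,280", "FovCounted,278",
                             "BindingDensity,0.62", "CartridgeID,synthetic"),
         Code_Summary = character(0))
}

#' Read an nCounter RCC sample file
#'
#' Parses one RCC-dialect file into an \code{\linkS4class{RCCSample}}. The
#' probe table reproduces the Code_Summary rows in file order; every other
#' section is preserved verbatim so \code{\link{writeRCC}} inverts the read
#' exactly.
#'
#' @param path path to an RCC file.
#' @return An \code{\linkS4class{RCCSample}}.
#' @seealso \code{\link{writeRCC}}, \code{\link{assembleCohort}}
#' @export
#' @examples
#' f <- tempfile(fileext = ".RCC")
#' s <- RCCSample("S1", data.frame(
#'     CodeClass = c("Negative", "Positive", "Positive", "Endogenous"),
#'     Name = c("NEG_A", "POS_A", "POS_B", "HADH"),
#'     Accession = c("", "", "", "NM_005327"),
#'     Count = c(12L, 5032L, 1250L, 210L)))
#' writeRCC(s, f)
#' readRCC(f)
readRCC <- function(path) {
    if (!file.exists(path))
        stop(sprintf("RCC file not found: '%s'", path))
    lines <- readLines(path, warn = FALSE)
    opens <- grep("^<[A-Za-z_][A-Za-z0-9_]*>$", lines)
    sections <- list()
    for (i in opens) {
        name <- sub("^<([A-Za-z_][A-Za-z0-9_]*)>$", "\\1", lines[i])
        close_tag <- paste0("</", name, ">")
        j <- which(lines == close_tag)
        j <- j[j > i][1]
        if (is.na(j))
            stop(sprintf("RCC format error in '%s': section '%s' not closed",
                         path, name))
        sections[[name]] <- if (j > i + 1L) lines[(i + 1L):(j - 1L)] else character(0)
    }
    if (!"Code_Summary" %in% names(sections))
        stop(sprintf("RCC format error in '%s': missing Code_Summary section",
                     path))
    body <- sections[["Code_Summary"]]
    body <- body[nzchar(body)]
    if (length(body) < 2L || !identical(body[1L], "CodeClass,Name,Accession,Count"))
        stop(sprintf(
            "RCC format error in '%s': Code_Summary must start with header 'CodeClass,Name,Accession,Count'",
            path))
    fields <- strsplit(body[-1L], ",", fixed = TRUE)
    probes <- data.frame(
        CodeClass = vapply(fields, function(x) x[1L], ""),
        Name      = vapply(fields, function(x) if (length(x) >= 2L) x[2L] else "", ""),
        Accession = vapply(fields, function(x) if (length(x) >= 3L) x[3L] else "", ""),
        Count_raw = vapply(fields, function(x) if (length(x) >= 4L) x[4L] else "", ""),
        stringsAsFactors = FALSE)
    bad <- which(!grepl("^[0-9]+$", probes$Count_raw))
    if (length(bad))
        stop(sprintf(
            "RCC value error in '%s': non-integer or negative Count '%s' in Code_Summary row %d (%s)",
            path, probes$Count_raw[bad[1L]], bad[1L], probes$Name[bad[1L]]))
    probes$Count <- as.integer(probes$Count_raw)
    probes$Count_raw <- NULL
    bad_class <- setdiff(unique(probes$CodeClass), .PROBE_CLASSES)
    if (length(bad_class))
        stop(sprintf("RCC value error in '%s': unsupported CodeClass %s",
                     path, paste(sQuote(bad_class), collapse = ", ")))

    sample_id <- NA_character_
    sa <- sections[["Sample_Attributes"]]
    if (!is.null(sa)) {
        id_line <- grep("^ID,", sa, value = TRUE)
        if (length(id_line)) sample_id <- sub("^ID,", "", id_line[1L])
    }
    if (is.na(sample_id) || !nzchar(sample_id))
        sample_id <- sub("\\.[Rr][Cc][Cc]$", "", basename(path))
    sections[["Code_Summary"]] <- character(0)
    RCCSample(sample_id, probes, sections = sections)
}

#' Write an nCounter RCC sample file
#'
#' Emits an RCC-dialect file that \code{\link{readRCC}} inverts exactly.
#' Preserved sections are written verbatim in their stored order; the
#' Code_Summary body is regenerated from the probe table.
#'
#' @param sample an \code{\linkS4class{RCCSample}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeRCC <- function(sample, path) {
    stopifnot(is(sample, "RCCSample"))
    validObject(sample)
    if (nrow(sample@probes) == 0L)
        stop("refusing to write an RCC file with no probes")
    sections <- sample@sections
    if (length(sections) == 0L)
        sections <- .DEFAULT_SECTIONS(sample@sampleID)
    if (!"Code_Summary" %in% names(sections))
        sections[["Code_Summary"]] <- character(0)
    p <- sample@probes
    cs <- c("CodeClass,Name,Accession,Count",
            sprintf("%s,%s,%s,%d", p$CodeClass, p$Name, p$Accession, p$Count))
    out <- character(0)
    for (name in names(sections)) {
        body <- if (name == "Code_Summary") cs else sections[[name]]
        out <- c(out, paste0("<", name, ">"), body, paste0("</", name, ">"))
    }
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(out, con, sep = "\n")
    invisible(path)
}

#' Assemble individual samples into a cohort
#'
#' Checks that all samples share an identical probe set, assigns cohort
#' groups, and returns a \code{\linkS4class{PanelCohort}} with samples
#' ordered controls first, then patients (both sub-orders stable in input
#' order).
#'
#' @param samples list of \code{\linkS4class{RCCSample}} objects.
#' @param groups optional named character vector \code{sample_id -> group}
#'   (\code{"control"}/\code{"patient"}); required for samples whose
#'   \code{group} slot is unset.
#' @return A \code{\linkS4class{PanelCohort}}.
#' @export
assembleCohort <- function(samples, groups = NULL) {
    if (length(samples) < 2L)
        stop("at least 2 samples are required to assemble a cohort")
    ids <- vapply(samples, function(s) s@sampleID, "")
    if (anyDuplicated(ids))
        stop(sprintf("duplicate sample_id: %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    grp <- vapply(samples, function(s) s@group, "")
    if (!is.null(groups)) {
        missing_ids <- setdiff(ids, names(groups))
        if (length(missing_ids) && any(is.na(grp[match(missing_ids, ids)])))
            stop(sprintf("group metadata missing for sample(s): %s",
                         paste(missing_ids, collapse = ", ")))
        grp[ids %in% names(groups)] <- groups[ids[ids %in% names(groups)]]
    }
    if (any(is.na(grp)))
        stop(sprintf("no group assigned for sample(s): %s",
                     paste(ids[is.na(grp)], collapse = ", ")))
    if (!all(grp %in% .SAMPLE_GROUPS))
        stop("groups must be 'control' or 'patient'")

    key <- function(s) paste(s@probes$CodeClass, s@probes$Name, sep = ":")
    ref_key <- key(samples[[1L]])
    for (s in samples[-1L]) {
        k <- key(s)
        if (!setequal(k, ref_key)) {
            diff <- union(setdiff(k, ref_key), setdiff(ref_key, k))
            stop(sprintf("probe-set mismatch between samples '%s' and '%s': %s",
                         ids[1L], s@sampleID, paste(diff, collapse = ", ")))
        }
    }
    ref <- samples[[1L]]@probes
    counts <- vapply(samples, function(s) {
        s@probes$Count[match(ref_key, key(s))]
    }, integer(nrow(ref)))
    counts <- matrix(counts, nrow = nrow(ref),
                     dimnames = list(ref$Name, ids))
    PanelCohort(counts, codeClass = ref$CodeClass, group = grp,
                accession = ref$Accession)
}

#' Read or write a cohort count matrix as TSV
#'
#' The matrix TSV holds one probe per row with columns \code{code_class},
#' \code{name}, \code{accession}, then one column per sample; a sidecar TSV
#' (\code{sample_id}, \code{group}) assigns each sample to the control or
#' patient arm. The pair of files round-trips a
#' \code{\linkS4class{PanelCohort}} losslessly.
#'
#' @param path matrix TSV path.
#' @param metadataPath sidecar TSV path.
#' @return \code{readCountMatrix} returns a \code{\linkS4class{PanelCohort}};
#'   \code{writeCountMatrix} invisibly returns \code{path}.
#' @export
readCountMatrix <- function(path, metadataPath) {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) < 2L)
        stop(sprintf("count matrix '%s' has no data rows", path))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    widths <- lengths(fields)
    if (any(widths != widths[1L])) {
        bad <- which(widths != widths[1L])[1L]
        stop(sprintf("format error in '%s': ragged row at line %d (%d fields, expected %d)",
                     path, bad, widths[bad], widths[1L]))
    }
    header <- fields[[1L]]
    if (length(header) < 4L || !identical(header[1:3], c("code_class", "name", "accession")))
        stop(sprintf("format error in '%s': header must start with code_class, name, accession",
                     path))
    sample_ids <- header[-(1:3)]
    body <- do.call(rbind, fields[-1L])
    counts <- matrix(suppressWarnings(as.numeric(body[, -(1:3), drop = FALSE])),
                     nrow = nrow(body),
                     dimnames = list(body[, 2L], sample_ids))
    if (any(is.na(counts)))
        stop(sprintf("value error in '%s': non-numeric count", path))

    meta <- utils::read.delim(metadataPath, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "group") %in% names(meta)))
        stop(sprintf("metadata sidecar '%s' must have columns sample_id, group",
                     metadataPath))
    missing_ids <- setdiff(sample_ids, meta$sample_id)
    if (length(missing_ids))
        stop(sprintf("metadata sidecar '%s' missing sample_id(s): %s",
                     metadataPath, paste(missing_ids, collapse = ", ")))
    grp <- meta$group[match(sample_ids, meta$sample_id)]
    PanelCohort(counts, codeClass = body[, 1L], group = grp,
                accession = body[, 3L])
}

#' @rdname readCountMatrix
#' @param cohort a \code{\linkS4class{PanelCohort}}.
#' @export
writeCountMatrix <- function(cohort, path, metadataPath) {
    stopifnot(is(cohort, "PanelCohort"))
    m <- counts(cohort)
    header <- paste(c("code_class", "name", "accession", colnames(m)),
                    collapse = "\t")
    rows <- paste(rowData(cohort)$CodeClass, rownames(m),
                  rowData(cohort)$Accession,
                  apply(m, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(header, rows), path)
    writeLines(c("sample_id\tgroup",
                 paste(colnames(m), colData(cohort)$Group, sep = "\t")),
               metadataPath)
    invisible(path)
}

#' Read all RCC files of a directory into a cohort
#'
#' Globs \code{*.RCC} / \code{*.rcc} under \code{dir}, reads each file, and
#' assembles them with group assignments from a \code{samples.tsv} sidecar
#' (columns \code{sample_id}, \code{group}) unless \code{groups} is given.
#'
#' @param dir directory of RCC files.
#' @param groups optional named vector \code{sample_id -> group}.
#' @return A \code{\linkS4class{PanelCohort}}.
#' @export
readRCCDirectory <- function(dir, groups = NULL) {
    files <- sort(list.files(dir, pattern = "\\.[Rr][Cc][Cc]$",
                             full.names = TRUE))
    if (length(files) < 2L)
        stop(sprintf("fewer than 2 RCC files found under '%s'", dir))
    samples <- lapply(files, readRCC)
    if (is.null(groups)) {
        sidecar <- file.path(dir, "samples.tsv")
        if (!file.exists(sidecar))
            stop(sprintf("no 'samples.tsv' sidecar under '%s' and no groups given",
                         dir))
        meta <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
        groups <- stats::setNames(meta$group, meta$sample_id)
    }
    assembleCohort(samples, groups = groups)
}
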