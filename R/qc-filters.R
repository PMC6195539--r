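#' Genotype- and variant-level quality-control filters
#'
#' Four filters define the analyzable variant set of a cohort:
#' \describe{
#'   \item{[filterGQ()]}{calls with genotype quality strictly below the
#'     threshold (default 20) become missing; no variant is removed.}
#'   \item{[filterHomContamination()]}{homozygous-alt calls whose reference
#'     reads strictly exceed 5% of the total depth at the call are
#'     invalidated (set missing), to remove likely false homozygotes;
#'     zero-depth homozygous calls are unverifiable and also invalidated.
#'     The filter acts per call, never on the whole variant, so valid
#'     heterozygotes at the same site are untouched.}
#'   \item{[filterMissingness()]}{variants whose missing-call fraction
#'     strictly exceeds the threshold (default 10%) in the case group
#'     \emph{or} in the control group are dropped. Applied after the
#'     genotype-level filters, so the fractions refer to filtered
#'     genotypes.}
#'   \item{[excludeIndels()]}{insertion/deletion variants are removed
#'     (unreliable calls and ambiguous allele representation).}
#' }
#' [runQC()] composes them in the fixed order GQ, contamination,
#' missingness, indels, records a per-variant summary retrievable with
#' [qcSummary()], and is idempotent. No filter ever turns a missing call
#' back into a genotype or alters an alt-allele count other than to
#' missing.
#'
#' @param x a [HomCohort-class].
#' @param threshold phred GQ cutoff; calls with `GQ < threshold` are set
#'   missing (strict inequality: GQ exactly at the threshold is retained).
#' @param maxRefFraction maximum tolerated reference-read fraction of a
#'   homozygous-alt call (strict: exactly 5% is retained).
#' @param maxFraction maximum tolerated per-group missing-call fraction of
#'   a variant (strict: exactly 10% missing is retained).
#' @return a filtered `HomCohort`.
#' @name qc-filters
NULL

.bumpQc <- function(x, filter, perVariant) {
    qc <- S4Vectors::metadata(x)$qcSummary
    add <- data.frame(variant_id = names(perVariant), filter = filter,
                      n_calls_invalidated = as.integer(perVariant),
                      row.names = NULL)
    add <- add[add$n_calls_invalidated > 0, , drop = FALSE]
    S4Vectors::metadata(x)$qcSummary <- rbind(qc, add)
    x
}

#' @rdname qc-filters
#' @export
filterGQ <- function(x, threshold = 20) {
    stopifnot(is(x, "HomCohort"))
    if (threshold < 0) stop("invalid 'threshold': must be non-negative")
    gt <- genotypes(x); gq <- genoQual(x)
    if (all(is.na(gq))) {
        warning("no GQ values present; GQ filter is inert")
        return(x)
    }
    bad <- !is.na(gt) & !is.na(gq) & gq < threshold
    gt[bad] <- NA_integer_
    assay(x, "GT") <- gt
    .bumpQc(x, "gq", rowSums(bad))
}

#' @rdname qc-filters
#' @export
filterHomContamination <- function(x, maxRefFraction = 0.05) {
    stopifnot(is(x, "HomCohort"))
    .assertScalar(maxRefFraction, "maxRefFraction", min = 0, max = 1)
    gt <- genotypes(x); rdm <- refDepth(x); adm <- altDepth(x)
    if (all(is.na(rdm)) && all(is.na(adm))) {
        warning("no AD values present; contamination filter is inert")
        return(x)
    }
    depth <- rdm + adm
    hom <- !is.na(gt) & gt == 2L & !is.na(depth)
    bad <- hom & (depth == 0 | rdm / depth > maxRefFraction)
    gt[bad] <- NA_integer_
    assay(x, "GT") <- gt
    .bumpQc(x, "hom_contamination", rowSums(bad))
}

#' @rdname qc-filters
#' @export
filterMissingness <- function(x, maxFraction = 0.10) {
    stopifnot(is(x, "HomCohort"))
    .assertScalar(maxFraction, "maxFraction", min = 0, max = 1)
    grp <- as.character(x$group)
    if (!any(grp == "case") || !any(grp == "control"))
        stop("missingness fractions undefined: a group is empty")
    gt <- genotypes(x)
    miss <- is.na(gt)
    fCase <- rowMeans(miss[, grp == "case", drop = FALSE])
    fCtrl <- rowMeans(miss[, grp == "control", drop = FALSE])
    drop <- fCase > maxFraction | fCtrl > maxFraction
    dropped <- rownames(x)[drop]
    x <- x[!drop, ]
    if (length(dropped)) {
        add <- data.frame(variant_id = dropped, filter = "missingness",
                          n_calls_invalidated = NA_integer_)
        S4Vectors::metadata(x)$qcSummary <-
            rbind(S4Vectors::metadata(x)$qcSummary, add)
    }
    x
}

#' @rdname qc-filters
#' @export
excludeIndels <- function(x) {
    stopifnot(is(x, "HomCohort"))
    drop <- rowData(x)$isIndel
    dropped <- rownames(x)[drop]
    x <- x[!drop, ]
    if (length(dropped)) {
        add <- data.frame(variant_id = dropped, filter = "indel",
                          n_calls_invalidated = NA_integer_)
        S4Vectors::metadata(x)$qcSummary <-
            rbind(S4Vectors::metadata(x)$qcSummary, add)
    }
    x
}

#' @rdname qc-filters
#' @param gqThreshold,dropIndels parameters forwarded to the individual
#'   filters; `dropIndels = FALSE` keeps indels (for data already pruned).
#' @export
runQC <- function(x, gqThreshold = 20, maxRefFraction = 0.05,
                  maxFraction = 0.10, dropIndels = TRUE) {
    x <- filterGQ(x, gqThreshold)
    x <- filterHomContamination(x, maxRefFraction)
    x <- filterMissingness(x, maxFraction)
    if (dropIndels) x <- excludeIndels(x)
    x
}

#' QC summary table
#'
#' Per-variant record of what each filter invalidated or removed:
#' columns `variant_id`, `filter` and `n_calls_invalidated` (`NA` for
#' variant-level removals by the missingness and indel filters).
#'
#' @param x a `HomCohort` that went through [runQC()] or the individual
#'   filters.
#' @return a `data.frame` (zero rows if nothing was filtered).
#' @export
qcSummary <- function(x) {
    qc <- S4Vectors::metadata(x)$qcSummary
    if (is.null(qc))
        qc <- data.frame(variant_id = character(), filter = character(),
                         n_calls_invalidated = integer())
    qc
}

#' @describeIn qcSummary write the summary as TSV.
#' @param path output path.
#' @export
writeQcSummary <- function(x, path) {
    utils::write.table(qcSummary(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
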