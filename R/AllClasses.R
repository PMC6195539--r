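#' @import methods
#' @import SummarizedExperiment
NULL

.CSQ_CLASSES <- c("missense", "nonsense", "splice_junction", "other")

#' HomCohort: a case-control genotype matrix for homozygous-burden analysis
#'
#' `HomCohort` extends [SummarizedExperiment::RangedSummarizedExperiment].
#' Rows are biallelic variants, columns are subjects. Four assays hold the
#' per-call data the quality filters operate on:
#' \describe{
#'   \item{GT}{integer alt-allele count in \{0, 1, 2\}; `NA` marks a missing
#'     (filtered or uncalled) genotype}
#'   \item{GQ}{phred-scaled genotype quality}
#'   \item{RD}{reference-allele read depth}
#'   \item{AD}{alternate-allele read depth}
#' }
#' `rowRanges()` carries the variant annotations consumed by the category
#' classifier (`gene`, `csqClass`, `cadd`, `popmaxAF`, `isIndel`, `ref`,
#' `alt`), and `colData()$group` labels each subject `"case"` or
#' `"control"`.
#'
#' @seealso [HomCohort()] for construction, [runQC()], [classifyVariants()],
#'   [burdenTest()].
#' @aliases HomCohort-class
#' @exportClass HomCohort
setClass("HomCohort", contains = "RangedSummarizedExperiment")

setValidity("HomCohort", function(object) {
    msg <- character()
    need <- c("GT", "GQ", "RD", "AD")
    if (!all(need %in% assayNames(object)))
        msg <- c(msg, paste("assays must include", paste(need, collapse = ", ")))
    if (!"group" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    else if (!all(as.character(object$group) %in% c("case", "control")))
        msg <- c(msg, "subject groups must be 'case' or 'control'")
    rd <- rowData(object)
    needCols <- c("gene", "csqClass", "cadd", "popmaxAF", "isIndel",
                  "ref", "alt")
    missing <- setdiff(needCols, colnames(rd))
    if (length(missing))
        msg <- c(msg, paste("rowData lacks column(s):",
                            paste(missing, collapse = ", ")))
    if ("csqClass" %in% colnames(rd) &&
        !all(rd$csqClass %in% .CSQ_CLASSES | is.na(rd$csqClass)))
        msg <- c(msg, paste("csqClass values must be one of",
                            paste(.CSQ_CLASSES, collapse = "|")))
    if ("popmaxAF" %in% colnames(rd)) {
        af <- rd$popmaxAF
        if (any(!is.na(af) & (af < 0 | af > 1)))
            msg <- c(msg, "popmaxAF must lie in [0, 1]")
    }
    if ("cadd" %in% colnames(rd) && any(!is.na(rd$cadd) & rd$cadd < 0))
        msg <- c(msg, "cadd must be non-negative")
    if ("GT" %in% assayNames(object)) {
        rng <- suppressWarnings(range(assay(object, "GT"), na.rm = TRUE))
        if (is.finite(rng[1L]) && (rng[1L] < 0L || rng[2L] > 2L))
            msg <- c(msg, "GT values must be 0, 1, 2 or NA")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a HomCohort from genotype matrices and annotations
#'
#' @param genotype integer matrix (variants x subjects) of alt-allele counts
#'   in \{0, 1, 2\}, `NA` for missing calls.
#' @param gq,refDepth,altDepth numeric matrices of the same dimension:
#'   phred genotype quality and ref/alt read depths. May be `NA` where the
#'   source data lacks the field.
#' @param variants `data.frame` (or `DataFrame`) with one row per variant
#'   and columns `chrom`, `pos`, `ref`, `alt`, `gene`, `csqClass`, `cadd`,
#'   `popmaxAF`, `isIndel`.
#' @param subjects `data.frame` with columns `id` and `group`
#'   (`"case"`/`"control"`), one row per subject.
#'
#' @return a validated [HomCohort-class] object.
#' @examples
#' v <- data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "T",
#'                 gene = "G000001", csqClass = "missense", cadd = 25,
#'                 popmaxAF = 0, isIndel = FALSE)
#' s <- data.frame(id = c("case_1", "ctrl_1"),
#'                 group = c("case", "control"))
#' gt <- matrix(c(2L, 0L), nrow = 1)
#' co <- HomCohort(gt, gq = matrix(60, 1, 2), refDepth = matrix(0, 1, 2),
#'                 altDepth = matrix(30, 1, 2), variants = v, subjects = s)
#' co
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
#' @export
HomCohort <- function(genotype, gq, refDepth, altDepth, variants, subjects) {
    genotype <- as.matrix(genotype)
    storage.mode(genotype) <- "integer"
    nv <- nrow(genotype); ns <- ncol(genotype)
    fixDim <- function(m) {
        m <- as.matrix(m)
        if (!identical(dim(m), c(nv, ns)))
            stop("all assay matrices must share the genotype dimensions")
        m
    }
    gq <- fixDim(gq); refDepth <- fixDim(refDepth); altDepth <- fixDim(altDepth)
    variants <- as.data.frame(variants)
    subjects <- as.data.frame(subjects)
    if (nrow(variants) != nv)
        stop("'variants' must have one row per genotype row")
    if (nrow(subjects) != ns)
        stop("'subjects' must have one row per genotype column")
    if (nv > 0) {
        rr <- GRanges(seqnames = as.character(variants$chrom),
                      ranges = IRanges(start = as.integer(variants$pos),
                                       width = nchar(as.character(variants$ref))))
    } else {
        rr <- GRanges()
    }
    keep <- setdiff(colnames(variants), c("chrom", "pos", "id"))
    S4Vectors::mcols(rr) <- DataFrame(variants[, keep, drop = FALSE])
    vid <- if (!is.null(variants$id)) as.character(variants$id) else
        sprintf("v%06d", seq_len(nv))
    names(rr) <- vid
    dimnames(genotype) <- list(vid, subjects$id)
    cd <- DataFrame(group = factor(as.character(subjects$group),
                                   levels = c("case", "control")),
                    row.names = subjects$id)
    se <- SummarizedExperiment(
        assays = list(GT = genotype, GQ = gq, RD = refDepth, AD = altDepth),
        rowRanges = rr, colData = cd)
    new("HomCohort", se)
}

#' @describeIn HomCohort genotype (alt-allele count) matrix.
#' @param x a `HomCohort`.
#' @export
genotypes <- function(x) assay(x, "GT")

#' @describeIn HomCohort genotype-quality matrix.
#' @export
genoQual <- function(x) assay(x, "GQ")

#' @describeIn HomCohort reference-allele read-depth matrix.
#' @export
refDepth <- function(x) assay(x, "RD")

#' @describeIn HomCohort alternate-allele read-depth matrix.
#' @export
altDepth <- function(x) assay(x, "AD")

#' @describeIn HomCohort subject group factor (case/control).
#' @export
subjectGroups <- function(x) x$group

#' @describeIn HomCohort gene symbol of each variant.
#' @export
variantGenes <- function(x) as.character(rowData(x)$gene)

#' @describeIn HomCohort bookkeeping record of the synthetic generator
#'   (`NULL` for cohorts that were not simulated).
#' @export
truthRecord <- function(x) S4Vectors::metadata(x)$truth

setMethod("show", "HomCohort", function(object) {
    grp <- table(object$group)
    cat(sprintf("HomCohort: %d variants x %d subjects (%d cases, %d controls)\n",
                nrow(object), ncol(object),
                grp[["case"]], grp[["control"]]))
    if (nrow(object)) {
        rd <- rowData(object)
        cat(sprintf("  genes: %d | indels: %d | csq: %s\n",
                    length(unique(rd$gene)), sum(rd$isIndel),
                    paste(names(table(rd$csqClass)), collapse = "/")))
    }
    qc <- S4Vectors::metadata(object)$qcSummary
    if (!is.null(qc))
        cat(sprintf("  QC applied: %d call(s) invalidated, see qcSummary()\n",
                    sum(qc$n_calls_invalidated)))
})

#' BurdenResult: homozygous-carrier counts and one-tailed Fisher p
#'
#' Produced by [burdenTest()] and [complementBurden()]. Carrier counts are
#' subject-level (a subject counts once however many qualifying homozygous
#' genotypes it carries), percentages are `100 * hom / total`, and `fisherP`
#' is the upper-tail hypergeometric probability of at least the observed
#' number of carrier cases given the margins.
#'
#' @aliases BurdenResult-class
#' @exportClass BurdenResult
setClass("BurdenResult", representation(
    caseHom = "integer", caseTotal = "integer",
    controlHom = "integer", controlTotal = "integer",
    casePct = "numeric", controlPct = "numeric",
    fisherP = "numeric", category = "character", geneSetName = "character"))

setValidity("BurdenResult", function(object) {
    msg <- character()
    if (object@caseHom < 0L || object@caseHom > object@caseTotal)
        msg <- c(msg, "caseHom must lie in [0, caseTotal]")
    if (object@controlHom < 0L || object@controlHom > object@controlTotal)
        msg <- c(msg, "controlHom must lie in [0, controlTotal]")
    if (object@fisherP <= 0 || object@fisherP > 1)
        msg <- c(msg, "fisherP must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' @describeIn BurdenResult carrier counts as a named integer vector
#'   (`caseHom`, `caseTotal`, `controlHom`, `controlTotal`).
#' @param object a `BurdenResult`.
#' @export
carrierCounts <- function(object) {
    c(caseHom = object@caseHom, caseTotal = object@caseTotal,
      controlHom = object@controlHom, controlTotal = object@controlTotal)
}

#' @describeIn BurdenResult the one-tailed Fisher exact p-value.
#' @export
fisherP <- function(object) object@fisherP

setMethod("show", "BurdenResult", function(object) {
    cat(sprintf(
        "BurdenResult [%s | %s]\n  cases:    %d / %d (%.2f%%)\n  controls: %d / %d (%.2f%%)\n  one-tailed Fisher p = %.4g\n",
        object@geneSetName, object@category,
        object@caseHom, object@caseTotal, object@casePct,
        object@controlHom, object@controlTotal, object@controlPct,
        object@fisherP))
})

#' NullDistribution: random-gene-set empirical null for the burden statistic
#'
#' Produced by [simulateNull()]. Each replicate draws a gene set of
#' `setSize` genes uniformly without replacement from the cohort's gene
#' universe and records the case-minus-control difference in
#' homozygous-carrier frequency (proportions, not percentages).
#'
#' @aliases NullDistribution-class
#' @exportClass NullDistribution
setClass("NullDistribution", representation(
    diffs = "numeric", observedDiff = "numeric",
    nSims = "integer", setSize = "integer", seed = "integer",
    category = "character"))

setValidity("NullDistribution", function(object) {
    if (length(object@diffs) != object@nSims)
        return("length(diffs) must equal nSims")
    TRUE
})

#' @describeIn NullDistribution per-replicate frequency differences.
#' @param object a `NullDistribution`.
#' @export
nullDiffs <- function(object) object@diffs

#' @describeIn NullDistribution the target gene set's observed difference.
#' @export
observedDiff <- function(object) object@observedDiff

setMethod("show", "NullDistribution", function(object) {
    p <- empiricalP(object)
    cat(sprintf(
        "NullDistribution: %d replicates of %d-gene sets (seed %d)\n  observed diff = %.4g | empirical p = %.4g (corrected %.4g)\n",
        object@nSims, object@setSize, object@seed,
        object@observedDiff, p[["raw"]], p[["corrected"]]))
})

#' AnovaLSD: one-way ANOVA with Fisher's LSD post hoc
#'
#' Produced by [anovaRaw()] and [anovaFromSummary()]. `lsdP` is the
#' symmetric matrix of unadjusted pairwise LSD p-values computed with the
#' pooled within-group mean square.
#'
#' @aliases AnovaLSD-class
#' @exportClass AnovaLSD
setClass("AnovaLSD", representation(
    fStat = "numeric", dfBetween = "integer", dfWithin = "integer",
    pValue = "numeric", msWithin = "numeric",
    groups = "data.frame", lsdP = "matrix", degenerate = "logical"))

setValidity("AnovaLSD", function(object) {
    msg <- character()
    if (object@dfBetween != nrow(object@groups) - 1L)
        msg <- c(msg, "dfBetween must equal number of groups minus one")
    if (!isTRUE(all.equal(object@lsdP, t(object@lsdP))))
        msg <- c(msg, "lsdP must be symmetric")
    if (any(abs(diag(object@lsdP) - 1) > 1e-12))
        msg <- c(msg, "lsdP must have unit diagonal")
    if (length(msg)) msg else TRUE
})

setMethod("show", "AnovaLSD", function(object) {
    cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
                object@dfBetween, object@dfWithin, object@fStat,
                object@pValue,
                if (object@degenerate) "  [degenerate: zero within-group variance]" else ""))
    cat("Groups:\n")
    print(object@groups, row.names = FALSE)
    cat("Fisher LSD pairwise p-values:\n")
    print(round(object@lsdP, 4))
})
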