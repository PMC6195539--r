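#' Dataset minor allele frequency
#'
#' Minor allele frequency of each variant computed over the non-missing
#' calls of cases and controls combined: the alt-allele frequency folded to
#' the minor side, so the result lies in \[0, 0.5\]. Variants with zero
#' non-missing calls get `NA` and are flagged with a warning; the category
#' classifier excludes them.
#'
#' @param x a QC'd [HomCohort-class].
#' @return numeric vector, one frequency per variant.
#' @examples
#' # 15 alt alleles among 2 x 10,055 called alleles: MAF 7.46e-04
#' @export
datasetMAF <- function(x) {
    stopifnot(is(x, "HomCohort"))
    gt <- genotypes(x)
    called <- rowSums(!is.na(gt))
    af <- rowSums(gt, na.rm = TRUE) / (2 * called)
    maf <- pmin(af, 1 - af)
    if (any(called == 0)) {
        warning(sum(called == 0),
                " variant(s) have no non-missing calls; MAF set to NA")
        maf[called == 0] <- NA_real_
    }
    unname(maf)
}

#' Likely disruptive variant rule
#'
#' A variant is likely disruptive if it is a missense substitution with
#' CADD phred strictly above `caddMin`, a nonsense substitution, or a
#' splice-junction variant (within 3 bp of an exon/intron boundary, as
#' annotated upstream). `rule = "strictSplice"` additionally requires
#' splice-junction variants to pass the CADD cutoff — a defensible stricter
#' reading whose consequences differ for low-CADD splice variants; both
#' readings are exposed and neither is silently preferred.
#'
#' @param csqClass character vector of consequence classes
#'   (`missense|nonsense|splice_junction|other`).
#' @param cadd numeric vector of CADD phred scores.
#' @param caddMin CADD cutoff (strict `>`).
#' @param rule `"asStated"` (default) or `"strictSplice"`.
#' @return logical vector. Unknown consequence classes yield `FALSE` with
#'   a warning.
#' @export
isLikelyDisruptive <- function(csqClass, cadd, caddMin = 20,
                               rule = c("asStated", "strictSplice")) {
    rule <- match.arg(rule)
    unknown <- !csqClass %in% .CSQ_CLASSES
    if (any(unknown))
        warning(sum(unknown), " unknown consequence class(es) treated as",
                " not disruptive")
    caddOK <- !is.na(cadd) & cadd > caddMin
    out <- switch(rule,
        asStated = (csqClass == "missense" & caddOK) |
            csqClass == "nonsense" | csqClass == "splice_junction",
        strictSplice = (csqClass %in% c("missense", "splice_junction") &
            caddOK) | csqClass == "nonsense")
    out & !unknown
}

#' Assign nested rarity/impact categories
#'
#' Four nested categories (strict `<` thresholds throughout):
#' \describe{
#'   \item{A}{dataset MAF below `datasetMafMax` (ultra-rare in the cohort)}
#'   \item{B}{A, and population MAF below `popRareMax` (rare in all
#'     reference populations)}
#'   \item{C}{A, and population MAF below `popUltraRareMax`}
#'   \item{D}{C, and likely disruptive per [isLikelyDisruptive()]}
#' }
#' so membership nests D \eqn{\subseteq} C \eqn{\subseteq} B
#' \eqn{\subseteq} A. Classification is a pure function of
#' (dataset MAF, population MAF, consequence class, CADD).
#'
#' @param datasetMaf,popmaxAf,csqClass,cadd per-variant vectors.
#' @param datasetMafMax,popRareMax,popUltraRareMax,caddMin thresholds;
#'   defaults 0.001, 0.01, 0.001 and 20.
#' @param rule likely-disruptive rule, see [isLikelyDisruptive()].
#' @return logical matrix with columns `A`, `B`, `C`, `D`.
#' @export
assignCategories <- function(datasetMaf, popmaxAf, csqClass, cadd,
                             datasetMafMax = 0.001, popRareMax = 0.01,
                             popUltraRareMax = 0.001, caddMin = 20,
                             rule = c("asStated", "strictSplice")) {
    rule <- match.arg(rule)
    A <- !is.na(datasetMaf) & datasetMaf < datasetMafMax
    B <- A & !is.na(popmaxAf) & popmaxAf < popRareMax
    C <- A & !is.na(popmaxAf) & popmaxAf < popUltraRareMax
    D <- C & isLikelyDisruptive(csqClass, cadd, caddMin, rule)
    cbind(A = A, B = B, C = C, D = D)
}

#' Classify the variants of a cohort
#'
#' Computes [datasetMAF()] and stores it together with the
#' [assignCategories()] membership columns (`datasetMAF`, `catA` ...
#' `catD`) in `rowData(x)`, for [burdenTest()] and [simulateNull()] to
#' consume.
#'
#' @inheritParams assignCategories
#' @param x a QC'd [HomCohort-class].
#' @return `x` with classification columns added; the thresholds and rule
#'   used are recorded in `metadata(x)$classification`.
#' @export
classifyVariants <- function(x, datasetMafMax = 0.001, popRareMax = 0.01,
                             popUltraRareMax = 0.001, caddMin = 20,
                             rule = c("asStated", "strictSplice")) {
    rule <- match.arg(rule)
    rd <- rowData(x)
    dm <- datasetMAF(x)
    cats <- assignCategories(dm, rd$popmaxAF, rd$csqClass, rd$cadd,
                             datasetMafMax, popRareMax, popUltraRareMax,
                             caddMin, rule)
    rowData(x)$datasetMAF <- dm
    rowData(x)$catA <- cats[, "A"]
    rowData(x)$catB <- cats[, "B"]
    rowData(x)$catC <- cats[, "C"]
    rowData(x)$catD <- cats[, "D"]
    S4Vectors::metadata(x)$classification <- list(
        datasetMafMax = datasetMafMax, popRareMax = popRareMax,
        popUltraRareMax = popUltraRareMax, caddMin = caddMin, rule = rule)
    x
}

#' Export the classified-variants table
#'
#' @param x a classified `HomCohort`.
#' @return `data.frame` with one row per variant: id, gene, consequence
#'   class, CADD, dataset MAF, population MAF and the category letters.
#' @export
classifiedVariants <- function(x) {
    rd <- rowData(x)
    if (is.null(rd$datasetMAF))
        stop("run classifyVariants() first")
    cats <- cbind(A = rd$catA, B = rd$catB, C = rd$catC, D = rd$catD)
    data.frame(
        variant_id = rownames(x), gene = rd$gene, csq_class = rd$csqClass,
        cadd = rd$cadd, dataset_maf = rd$datasetMAF,
        popmax_af = rd$popmaxAF,
        categories = apply(cats, 1L, function(z)
            paste(colnames(cats)[z], collapse = "")),
        row.names = NULL)
}

#' Bundled table of homozygous rare variants in GABA-system genes
#'
#' The six homozygous rare variants observed in GABA-system genes in a
#' large schizophrenia case-control exome screen, transcribed verbatim
#' from the published summary table: genomic position, affected/unaffected
#' homozygote counts, gene, consequence class, cDNA and amino-acid change,
#' dataset MAF with the number of called individuals, maximum population
#' allele frequency and CADD phred. Serves as a worked example and as the
#' fixture behind the category-count checks. (One row carries a CADD of
#' 0.03 with a missense label; it is reproduced as printed, without
#' correction.)
#'
#' @return a `data.frame` with 6 rows.
#' @examples
#' exampleHomVariants()
#' @export
exampleHomVariants <- function() {
    path <- system.file("extdata", "gaba_hom_variants.tsv",
                        package = "homburden", mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Expand a homozygote summary table into a full cohort
#'
#' Builds a [HomCohort-class] that reproduces a published per-variant
#' summary: each row places its affected/unaffected homozygotes in the
#' case/control groups, the remaining alt alleles (to match the printed
#' dataset MAF at the printed number of called individuals) are placed as
#' heterozygous control calls, and uncalled individuals become missing
#' genotypes. Homozygotes of different variants land on different
#' subjects, so subject-level carrier counts equal the column sums of the
#' table. The construction is deterministic.
#'
#' @param tab a `data.frame` in the layout of [exampleHomVariants()].
#' @param nCases,nControls cohort totals.
#' @return a `HomCohort`.
#' @export
cohortFromVariantTable <- function(tab, nCases = 4225L, nControls = 5834L) {
    nv <- nrow(tab)
    ns <- nCases + nControls
    stopifnot(all(tab$n_affected_hom <= nCases),
              all(tab$n_unaffected_hom <= nControls),
              all(tab$n_individuals <= ns))
    gt <- matrix(0L, nv, ns)
    gq <- matrix(60, nv, ns)
    rdm <- matrix(30, nv, ns)
    adm <- matrix(0, nv, ns)
    caseOffset <- 0L
    for (i in seq_len(nv)) {
        altTotal <- round(2 * tab$n_individuals[i] * tab$dataset_maf[i])
        nA <- tab$n_affected_hom[i]; nU <- tab$n_unaffected_hom[i]
        homCase <- if (nA > 0) caseOffset + seq_len(nA) else integer(0)
        caseOffset <- caseOffset + nA  # distinct carriers across variants
        homCtrl <- if (nU > 0) nCases + seq_len(nU) else integer(0)
        nHet <- altTotal - 2L * (nA + nU)
        stopifnot(nHet >= 0)
        hetCtrl <- if (nHet > 0) nCases + nU + seq_len(nHet) else integer(0)
        nMiss <- ns - tab$n_individuals[i]
        missIdx <- if (nMiss > 0) ns - seq_len(nMiss) + 1L else integer(0)
        gt[i, homCase] <- 2L; gt[i, homCtrl] <- 2L; gt[i, hetCtrl] <- 1L
        gt[i, missIdx] <- NA_integer_
        hom <- c(homCase, homCtrl)
        rdm[i, hom] <- 0; adm[i, hom] <- 30
        rdm[i, hetCtrl] <- 15; adm[i, hetCtrl] <- 15
        gq[i, missIdx] <- NA
    }
    variants <- data.frame(
        chrom = tab$chrom, pos = tab$pos,
        ref = tab$ref, alt = tab$alt, gene = tab$gene,
        csqClass = tab$csq_class, cadd = tab$cadd,
        popmaxAF = tab$popmax_af, isIndel = FALSE)
    subjects <- data.frame(
        id = c(sprintf("case_%05d", seq_len(nCases)),
               sprintf("ctrl_%05d", seq_len(nControls))),
        group = rep(c("case", "control"), c(nCases, nControls)))
    HomCohort(gt, gq, rdm, adm, variants, subjects)
}
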