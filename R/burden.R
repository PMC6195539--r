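.categoryMask <- function(x, category) {
    if (is.null(category)) return(rep(TRUE, nrow(x)))
    category <- match.arg(category, c("A", "B", "C", "D"))
    col <- paste0("cat", category)
    m <- rowData(x)[[col]]
    if (is.null(m))
        stop("cohort is not classified; run classifyVariants() first")
    m
}

#' Count homozygous carriers of qualifying variants
#'
#' A subject is a carrier if it is homozygous-alt for at least one variant
#' that lies in a gene of `genes` and belongs to the requested rarity
#' category; each subject counts at most once (subject-level collapsing).
#'
#' @param x a QC'd, classified [HomCohort-class].
#' @param genes character vector of gene symbols (case-sensitive).
#' @param category one of `"A"`, `"B"`, `"C"`, `"D"`, or `NULL` to qualify
#'   every variant regardless of rarity (used by reduced-scale analyses in
#'   which the full-scale MAF threshold would leave no qualifying
#'   homozygote; see the package vignette).
#' @return named integer vector `caseHom`, `caseTotal`, `controlHom`,
#'   `controlTotal`. A gene set disjoint from the cohort's genes yields
#'   zero carriers with a warning.
#' @export
countHomCarriers <- function(x, genes, category = NULL) {
    stopifnot(is(x, "HomCohort"))
    grp <- as.character(x$group)
    tot <- c(caseTotal = sum(grp == "case"),
             controlTotal = sum(grp == "control"))
    inSet <- variantGenes(x) %in% genes
    if (!any(inSet) && length(genes))
        warning("gene set shares no genes with the cohort")
    rows <- which(inSet & .categoryMask(x, category))
    if (!length(rows))
        return(c(caseHom = 0L, caseTotal = tot[["caseTotal"]],
                 controlHom = 0L, controlTotal = tot[["controlTotal"]]))
    gt <- genotypes(x)[rows, , drop = FALSE]
    carrier <- colSums(gt == 2L, na.rm = TRUE) > 0
    c(caseHom = sum(carrier & grp == "case"),
      caseTotal = tot[["caseTotal"]],
      controlHom = sum(carrier & grp == "control"),
      controlTotal = tot[["controlTotal"]])
}

#' One-tailed Fisher exact test for carrier enrichment in cases
#'
#' Upper-tail probability, under the hypergeometric distribution with the
#' table's margins fixed, of observing at least the given number of
#' carrier cases — the one-sided Fisher exact test with the direction
#' fixed as enrichment in cases. With zero control carriers this equals
#' the closed form \eqn{\prod_{i=0}^{a-1} (n_1 - i) / (N - i)} where
#' \eqn{a} is the case-carrier count, \eqn{n_1} the number of cases and
#' \eqn{N} the total sample size.
#'
#' @param caseHom,caseTotal,controlHom,controlTotal the 2x2 carrier
#'   counts; alternatively pass the named vector from
#'   [countHomCarriers()] as `caseHom`.
#' @return the p-value in (0, 1\].
#' @examples
#' fisherOneTailed(6, 4225, 0, 5834)   # 0.0055
#' @export
fisherOneTailed <- function(caseHom, caseTotal = NULL, controlHom = NULL,
                            controlTotal = NULL) {
    if (is.null(caseTotal) && length(caseHom) == 4L) {
        counts <- caseHom
        caseHom <- counts[["caseHom"]]; caseTotal <- counts[["caseTotal"]]
        controlHom <- counts[["controlHom"]]
        controlTotal <- counts[["controlTotal"]]
    }
    if (caseTotal <= 0 || controlTotal <= 0)
        stop("degenerate margins: both groups must be non-empty")
    if (caseHom < 0 || caseHom > caseTotal ||
        controlHom < 0 || controlHom > controlTotal)
        stop("carrier counts must lie within the group totals")
    K <- caseHom + controlHom
    stats::phyper(caseHom - 1, caseTotal, controlTotal, K,
                  lower.tail = FALSE)
}

.burdenResult <- function(counts, p, category, name) {
    new("BurdenResult",
        caseHom = as.integer(counts[["caseHom"]]),
        caseTotal = as.integer(counts[["caseTotal"]]),
        controlHom = as.integer(counts[["controlHom"]]),
        controlTotal = as.integer(counts[["controlTotal"]]),
        casePct = .pct(counts[["caseHom"]], counts[["caseTotal"]]),
        controlPct = .pct(counts[["controlHom"]], counts[["controlTotal"]]),
        fisherP = p, category = category, geneSetName = name)
}

#' Homozygous-burden test for a gene set
#'
#' Counts homozygous carriers of qualifying variants per group
#' ([countHomCarriers()]) and tests for enrichment in cases with the
#' one-tailed Fisher exact test ([fisherOneTailed()]).
#'
#' @inheritParams countHomCarriers
#' @param geneSetName label stored in the result.
#' @return a [BurdenResult-class].
#' @export
burdenTest <- function(x, genes, category = NULL,
                       geneSetName = "gene_set") {
    counts <- countHomCarriers(x, genes, category)
    .burdenResult(counts, fisherOneTailed(counts),
                  if (is.null(category)) "all" else category, geneSetName)
}

#' Genome-complement burden test
#'
#' The control analysis: the same burden test computed over every gene of
#' the cohort \emph{not} in the excluded set, to check that a target-set
#' signal is not a genome-wide excess of homozygous carriers among cases.
#'
#' @inheritParams countHomCarriers
#' @param excludeGenes gene symbols to leave out.
#' @return a [BurdenResult-class].
#' @export
complementBurden <- function(x, excludeGenes, category = NULL) {
    rest <- setdiff(unique(variantGenes(x)), excludeGenes)
    counts <- if (length(rest)) countHomCarriers(x, rest, category)
        else c(caseHom = 0L, caseTotal = sum(x$group == "case"),
               controlHom = 0L, controlTotal = sum(x$group == "control"))
    .burdenResult(counts, fisherOneTailed(counts),
                  if (is.null(category)) "all" else category, "complement")
}

#' Power of the one-tailed Fisher exact test
#'
#' Probability that the one-tailed Fisher p-value falls below `alpha` when
#' the case and control carrier counts are drawn binomially at the given
#' carrier frequencies. `method = "exact"` sums the joint binomial
#' probability over the rejection region (enumerating the carrier counts
#' up to a negligible tail mass of 1e-12); `method = "montecarlo"` uses
#' seeded binomial replicates.
#'
#' @param pCase,pControl true carrier frequencies in \[0, 1\].
#' @param nCase,nControl group sizes.
#' @param alpha significance level in (0, 1).
#' @param method `"exact"` or `"montecarlo"`.
#' @param nSims,seed Monte Carlo settings.
#' @return the power in \[0, 1\].
#' @examples
#' fisherPower(3 / 4225, 0, 4225, 5834)   # about 0.35
#' @export
fisherPower <- function(pCase, pControl, nCase, nControl, alpha = 0.05,
                        method = c("exact", "montecarlo"),
                        nSims = 1e5, seed = 1L) {
    method <- match.arg(method)
    .assertScalar(pCase, "pCase", min = 0, max = 1)
    .assertScalar(pControl, "pControl", min = 0, max = 1)
    .assertScalar(nCase, "nCase", min = 1, integer = TRUE)
    .assertScalar(nControl, "nControl", min = 1, integer = TRUE)
    if (alpha <= 0 || alpha >= 1)
        stop("invalid 'alpha': must lie in (0, 1)")
    if (method == "exact") {
        aMax <- stats::qbinom(1 - 1e-12, nCase, pCase)
        cMax <- stats::qbinom(1 - 1e-12, nControl, pControl)
        a <- 0:aMax; cc <- 0:cMax
        pa <- stats::dbinom(a, nCase, pCase)
        pc <- stats::dbinom(cc, nControl, pControl)
        A <- matrix(a, length(a), length(cc))
        C <- matrix(cc, length(a), length(cc), byrow = TRUE)
        pv <- stats::phyper(A - 1, nCase, nControl, A + C,
                            lower.tail = FALSE)
        sum(outer(pa, pc)[pv <= alpha])
    } else {
        .withSeed(seed, {
            A <- stats::rbinom(nSims, nCase, pCase)
            C <- stats::rbinom(nSims, nControl, pControl)
            pv <- stats::phyper(A - 1, nCase, nControl, A + C,
                                lower.tail = FALSE)
            mean(pv <= alpha)
        })
    }
}
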