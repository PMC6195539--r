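# shared builders for small hand-constructed cohorts

# a cohort from explicit matrices with sensible annotation defaults
makeCohort <- function(gt, gq = NULL, rd = NULL, ad = NULL,
                       genes = NULL, csqClass = NULL, cadd = NULL,
                       popmaxAF = NULL, isIndel = NULL,
                       nCases = NULL) {
    gt <- as.matrix(gt)
    nv <- nrow(gt); ns <- ncol(gt)
    if (is.null(nCases)) nCases <- ceiling(ns / 2)
    if (is.null(gq)) gq <- matrix(60, nv, ns)
    if (is.null(rd)) {
        rd <- matrix(30, nv, ns); rd[gt == 2L] <- 0; rd[gt == 1L] <- 15
    }
    if (is.null(ad)) {
        ad <- matrix(0, nv, ns); ad[gt == 2L] <- 30; ad[gt == 1L] <- 15
    }
    fill <- function(x, default) {
        if (is.null(x)) x <- default
        rep(x, length.out = nv)
    }
    variants <- data.frame(
        chrom = fill(NULL, "chr1"), pos = seq_len(nv) * 100L,
        ref = fill(NULL, "A"), alt = fill(NULL, "T"),
        gene = fill(genes, sprintf("G%06d", seq_len(nv))),
        csqClass = fill(csqClass, "missense"),
        cadd = fill(cadd, 25),
        popmaxAF = fill(popmaxAF, 0),
        isIndel = fill(isIndel, FALSE))
    subjects <- data.frame(
        id = c(sprintf("case_%03d", seq_len(nCases)),
               sprintf("ctrl_%03d", seq_len(ns - nCases))),
        group = rep(c("case", "control"), c(nCases, ns - nCases)))
    HomCohort(gt, gq, rd, ad, variants, subjects)
}

smallConfig <- function(..., seed = 1) {
    cohortConfig(nCases = 50, nControls = 50, nGenes = 40,
                 variantsPerGene = 2, targetSetSize = 8, seed = seed, ...)
}

# independent brute-force one-tailed Fisher p: enumerate the full
# hypergeometric support from binomial coefficients
bruteFisher <- function(a, n1, c, n2) {
    K <- a + c; N <- n1 + n2
    support <- max(0, K - n2):min(K, n1)
    probs <- choose(n1, support) * choose(n2, K - support) / choose(N, K)
    sum(probs[support >= a])
}
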