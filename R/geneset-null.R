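#' Random-gene-set empirical null for the homozygous-burden statistic
#'
#' Draws `nSims` gene sets of `setSize` genes uniformly without
#' replacement from the cohort's gene universe (every gene present in the
#' matrix, including genes that can never contribute a carrier), computes
#' for each the case-minus-control difference in homozygous-carrier
#' frequency (proportions), and records the observed difference of the
#' target gene set. Replicates are independent draws, so sets may overlap
#' across replicates. Fully reproducible under a fixed seed.
#'
#' @inheritParams countHomCarriers
#' @param targetGenes the gene set whose observed difference is evaluated
#'   against the null.
#' @param setSize genes per replicate set (default: size of
#'   `targetGenes`).
#' @param nSims number of replicate sets.
#' @param seed integer RNG seed.
#' @return a [NullDistribution-class].
#' @seealso [empiricalP()]
#' @export
simulateNull <- function(x, targetGenes, category = NULL,
                         setSize = length(targetGenes), nSims = 5000L,
                         seed = 1L) {
    stopifnot(is(x, "HomCohort"))
    universe <- unique(variantGenes(x))
    .assertScalar(setSize, "setSize", min = 1, integer = TRUE)
    .assertScalar(nSims, "nSims", min = 1, integer = TRUE)
    if (setSize > length(universe))
        stop("setSize exceeds the gene universe (", length(universe),
             " genes)")
    grp <- as.character(x$group)
    isCase <- grp == "case"
    nCase <- sum(isCase); nCtrl <- sum(!isCase)

    qual <- which(.categoryMask(x, category))
    gt <- genotypes(x)[qual, , drop = FALSE]
    homIdx <- which(!is.na(gt) & gt == 2L, arr.ind = TRUE)
    geneOf <- variantGenes(x)[qual]
    # per-gene lists of distinct carrier subjects, split by group
    carriers <- lapply(
        split(homIdx[, 2L], geneOf[homIdx[, 1L]]), unique)

    freqDiff <- function(genes) {
        subj <- unique(unlist(carriers[genes], use.names = FALSE))
        if (!length(subj)) return(0)
        nc <- sum(isCase[subj])
        nc / nCase - (length(subj) - nc) / nCtrl
    }
    observed <- freqDiff(intersect(targetGenes, names(carriers)))
    diffs <- .withSeed(seed, vapply(seq_len(nSims), function(i) {
        freqDiff(intersect(sample(universe, setSize), names(carriers)))
    }, 0))
    new("NullDistribution", diffs = diffs, observedDiff = observed,
        nSims = as.integer(nSims), setSize = as.integer(setSize),
        seed = as.integer(seed),
        category = if (is.null(category)) "all" else category)
}

#' Empirical p-value of a null distribution
#'
#' Fraction of replicate gene sets whose case-minus-control carrier
#' frequency difference is greater than \emph{or equal to} the observed
#' difference (inclusive tie handling). The raw fraction (denominator
#' `nSims`) is the primary value; the `(count + 1) / (nSims + 1)`
#' correction, which can never be exactly zero, is reported alongside.
#'
#' @param dist a [NullDistribution-class].
#' @param observed override the stored observed difference.
#' @return named numeric vector with elements `raw` and `corrected`.
#' @export
empiricalP <- function(dist, observed = observedDiff(dist)) {
    stopifnot(is(dist, "NullDistribution"))
    if (!length(dist@diffs)) stop("empty null distribution")
    n <- length(dist@diffs)
    k <- sum(dist@diffs >= observed)
    c(raw = k / n, corrected = (k + 1) / (n + 1))
}

#' Export a null distribution
#'
#' Writes the per-replicate differences as TSV (columns `replicate`,
#' `diff`) and a JSON summary (observed difference, raw and corrected
#' empirical p, seed, number of replicates, set size).
#'
#' @param dist a [NullDistribution-class].
#' @param tsvPath,jsonPath output paths (`NULL` skips either file).
#' @return invisibly, the summary list.
#' @export
writeNullDistribution <- function(dist, tsvPath = NULL, jsonPath = NULL) {
    p <- empiricalP(dist)
    if (!is.null(tsvPath))
        utils::write.table(
            data.frame(replicate = seq_along(dist@diffs),
                       diff = dist@diffs),
            tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- list(observed_diff = dist@observedDiff,
                    empirical_p = unname(p[["raw"]]),
                    empirical_p_corrected = unname(p[["corrected"]]),
                    seed = dist@seed, n_sims = dist@nSims,
                    set_size = dist@setSize, category = dist@category)
    if (!is.null(jsonPath))
        jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE,
                             digits = NA)
    invisible(summary)
}
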