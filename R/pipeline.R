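#' Read a gene set from a plain-text file
#'
#' One gene symbol per line; blank lines and `#` comments are ignored.
#' Duplicate symbols are collapsed with a warning.
#'
#' @param path file path.
#' @return character vector of unique gene symbols.
#' @export
readGeneSet <- function(path) {
    x <- trimws(readLines(path))
    x <- x[nzchar(x) & !startsWith(x, "#")]
    if (!length(x)) stop("gene set file is empty: ", path)
    if (anyDuplicated(x)) {
        warning("duplicate gene symbols collapsed in ", path)
        x <- unique(x)
    }
    x
}

#' Drop listed subjects from a cohort
#'
#' Removes the subjects named in an exclusion list (e.g. a precomputed
#' ancestry-outlier list) and updates the group totals. Unknown ids are
#' warned about, not fatal.
#'
#' @param x a [HomCohort-class].
#' @param ids character vector of subject ids, or a path to a file with
#'   one id per line.
#' @return the reduced `HomCohort`.
#' @export
applySubjectExclusion <- function(x, ids) {
    stopifnot(is(x, "HomCohort"))
    if (length(ids) == 1L && file.exists(ids)) ids <- readGeneSet(ids)
    if (!length(ids)) return(x)
    unknown <- setdiff(ids, colnames(x))
    if (length(unknown))
        warning(length(unknown), " exclusion id(s) not found in the cohort")
    x[, !colnames(x) %in% ids]
}

#' Run the homozygous-burden screen end to end
#'
#' Composes the full analysis on a cohort: subject exclusion, QC
#' ([runQC()]), variant classification ([classifyVariants()]), the
#' per-category burden test for the target gene set ([burdenTest()]), the
#' random-gene-set simulation null ([simulateNull()]) where the gene
#' universe allows it, and the genome-complement control test
#' ([complementBurden()]).
#'
#' @param x a [HomCohort-class] or a VCF path readable by
#'   [readCohortVcf()].
#' @param targetGenes character vector of gene symbols, or a path for
#'   [readGeneSet()].
#' @param exclude optional subject exclusion list (ids or file path).
#' @param categories which rarity categories to report.
#' @inheritParams classifyVariants
#' @inheritParams runQC
#' @param nSims,setSize simulation-null settings; the null is skipped with
#'   a warning when `setSize` exceeds the cohort's gene universe.
#' @param seed RNG seed for the simulation null.
#' @return a list of class `"burdenScreen"`: `report` (one row per
#'   category: carrier counts, percentages, Fisher p, simulation p),
#'   `burdens` and `nulls` (per-category result objects), `complement`
#'   (a [BurdenResult-class] for category A), `cohort` (the QC'd,
#'   classified cohort) and `config` (all resolved parameters, for audit
#'   reproducibility).
#' @export
runPipeline <- function(x, targetGenes, exclude = NULL,
                        categories = c("A", "B", "C", "D"),
                        gqThreshold = 20, maxRefFraction = 0.05,
                        maxFraction = 0.10, dropIndels = TRUE,
                        datasetMafMax = 0.001, popRareMax = 0.01,
                        popUltraRareMax = 0.001, caddMin = 20,
                        rule = c("asStated", "strictSplice"),
                        nSims = 5000L, setSize = 120L, seed = 1L) {
    rule <- match.arg(rule)
    if (is.character(x) && length(x) == 1L) x <- readCohortVcf(x)
    stopifnot(is(x, "HomCohort"))
    if (is.character(targetGenes) && length(targetGenes) == 1L &&
        file.exists(targetGenes))
        targetGenes <- readGeneSet(targetGenes)
    if (!is.null(exclude)) x <- applySubjectExclusion(x, exclude)
    x <- runQC(x, gqThreshold, maxRefFraction, maxFraction, dropIndels)
    x <- classifyVariants(x, datasetMafMax, popRareMax, popUltraRareMax,
                          caddMin, rule)
    universe <- unique(variantGenes(x))
    doNull <- setSize <= length(universe)
    if (!doNull)
        warning("simulation null skipped: setSize (", setSize,
                ") exceeds the gene universe (", length(universe), ")")
    burdens <- list(); nulls <- list()
    rows <- lapply(categories, function(cat) {
        b <- burdenTest(x, targetGenes, cat, "target_set")
        burdens[[cat]] <<- b
        simP <- NA_real_
        if (doNull) {
            nd <- simulateNull(x, targetGenes, cat, setSize, nSims,
                               seed = seed + match(cat, LETTERS))
            nulls[[cat]] <<- nd
            simP <- unname(empiricalP(nd)[["raw"]])
        }
        data.frame(category = cat,
                   n_case_hom = b@caseHom, pct_case = b@casePct,
                   n_control_hom = b@controlHom, pct_control = b@controlPct,
                   fisher_p = b@fisherP, simulation_p = simP)
    })
    report <- do.call(rbind, rows)
    comp <- complementBurden(x, targetGenes,
                             if ("A" %in% categories) "A" else NULL)
    config <- list(gqThreshold = gqThreshold,
                   maxRefFraction = maxRefFraction,
                   maxFraction = maxFraction, dropIndels = dropIndels,
                   datasetMafMax = datasetMafMax, popRareMax = popRareMax,
                   popUltraRareMax = popUltraRareMax, caddMin = caddMin,
                   rule = rule, nSims = nSims, setSize = setSize,
                   seed = seed, nTargetGenes = length(targetGenes),
                   categories = categories)
    structure(list(report = report, burdens = burdens, nulls = nulls,
                   complement = comp, cohort = x, config = config),
              class = "burdenScreen")
}

#' @export
print.burdenScreen <- function(x, ...) {
    cat("Homozygous-burden screen\n")
    print(x$report, row.names = FALSE, digits = 4)
    cat(sprintf("complement (category %s): %d/%d cases vs %d/%d controls, p = %.4g\n",
                x$complement@category, x$complement@caseHom,
                x$complement@caseTotal, x$complement@controlHom,
                x$complement@controlTotal, x$complement@fisherP))
    invisible(x)
}

#' Write the screen report bundle
#'
#' Emits `burden_report.tsv` (the per-category table), a
#' `null_<category>.tsv` per simulated null, `qc_summary.tsv`, and
#' `manifest.json` holding the resolved configuration, seed and report —
#' everything needed to audit a run. Output is deterministic for a fixed
#' seed.
#'
#' @param screen a `"burdenScreen"` from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeBurdenReport <- function(screen, dir) {
    stopifnot(inherits(screen, "burdenScreen"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(screen$report, file.path(dir, "burden_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (cat in names(screen$nulls))
        writeNullDistribution(screen$nulls[[cat]],
                              file.path(dir, paste0("null_", cat, ".tsv")))
    writeQcSummary(screen$cohort, file.path(dir, "qc_summary.tsv"))
    manifest <- list(config = screen$config,
                     report = screen$report,
                     complement = list(
                         case_hom = screen$complement@caseHom,
                         control_hom = screen$complement@controlHom,
                         fisher_p = screen$complement@fisherP))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}
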