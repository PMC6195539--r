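#' Configuration for the synthetic exome-cohort generator
#'
#' Bundles and validates every knob of [simulateCohort()]. Defaults emulate
#' a large case-control exome dataset: ~18,024 sequenced genes, a
#' per-variant alt-allele frequency spectrum spanning ultra-rare
#' (below 0.001) to moderately common, phred genotype qualities around 60,
#' negative-binomial read depths around 30x, and small rates of injected
#' contamination and low-quality calls that exercise the QC filters.
#'
#' @param nCases,nControls subject counts per group.
#' @param nGenes number of genes; every gene receives at least one variant
#'   so the gene universe for resampling equals the gene list.
#' @param variantsPerGene mean variants per gene (>= 1); per-gene counts
#'   are 1 + Poisson(variantsPerGene - 1).
#' @param mafSpectrum `list(min=, max=)` bounds of a log-uniform per-variant
#'   alt-allele frequency distribution. Must place mass below 0.001
#'   (i.e. `min < 0.001`). `max = 0` degenerates to all-reference genotypes.
#' @param targetSetSize size of the designated target gene set recorded in
#'   the truth record (the set a planted enrichment goes into).
#' @param plantedCaseHomExcess number of case subjects converted into clean
#'   homozygous-alt carriers at an ultra-rare target-set variant; 0 gives an
#'   exchangeable null in which group labels carry no signal.
#' @param gqDistribution `list(mean=, sd=)` of the normal draw for clean-call
#'   GQ, clamped to \[20, 99\] so clean calls never cross the GQ filter.
#' @param depthDistribution `list(mean=, size=)` negative-binomial total read
#'   depth per call.
#' @param contaminationRate fraction of homozygous-alt calls given reference
#'   reads exceeding 5% of depth (the contamination-filter boundary).
#' @param missingRate fraction of calls given GQ below 20.
#' @param indelRate fraction of variants simulated as 1-bp insertions.
#' @param seed integer RNG seed; generation is bit-reproducible given the
#'   full configuration.
#'
#' @return a validated list of class `"CohortConfig"`.
#' @export
cohortConfig <- function(nCases, nControls,
                         nGenes = 18024L,
                         variantsPerGene = 2,
                         mafSpectrum = list(min = 1e-5, max = 0.2),
                         targetSetSize = 120L,
                         plantedCaseHomExcess = 0L,
                         gqDistribution = list(mean = 60, sd = 15),
                         depthDistribution = list(mean = 30, size = 10),
                         contaminationRate = 0.01,
                         missingRate = 0.02,
                         indelRate = 0.02,
                         seed = 1L) {
    .assertScalar(nCases, "nCases", min = 1, integer = TRUE)
    .assertScalar(nControls, "nControls", min = 1, integer = TRUE)
    .assertScalar(nGenes, "nGenes", min = 1, integer = TRUE)
    .assertScalar(variantsPerGene, "variantsPerGene", min = 1)
    .assertScalar(targetSetSize, "targetSetSize", min = 1, integer = TRUE)
    if (targetSetSize > nGenes)
        stop("invalid 'targetSetSize': exceeds nGenes")
    .assertScalar(plantedCaseHomExcess, "plantedCaseHomExcess",
                  min = 0, integer = TRUE)
    if (plantedCaseHomExcess > nCases)
        stop("invalid 'plantedCaseHomExcess': exceeds nCases")
    .assertScalar(mafSpectrum$min, "mafSpectrum$min", min = 0, max = 1)
    .assertScalar(mafSpectrum$max, "mafSpectrum$max", min = 0, max = 1)
    if (mafSpectrum$max > 0 && mafSpectrum$min > mafSpectrum$max)
        stop("invalid 'mafSpectrum': min exceeds max")
    if (mafSpectrum$max > 0 && mafSpectrum$min >= 0.001)
        stop("invalid 'mafSpectrum': must place mass below 0.001")
    .assertScalar(gqDistribution$mean, "gqDistribution$mean", min = 0)
    .assertScalar(gqDistribution$sd, "gqDistribution$sd", min = 0)
    .assertScalar(depthDistribution$mean, "depthDistribution$mean", min = 0)
    .assertScalar(depthDistribution$size, "depthDistribution$size", min = 1e-8)
    .assertScalar(contaminationRate, "contaminationRate", min = 0, max = 1)
    .assertScalar(missingRate, "missingRate", min = 0, max = 1)
    .assertScalar(indelRate, "indelRate", min = 0, max = 1)
    .assertScalar(seed, "seed", integer = TRUE)
    structure(list(
        nCases = as.integer(nCases), nControls = as.integer(nControls),
        nGenes = as.integer(nGenes), variantsPerGene = variantsPerGene,
        mafSpectrum = mafSpectrum, targetSetSize = as.integer(targetSetSize),
        plantedCaseHomExcess = as.integer(plantedCaseHomExcess),
        gqDistribution = gqDistribution,
        depthDistribution = depthDistribution,
        contaminationRate = contaminationRate, missingRate = missingRate,
        indelRate = indelRate, seed = as.integer(seed)),
        class = "CohortConfig")
}

#' Simulate a case-control exome cohort
#'
#' Draws per-variant alt-allele frequencies from the configured spectrum,
#' genotypes under Hardy-Weinberg equilibrium, genotype qualities and read
#' depths from the configured distributions, then injects the configured QC
#' artefacts (low-GQ calls; homozygous-alt calls contaminated with more
#' than 5% reference reads) and, optionally, plants
#' `plantedCaseHomExcess` case subjects as clean homozygous carriers of an
#' ultra-rare variant in the designated target gene set.
#'
#' Clean (non-injected) calls are generated so they cannot cross the QC
#' boundaries: clean GQ is clamped to at least 20 and clean homozygous-alt
#' calls carry at most 5% reference reads. Injected artefacts are therefore
#' exactly the calls QC removes, which makes the returned truth record an
#' exact oracle for filter tests.
#'
#' @param config a [cohortConfig()] object.
#' @return a [HomCohort-class]; `truthRecord(x)` holds the bookkeeping:
#'   `targetGenes`, `plantedCases`, `plantedControls`, `plantedCalls`
#'   (variant/subject indices), `trueAF`, and the injected artefact call
#'   indices `lowGQCalls` / `contaminatedCalls` (two-column matrices).
#' @examples
#' cfg <- cohortConfig(nCases = 40, nControls = 40, nGenes = 50,
#'                     targetSetSize = 10, seed = 7)
#' co <- simulateCohort(cfg)
#' co
#' @export
simulateCohort <- function(config) {
    if (!inherits(config, "CohortConfig"))
        stop("'config' must be created by cohortConfig()")
    .withSeed(config$seed, .simulateCohortImpl(config))
}

.simulateCohortImpl <- function(config) {
    ns <- config$nCases + config$nControls
    genes <- sprintf("G%06d", seq_len(config$nGenes))
    nVarPerGene <- 1L + stats::rpois(config$nGenes,
                                     config$variantsPerGene - 1)
    nv <- sum(nVarPerGene)
    geneOfVar <- rep(genes, nVarPerGene)
    geneIdxOfVar <- rep(seq_len(config$nGenes), nVarPerGene)

    # allele frequencies: log-uniform between the spectrum bounds
    sp <- config$mafSpectrum
    if (sp$max == 0) {
        af <- rep(0, nv)
    } else {
        lo <- max(sp$min, 1e-12)
        af <- 10^stats::runif(nv, log10(lo), log10(sp$max))
    }

    # variant coordinates: genes laid round-robin on 22 autosomes
    chromIdx <- (geneIdxOfVar - 1L) %% 22L + 1L
    chrom <- paste0("chr", chromIdx)
    pos <- integer(nv)
    for (cc in unique(chromIdx)) {
        i <- which(chromIdx == cc)
        pos[i] <- 10000L + seq_along(i) * 500L
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nv, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    isIndel <- stats::runif(nv) < config$indelRate
    alt[isIndel] <- paste0(alt[isIndel], "A")  # 1-bp insertions
    csqClass <- sample(.CSQ_CLASSES, nv, replace = TRUE,
                       prob = c(0.55, 0.05, 0.05, 0.35))
    cadd <- pmin(stats::rgamma(nv, shape = 2, scale = 6), 50)
    popmaxAF <- pmin(af * 10^stats::runif(nv, -0.5, 0.5), 1)
    popmaxAF[stats::runif(nv) < 0.2] <- 0  # absent from reference panels

    n <- nv * ns
    gt <- matrix(stats::rbinom(n, 2L, af), nrow = nv)  # af recycles by row

    subjects <- data.frame(
        id = c(sprintf("case_%05d", seq_len(config$nCases)),
               sprintf("ctrl_%05d", seq_len(config$nControls))),
        group = rep(c("case", "control"),
                    c(config$nCases, config$nControls)))

    # designated target gene set, and planted case carriers inside it
    targetGenes <- sample(genes, config$targetSetSize)
    plantedCalls <- matrix(integer(0), ncol = 2,
                           dimnames = list(NULL, c("variant", "subject")))
    plantedCases <- character(0)
    k <- config$plantedCaseHomExcess
    if (k > 0) {
        cand <- which(geneOfVar %in% targetGenes & !isIndel & af < 0.001)
        if (!length(cand))
            cand <- which(geneOfVar %in% targetGenes & !isIndel)
        if (!length(cand))
            cand <- which(geneOfVar %in% targetGenes)
        who <- sample(config$nCases, k)
        at <- cand[sample.int(length(cand), k, replace = TRUE)]
        gt[cbind(at, who)] <- 2L
        plantedCalls <- cbind(variant = at, subject = who)
        plantedCases <- subjects$id[who]
    }
    plantedLin <- (plantedCalls[, "subject"] - 1L) * nv +
        plantedCalls[, "variant"]

    # genotype quality: clean calls clamped into [20, 99]
    gq <- round(stats::rnorm(n, config$gqDistribution$mean,
                             config$gqDistribution$sd))
    gq <- pmin(pmax(gq, 20), 99)
    gq <- matrix(gq, nrow = nv)
    nLow <- round(config$missingRate * n)
    lowIdx <- integer(0)
    if (nLow > 0) {
        pool <- setdiff(seq_len(n), plantedLin)
        lowIdx <- sample(pool, min(nLow, length(pool)))
        gq[lowIdx] <- sample(0:19, length(lowIdx), replace = TRUE)
    }

    # read depths; hom-alt calls get depth >= 1 and <= 5% reference reads
    depth <- stats::rnbinom(n, size = config$depthDistribution$size,
                            mu = config$depthDistribution$mean)
    hom <- gt == 2L
    depth[hom] <- pmax(depth[hom], 1L)
    pAlt <- c(0.002, 0.5, 0.998)[as.vector(gt) + 1L]
    ad <- stats::rbinom(n, depth, pAlt)
    rd <- depth - ad
    rdHom <- rd[hom]
    over <- rdHom > floor(0.05 * depth[hom])
    rdHom[over] <- floor(0.05 * depth[hom])[over]
    rd[hom] <- rdHom
    ad[hom] <- depth[hom] - rdHom

    contamIdx <- integer(0)
    if (config$contaminationRate > 0) {
        homIdx <- setdiff(which(as.vector(gt) == 2L), plantedLin)
        nCon <- round(config$contaminationRate * length(homIdx))
        if (nCon > 0) {
            contamIdx <- sample(homIdx, nCon)
            d <- depth[contamIdx]
            frac <- stats::runif(nCon, 0.051, 0.40)
            r <- pmax(ceiling(frac * d), floor(0.05 * d) + 1L)
            r <- pmin(r, d)
            rd[contamIdx] <- r
            ad[contamIdx] <- d - r
        }
    }
    if (length(plantedLin)) {  # planted carriers are clean by construction
        gq[plantedLin] <- 80
        rd[plantedLin] <- 0L
        ad[plantedLin] <- 30L
    }
    rd <- matrix(rd, nrow = nv)
    ad <- matrix(ad, nrow = nv)

    variants <- data.frame(
        chrom = chrom, pos = pos, ref = ref, alt = alt, gene = geneOfVar,
        csqClass = csqClass, cadd = cadd, popmaxAF = popmaxAF,
        isIndel = isIndel)
    co <- HomCohort(gt, gq, rd, ad, variants, subjects)
    linToRc <- function(idx) cbind(variant = (idx - 1L) %% nv + 1L,
                                   subject = (idx - 1L) %/% nv + 1L)
    S4Vectors::metadata(co)$truth <- list(
        targetGenes = targetGenes,
        plantedCases = plantedCases,
        plantedControls = character(0),
        plantedCalls = plantedCalls,
        trueAF = af,
        lowGQCalls = linToRc(lowIdx),
        contaminatedCalls = linToRc(contamIdx),
        seed = config$seed)
    co
}
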