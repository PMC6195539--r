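test_that("configuration rejects out-of-range values with named errors", {
    expect_error(cohortConfig(nCases = 0, nControls = 10), "nCases")
    expect_error(cohortConfig(nCases = 10, nControls = 10,
                              contaminationRate = 1.5), "contaminationRate")
    expect_error(cohortConfig(nCases = 10, nControls = 10,
                              missingRate = -0.1), "missingRate")
    expect_error(cohortConfig(nCases = 10, nControls = 10,
                              mafSpectrum = list(min = 0.01, max = 0.5)),
                 "mafSpectrum")
    expect_error(cohortConfig(nCases = 10, nControls = 10, nGenes = 5,
                              targetSetSize = 10), "targetSetSize")
    expect_error(cohortConfig(nCases = 10, nControls = 10, seed = NaN),
                 "seed")
})

test_that("generation is bit-identical under a fixed seed", {
    cfg <- smallConfig(plantedCaseHomExcess = 0, seed = 31)
    a <- simulateCohort(cfg)
    b <- simulateCohort(cfg)
    expect_identical(genotypes(a), genotypes(b))
    expect_identical(genoQual(a), genoQual(b))
    expect_identical(refDepth(a), refDepth(b))
    expect_identical(altDepth(a), altDepth(b))
    expect_identical(as.data.frame(rowData(a)), as.data.frame(rowData(b)))
    expect_identical(truthRecord(a)$targetGenes, truthRecord(b)$targetGenes)
})

test_that("planted case carriers are recoverable from the truth record", {
    cfg <- smallConfig(plantedCaseHomExcess = 6, seed = 7)
    co <- simulateCohort(cfg)
    tr <- truthRecord(co)
    expect_length(tr$plantedCases, 6)
    expect_true(all(tr$plantedCases %in% colnames(co)))
    expect_true(all(as.character(co$group[match(tr$plantedCases,
                                                colnames(co))]) == "case"))
    # counting homozygous carriers in the target set recovers >= 6 cases
    counts <- countHomCarriers(co, tr$targetGenes)
    expect_gte(counts[["caseHom"]], 6)
    # every planted call is a clean homozygote in a target-set gene
    pc <- tr$plantedCalls
    expect_true(all(genotypes(co)[pc] == 2L))
    expect_true(all(variantGenes(co)[pc[, "variant"]] %in% tr$targetGenes))
})

test_that("a degenerate spectrum at frequency zero gives all-reference calls", {
    cfg <- smallConfig(mafSpectrum = list(min = 0, max = 0),
                       contaminationRate = 0, seed = 2)
    co <- simulateCohort(cfg)
    expect_true(all(genotypes(co) == 0L))
})

test_that("observed allele frequencies converge to the configured truth", {
    for (n in c(200L, 2000L)) {
        cfg <- cohortConfig(nCases = n, nControls = n, nGenes = 30,
                            variantsPerGene = 1, targetSetSize = 5,
                            mafSpectrum = list(min = 9e-4, max = 0.3),
                            missingRate = 0, contaminationRate = 0,
                            seed = 5)
        co <- simulateCohort(cfg)
        af <- rowSums(genotypes(co)) / (2 * ncol(co))
        err <- abs(af - truthRecord(co)$trueAF)
        # binomial standard error shrinks as 1/sqrt(n)
        tol <- 5 * sqrt(0.3 * 0.7 / (2 * 2 * n))
        expect_lt(stats::median(err), tol)
    }
})

test_that("injected artefact rates match the configuration", {
    cfg <- cohortConfig(nCases = 150, nControls = 150, nGenes = 100,
                        variantsPerGene = 2, targetSetSize = 10,
                        mafSpectrum = list(min = 1e-4, max = 0.3),
                        contaminationRate = 0.10, missingRate = 0.05,
                        seed = 9)
    co <- simulateCohort(cfg)
    tr <- truthRecord(co)
    n <- length(genotypes(co))
    # low-GQ fraction: injected exactly at the configured (rounded) count
    expect_equal(sum(genoQual(co) < 20), round(0.05 * n))
    expect_equal(nrow(tr$lowGQCalls), round(0.05 * n))
    # contaminated hom calls carry > 5% ref reads; clean homs never do
    gt <- genotypes(co); rd <- refDepth(co); ad <- altDepth(co)
    hom <- which(gt == 2L)
    refFrac <- rd[hom] / (rd[hom] + ad[hom])
    contam <- matrix(FALSE, nrow(co), ncol(co))
    contam[tr$contaminatedCalls] <- TRUE
    expect_true(all(refFrac[contam[hom]] > 0.05))
    expect_true(all(refFrac[!contam[hom]] <= 0.05))
    nHomUnplanted <- length(hom) - nrow(tr$plantedCalls)
    expect_equal(nrow(tr$contaminatedCalls), round(0.10 * nHomUnplanted))
})

test_that("without planted enrichment the target-set difference is sign-balanced", {
    signs <- vapply(1:200, function(s) {
        cfg <- cohortConfig(nCases = 30, nControls = 30, nGenes = 60,
                            variantsPerGene = 1, targetSetSize = 20,
                            mafSpectrum = list(min = 1e-4, max = 0.3),
                            contaminationRate = 0, missingRate = 0,
                            indelRate = 0, seed = s)
        co <- simulateCohort(cfg)
        counts <- countHomCarriers(co, truthRecord(co)$targetGenes)
        sign(counts[["caseHom"]] / counts[["caseTotal"]] -
             counts[["controlHom"]] / counts[["controlTotal"]])
    }, 0)
    nz <- signs[signs != 0]
    expect_gt(length(nz), 50)
    bt <- stats::binom.test(sum(nz > 0), length(nz), 0.5)
    expect_gt(bt$p.value, 0.001)
})
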