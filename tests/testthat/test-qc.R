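test_that("GQ filter uses a strict threshold and counts match a direct oracle", {
    gq <- matrix(c(19, 20, 21, 0, 60, 19.9), 3, 2)
    gt <- matrix(1L, 3, 2)
    co <- makeCohort(gt, gq = gq)
    flt <- filterGQ(co)
    expect_identical(unname(is.na(genotypes(flt))),
                     matrix(c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE), 3, 2))
    expect_error(filterGQ(co, threshold = -1), "non-negative")
    # random matrix: newly-missing fraction equals the fraction with gq < 20
    set.seed(1)
    gq2 <- matrix(sample(0:99, 600, replace = TRUE), 30, 20)
    co2 <- makeCohort(matrix(1L, 30, 20), gq = gq2)
    flt2 <- filterGQ(co2)
    expect_equal(mean(is.na(genotypes(flt2))), mean(gq2 < 20))
    expect_equal(sum(qcSummary(flt2)$n_calls_invalidated), sum(gq2 < 20))
    # no variant is removed at this step
    expect_equal(nrow(flt2), 30)
})

test_that("contamination filter invalidates hom-alt calls above 5% ref reads", {
    gt <- matrix(c(2L, 2L, 1L, 2L), 4, 1)
    rd <- matrix(c(6, 5, 50, 0), 4, 1)
    ad <- matrix(c(94, 95, 50, 0), 4, 1)
    co <- makeCohort(gt, rd = rd, ad = ad, nCases = 1)
    flt <- filterHomContamination(co)
    out <- unname(genotypes(flt)[, 1])
    expect_true(is.na(out[1]))      # 6/100 ref reads: exceeds 5%
    expect_equal(out[2], 2L)        # 5/100: does not exceed 5%
    expect_equal(out[3], 1L)        # heterozygote untouched
    expect_true(is.na(out[4]))      # zero-depth homozygote unverifiable
})

test_that("missingness filter drops on a strict per-group threshold", {
    # 100 cases, 100 controls; variant 1: 11% missing in cases only;
    # variant 2: exactly 10% missing in each group; variant 3: complete
    gt <- matrix(1L, 3, 200)
    gt[1, 1:11] <- NA
    gt[2, c(1:10, 101:110)] <- NA
    co <- makeCohort(gt, nCases = 100)
    flt <- filterMissingness(co)
    expect_identical(rownames(flt), c("v000002", "v000003"))
    # no missing calls at all: identity
    co2 <- makeCohort(matrix(1L, 3, 10))
    expect_equal(dim(filterMissingness(co2)), dim(co2))
    # empty group: fraction undefined
    one <- makeCohort(matrix(1L, 2, 4), nCases = 4)
    expect_error(filterMissingness(one), "empty")
})

test_that("indel exclusion removes exactly the flagged variants", {
    co <- makeCohort(matrix(0L, 10, 4),
                     isIndel = rep(c(TRUE, FALSE), c(3, 7)))
    expect_equal(nrow(excludeIndels(co)), 7)
    snv <- makeCohort(matrix(0L, 4, 4), isIndel = FALSE)
    expect_equal(nrow(excludeIndels(snv)), 4)
    indels <- makeCohort(matrix(0L, 4, 4), isIndel = TRUE)
    empty <- excludeIndels(indels)
    expect_equal(nrow(empty), 0)
    expect_s4_class(empty, "HomCohort")
})

test_that("composed QC is idempotent and leaves clean cohorts unchanged", {
    cfg <- smallConfig(contaminationRate = 0, missingRate = 0,
                       indelRate = 0, seed = 21)
    clean <- simulateCohort(cfg)
    once <- runQC(clean)
    expect_identical(genotypes(once), genotypes(clean))
    expect_equal(nrow(once), nrow(clean))
    dirty <- simulateCohort(smallConfig(contaminationRate = 0.1,
                                        missingRate = 0.05, seed = 22))
    once <- runQC(dirty)
    twice <- runQC(once)
    expect_identical(genotypes(twice), genotypes(once))
    expect_identical(rownames(twice), rownames(once))
})

test_that("QC never resurrects missing calls nor changes non-missing genotypes", {
    dirty <- simulateCohort(smallConfig(contaminationRate = 0.15,
                                        missingRate = 0.10, seed = 23))
    before <- genotypes(dirty)
    after0 <- runQC(dirty, dropIndels = FALSE)
    after <- genotypes(after0)[rownames(after0), , drop = FALSE]
    common <- rownames(after0)
    b <- before[common, , drop = FALSE]
    a <- genotypes(after0)
    expect_true(all(is.na(a[is.na(b)])))
    changed <- !is.na(b) & !is.na(a) & a != b
    expect_false(any(changed))
})

test_that("surviving calls after QC match the generator's bookkeeping", {
    cfg <- cohortConfig(nCases = 80, nControls = 80, nGenes = 60,
                        variantsPerGene = 2, targetSetSize = 10,
                        mafSpectrum = list(min = 9e-4, max = 0.3),
                        contaminationRate = 0.2, missingRate = 0.04,
                        indelRate = 0, seed = 8)
    co <- simulateCohort(cfg)
    tr <- truthRecord(co)
    step1 <- filterGQ(co)
    expected <- matrix(FALSE, nrow(co), ncol(co))
    expected[tr$lowGQCalls] <- TRUE
    expect_identical(unname(is.na(genotypes(step1)) &
                            !is.na(genotypes(co))), expected)
    step2 <- filterHomContamination(step1)
    # contaminated calls either already dropped by GQ or dropped here
    nowNA <- is.na(genotypes(step2))
    expect_true(all(nowNA[tr$contaminatedCalls]))
    # the step invalidates exactly the injected calls GQ had not caught
    contamMask <- matrix(FALSE, nrow(co), ncol(co))
    contamMask[tr$contaminatedCalls] <- TRUE
    newlyNA <- unname(nowNA & !is.na(genotypes(step1)))
    expect_identical(newlyNA, contamMask & !expected)
    # variant-level missingness removal matches a direct recount
    step3 <- filterMissingness(step2)
    miss <- is.na(genotypes(step2))
    grp <- as.character(co$group)
    keep <- rowMeans(miss[, grp == "case", drop = FALSE]) <= 0.10 &
            rowMeans(miss[, grp == "control", drop = FALSE]) <= 0.10
    expect_identical(rownames(step3), rownames(co)[keep])
})

test_that("QC output is invariant to subject and variant ordering", {
    dirty <- simulateCohort(smallConfig(contaminationRate = 0.1,
                                        missingRate = 0.05, seed = 25))
    qc1 <- runQC(dirty)
    set.seed(4)
    perm <- dirty[sample(nrow(dirty)), sample(ncol(dirty))]
    qc2 <- runQC(perm)
    expect_setequal(rownames(qc2), rownames(qc1))
    expect_identical(genotypes(qc2)[rownames(qc1), colnames(qc1)],
                     genotypes(qc1))
})
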