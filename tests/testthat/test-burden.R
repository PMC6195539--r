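test_that("one-tailed Fisher p matches hand-derived and closed-form values", {
    expect_equal(fisherOneTailed(6, 4225, 0, 5834), 0.0055, tolerance = 5e-3)
    expect_equal(fisherOneTailed(0, 100, 0, 200), 1)
    # 2/5 vs 0/5 carriers: 56/252 by full enumeration of the support
    expect_equal(fisherOneTailed(2, 5, 0, 5), 56 / 252)
    # zero-control closed form: prod (n1 - i) / (N - i)
    for (a in 1:6) {
        closed <- prod((4225 - 0:(a - 1)) / (10059 - 0:(a - 1)))
        expect_equal(fisherOneTailed(a, 4225, 0, 5834), closed)
    }
    expect_error(fisherOneTailed(1, 0, 0, 5), "degenerate")
    expect_error(fisherOneTailed(6, 5, 0, 5), "within")
})

test_that("Fisher p equals brute-force enumeration and fisher.test", {
    set.seed(42)
    # exhaustive over small tables, random over the N <= 200 range
    smalls <- expand.grid(n1 = 2:12, n2 = 2:12, K = 0:8)
    smalls <- smalls[smalls$K <= smalls$n1 + smalls$n2, ]
    randos <- data.frame(n1 = sample(5:150, 300, TRUE),
                         n2 = sample(5:150, 300, TRUE))
    randos <- randos[randos$n1 + randos$n2 <= 200, ]
    randos$K <- vapply(seq_len(nrow(randos)), function(i)
        sample(0:min(20, randos$n1[i] + randos$n2[i]), 1), 0L)
    tables <- rbind(smalls, randos)
    for (i in seq_len(nrow(tables))) {
        n1 <- tables$n1[i]; n2 <- tables$n2[i]; K <- tables$K[i]
        support <- max(0, K - n2):min(K, n1)
        a <- support[sample.int(length(support), 1)]
        p <- fisherOneTailed(a, n1, K - a, n2)
        expect_equal(p, bruteFisher(a, n1, K - a, n2), tolerance = 1e-12)
    }
    # spot-check against the reference implementation
    ft <- stats::fisher.test(matrix(c(6, 4219, 0, 5834), 2),
                             alternative = "greater")
    expect_equal(fisherOneTailed(6, 4225, 0, 5834), ft$p.value,
                 tolerance = 1e-10)
})

test_that("the one-tailed p is monotone decreasing in the case carrier count", {
    for (K in c(3, 10, 40)) {
        p <- vapply(0:K, function(a) fisherOneTailed(a, 120, K - a, 180), 0)
        expect_true(all(diff(p) < 0))
    }
})

test_that("carrier counting collapses at the subject level per category", {
    tab <- exampleHomVariants()
    co <- classifyVariants(runQC(cohortFromVariantTable(tab)))
    counts <- countHomCarriers(co, tab$gene, "C")
    expect_identical(counts, c(caseHom = 4L, caseTotal = 4225L,
                               controlHom = 0L, controlTotal = 5834L))
    for (cat in c("A", "B", "C", "D")) {
        b <- burdenTest(co, tab$gene, cat)
        expect_equal(carrierCounts(b)[["caseHom"]],
                     sum(rowData(co)[[paste0("cat", cat)]]))
    }
    # per-category counts are monotone non-increasing A -> D
    ns <- vapply(c("A", "B", "C", "D"), function(cat)
        countHomCarriers(co, tab$gene, cat)[["caseHom"]], 0L)
    expect_true(all(diff(ns) <= 0))
    # a subject homozygous for two qualifying variants counts once
    gt <- matrix(0L, 2, 6); gt[, 1] <- 2L
    multi <- classifyVariants(makeCohort(gt, genes = c("GA", "GB")),
                              datasetMafMax = 0.9)
    expect_equal(countHomCarriers(multi, c("GA", "GB"), "A")[["caseHom"]],
                 1L)
    # disjoint gene set warns and returns zero carriers
    expect_warning(z <- countHomCarriers(multi, "ABSENT", "A"), "no genes")
    expect_equal(z[["caseHom"]], 0L)
    # empty qualification
    none <- classifyVariants(makeCohort(gt, genes = c("GA", "GB")),
                             datasetMafMax = 1e-6)
    expect_equal(unname(countHomCarriers(none, c("GA", "GB"), "A")),
                 c(0L, 3L, 0L, 3L))
})

test_that("complement burden excludes the target set and degenerates correctly", {
    co <- simulateCohort(smallConfig(plantedCaseHomExcess = 5, seed = 19))
    tr <- truthRecord(co)
    allGenes <- unique(variantGenes(co))
    # excluding nothing equals the whole-genome burden
    whole <- burdenTest(co, allGenes)
    comp0 <- complementBurden(co, character(0))
    expect_identical(carrierCounts(comp0), carrierCounts(whole))
    # excluding everything: no qualifying variants, p = 1
    compAll <- suppressWarnings(complementBurden(co, allGenes))
    expect_equal(fisherP(compAll), 1)
    expect_equal(carrierCounts(compAll)[["caseHom"]], 0L)
    # enrichment planted in the target set should not inflate the complement
    comp <- complementBurden(co, tr$targetGenes)
    tgt <- burdenTest(co, tr$targetGenes)
    expect_gte(fisherP(comp), fisherP(tgt))
})

test_that("exact Fisher power matches the closed-form zero-control scenario", {
    # with control frequency 0 the test rejects iff enough case carriers
    p1 <- 3 / 4225
    pw <- fisherPower(p1, 0, 4225, 5834)
    aMin <- 4  # smallest count with p <= 0.05 (3 carriers give 0.0741)
    expect_equal(pw, 1 - pbinom(aMin - 1, 4225, p1), tolerance = 1e-9)
    expect_equal(fisherPower(0, 0, 100, 100), 0)
    expect_gt(fisherPower(1, 0, 200, 200), 0.999)
    expect_error(fisherPower(0.1, 0, 100, 100, alpha = 0), "alpha")
})

test_that("exact and Monte Carlo power agree within simulation error", {
    for (sc in list(c(3 / 4225, 0, 4225, 5834),
                    c(0.05, 0.01, 300, 300))) {
        ex <- fisherPower(sc[1], sc[2], sc[3], sc[4])
        mc <- fisherPower(sc[1], sc[2], sc[3], sc[4],
                          method = "montecarlo", nSims = 1e5, seed = 6)
        expect_lt(abs(mc - ex), 4 * sqrt(ex * (1 - ex) / 1e5) + 0.002)
    }
})
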