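test_that("quantile normalization equalizes column distributions", {
    m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
                dimnames = list(paste0("p", 1:3), c("a", "b")))
    out <- quantileNormalize(m)
    expect_equal(out[, "a"], c(p1 = 2.5, p2 = 3.5, p3 = 4.5))
    expect_equal(out[, "b"], c(p1 = 2.5, p2 = 3.5, p3 = 4.5))

    set.seed(1)
    r <- matrix(rexp(60) + 0.1, nrow = 12,
                dimnames = list(paste0("p", 1:12), paste0("s", 1:5)))
    qn <- quantileNormalize(r)
    # identical multiset in every column
    for (j in 2:5)
        expect_equal(sort(qn[, j]), sort(qn[, 1]), ignore_attr = TRUE)
    # idempotence
    expect_equal(quantileNormalize(qn), qn)
    # identical columns unchanged
    same <- matrix(rep(c(1, 5, 2), 3), nrow = 3,
                   dimnames = list(paste0("p", 1:3), paste0("s", 1:3)))
    expect_equal(quantileNormalize(same), same)

    expect_error(quantileNormalize(m[, 1, drop = FALSE]), "2 columns")
    m2 <- m; m2[1, 1] <- 0
    expect_error(quantileNormalize(m2), "positive")
})

test_that("moderated t reduces to the pooled t when the prior is off", {
    set.seed(11)
    m <- matrix(rnorm(200 * 12), nrow = 200,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:12)))
    de <- moderatedTTest(m, 1:6, 7:12, priorDf = 0)
    oracle <- pooledTOracle(m, 1:6, 7:12)
    expect_equal(de$t, unname(oracle[, "t"]), tolerance = 1e-10)
    expect_equal(de$p, unname(oracle[, "p"]), tolerance = 1e-10)
    expect_equal(unique(de$df), 10)
})

test_that("moderated t handles identical and degenerate rows", {
    set.seed(2)
    m <- matrix(rnorm(100 * 8), nrow = 100,
                dimnames = list(paste0("g", 1:100), paste0("s", 1:8)))
    m[1, ] <- 3.14          # identical across all samples
    m[2, 1:4] <- 1; m[2, 5:8] <- 1  # zero variance, zero fc
    de <- moderatedTTest(m, 1:4, 5:8)
    expect_equal(de["g1", "log2fc"], 0)
    expect_equal(de["g1", "t"], 0)
    expect_equal(de["g1", "p"], 1)
    # a zero-variance row with a real difference: shrinkage gives finite t
    m[3, 1:4] <- 2; m[3, 5:8] <- 0
    de3 <- moderatedTTest(m, 1:4, 5:8)
    expect_true(is.finite(de3["g3", "t"]) && de3["g3", "t"] > 0)
    # all rows zero-variance: prior unestimable
    flat <- matrix(1, nrow = 5, ncol = 8,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
    expect_error(moderatedTTest(flat, 1:4, 5:8), "zero variance")
    expect_error(moderatedTTest(m, 1:4, 4:8), "disjoint")
})

test_that("an infinite prior drives every variance to the prior value", {
    set.seed(3)
    m <- matrix(rnorm(50 * 10, sd = rep(c(1, 3), each = 25)), nrow = 50,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:10)))
    de <- moderatedTTest(m, 1:5, 6:10, priorDf = Inf)
    s20 <- attr(de, "priorVar")
    expected <- de$log2fc / sqrt(s20 * (1 / 5 + 1 / 5))
    expect_equal(de$t, expected, tolerance = 1e-12)
    expect_true(all(is.infinite(de$df)))
})

test_that("moderated t is calibrated under the null and matches limma", {
    set.seed(42)
    m <- matrix(rnorm(5000 * 10), nrow = 5000,
                dimnames = list(paste0("g", 1:5000), paste0("s", 1:10)))
    de <- moderatedTTest(m, 1:5, 6:10)
    frac <- mean(de$p < 0.05)
    expect_gte(frac, 0.04)
    expect_lte(frac, 0.06)
    # independent implementation of the same empirical-Bayes model
    design <- cbind(intercept = 1, group = rep(c(1, 0), each = 5))
    fit <- limma::eBayes(limma::lmFit(m, design))
    expect_equal(de$t, unname(fit$t[, "group"]), tolerance = 0.02)
    expect_equal(de$log2fc, unname(fit$coefficients[, "group"]),
                 tolerance = 1e-10)
})

test_that("BH adjustment equals the literal step-up evaluation", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(rep(0.05, 10)), rep(0.05, 10))
    set.seed(9)
    for (i in 1:5) {
        p <- runif(sample(5:50, 1))
        expect_equal(bhAdjust(p), bhStepUpOracle(p), tolerance = 1e-12)
    }
    # monotone when input sorted ascending
    p <- sort(runif(30))
    expect_true(all(diff(bhAdjust(p)) >= 0))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("probe collapse retains the stated probe per gene", {
    de <- data.frame(log2fc = c(1.5, -2.0, 1.6, -2.0, 0.3),
                     t = 1, p = c(0.01, 0.03, 0.02, 0.02, 0.5),
                     fdr = 0.05, df = 10,
                     row.names = c("pA1", "pA2", "pB1", "pB2", "pC1"))
    ann <- data.frame(probe = rownames(de),
                      gene = c("A", "A", "B", "B", "C"))
    lp <- collapseProbes(de, ann, "lowest_p")
    expect_equal(lp["A", "probe"], "pA1")       # lowest p wins
    expect_equal(lp["C", "log2fc"], 0.3)        # single probe unchanged
    # p tie in gene B: larger |fc| wins
    expect_equal(lp["B", "probe"], "pB2")
    fc <- collapseProbes(de, ann, "largest_abs_fc")
    expect_equal(fc["A", "log2fc"], -2.0)       # signed value retained
    bad <- ann[-1, ]
    expect_error(collapseProbes(de, bad, "lowest_p"), "pA1")
})

test_that("lineage signature thresholds are strict as printed", {
    gd <- makeGeneDe(c("in1", "fdrOut", "fcOut", "fcEdge", "fdrEdge"),
                     log2fc = c(1.2, 3.0, 0.5, 1.0, 1.2),
                     fdr = c(0.04, 0.06, 0.01, 0.01, 0.05))
    sig <- buildLineageSignature(gd)
    expect_setequal(sigGenes(sig), "in1")
    expect_equal(sigFoldChanges(sig)[["in1"]], 1.2)
    empty <- makeGeneDe("g", 0.1, 0.9)
    expect_warning(s0 <- buildLineageSignature(empty), "empty")
    expect_length(s0, 0)
})

test_that("culture signature takes the union and the largest |fc|", {
    de1 <- makeGeneDe(c("a", "b", "c"), log2fc = c(1.8, 1.4, 1.6),
                      fdr = c(0.03, 0.01, 0.02))
    de2 <- makeGeneDe(c("a", "b", "c"), log2fc = c(0.2, 1.4, -1.8),
                      fdr = c(0.50, 0.01, 0.01))
    sig <- buildCultureSignature(de1, de2)
    # a passes only in comparison 1; b (|fc| = 1.4 < 1.5) never passes;
    # c passes in both and keeps the larger-magnitude value -1.8
    expect_setequal(sigGenes(sig), c("a", "c"))
    expect_equal(sigFoldChanges(sig)[["a"]], 1.8)
    expect_equal(sigFoldChanges(sig)[["c"]], -1.8)
})

test_that("stem-cell voting applies the support threshold and tie rule", {
    mkTable <- function(fc, p) data.frame(gene = names(fc),
                                          logFC = unname(fc),
                                          adjP = p)
    # gene "five" up in 5 of 18, "four" up in 4, "tie" up in 6 / down in 6
    tables <- lapply(1:18, function(i) {
        fc <- c(five = if (i <= 5) 2 else 0,
                four = if (i <= 4) 2 else 0,
                tie = if (i <= 6) 2 else if (i <= 12) -2 else 0)
        mkTable(fc, 0.01)
    })
    sig <- stemCellVoting(tables, votingParams())
    expect_setequal(upGenes(sig), "five")
    expect_false("four" %in% upGenes(sig))
    expect_false("tie" %in% c(upGenes(sig), downGenes(sig)))
    # direction with more support wins
    tables7 <- lapply(1:18, function(i)
        mkTable(c(g = if (i <= 7) 2 else if (i <= 12) -2 else 0), 0.01))
    sig7 <- stemCellVoting(tables7, votingParams())
    expect_setequal(upGenes(sig7), "g")
    expect_length(downGenes(sig7), 0)
    expect_error(stemCellVoting(tables[1:3], votingParams(minSupport = 5)),
                 "exceeds")
})
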