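test_that("size factors follow the median-of-ratios construction", {
    m <- matrix(c(2, 2, 8, 4, 4, 16), nrow = 3,
                dimnames = list(paste0("g", 1:3), c("s1", "s2")))
    expect_equal(cohortSizeFactors(m),
                 c(s1 = 1 / sqrt(2), s2 = sqrt(2)))
    # identical columns: all factors 1
    same <- matrix(rep(c(3, 7, 11), 4), nrow = 3,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
    expect_equal(unname(cohortSizeFactors(same)), rep(1, 4))
    # scale equivariance of the factor ratios: doubling one sample's
    # column doubles its factor relative to every other sample (absolute
    # factors shift together because the gene geometric means move too)
    set.seed(4)
    r <- matrix(rexp(50 * 4) + 0.5, nrow = 50,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
    sf <- cohortSizeFactors(r)
    r2 <- r; r2[, 2] <- 2 * r[, 2]
    sf2 <- cohortSizeFactors(r2)
    expect_equal(sf2[2] / sf2[-2], 2 * sf[2] / sf[-2],
                 tolerance = 1e-12)
    # agreement with the reference implementation
    expect_equal(unname(cohortSizeFactors(r)),
                 unname(DESeq2::estimateSizeFactorsForMatrix(r)),
                 tolerance = 1e-10)
    zero <- r; zero[, 1] <- 0
    expect_error(cohortSizeFactors(zero), "positive")
})

test_that("cohort preprocessing yields per-gene z-scores", {
    m <- matrix(c(1, 3, 7, 15, 0, 2, 6, 14), nrow = 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
    z <- preprocessCohort(m, sf = setNames(rep(1, 4), paste0("s", 1:4)))
    hand <- t(apply(log2(m + 1), 1, function(r) (r - mean(r)) / sd(r)))
    expect_equal(z, hand, ignore_attr = TRUE)
    expect_true(all(abs(rowMeans(z)) < 1e-9))
    expect_equal(unname(apply(z, 1, sd)), rep(1, 2))
    # constant gene is dropped and reported
    m2 <- rbind(m, flat = rep(5, 4))
    expect_message(z2 <- preprocessCohort(m2,
        sf = setNames(rep(1, 4), paste0("s", 1:4))), "flat")
    expect_false("flat" %in% rownames(z2))
    expect_equal(attr(z2, "dropped"), "flat")
    flatOnly <- matrix(1, 2, 4, dimnames = list(c("a", "b"),
                                                paste0("s", 1:4)))
    expect_error(preprocessCohort(flatOnly,
        sf = setNames(rep(1, 4), paste0("s", 1:4))), "zero variance")
})

test_that("spearmanRho equals rank-then-Pearson with average ranks", {
    x <- c(1, 2, 2, 4); y <- c(3, 1, 2, 4)
    expect_equal(spearmanRho(x, y), spearmanOracle(x, y))
    set.seed(8)
    for (i in 1:10) {
        a <- sample(1:6, 12, replace = TRUE)
        b <- rnorm(12)
        expect_equal(spearmanRho(a, b), spearmanOracle(a, b),
                     tolerance = 1e-12)
    }
    z <- rnorm(10)
    expect_equal(spearmanRho(z, z), 1)
    expect_equal(spearmanRho(z, rev(sort(z))[rank(z)]), -1)
    expect_error(spearmanRho(rep(1, 5), rnorm(5)), "constant")
    expect_error(spearmanRho(1:3, 1:4), "equal length")
})

test_that("Co-Sq labels follow the strict +/-0.2 thresholds", {
    # 4 signature genes; a sample with z-ranks (3,2,1,4) against fold
    # changes ranked (1,2,3,4) has Spearman exactly 0.2
    sig <- LineageSignature(c(g1 = 1.1, g2 = 1.2, g3 = 1.3, g4 = 1.4))
    z <- cbind(exact = c(3, 2, 1, 4),
               pos = c(1.1, 1.2, 1.3, 1.4),
               neg = c(1.4, 1.3, 1.2, 1.1))
    rownames(z) <- paste0("g", 1:4)
    res <- cosqClassify(z, sig)
    expect_equal(unname(sampleScores(res)["exact"]), 0.2)
    expect_equal(unname(sampleLabels(res)),
                 c("undetermined", "squamous-like", "columnar-like"))
    # every sample gets exactly one label
    expect_equal(sum(table(sampleLabels(res))), ncol(z))
})

test_that("Co-Sq scores are invariant to monotone per-sample transforms", {
    set.seed(12)
    z <- matrix(rnorm(80 * 6), nrow = 80,
                dimnames = list(paste0("g", 1:80), paste0("s", 1:6)))
    sig <- simulateSignature(sample(rownames(z), 30), seed = 2)
    r1 <- cosqClassify(z, sig)
    zt <- z
    for (j in seq_len(ncol(z)))
        zt[, j] <- j * exp(z[, j]) + j   # strictly monotone, per sample
    r2 <- cosqClassify(zt, sig)
    expect_equal(sampleScores(r1), sampleScores(r2), tolerance = 1e-12)
})

test_that("signature genes missing from the matrix are excluded", {
    set.seed(13)
    z <- matrix(rnorm(40 * 4), nrow = 40,
                dimnames = list(paste0("g", 1:40), paste0("s", 1:4)))
    fc <- setNames(runif(10, 1.1, 2), c(paste0("g", 1:5),
                                        paste0("missing", 1:5)))
    sig <- LineageSignature(fc)
    expect_message(res <- cosqClassify(z, sig), "not measured")
    expect_equal(res@nOverlap, 5L)
    few <- LineageSignature(setNames(c(1.5, 1.6), c("g1", "nope")))
    expect_error(suppressMessages(cosqClassify(z, few)), "fewer than 3")
})

test_that("random-set null is seeded, centred and shape-consistent", {
    set.seed(21)
    z <- matrix(rnorm(300 * 20), nrow = 300,
                dimnames = list(paste0("g", 1:300), paste0("s", 1:20)))
    z <- t(scale(t(z)))
    sig <- simulateSignature(sample(rownames(z), 50), seed = 5)
    n1 <- randomSetNull(z, sig, nSets = 50, seed = 99)
    n2 <- randomSetNull(z, sig, nSets = 50, seed = 99)
    expect_identical(nullScores(n1), nullScores(n2))
    expect_equal(dim(nullScores(n1)), c(50L, 20L))
    expect_true(all(abs(nullScores(n1)) <= 1))
    # centred: grand mean within 3 standard errors (sets as units)
    setMeans <- rowMeans(nullScores(n1))
    expect_lt(abs(mean(setMeans)),
              3 * sd(setMeans) / sqrt(length(setMeans)))
    small <- z[1:30, ]
    expect_error(randomSetNull(small, sig, nSets = 5, seed = 1),
                 "smaller")
})
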