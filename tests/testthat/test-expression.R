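test_that("count containers validate their inputs", {
    m <- matrix(1:4, 2, 2, dimnames = list(c("c1", "c2"), c("s1", "s2")))
    meta <- data.frame(sample_id = c("s1", "s2"), genotype = "G1",
                       phenotype = "bleached", treatment = "control",
                       timepoint = c("T1", "T2"))
    se <- countSE(m, meta)
    expect_s4_class(se, "SummarizedExperiment")

    expect_error(countSE(matrix(1:4, 2, 2), meta), "dimnames")
    bad <- m; bad[1, 1] <- -1
    expect_error(countSE(bad, meta), "non-negative")
    meta2 <- meta; meta2$sample_id <- c("s1", "sX")
    expect_error(countSE(m, meta2), "does not match")
})

test_that("the mean-count filter is boundary-inclusive", {
    m <- matrix(c(4.9, 4.9, 5, 5, 10, 10), 3, 2, byrow = TRUE,
                dimnames = list(paste0("c", 1:3), c("s1", "s2")))
    meta <- data.frame(sample_id = c("s1", "s2"), genotype = "G1",
                       phenotype = "b", treatment = "control",
                       timepoint = c("T1", "T2"))
    se <- countSE(round(m * 10) / 10, meta)
    expect_equal(rownames(filterByMeanCount(se, 5)), c("c2", "c3"))

    zero <- countSE(matrix(0, 2, 2,
        dimnames = list(paste0("c", 1:2), c("s1", "s2"))), meta)
    expect_warning(out <- filterByMeanCount(zero, 5), "no contig")
    expect_equal(nrow(out), 0)
})

test_that("median-of-ratios normalization is scale-invariant and recovers planted factors", {
    meta4 <- data.frame(sample_id = paste0("s", 1:4), genotype = "G1",
                        phenotype = "b", treatment = "control",
                        timepoint = "T1")
    base <- withr::with_seed(3, matrix(rpois(400, 50), 100, 4,
        dimnames = list(sprintf("c%03d", 1:100), paste0("s", 1:4))))

    # B = 2A: size-factor ratio 2, identical normalized profiles
    two <- base[, 1:2]; two[, 2] <- 2 * base[, 1]
    nTwo <- normalizeLog(countSE(two, meta4[1:2, ]))
    expect_equal(unname(nTwo$sizeFactor[2] / nTwo$sizeFactor[1]), 2,
                 tolerance = 1e-12)
    lt <- SummarizedExperiment::assay(nTwo, "logcounts")
    expect_equal(lt[, 1], lt[, 2], tolerance = 1e-12, ignore_attr = TRUE)

    # rescaling one sample's library: every count/size-factor ratio picks up
    # the same constant, so all between-sample contrasts are unchanged
    doubled <- base; doubled[, 2] <- 2 * base[, 2]
    n1 <- normalizeLog(countSE(base, meta4))
    n2 <- normalizeLog(countSE(doubled, meta4))
    expect_equal(unname(n2$sizeFactor[2] / n1$sizeFactor[2]),
                 2^(3 / 4), tolerance = 1e-12)
    ratio1 <- log2(2^SummarizedExperiment::assay(n1, "logcounts") - 1)
    ratio2 <- log2(2^SummarizedExperiment::assay(n2, "logcounts") - 1)
    expect_lt(stats::sd(ratio2 - ratio1), 1e-9)
    expect_equal(mean(ratio2 - ratio1), log2(2) / 4, tolerance = 1e-9)

    # identical samples -> unit factors
    same <- base; same[, ] <- base[, 1]
    expect_equal(unname(normalizeLog(countSE(same, meta4))$sizeFactor),
                 rep(1, 4))

    # planted 2x library-size gradient under NB noise, recovered within 5%
    sfTrue <- c(1, 1.26, 1.59, 2)
    sim <- withr::with_seed(9, {
        q <- rlnorm(2000, log(100), 1)
        mu <- outer(q, sfTrue)
        matrix(rnbinom(length(mu), mu = as.vector(mu), size = 10), 2000, 4,
               dimnames = list(sprintf("c%04d", 1:2000), paste0("s", 1:4)))
    })
    sfHat <- normalizeLog(countSE(sim, meta4))$sizeFactor
    sfHat <- sfHat / exp(mean(log(sfHat)))
    sfRef <- sfTrue / exp(mean(log(sfTrue)))
    expect_equal(unname(sfHat), sfRef, tolerance = 0.05)
})

test_that("size factors agree with the DESeq2 median-of-ratios oracle", {
    skip_if_not_installed("DESeq2")
    m <- withr::with_seed(5, matrix(rpois(600, 80) + 1, 100, 6,
        dimnames = list(sprintf("c%03d", 1:100), paste0("s", 1:6))))
    meta <- data.frame(sample_id = paste0("s", 1:6), genotype = "G1",
                       phenotype = "b", treatment = "control",
                       timepoint = "T1")
    ours <- normalizeLog(countSE(m, meta))$sizeFactor
    ref <- DESeq2::estimateSizeFactorsForMatrix(m)
    expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("PERMANOVA matches its exhaustive and vegan oracles", {
    # two maximally separated triplets among 6 samples -> exact p = 2/20
    x <- matrix(0, 5, 6, dimnames = list(NULL, paste0("s", 1:6)))
    x[, 4:6] <- 10
    g <- rep(c("a", "b"), each = 3)
    res <- permanovaTest(x, g, exhaustive = TRUE)
    expect_equal(res$p_value, 0.1)
    expect_equal(res$n_perm, 20)

    # pseudo-F equals the independent Gower-centering formula and vegan
    y <- withr::with_seed(2, matrix(rnorm(7 * 8), 7, 8))
    gy <- c("a", "a", "a", "b", "b", "b", "b", "a")
    d <- dist(t(y), method = "manhattan")
    res2 <- permanovaTest(y, gy, nPerm = 99, seed = 1)
    expect_equal(res2$pseudo_f, gowerPseudoF(d, gy), tolerance = 1e-9)
    if (requireNamespace("vegan", quietly = TRUE)) {
        ad <- vegan::adonis2(d ~ g, data = data.frame(g = gy),
                             permutations = 2)
        expect_equal(res2$pseudo_f, ad$F[1], tolerance = 1e-9)
        expect_equal(res2$variance_explained, ad$R2[1], tolerance = 1e-9)
    }

    # observed labeling is in the reference set: p >= 1/(nPerm+1)
    expect_gte(res2$p_value, 1 / 100)
    expect_error(permanovaTest(y, c("a", rep("b", 7)), seed = 1), "singleton")
    expect_error(permanovaTest(y, gy), "seed")
})

test_that("treatment responses recover planted interactions and remove drift", {
    meta <- studyMeta(genos = sprintf("G%02d", 1:4),
                      treatments = c("control", "constant_high"))
    n <- 30
    base <- matrix(5, n, nrow(meta),
                   dimnames = list(sprintf("c%03d", 1:n), meta$sample_id))
    isT2 <- meta$timepoint == "T2"
    isCH <- meta$treatment == "constant_high"
    planted <- 1:5
    mat <- base
    mat[planted, isT2 & isCH] <- mat[planted, isT2 & isCH] + 2
    mat[6:10, isT2] <- mat[6:10, isT2] + 1.5  # shared drift, both arms
    se <- logcountsSE(mat, meta)
    stats <- treatmentResponse(se)
    expect_equal(unname(stats$lfc_constant_high[planted]), rep(2, 5),
                 tolerance = 1e-9)
    expect_equal(unname(stats$lfc_constant_high[6:10]), rep(0, 5),
                 tolerance = 1e-9)
    expect_lt(max(stats$p_constant_high[planted]), 1e-12)

    # oracle: four-cell mean-difference arithmetic on the balanced design
    cellMean <- function(i, trt, tp)
        mean(mat[i, meta$treatment == trt & meta$timepoint == tp])
    for (i in c(1, 6, 15)) {
        oracle <- (cellMean(i, "constant_high", "T2") -
                   cellMean(i, "constant_high", "T1")) -
                  (cellMean(i, "control", "T2") - cellMean(i, "control", "T1"))
        expect_equal(stats$lfc_constant_high[i], oracle, tolerance = 1e-9)
    }

    # aliased interaction (treatment observed only at T2) -> error
    metaBad <- meta[!(isCH & meta$timepoint == "T1"), ]
    expect_error(
        treatmentResponse(logcountsSE(mat[, metaBad$sample_id], metaBad)),
        "aliased")
})

test_that("BH adjustment matches the hand-computed step-up", {
    expect_equal(bhFDR(0.04), 0.04)
    expect_equal(bhFDR(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhFDR(rep(1, 5)), rep(1, 5))
    expect_error(bhFDR(c(0.5, 1.2)), "\\[0, 1\\]")

    p <- withr::with_seed(1, runif(50))
    adj <- bhFDR(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in p order
})

test_that("constant-high z-scores follow the three-treatment contrast", {
    stats <- data.frame(lfc_constant_high = c(3, 3, 0),
                        lfc_pulse = c(0, 1, 0),
                        lfc_pulse_high = c(1, 1, 0.5),
                        lfc_pulse_increase = c(2, 1, 1),
                        row.names = paste0("c", 1:3))
    z <- constantHighZ(stats)
    expect_equal(z$z[1], 2)
    expect_true(z$flagged[2] && is.na(z$z[2]))
    expect_equal(z$z[3], -1)
    expect_error(constantHighZ(stats[, -2]), "missing treatment")
})

test_that("significance overlaps count intersections over unions", {
    sets <- list(a = c("A", "B", "C"), b = c("B", "C", "D"))
    res <- sharedSignificance(sets)
    expect_equal(res$shared_fraction, 0.5)
    expect_equal(res$pairwise["a", "b"], 0.5)
    expect_equal(sharedSignificance(list(x = "A", y = "B"))$shared_fraction, 0)
    expect_equal(sharedSignificance(list(x = c("A", "B"),
                                         y = c("A", "B")))$shared_fraction, 1)
    expect_equal(unname(res$region_counts[c("+-", "++", "-+")]),
                 c(1L, 2L, 1L), ignore_attr = TRUE)
})

test_that("genotype responses are exact difference-of-differences", {
    meta <- studyMeta(genos = c("G01", "G02"),
                      treatments = c("control", "constant_high"))
    mat <- matrix(2, 3, nrow(meta),
                  dimnames = list(paste0("c", 1:3), meta$sample_id))
    pick <- function(g, trt, tp)
        meta$sample_id[meta$genotype == g & meta$treatment == trt &
                       meta$timepoint == tp]
    mat[1, pick("G01", "constant_high", "T2")] <- 3        # CH rises by 1
    mat[2, pick("G02", "constant_high", "T2")] <- 3        # both rise by 1
    mat[2, pick("G02", "control", "T2")] <- 3
    gr <- genotypeResponse(logcountsSE(mat, meta))
    expect_equal(gr[1, "G01"], 1)
    expect_equal(gr[2, "G02"], 0)
    expect_equal(gr[3, ], c(G01 = 0, G02 = 0))

    metaM <- meta[-1, ]
    expect_warning(genotypeResponse(logcountsSE(mat[, metaM$sample_id],
                                                metaM)), "missing a cell")
})

test_that("the correlation screen matches its t-distribution oracle", {
    pot <- c(G01 = 0.2, G02 = -1, G03 = 0.4, G04 = 1.3, G05 = 0.8,
             G06 = -0.3, G07 = 0.5, G08 = 2.0, G09 = -0.7, G10 = 0.1)
    resp <- rbind(exact = -0.5 * pot,
                  flat = rep(1, 10))
    colnames(resp) <- names(pot)
    res <- correlationScreen(resp, pot)
    expect_equal(attr(res, "nExcluded"), 1)
    expect_equal(res$r[res$contig == "exact"], -1, tolerance = 1e-12)

    # construct a contig with exact sample correlation -0.965 over n = 10
    x <- scale(pot)[, 1]
    eps <- withr::with_seed(4, rnorm(10))
    eps <- residuals(lm(eps ~ x))
    eps <- eps / sqrt(sum(eps^2) / 9)
    r <- -0.965
    y <- r * x + sqrt(1 - r^2) * eps
    expect_equal(cor(y, pot), r, tolerance = 1e-12)
    res2 <- correlationScreen(rbind(probe = y, other = seq_len(10)), pot)
    pProbe <- res2$p[res2$contig == "probe"]
    tOracle <- r * sqrt(8) / sqrt(1 - r^2)
    expect_equal(pProbe, 2 * pt(-abs(tOracle), 8), tolerance = 1e-12)
    expect_equal(pProbe, 6.2e-6, tolerance = 0.02)

    expect_error(correlationScreen(resp[, 1:3], pot[1:3]), "at least 4")
})
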