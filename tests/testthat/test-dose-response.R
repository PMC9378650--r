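test_that("the Weibull decline honours its identities and bounds", {
    expect_equal(weibullW1(5, b = 2, e = 5), exp(-1))
    expect_equal(weibullW1(0, b = 2, e = 5), 1)
    # closed-form inversion: response 0.9 at e * (-ln 0.9)^(1/b)
    x90 <- 5 * (-log(0.9))^(1 / 2)
    expect_equal(weibullW1(x90, b = 2, e = 5), 0.9, tolerance = 1e-12)
    expect_error(weibullW1(1, b = -1, e = 5), "positive")
    expect_error(weibullW1(1, b = 1, e = 0), "positive")

    for (seed in 1:20) {
        par <- withr::with_seed(seed, c(b = runif(1, 0.3, 5),
                                        e = runif(1, 0.5, 10)))
        x <- seq(0, 3 * par[["e"]], length.out = 200)
        y <- weibullW1(x, par["b"], par["e"])
        # strictly decreasing wherever the response is numerically nonzero
        ok <- y[-1] > 1e-100
        expect_true(all(diff(y)[ok] < 0))
        expect_true(all(y >= 0 & y <= 1))
        expect_true(all(y[x < par[["e"]]] > exp(-1)))
    }
})

test_that("relative fv/fm normalizes by the fragment's initial readings", {
    traj <- data.frame(timestamp = ORIGIN + c(0, 86400, 2 * 86400),
                       edhw = c(0, 0.5, 1.2))
    pam <- data.frame(
        fragment_id = c("f1", "f1", "f1", "f2", "f2", "f2", "f3"),
        genotype = "G1", phenotype = "bleached", treatment = "control",
        timestamp = ORIGIN + c(0, 0, 2 * 86400, 0, 0, 86400, 86400),
        fvfm = c(0.60, 0.60, 0.54, 0.58, 0.62, 0.60, 0.5))
    expect_warning(pts <- relativeFvFm(pam, traj), "1 fragment")
    expect_equal(attr(pts, "nDropped"), 1)
    f1 <- pts[pts$fragment_id == "f1", ]
    expect_equal(f1$response, c(1, 1, 0.9))
    expect_equal(f1$dose, c(0, 0, 1.2))
    f2 <- pts[pts$fragment_id == "f2", ]
    expect_equal(f2$response[3], 1.0)
    expect_false("f3" %in% pts$fragment_id)
})

test_that("fitting recovers exact model data and flags degenerate input", {
    doses <- seq(0.5, 8, by = 0.5)
    pts <- weibullPoints(b = 1.5, e = 4, doses = doses)
    fit <- fitWeibull(pts)
    expect_equal(fit@b, 1.5, tolerance = 1e-6)
    expect_equal(fit@e, 4, tolerance = 1e-6)
    expect_lt(fit@sigma2 * (fit@nPoints - 2), 1e-12)
    expect_true(fit@converged)

    # multi-start grid-search oracle agrees with the optimiser
    grid <- expand.grid(b = seq(0.5, 3, by = 0.025),
                        e = seq(2, 6, by = 0.025))
    rss <- mapply(function(b, e) sum((pts$response - weibullW1(doses, b, e))^2),
                  grid$b, grid$e)
    best <- grid[which.min(rss), ]
    expect_equal(best$b, 1.5, tolerance = 1e-4)
    expect_equal(best$e, 4, tolerance = 1e-4)

    flat <- data.frame(dose = c(0, 1, 2, 3, 4, 5), response = rep(1, 6))
    res <- tryCatch(withCallingHandlers(
        fitWeibull(flat),
        warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) "error")
    if (!identical(res, "error")) expect_false(res@converged)

    expect_error(fitWeibull(pts[1:4, ]), "at least 6")
    expect_error(fitWeibull(data.frame(dose = rep(2, 6),
                                       response = rep(0.5, 6))), "identical")
})

test_that("ED10 closed form, limits and delta-method SE are correct", {
    fit <- makeFit(ed = 1, se = 0.1, b = 1)
    fit@b <- 1; fit@e <- 10
    ed <- ed10WithSE(fit, level = 10)
    expect_equal(unname(ed["ed"]), 10 * (-log(0.9)), tolerance = 1e-9)
    # numeric root-finding oracle
    root <- uniroot(function(x) weibullW1(x, 1, 10) - 0.9, c(1e-6, 10),
                    tol = 1e-12)$root
    expect_equal(unname(ed["ed"]), root, tolerance = 1e-9)

    # step-function limit: b large -> ED10 -> e
    fitB <- makeFit(ed = 4, se = 0.1, b = 1)
    fitB@b <- 1e3; fitB@e <- 5
    expect_equal(unname(ed10WithSE(fitB, 10)["ed"]), 5, tolerance = 0.05)

    # zero covariance -> zero SE
    fit0 <- makeFit(ed = 3, se = 1)
    fit0@cov <- matrix(0, 2, 2)
    expect_equal(unname(ed10WithSE(fit0)["se"]), 0)

    fitBad <- makeFit(ed = 3, se = 1)
    fitBad@cov <- matrix(c(1, 2, 2, 1), 2, 2)  # indefinite
    expect_error(ed10WithSE(fitBad), "positive semi-definite")
})

test_that("randomized ED10 closed form equals numeric inversion", {
    for (seed in 1:50) {
        par <- withr::with_seed(seed, c(b = runif(1, 0.2, 8),
                                        e = runif(1, 0.1, 20)))
        ed <- par[["e"]] * (-log(0.9))^(1 / par[["b"]])
        root <- uniroot(function(x) weibullW1(x, par[["b"]], par[["e"]]) - 0.9,
                        c(1e-9, par[["e"]] * 2), tol = 1e-13)$root
        expect_equal(ed, root, tolerance = 1e-9)
    }
})

test_that("Cook's filtering removes the planted outlier and refuses small n", {
    doses <- rep(seq(0.5, 8, by = 0.5), 3)
    pts <- weibullPoints(b = 1.5, e = 4, doses = doses, noiseSd = 0.03,
                         seed = 11)
    fit <- fitWeibull(pts)
    clean <- cooksFilter(pts, fit)
    # well-behaved data: few exclusions and a near-identical refit
    expect_lte(length(clean$excluded), 0.15 * nrow(pts))
    expect_equal(clean$fit@ed, fit@ed, tolerance = 0.05)

    # one gross outlier: leave-one-out oracle confirms it carries max D
    bad <- rbind(pts, data.frame(dose = 0.1, response = 0.1))
    fitB <- fitWeibull(bad)
    res <- cooksFilter(bad, fitB)
    expect_true(nrow(bad) %in% res$excluded)
    expect_equal(res$fit@nExcluded, length(res$excluded))
    rssDrop <- vapply(seq_len(nrow(bad)), function(i) {
        f <- fitWeibull(bad[-i, ])
        sum((bad$response[-i] - weibullW1(bad$dose[-i], f@b, f@e))^2)
    }, numeric(1))
    expect_equal(which.min(rssDrop), nrow(bad))

    # n = 6 with a flagged point -> refusal path
    six <- data.frame(dose = c(0.5, 1, 2, 3, 4, 5),
                      response = c(1, 0.98, 0.9, 0.75, 0.6, 0.05))
    fit6 <- fitWeibull(six)
    expect_warning(keep <- cooksFilter(six, fit6), "fewer than 6")
    expect_identical(keep$fit@nPoints, 6L)

    # an exact fit never excludes
    exact <- weibullPoints(1.5, 4, seq(0.5, 8, 0.5))
    fx <- fitWeibull(exact)
    expect_length(cooksFilter(exact, fx)$excluded, 0)
})

test_that("ED10 comparisons follow the normal reference and antisymmetry", {
    fa <- makeFit(5, 1, group = c(treatment = "control"))
    fb <- makeFit(8, 1, group = c(treatment = "constant_high"))
    same <- compareED10(fa, fa)
    expect_equal(same$statistic, 0)
    expect_equal(same$p_value, 1)

    cmp <- compareED10(fa, fb)
    expect_equal(cmp$delta, -3)
    expect_equal(cmp$se, sqrt(2))
    expect_equal(cmp$statistic, -3 / sqrt(2), tolerance = 1e-12)
    expect_equal(cmp$p_value, 2 * pnorm(-3 / sqrt(2)), tolerance = 1e-12)
    expect_equal(cmp$p_value, 0.0339, tolerance = 1e-2)

    rev <- compareED10(fb, fa)
    expect_equal(rev$delta, -cmp$delta)
    expect_equal(rev$statistic, -cmp$statistic)
    expect_equal(rev$p_value, cmp$p_value)

    z1 <- makeFit(5, 1); z1@edSE <- 0
    z2 <- makeFit(8, 1); z2@edSE <- 0
    expect_error(compareED10(z1, z2), "zero")
})

test_that("baseline ANOVA matches hand-computed sums of squares", {
    near <- withr::with_seed(1, data.frame(
        fvfm = 0.6 + rnorm(40, 0, 1e-9),
        phenotype = rep(c("b", "nb"), 20),
        treatment = rep(c("control", "pulse"), each = 20)))
    res <- baselineAnova(near)
    expect_lt(res$anova$sum_sq[1], 1e-12)
    expect_lt(res$anova$sum_sq[2], 1e-12)

    # 2x2 balanced, planted +0.1 treatment shift, zero noise
    m <- 5
    toy <- data.frame(
        fvfm = c(rep(0.6, m), rep(0.6, m), rep(0.7, m), rep(0.7, m)),
        phenotype = rep(rep(c("b", "nb"), each = m), 2),
        treatment = rep(c("X", "Y"), each = 2 * m))
    res2 <- baselineAnova(toy)
    # hand SS: N/4 cells; treatment SS = N * (shift/2)^2 * ... computed directly
    grand <- mean(toy$fvfm)
    ssTrt <- sum(tapply(toy$fvfm, toy$treatment, function(v)
        length(v) * (mean(v) - grand)^2))
    expect_equal(res2$anova$sum_sq[res2$anova$term == "treatment"], ssTrt,
                 tolerance = 1e-12)
    expect_equal(ssTrt, 20 * 0.05^2, tolerance = 1e-12)
    expect_lt(res2$anova$sum_sq[3], 1e-20)  # zero residual
    expect_true(is.matrix(res2$tukey))

    expect_error(baselineAnova(data.frame(fvfm = 1:4, phenotype = "b",
                                          treatment = c("X", "X", "Y", "Y"))),
                 "2 levels")
})

test_that("grouped fitting tabulates one converged fit per group", {
    doses <- seq(0.5, 8, by = 0.5)
    pts <- rbind(
        cbind(weibullPoints(1.5, 4, doses, 0.03, seed = 1),
              treatment = "control", genotype = "G1"),
        cbind(weibullPoints(1.5, 6, doses, 0.03, seed = 2),
              treatment = "constant_high", genotype = "G1"))
    res <- fitGroupedED10(pts, by = c("treatment", "genotype"))
    expect_equal(nrow(res$table), 2)
    expect_true(all(res$table$converged))
    edC <- res$table$ed[res$table$treatment == "control"]
    edT <- res$table$ed[res$table$treatment == "constant_high"]
    expect_equal(edC, 4 * (-log(0.9))^(1 / 1.5), tolerance = 0.15)
    expect_gt(edT, edC)
})
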