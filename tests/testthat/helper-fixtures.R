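# Small fixtures built in code, shared across test files.

ORIGIN <- as.POSIXct("2019-08-01 00:00:00", tz = "UTC")

# a constant-temperature series sampled every `byMin` minutes
constantSeries <- function(tempC, days, byMin = 10, tank = "T1",
                           trt = "constant") {
    tsec <- seq(0, days * 86400, by = byMin * 60)
    TemperatureSeries(ORIGIN + tsec, rep(tempC, length(tsec)), tank, trt)
}

# an arbitrary temperature function of time-in-days
profileSeries <- function(fun, days, byMin = 10, tank = "T1", trt = "prof") {
    tDays <- seq(0, days, by = byMin / (24 * 60))
    TemperatureSeries(ORIGIN + tDays * 86400, fun(tDays), tank, trt)
}

# a WeibullFit with prescribed ED and SE (for comparison-level tests);
# cov is chosen so the delta-method SE of the ED equals `se` exactly.
makeFit <- function(ed, se, b = 1, group = character()) {
    k <- -log(0.9)
    e <- ed / k^(1 / b)
    covEE <- (se * e / ed)^2
    fit <- new("WeibullFit", b = b, e = e,
               cov = matrix(c(0, 0, 0, covEE), 2, 2,
                            dimnames = list(c("b", "e"), c("b", "e"))),
               sigma2 = 0.001, nPoints = 60L, nExcluded = 0L,
               ed = ed, edSE = se, edLevel = 10, group = group,
               converged = TRUE)
    validObject(fit)
    fit
}

# exact dose-response points from a Weibull decline
weibullPoints <- function(b, e, doses, noiseSd = 0, seed = NULL) {
    mk <- function() data.frame(
        dose = doses,
        response = weibullW1(doses, b, e) +
            (if (noiseSd > 0) stats::rnorm(length(doses), 0, noiseSd) else 0))
    if (is.null(seed)) mk() else withr::with_seed(seed, mk())
}

# exhaustive two-sided rank-sum p-value (independent of wilcox.test):
# enumerates every assignment of group labels and compares rank sums
enumRankSumP <- function(x, y) {
    all <- c(x, y)
    rk <- rank(all)
    n1 <- length(x)
    obs <- sum(rk[seq_len(n1)])
    combos <- utils::combn(length(all), n1)
    sums <- apply(combos, 2, function(idx) sum(rk[idx]))
    mu <- n1 * (length(all) + 1) / 2
    mean(abs(sums - mu) >= abs(obs - mu) - 1e-12)
}

# independent PERMANOVA pseudo-F via Gower centering and the hat matrix
gowerPseudoF <- function(d, grouping) {
    D2 <- as.matrix(d)^2
    n <- nrow(D2)
    J <- diag(n) - matrix(1 / n, n, n)
    G <- -0.5 * J %*% D2 %*% J
    X <- stats::model.matrix(~ factor(grouping))
    H <- X %*% solve(crossprod(X), t(X))
    a <- length(unique(grouping))
    num <- sum(diag(H %*% G %*% H)) / (a - 1)
    den <- sum(diag((diag(n) - H) %*% G %*% (diag(n) - H))) / (n - a)
    num / den
}

# NB count container with planted per-sample scale factors, no signal
nullCountSE <- function(nContigs, meta, sf, dispersion = 0.1, seed = 1,
                        baselineMeanlog = log(60), baselineSdlog = 1.2) {
    withr::with_seed(seed, {
        q <- stats::rlnorm(nContigs, baselineMeanlog, baselineSdlog)
        mu <- outer(q, sf)
        counts <- matrix(
            stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion),
            nContigs, length(sf),
            dimnames = list(sprintf("c%04d", seq_len(nContigs)),
                            meta$sample_id))
        countSE(counts, meta)
    })
}

# the 100-sample study design
studyMeta <- function(genos = sprintf("G%02d", 1:10),
                      treatments = c("control", "constant_high", "pulse",
                                     "pulse_increase", "pulse_high")) {
    meta <- expand.grid(timepoint = c("T1", "T2"), treatment = treatments,
                        genotype = genos, stringsAsFactors = FALSE)
    meta$phenotype <- ifelse(match(meta$genotype, genos) <= length(genos) / 2,
                             "bleached", "nonbleached")
    meta$sample_id <- sprintf("s_%s_%s_%s", meta$genotype, meta$treatment,
                              meta$timepoint)
    meta
}

# a SummarizedExperiment carrying a prebuilt logcounts table
logcountsSE <- function(mat, meta) {
    SummarizedExperiment::SummarizedExperiment(
        assays = list(logcounts = mat),
        colData = S4Vectors::DataFrame(meta, row.names = colnames(mat)))
}
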