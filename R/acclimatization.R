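#' @include dose-response.R
NULL

#' Acclimatization potential of one genotype (or phenotype)
#'
#' The durable gain or loss of thermal tolerance conferred by a
#' pre-exposure: ED10(treatment) - ED10(control), in DHW, with the SEs
#' combined in quadrature and a two-sided normal test of delta = 0. The two
#' fits must describe the same genotype/phenotype group.
#'
#' @param fitTreatment,fitControl [WeibullFit-class] objects for the same
#'   genotype (or phenotype) under a heated pre-exposure and the control.
#' @return One-row data.frame: shared grouping labels, \code{delta_dhw},
#'   \code{se}, \code{statistic}, \code{p_value}.
#' @export
acclimatizationPotential <- function(fitTreatment, fitControl) {
    stopifnot(is(fitTreatment, "WeibullFit"), is(fitControl, "WeibullFit"))
    shared <- setdiff(names(fitTreatment@group), "treatment")
    if (!identical(fitTreatment@group[shared], fitControl@group[shared]))
        stop("fits do not share a grouping label (genotype/phenotype mismatch)")
    cmp <- compareED10(fitTreatment, fitControl)
    out <- data.frame(as.list(fitTreatment@group[shared]),
                      delta_dhw = cmp$delta, se = cmp$se,
                      statistic = cmp$statistic, p_value = cmp$p_value)
    rownames(out) <- NULL
    out
}

#' Bootstrap broad-sense heritability of acclimatization potential
#'
#' For each genotype, \code{nBoot} normal deviates are drawn per treatment
#' from (ED10, SE); draw j of the treatment is paired with draw j of the
#' control, giving \code{nBoot} acclimatization-potential values per
#' genotype. A one-way ANOVA across genotypes on the pooled draws partitions
#' the sums of squares, and broad-sense heritability is estimated as
#' \deqn{H^2 = SS_{between} / SS_{total},}
#' the fraction of total variance in acclimatization potential explained by
#' genotype. With all SEs zero and distinct genotype means, H^2 = 1 exactly.
#'
#' @param estimates data.frame with one row per genotype and columns
#'   \code{genotype}, \code{ed_treatment}, \code{se_treatment},
#'   \code{ed_control}, \code{se_control} (degC-weeks).
#' @param nBoot bootstrap replicates per genotype x treatment (default 1000).
#' @param seed integer seed; recorded in the output.
#' @return list of class \code{"heritability_result"}: \code{h2},
#'   \code{n_boot}, \code{ss_between}, \code{ss_total}, \code{anova_p},
#'   \code{seed}, and \code{draws} (genotype x nBoot matrix of bootstrap
#'   deltas, for plotting).
#' @export
bootstrapHeritability <- function(estimates, nBoot = 1000, seed) {
    need <- c("genotype", "ed_treatment", "se_treatment",
              "ed_control", "se_control")
    stopifnot(all(need %in% names(estimates)))
    if (nrow(estimates) < 2L) stop("need at least 2 genotypes")
    if (any(estimates$se_treatment < 0 | estimates$se_control < 0))
        stop("standard errors must be non-negative")
    if (nBoot < 2L) stop("nBoot must be at least 2")
    if (missing(seed)) stop("a seed is required for reproducibility")

    k <- nrow(estimates)
    draws <- withr::with_seed(seed, {
        m <- matrix(NA_real_, k, nBoot,
                    dimnames = list(estimates$genotype, NULL))
        for (i in seq_len(k)) {
            dt <- stats::rnorm(nBoot, estimates$ed_treatment[i],
                               estimates$se_treatment[i])
            dc <- stats::rnorm(nBoot, estimates$ed_control[i],
                               estimates$se_control[i])
            m[i, ] <- dt - dc
        }
        m
    })
    grand <- mean(draws)
    ssBetween <- nBoot * sum((rowMeans(draws) - grand)^2)
    ssTotal <- sum((draws - grand)^2)
    N <- k * nBoot
    ssWithin <- ssTotal - ssBetween
    fStat <- (ssBetween / (k - 1)) / (ssWithin / (N - k))
    anovaP <- if (ssWithin == 0) 0 else
        stats::pf(fStat, k - 1, N - k, lower.tail = FALSE)
    h2 <- if (ssTotal == 0) NA_real_ else ssBetween / ssTotal

    structure(list(h2 = h2, n_boot = as.integer(nBoot),
                   ss_between = ssBetween, ss_total = ssTotal,
                   anova_p = anovaP, seed = as.integer(seed),
                   draws = draws),
              class = "heritability_result")
}

#' @export
print.heritability_result <- function(x, ...) {
    cat(sprintf(
        "Bootstrap broad-sense heritability\n  H2 = %.4f  (SSb %.3f / SSt %.3f)\n  %d genotypes x %d draws, ANOVA p = %.3g, seed %d\n",
        x$h2, x$ss_between, x$ss_total, nrow(x$draws), x$n_boot,
        x$anova_p, x$seed))
    invisible(x)
}

#' One-sample test of the mean acclimatization effect
#'
#' Two-sided one-sample t-test of the per-genotype delta-DHW values against
#' a zero mean.
#'
#' @param deltas numeric vector of per-genotype acclimatization potentials
#'   (degC-weeks).
#' @return list: \code{mean}, \code{se}, \code{statistic}, \code{df},
#'   \code{p_value}.
#' @export
meanEffectTest <- function(deltas) {
    if (length(deltas) < 2L) stop("need at least 2 genotypes")
    if (stats::sd(deltas) == 0) stop("zero variance across genotypes")
    tt <- stats::t.test(deltas, mu = 0)
    list(mean = unname(tt$estimate), se = unname(tt$stderr),
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}

#' Regression of plasticity on basal thermal tolerance
#'
#' Ordinary least squares of per-genotype acclimatization potential on
#' basal (control) ED10, optionally excluding named genotypes, to ask
#' whether genotypes that already tolerate heat gain less from
#' pre-exposure.
#'
#' @param basal numeric vector of control ED10 per genotype (degC-weeks).
#' @param deltas numeric vector of acclimatization potentials, same order.
#' @param genotype optional genotype labels (needed when \code{drop} is
#'   used).
#' @param drop optional genotype labels to exclude before fitting.
#' @return list: \code{slope}, \code{intercept}, \code{r2}, \code{p_value}
#'   (two-sided slope test), \code{n}.
#' @export
basalPlasticityRegression <- function(basal, deltas, genotype = NULL,
                                      drop = NULL) {
    stopifnot(length(basal) == length(deltas))
    if (!is.null(drop)) {
        if (is.null(genotype)) stop("genotype labels required to drop by name")
        keep <- !(genotype %in% drop)
        basal <- basal[keep]; deltas <- deltas[keep]
    }
    if (length(basal) < 3L) stop("need at least 3 genotypes after drops")
    fit <- stats::lm(deltas ~ basal)
    sm <- summary(fit)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = sm$r.squared,
         p_value = sm$coefficients[2, 4],
         n = length(basal))
}

#' Dose at which a fragment first crosses a response level
#'
#' Linear interpolation between the bracketing doses at the first downward
#' crossing of \code{level} (default 0.9, i.e. a 10 percent decline in
#' relative fv/fm). Fragments that never cross are censored.
#'
#' @param dose numeric vector of accumulated doses (degC-weeks), ascending.
#' @param response numeric vector of relative fv/fm at each dose.
#' @param level response level to cross (default 0.9).
#' @return list: \code{dose} (degC-weeks, \code{NA} if censored),
#'   \code{censored} (logical).
#' @export
fragmentCrossingDose <- function(dose, response, level = 0.9) {
    stopifnot(length(dose) == length(response), length(dose) >= 2L)
    o <- order(dose)
    dose <- dose[o]; response <- response[o]
    if (response[1] < level)
        stop("trajectory starts below the crossing level")
    below <- which(response < level)
    if (!length(below)) return(list(dose = NA_real_, censored = TRUE))
    i <- below[1]
    x0 <- dose[i - 1]; x1 <- dose[i]
    y0 <- response[i - 1]; y1 <- response[i]
    list(dose = x0 + (level - y0) * (x1 - x0) / (y1 - y0), censored = FALSE)
}

#' Rank test of crossing doses between phenotypes
#'
#' Two-sided Wilcoxon rank-sum test of the dose at which fragments of two
#' phenotypes crossed the decline threshold. Small untied samples use the
#' exact distribution; otherwise the normal approximation with midrank tie
#' correction is used. Censored (NA) values are removed with a warning and
#' their count reported.
#'
#' @param x,y numeric crossing doses for the two phenotypes; NAs are
#'   treated as censored fragments and dropped.
#' @return list: \code{median_difference} (median(x) - median(y),
#'   degC-weeks), \code{mean_difference}, \code{statistic} (W),
#'   \code{p_value}, \code{n_censored}.
#' @export
phenotypeRankTest <- function(x, y) {
    nCens <- sum(is.na(x)) + sum(is.na(y))
    if (nCens > 0)
        warning(sprintf("%d censored fragment(s) excluded from rank test",
                        nCens), call. = FALSE)
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 3L || length(y) < 3L)
        stop("each phenotype needs at least 3 uncensored crossings")
    if (length(unique(c(x, y))) == 1L) {
        warning("all crossing doses tied across groups; p = 1", call. = FALSE)
        return(list(median_difference = 0, mean_difference = 0,
                    statistic = length(x) * length(y) / 2, p_value = 1,
                    n_censored = nCens))
    }
    hasTies <- anyDuplicated(c(x, y)) > 0
    wt <- suppressWarnings(stats::wilcox.test(
        x, y, exact = !hasTies && length(x) + length(y) < 50,
        correct = FALSE))
    list(median_difference = stats::median(x) - stats::median(y),
         mean_difference = mean(x) - mean(y),
         statistic = unname(wt$statistic), p_value = wt$p.value,
         n_censored = nCens)
}
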