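#' @include AllClasses.R
#' @importFrom minpack.lm nlsLM
NULL

#' Two-parameter Weibull decline with upper asymptote fixed at 1
#'
#' The type-1 Weibull dose-response function on the log-dose axis,
#' \deqn{f(x) = \exp(-\exp(b (\log x - \log e))),}
#' with the upper limit fixed at 1 and lower asymptote 0. \code{f(0)} is
#' defined as 1 (the continuous limit), so dose-0 points never evaluate a
#' log of zero. For \code{b > 0} the curve is strictly decreasing, equals
#' \code{exp(-1)} at \code{x = e}, and is bounded in (0, 1].
#'
#' @param dose non-negative dose (degC-weeks); vectorized.
#' @param b slope parameter, > 0.
#' @param e inflection dose, > 0.
#' @return Response values in (0, 1].
#' @examples
#' weibullW1(5, b = 2, e = 5)  # exp(-1)
#' weibullW1(0, b = 2, e = 5)  # 1 by the limit convention
#' @export
weibullW1 <- function(dose, b, e) {
    if (b <= 0 || e <= 0) stop("b and e must be positive")
    if (any(dose < 0)) stop("dose must be non-negative")
    out <- numeric(length(dose))
    pos <- dose > 0
    out[!pos] <- 1
    out[pos] <- exp(-exp(b * (log(dose[pos]) - log(e))))
    out
}

## analytic Jacobian of weibullW1 w.r.t. (b, e); rows = points
.weibullJacobian <- function(dose, b, e) {
    J <- matrix(0, length(dose), 2, dimnames = list(NULL, c("b", "e")))
    pos <- dose > 0
    L <- log(dose[pos]) - log(e)
    u <- exp(b * L)
    f <- exp(-u)
    J[pos, 1] <- -f * u * L
    J[pos, 2] <- f * u * b / e
    J
}

#' Relative fv/fm against accumulated thermal dose
#'
#' Divides every PAM reading of a fragment by the mean of that fragment's
#' initial (dose-0) readings, so each trajectory starts at 1 by
#' construction, and attaches the accumulated eDHW at each measurement
#' instant from a stress-test dose trajectory. Fragments without any dose-0
#' reading are excluded with a warning; the number dropped is recorded in
#' the \code{"nDropped"} attribute.
#'
#' @param pam data.frame with columns \code{fragment_id}, \code{genotype},
#'   \code{phenotype}, \code{treatment}, \code{timestamp}, \code{fvfm}.
#' @param trajectory dose trajectory of the stress-test tank(s) from
#'   [doseTrajectory()] (average replicate tanks before calling, if needed).
#' @param tol doses at or below \code{tol} count as initial readings.
#' @return data.frame of dose-response points: \code{fragment_id},
#'   \code{genotype}, \code{phenotype}, \code{treatment}, \code{dose},
#'   \code{response}.
#' @export
relativeFvFm <- function(pam, trajectory, tol = 1e-9) {
    need <- c("fragment_id", "genotype", "phenotype", "treatment",
              "timestamp", "fvfm")
    stopifnot(all(need %in% names(pam)))
    if (any(pam$fvfm < 0 | pam$fvfm > 1))
        stop("fvfm readings must lie in [0, 1]")
    dose <- doseAt(trajectory, pam$timestamp)
    out <- lapply(split(seq_len(nrow(pam)), pam$fragment_id), function(idx) {
        d <- dose[idx]
        init <- d <= tol
        if (!any(init)) return(NULL)
        base <- mean(pam$fvfm[idx][init])
        data.frame(fragment_id = pam$fragment_id[idx],
                   genotype = pam$genotype[idx],
                   phenotype = pam$phenotype[idx],
                   treatment = pam$treatment[idx],
                   dose = d, response = pam$fvfm[idx] / base)
    })
    nDropped <- sum(vapply(out, is.null, logical(1)))
    if (nDropped > 0)
        warning(sprintf("%d fragment(s) without initial readings dropped",
                        nDropped), call. = FALSE)
    res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    rownames(res) <- NULL
    attr(res, "nDropped") <- nDropped
    res
}

#' Fit the Weibull decline to dose-response points
#'
#' Least-squares estimation of (b, e) with the upper asymptote fixed at 1,
#' via Levenberg-Marquardt with box constraints and multi-start. The
#' parameter covariance is \code{sigma2 * solve(t(J) %*% J)} from the
#' analytic Jacobian at the optimum. The effective dose at \code{edLevel}
#' percent decline and its delta-method SE are computed at construction.
#'
#' Initialization: \code{e0} is the dose whose response is nearest
#' \code{exp(-1)} (falling back to the median positive dose), \code{b0 = 1};
#' five perturbed restarts are tried before declaring non-convergence.
#' Bounds: \code{b} in [0.01, 1e3], \code{e} in [1e-3, 10 max dose]. A fit
#' pinned at a bound is returned with \code{converged = FALSE} and a
#' warning, never silently.
#'
#' @param points data.frame with columns \code{dose} (>= 0) and
#'   \code{response} (> 0); at least 6 points over more than one distinct
#'   dose.
#' @param edLevel percent decline defining the effective dose (default 10,
#'   i.e. ED10).
#' @param group optional named character vector identifying the group.
#' @return A [WeibullFit-class] object.
#' @export
fitWeibull <- function(points, edLevel = 10, group = character()) {
    stopifnot(all(c("dose", "response") %in% names(points)))
    x <- points$dose
    y <- points$response
    if (length(x) < 6L) stop("need at least 6 dose-response points")
    if (length(unique(x)) < 2L) stop("all doses identical; cannot fit")
    if (any(x < 0)) stop("doses must be non-negative")
    if (!all(is.finite(y))) stop("responses must be finite")

    posDose <- x[x > 0]
    e0 <- posDose[which.min(abs(y[x > 0] - exp(-1)))]
    if (!length(e0) || !is.finite(e0) || e0 <= 0) e0 <- stats::median(posDose)
    starts <- list(c(b = 1, e = e0),
                   c(b = 0.3, e = e0), c(b = 3, e = e0),
                   c(b = 1, e = e0 * 0.5), c(b = 1, e = e0 * 2),
                   c(b = 0.5, e = e0 * 4))
    lower <- c(b = 0.01, e = 1e-3)
    upper <- c(b = 1e3, e = 10 * max(x))

    best <- NULL
    bestRSS <- Inf
    for (st in starts) {
        fit <- tryCatch(
            suppressWarnings(minpack.lm::nlsLM(
                y ~ weibullW1(x, b, e), start = as.list(st),
                lower = lower, upper = upper,
                control = minpack.lm::nls.lm.control(maxiter = 200))),
            error = function(err) NULL)
        if (is.null(fit)) next
        rss <- sum(stats::resid(fit)^2)
        if (rss < bestRSS) { best <- fit; bestRSS <- rss }
    }
    if (is.null(best)) {
        rss0 <- min(vapply(starts, function(st)
            sum((y - weibullW1(x, st["b"], st["e"]))^2), numeric(1)))
        stop(sprintf("Weibull fit failed to converge (best objective %.4g)",
                     rss0))
    }
    cf <- stats::coef(best)
    b <- unname(cf["b"]); e <- unname(cf["e"])
    atBound <- (b - lower["b"] < 1e-6 * b) || (upper["b"] - b < 1e-6 * b) ||
        (e - lower["e"] < 1e-6 * e) || (upper["e"] - e < 1e-6 * e)
    if (atBound)
        warning("fit pinned at a parameter bound; flagging as not converged",
                call. = FALSE)

    n <- length(x)
    sigma2 <- bestRSS / (n - 2)
    J <- .weibullJacobian(x, b, e)
    JtJ <- crossprod(J)
    covm <- tryCatch(sigma2 * solve(JtJ), error = function(err) {
        s <- svd(JtJ)
        dpos <- ifelse(s$d > max(s$d) * 1e-12, 1 / s$d, 0)
        sigma2 * (s$v %*% (dpos * t(s$u)))
    })
    covm <- (covm + t(covm)) / 2
    dimnames(covm) <- list(c("b", "e"), c("b", "e"))

    obj <- new("WeibullFit", b = b, e = e, cov = covm, sigma2 = sigma2,
               nPoints = as.integer(n), nExcluded = 0L,
               ed = NA_real_, edSE = NA_real_, edLevel = edLevel,
               group = group, converged = !atBound)
    ed <- ed10WithSE(obj, level = edLevel)
    obj@ed <- ed[["ed"]]
    obj@edSE <- ed[["se"]]
    validObject(obj)
    obj
}

#' Effective dose (default ED10) and its delta-method standard error
#'
#' For the Weibull decline with upper limit 1, the dose at which the
#' response has dropped by \code{level} percent has the closed form
#' \deqn{ED = e \, (-\log(1 - level/100))^{1/b}.}
#' The SE propagates the fitted (b, e) covariance through the gradient
#' \code{dED/db = -ED log(-log(1 - level/100)) / b^2},
#' \code{dED/de = ED / e}.
#'
#' @param fit a [WeibullFit-class].
#' @param level percent decline (default the fit's own \code{edLevel}).
#' @return Named numeric vector \code{c(ed = , se = )}, in degC-weeks.
#' @export
ed10WithSE <- function(fit, level = fit@edLevel) {
    stopifnot(is(fit, "WeibullFit"), level > 0, level < 100)
    ev <- eigen(fit@cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
        stop("fit covariance is not positive semi-definite")
    k <- -log(1 - level / 100)
    ed <- fit@e * k^(1 / fit@b)
    grad <- c(-ed * log(k) / fit@b^2, ed / fit@e)
    se <- sqrt(max(0, drop(t(grad) %*% fit@cov %*% grad)))
    c(ed = ed, se = se)
}

#' Influence filtering by Cook's distance, with one refit
#'
#' Cook's distances are computed from the linear-approximation hat matrix
#' \code{H = J (J'J)^-1 J'} at the fitted parameters:
#' \deqn{D_i = r_i^2 h_{ii} / (p \sigma^2 (1 - h_{ii})^2), \quad p = 2.}
#' Points with \code{D > 3 mean(D)} are removed in a single pass and the
#' curve is refit once. If the exclusion would leave fewer than 6 points the
#' original fit is returned unchanged with a warning.
#'
#' @param points the data.frame the fit was estimated from.
#' @param fit the converged [WeibullFit-class].
#' @return list with \code{points} (retained rows), \code{fit} (the refit,
#'   with \code{nExcluded} recorded) and \code{excluded} (row indices
#'   removed).
#' @export
cooksFilter <- function(points, fit) {
    stopifnot(is(fit, "WeibullFit"))
    x <- points$dose; y <- points$response
    r <- y - weibullW1(x, fit@b, fit@e)
    if (fit@sigma2 < .Machine$double.eps)  # an exact fit has no influence
        return(list(points = points, fit = fit, excluded = integer(0)))
    J <- .weibullJacobian(x, fit@b, fit@e)
    H <- J %*% solve(crossprod(J), t(J))
    h <- pmin(diag(H), 1 - 1e-10)
    p <- 2
    D <- r^2 * h / (p * fit@sigma2 * (1 - h)^2)
    flag <- D > 3 * mean(D)
    if (!any(flag))
        return(list(points = points, fit = fit, excluded = integer(0)))
    if (sum(!flag) < 6L) {
        warning("exclusion would leave fewer than 6 points; keeping all",
                call. = FALSE)
        return(list(points = points, fit = fit, excluded = integer(0)))
    }
    kept <- points[!flag, , drop = FALSE]
    refit <- fitWeibull(kept, edLevel = fit@edLevel, group = fit@group)
    refit@nExcluded <- as.integer(sum(flag))
    list(points = kept, fit = refit, excluded = which(flag))
}

#' Compare the effective doses of two fitted curves
#'
#' Difference of effective doses with SEs combined in quadrature and a
#' two-sided p-value from the standard normal reference (the reference is
#' recorded in the output).
#'
#' @param fitA,fitB [WeibullFit-class] objects.
#' @param labelA,labelB optional group labels for the output row.
#' @return One-row data.frame: \code{group_a}, \code{group_b}, \code{delta}
#'   (ED_a - ED_b, degC-weeks), \code{se}, \code{statistic}, \code{p_value},
#'   \code{reference}.
#' @export
compareED10 <- function(fitA, fitB,
                        labelA = paste(fitA@group, collapse = ":"),
                        labelB = paste(fitB@group, collapse = ":")) {
    stopifnot(is(fitA, "WeibullFit"), is(fitB, "WeibullFit"))
    if (fitA@edSE == 0 && fitB@edSE == 0)
        stop("both standard errors are zero; no comparison possible")
    delta <- fitA@ed - fitB@ed
    se <- sqrt(fitA@edSE^2 + fitB@edSE^2)
    z <- delta / se
    data.frame(group_a = labelA, group_b = labelB,
               delta = delta, se = se, statistic = z,
               p_value = 2 * stats::pnorm(-abs(z)),
               reference = "normal")
}

#' Two-way ANOVA of initial fv/fm across phenotype and treatment
#'
#' Main-effects two-way ANOVA (no interaction) of fragment-level pre-ramp
#' fv/fm, used to confirm recovery from pre-exposure before stress testing,
#' plus Tukey HSD across treatment pairs.
#'
#' @param initial data.frame with columns \code{fvfm}, \code{phenotype},
#'   \code{treatment}.
#' @return list with \code{anova} (data.frame: term, df, sum_sq, f, p) and
#'   \code{tukey} (the treatment-pair matrix from [TukeyHSD()]).
#' @export
baselineAnova <- function(initial) {
    stopifnot(all(c("fvfm", "phenotype", "treatment") %in% names(initial)))
    initial$phenotype <- factor(initial$phenotype)
    initial$treatment <- factor(initial$treatment)
    if (nlevels(initial$phenotype) < 2L || nlevels(initial$treatment) < 2L)
        stop("both factors need at least 2 levels")
    if (any(table(initial$phenotype) == 0) || any(table(initial$treatment) == 0))
        stop("non-estimable design: empty factor level")
    fit <- stats::aov(fvfm ~ phenotype + treatment, data = initial)
    sm <- summary(fit)[[1]]
    tab <- data.frame(term = trimws(rownames(sm)), df = sm[["Df"]],
                      sum_sq = sm[["Sum Sq"]], f = sm[["F value"]],
                      p = sm[["Pr(>F)"]])
    list(anova = tab,
         tukey = stats::TukeyHSD(fit, which = "treatment")$treatment)
}

#' Fit Weibull curves per group, with influence filtering
#'
#' Splits dose-response points by one or more grouping columns, fits each
#' group with [fitWeibull()], applies [cooksFilter()] once, and tabulates
#' the per-group estimates.
#'
#' @param points data.frame from [relativeFvFm()].
#' @param by character vector of grouping column names, e.g.
#'   \code{c("treatment", "phenotype")} or \code{c("treatment", "genotype")}.
#' @param edLevel percent decline defining the effective dose.
#' @param cooks apply the Cook's-distance exclusion pass (default TRUE).
#' @return list with \code{fits} (named list of [WeibullFit-class]) and
#'   \code{table} (one row per group: grouping columns, b, e, ed, ed_se, n,
#'   n_excluded, converged).
#' @export
fitGroupedED10 <- function(points, by = c("treatment", "phenotype"),
                           edLevel = 10, cooks = TRUE) {
    stopifnot(all(by %in% names(points)))
    key <- interaction(points[by], drop = TRUE, sep = ":")
    fits <- list()
    rows <- list()
    for (g in levels(key)) {
        sub <- points[key == g, , drop = FALSE]
        grp <- vapply(by, function(cn) as.character(sub[[cn]][1]), character(1))
        names(grp) <- by
        fit <- fitWeibull(sub[, c("dose", "response")], edLevel = edLevel,
                          group = grp)
        if (cooks) fit <- cooksFilter(sub[, c("dose", "response")], fit)$fit
        fits[[g]] <- fit
        rows[[g]] <- data.frame(as.list(grp), b = fit@b, e = fit@e,
                                ed = fit@ed, ed_se = fit@edSE,
                                n = fit@nPoints, n_excluded = fit@nExcluded,
                                converged = fit@converged)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    list(fits = fits, table = tab)
}
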