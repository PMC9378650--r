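#' @import methods
NULL

setOldClass(c("POSIXct", "POSIXt"))

#' TemperatureSeries: a timestamped logger record for one tank
#'
#' Holds the temperature time series of a single tank under a single
#' treatment. This is the dose axis for everything downstream: eDHW
#' accumulation, dose trajectories and rate-of-change summaries all start
#' from a \code{TemperatureSeries}.
#'
#' @slot timestamps \code{POSIXct}, strictly increasing, at least 2 instants.
#' @slot tempC numeric, temperature in degrees Celsius per instant; must be
#'   finite and within (0, 45).
#' @slot tankId character scalar, tank label.
#' @slot treatment character scalar, treatment label (e.g. \code{"control"},
#'   \code{"constant_high"}, \code{"pulse"}, \code{"pulse_increase"},
#'   \code{"pulse_high"}, \code{"stress_test"}).
#'
#' @seealso [TemperatureSeries()] for the constructor, [computeEDHW()],
#'   [doseTrajectory()], [rateOfChange()].
#' @export
setClass("TemperatureSeries",
    representation(
        timestamps = "POSIXct",
        tempC = "numeric",
        tankId = "character",
        treatment = "character"
    )
)

setValidity("TemperatureSeries", function(object) {
    msg <- character(0)
    n <- length(object@timestamps)
    if (n != length(object@tempC))
        msg <- c(msg, "timestamps and tempC must have equal length")
    if (n < 2L)
        msg <- c(msg, "a TemperatureSeries needs at least 2 instants")
    if (n >= 2L && any(diff(as.numeric(object@timestamps)) <= 0))
        msg <- c(msg, sprintf(
            "timestamps must be strictly increasing (tank '%s')",
            object@tankId))
    if (!all(is.finite(object@tempC)))
        msg <- c(msg, "temperatures must be finite")
    else if (any(object@tempC <= 0 | object@tempC >= 45))
        msg <- c(msg, "temperatures must lie within (0, 45) degrees C")
    if (length(object@tankId) != 1L || length(object@treatment) != 1L)
        msg <- c(msg, "tankId and treatment must be length-1 labels")
    if (length(msg)) msg else TRUE
})

#' Construct a TemperatureSeries
#'
#' @param timestamps `POSIXct` (or anything coercible via [as.POSIXct()]),
#'   strictly increasing.
#' @param tempC numeric vector of temperatures in degrees C.
#' @param tankId tank label.
#' @param treatment treatment label.
#' @return A [TemperatureSeries-class] object.
#' @examples
#' ts <- TemperatureSeries(
#'     as.POSIXct("2019-08-01", tz = "UTC") + 3600 * 0:23,
#'     rep(31.5, 24), tankId = "T1", treatment = "constant_high")
#' computeEDHW(ts, threshold = 28.5)
#' @export
TemperatureSeries <- function(timestamps, tempC, tankId = "tank1",
                              treatment = "unknown") {
    if (!inherits(timestamps, "POSIXct"))
        timestamps <- as.POSIXct(timestamps, tz = "UTC")
    new("TemperatureSeries", timestamps = timestamps, tempC = as.numeric(tempC),
        tankId = as.character(tankId), treatment = as.character(treatment))
}

setMethod("show", "TemperatureSeries", function(object) {
    n <- length(object@timestamps)
    cat(sprintf(
        "TemperatureSeries: tank '%s', treatment '%s'\n  %d instants, %s .. %s\n  temp %.2f-%.2f degC\n",
        object@tankId, object@treatment, n,
        format(object@timestamps[1]), format(object@timestamps[n]),
        min(object@tempC), max(object@tempC)))
})

#' WeibullFit: a fitted dose-response curve with its ED estimate
#'
#' Result of least-squares fitting of the two-parameter Weibull decline
#' (upper asymptote fixed at 1) of relative fv/fm against accumulated
#' thermal dose. Carries the slope \code{b}, inflection dose \code{e},
#' the parameter covariance from the Jacobian at the optimum, and the
#' effective dose (default ED10) with its delta-method standard error.
#'
#' @slot b numeric, slope parameter (> 0).
#' @slot e numeric, inflection dose in degC-weeks (> 0); the response equals
#'   exp(-1) at dose \code{e}.
#' @slot cov 2x2 parameter covariance matrix (order b, e).
#' @slot sigma2 residual variance.
#' @slot nPoints number of points used in the fit.
#' @slot nExcluded number of points removed by influence filtering.
#' @slot ed numeric, effective dose at \code{edLevel} percent decline.
#' @slot edSE delta-method standard error of \code{ed}.
#' @slot edLevel percent decline defining the effective dose (default 10).
#' @slot group named character vector identifying the fitted group, e.g.
#'   \code{c(treatment = "constant_high", genotype = "G03")}.
#' @slot converged logical; \code{FALSE} flags a boundary or dubious fit.
#' @seealso [fitWeibull()], [ed10WithSE()], [compareED10()]
#' @export
setClass("WeibullFit",
    representation(
        b = "numeric",
        e = "numeric",
        cov = "matrix",
        sigma2 = "numeric",
        nPoints = "integer",
        nExcluded = "integer",
        ed = "numeric",
        edSE = "numeric",
        edLevel = "numeric",
        group = "character",
        converged = "logical"
    )
)

setValidity("WeibullFit", function(object) {
    msg <- character(0)
    if (object@b <= 0) msg <- c(msg, "slope b must be positive")
    if (object@e <= 0) msg <- c(msg, "inflection e must be positive")
    if (!identical(dim(object@cov), c(2L, 2L)))
        msg <- c(msg, "cov must be 2x2")
    else if (max(abs(object@cov - t(object@cov))) > 1e-8 * (1 + max(abs(object@cov))))
        msg <- c(msg, "cov must be symmetric")
    if (length(msg)) msg else TRUE
})

setMethod("show", "WeibullFit", function(object) {
    grp <- if (length(object@group))
        paste(names(object@group), object@group, sep = "=", collapse = ", ")
    else "(ungrouped)"
    cat(sprintf(
        "WeibullFit [%s]\n  b = %.4f, e = %.4f degC-weeks\n  ED%g = %.4f +/- %.4f degC-weeks\n  n = %d (excluded %d), converged: %s\n",
        grp, object@b, object@e, object@edLevel, object@ed, object@edSE,
        object@nPoints, object@nExcluded, object@converged))
})
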