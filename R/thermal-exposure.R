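#' @include AllClasses.R
NULL

DAYS_PER_WEEK <- 7
SECONDS_PER_DAY <- 86400

## time axis of a series, in days since its first instant
.timeDays <- function(series) {
    t0 <- as.numeric(series@timestamps)
    (t0 - t0[1]) / SECONDS_PER_DAY
}

.warnOnGaps <- function(series, maxGapHours = 6) {
    gaps <- diff(as.numeric(series@timestamps)) / 3600
    if (any(gaps > maxGapHours))
        warning(sprintf(
            "tank '%s': %d logger gap(s) longer than %g h; integrating across them",
            series@tankId, sum(gaps > maxGapHours), maxGapHours), call. = FALSE)
    invisible(series)
}

#' Read a temperature logger CSV into TemperatureSeries objects
#'
#' Expects columns \code{timestamp} (ISO-8601), \code{tank},
#' \code{treatment} and \code{temp_c}. One series is returned per
#' (tank, treatment) combination, with rows sorted by time. Rows with an
#' unparseable timestamp or temperature are dropped with a warning that
#' reports their line numbers.
#'
#' @param path path to the CSV file.
#' @param tz time zone used to parse timestamps (default \code{"UTC"}).
#' @return A named list of [TemperatureSeries-class] objects
#'   (\code{"<treatment>.<tank>"}); empty (with a warning) for an empty file.
#' @export
readTemperatureLog <- function(path, tz = "UTC") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    required <- c("timestamp", "tank", "treatment", "temp_c")
    missing <- setdiff(required, names(df))
    if (length(missing))
        stop("temperature log is missing column(s): ",
             paste(missing, collapse = ", "))
    if (nrow(df) == 0L) {
        warning("empty temperature log: ", path, call. = FALSE)
        return(list())
    }
    formats <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                 "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")
    ts <- as.POSIXct(rep(NA_character_, nrow(df)), tz = tz, optional = TRUE)
    for (fmt in formats) {
        miss <- is.na(ts)
        if (!any(miss)) break
        ts[miss] <- as.POSIXct(strptime(df$timestamp[miss], fmt, tz = tz))
    }
    temp <- suppressWarnings(as.numeric(df$temp_c))
    bad <- is.na(ts) | is.na(temp)
    if (any(bad)) {
        warning(sprintf("dropping %d malformed row(s) at line(s): %s",
                        sum(bad),
                        paste(which(bad) + 1L, collapse = ", ")), call. = FALSE)
        df <- df[!bad, , drop = FALSE]
        ts <- ts[!bad]; temp <- temp[!bad]
    }
    key <- paste(df$treatment, df$tank, sep = ".")
    out <- lapply(split(seq_len(nrow(df)), key), function(idx) {
        o <- idx[order(ts[idx])]
        tk <- df$tank[o[1]]
        if (anyDuplicated(as.numeric(ts[o])))
            stop(sprintf("duplicated timestamp in tank '%s'", tk))
        TemperatureSeries(ts[o], temp[o], tankId = tk,
                          treatment = df$treatment[o[1]])
    })
    out[sort(names(out))]
}

## trapezoidal integral of max(0, T - threshold) over a time axis in days,
## returned in degC-weeks
.edhwTrapezoid <- function(tDays, temp, threshold) {
    hot <- pmax(0, temp - threshold)
    dt <- diff(tDays)
    sum(dt * (hot[-length(hot)] + hot[-1]) / 2) / DAYS_PER_WEEK
}

#' Experimental Degree Heating Weeks (eDHW)
#'
#' Time-integrates the positive exceedance of temperature above a
#' climatological threshold (hotspots) by the trapezoid rule over the raw
#' logger intervals, and expresses the result in degC-weeks. The default
#' threshold of 28.5 degC is the Kaneohe Bay mean monthly maximum + 1 degC;
#' because the +1 degC is already in the threshold, every positive
#' exceedance accumulates (no secondary hotspot gate). Logger gaps longer
#' than 6 h trigger a warning but are integrated across.
#'
#' @param series a [TemperatureSeries-class].
#' @param threshold accumulation threshold in degC (default 28.5).
#' @return eDHW in degC-weeks (>= 0); 0 when the series never exceeds the
#'   threshold.
#' @examples
#' ts <- TemperatureSeries(
#'     as.POSIXct("2019-08-01", tz = "UTC") + 600 * 0:(7 * 144),
#'     rep(31.5, 7 * 144 + 1), "T1", "constant_high")
#' computeEDHW(ts)  # 3 degC sustained for one week -> 3 degC-weeks
#' @export
computeEDHW <- function(series, threshold = 28.5) {
    stopifnot(is(series, "TemperatureSeries"), is.finite(threshold))
    validObject(series)
    .warnOnGaps(series)
    .edhwTrapezoid(.timeDays(series), series@tempC, threshold)
}

#' Cumulative eDHW trajectory at every logger instant
#'
#' The running (non-decreasing) trapezoidal integral of hotspots, in
#' degC-weeks, evaluated at each logged instant. Its final value equals
#' [computeEDHW()] on the same series. This trajectory is the dose axis for
#' stress-test dose-response fitting: PAM measurement instants are mapped to
#' accumulated dose with [doseAt()].
#'
#' @inheritParams computeEDHW
#' @return A data.frame with columns \code{timestamp} and \code{edhw}.
#' @export
doseTrajectory <- function(series, threshold = 28.5) {
    stopifnot(is(series, "TemperatureSeries"), is.finite(threshold))
    validObject(series)
    tDays <- .timeDays(series)
    hot <- pmax(0, series@tempC - threshold)
    dt <- diff(tDays)
    inc <- dt * (hot[-length(hot)] + hot[-1]) / 2 / DAYS_PER_WEEK
    data.frame(timestamp = series@timestamps, edhw = c(0, cumsum(inc)))
}

#' Interpolate accumulated dose at arbitrary instants
#'
#' @param trajectory a data.frame from [doseTrajectory()].
#' @param instants `POSIXct` instants at which the cumulative dose is wanted;
#'   they must lie within the logged range.
#' @return Numeric vector of accumulated eDHW (degC-weeks) at each instant.
#' @export
doseAt <- function(trajectory, instants) {
    stopifnot(all(c("timestamp", "edhw") %in% names(trajectory)))
    tx <- as.numeric(trajectory$timestamp)
    ti <- as.numeric(as.POSIXct(instants,
        tz = attr(trajectory$timestamp, "tzone") %||% "UTC"))
    if (any(ti < tx[1] - 1e-6 | ti > tx[length(tx)] + 1e-6))
        stop("query instant outside the logged range")
    stats::approx(tx, trajectory$edhw, xout = ti, rule = 1)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean absolute rate of temperature change
#'
#' Mean of |dT/dt| over consecutive logger intervals, in degC per hour.
#' Averaging across replicate tanks is the caller's mean of per-tank values.
#'
#' @param series a [TemperatureSeries-class].
#' @return Mean absolute rate in degC/hr (>= 0).
#' @export
rateOfChange <- function(series) {
    stopifnot(is(series, "TemperatureSeries"))
    validObject(series)
    dtHours <- diff(as.numeric(series@timestamps)) / 3600
    if (any(dtHours <= 0)) stop("zero-length logger interval")
    mean(abs(diff(series@tempC) / dtHours))
}

#' Per-tank exposure summary table
#'
#' @param seriesList a list of [TemperatureSeries-class] objects, e.g. from
#'   [readTemperatureLog()] or [generateProfiles()].
#' @param threshold accumulation threshold in degC.
#' @return A data.frame with one row per series: \code{treatment},
#'   \code{tank}, \code{edhw}, \code{mean_rate}, \code{max_temp},
#'   \code{threshold}.
#' @export
exposureSummary <- function(seriesList, threshold = 28.5) {
    stopifnot(length(seriesList) > 0)
    rows <- lapply(seriesList, function(s) {
        data.frame(treatment = s@treatment, tank = s@tankId,
                   edhw = computeEDHW(s, threshold),
                   mean_rate = rateOfChange(s),
                   max_temp = max(s@tempC),
                   threshold = threshold)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
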