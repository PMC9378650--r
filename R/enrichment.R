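#' @include expression.R
NULL

#' Load a contig -> GO annotation map
#'
#' Reads the two-column tab-separated format used by rank-based GO
#' enrichment tools: contig id, then a semicolon-joined list of category
#' ids. Duplicate contig rows are merged by union; an empty category field
#' records the contig with an empty set; malformed (empty after trimming)
#' category tokens are skipped with a warning.
#'
#' @param path path to the annotation file (no header).
#' @return named list mapping contig id to a character vector of category
#'   ids.
#' @export
loadAnnotations <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    out <- list()
    nBad <- 0L
    for (ln in lines) {
        parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        id <- trimws(parts[1])
        cats <- if (length(parts) < 2L || !nzchar(trimws(parts[2])))
            character(0)
        else trimws(strsplit(parts[2], ";", fixed = TRUE)[[1]])
        bad <- !nzchar(cats)
        nBad <- nBad + sum(bad)
        cats <- unique(cats[!bad])
        out[[id]] <- union(out[[id]] %||% character(0), cats)
    }
    if (nBad > 0)
        warning(sprintf("%d malformed category token(s) skipped", nBad),
                call. = FALSE)
    out
}

#' Rank-based functional enrichment on continuous scores
#'
#' For each annotation category within the size bounds, a two-sided
#' Mann-Whitney U test of in-category versus out-of-category "heats"
#' (continuous per-contig scores such as constant-high z-scores or
#' plasticity correlation coefficients). Being rank-based, the result is
#' invariant to any strictly monotone transform of the heats. Small untied
#' problems (total contigs <= \code{exactMax}) use the exact U
#' distribution; otherwise the normal approximation with midrank tie
#' correction and continuity correction. Direction records whether the
#' category sits in high or low
#' heats; BH FDR is applied across the tested categories.
#'
#' Categories are tested as given: no GO-hierarchy collapsing is performed
#' (supply pre-expanded ancestor annotations if hierarchical propagation is
#' wanted); this is recorded in the \code{"method"} attribute.
#'
#' @param heats named numeric vector of per-contig scores.
#' @param annotations annotation map from [loadAnnotations()].
#' @param minSize smallest category size tested (default 10).
#' @param maxFrac largest category size, as a fraction of scored contigs
#'   (default 0.1).
#' @param fdrThreshold FDR used to label significance (default 0.1).
#' @return data.frame sorted by FDR: \code{category}, \code{n_genes},
#'   \code{u_statistic}, \code{direction} (\code{"high"}/\code{"low"}),
#'   \code{median_heat}, \code{p}, \code{fdr}, \code{significant}.
#' @export
mwuEnrichment <- function(heats, annotations, minSize = 10, maxFrac = 0.1,
                          fdrThreshold = 0.1, exactMax = 12) {
    heats <- heats[!is.na(heats)]
    ids <- names(heats)
    if (is.null(ids)) stop("heats must be a named vector")
    byCat <- list()
    for (id in intersect(ids, names(annotations)))
        for (cat in annotations[[id]])
            byCat[[cat]] <- c(byCat[[cat]], id)
    total <- length(heats)
    sizes <- lengths(byCat)
    keep <- sizes >= minSize & sizes <= maxFrac * total
    if (!any(keep)) {
        warning("no category passes the size filters", call. = FALSE)
        return(data.frame(category = character(0), n_genes = integer(0),
                          u_statistic = numeric(0), direction = character(0),
                          median_heat = numeric(0), p = numeric(0),
                          fdr = numeric(0), significant = logical(0)))
    }
    byCat <- byCat[keep]
    hasTies <- anyDuplicated(heats) > 0
    useExact <- total <= exactMax && !hasTies
    rows <- lapply(names(byCat), function(cat) {
        inIds <- byCat[[cat]]
        hin <- heats[inIds]
        hout <- heats[setdiff(ids, inIds)]
        wt <- suppressWarnings(stats::wilcox.test(
            hin, hout, exact = useExact, correct = TRUE))
        data.frame(category = cat, n_genes = length(hin),
                   u_statistic = unname(wt$statistic),
                   direction = if (stats::median(hin) >= stats::median(hout))
                       "high" else "low",
                   median_heat = stats::median(hin),
                   p = wt$p.value)
    })
    out <- do.call(rbind, rows)
    out$fdr <- bhFDR(out$p)
    out$significant <- out$fdr < fdrThreshold
    out <- out[order(out$fdr, out$p), ]
    rownames(out) <- NULL
    attr(out, "method") <- paste0(
        "two-sided Mann-Whitney U (", if (useExact) "exact" else
            "normal approximation, midrank tie correction",
        "); categories tested as given, no hierarchy collapsing")
    out
}
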