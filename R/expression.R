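#' @include thermal-exposure.R
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame
NULL

#' Assemble a contig x sample count container
#'
#' Wraps a raw count matrix and its sample metadata in a
#' \link[SummarizedExperiment]{SummarizedExperiment} with assay
#' \code{"counts"}; all downstream expression operations accept this
#' container.
#'
#' @param counts integer matrix, contigs in rows, samples in columns;
#'   dimnames required, counts finite and non-negative.
#' @param meta data.frame with one row per sample (matched to columns by
#'   \code{sample_id} or row order) carrying \code{genotype},
#'   \code{phenotype}, \code{treatment} and \code{timepoint}.
#' @return A \code{SummarizedExperiment}.
#' @export
countSE <- function(counts, meta) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must carry contig and sample dimnames")
    if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
        stop("duplicate contig or sample ids")
    if (any(!is.finite(counts)) || any(counts < 0))
        stop("counts must be finite and non-negative")
    need <- c("genotype", "phenotype", "treatment", "timepoint")
    stopifnot(all(need %in% names(meta)))
    if ("sample_id" %in% names(meta)) {
        if (!setequal(meta$sample_id, colnames(counts)))
            stop("meta sample_id does not match count columns")
        meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
    } else if (nrow(meta) != ncol(counts)) {
        stop("meta must have one row per sample")
    }
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(meta, row.names = colnames(counts)))
}

#' Filter contigs by mean count across all samples
#'
#' Retains contigs averaging at least \code{minMean} reads per sample
#' (boundary inclusive), preserving row order.
#'
#' @param se a count container from [countSE()].
#' @param minMean minimum mean count (default 5 reads).
#' @return The filtered \code{SummarizedExperiment} (empty, with a warning,
#'   if nothing passes).
#' @export
filterByMeanCount <- function(se, minMean = 5) {
    keep <- rowMeans(SummarizedExperiment::assay(se, "counts")) >= minMean
    if (!any(keep))
        warning("no contig passes the mean-count filter", call. = FALSE)
    se[keep, ]
}

#' Median-of-ratios size factors and log2 normalization
#'
#' Per-sample size factors are the median ratio of each sample's counts to
#' the per-contig geometric mean, computed over contigs with nonzero counts
#' in every sample; normalized values are \code{log2(count / sizeFactor +
#' 1)}. If no contig is nonzero in all samples the function falls back to
#' total-count scaling (library sizes rescaled to geometric mean 1) with a
#' warning. The normalized table is invariant to rescaling any sample's
#' library size.
#'
#' @param se a count container from [countSE()].
#' @return The container with an added assay \code{"logcounts"} and a
#'   \code{sizeFactor} column in \code{colData}.
#' @export
normalizeLog <- function(se) {
    counts <- SummarizedExperiment::assay(se, "counts")
    if (any(colSums(counts) == 0))
        stop("every sample needs at least one nonzero count")
    allNonzero <- rowSums(counts == 0) == 0
    if (any(allNonzero)) {
        logGeo <- rowMeans(log(counts[allNonzero, , drop = FALSE]))
        sf <- apply(counts[allNonzero, , drop = FALSE], 2, function(cnt)
            exp(stats::median(log(cnt) - logGeo)))
    } else {
        warning("no contig nonzero in all samples; using total-count scaling",
                call. = FALSE)
        libs <- colSums(counts)
        sf <- libs / exp(mean(log(libs)))
    }
    norm <- log2(sweep(counts, 2, sf, "/") + 1)
    SummarizedExperiment::assay(se, "logcounts") <- norm
    se$sizeFactor <- sf
    se
}

## all distinct arrangements of a multiset of labels (small n only)
.multisetPerms <- function(labels) {
    tab <- table(labels)
    lev <- names(tab)
    n <- length(labels)
    res <- list()
    rec <- function(prefix, counts) {
        if (length(prefix) == n) {
            res[[length(res) + 1L]] <<- prefix
            return(invisible())
        }
        for (i in seq_along(lev)) {
            if (counts[i] > 0L) {
                counts[i] <- counts[i] - 1L
                rec(c(prefix, lev[i]), counts)
                counts[i] <- counts[i] + 1L
            }
        }
    }
    rec(character(0), as.integer(tab))
    do.call(rbind, res)
}

## distance-based one-way SS partition (McArdle-Anderson)
.permanovaF <- function(d2, grouping) {
    n <- length(grouping)
    ssTotal <- sum(d2) / (2 * n)  # d2 is a full symmetric matrix
    ssWithin <- 0
    for (g in unique(grouping)) {
        idx <- which(grouping == g)
        ssWithin <- ssWithin + sum(d2[idx, idx]) / (2 * length(idx))
    }
    a <- length(unique(grouping))
    ssBetween <- ssTotal - ssWithin
    fStat <- (ssBetween / (a - 1)) / (ssWithin / (n - a))
    c(f = fStat, r2 = ssBetween / ssTotal)
}

#' PERMANOVA on Manhattan distances
#'
#' Permutational multivariate ANOVA of a normalized expression table (or a
#' precomputed distance) against a single grouping factor, using the
#' distance-based pseudo-F of the McArdle-Anderson sums-of-squares
#' partition. Labels are permuted freely (no strata); the p-value is
#' \code{(1 + #(F_perm >= F_obs)) / (nPerm + 1)}. With
#' \code{exhaustive = TRUE} all distinct label arrangements are enumerated
#' and the p-value is the exact proportion with \code{F >= F_obs}
#' (practical only for small n).
#'
#' @param x features x samples numeric matrix (e.g. the \code{logcounts}
#'   assay), or a \code{dist} over samples.
#' @param grouping factor of length n samples.
#' @param nPerm number of random permutations (default 999).
#' @param seed integer seed (required unless exhaustive).
#' @param exhaustive enumerate all distinct labelings instead of sampling.
#' @return list: \code{pseudo_f}, \code{variance_explained} (R^2),
#'   \code{p_value}, \code{n_perm}.
#' @export
permanovaTest <- function(x, grouping, nPerm = 999, seed = NULL,
                          exhaustive = FALSE) {
    grouping <- as.character(grouping)
    tab <- table(grouping)
    if (length(tab) < 2L) stop("need at least 2 groups")
    if (any(tab < 2L)) stop("singleton group in PERMANOVA design")
    d <- if (inherits(x, "dist")) x else stats::dist(t(x), method = "manhattan")
    d2 <- as.matrix(d)^2
    n <- nrow(d2)
    stopifnot(n == length(grouping))
    obs <- .permanovaF(d2, grouping)

    if (exhaustive) {
        arr <- .multisetPerms(grouping)
        fs <- apply(arr, 1, function(g) .permanovaF(d2, g)["f"])
        p <- mean(fs >= obs["f"] - 1e-12)
        nP <- nrow(arr)
    } else {
        if (is.null(seed)) stop("a seed is required for permutation testing")
        fs <- withr::with_seed(seed, vapply(seq_len(nPerm), function(i)
            .permanovaF(d2, sample(grouping))["f"], numeric(1)))
        p <- (1 + sum(fs >= obs["f"] - 1e-12)) / (nPerm + 1)
        nP <- nPerm
    }
    list(pseudo_f = unname(obs["f"]),
         variance_explained = unname(obs["r2"]),
         p_value = p, n_perm = nP)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p numeric p-values in [0, 1].
#' @return Step-up adjusted values, order preserved.
#' @export
bhFDR <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Control-corrected treatment responses per contig
#'
#' Per contig, an ordinary linear model of normalized log2 expression with
#' additive phenotype, genotype, timepoint and treatment terms plus the
#' timepoint x treatment interaction. The control-corrected log2
#' fold-change of each heated treatment is its interaction coefficient:
#' the T2 - T1 change in that treatment minus the concurrent T2 - T1 change
#' in the control. Two-sided p-values come from the unmoderated coefficient
#' t-test; BH FDR is applied within treatment.
#'
#' Phenotype is constant within genotype in this design, so the phenotype
#' main effect is absorbed by the genotype terms; such aliased main-effect
#' columns are dropped automatically. An aliased interaction column is an
#' error (the contrast of interest would not be estimable).
#'
#' @param se a normalized container from [normalizeLog()] with colData
#'   factors \code{phenotype}, \code{genotype}, \code{treatment},
#'   \code{timepoint}.
#' @param control label of the control treatment (default
#'   \code{"control"}).
#' @param timepointRef label of the first timepoint (default \code{"T1"}).
#' @return data.frame with one row per contig and columns
#'   \code{lfc_<treatment>}, \code{p_<treatment>}, \code{fdr_<treatment>}
#'   for each heated treatment.
#' @export
treatmentResponse <- function(se, control = "control", timepointRef = "T1") {
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    mat <- SummarizedExperiment::assay(se, "logcounts")
    cd$treatment <- stats::relevel(factor(cd$treatment), ref = control)
    cd$timepoint <- stats::relevel(factor(cd$timepoint), ref = timepointRef)
    cd$genotype <- factor(cd$genotype)
    cd$phenotype <- factor(cd$phenotype)
    if (nlevels(cd$timepoint) != 2L)
        stop("exactly two timepoints are required")
    design <- stats::model.matrix(
        ~ phenotype + genotype + timepoint + treatment + timepoint:treatment,
        data = cd)
    qrd <- qr(design)
    if (qrd$rank < ncol(design)) {
        aliased <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
        if (any(grepl(":", aliased, fixed = TRUE)))
            stop("rank-deficient design; aliased term(s): ",
                 paste(aliased, collapse = ", "))
        design <- design[, setdiff(colnames(design), aliased), drop = FALSE]
    }
    fit <- limma::lmFit(mat, design)
    tpLev <- levels(cd$timepoint)[2]
    heated <- setdiff(levels(cd$treatment), control)
    out <- data.frame(row.names = rownames(mat))
    for (trt in heated) {
        cn <- paste0("timepoint", tpLev, ":treatment", trt)
        if (!cn %in% colnames(design))
            stop("interaction column missing for treatment ", trt)
        lfc <- fit$coefficients[, cn]
        seCoef <- fit$stdev.unscaled[, cn] * fit$sigma
        tstat <- lfc / seCoef
        p <- 2 * stats::pt(-abs(tstat), df = fit$df.residual)
        p[is.nan(p)] <- 1  # zero coefficient with zero residual variance
        out[[paste0("lfc_", trt)]] <- lfc
        out[[paste0("p_", trt)]] <- p
        out[[paste0("fdr_", trt)]] <- bhFDR(p)
    }
    out
}

#' Summaries of response magnitude across treatments
#'
#' Per-treatment mean absolute log2 fold-change with SE, a one-way ANOVA of
#' |lfc| across treatments with Tukey HSD, and an OLS regression of the
#' per-treatment mean response on the treatment's accumulated eDHW (both
#' the mean |lfc| and the signed mean lfc variants are fit).
#'
#' @param stats output of [treatmentResponse()].
#' @param exposures data.frame with columns \code{treatment} and
#'   \code{edhw} (one row per heated treatment; replicate tanks averaged).
#' @return list: \code{per_treatment} (treatment, mean_abs_lfc, se,
#'   mean_lfc, edhw), \code{anova} (data.frame), \code{tukey} (matrix),
#'   \code{regression_abs} and \code{regression_signed} (slope, r2,
#'   p_value), the latter two \code{NULL} with a warning if fewer than 3
#'   treatments are available.
#' @export
lfcMagnitudeSummary <- function(stats, exposures) {
    lfcCols <- grep("^lfc_", names(stats), value = TRUE)
    treatments <- sub("^lfc_", "", lfcCols)
    perTrt <- data.frame(
        treatment = treatments,
        mean_abs_lfc = vapply(lfcCols, function(cn) mean(abs(stats[[cn]])),
                              numeric(1)),
        se = vapply(lfcCols, function(cn)
            stats::sd(abs(stats[[cn]])) / sqrt(nrow(stats)), numeric(1)),
        mean_lfc = vapply(lfcCols, function(cn) mean(stats[[cn]]), numeric(1)))
    perTrt$edhw <- exposures$edhw[match(perTrt$treatment, exposures$treatment)]
    rownames(perTrt) <- NULL

    long <- data.frame(
        value = unlist(lapply(lfcCols, function(cn) abs(stats[[cn]]))),
        treatment = factor(rep(treatments, each = nrow(stats))))
    fit <- stats::aov(value ~ treatment, data = long)
    sm <- summary(fit)[[1]]
    anovaTab <- data.frame(term = trimws(rownames(sm)), df = sm[["Df"]],
                           sum_sq = sm[["Sum Sq"]], f = sm[["F value"]],
                           p = sm[["Pr(>F)"]])
    tukey <- stats::TukeyHSD(fit)$treatment

    regAbs <- regSigned <- NULL
    if (sum(!is.na(perTrt$edhw)) >= 3) {
        f1 <- stats::lm(mean_abs_lfc ~ edhw, data = perTrt)
        s1 <- summary(f1)
        regAbs <- list(slope = unname(stats::coef(f1)[2]), r2 = s1$r.squared,
                       p_value = s1$coefficients[2, 4])
        f2 <- stats::lm(mean_lfc ~ edhw, data = perTrt)
        s2 <- summary(f2)
        regSigned <- list(slope = unname(stats::coef(f2)[2]), r2 = s2$r.squared,
                          p_value = s2$coefficients[2, 4])
    } else {
        warning("fewer than 3 treatments with eDHW; regression skipped",
                call. = FALSE)
    }
    list(per_treatment = perTrt, anova = anovaTab, tukey = tukey,
         regression_abs = regAbs, regression_signed = regSigned)
}

#' Constant-high specificity z-score per contig
#'
#' How far the constant-high response of each contig stands out from the
#' pulsed treatments:
#' \code{z = (lfc_CH - mean(lfc_pulse, lfc_pulse_high, lfc_pulse_increase))
#' / sd(those three)} with the n-1 denominator. Contigs whose three pulsed
#' responses are identical (sd 0) are flagged and get \code{NA}.
#'
#' @param stats output of [treatmentResponse()].
#' @param chTreatment constant-high column label (default
#'   \code{"constant_high"}).
#' @param pulseTreatments the three comparison treatments.
#' @return data.frame (rownames = contigs): \code{z}, \code{flagged}.
#' @export
constantHighZ <- function(stats, chTreatment = "constant_high",
                          pulseTreatments = c("pulse", "pulse_high",
                                              "pulse_increase")) {
    cols <- paste0("lfc_", c(chTreatment, pulseTreatments))
    if (!all(cols %in% names(stats)))
        stop("missing treatment column(s): ",
             paste(setdiff(cols, names(stats)), collapse = ", "))
    ch <- stats[[cols[1]]]
    others <- as.matrix(stats[cols[-1]])
    mu <- rowMeans(others)
    sdv <- apply(others, 1, stats::sd)
    flagged <- sdv == 0
    z <- ifelse(flagged, NA_real_, (ch - mu) / sdv)
    data.frame(z = z, flagged = flagged, row.names = rownames(stats))
}

#' Overlap of significant contig sets across treatments
#'
#' Intersection-over-union for every set pair and for the all-treatment
#' intersection over the union, plus venn-style counts of every membership
#' pattern.
#'
#' @param sets named list of character vectors (significant contig ids per
#'   treatment); empty sets allowed.
#' @return list: \code{pairwise} (matrix of |intersection|/|union|),
#'   \code{shared_fraction} (|intersection of all| / |union of all|),
#'   \code{region_counts} (named vector; names are +/- membership
#'   patterns).
#' @export
sharedSignificance <- function(sets) {
    if (length(sets) < 2L) stop("need at least 2 sets")
    k <- length(sets)
    nm <- names(sets) %||% paste0("set", seq_len(k))
    pw <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
    for (i in seq_len(k)) for (j in seq_len(k)) {
        u <- length(union(sets[[i]], sets[[j]]))
        pw[i, j] <- if (u == 0) 0 else
            length(intersect(sets[[i]], sets[[j]])) / u
    }
    allUnion <- Reduce(union, sets)
    allInter <- Reduce(intersect, sets)
    shared <- if (length(allUnion) == 0) 0 else
        length(allInter) / length(allUnion)
    pattern <- vapply(allUnion, function(id)
        paste(ifelse(vapply(sets, function(s) id %in% s, logical(1)),
                     "+", "-"), collapse = ""), character(1))
    list(pairwise = pw, shared_fraction = shared,
         region_counts = if (length(pattern)) table(pattern) else table(character(0)))
}

#' Per-genotype control-corrected constant-high response
#'
#' For every contig and genotype, the direct difference-of-differences on
#' normalized log2 values:
#' \code{(x[CH, T2] - x[CH, T1]) - (x[control, T2] - x[control, T1])}.
#' Cells with several samples are averaged; genotypes missing any of the
#' four cells are dropped with a warning.
#'
#' @param se a normalized container from [normalizeLog()].
#' @param treatmentName heated treatment (default \code{"constant_high"}).
#' @param control control treatment label.
#' @return contigs x genotypes matrix of responses (log2 units).
#' @export
genotypeResponse <- function(se, treatmentName = "constant_high",
                             control = "control") {
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    mat <- SummarizedExperiment::assay(se, "logcounts")
    genos <- unique(as.character(cd$genotype))
    cellMean <- function(g, trt, tp) {
        idx <- cd$genotype == g & cd$treatment == trt & cd$timepoint == tp
        if (!any(idx)) return(NULL)
        rowMeans(mat[, idx, drop = FALSE])
    }
    cols <- list()
    for (g in genos) {
        cells <- list(cellMean(g, treatmentName, "T2"),
                      cellMean(g, treatmentName, "T1"),
                      cellMean(g, control, "T2"),
                      cellMean(g, control, "T1"))
        if (any(vapply(cells, is.null, logical(1)))) {
            warning(sprintf("genotype '%s' missing a cell; dropped", g),
                    call. = FALSE)
            next
        }
        cols[[g]] <- (cells[[1]] - cells[[2]]) - (cells[[3]] - cells[[4]])
    }
    do.call(cbind, cols)
}

#' Contigs eligible for the plasticity correlation screen
#'
#' The screen's expression filter: a contig is eligible when its mean
#' normalized expression over the constant-high and control samples
#' exceeds the global lower quartile of those means. (Zero response
#' variance is additionally excluded inside [correlationScreen()].)
#'
#' @param se a normalized container from [normalizeLog()].
#' @param treatments treatments whose samples define expression (default
#'   control + constant_high).
#' @return logical vector over contigs.
#' @export
screenEligible <- function(se, treatments = c("control", "constant_high")) {
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    idx <- cd$treatment %in% treatments
    m <- rowMeans(SummarizedExperiment::assay(se, "logcounts")[, idx,
                                                               drop = FALSE])
    m > stats::quantile(m, 0.25)
}

#' Correlate per-genotype expression responses with acclimatization
#' potential
#'
#' Pearson correlation, per contig, of the genotype-level control-corrected
#' constant-high response against the genotype's acclimatization potential
#' (delta DHW). Two-sided p-values use \code{t = r sqrt(n-2) /
#' sqrt(1-r^2)}; BH FDR is applied across contigs. Contigs with zero
#' response variance are excluded and counted in the \code{"nExcluded"}
#' attribute.
#'
#' @param responses contigs x genotypes matrix from [genotypeResponse()].
#' @param potentials named numeric vector of per-genotype delta DHW.
#' @return data.frame sorted by decreasing |r|: \code{contig}, \code{r},
#'   \code{p}, \code{fdr}, \code{n}.
#' @export
correlationScreen <- function(responses, potentials) {
    common <- intersect(colnames(responses), names(potentials))
    if (length(common) < 4L) stop("need at least 4 genotypes with both values")
    resp <- responses[, common, drop = FALSE]
    pot <- potentials[common]
    v <- apply(resp, 1, stats::var)
    excl <- v == 0 | !is.finite(v)
    resp <- resp[!excl, , drop = FALSE]
    n <- length(common)
    r <- as.vector(stats::cor(t(resp), pot))
    tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    out <- data.frame(contig = rownames(resp), r = r, p = p,
                      fdr = bhFDR(p), n = n)
    out <- out[order(-abs(out$r)), ]
    rownames(out) <- NULL
    attr(out, "nExcluded") <- sum(excl)
    out
}
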