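#' @include acclimatization.R
NULL

#' Configuration of a synthetic acclimatization study
#'
#' Fixes the conditions of the emulated experiment: ten genotypes split
#' evenly between historical bleaching phenotypes, five 5-day pre-exposure
#' regimes between 28 and 31.5 degC in duplicate tanks, a 10-day
#' 28 -> 32.5 degC stress-test ramp followed by an 11-day plateau, six
#' fragments per genotype x treatment, PAM readings every 2-3 days, and a
#' 100-sample (10 genotypes x 5 treatments x 2 timepoints)
#' negative-binomial count matrix with planted treatment responses and one
#' planted plasticity-correlated contig.
#'
#' @param nGenotypes number of coral genotypes (colonies).
#' @param nFragmentsPerCell fragments per genotype x treatment.
#' @param fvfmNoiseSd additive Gaussian noise sd on relative fv/fm.
#' @param nbDispersion negative-binomial dispersion of the counts.
#' @param nContigs number of contigs simulated.
#' @param plantedScreenR target Pearson correlation of the planted
#'   plasticity-tracking contig.
#' @param deltaMean,deltaSd mean and sd (degC-weeks) of the per-genotype
#'   constant-high acclimatization potential.
#' @param bTrue common Weibull slope of the planted decline curves.
#' @param threshold eDHW accumulation threshold (degC).
#' @return list of class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(nGenotypes = 10, nFragmentsPerCell = 6,
                            fvfmNoiseSd = 0.04, nbDispersion = 0.1,
                            nContigs = 2000, plantedScreenR = -0.95,
                            deltaMean = 0.61, deltaSd = 0.8,
                            bTrue = 2.5, threshold = 28.5) {
    cfg <- list(
        nGenotypes = as.integer(nGenotypes),
        nFragmentsPerCell = as.integer(nFragmentsPerCell),
        treatments = c("control", "constant_high", "pulse",
                       "pulse_increase", "pulse_high"),
        fvfmNoiseSd = fvfmNoiseSd,
        nbDispersion = nbDispersion,
        nContigs = as.integer(nContigs),
        plantedScreenR = plantedScreenR,
        deltaMean = deltaMean, deltaSd = deltaSd,
        deltaMeanOther = c(pulse = 0.40, pulse_increase = 0.25,
                           pulse_high = 0.25),
        deltaSdOther = 0.5,
        bTrue = bTrue, threshold = threshold,
        basalMean = c(bleached = 3.2, nonbleached = 5.2), basalSd = 0.4,
        samplingMinutes = 10, nTanks = 2L,
        preExposureDays = 5, stressRampDays = 10, stressPlateauDays = 11,
        stressPeak = 32.5, stressBase = 28,
        pamDays = c(0, 3, 6, 9, 11, 13, 16, 19),
        origin = as.POSIXct("2019-08-01 00:00:00", tz = "UTC"))
    stopifnot(cfg$nGenotypes >= 2, cfg$nFragmentsPerCell >= 1,
              cfg$nContigs >= 10, cfg$nbDispersion >= 0,
              cfg$fvfmNoiseSd >= 0, abs(cfg$plantedScreenR) < 1)
    class(cfg) <- "SyntheticConfig"
    cfg
}

## idealized (noise-free) temperature at time t (days) for a regime
.profileTemp <- function(treatment, tDays, cfg) {
    switch(treatment,
        control = 28 + 0.15 * sin(2 * pi * tDays),
        constant_high = rep(31.5, length(tDays)),
        pulse = 29.75 + 1.75 * sin(2 * pi * tDays),
        pulse_increase = {
            low <- 28 + 1.5 * tDays / cfg$preExposureDays
            (low + 31.5) / 2 + (31.5 - low) / 2 * sin(2 * pi * tDays)
        },
        pulse_high = 30.5 + 1.0 * sin(2 * pi * tDays),
        stress_test = ifelse(
            tDays <= cfg$stressRampDays,
            cfg$stressBase + (cfg$stressPeak - cfg$stressBase) *
                tDays / cfg$stressRampDays,
            cfg$stressPeak),
        stop("unknown treatment profile: ", treatment))
}

#' Generate logger series for the pre-exposure regimes and stress test
#'
#' Five 5-day pre-exposure profiles (control wobbling around 28 degC;
#' constant high flat at 31.5; pulse oscillating 28-31.5 daily; pulse
#' increase with rising troughs; pulse high oscillating 29.5-31.5) and a
#' stress test ramping 28 -> 32.5 degC over 10 days then flat for 11 days,
#' each in duplicate tanks at 10-minute sampling with small seeded per-tank
#' jitter. Identical (config, seed) inputs yield bit-identical series.
#'
#' @param config a [syntheticConfig()].
#' @param seed integer seed.
#' @return named list of [TemperatureSeries-class]
#'   (\code{"<treatment>.<tank>"}).
#' @export
generateProfiles <- function(config, seed) {
    stopifnot(inherits(config, "SyntheticConfig"))
    dt <- config$samplingMinutes / (24 * 60)
    regimes <- c(config$treatments, "stress_test")
    withr::with_seed(seed, {
        out <- list()
        for (trt in regimes) {
            days <- if (trt == "stress_test")
                config$stressRampDays + config$stressPlateauDays
            else config$preExposureDays
            tDays <- seq(0, days, by = dt)
            base <- .profileTemp(trt, tDays, config)
            for (tank in seq_len(config$nTanks)) {
                offset <- stats::rnorm(1, 0, 0.05)
                jitter <- stats::rnorm(length(tDays), 0, 0.02)
                nm <- paste0(trt, ".tank", tank)
                out[[nm]] <- TemperatureSeries(
                    config$origin + tDays * SECONDS_PER_DAY,
                    base + offset + jitter,
                    tankId = paste0(trt, "_tank", tank), treatment = trt)
            }
        }
        out
    })
}

## noise-free accumulated dose (degC-weeks) of the stress-test ramp at day t
.stressDoseIdeal <- function(tDays, cfg) {
    rate <- (cfg$stressPeak - cfg$stressBase) / cfg$stressRampDays
    exceed <- cfg$threshold - cfg$stressBase
    tCross <- exceed / rate
    rampPart <- function(t) {
        t <- pmin(pmax(t, tCross), cfg$stressRampDays)
        rate / 2 * (t^2 - tCross^2) - exceed * (t - tCross)
    }
    plateau <- pmax(0, tDays - cfg$stressRampDays) *
        (cfg$stressPeak - cfg$threshold)
    (rampPart(tDays) + plateau) / DAYS_PER_WEEK
}

## delta-method ED10 SE expected for one group under the planted design
.expectedEdSE <- function(b, e, doses, nFrag, noiseSd, edLevel = 10) {
    dose <- rep(doses, nFrag)
    J <- .weibullJacobian(dose, b, e)
    covm <- noiseSd^2 * solve(crossprod(J))
    k <- -log(1 - edLevel / 100)
    ed <- e * k^(1 / b)
    grad <- c(-ed * log(k) / b^2, ed / e)
    sqrt(drop(t(grad) %*% covm %*% grad))
}

#' Plant the ground truth of a synthetic study
#'
#' Draws per-genotype basal ED10 values (phenotype-offset normals),
#' per-treatment acclimatization deltas (constant-high deltas from
#' N(deltaMean, deltaSd^2)), converts them to Weibull inflection doses at
#' the common slope, plants per-contig treatment log2 fold-changes scaled
#' by each regime's accumulated eDHW, designates one contig whose
#' genotype-level constant-high response tracks acclimatization potential
#' at the target correlation, and records the analytically expected ED10
#' standard errors and the implied heritability of the planted study.
#'
#' @param config a [syntheticConfig()].
#' @param seed integer seed.
#' @return list of class \code{"TruthRecord"}: \code{ed10_true} (genotype x
#'   treatment), \code{delta_true}, \code{e_true}, \code{b_true},
#'   \code{phenotype}, \code{edhw_by_treatment},
#'   \code{treatment_lfc_true} (contig x heated treatment),
#'   \code{timepoint_shift_true}, \code{screen_contig_id},
#'   \code{screen_slope}, \code{ch_specific_contigs},
#'   \code{expected_ed_se}, \code{h2_planted}, \code{seed}.
#' @export
generateTruth <- function(config, seed) {
    stopifnot(inherits(config, "SyntheticConfig"))
    genos <- sprintf("G%02d", seq_len(config$nGenotypes))
    phen <- ifelse(seq_len(config$nGenotypes) <= config$nGenotypes / 2,
                   "bleached", "nonbleached")
    names(phen) <- genos
    heated <- setdiff(config$treatments, "control")
    doses <- .stressDoseIdeal(config$pamDays, config)
    maxDose <- max(doses)  # ED10s must be observable within the PAM design

    withr::with_seed(seed, {
        basal <- stats::rnorm(config$nGenotypes,
                              config$basalMean[phen], config$basalSd)
        ed10 <- matrix(NA_real_, config$nGenotypes, length(config$treatments),
                       dimnames = list(genos, config$treatments))
        ed10[, "control"] <- basal
        for (trt in heated) {
            mu <- if (trt == "constant_high") config$deltaMean
                  else config$deltaMeanOther[[trt]]
            sdv <- if (trt == "constant_high") config$deltaSd
                   else config$deltaSdOther
            ed10[, trt] <- basal + stats::rnorm(config$nGenotypes, mu, sdv)
        }
        ed10 <- pmin(pmax(ed10, 0.4), 0.9 * maxDose)
        deltaTrue <- ed10[, "constant_high"] - ed10[, "control"]

        k <- -log(0.9)
        eTrue <- ed10 / k^(1 / config$bTrue)

        ## planted expression responses, scaled by accumulated regime dose
        edhwTrt <- .profileEDHW(config)
        lfc <- matrix(0, config$nContigs, length(heated),
                      dimnames = list(sprintf("contig_%04d",
                                              seq_len(config$nContigs)),
                                      heated))
        nResponsive <- min(200L, config$nContigs %/% 4L)
        nChOnly <- min(50L, config$nContigs %/% 10L)
        special <- sample(config$nContigs, nResponsive + nChOnly + 1L)
        responsive <- special[seq_len(nResponsive)]
        chOnly <- special[nResponsive + seq_len(nChOnly)]
        screenIdx <- special[nResponsive + nChOnly + 1L]
        beta <- sample(c(-1, 1), nResponsive, replace = TRUE) *
            abs(stats::rnorm(nResponsive, 1.2, 0.3))
        for (j in seq_along(heated))
            lfc[responsive, j] <- beta *
                edhwTrt[heated[j]] / edhwTrt["constant_high"]
        lfc[chOnly, "constant_high"] <-
            abs(stats::rnorm(nChOnly, 1.5, 0.3))

        ## common T1 -> T2 drift, shared by control and treatments
        shift <- numeric(config$nContigs)
        drifting <- sample(config$nContigs, config$nContigs %/% 5L)
        shift[drifting] <- stats::rnorm(length(drifting), 0, 0.3)

        ## screen contig: response = slope * standardized delta; slope set so
        ## the planted correlation is the target once NB noise is added
        zDelta <- as.vector(scale(deltaTrue))
        sigmaNB <- 2 * sqrt(1 / 2000 + config$nbDispersion) / log(2)
        rT <- config$plantedScreenR
        slope <- sign(rT) * sigmaNB * abs(rT) / sqrt(1 - rT^2)

        expectedSE <- matrix(NA_real_, config$nGenotypes,
                             length(config$treatments),
                             dimnames = dimnames(ed10))
        for (g in seq_len(config$nGenotypes))
            for (j in seq_along(config$treatments))
                expectedSE[g, j] <- .expectedEdSE(
                    config$bTrue, eTrue[g, j], doses,
                    config$nFragmentsPerCell, max(config$fvfmNoiseSd, 1e-12))

        ## heritability implied by the planted deltas and expected fit SEs
        nB <- 1000
        kG <- config$nGenotypes
        s2 <- mean(expectedSE[, "constant_high"]^2 + expectedSE[, "control"]^2)
        ssDelta <- sum((deltaTrue - mean(deltaTrue))^2)
        h2Planted <- (nB * ssDelta + (kG - 1) * s2) /
            (nB * ssDelta + (kG - 1) * s2 + kG * (nB - 1) * s2)

        truth <- list(ed10_true = ed10, delta_true = deltaTrue,
                      e_true = eTrue, b_true = config$bTrue,
                      phenotype = phen, edhw_by_treatment = edhwTrt,
                      treatment_lfc_true = lfc,
                      timepoint_shift_true = shift,
                      screen_contig_id = rownames(lfc)[screenIdx],
                      screen_slope = slope,
                      ch_specific_contigs = rownames(lfc)[chOnly],
                      expected_ed_se = expectedSE,
                      h2_planted = h2Planted, seed = as.integer(seed))
        class(truth) <- "TruthRecord"
        validateTruth(truth)
        truth
    })
}

## noise-free eDHW of each pre-exposure regime over its 5 days
.profileEDHW <- function(cfg) {
    dt <- 1 / (24 * 60)  # 1-minute grid for the closed profiles
    tDays <- seq(0, cfg$preExposureDays, by = dt)
    vapply(cfg$treatments, function(trt) {
        temp <- .profileTemp(trt, tDays, cfg)
        .edhwTrapezoid(tDays, temp, cfg$threshold)
    }, numeric(1))
}

#' Validate the internal consistency of a TruthRecord
#'
#' Checks the delta identity (delta = ED10 constant_high - ED10 control)
#' and basic shape constraints; called at generation time.
#'
#' @param truth a \code{TruthRecord}.
#' @return invisibly \code{TRUE}; errors otherwise.
#' @export
validateTruth <- function(truth) {
    stopifnot(inherits(truth, "TruthRecord"))
    d <- truth$ed10_true[, "constant_high"] - truth$ed10_true[, "control"]
    if (max(abs(d - truth$delta_true)) > 1e-9)
        stop("TruthRecord inconsistent: delta != ED10[CH] - ED10[control]")
    if (any(truth$ed10_true <= 0)) stop("planted ED10 must be positive")
    if (!truth$screen_contig_id %in% rownames(truth$treatment_lfc_true))
        stop("screen contig id not among contigs")
    invisible(TRUE)
}

#' Simulate stress-test PAM trajectories from planted ED10 values
#'
#' Per fragment: duplicate initial readings at dose 0, then relative
#' responses \code{weibullW1(dose; b, e) + N(0, sd)} (truncated to
#' (0, 1.1]) at each PAM instant, multiplied by a fragment baseline fv/fm.
#' Doses come from the stress-test dose trajectory averaged across the
#' replicate tanks, so a noise-free run reproduces the planted ED10 values
#' exactly through the full fitting pipeline.
#'
#' @param config a [syntheticConfig()].
#' @param truth a \code{TruthRecord} from [generateTruth()].
#' @param stressSeries list of the stress-test [TemperatureSeries-class]
#'   (replicate tanks).
#' @param seed integer seed.
#' @return list: \code{pam} (data.frame: fragment_id, genotype, phenotype,
#'   treatment, timestamp, fvfm), \code{trajectory} (tank-averaged dose
#'   trajectory), \code{doses} (dose at each PAM instant).
#' @export
generateStressTest <- function(config, truth, stressSeries, seed) {
    stopifnot(inherits(config, "SyntheticConfig"),
              inherits(truth, "TruthRecord"))
    trajs <- lapply(stressSeries, doseTrajectory, threshold = config$threshold)
    trajectory <- trajs[[1]]
    if (length(trajs) > 1)
        trajectory$edhw <- rowMeans(vapply(trajs, `[[`, "edhw",
                                           FUN.VALUE = numeric(nrow(trajectory))))
    pamTimes <- config$origin + config$pamDays * SECONDS_PER_DAY
    doses <- doseAt(trajectory, pamTimes)
    if (any(truth$ed10_true >= max(doses)))
        stop("infeasible planted ED10: exceeds the maximum accumulated dose")

    genos <- rownames(truth$ed10_true)
    rows <- withr::with_seed(seed, {
        acc <- list()
        for (trt in config$treatments) for (g in genos) {
            eGT <- truth$e_true[g, trt]
            for (f in seq_len(config$nFragmentsPerCell)) {
                fid <- sprintf("F_%s_%s_%02d", trt, g, f)
                base <- stats::rnorm(1, 0.62, 0.02)
                respInit <- 1 + stats::rnorm(2, 0, config$fvfmNoiseSd)
                resp <- weibullW1(doses[-1], truth$b_true, eGT) +
                    stats::rnorm(length(doses) - 1, 0, config$fvfmNoiseSd)
                resp <- pmin(pmax(c(respInit, resp), 1e-3), 1.1)
                acc[[fid]] <- data.frame(
                    fragment_id = fid, genotype = g,
                    phenotype = unname(truth$phenotype[g]), treatment = trt,
                    timestamp = c(pamTimes[1], pamTimes),
                    fvfm = pmin(base * resp, 1))
            }
        }
        acc
    })
    pam <- do.call(rbind, rows)
    rownames(pam) <- NULL
    list(pam = pam, trajectory = trajectory, doses = doses)
}

#' Simulate the tag-seq count matrix with planted responses
#'
#' Negative-binomial counts for genotype x treatment x timepoint samples
#' (one fragment per cell): log-normal per-contig baselines, recorded
#' per-sample size factors, a shared T1 -> T2 drift in a fifth of contigs
#' (removed by control correction), planted timepoint x treatment
#' interactions scaled by each regime's eDHW, a block of constant-high-only
#' responders, and the designated screen contig whose per-genotype
#' constant-high response follows the planted acclimatization deltas. About
#' 20 percent of contigs are annotated from a 50-term synthetic ontology,
#' with one term concentrated in the constant-high-specific block.
#'
#' @param config a [syntheticConfig()].
#' @param truth a \code{TruthRecord} from [generateTruth()].
#' @param seed integer seed.
#' @return list: \code{se} (count container from [countSE()]),
#'   \code{annotations} (AnnotationMap), \code{truth} (input truth with
#'   \code{size_factors_true} attached).
#' @export
generateCounts <- function(config, truth, seed) {
    stopifnot(inherits(config, "SyntheticConfig"),
              inherits(truth, "TruthRecord"))
    genos <- rownames(truth$ed10_true)
    contigs <- rownames(truth$treatment_lfc_true)
    meta <- expand.grid(timepoint = c("T1", "T2"),
                        treatment = config$treatments,
                        genotype = genos,
                        stringsAsFactors = FALSE)
    meta$phenotype <- unname(truth$phenotype[meta$genotype])
    meta$sample_id <- sprintf("s_%s_%s_%s", meta$genotype, meta$treatment,
                              meta$timepoint)
    nS <- nrow(meta)
    heated <- colnames(truth$treatment_lfc_true)
    zDelta <- as.vector(scale(truth$delta_true))
    names(zDelta) <- genos

    withr::with_seed(seed, {
        q <- stats::rlnorm(config$nContigs, log(60), 1.2)
        special <- unique(c(which(rowSums(abs(truth$treatment_lfc_true)) > 0),
                            match(truth$screen_contig_id, contigs)))
        q[special] <- pmax(q[special], 20)
        q[match(truth$screen_contig_id, contigs)] <- 2000

        sf <- exp(stats::rnorm(nS, 0, 0.15))
        sf <- sf / exp(mean(log(sf)))

        log2mu <- matrix(log2(q), config$nContigs, nS)
        isT2 <- meta$timepoint == "T2"
        for (j in which(isT2)) {
            trt <- meta$treatment[j]
            log2mu[, j] <- log2mu[, j] + truth$timepoint_shift_true
            if (trt %in% heated)
                log2mu[, j] <- log2mu[, j] + truth$treatment_lfc_true[, trt]
        }
        # screen contig: the constant-high T2 - T1 contrast carries the
        # planted slope x standardized delta; splitting it antisymmetrically
        # keeps the count means near baseline so the contig's noise matches
        # the calibration
        iScr <- match(truth$screen_contig_id, contigs)
        isCH <- meta$treatment == "constant_high"
        shiftScr <- truth$screen_slope * zDelta[meta$genotype] / 2
        log2mu[iScr, isCH & isT2] <- log2mu[iScr, isCH & isT2] +
            shiftScr[isCH & isT2]
        log2mu[iScr, isCH & !isT2] <- log2mu[iScr, isCH & !isT2] -
            shiftScr[isCH & !isT2]
        mu <- sweep(2^log2mu, 2, sf, "*")
        counts <- if (config$nbDispersion < 1e-8)
            stats::rpois(length(mu), lambda = as.vector(mu))
        else
            stats::rnbinom(length(mu), mu = as.vector(mu),
                           size = 1 / config$nbDispersion)
        counts <- matrix(counts, config$nContigs, nS,
                         dimnames = list(contigs, meta$sample_id))

        terms <- sprintf("GO:%07d", seq_len(50))
        annotations <- list()
        annotated <- sample(contigs, round(0.2 * config$nContigs))
        for (id in annotated)
            annotations[[id]] <- sample(terms[-1], sample(1:3, 1))
        enriched <- sample(truth$ch_specific_contigs,
                           round(0.6 * length(truth$ch_specific_contigs)))
        for (id in enriched)
            annotations[[id]] <- union(annotations[[id]] %||% character(0),
                                       terms[1])

        truth$size_factors_true <- stats::setNames(sf, meta$sample_id)
        list(se = countSE(counts, meta), annotations = annotations,
             truth = truth)
    })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [generateProfiles()], [generateTruth()],
#' [generateStressTest()] and [generateCounts()] with sub-seeds derived
#' from one master seed.
#'
#' @param config a [syntheticConfig()].
#' @param seed integer master seed.
#' @return list: \code{profiles}, \code{truth}, \code{stress} (pam +
#'   trajectory + doses), \code{counts} (se + annotations + truth).
#' @export
generateStudy <- function(config = syntheticConfig(), seed = 1) {
    profiles <- generateProfiles(config, seed)
    truth <- generateTruth(config, seed + 1000L)
    stressSeries <- profiles[grep("^stress_test", names(profiles))]
    stress <- generateStressTest(config, truth, stressSeries, seed + 2000L)
    counts <- generateCounts(config, truth, seed + 3000L)
    list(profiles = profiles, truth = counts$truth, stress = stress,
         counts = counts)
}
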