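## Amplification-quality cascade: ceiling imputation -> per-well quality
## exclusion -> no-template-control contamination screen -> detection-rate
## filter.  The cascade is idempotent and conserving: every input well ends
## up either retained or excluded with a recorded reason.

#' Censor wells at the detection ceiling
#'
#' Wells with a Cq above the ceiling, or reported as undetected (\code{NA}
#' Cq), are considered below the detection threshold: their Cq is imputed at
#' the ceiling and they are flagged not detected.  All other wells keep their
#' measured Cq and are flagged detected.  The imputed value participates in
#' downstream means (censored observation), but a not-detected well never
#' counts as "expressed".
#'
#' @param wells a well \code{data.frame} (see [readCqTable()]); may already
#'   carry \code{cq_imputed}/\code{detected}, in which case they are
#'   recomputed (the operation is idempotent).
#' @param ceiling positive detection ceiling (default study value 34).
#' @return the well table with columns \code{cq_imputed} and \code{detected}
#'   added.
#' @examples
#' w <- data.frame(sample_id = "S1", probe_id = c("a", "b", "c"),
#'                 cq = c(36.2, NA, 28.5), amp_score = 1.5, cq_conf = 0.9,
#'                 is_ntc = FALSE)
#' imputeCeiling(w, 34)[, c("cq_imputed", "detected")]
#' @export
imputeCeiling <- function(wells, ceiling = 34) {
    stopifnot(is.data.frame(wells))
    if (!is.numeric(ceiling) || length(ceiling) != 1L || ceiling <= 0)
        stop("'ceiling' must be a single positive number")
    if (any(wells$cq < 0, na.rm = TRUE))
        stop("negative Cq value(s) in input")
    censored <- is.na(wells$cq) | wells$cq > ceiling
    wells$cq_imputed <- ifelse(censored, ceiling, wells$cq)
    wells$detected <- !censored
    wells
}

#' Apply the amplification-quality filter
#'
#' Detected wells whose amplification score or Cq confidence falls below the
#' configured minima are excluded from analysis, with the first failing
#' metric recorded as the exclusion reason.  Wells censored at the ceiling
#' are retained as censored observations and are never quality-excluded (the
#' quality rule applies only to wells that amplified below the ceiling).
#' Values exactly at a threshold pass.
#'
#' @param wells output of [imputeCeiling()].
#' @param ampScoreMin minimum amplification score.
#' @param cqConfMin minimum Cq confidence.
#' @return the well table with logical \code{qc_pass} and character
#'   \code{exclusion_reason} (\code{NA}, \code{"amp_score"} or
#'   \code{"cq_conf"}) columns added.
#' @export
applyQualityFilter <- function(wells, ampScoreMin = 1.0, cqConfMin = 0.8) {
    if (!all(c("cq_imputed", "detected") %in% names(wells)))
        stop("run imputeCeiling() before applyQualityFilter()")
    badAmp <- wells$detected & !is.na(wells$amp_score) &
        wells$amp_score < ampScoreMin
    badConf <- wells$detected & !badAmp & !is.na(wells$cq_conf) &
        wells$cq_conf < cqConfMin
    wells$qc_pass <- !(badAmp | badConf)
    wells$exclusion_reason <- NA_character_
    wells$exclusion_reason[badAmp] <- "amp_score"
    wells$exclusion_reason[badConf] <- "cq_conf"
    wells
}

#' Assemble a CqExperiment from QC'd wells and sample metadata
#'
#' Runs ceiling imputation and the quality filter on all wells, separates the
#' no-template-control (NTC) records, and pivots the experimental wells into
#' the probes-by-samples assays of a [CqExperiment-class].  Cells without a
#' well are \code{NA} Cq with \code{detected = FALSE, qcPass = FALSE}.
#'
#' @param wells well \code{data.frame}, experimental and NTC rows together.
#' @param samples validated sample metadata (see [readSampleSheet()]); every
#'   non-NTC well must reference exactly one row.
#' @param config a [cqConfig()] list.
#' @return a \code{CqExperiment}; QC'd NTC records are stored in
#'   \code{metadata(x)$ntc} and the configuration in
#'   \code{metadata(x)$config}.
#' @export
buildCqExperiment <- function(wells, samples, config = cqConfig()) {
    wells <- applyQualityFilter(imputeCeiling(wells, config$cqCeiling),
                                config$ampScoreMin, config$cqConfMin)
    ntc <- wells[wells$is_ntc, , drop = FALSE]
    exp <- wells[!wells$is_ntc, , drop = FALSE]
    unknown <- setdiff(unique(exp$sample_id), samples$sample_id)
    if (length(unknown))
        stop("well(s) reference sample(s) absent from the sample sheet: ",
             paste(unknown, collapse = ", "))
    probes <- sort(unique(wells$probe_id))
    sids <- samples$sample_id
    grid <- function(values, default) {
        m <- matrix(default, length(probes), length(sids),
                    dimnames = list(probes, sids))
        m[cbind(match(exp$probe_id, probes), match(exp$sample_id, sids))] <-
            values
        m
    }
    cd <- S4Vectors::DataFrame(samples, row.names = sids)
    se <- SummarizedExperiment(
        assays = list(cq = grid(exp$cq_imputed, NA_real_),
                      detected = grid(exp$detected, FALSE),
                      qcPass = grid(exp$qc_pass, FALSE)),
        colData = cd)
    out <- methods::new("CqExperiment", se)
    metadata(out)$ntc <- ntc
    metadata(out)$config <- config
    metadata(out)$exclusions <-
        exp[!exp$qc_pass,
            c("sample_id", "probe_id", "exclusion_reason"), drop = FALSE]
    out
}

#' No-template-control contamination screen
#'
#' A probe is excluded when its water-only (NTC) well shows a good-quality
#' amplification (detected below the ceiling, quality-passing) whose Cq lies
#' within \code{delta} cycles (absolute difference) of the mean imputed Cq of
#' that probe's quality-passing experimental wells — amplification in water
#' that close to the biological signal indicates probe-level contamination.
#'
#' @param x a [CqExperiment-class] carrying NTC records in its metadata (as
#'   built by [buildCqExperiment()]).
#' @param delta proximity window in cycles; defaults to the configured
#'   \code{ntcDelta}.
#' @return sorted character vector of contaminated probe ids; the full
#'   per-probe evaluation is attached as attribute \code{"report"}.
#' @export
ntcExclusion <- function(x, delta = NULL) {
    stopifnot(is(x, "CqExperiment"))
    ntc <- metadata(x)$ntc
    if (is.null(delta)) delta <- metadata(x)$config$ntcDelta
    if (is.null(ntc) || nrow(ntc) == 0L) {
        out <- character(0)
        attr(out, "report") <- data.frame(probe_id = character(0))
        return(out)
    }
    usable <- usableCq(x)
    rep <- data.frame(probe_id = ntc$probe_id,
                      ntc_cq = ntc$cq_imputed,
                      ntc_good = ntc$detected & ntc$qc_pass,
                      expt_mean = NA_real_, n_expt = 0L, excluded = FALSE,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(rep))) {
        p <- rep$probe_id[i]
        if (!p %in% rownames(usable)) next
        vals <- usable[p, ]
        vals <- vals[!is.na(vals)]
        rep$n_expt[i] <- length(vals)
        if (!rep$ntc_good[i]) next
        if (length(vals) == 0L) {
            warning("probe '", p, "': NTC amplification but zero ",
                    "quality-passing experimental wells; not excluded")
            next
        }
        rep$expt_mean[i] <- mean(vals)
        rep$excluded[i] <- abs(rep$ntc_cq[i] - rep$expt_mean[i]) <= delta
    }
    out <- sort(rep$probe_id[rep$excluded])
    attr(out, "report") <- rep[order(rep$probe_id), ]
    out
}

#' Minimum expressed-sample count for the detection filter
#'
#' Converts a detection fraction into a realized sample count.  The floor
#' convention matches the realized threshold of a 20\% rule on 56 samples
#' (11 of 56); a minimum of 1 is enforced.
#'
#' @param nSamples number of samples (>= 1).
#' @param fraction required fraction in (0, 1).
#' @param convention \code{"floor"} or \code{"ceil"}.
#' @return integer count.
#' @examples
#' minDetectionCount(56, 0.20)        # 11
#' minDetectionCount(4, 0.50)         # 2
#' @export
minDetectionCount <- function(nSamples, fraction,
                              convention = c("floor", "ceil")) {
    convention <- match.arg(convention)
    if (nSamples < 1) stop("'nSamples' must be >= 1")
    if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
        stop("'fraction' must lie in (0, 1)")
    k <- switch(convention, floor = floor(fraction * nSamples),
                ceil = ceiling(fraction * nSamples))
    max(1L, as.integer(k))
}

#' Detection-rate filter
#'
#' A probe counts as expressed in a sample when its well is detected below
#' the ceiling and quality-passing.  Probes expressed in fewer than
#' \code{minCount} samples are dropped.
#'
#' @param x a [CqExperiment-class].
#' @param minCount minimum expressed-sample count (see
#'   [minDetectionCount()]).
#' @return list with sorted character vectors \code{kept} and \code{dropped}
#'   (a disjoint partition of all probes) and the named integer vector
#'   \code{counts} of expressed samples per probe.
#' @export
detectionFilter <- function(x, minCount) {
    stopifnot(is(x, "CqExperiment"), minCount >= 1)
    expressed <- detectionMask(x) & qcMask(x)
    counts <- rowSums(expressed)
    keep <- counts >= minCount
    list(kept = sort(rownames(x)[keep]),
         dropped = sort(rownames(x)[!keep]),
         counts = counts)
}

#' Per-well QC report
#'
#' One row per excluded well or contaminated probe with its reason, plus a
#' summary count per reason, suitable for writing as the pipeline's QC TSV.
#'
#' @param x a [CqExperiment-class].
#' @param ntcExcluded optional result of [ntcExclusion()].
#' @return list with \code{exclusions} (data.frame) and \code{summary}
#'   (named integer vector of counts per reason).
#' @export
qcReport <- function(x, ntcExcluded = NULL) {
    wellEx <- metadata(x)$exclusions
    if (is.null(wellEx))
        wellEx <- data.frame(sample_id = character(0),
                             probe_id = character(0),
                             exclusion_reason = character(0))
    ex <- data.frame(probe_id = wellEx$probe_id,
                     sample_id = wellEx$sample_id,
                     reason = wellEx$exclusion_reason,
                     stringsAsFactors = FALSE)
    if (!is.null(ntcExcluded) && length(ntcExcluded))
        ex <- rbind(ex, data.frame(probe_id = as.character(ntcExcluded),
                                   sample_id = NA_character_,
                                   reason = "ntc_contamination"))
    list(exclusions = ex, summary = c(table(ex$reason)))
}
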