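#' Run the full QC / normalization / differential-expression chain
#'
#' Convenience wrapper: builds the [CqExperiment-class], screens probes
#' against the no-template controls, applies the detection-rate filter,
#' selects or validates the endogenous controls, normalizes, and tests the
#' requested two-group contrast.
#'
#' Endogenous controls: when \code{config$endogenousControls} is
#' \code{"auto"}, the candidates are ranked by [scoreEndogenousControls()]
#' over all probes surviving the NTC screen and the top \code{nControls}
#' eligible probes are taken; otherwise the configured probe list is used
#' as-is (after checking eligibility via [deltaCq()]).
#'
#' @param wells well table (see [readCqTable()]).
#' @param samples sample sheet (see [readSampleSheet()]).
#' @param group two-level \code{colData} column to contrast (default
#'   \code{"diagnosis"}).
#' @param testLevel test-group level (default \code{"AD"} when present).
#' @param config a [cqConfig()] list.
#' @param nControls number of controls picked under \code{"auto"}.
#' @return list with the intermediate objects: \code{cqex}
#'   (\code{CqExperiment}), \code{ntcExcluded}, \code{detection} (kept /
#'   dropped / counts), \code{controls}, \code{norm}
#'   (\code{NormalizedCq} over the expressed test probes) and \code{de} (the
#'   [deAnalysis()] table).
#' @export
runPipeline <- function(wells, samples, group = "diagnosis",
                        testLevel = NULL, config = cqConfig(),
                        nControls = 5L) {
    cqex <- buildCqExperiment(wells, samples, config)
    contaminated <- ntcExclusion(cqex)
    clean <- cqex[setdiff(rownames(cqex), contaminated), ]

    controls <- config$endogenousControls
    if (identical(controls, "auto")) {
        scores <- scoreEndogenousControls(clean, rownames(clean))
        eligible <- scores$probe_id[scores$eligible]
        if (length(eligible) < nControls)
            stop("only ", length(eligible),
                 " probes expressed in every sample; cannot auto-select ",
                 nControls, " controls")
        controls <- eligible[seq_len(nControls)]
    }

    minCount <- minDetectionCount(ncol(clean), config$detectionFraction,
                                  config$detectionRounding)
    det <- detectionFilter(clean, minCount)
    keepProbes <- union(det$kept, controls)
    expressed <- clean[keepProbes[order(match(keepProbes,
                                              rownames(clean)))], ]

    norm <- deltaCq(expressed, controls)
    if (is.null(testLevel) && group == "diagnosis") testLevel <- "AD"
    de <- deAnalysis(norm, group, testLevel = testLevel, config = config)
    list(cqex = cqex, ntcExcluded = contaminated, detection = det,
         controls = controls, norm = norm, de = de)
}
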