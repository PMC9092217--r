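#' Pipeline configuration
#'
#' Collects the thresholds of the QC and statistics cascade in one validated
#' list.  Defaults follow the standard TaqMan advanced-array workflow for CSF
#' biofluid studies: detection ceiling at Cq 34, amplification-score minimum
#' 1.0, Cq-confidence minimum 0.8, no-template-control proximity window of
#' 1 cycle, a 20\% detection-rate filter (floor convention), differential
#' expression at FDR 0.20 with a 1.5 fold-change call, and pathway
#' over-representation at FDR 0.01.
#'
#' @param cqCeiling detection ceiling; wells above it (or reported undetected)
#'   are censored at this value.
#' @param ampScoreMin minimum amplification score for a detected well to pass
#'   quality filtering (values exactly at the threshold pass).
#' @param cqConfMin minimum Cq confidence, in \[0,1\] (at-threshold passes).
#' @param ntcDelta no-template-control proximity window (cycles): a probe whose
#'   clean-water well amplifies within this absolute distance of the
#'   experimental mean is flagged as contaminated.
#' @param detectionFraction minimum fraction of samples in which a probe must
#'   be expressed, in (0,1).
#' @param detectionRounding \code{"floor"} or \code{"ceil"}: how
#'   \code{detectionFraction * n} is converted to a sample count.
#' @param fdrQDE Benjamini-Hochberg level for differential expression.
#' @param fcThreshold fold-change magnitude required to call a probe changed.
#' @param fdrQORA Benjamini-Hochberg level for over-representation analysis.
#' @param endogenousControls character vector of control probe ids, or
#'   \code{"auto"} to rank candidates by cross-sample stability.
#' @param seed integer seed for any randomized step.
#' @return a named list of class \code{cq_config}.
#' @examples
#' cfg <- cqConfig()
#' cfg$cqCeiling
#' @export
cqConfig <- function(cqCeiling = 34, ampScoreMin = 1.0, cqConfMin = 0.8,
                     ntcDelta = 1.0, detectionFraction = 0.20,
                     detectionRounding = c("floor", "ceil"),
                     fdrQDE = 0.20, fcThreshold = 1.5, fdrQORA = 0.01,
                     endogenousControls = "auto", seed = 1L) {
    detectionRounding <- match.arg(detectionRounding)
    num <- c(cqCeiling = cqCeiling, ampScoreMin = ampScoreMin,
             cqConfMin = cqConfMin, ntcDelta = ntcDelta,
             fdrQDE = fdrQDE, fcThreshold = fcThreshold, fdrQORA = fdrQORA)
    if (any(!is.finite(num)) || any(num <= 0))
        stop("all numeric thresholds must be finite and strictly positive")
    if (!is.numeric(detectionFraction) || detectionFraction <= 0 ||
        detectionFraction >= 1)
        stop("'detectionFraction' must lie in (0, 1)")
    if (cqConfMin > 1)
        stop("'cqConfMin' must lie in [0, 1]")
    structure(list(cqCeiling = cqCeiling, ampScoreMin = ampScoreMin,
                   cqConfMin = cqConfMin, ntcDelta = ntcDelta,
                   detectionFraction = detectionFraction,
                   detectionRounding = detectionRounding,
                   fdrQDE = fdrQDE, fcThreshold = fcThreshold,
                   fdrQORA = fdrQORA,
                   endogenousControls = endogenousControls,
                   seed = as.integer(seed)),
              class = "cq_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Key names match the arguments of [cqConfig()]; keys absent from the file
#' keep their defaults, unknown keys are an error.
#'
#' @param path path to a YAML file.
#' @return a \code{cq_config} list.
#' @export
readCqConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
    known <- names(formals(cqConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    do.call(cqConfig, vals)
}

#' @export
print.cq_config <- function(x, ...) {
    cat("qPCR pipeline configuration\n")
    for (k in names(x))
        cat(sprintf("  %-18s %s\n", k, paste(x[[k]], collapse = ", ")))
    invisible(x)
}
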