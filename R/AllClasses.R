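#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' CqExperiment: quality-controlled Cq values for a qPCR array study
#'
#' A \linkS4class{SummarizedExperiment} holding, for every probe (row) and
#' sample (column), the ceiling-imputed quantification cycle together with the
#' per-well detection and quality masks produced by the QC cascade.  Required
#' assays:
#' \describe{
#'   \item{\code{cq}}{ceiling-imputed Cq; \code{NA} where no well was run}
#'   \item{\code{detected}}{logical; \code{FALSE} for wells at/above the
#'     detection ceiling (censored observations)}
#'   \item{\code{qcPass}}{logical; \code{FALSE} for wells excluded on
#'     amplification-score or Cq-confidence grounds}
#' }
#' Sample metadata (diagnosis, sex, APOE genotype, age, MMSE, fraction pool)
#' live in \code{colData}; no-template-control records and the pipeline
#' configuration are kept in \code{metadata(x)$ntc} / \code{metadata(x)$config}.
#'
#' @aliases CqExperiment-class
#' @exportClass CqExperiment
setClass("CqExperiment", contains = "SummarizedExperiment")

setValidity("CqExperiment", function(object) {
    need <- c("cq", "detected", "qcPass")
    missing <- setdiff(need, assayNames(object))
    if (length(missing))
        return(sprintf("missing assay(s): %s", paste(missing, collapse = ", ")))
    if (!is.logical(assay(object, "detected")))
        return("'detected' assay must be logical")
    if (!is.logical(assay(object, "qcPass")))
        return("'qcPass' assay must be logical")
    if (is.null(rownames(object)) || is.null(colnames(object)))
        return("probe (row) and sample (column) names are required")
    TRUE
})

#' NormalizedCq: endogenous-control normalized Cq values
#'
#' A \linkS4class{SummarizedExperiment} whose single required assay
#' \code{dcq} holds the within-sample normalized value
#' \eqn{\Delta Cq = Cq_{probe} - \bar{Cq}_{controls}} for every test probe.
#' The control probes used as normalizers are recorded in the
#' \code{controls} slot and are excluded from the test-probe rows.
#'
#' @slot controls character vector of endogenous-control probe identifiers.
#' @aliases NormalizedCq-class
#' @exportClass NormalizedCq
setClass("NormalizedCq", contains = "SummarizedExperiment",
         representation(controls = "character"))

setValidity("NormalizedCq", function(object) {
    if (!"dcq" %in% assayNames(object))
        return("missing 'dcq' assay")
    if (length(object@controls) == 0L)
        return("'controls' slot must name at least one probe")
    TRUE
})

#' @describeIn CqExperiment-class ceiling-imputed Cq matrix (probes x samples).
#' @param x a \code{CqExperiment} or \code{NormalizedCq}.
#' @export
cqValues <- function(x) assay(x, "cq")

#' @describeIn CqExperiment-class logical detection mask (censored wells are
#'   \code{FALSE}).
#' @export
detectionMask <- function(x) assay(x, "detected")

#' @describeIn CqExperiment-class logical quality mask (quality-excluded wells
#'   are \code{FALSE}).
#' @export
qcMask <- function(x) assay(x, "qcPass")

#' @describeIn CqExperiment-class Cq matrix with quality-excluded wells set to
#'   \code{NA}; this is the matrix downstream group means and tests consume
#'   (censored-at-ceiling wells keep their imputed value).
#' @export
usableCq <- function(x) {
    m <- assay(x, "cq")
    m[!assay(x, "qcPass")] <- NA_real_
    m
}

#' @describeIn NormalizedCq-class normalized \eqn{\Delta Cq} matrix.
#' @param x a \code{NormalizedCq}.
#' @export
dcqValues <- function(x) assay(x, "dcq")

#' @describeIn NormalizedCq-class endogenous-control probes used as the
#'   normalizer.
#' @export
controlProbes <- function(x) x@controls

setMethod("show", "CqExperiment", function(object) {
    cat(sprintf("CqExperiment: %d probes x %d samples\n",
                nrow(object), ncol(object)))
    det <- assay(object, "detected") & assay(object, "qcPass")
    cat(sprintf("  expressed wells (detected & qc-pass): %d / %d\n",
                sum(det, na.rm = TRUE), length(det)))
    ntc <- metadata(object)$ntc
    if (!is.null(ntc))
        cat(sprintf("  no-template-control records: %d\n", nrow(ntc)))
    cd <- colData(object)
    if ("diagnosis" %in% colnames(cd))
        cat("  diagnosis: ", paste(sprintf("%s=%d", names(table(cd$diagnosis)),
            table(cd$diagnosis)), collapse = " "), "\n", sep = "")
})

setMethod("show", "NormalizedCq", function(object) {
    cat(sprintf("NormalizedCq: %d test probes x %d samples\n",
                nrow(object), ncol(object)))
    cat("  controls: ", paste(object@controls, collapse = ", "), "\n", sep = "")
})
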