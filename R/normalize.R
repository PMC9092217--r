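## Endogenous-control selection and relative quantification.  Cq is inverse
## to log2 abundance, so RQ = 2^(-ddCq) and RQ > 1 means increased expression
## in the test group.

#' Score candidate endogenous controls
#'
#' Candidates are ranked by across-sample standard deviation of the imputed
#' Cq (group-blind; lower is more stable), a reproducible, monotone stand-in
#' for vendor stability scores.  A candidate is only eligible for automatic
#' selection when it shows stable, good-quality expression in every sample
#' (detected below the ceiling and quality-passing everywhere).
#'
#' @param x a [CqExperiment-class].
#' @param candidates character vector of candidate probe ids present in
#'   \code{x}.
#' @return \code{data.frame} with columns \code{probe_id, stability_score,
#'   detection_rate, eligible, rank}, ordered by ascending stability score.
#' @export
scoreEndogenousControls <- function(x, candidates) {
    stopifnot(is(x, "CqExperiment"))
    if (length(candidates) == 0L) stop("empty candidate list")
    miss <- setdiff(candidates, rownames(x))
    if (length(miss))
        stop("candidate(s) absent from the experiment: ",
             paste(miss, collapse = ", "))
    cqm <- cqValues(x)[candidates, , drop = FALSE]
    expressed <- (detectionMask(x) & qcMask(x))[candidates, , drop = FALSE]
    out <- data.frame(
        probe_id = candidates,
        stability_score = apply(cqm, 1L, stats::sd),
        detection_rate = rowMeans(expressed),
        stringsAsFactors = FALSE)
    out$eligible <- out$detection_rate == 1
    out <- out[order(out$stability_score, out$probe_id), , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}

#' Normalize to the endogenous-control mean
#'
#' Computes, within each sample, \eqn{\Delta Cq = Cq_{probe} -
#' \bar{Cq}_{controls}}.  Every control must be detected and quality-passing
#' in every sample; otherwise normalization aborts naming the offending probe
#' and sample.  Control probes are removed from the test-probe rows unless a
#' probe is explicitly allowed to be both (a warning is then emitted, since a
#' changing probe inside the normalizer biases every \eqn{\Delta Cq}).
#'
#' Quality-excluded test wells propagate as \code{NA}; censored-at-ceiling
#' wells keep their imputed value.
#'
#' @param x a [CqExperiment-class].
#' @param controls character vector of control probe ids.
#' @param allowControlOverlap keep controls among the test probes too.
#' @return a [NormalizedCq-class].
#' @examples
#' # a probe at Cq 30 over controls averaging 25 has dCq = 5
#' @export
deltaCq <- function(x, controls, allowControlOverlap = FALSE) {
    stopifnot(is(x, "CqExperiment"))
    if (length(controls) == 0L) stop("no control probes given")
    miss <- setdiff(controls, rownames(x))
    if (length(miss))
        stop("control probe(s) absent: ", paste(miss, collapse = ", "))
    ok <- (detectionMask(x) & qcMask(x))[controls, , drop = FALSE]
    if (!all(ok)) {
        bad <- which(!ok, arr.ind = TRUE)[1L, ]
        stop(sprintf(
            "control '%s' is not detected/quality-passing in sample '%s'",
            controls[bad[1L]], colnames(x)[bad[2L]]))
    }
    ctlMean <- colMeans(cqValues(x)[controls, , drop = FALSE])
    testProbes <- if (allowControlOverlap) {
        warning("control probe(s) retained in the test set; a changing ",
                "normalizer biases all normalized values")
        rownames(x)
    } else setdiff(rownames(x), controls)
    usable <- usableCq(x)[testProbes, , drop = FALSE]
    dcq <- sweep(usable, 2L, ctlMean, "-")
    se <- SummarizedExperiment(assays = list(dcq = dcq), colData = colData(x))
    metadata(se) <- metadata(x)
    methods::new("NormalizedCq", se,
                 controls = if (allowControlOverlap) controls
                            else as.character(controls))
}

#' Relative quantification between two groups
#'
#' \eqn{\Delta\Delta Cq} is the mean \eqn{\Delta Cq} of the test samples
#' minus the mean of the reference samples; fold change is
#' \eqn{RQ = 2^{-\Delta\Delta Cq}} (one cycle earlier in the test group is a
#' doubling).  Group means are arithmetic means over available (quality
#' passing) values, censored wells included.
#'
#' @param norm a [NormalizedCq-class].
#' @param testSamples,refSamples sample ids of the two groups.
#' @param probe single probe id.
#' @param groupTest,groupRef labels recorded in the output.
#' @return one-row \code{data.frame} with \code{probe_id, group_test,
#'   group_ref, n_test, n_ref, delta_delta_cq, rq}.
#' @export
deltaDeltaCq <- function(norm, testSamples, refSamples, probe,
                         groupTest = "test", groupRef = "ref") {
    stopifnot(is(norm, "NormalizedCq"))
    if (!probe %in% rownames(norm)) stop("unknown probe: ", probe)
    if (length(testSamples) == 0L || length(refSamples) == 0L)
        stop("both groups must be non-empty")
    dm <- dcqValues(norm)
    xt <- dm[probe, testSamples]; xt <- xt[!is.na(xt)]
    xr <- dm[probe, refSamples];  xr <- xr[!is.na(xr)]
    if (length(xt) == 0L || length(xr) == 0L)
        stop("probe '", probe, "': a group has zero usable values")
    ddcq <- mean(xt) - mean(xr)
    data.frame(probe_id = probe, group_test = groupTest, group_ref = groupRef,
               n_test = length(xt), n_ref = length(xr),
               delta_delta_cq = ddcq, rq = 2^(-ddcq),
               stringsAsFactors = FALSE)
}
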