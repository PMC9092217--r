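## Cohort characteristics: pooled summaries from per-group mean/SD/n, design
## balance checks, and characteristics-table style summaries of covariates.

#' Pool group means
#'
#' Size-weighted mean of per-group means: \eqn{\sum n_i m_i / \sum n_i}.
#'
#' @param means numeric vector of group means.
#' @param ns integer vector of group sizes.
#' @return pooled mean.
#' @examples
#' pooledMean(c(29.5, 29.1), c(14, 14))   # 29.3
#' @export
pooledMean <- function(means, ns) {
    if (length(means) == 0L) stop("no groups supplied")
    stopifnot(length(means) == length(ns), all(ns >= 1))
    sum(ns * means) / sum(ns)
}

#' Pool group standard deviations
#'
#' Exact variance decomposition: within-group sums of squares
#' \eqn{\sum (n_i - 1) s_i^2} plus between-group dispersion
#' \eqn{\sum n_i (m_i - \bar m)^2}, divided by \eqn{\sum n_i - 1}.
#' Equals the SD of the concatenated raw values.
#'
#' @param means,sds,ns per-group mean, SD and size (each \code{n >= 2}).
#' @return pooled standard deviation.
#' @examples
#' pooledSD(c(29.5, 29.1), c(0.8, 1.7), c(14, 14))   # 1.32
#' @export
pooledSD <- function(means, sds, ns) {
    stopifnot(length(means) == length(sds), length(means) == length(ns))
    if (any(ns < 2)) stop("every group needs n >= 2")
    gm <- pooledMean(means, ns)
    ss <- sum((ns - 1) * sds^2) + sum(ns * (means - gm)^2)
    sqrt(ss / (sum(ns) - 1))
}

#' Design-balance report
#'
#' Counts samples in every diagnosis x sex x APOE cell and checks the
#' counts against the declared per-cell size.
#'
#' @param samples sample metadata \code{data.frame} with \code{diagnosis},
#'   \code{sex}, \code{apoe}.
#' @param expectedN declared per-cell n (default 7, the balanced 2x2x2
#'   design of 56 participants).
#' @return list with \code{table} (counts \code{data.frame} over the 8
#'   cells), \code{pass} (logical) and \code{deficient} (labels of cells
#'   departing from \code{expectedN}).
#' @export
balanceReport <- function(samples, expectedN = 7L) {
    grid <- expand.grid(diagnosis = .DIAGNOSIS, sex = .SEX, apoe = .APOE,
                        stringsAsFactors = FALSE)
    grid$n <- mapply(function(d, s, a)
        sum(samples$diagnosis == d & samples$sex == s & samples$apoe == a),
        grid$diagnosis, grid$sex, grid$apoe)
    bad <- grid$n != expectedN
    list(table = grid, pass = !any(bad),
         deficient = paste(grid$diagnosis, grid$sex, grid$apoe)[bad])
}

#' Characteristics-table covariate summary
#'
#' Per-cell and per-margin mean/SD/n of a numeric covariate, in the layout
#' of a participant-characteristics table (cells of diagnosis x APOE within
#' each sex, plus sex-pooled totals).
#'
#' @param samples sample metadata \code{data.frame}.
#' @param var name of the numeric column to summarize (e.g. \code{"mmse"},
#'   \code{"age_years"}).
#' @return \code{data.frame} with columns \code{diagnosis, apoe, sex, n,
#'   mean, sd}; rows with \code{sex == "total"} pool both sexes.
#' @export
cohortSummary <- function(samples, var) {
    stopifnot(var %in% names(samples))
    smry <- function(sub, sexLabel, d, a) {
        v <- sub[[var]][!is.na(sub[[var]])]
        data.frame(diagnosis = d, apoe = a, sex = sexLabel,
                   n = length(v), mean = mean(v),
                   sd = if (length(v) >= 2) stats::sd(v) else NA_real_)
    }
    rows <- list()
    for (d in .DIAGNOSIS) for (a in .APOE) {
        for (s in .SEX) {
            sub <- samples[samples$diagnosis == d & samples$apoe == a &
                           samples$sex == s, , drop = FALSE]
            rows[[length(rows) + 1L]] <- smry(sub, s, d, a)
        }
        sub <- samples[samples$diagnosis == d & samples$apoe == a, ,
                       drop = FALSE]
        rows[[length(rows) + 1L]] <- smry(sub, "total", d, a)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
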