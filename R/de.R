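## Differential expression on normalized Cq: per-probe Welch tests with
## Benjamini-Hochberg control and a fold-change call, plus sex-stratified
## two-way factorial ANOVA (disease x APOE) with Tukey HSD post hocs.

#' Welch's unpaired two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] (unequal variances,
#' Welch-Satterthwaite degrees of freedom, two-sided) with an explicit
#' contract for the degenerate zero-variance cases the base function
#' refuses: both groups constant and equal means gives \code{t = 0, p = 1};
#' both constant with unequal means gives \code{p = 0} with a
#' degenerate-variance warning.
#'
#' @param x,y numeric vectors with at least two non-missing values each.
#' @return list with \code{t}, \code{df} and \code{p}.
#' @export
welchTest <- function(x, y) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L)
        stop("each group needs at least two values")
    vx <- stats::var(x); vy <- stats::var(y)
    if (vx == 0 && vy == 0) {
        if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p = 1))
        warning("zero variance in both groups with unequal means")
        return(list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_, p = 0))
    }
    ht <- stats::t.test(x, y, var.equal = FALSE)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' Benjamini-Hochberg critical value at a given rank
#'
#' The step-up line evaluated at rank \code{k} of \code{m} ordered p-values:
#' \eqn{(k/m) q}.  For a 71-test family at q = 0.20 the rank-4 critical
#' value is 0.0113, the realized significance line when four tests reject.
#'
#' @param m number of tests.
#' @param q FDR level in (0, 1).
#' @param k rank, 1..m.
#' @return the critical value.
#' @export
bhCriticalValue <- function(m, q, k) {
    if (k < 1 || k > m) stop("'k' must lie in 1..m")
    if (q <= 0 || q >= 1) stop("'q' must lie in (0, 1)")
    (k / m) * q
}

#' Benjamini-Hochberg step-up procedure
#'
#' Rejects the hypotheses with the \code{k} smallest p-values, where \code{k}
#' is the largest rank whose ordered p-value sits at or below its critical
#' line \eqn{(k/m) q}.  Equivalent to \code{p.adjust(p, "BH") <= q}; this
#' implementation additionally reports the realized threshold — the boundary
#' ordered p-value \eqn{p_{(k)}} (0 when nothing is rejected) — so the
#' significance line of a volcano plot can be drawn for exactly the tested
#' family.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param q FDR level in (0, 1).
#' @return list with logical \code{rejected} (same order as \code{p}) and
#'   numeric \code{threshold}.
#' @export
bhAdjust <- function(p, q) {
    if (length(p) == 0L)
        return(list(rejected = logical(0), threshold = 0))
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    if (q <= 0 || q >= 1) stop("'q' must lie in (0, 1)")
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    below <- which(ps <= (seq_len(m) / m) * q)
    if (length(below) == 0L)
        return(list(rejected = rep(FALSE, m), threshold = 0))
    k <- max(below)
    list(rejected = p <= ps[k], threshold = ps[k])
}

#' Two-group differential expression on normalized Cq
#'
#' Per-probe Welch tests of \eqn{\Delta Cq} between the two levels of a
#' grouping factor, Benjamini-Hochberg control across exactly the tested
#' probe family, and a fold-change call at \code{fcThreshold}.  A probe is
#' significant when it is both BH-rejected and shows at least the threshold
#' fold change; probes reaching p < 0.05 and the fold-change threshold
#' without BH rejection are labelled suggestive.  Probes with fewer than two
#' usable values in either group are reported untested and excluded from the
#' BH family.
#'
#' @param norm a [NormalizedCq-class].
#' @param group name of a two-level \code{colData} column (e.g.
#'   \code{"diagnosis"}), or a factor/vector along the samples.
#' @param testLevel level treated as the test group (fold changes are
#'   test vs. reference); default: first level encountered.
#' @param config a [cqConfig()] list (uses \code{fdrQDE},
#'   \code{fcThreshold}).
#' @return \code{data.frame}, one row per probe, with test results
#'   (\code{delta_delta_cq, rq, t_stat, welch_df, p_value}), decisions
#'   (\code{bh_rejected, fc_flag, significant, tested}) and volcano columns
#'   (\code{log2_fc, neg_log10_p, class}); the realized BH threshold and
#'   family size are attached as attributes \code{"bh_threshold"} and
#'   \code{"m"}.
#' @export
deAnalysis <- function(norm, group, testLevel = NULL, config = cqConfig()) {
    stopifnot(is(norm, "NormalizedCq"))
    g <- if (is.character(group) && length(group) == 1L) {
        if (!group %in% colnames(colData(norm)))
            stop("no colData column '", group, "'")
        as.character(colData(norm)[[group]])
    } else as.character(group)
    lev <- unique(g)
    if (length(lev) != 2L)
        stop("grouping must have exactly two levels; found: ",
             paste(lev, collapse = ", "))
    if (is.null(testLevel)) testLevel <- lev[1L]
    if (!testLevel %in% lev) stop("unknown testLevel: ", testLevel)
    refLevel <- setdiff(lev, testLevel)
    dm <- dcqValues(norm)
    res <- lapply(rownames(dm), function(p) {
        xt <- dm[p, g == testLevel]; xt <- xt[!is.na(xt)]
        xr <- dm[p, g == refLevel];  xr <- xr[!is.na(xr)]
        if (length(xt) < 2L || length(xr) < 2L)
            return(data.frame(probe_id = p, delta_delta_cq = NA_real_,
                              rq = NA_real_, t_stat = NA_real_,
                              welch_df = NA_real_, p_value = NA_real_,
                              tested = FALSE))
        wt <- welchTest(xt, xr)
        ddcq <- mean(xt) - mean(xr)
        data.frame(probe_id = p, delta_delta_cq = ddcq, rq = 2^(-ddcq),
                   t_stat = wt$t, welch_df = wt$df, p_value = wt$p,
                   tested = TRUE)
    })
    out <- do.call(rbind, res)
    bh <- bhAdjust(out$p_value[out$tested], config$fdrQDE)
    out$bh_rejected <- FALSE
    out$bh_rejected[out$tested] <- bh$rejected
    out$fc_flag <- !is.na(out$rq) &
        abs(log2(out$rq)) >= log2(config$fcThreshold)
    out$significant <- out$bh_rejected & out$fc_flag
    out$log2_fc <- log2(out$rq)
    out$neg_log10_p <- -log10(out$p_value)
    out$class <- ifelse(out$significant, "significant",
                 ifelse(out$fc_flag & !is.na(out$p_value) &
                        out$p_value < 0.05, "fc-only-suggestive", "null"))
    out$class[!out$tested] <- "untested"
    attr(out, "bh_threshold") <- bh$threshold
    attr(out, "m") <- sum(out$tested)
    attr(out, "groups") <- c(test = testLevel, ref = refLevel)
    rownames(out) <- NULL
    out
}

#' Sex-stratified two-way ANOVA with Tukey post hocs
#'
#' Within each level of the stratifying factor (by default sex), fits a
#' fixed-effects two-way ANOVA \code{dcq ~ diagnosis * apoe} per probe and
#' runs Tukey HSD over the four cell means using the ANOVA error term.
#' Probes with an empty cell in a stratum are skipped with a reason; probes
#' with zero variance everywhere return p = 1 for all effects with a
#' warning.
#'
#' @param norm a [NormalizedCq-class] whose \code{colData} carries
#'   \code{diagnosis}, \code{apoe} and the stratifying column.
#' @param stratum name of the stratifying \code{colData} column.
#' @param probes probes to analyze (default: all rows).
#' @return list with \code{anova} (long \code{data.frame}: probe, stratum,
#'   effect, F, df_num, df_den, p), \code{tukey} (probe, stratum, contrast,
#'   diff, p_adj) and \code{skipped} (probe, stratum, reason).
#' @export
stratifiedAnova <- function(norm, stratum = "sex", probes = rownames(norm)) {
    stopifnot(is(norm, "NormalizedCq"))
    cd <- colData(norm)
    for (col in c("diagnosis", "apoe", stratum))
        if (!col %in% colnames(cd)) stop("no colData column '", col, "'")
    dm <- dcqValues(norm)
    anova_rows <- list(); tukey_rows <- list(); skipped <- list()
    for (s in unique(as.character(cd[[stratum]]))) {
        sel <- as.character(cd[[stratum]]) == s
        dia <- factor(as.character(cd$diagnosis[sel]))
        apo <- factor(as.character(cd$apoe[sel]))
        for (p in probes) {
            y <- dm[p, sel]
            keep <- !is.na(y)
            d <- data.frame(y = y[keep], dia = dia[keep], apo = apo[keep])
            cells <- table(d$dia, d$apo)
            if (length(cells) < 4L || any(cells < 2L)) {
                skipped[[length(skipped) + 1L]] <- data.frame(
                    probe_id = p, stratum = s,
                    reason = "empty or degenerate cell")
                next
            }
            if (stats::var(d$y) == 0) {
                warning("probe '", p, "', stratum '", s,
                        "': zero variance; p set to 1")
                anova_rows[[length(anova_rows) + 1L]] <- data.frame(
                    probe_id = p, stratum = s,
                    effect = c("diagnosis", "apoe", "interaction"),
                    F = 0, df_num = 1L,
                    df_den = nrow(d) - 4L, p = 1)
                next
            }
            fit <- stats::aov(y ~ dia * apo, data = d)
            tab <- summary(fit)[[1L]]
            eff <- c("diagnosis", "apoe", "interaction")
            anova_rows[[length(anova_rows) + 1L]] <- data.frame(
                probe_id = p, stratum = s, effect = eff,
                F = tab[1:3, "F value"], df_num = tab[1:3, "Df"],
                df_den = tab[4L, "Df"], p = tab[1:3, "Pr(>F)"])
            tk <- stats::TukeyHSD(fit, "dia:apo")[["dia:apo"]]
            tukey_rows[[length(tukey_rows) + 1L]] <- data.frame(
                probe_id = p, stratum = s, contrast = rownames(tk),
                diff = tk[, "diff"], p_adj = tk[, "p adj"],
                row.names = NULL)
        }
    }
    rb <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
    list(anova = rb(anova_rows,
                    data.frame(probe_id = character(0), stratum = character(0),
                               effect = character(0), F = numeric(0),
                               df_num = integer(0), df_den = integer(0),
                               p = numeric(0))),
         tukey = rb(tukey_rows,
                    data.frame(probe_id = character(0), stratum = character(0),
                               contrast = character(0), diff = numeric(0),
                               p_adj = numeric(0))),
         skipped = rb(skipped,
                      data.frame(probe_id = character(0),
                                 stratum = character(0),
                                 reason = character(0))))
}

#' Main-effect F from cell summary statistics
#'
#' Reconstructs a main-effect F test from per-cell means, standard
#' deviations and sizes alone — the situation of a published characteristics
#' table where raw covariate values are unavailable.  The between-group sum
#' of squares comes from the (size-weighted) level means, the within-cell
#' mean square from the cell variances; the error degrees of freedom are
#' \eqn{\sum n_i - } number of cells.
#'
#' @param cells \code{data.frame} with one row per design cell: factor
#'   columns plus \code{mean}, \code{sd}, \code{n} (each \code{n >= 2}).
#' @param effect name of the factor column whose main effect is tested.
#' @return list with \code{F}, \code{df_num}, \code{df_den}, \code{p}.
#' @examples
#' cells <- data.frame(g = c("a", "b"), mean = c(0, 1), sd = 1, n = 5)
#' anovaFromCellSummaries(cells, "g")   # F = 2.5 on (1, 8)
#' @export
anovaFromCellSummaries <- function(cells, effect) {
    stopifnot(is.data.frame(cells),
              all(c("mean", "sd", "n") %in% names(cells)),
              effect %in% names(cells))
    if (any(cells$n < 2)) stop("every cell needs n >= 2")
    N <- sum(cells$n)
    grand <- sum(cells$n * cells$mean) / N
    lev <- split(cells, cells[[effect]])
    ssb <- sum(vapply(lev, function(l) {
        nl <- sum(l$n)
        ml <- sum(l$n * l$mean) / nl
        nl * (ml - grand)^2
    }, numeric(1)))
    dfn <- length(lev) - 1L
    ssw <- sum((cells$n - 1) * cells$sd^2)
    dfd <- N - nrow(cells)
    Fval <- (ssb / dfn) / (ssw / dfd)
    list(F = Fval, df_num = dfn, df_den = dfd,
         p = stats::pf(Fval, dfn, dfd, lower.tail = FALSE))
}
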