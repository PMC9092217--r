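## Synthetic study generator.  Emulates the statistical structure the
## pipeline assumes: a balanced diagnosis x sex x APOE design, Gaussian Cq
## noise on the log2 scale, right-censoring at the detection ceiling (which
## ties detection dropout to how close a probe's baseline sits to the
## ceiling, a probit link for free), sporadic quality-metric failures,
## water-only control wells with optional planted contamination, and planted
## group effects expressed as ddCq shifts.  Every generated truth is
## recorded so downstream results can be checked against it exactly.

#' Specification of a synthetic qPCR array study
#'
#' Defaults emulate a 56-participant balanced 2x2x2 cohort (7 per
#' diagnosis x sex x APOE cell) assayed on a ~190-probe panel with five
#' tightly-expressed endogenous-control probes, within-group SD of 0.8
#' cycles, detection ceiling 34, and a 2\% well quality-failure rate.
#'
#' A planted "1.5-fold increase" in a test level is encoded as a ddCq shift
#' of \eqn{-\log_2 1.5 \approx -0.585} cycles: the shift is *added to the Cq*
#' of the test-level samples (lower Cq = more abundant).  Effects are rows of
#' \code{effects}: \code{probe} (index or id), \code{factor} (one of
#' \code{diagnosis}, \code{sex}, \code{apoe}, \code{interaction}),
#' \code{shift} (cycles).  Test levels are \code{AD}, \code{female},
#' \code{e3,4}; \code{interaction} applies \code{+shift/2} to the
#' (AD, e3,4) and (CTL, e3,3) cells and \code{-shift/2} to the other two (a
#' pure disease x APOE interaction pattern).
#'
#' @param nPerCell samples per design cell.
#' @param nProbes number of test probes.
#' @param nControls number of endogenous-control probes.
#' @param controlSd within-group SD of the control probes (cycles).
#' @param baselineRange range of the uniform draw for test-probe baseline
#'   mean Cq.
#' @param withinSd within-group SD of test probes (cycles).
#' @param effects \code{data.frame(probe, factor, shift)} of planted
#'   effects; empty for a null study.
#' @param ceiling detection ceiling.
#' @param qualityFailRate fraction of detected wells given a failing
#'   amplification score or Cq confidence.
#' @param ntcContaminated probe ids (or indices) whose water-only well
#'   amplifies within 1 cycle of the experimental mean.
#' @param seed integer seed; the same spec generates bit-identical data.
#' @param allowControlEffects permit planting an effect on a control probe
#'   (normally a spec error, since a changing normalizer is a design fault).
#' @return a validated list of class \code{synthetic_spec}.
#' @export
syntheticSpec <- function(nPerCell = 7L, nProbes = 190L, nControls = 5L,
                          controlSd = 0.15, baselineRange = c(24, 33),
                          withinSd = 0.8,
                          effects = data.frame(probe = character(0),
                                               factor = character(0),
                                               shift = numeric(0)),
                          ceiling = 34, qualityFailRate = 0.02,
                          ntcContaminated = character(0), seed = 1L,
                          allowControlEffects = FALSE) {
    stopifnot(nPerCell >= 2, nProbes >= 1, nControls >= 1,
              controlSd > 0, withinSd > 0, ceiling > 0,
              length(baselineRange) == 2L,
              baselineRange[1] < baselineRange[2])
    if (qualityFailRate < 0 || qualityFailRate > 1)
        stop("'qualityFailRate' must lie in [0, 1]")
    if (controlSd > 0.2)
        warning("control probes should be tightly expressed ",
                "(SD <= 0.2 cycles)")
    effects <- as.data.frame(effects)
    if (nrow(effects)) {
        stopifnot(all(c("probe", "factor", "shift") %in% names(effects)))
        ok <- effects$factor %in%
            c("diagnosis", "sex", "apoe", "interaction")
        if (!all(ok))
            stop("unknown effect factor(s): ",
                 paste(unique(effects$factor[!ok]), collapse = ", "))
    }
    structure(list(nPerCell = as.integer(nPerCell),
                   nProbes = as.integer(nProbes),
                   nControls = as.integer(nControls),
                   controlSd = controlSd, baselineRange = baselineRange,
                   withinSd = withinSd, effects = effects,
                   ceiling = ceiling, qualityFailRate = qualityFailRate,
                   ntcContaminated = as.character(ntcContaminated),
                   seed = as.integer(seed),
                   allowControlEffects = allowControlEffects),
              class = "synthetic_spec")
}

.probe_ids <- function(spec) {
    list(test = sprintf("syn-miR-%04d", seq_len(spec$nProbes)),
         control = sprintf("syn-ctrl-%02d", seq_len(spec$nControls)))
}

#' Generate a complete synthetic well-level dataset
#'
#' Draws the sample sheet, every experimental well (Gaussian Cq around the
#' probe/cell mean, emitted as the undetected sentinel when the draw exceeds
#' the ceiling), one water-only (NTC) well per probe, and the truth table
#' recording baselines, planted effects, contaminated probes and
#' quality-failed wells.
#'
#' @param spec a [syntheticSpec()].
#' @return list with \code{wells} (experimental + NTC rows, the schema
#'   [readCqTable()] reads), \code{samples} (sample sheet) and \code{truth}.
#' @export
generateCqDataset <- function(spec) {
    stopifnot(inherits(spec, "synthetic_spec"))
    set.seed(spec$seed)
    ids <- .probe_ids(spec)
    probes <- c(ids$test, ids$control)

    ## resolve planted-effect probe references (index -> id)
    eff <- spec$effects
    if (nrow(eff)) {
        if (is.numeric(eff$probe)) eff$probe <- ids$test[eff$probe]
        onCtl <- eff$probe %in% ids$control
        if (any(onCtl) && !spec$allowControlEffects)
            stop("planted effect on control probe(s): ",
                 paste(eff$probe[onCtl], collapse = ", "),
                 " (set allowControlEffects = TRUE to override)")
        if (any(onCtl))
            warning("effect planted on a control probe; the normalizer ",
                    "will absorb part of every planted shift")
        unknown <- setdiff(eff$probe, probes)
        if (length(unknown))
            stop("planted effect on unknown probe(s): ",
                 paste(unknown, collapse = ", "))
    }

    ## sample sheet: balanced 2x2x2 design
    grid <- expand.grid(apoe = .APOE, sex = .SEX, diagnosis = .DIAGNOSIS,
                        stringsAsFactors = FALSE)
    samples <- grid[rep(seq_len(nrow(grid)), each = spec$nPerCell), ]
    n <- nrow(samples)
    samples$sample_id <- sprintf("S%03d", seq_len(n))
    samples$age_years <- round(stats::rnorm(n, 72.5, 7), 1)
    samples$mmse <- ifelse(
        samples$diagnosis == "CTL",
        pmin(30L, pmax(24L, round(stats::rnorm(n, 29.3, 1.3)))),
        pmin(30L, pmax(0L, round(stats::rnorm(n, 21.5, 3.1)))))
    samples$fraction_pool <- NA_character_
    samples <- samples[, c("sample_id", "diagnosis", "sex", "apoe",
                           "age_years", "mmse", "fraction_pool")]
    rownames(samples) <- NULL

    ## probe baselines and per-probe noise
    base <- c(stats::runif(spec$nProbes, spec$baselineRange[1],
                           spec$baselineRange[2]),
              stats::runif(spec$nControls, spec$baselineRange[1],
                           spec$baselineRange[1] + 2))
    names(base) <- probes
    sds <- c(rep(spec$withinSd, spec$nProbes),
             rep(spec$controlSd, spec$nControls))
    names(sds) <- probes

    ## per-sample shift matrix from planted effects
    shift <- matrix(0, length(probes), n, dimnames = list(probes, NULL))
    if (nrow(eff)) for (i in seq_len(nrow(eff))) {
        p <- eff$probe[i]; d <- eff$shift[i]
        sel <- switch(eff$factor[i],
            diagnosis = samples$diagnosis == "AD",
            sex = samples$sex == "female",
            apoe = samples$apoe == "e3,4",
            interaction = NULL)
        if (eff$factor[i] == "interaction") {
            pos <- (samples$diagnosis == "AD") == (samples$apoe == "e3,4")
            shift[p, pos] <- shift[p, pos] + d / 2
            shift[p, !pos] <- shift[p, !pos] - d / 2
        } else {
            shift[p, sel] <- shift[p, sel] + d
        }
    }

    ## experimental wells
    mu <- base + matrix(0, length(probes), n) + shift  # recycles base by row
    cq <- mu + matrix(stats::rnorm(length(probes) * n, 0, sds),
                      length(probes), n)
    censored <- cq > spec$ceiling
    wells <- data.frame(
        sample_id = rep(samples$sample_id, each = length(probes)),
        probe_id = rep(probes, times = n),
        cq = as.vector(ifelse(censored, NA_real_, cq)),
        stringsAsFactors = FALSE)

    ## quality metrics; failures only matter for detected wells
    cens <- as.vector(censored)
    nw <- nrow(wells)
    wells$amp_score <- round(stats::runif(nw, 1.2, 2.0), 3)
    wells$cq_conf <- round(stats::runif(nw, 0.85, 1.0), 3)
    ## controls are, by construction, probes with good-quality expression
    ## in every sample, so quality failures hit test probes only
    isCtlWell <- wells$probe_id %in% ids$control
    fail <- stats::runif(nw) < spec$qualityFailRate & !isCtlWell
    failAmp <- fail & stats::runif(nw) < 0.5
    failConf <- fail & !failAmp
    wells$amp_score[failAmp] <- round(stats::runif(sum(failAmp), 0.2, 0.95), 3)
    wells$cq_conf[failConf] <- round(stats::runif(sum(failConf), 0.2, 0.75), 3)
    wells$is_ntc <- FALSE

    ## NTC wells: one per probe; contaminated probes amplify near the
    ## experimental mean, clean probes stay undetected
    contam <- spec$ntcContaminated
    if (length(contam) && all(grepl("^[0-9]+$", contam)))
        contam <- ids$test[as.integer(contam)]
    unknown <- setdiff(contam, probes)
    if (length(unknown))
        stop("unknown NTC-contaminated probe(s): ",
             paste(unknown, collapse = ", "))
    exptMean <- rowMeans(ifelse(censored, spec$ceiling, cq))
    ntc <- data.frame(sample_id = "NTC01", probe_id = probes,
                      cq = NA_real_, amp_score = 0, cq_conf = 0,
                      is_ntc = TRUE, stringsAsFactors = FALSE)
    if (length(contam)) {
        j <- match(contam, probes)
        ntc$cq[j] <- pmin(exptMean[j] + stats::runif(length(j), -0.8, 0.8),
                          spec$ceiling - 1e-6)
        ntc$amp_score[j] <- round(stats::runif(length(j), 1.2, 2.0), 3)
        ntc$cq_conf[j] <- round(stats::runif(length(j), 0.85, 1.0), 3)
    }

    failIdx <- which((failAmp | failConf) & !cens)
    failWells <- wells[failIdx, c("sample_id", "probe_id"), drop = FALSE]
    failWells$reason <- ifelse(failAmp[failIdx], "amp_score", "cq_conf")
    rownames(failWells) <- NULL

    list(wells = rbind(wells, ntc),
         samples = samples,
         truth = list(baselines = data.frame(probe_id = probes,
                                             baseline_cq = unname(base),
                                             within_sd = unname(sds),
                                             is_control = probes %in%
                                                 ids$control),
                      effects = eff,
                      controls = ids$control,
                      ntc_contaminated = sort(contam),
                      quality_failures = failWells,
                      ceiling = spec$ceiling))
}

#' Generate synthetic prediction, validated-pair and pathway tables
#'
#' For every miRNA, each gene is independently assigned to both sources
#' (probability \code{overlapRate}), source A only (\code{retainA}), source
#' B only (\code{retainB}) or neither.  Retained pairs receive scores that
#' pass the standard cutoffs (CWCS <= -0.3 for the TargetScan-style table,
#' score >= 60 for the miRDB-style table); a matching number of decoy rows
#' with failing scores is added so threshold filtering has something to do.
#' Validated pairs are sampled with declared enrichment inside the predicted
#' union, and pathway gene sets are built so that roughly half are enriched
#' in the union's target genes.  The truth list carries the exact per-strategy
#' contingency counts implied by the construction.
#'
#' @param nMirnas,nGenes dimensions of the closed universe.
#' @param retainA,retainB,overlapRate per-gene assignment probabilities.
#' @param validatedRate probability that a predicted-union pair is
#'   validated; non-predicted pairs are validated at a tenth of this rate.
#' @param nPathways number of pathway sets (half enriched, half random).
#' @param seed integer seed.
#' @return list with \code{targetscan}, \code{mirdb} (score tables),
#'   \code{validated} (\code{pairs} + \code{universe}), \code{pathways}
#'   (named list) and \code{truth} (strategy contingency counts and the
#'   enriched-pathway names).
#' @export
generateTargetTables <- function(nMirnas = 4L, nGenes = 500L,
                                 retainA = 0.10, retainB = 0.10,
                                 overlapRate = 0.05, validatedRate = 0.20,
                                 nPathways = 20L, seed = 1L) {
    rates <- c(retainA, retainB, overlapRate, validatedRate)
    if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
    if (retainA + retainB + overlapRate > 1)
        stop("retainA + retainB + overlapRate must not exceed 1")
    set.seed(seed)
    mirnas <- sprintf("syn-miR-%04d", seq_len(nMirnas))
    genes <- sprintf("GENE%04d", seq_len(nGenes))

    assign <- matrix(sample(c("both", "A", "B", "none"),
                            nMirnas * nGenes, replace = TRUE,
                            prob = c(overlapRate, retainA, retainB,
                                     1 - overlapRate - retainA - retainB)),
                     nMirnas, nGenes, dimnames = list(mirnas, genes))
    pairGrid <- expand.grid(mirna_id = mirnas, gene_id = genes,
                            stringsAsFactors = FALSE)
    cls <- assign[cbind(match(pairGrid$mirna_id, mirnas),
                        match(pairGrid$gene_id, genes))]

    inA <- cls %in% c("A", "both")
    inB <- cls %in% c("B", "both")
    mkTable <- function(keepMask, passScore, failScore, decoyFrac = 0.5) {
        keep <- pairGrid[keepMask, , drop = FALSE]
        keep$score <- passScore(nrow(keep))
        pool <- pairGrid[!keepMask, , drop = FALSE]
        nd <- min(nrow(pool), ceiling(decoyFrac * nrow(keep)))
        decoy <- pool[sample.int(nrow(pool), nd), , drop = FALSE]
        decoy$score <- failScore(nrow(decoy))
        out <- rbind(keep, decoy)
        rownames(out) <- NULL
        out
    }
    tsTab <- mkTable(inA,
                     function(k) round(stats::runif(k, -2, -0.3), 3),
                     function(k) round(stats::runif(k, -0.29, -0.01), 3))
    dbTab <- mkTable(inB,
                     function(k) round(stats::runif(k, 60, 100), 1),
                     function(k) round(stats::runif(k, 10, 59.9), 1))

    unionMask <- inA | inB
    valMask <- (unionMask & stats::runif(nrow(pairGrid)) < validatedRate) |
        (!unionMask & stats::runif(nrow(pairGrid)) < validatedRate / 10)
    validated <- list(pairs = pairGrid[valMask, , drop = FALSE],
                      universe = genes)
    rownames(validated$pairs) <- NULL

    counts <- function(predMask) {
        TP <- sum(predMask & valMask); FP <- sum(predMask & !valMask)
        FN <- sum(!predMask & valMask)
        TN <- sum(!predMask & !valMask)
        c(TP = TP, FP = FP, FN = FN, TN = TN)
    }
    truthCounts <- rbind(union = counts(unionMask),
                         intersection = counts(cls == "both"),
                         A = counts(inA), B = counts(inB))

    unionGenes <- sort(unique(pairGrid$gene_id[unionMask]))
    half <- nPathways %/% 2L
    pathways <- list()
    for (i in seq_len(nPathways)) {
        sz <- sample(15:40, 1L)
        if (i <= half && length(unionGenes) >= 5L) {
            nin <- min(length(unionGenes), sz)
            set <- c(sample(unionGenes, nin),
                     sample(setdiff(genes, unionGenes), sz - nin))
        } else {
            set <- sample(genes, sz)
        }
        pathways[[sprintf("PATHWAY_%02d", i)]] <- sort(unique(set))
    }

    list(targetscan = tsTab, mirdb = dbTab, validated = validated,
         pathways = pathways,
         truth = list(counts = truthCounts,
                      enriched = names(pathways)[seq_len(half)]))
}

#' Write a runnable synthetic study directory
#'
#' Emits exactly the TSV formats the readers consume (wells, sample sheet)
#' plus truth tables, and optionally the target-prediction files and a GMT
#' pathway file, so a complete analysis can be replayed from disk.
#'
#' @param dataset result of [generateCqDataset()].
#' @param dir output directory (created if needed).
#' @param targetTables optional result of [generateTargetTables()].
#' @return \code{dir}, invisibly.
#' @export
writeStudy <- function(dataset, dir, targetTables = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeCqTable(dataset$wells, file.path(dir, "wells.tsv"), "tsv")
    writeSampleSheet(dataset$samples, file.path(dir, "samples.tsv"), "tsv")
    utils::write.table(dataset$truth$baselines,
                       file.path(dir, "truth_baselines.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(dataset$truth$effects,
                       file.path(dir, "truth_effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(targetTables)) {
        utils::write.table(targetTables$targetscan,
                           file.path(dir, "predictions_targetscan.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(targetTables$mirdb,
                           file.path(dir, "predictions_mirdb.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(targetTables$validated$pairs,
                           file.path(dir, "validated_pairs.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        gmt <- vapply(names(targetTables$pathways), function(nm)
            paste(c(nm, "synthetic", targetTables$pathways[[nm]]),
                  collapse = "\t"), character(1))
        writeLines(gmt, file.path(dir, "pathways.gmt"))
    }
    invisible(dir)
}
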