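## Target-prediction ensemble: score-threshold filtering of prediction
## tables, union/intersection set algebra, benchmarking against validated
## interactions, strategy selection, and hypergeometric pathway
## over-representation.

.pair_key <- function(df) paste(df$mirna_id, df$gene_id, sep = "\r")

.as_pairs <- function(df) {
    stopifnot(all(c("mirna_id", "gene_id") %in% names(df)))
    out <- unique(df[, c("mirna_id", "gene_id")])
    rownames(out) <- NULL
    out
}

#' Filter a prediction table at its source's score cutoff
#'
#' TargetScan-style tables use the cumulative weighted context score (CWCS;
#' more negative predicts stronger repression): pairs with CWCS above the
#' cutoff (default -0.3) are excluded.  miRDB-style tables use a 0-100
#' target score: pairs scoring below the cutoff (default 60) are excluded;
#' a score exactly at the cutoff is kept.
#'
#' @param table \code{data.frame} with \code{mirna_id, gene_id, score}.
#' @param source \code{"targetscan"} or \code{"mirdb"}.
#' @param threshold score cutoff; default depends on \code{source}.
#' @return \code{data.frame} of retained unique (mirna_id, gene_id) pairs.
#' @export
filterPredictions <- function(table, source = c("targetscan", "mirdb"),
                              threshold = NULL) {
    source <- match.arg(source)
    stopifnot(all(c("mirna_id", "gene_id", "score") %in% names(table)))
    keep <- switch(source,
        targetscan = {
            if (is.null(threshold)) threshold <- -0.3
            table$score <= threshold
        },
        mirdb = {
            if (is.null(threshold)) threshold <- 60
            table$score >= threshold
        })
    .as_pairs(table[keep, , drop = FALSE])
}

#' Combine two target sets
#'
#' Standard set semantics on (mirna, gene) pairs.
#'
#' @param setA,setB pair \code{data.frame}s (\code{mirna_id, gene_id}).
#' @param mode \code{"union"}, \code{"intersection"}, \code{"A"} or
#'   \code{"B"}.
#' @return pair \code{data.frame}.
#' @export
combineTargets <- function(setA, setB,
                           mode = c("union", "intersection", "A", "B")) {
    mode <- match.arg(mode)
    a <- .as_pairs(setA); b <- .as_pairs(setB)
    out <- switch(mode,
        union = unique(rbind(a, b)),
        intersection = a[.pair_key(a) %in% .pair_key(b), , drop = FALSE],
        A = a, B = b)
    rownames(out) <- NULL
    out
}

#' Gene-level projection of a target-pair set
#' @param pairs pair \code{data.frame}.
#' @return sorted character vector of unique target genes.
#' @export
geneTargets <- function(pairs) sort(unique(.as_pairs(pairs)$gene_id))

#' Inclusion-exclusion accounting for a two-set union
#'
#' Given the sizes of two prediction sets and their overlap, returns the
#' union size and the counts unique to each source — the arithmetic behind a
#' two-circle Venn of predicted targets (e.g. 272 and 2,245 targets sharing
#' 198 give a union of 2,319 with 74 and 2,047 unique).
#'
#' @param sizeA,sizeB set sizes.
#' @param sizeOverlap size of the intersection.
#' @return named list: \code{union}, \code{unique_a}, \code{unique_b}.
#' @export
unionAccounting <- function(sizeA, sizeB, sizeOverlap) {
    if (sizeOverlap > min(sizeA, sizeB))
        stop("overlap exceeds one of the set sizes")
    list(union = sizeA + sizeB - sizeOverlap,
         unique_a = sizeA - sizeOverlap,
         unique_b = sizeB - sizeOverlap)
}

#' Benchmark a predicted target set against validated interactions
#'
#' Classifies every (mirna, gene) pair of the closed universe — the supplied
#' miRNAs crossed with the declared gene universe — as TP/FP/FN/TN according
#' to membership in the predicted and validated sets, and reports
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP) and precision TP/(TP+FP).
#' Metrics whose denominator is zero are returned as \code{NA}.
#'
#' @param predicted pair \code{data.frame}.
#' @param validated list with \code{pairs} (pair \code{data.frame}) and
#'   \code{universe} (character vector of genes; every validated gene must
#'   belong to it).
#' @param mirnas miRNAs spanning the universe; default: all miRNAs seen in
#'   either set.
#' @param strategy label recorded in the output.
#' @return one-row \code{data.frame} with strategy, counts and metrics.
#' @export
benchmarkStrategy <- function(predicted, validated, mirnas = NULL,
                              strategy = "predicted") {
    stopifnot(is.list(validated), !is.null(validated$pairs),
              !is.null(validated$universe))
    pred <- .as_pairs(predicted)
    val <- .as_pairs(validated$pairs)
    uni <- unique(validated$universe)
    if (length(uni) == 0L) stop("empty gene universe")
    bad <- setdiff(val$gene_id, uni)
    if (length(bad))
        stop("validated gene(s) outside the declared universe: ",
             paste(utils::head(bad, 5L), collapse = ", "))
    if (is.null(mirnas)) mirnas <- union(pred$mirna_id, val$mirna_id)
    pred <- pred[pred$mirna_id %in% mirnas & pred$gene_id %in% uni, ]
    predKey <- .pair_key(pred)
    valKey <- .pair_key(val[val$mirna_id %in% mirnas, , drop = FALSE])
    total <- length(mirnas) * length(uni)
    TP <- sum(predKey %in% valKey)
    FP <- length(predKey) - TP
    FN <- length(valKey) - TP
    TN <- total - TP - FP - FN
    sfe <- function(num, den) if (den == 0) NA_real_ else num / den
    data.frame(strategy = strategy, TP = TP, FP = FP, FN = FN, TN = TN,
               sensitivity = sfe(TP, TP + FN),
               specificity = sfe(TN, TN + FP),
               precision = sfe(TP, TP + FP),
               stringsAsFactors = FALSE)
}

#' Declare the default closed gene universe for benchmarking
#'
#' The smallest defensible closed world: the union of every gene appearing
#' in either prediction set and every validated gene.  Used when no
#' external universe (e.g. all protein-coding genes) is supplied.
#'
#' @param setA,setB prediction pair sets.
#' @param validatedPairs validated pair \code{data.frame}.
#' @return sorted character vector of gene ids.
#' @export
declareUniverse <- function(setA, setB, validatedPairs) {
    sort(unique(c(.as_pairs(setA)$gene_id, .as_pairs(setB)$gene_id,
                  .as_pairs(validatedPairs)$gene_id)))
}

#' Benchmark the four standard ensemble strategies
#'
#' Convenience wrapper producing one [benchmarkStrategy()] row each for the
#' union, the intersection, and the two single-source sets.
#'
#' @param setA,setB filtered pair sets from the two prediction sources.
#' @inheritParams benchmarkStrategy
#' @return four-row \code{data.frame}.
#' @export
benchmarkAll <- function(setA, setB, validated, mirnas = NULL) {
    modes <- c("union", "intersection", "A", "B")
    do.call(rbind, lapply(modes, function(m)
        benchmarkStrategy(combineTargets(setA, setB, m), validated,
                          mirnas = mirnas, strategy = m)))
}

#' Select the ensemble strategy from a benchmark table
#'
#' Default rule: lexicographic maximization of sensitivity, then precision,
#' then specificity.  Ties fall to the first strategy in table order and are
#' reported via a message, and the full table always accompanies the choice
#' so it remains auditable.
#'
#' @param results \code{data.frame} from [benchmarkAll()] (>= 2 rows).
#' @param rule character vector of metric names in priority order.
#' @return the selected strategy label; the benchmark table is attached as
#'   attribute \code{"table"}.
#' @export
selectStrategy <- function(results,
                           rule = c("sensitivity", "precision",
                                    "specificity")) {
    stopifnot(is.data.frame(results), nrow(results) >= 2L,
              all(rule %in% names(results)))
    keys <- lapply(results[rule], function(v) -replace(v, is.na(v), -Inf))
    ord <- do.call(order, keys)
    best <- ord[1L]
    tied <- vapply(seq_len(nrow(results)), function(i)
        all(vapply(rule, function(r)
            isTRUE(all.equal(results[[r]][i], results[[r]][best])),
            logical(1))), logical(1))
    if (sum(tied) > 1L) {
        best <- which(tied)[1L]
        message("strategy tie on all metrics between: ",
                paste(results$strategy[tied], collapse = ", "),
                "; keeping '", results$strategy[best], "'")
    }
    structure(results$strategy[best], table = results)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric test of each pathway gene set's overlap with the
#' target genes, within a declared gene universe, followed by
#' Benjamini-Hochberg control across the tested pathways.  Pathways with
#' members outside the universe are skipped with a warning.
#'
#' @param targets character vector of target genes (intersected with the
#'   universe).
#' @param pathways named list of gene-set character vectors (e.g. from
#'   [readGmt()]).
#' @param universe character vector of all considered genes.
#' @param q BH level.
#' @return \code{data.frame} sorted by p-value: pathway, set size, overlap,
#'   p, and the BH decision at \code{q}.
#' @export
overRepresentation <- function(targets, pathways, universe, q = 0.01) {
    universe <- unique(universe)
    targets <- intersect(unique(targets), universe)
    k <- length(targets)
    keep <- vapply(names(pathways), function(nm) {
        out <- all(pathways[[nm]] %in% universe)
        if (!out) warning("pathway '", nm,
                          "' has genes outside the universe; skipped")
        out
    }, logical(1))
    pathways <- pathways[keep]
    if (length(pathways) == 0L)
        return(data.frame(pathway = character(0), size = integer(0),
                          overlap = integer(0), p = numeric(0),
                          bh_rejected = logical(0)))
    res <- data.frame(
        pathway = names(pathways),
        size = vapply(pathways, function(s) length(unique(s)), integer(1)),
        stringsAsFactors = FALSE)
    res$overlap <- vapply(pathways, function(s)
        length(intersect(unique(s), targets)), integer(1))
    res$p <- stats::phyper(res$overlap - 1L, res$size,
                           length(universe) - res$size, k,
                           lower.tail = FALSE)
    res$bh_rejected <- bhAdjust(res$p, q)$rejected
    res <- res[order(res$p, res$pathway), ]
    rownames(res) <- NULL
    res
}

#' Read gene sets in GMT format
#'
#' @param path path to a tab-separated GMT file (set name, description,
#'   genes...).
#' @return named list of gene-id character vectors.
#' @export
readGmt <- function(path) fgsea::gmtPathways(path)
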