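## Presence/absence profiling of SEC fraction pools and three-set Venn
## partitioning of the expressed-probe sets.

#' Expressed-probe profile of one fraction pool
#'
#' A probe counts as expressed in the pool when it is detected below the
#' ceiling and quality-passing in at least \code{minSamples} of the pool's
#' donor samples (the standard inclusion rule for small pooled-fraction
#' panels is 2 of 4 donors).
#'
#' @param x a [CqExperiment-class]; either already restricted to the pool's
#'   donors, or carrying a \code{fraction_pool} column in \code{colData}
#'   together with the \code{pool} argument.
#' @param minSamples minimum expressed-donor count.
#' @param pool optional pool label used to subset by
#'   \code{colData(x)$fraction_pool}.
#' @return list with \code{pool} (label) and \code{probes} (sorted character
#'   vector of expressed probes), of class \code{presence_profile}.
#' @export
presenceProfile <- function(x, minSamples = 2L, pool = NULL) {
    stopifnot(is(x, "CqExperiment"))
    if (!is.null(pool)) {
        sel <- !is.na(colData(x)$fraction_pool) &
            colData(x)$fraction_pool == pool
        x <- x[, sel]
    } else pool <- "pool"
    if (ncol(x) < minSamples)
        stop("pool has fewer donors (", ncol(x), ") than 'minSamples' (",
             minSamples, ")")
    expressed <- detectionMask(x) & qcMask(x)
    structure(list(pool = pool,
                   probes = sort(rownames(x)[rowSums(expressed) >= minSamples])),
              class = "presence_profile")
}

#' Three-set Venn partition
#'
#' Partitions the union of three probe sets into the seven disjoint Venn
#' regions.  Region names are built from the profile labels, joined with
#' \code{"&"} for intersections and suffixed \code{"only"} for the exclusive
#' regions.
#'
#' @param profiles list of exactly three \code{presence_profile} objects (or
#'   plain character vectors, optionally named).
#' @return list with \code{counts} (named integer vector over the 7 regions,
#'   summing to the union size) and \code{members} (per-region sorted probe
#'   lists); per-set totals are attached as attribute \code{"set_totals"}.
#' @export
vennPartition <- function(profiles) {
    if (length(profiles) != 3L) stop("exactly three profiles required")
    sets <- lapply(profiles, function(p)
        if (inherits(p, "presence_profile")) p$probes else as.character(p))
    labels <- vapply(seq_along(profiles), function(i) {
        p <- profiles[[i]]
        if (inherits(p, "presence_profile")) p$pool
        else if (!is.null(names(profiles)[i]) && nzchar(names(profiles)[i]))
            names(profiles)[i]
        else LETTERS[i]
    }, character(1))
    all <- sort(unique(unlist(sets)))
    inA <- all %in% sets[[1]]; inB <- all %in% sets[[2]]
    inC <- all %in% sets[[3]]
    code <- paste0(as.integer(inA), as.integer(inB), as.integer(inC))
    regions <- c("100", "010", "001", "110", "101", "011", "111")
    rname <- c(paste0(labels[1], ".only"), paste0(labels[2], ".only"),
               paste0(labels[3], ".only"),
               paste(labels[1], labels[2], sep = "&"),
               paste(labels[1], labels[3], sep = "&"),
               paste(labels[2], labels[3], sep = "&"),
               paste(labels, collapse = "&"))
    members <- lapply(regions, function(r) all[code == r])
    names(members) <- rname
    counts <- vapply(members, length, integer(1))
    out <- list(counts = counts, members = members)
    attr(out, "set_totals") <- stats::setNames(
        vapply(sets, function(s) length(unique(s)), integer(1)), labels)
    out
}
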