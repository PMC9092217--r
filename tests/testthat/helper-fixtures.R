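# Fixtures are built in code; nothing is read from disk except what a test
# itself writes to tempdir().

# one experimental well row
well <- function(sample, probe, cq, amp = 1.5, conf = 0.95, ntc = FALSE) {
    data.frame(sample_id = sample, probe_id = probe, cq = cq,
               amp_score = amp, cq_conf = conf, is_ntc = ntc,
               stringsAsFactors = FALSE)
}

wells_df <- function(...) do.call(rbind, list(...))

# minimal sample sheet for n samples split over two diagnosis groups
sheet <- function(ids, diagnosis = rep(c("AD", "CTL"), length.out = length(ids)),
                  sex = rep(c("female", "male"), length.out = length(ids)),
                  apoe = rep(c("e3,3", "e3,4"), length.out = length(ids))) {
    data.frame(sample_id = ids, diagnosis = diagnosis, sex = sex,
               apoe = apoe, age_years = 72, mmse = 28L,
               fraction_pool = NA_character_, stringsAsFactors = FALSE)
}

# NormalizedCq straight from a dcq matrix (rows probes, cols samples)
make_norm <- function(dcq, coldata = NULL, controls = "ctrl") {
    if (is.null(colnames(dcq)))
        colnames(dcq) <- sprintf("S%02d", seq_len(ncol(dcq)))
    if (is.null(rownames(dcq)))
        rownames(dcq) <- sprintf("p%03d", seq_len(nrow(dcq)))
    cd <- if (is.null(coldata))
        S4Vectors::DataFrame(row.names = colnames(dcq))
    else S4Vectors::DataFrame(coldata, row.names = colnames(dcq))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dcq = dcq), colData = cd)
    methods::new("NormalizedCq", se, controls = controls)
}

# balanced 2x2x2 factor frame, nPerCell samples per cell
design_2x2x2 <- function(nPerCell = 7L) {
    g <- expand.grid(apoe = c("e3,3", "e3,4"), sex = c("female", "male"),
                     diagnosis = c("AD", "CTL"), stringsAsFactors = FALSE)
    g <- g[rep(seq_len(nrow(g)), each = nPerCell), ]
    g$sample_id <- sprintf("S%03d", seq_len(nrow(g)))
    rownames(g) <- NULL
    g
}
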