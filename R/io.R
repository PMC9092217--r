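## Tabular I/O for well-level Cq exports and sample sheets.  Instrument
## export schemas vary by vendor software version, so the column mapping is
## configurable; defaults match the canonical names used throughout the
## package.

.SENTINEL_TOKENS <- c("undetected", "undetermined")
.WELL_COLS <- c("sample_id", "probe_id", "cq", "amp_score", "cq_conf", "is_ntc")

.read_delim <- function(path, dialect) {
    sep <- switch(match.arg(dialect, c("csv", "tsv")), csv = ",", tsv = "\t")
    utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character", comment.char = "#",
                      fileEncoding = "UTF-8")
}

.map_columns <- function(df, required, colMap, what) {
    nm <- tolower(trimws(names(df)))
    if (!is.null(colMap)) {
        ## colMap: required name -> name used in the file
        idx <- match(tolower(colMap), nm)
        if (anyNA(idx))
            stop(sprintf("%s: mapped column(s) not found: %s", what,
                         paste(colMap[is.na(idx)], collapse = ", ")))
        names(df)[idx] <- names(colMap)
        nm <- tolower(names(df))
    }
    miss <- setdiff(required, nm)
    if (length(miss))
        stop(sprintf("%s: missing required column(s): %s", what,
                     paste(miss, collapse = ", ")))
    names(df) <- nm
    df
}

.parse_logical <- function(x, column) {
    out <- rep(NA, length(x))
    out[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
    out[tolower(x) %in% c("false", "f", "0", "no", "")] <- FALSE
    if (anyNA(out))
        stop(sprintf("column '%s': unparseable logical value(s) at row(s) %s",
                     column, paste(which(is.na(out)), collapse = ", ")))
    out
}

#' Read a well-level Cq export
#'
#' Parses one plate export into a well table with columns
#' \code{sample_id, probe_id, cq, amp_score, cq_conf, is_ntc}.  The literal
#' strings \code{"Undetected"}/\code{"Undetermined"} (case-insensitive) map to
#' an \code{NA} Cq, the non-amplification sentinel, which is kept distinct
#' from the imputed ceiling until [imputeCeiling()] runs.  Row order is
#' preserved and no row is silently dropped: any malformed row is a
#' line-numbered error.
#'
#' @param path file path.
#' @param dialect \code{"csv"} or \code{"tsv"}.
#' @param colMap optional named character vector mapping the canonical column
#'   names to the names used in the file, e.g.
#'   \code{c(sample_id = "Sample Name", cq = "Crt")}.
#' @return a \code{data.frame} of wells, one row per input row.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("sample_id,probe_id,cq,amp_score,cq_conf,is_ntc",
#'              "S01,hsa-miR-16-5p,28.4,1.6,0.97,false",
#'              "S01,hsa-miR-9-5p,Undetected,0,0,false"), tf)
#' readCqTable(tf, "csv")
#' @export
readCqTable <- function(path, dialect = c("csv", "tsv"), colMap = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- .read_delim(path, dialect)
    df <- .map_columns(df, .WELL_COLS, colMap, "Cq table")
    df <- df[, .WELL_COLS, drop = FALSE]
    if (nrow(df) == 0L) {
        df$cq <- numeric(0); df$amp_score <- numeric(0)
        df$cq_conf <- numeric(0); df$is_ntc <- logical(0)
        return(df)
    }
    raw <- trimws(df$cq)
    sentinel <- tolower(raw) %in% .SENTINEL_TOKENS
    cq <- suppressWarnings(as.numeric(raw))
    bad <- !sentinel & is.na(cq)
    if (any(bad))
        stop("column 'cq': non-numeric value(s) other than the undetected ",
             "sentinel at row(s) ", paste(which(bad), collapse = ", "))
    if (any(cq < 0, na.rm = TRUE))
        stop("column 'cq': negative value(s) at row(s) ",
             paste(which(cq < 0), collapse = ", "))
    df$cq <- cq
    df$amp_score <- suppressWarnings(as.numeric(df$amp_score))
    df$cq_conf <- suppressWarnings(as.numeric(df$cq_conf))
    if (any(df$cq_conf < 0 | df$cq_conf > 1, na.rm = TRUE))
        stop("column 'cq_conf': values must lie in [0, 1]")
    df$is_ntc <- .parse_logical(df$is_ntc, "is_ntc")
    key <- paste(df$sample_id, df$probe_id, sep = "\r")
    if (anyDuplicated(key))
        stop("duplicate (sample_id, probe_id) pair(s): ",
             paste(unique(sub("\r", " / ", key[duplicated(key)])),
                   collapse = "; "))
    rownames(df) <- NULL
    df
}

#' Write a well table
#'
#' Inverse of [readCqTable()]: the undetected sentinel (\code{NA} Cq) is
#' written back as the literal \code{"Undetected"} so that a write/read
#' round trip reproduces every field.
#'
#' @param wells a well \code{data.frame} as returned by [readCqTable()].
#' @param path output path.
#' @param dialect \code{"csv"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
writeCqTable <- function(wells, path, dialect = c("csv", "tsv")) {
    sep <- switch(match.arg(dialect), csv = ",", tsv = "\t")
    out <- wells[, .WELL_COLS, drop = FALSE]
    out$cq <- ifelse(is.na(out$cq), "Undetected",
                     formatC(out$cq, format = "g", digits = 17))
    out$is_ntc <- ifelse(out$is_ntc, "true", "false")
    utils::write.table(out, path, sep = sep, quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

.DIAGNOSIS <- c("AD", "CTL")
.SEX <- c("female", "male")
.APOE <- c("e3,3", "e3,4")
.POOLS <- c("Fx6-9", "Fx10-13", "Fx14-17")

#' Read and validate a sample sheet
#'
#' Expects columns \code{sample_id, diagnosis, sex, apoe, age_years, mmse}
#' and optionally \code{fraction_pool}.  Factor columns are validated against
#' the closed vocabularies of the study design (\code{AD/CTL},
#' \code{female/male}, \code{e3,3/e3,4}, pools \code{Fx6-9/Fx10-13/Fx14-17});
#' MMSE must be an integer in \[0, 30\] (may be missing for fraction-pool
#' donors); duplicated sample ids are an integrity error.
#'
#' @inheritParams readCqTable
#' @return a validated \code{data.frame} of sample metadata.
#' @export
readSampleSheet <- function(path, dialect = c("csv", "tsv"), colMap = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- .read_delim(path, dialect)
    req <- c("sample_id", "diagnosis", "sex", "apoe", "age_years", "mmse")
    df <- .map_columns(df, req, colMap, "sample sheet")
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample_id: ",
             paste(unique(df$sample_id[duplicated(df$sample_id)]),
                   collapse = ", "))
    chk <- function(col, allowed, optional = FALSE) {
        x <- trimws(df[[col]])
        x[x == ""] <- NA
        hit <- match(tolower(x), tolower(allowed))
        bad <- is.na(hit) & !is.na(x)
        if (!optional) bad <- bad | is.na(x)
        if (any(bad))
            stop(sprintf("column '%s': invalid value(s) %s; allowed: %s",
                         col, paste(unique(x[bad]), collapse = ", "),
                         paste(allowed, collapse = ", ")))
        allowed[hit]
    }
    df$diagnosis <- chk("diagnosis", .DIAGNOSIS)
    df$sex <- chk("sex", .SEX)
    df$apoe <- chk("apoe", .APOE)
    df$age_years <- suppressWarnings(as.numeric(df$age_years))
    mmse <- suppressWarnings(as.numeric(df$mmse))
    ok <- is.na(mmse) | (mmse == round(mmse) & mmse >= 0 & mmse <= 30)
    if (!all(ok))
        stop("column 'mmse': values must be integers in [0, 30]; bad row(s) ",
             paste(which(!ok), collapse = ", "))
    df$mmse <- as.integer(mmse)
    if ("fraction_pool" %in% names(df)) {
        df$fraction_pool <- chk("fraction_pool", .POOLS, optional = TRUE)
    } else {
        df$fraction_pool <- NA_character_
    }
    rownames(df) <- NULL
    df[, c(req, "fraction_pool")]
}

#' Write a sample sheet
#' @param samples sample metadata \code{data.frame}.
#' @inheritParams writeCqTable
#' @return \code{path}, invisibly.
#' @export
writeSampleSheet <- function(samples, path, dialect = c("csv", "tsv")) {
    sep <- switch(match.arg(dialect), csv = ",", tsv = "\t")
    ## APOE tokens contain a comma, so CSV output must quote strings
    utils::write.table(samples, path, sep = sep, quote = identical(sep, ","),
                       row.names = FALSE, fileEncoding = "UTF-8", na = "")
    invisible(path)
}
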