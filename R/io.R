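#' Read an expression matrix from TSV/CSV
#'
#' Expected layout: header row `id, <t1>, <t2>, ...` where the remaining
#' header fields parse as strictly increasing numeric sampling times in
#' hours; one row per molecule; empty cells or `NA` mark missing values.
#' The delimiter is chosen by file extension (`.csv` = comma, otherwise tab)
#' unless `sep` overrides it.
#'
#' @param path File to read.
#' @param sep Field delimiter override.
#' @return List with `times` (numeric) and `x` (numeric matrix, molecule ids
#'   as row names).
#' @export
read_matrix <- function(path, sep = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(sep))
        sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    nf <- utils::count.fields(path, sep = sep, quote = "\"",
                              blank.lines.skip = TRUE)
    if (length(unique(nf)) > 1)
        stop("ragged rows in ", path, ": line(s) ",
             paste(which(nf != nf[1]), collapse = ", "),
             " have a different number of fields than line 1")
    df <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE,
                     na.strings = c("NA", ""), quote = "\"",
                     comment.char = "")
    if (ncol(df) < 5)
        stop("need an id column plus at least 4 timepoint columns")
    times <- suppressWarnings(as.numeric(names(df)[-1]))
    if (anyNA(times))
        stop("non-numeric time header field(s): ",
             paste(names(df)[-1][is.na(times)], collapse = ", "))
    if (any(diff(times) <= 0))
        stop("header times must be strictly increasing")
    ids <- as.character(df[[1]])
    dup <- duplicated(ids)
    if (any(dup))
        stop("duplicate molecule id(s) at data line(s) ",
             paste(which(dup), collapse = ", "), ": ",
             paste(unique(ids[dup]), collapse = ", "))
    x <- as.matrix(df[-1])
    if (!is.numeric(x)) {
        bad <- which(apply(df[-1], 2, function(col)
            any(!is.na(col) & is.na(suppressWarnings(as.numeric(col))))))
        stop("non-numeric expression value(s) in column(s) ",
             paste(names(df)[-1][bad], collapse = ", "))
    }
    rownames(x) <- ids
    colnames(x) <- times
    list(times = times, x = x)
}

# full-precision numeric formatting so written files round-trip exactly
fmt_num <- function(v) {
    out <- vapply(v, function(z) {
        if (is.na(z)) return(NA_character_)
        sprintf("%.17g", z)
    }, character(1))
    out
}

write_tsv <- function(df, path) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], fmt_num)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    ok <- tryCatch({
        write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                    na = "NA")
        TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
    invisible(path)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_matrix()]: `id` column, header of sampling times, full
#' float precision.
#'
#' @param x Numeric matrix, rows = molecules.
#' @param times Sampling times in hours.
#' @param path Output file.
#' @export
write_matrix <- function(x, times, path) {
    stopifnot(length(times) == ncol(x))
    ids <- rownames(x)
    if (is.null(ids)) ids <- paste0("row", seq_len(nrow(x)))
    df <- data.frame(id = ids, as.data.frame(x), check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df) <- c("id", as.character(times))
    write_tsv(df, path)
}

#' Write per-molecule scoring results as TSV
#'
#' Columns `id`, `n_used`, `mic`, `p`, `q`, `called`, written at full float
#' precision so a round trip reproduces the values exactly.
#'
#' @param results A [micop_call()] result.
#' @param path Output file.
#' @export
write_results <- function(results, path) {
    cols <- c("id", "n_used", "mic", "p", "q", "called")
    stopifnot(all(cols %in% names(results)))
    write_tsv(as.data.frame(results)[cols], path)
}

#' Write benchmark cells as long-format TSV
#'
#' One row per condition x seed with columns `n_cycles`, `interval`,
#' `noise_sd`, `decaying`, `seed`, `tp`, `fp`, `tn`, `fn`, `mcc`.
#'
#' @param cells A [benchmark_sweep()] result.
#' @param path Output file.
#' @export
write_benchmark <- function(cells, path) {
    cols <- c("n_cycles", "interval", "noise_sd", "decaying", "seed",
              "tp", "fp", "tn", "fn", "mcc")
    stopifnot(all(cols %in% names(cells)))
    write_tsv(as.data.frame(cells)[cols], path)
}
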