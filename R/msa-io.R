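#' Construct an MSA from gapped strings
#'
#' Normalizes case and gap synonyms ('.' becomes '-') and validates the
#' alignment invariants: equal row lengths, alphabet \{A,C,G,T,N,-\}, no
#' all-indel column, no all-indel row.
#'
#' @param rows character vector of gapped sequences, all the same length.
#' @param ids sequence identifiers; defaults to \code{seq1, seq2, ...}.
#' @param strict if TRUE (default) any violation is an error; if FALSE,
#'   all-indel columns are dropped with a warning and characters outside the
#'   alphabet are mapped to N with a warning.
#' @return a validated [MSA].
#' @examples
#' msaFromStrings(c("A-C", "AGC"))
#' @export
msaFromStrings <- function(rows, ids = NULL, strict = TRUE) {
    if (length(rows) < 1L) stop("empty input: no sequences")
    if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
    stopifnot(length(ids) == length(rows))
    widths <- nchar(rows)
    if (length(unique(widths)) != 1L)
        stop("length mismatch: records have unequal aligned lengths (",
             paste(unique(widths), collapse = ", "), ")")
    if (widths[1L] == 0L) stop("empty input: zero-length records")
    ch <- matrix(unlist(strsplit(toupper(rows), "", fixed = TRUE), use.names = FALSE),
                 nrow = length(rows), byrow = TRUE)
    ch[ch == "."] <- "-"
    bad <- !(ch %in% MSA_ALPHABET)
    if (any(bad)) {
        if (strict)
            stop("alphabet error: characters outside {A,C,G,T,N,-}: ",
                 paste(unique(ch[bad]), collapse = " "))
        warning(sum(bad), " characters outside the alphabet mapped to N")
        ch[bad] <- "N"
    }
    allGapCol <- colSums(ch != "-") == 0L
    if (any(allGapCol)) {
        if (strict)
            stop("degenerate column: column(s) ",
                 paste(which(allGapCol), collapse = ", "), " contain only indels")
        warning("dropping ", sum(allGapCol), " all-indel column(s)")
        ch <- ch[, !allGapCol, drop = FALSE]
        if (ncol(ch) == 0L) stop("degenerate input: all columns were indel-only")
    }
    if (any(rowSums(ch != "-") == 0L))
        stop("degenerate row: row(s) ",
             paste(which(rowSums(ch != "-") == 0L), collapse = ", "),
             " contain only indels")
    new("MSA", ids = as.character(ids), chars = ch)
}

#' Read an aligned FASTA file into an MSA
#'
#' All records must have equal aligned length. Characters are uppercased and
#' '.' is accepted as a gap synonym for '-'. Duplicate identifiers are
#' allowed; rows are addressed by index.
#'
#' @param path path to a FASTA file with >= 1 record.
#' @param strict passed to [msaFromStrings()]: errors on degenerate columns
#'   and foreign characters (TRUE, default) or repairs them with a warning.
#' @return a validated [MSA]; row i is the i-th record of the file.
#' @export
readMsa <- function(path, strict = TRUE) {
    recs <- Biostrings::readBStringSet(path)
    if (length(recs) == 0L) stop("empty input: no FASTA records in ", path)
    # keep only the first token of each FASTA header, like most tools do
    ids <- sub("\\s.*$", "", names(recs))
    msaFromStrings(as.character(recs), ids = ids, strict = strict)
}

#' Write an MSA (or a column window of one) as aligned FASTA
#'
#' @param msa an [MSA].
#' @param path output file path.
#' @param from,to optional global column window to write (defaults: all).
#' @return invisibly, \code{path}.
#' @export
writeMsa <- function(msa, path, from = 1L, to = ncol(msa)) {
    stopifnot(from >= 1L, to <= ncol(msa), from <= to)
    rows <- apply(msa@chars[, from:to, drop = FALSE], 1L, paste, collapse = "")
    x <- Biostrings::BStringSet(rows)
    names(x) <- msa@ids
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' Sequence identifiers of an MSA
#' @param msa an [MSA].
#' @return character vector of row identifiers.
#' @export
rowIds <- function(msa) msa@ids

#' Gapped row strings of an MSA
#' @param msa an [MSA].
#' @return character vector of aligned (gapped) row strings.
#' @export
msaRows <- function(msa) apply(msa@chars, 1L, paste, collapse = "")

#' The character matrix of an MSA
#' @param msa an [MSA].
#' @return the m x n single-character matrix.
#' @export
msaChars <- function(msa) msa@chars

#' Ungapped sequence of one MSA row
#'
#' @param msa an [MSA].
#' @param row 1-based row index.
#' @return the row string with all '-' removed (never empty).
#' @examples
#' ungapped(runningExample(), 1)  # "AACCGA"
#' @export
ungapped <- function(msa, row) {
    if (length(row) != 1L || is.na(row) || row < 1L || row > nrow(msa))
        stop("row index out of range")
    v <- msa@chars[row, ]
    paste(v[v != "-"], collapse = "")
}

#' Gapped substring of one MSA row
#'
#' 1-based, closed interval: \code{msaSlice(msa, r, b, e)} is the row's
#' characters at columns b..e inclusive, gaps retained.
#'
#' @param msa an [MSA].
#' @param row 1-based row index.
#' @param b,e column interval, 1 <= b <= e <= n.
#' @return character scalar of length e - b + 1.
#' @export
msaSlice <- function(msa, row, b, e) {
    if (row < 1L || row > nrow(msa)) stop("row index out of range")
    if (b < 1L || e > ncol(msa) || b > e) stop("column interval out of range")
    paste(msa@chars[row, b:e], collapse = "")
}
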