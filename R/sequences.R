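#' Normalize an RNA sequence string
#'
#' Uppercases, maps T to U and validates that only A, C, G, U remain.
#' Ambiguity codes are deliberately rejected: every downstream computation
#' (folding, kernel scoring) is defined on the four-letter alphabet only.
#'
#' @param x character vector of sequences (names preserved).
#' @param what label used in error messages (e.g. a record id).
#' @return character vector of validated sequences over A, C, G, U.
#' @examples
#' normalizeRna("gattaca")
#' @export
normalizeRna <- function(x, what = names(x)) {
    out <- chartr("acgut", "ACGUU", as.character(x))
    out <- chartr("T", "U", out)
    bad <- grep("[^ACGU]", out)
    if (length(bad)) {
        id <- if (!is.null(what)) what[bad[1]] else paste("element", bad[1])
        ch <- regmatches(out[bad[1]], regexpr("[^ACGU]", out[bad[1]]))
        stop("invalid residue '", ch, "' in sequence ", id,
             " (only A, C, G, U / T accepted)")
    }
    names(out) <- names(x)
    out
}

#' Read RNA sequences from a FASTA file
#'
#' Multi-record, wrapped-line FASTA via Biostrings; records are normalized
#' with [normalizeRna()] (T mapped to U, anything else an error naming the
#' record).
#'
#' @param path FASTA file.
#' @return named character vector of RNA sequences.
#' @export
readFastaRNA <- function(path) {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("no sequences in FASTA file ", path)
    ids <- sub("\\s.*$", "", names(set))
    if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path)
    seqs <- as.character(set)
    names(seqs) <- ids
    normalizeRna(seqs)
}

#' Write RNA sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file (written atomically).
#' @return invisibly, the path.
#' @export
writeFastaRNA <- function(seqs, path) {
    seqs <- normalizeRna(seqs)
    set <- Biostrings::RNAStringSet(seqs)
    writeAtomic(path, function(tmp) Biostrings::writeXStringSet(set, tmp))
}

# encode A/C/G/U as 0..3 for the compiled folding routine
encodeRna <- function(seq) {
    match(strsplit(seq, "")[[1]], RNA_ALPHABET) - 1L
}
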