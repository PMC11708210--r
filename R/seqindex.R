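## Sequence I/O, the genome match index, matching statistics, and greedy
## factorization into maximal-match factors.
##
## Conventions: sequences are named character vectors over {A,C,G,T,N};
## all coordinates are 0-based half-open; conversions to 1-based happen
## only at I/O boundaries (FASTA/GFF3/BED writers and readers).

.BASE_CODES <- local({
    lut <- integer(256)
    lut[utf8ToInt("A")] <- 1L
    lut[utf8ToInt("C")] <- 2L
    lut[utf8ToInt("G")] <- 3L
    lut[utf8ToInt("T")] <- 4L
    lut
})

## Encode one sequence string as integers: A,C,G,T = 1..4, anything else 0.
encode_dna <- function(x) {
    .BASE_CODES[utf8ToInt(x)]
}

decode_dna <- function(codes) {
    intToUtf8(utf8ToInt("NACGT")[codes + 1L])
}

## Uppercase and map everything outside {A,C,G,T,N} to N.
normalize_residues <- function(x) {
    out <- gsub("[^ACGTN]", "N", toupper(x), perl = TRUE)
    names(out) <- names(x)
    out
}

#' Read a genome FASTA file
#'
#' Reads a (possibly multi-record, line-wrapped) FASTA file and normalizes
#' residues: lowercase is uppercased and any character outside
#' \code{{A,C,G,T,N}} becomes \code{N}.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, one element per record, in file order.
#' @export
load_fasta <- function(path) {
    if (!file.exists(path)) stop("FASTA file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    nonblank <- which(nzchar(trimws(lines)))
    if (length(nonblank) == 0L) stop("input-format error: empty FASTA file: ", path)
    if (!startsWith(trimws(lines[nonblank[1]]), ">"))
        stop("input-format error in ", path, " at line ", nonblank[1],
             ": expected a FASTA header ('>'), got: ", lines[nonblank[1]])
    bad <- nonblank[!grepl("^>", lines[nonblank]) &
                    !grepl("^[A-Za-z.*-]+$", lines[nonblank])]
    if (length(bad) > 0L)
        stop("input-format error in ", path, " at line ", bad[1],
             ": not FASTA sequence or header: ", lines[bad[1]])
    seqs <- Biostrings::readBStringSet(path)
    if (any(!nzchar(names(seqs))))
        stop("input-format error in ", path, ": malformed (empty) FASTA header")
    out <- normalize_residues(as.character(seqs))
    names(out) <- sub("\\s.*$", "", names(seqs))
    out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
    invisible(path)
}

#' Build the match index over a genome
#'
#' Prepares the index used for all maximal-match queries: the concatenation
#' of every chromosome and its reverse complement, with unique separator
#' sentinels so that no match crosses a chromosome boundary, a strand
#' boundary, or an N run.
#'
#' @param seqs Named character vector of chromosome sequences (as returned
#'   by [load_fasta()]), or anything coercible via `as.character()`.
#' @return An object of class `match_index` with elements `ids`, `lengths`,
#'   `enc` (integer encodings), `total_length`, and `composition` (relative
#'   A,C,G,T frequencies over non-N residues).
#' @export
build_index <- function(seqs) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
        names(seqs) <- paste0("seq", seq_along(seqs))
    if (length(seqs) == 0L) stop("no sequences given")
    seqs <- normalize_residues(seqs)
    enc <- lapply(seqs, encode_dna)
    counts <- integer(4)
    for (e in enc) {
        tab <- tabulate(e, nbins = 4L)
        counts <- counts + tab
    }
    if (sum(counts) == 0L)
        stop("degenerate input: all residues are N; cannot build a match index")
    comp <- counts / sum(counts)
    names(comp) <- c("A", "C", "G", "T")
    structure(
        list(ids = names(seqs),
             lengths = setNames(vapply(enc, length, 0L), names(seqs)),
             enc = enc,
             total_length = sum(lengths(enc)),
             composition = comp),
        class = "match_index")
}

#' @export
print.match_index <- function(x, ...) {
    cat("match_index:", length(x$ids), "sequence(s),",
        x$total_length, "bp total\n")
    cat("composition:",
        paste(sprintf("%s=%.3f", names(x$composition), x$composition),
              collapse = " "), "\n")
    invisible(x)
}

#' Matching statistics for every genome position
#'
#' For each position i of each chromosome, computes MS\[i\]: the length of the
#' longest prefix of the suffix starting at i that occurs at least once at a
#' different position in the genome (forward strand) or anywhere in the
#' reverse-complemented genome. Matches never extend across chromosome
#' boundaries or N runs, and N matches nothing, so MS is 0 at N positions.
#'
#' @param index A `match_index` from [build_index()].
#' @return A named list of integer vectors, one per chromosome.
#' @export
matching_statistics <- function(index) {
    stopifnot(inherits(index, "match_index"))
    .Call_matching_stats(index$enc)
}

#' Greedy factorization of a region into maximal-match factors
#'
#' Decomposes the interval `[from, to)` left to right: the factor starting at
#' position p spans `max(MS[p], 1)` positions (so a position matching nothing
#' is its own factor, guaranteeing that the factors tile the region), and the
#' next factor starts immediately after it. The observed factor count mo of a
#' sliding window is the number of these factors intersecting it.
#'
#' @param ms Integer vector of matching statistics for one chromosome.
#' @param from,to 0-based half-open bounds of the region to factorize;
#'   defaults to the whole chromosome.
#' @return A data.frame with columns `start` and `length` (0-based).
#' @export
factorize <- function(ms, from = 0L, to = length(ms)) {
    stopifnot(from >= 0L, to <= length(ms))
    if (from >= to) return(data.frame(start = integer(0), length = integer(0)))
    as.data.frame(.Call_factorize(as.integer(ms), as.integer(from), as.integer(to)))
}

#' Count factors intersecting each window
#'
#' A factor intersects a window if their spans share at least 1 bp. Factors
#' are the single whole-chromosome greedy parse, so overlapping windows count
#' against the same factorization.
#'
#' @param factors data.frame from [factorize()] (whole chromosome).
#' @param wstart,wend Integer vectors of window bounds (0-based half-open).
#' @return Integer vector of factor counts (mo), one per window.
#' @keywords internal
count_factors_in_windows <- function(factors, wstart, wend) {
    fs <- factors$start
    fe <- factors$start + factors$length
    ## factors with start < wend minus factors with end <= wstart
    findInterval(wend - 1L, fs) - findInterval(wstart, fe)
}

reverse_complement <- function(x) {
    out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
    names(out) <- names(x)
    out
}
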