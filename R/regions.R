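## Merge unique windows into unique regions (URs) and BED3 I/O.

#' Extract unique regions from classified windows
#'
#' Takes the union of all windows flagged unique, merges overlapping and
#' book-ended windows into maximal runs, and discards merged intervals
#' shorter than `min_length` ("at least" semantics: an interval exactly
#' `min_length` long is kept).
#'
#' @param profile A `cm_profile` with a logical `unique` column
#'   (see [classify_unique()]).
#' @param min_length Minimum UR length in bp (default 10000).
#' @return A data.frame (`ur_set`) with columns chrom, start, end (0-based
#'   half-open), sorted by (chrom, start), pairwise non-overlapping. The
#'   window configuration, alpha, and min_length travel as attributes.
#' @export
extract_unique_regions <- function(profile, min_length = 10000L) {
    stopifnot(!is.null(profile$unique))
    u <- profile[profile$unique, , drop = FALSE]
    if (nrow(u) == 0L) {
        out <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0))
    } else {
        merged <- lapply(split(u, u$chrom), function(d) {
            ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L,
                                                   end = d$end))
            data.frame(chrom = d$chrom[1],
                       start = IRanges::start(ir) - 1L,
                       end = IRanges::end(ir))
        })
        out <- do.call(rbind, merged)
        out <- out[out$end - out$start >= min_length, , drop = FALSE]
        out <- out[order(out$chrom, out$start), , drop = FALSE]
    }
    rownames(out) <- NULL
    attr(out, "window") <- attr(profile, "window")
    attr(out, "step") <- attr(profile, "step")
    attr(out, "alpha") <- attr(profile, "alpha")
    attr(out, "min_length") <- as.integer(min_length)
    class(out) <- c("ur_set", "data.frame")
    out
}

#' Read a BED3 file of genomic intervals
#'
#' Standard 3-column BED: chrom, start, end, 0-based half-open. Lines
#' starting with `#`, `track`, or `browser` are ignored.
#'
#' @param path Path to a BED file.
#' @return A data.frame with columns chrom, start, end.
#' @export
read_bed <- function(path) {
    if (!file.exists(path)) stop("BED file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
    lineno <- which(keep)
    if (length(lineno) == 0L)
        return(data.frame(chrom = character(0), start = integer(0),
                          end = integer(0)))
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("BED format error at line ", lineno[which(nf < 3L)[1]],
             ": fewer than 3 tab-separated fields")
    chrom <- vapply(fields, `[`, "", 1L)
    start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
    end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
    bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
    if (length(bad) > 0L)
        stop("BED format error at line ", lineno[bad[1]],
             ": invalid interval (need 0 <= start < end): ", lines[keep][bad[1]])
    data.frame(chrom = chrom, start = start, end = end)
}

#' Write intervals as BED3
#'
#' Provenance attributes (window, step, alpha, min_length), when present,
#' are written as `#` header comments and ignored on read.
#'
#' @param intervals A data.frame with chrom, start, end (e.g. a `ur_set`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
    con <- file(path, "w")
    on.exit(close(con))
    prov <- Filter(Negate(is.null),
                   attributes(intervals)[c("window", "step", "alpha",
                                           "min_length")])
    for (k in names(prov))
        writeLines(sprintf("# %s=%s", k, format(prov[[k]])), con)
    if (nrow(intervals) > 0L)
        writeLines(sprintf("%s\t%d\t%d", intervals$chrom,
                           as.integer(intervals$start),
                           as.integer(intervals$end)), con)
    invisible(path)
}
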