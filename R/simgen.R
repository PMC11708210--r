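## Sequence simulation: i.i.d. random sequences, point-mutation simulation,
## repeat planting, and the detection-decay experiment that measures how the
## flagging of planted repeat copies degrades with their divergence.

.BASES <- c("A", "C", "G", "T")

#' Simulate an i.i.d. random DNA sequence
#'
#' @param length Sequence length in bp.
#' @param composition Relative A,C,G,T frequencies (default uniform).
#' @param seed Integer seed; the same seed gives the same sequence. `NULL`
#'   uses (and advances) the current RNG state.
#' @return A single character string.
#' @export
random_sequence <- function(length, composition = rep(0.25, 4), seed = NULL) {
    stopifnot(length >= 1, length(composition) == 4, all(composition >= 0),
              sum(composition) > 0)
    if (!is.null(seed)) set.seed(seed)
    paste(sample(.BASES, length, replace = TRUE,
                 prob = composition / sum(composition)), collapse = "")
}

#' Apply random point substitutions to a sequence
#'
#' Each non-N site is independently substituted with probability `rate`; a
#' substituted site receives one of its 3 alternative bases uniformly, so a
#' mutated site never retains its original base. N sites are untouched and
#' the length is unchanged (substitutions only, no indels).
#'
#' @param seq A character string over \code{{A,C,G,T,N}}.
#' @param rate Per-site substitution probability in \code{[0, 1]}.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return The mutated sequence (character string).
#' @export
mutate_sequence <- function(seq, rate, seed = NULL) {
    stopifnot(rate >= 0, rate <= 1)
    if (!is.null(seed)) set.seed(seed)
    if (rate == 0) return(seq)
    enc <- encode_dna(seq)
    hit <- which(runif(length(enc)) < rate & enc > 0L)
    if (length(hit) > 0L) {
        ## shift by 1..3 within the 4-letter alphabet: always a different base
        enc[hit] <- (enc[hit] - 1L +
                     sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L
    }
    decode_dna(enc)
}

#' Plant identical repeat copies in a random background
#'
#' Generates a random repeat unit and inserts `copies` identical copies at
#' random positions of a random background sequence (insertion, so copies
#' never overlap and the composite is `background_length + copies *
#' repeat_length` bp long).
#'
#' @param background_length Background length in bp (default 25000).
#' @param repeat_length Repeat unit length in bp (default 3700).
#' @param copies Number of identical copies (default 2).
#' @param composition Base composition of background and repeat unit.
#' @param seed Integer seed.
#' @return A list: `seq` (composite sequence), `copies` (data.frame with the
#'   0-based half-open coordinates of every planted copy), `unit` (the
#'   repeat unit).
#' @export
plant_repeats <- function(background_length = 25000L, repeat_length = 3700L,
                          copies = 2L, composition = rep(0.25, 4),
                          seed = NULL) {
    stopifnot(copies >= 1L, repeat_length >= 1L,
              copies * repeat_length < background_length)
    if (!is.null(seed)) set.seed(seed)
    bg <- random_sequence(background_length, composition, seed = NULL)
    unit <- random_sequence(repeat_length, composition, seed = NULL)
    at <- sort(sample.int(background_length + 1L, copies) - 1L)
    pieces <- character(0)
    coords <- integer(copies)
    prev <- 0L
    for (k in seq_len(copies)) {
        pieces <- c(pieces, substr(bg, prev + 1L, at[k]), unit)
        coords[k] <- at[k] + (k - 1L) * repeat_length
        prev <- at[k]
    }
    pieces <- c(pieces, substr(bg, prev + 1L, background_length))
    list(seq = paste(pieces, collapse = ""),
         copies = data.frame(start = coords, end = coords + repeat_length),
         unit = unit)
}

#' Detection decay of planted repeats as a function of divergence
#'
#' The sensitivity experiment: two (by default) identical copies of a repeat
#' unit are planted in a random background; every copy is then independently
#' mutated at the nominal per-site substitution rate, mirroring a point
#' mutation process acting on each insertion after duplication (the methods
#' vignette discusses this choice and the alternative single-copy regime).
#' The composite is scored with non-overlapping windows against a null
#' calibrated for the composite length, and the percentage of repeat-copy
#' nucleotides covered by at least one window NOT classified unique (i.e.
#' detected as repetitive) is recorded.
#'
#' @param rates Increasing grid of per-site substitution rates
#'   (default 0 to 0.6 by 0.05).
#' @param replicates Replicates per rate (default 20).
#' @param window Window length in bp (default 1000); the stride equals the
#'   window (non-overlapping windows).
#' @param alpha Level of the uniqueness test (default 0.05).
#' @param background_length,repeat_length,copies Composite design, as in
#'   [plant_repeats()].
#' @param null_replicates Random replicates for the null calibration.
#' @param mutate_all_copies If `TRUE` (the default), every copy is mutated
#'   independently at the nominal rate; if `FALSE`, only one copy is mutated
#'   so that the rate equals the expected pairwise divergence between the
#'   copies.
#' @param seed Integer seed.
#' @return A data.frame (rate, mean_detected_pct, sd, n) with attribute
#'   `breakpoint`: the smallest grid rate whose mean detected percentage
#'   falls below 50.
#' @export
detection_decay <- function(rates = seq(0, 0.6, by = 0.05), replicates = 20L,
                            window = 1000L, alpha = 0.05,
                            background_length = 25000L,
                            repeat_length = 3700L, copies = 2L,
                            null_replicates = 20L,
                            mutate_all_copies = TRUE, seed = 1L) {
    stopifnot(length(rates) >= 1L, !is.unsorted(rates))
    total_len <- background_length + copies * repeat_length
    null <- calibrate_null(total_len, window = window, step = window,
                           replicates = null_replicates, seed = seed)
    detected <- matrix(NA_real_, nrow = replicates, ncol = length(rates))
    for (j in seq_along(rates)) {
        for (r in seq_len(replicates)) {
            set.seed(seed + 1000L * j + r)
            pl <- plant_repeats(background_length, repeat_length, copies,
                                seed = NULL)
            seq <- pl$seq
            which_mut <- if (mutate_all_copies) seq_len(copies) else
                seq_len(copies)[-1]
            for (k in which_mut) {
                s0 <- pl$copies$start[k]
                e0 <- pl$copies$end[k]
                mut <- mutate_sequence(substr(seq, s0 + 1L, e0), rates[j],
                                       seed = NULL)
                seq <- paste0(substr(seq, 1L, s0), mut,
                              substr(seq, e0 + 1L, nchar(seq)))
            }
            idx <- build_index(c(composite = seq))
            prof <- window_complexity(idx, null, step = window)
            prof <- classify_unique(prof, null, alpha = alpha)
            detected[r, j] <- .copy_detected_pct(prof, pl$copies)
        }
    }
    out <- data.frame(rate = rates,
                      mean_detected_pct = colMeans(detected),
                      sd = apply(detected, 2, sd),
                      n = replicates)
    below <- which(out$mean_detected_pct < 50)
    attr(out, "breakpoint") <- if (length(below) > 0L)
        rates[below[1]] else NA_real_
    out
}

## % of planted-copy nucleotides covered by >= 1 window not classified unique.
.copy_detected_pct <- function(profile, copies) {
    nonuniq <- profile[!profile$unique, , drop = FALSE]
    if (nrow(nonuniq) == 0L) return(0)
    cover <- IRanges::reduce(IRanges::IRanges(start = nonuniq$start + 1L,
                                              end = nonuniq$end))
    cp <- IRanges::IRanges(start = copies$start + 1L, end = copies$end)
    hit <- sum(IRanges::width(IRanges::intersect(cover, cp)))
    100 * hit / sum(IRanges::width(cp))
}

#' Write a detection-decay curve as TSV
#'
#' @param curve Output of [detection_decay()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decay_curve <- function(curve, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# detection-decay curve; breakpoint=%s",
                       format(attr(curve, "breakpoint"))), con)
    write.table(curve, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
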