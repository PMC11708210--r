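## Sliding-window match complexity Cm, Monte Carlo calibration of its null
## distribution on random sequences, and classification of windows as unique.
##
## Cm = (mo - 1) / (me - 1), where mo is the observed number of maximal-match
## factors intersecting a window and me its expectation on random sequence of
## matched length and composition. The subtraction of 1 pins Cm to 0 for a
## window spanned by a single factor (a perfect repeat) and to an expectation
## of 1 on random sequence.

## Window start positions: advance by `step`, with the last window flush with
## the chromosome end. Empty when the chromosome is shorter than the window.
window_starts <- function(chrom_length, window, step) {
    if (chrom_length < window) return(integer(0))
    s <- seq.int(0L, chrom_length - window, by = step)
    if (s[length(s)] != chrom_length - window)
        s <- c(s, chrom_length - window)
    as.integer(s)
}

#' Calibrate the null model of match complexity
#'
#' Generates `replicates` i.i.d. random sequences of the stated length and
#' composition, indexes each (both strands), factorizes, and counts factors
#' per sliding window. The expectation `me` is the mean factor count over all
#' null windows, and the empirical null distribution of Cm is
#' `(mo - 1) / (me - 1)` over the same windows.
#'
#' @param total_length Length (bp) of each random replicate; should match the
#'   genome to be analyzed, since chance-match lengths grow with genome size.
#' @param composition Relative A,C,G,T frequencies (need not be normalized).
#' @param window,step Window length and stride in bp.
#' @param replicates Number of independent random replicates (default 20).
#' @param seed Integer seed; identical seeds give identical null models.
#' @return An object of class `cm_null`: list with `me`, `null_cm` (empirical
#'   null sample of Cm), and the calibration metadata.
#' @export
calibrate_null <- function(total_length, composition = rep(0.25, 4),
                           window, step = max(1L, window %/% 10L),
                           replicates = 20L, seed = 1L) {
    stopifnot(replicates >= 1L, total_length >= window, window >= 2L,
              step >= 1L, step <= window)
    composition <- composition / sum(composition)
    mo <- vector("list", replicates)
    for (r in seq_len(replicates)) {
        seq_r <- random_sequence(total_length, composition,
                                 seed = seed + r - 1L)
        idx <- build_index(c(null_rep = seq_r))
        ms <- matching_statistics(idx)[[1]]
        fac <- factorize(ms)
        ws <- window_starts(total_length, window, step)
        mo[[r]] <- count_factors_in_windows(fac, ws, ws + window)
    }
    mo <- unlist(mo)
    me <- mean(mo)
    if (me <= 1)
        stop("calibration error: me = ", format(me), " <= 1; the window (",
             window, " bp) is too short relative to the genome length -- ",
             "use a larger window")
    structure(
        list(me = me,
             null_cm = (mo - 1) / (me - 1),
             window = as.integer(window),
             step = as.integer(step),
             replicates = as.integer(replicates),
             seed = as.integer(seed),
             total_length = as.integer(total_length),
             composition = composition),
        class = "cm_null")
}

#' @export
print.cm_null <- function(x, ...) {
    cat(sprintf("cm_null: me = %.3f (window %d bp, step %d bp, %d x %d bp replicates)\n",
                x$me, x$window, x$step, x$replicates, x$total_length))
    invisible(x)
}

#' Sliding-window match complexity profile
#'
#' Computes one row per window position on every chromosome: the observed
#' factor count `mo` and `cm = (mo - 1) / (me - 1)` against the calibrated
#' null. Windows with more than `max_n_frac` N residues get a missing Cm
#' (assembly gaps are not repeats). Chromosomes shorter than the window
#' contribute no rows.
#'
#' @param index A `match_index`.
#' @param null A `cm_null` calibrated with the same window length.
#' @param step Window stride in bp (default: the null's calibration stride).
#' @param ms Precomputed [matching_statistics()] of `index`, if available.
#' @param max_n_frac Maximum tolerated fraction of N per window (default 0.5).
#' @return A data.frame (`cm_profile`) with columns chrom, start, end, mo, cm.
#' @export
window_complexity <- function(index, null, step = null$step,
                              ms = matching_statistics(index),
                              max_n_frac = 0.5) {
    stopifnot(inherits(index, "match_index"), inherits(null, "cm_null"))
    window <- null$window
    rows <- lapply(seq_along(index$ids), function(i) {
        len <- index$lengths[[i]]
        ws <- window_starts(len, window, step)
        if (length(ws) == 0L)
            return(data.frame(chrom = character(0), start = integer(0),
                              end = integer(0), mo = integer(0),
                              cm = numeric(0)))
        fac <- factorize(ms[[i]])
        mo <- count_factors_in_windows(fac, ws, ws + window)
        cm <- (mo - 1) / (null$me - 1)
        n_cum <- c(0L, cumsum(index$enc[[i]] == 0L))
        n_in_win <- n_cum[ws + window + 1L] - n_cum[ws + 1L]
        cm[n_in_win > max_n_frac * window] <- NA_real_
        data.frame(chrom = index$ids[i], start = ws, end = ws + window,
                   mo = mo, cm = cm)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "window") <- window
    attr(out, "step") <- as.integer(step)
    class(out) <- c("cm_profile", "data.frame")
    out
}

#' Flag windows indistinguishable from random sequence
#'
#' One-sided lower test: a window is unique iff its Cm is at least the
#' `alpha`-quantile of the empirical null Cm distribution (low Cm means
#' repetitive). The threshold comparison is inclusive; windows with missing
#' Cm (N-rich) are never unique.
#'
#' @param profile A `cm_profile` from [window_complexity()].
#' @param null The `cm_null` used to build the profile.
#' @param alpha Test level in (0, 0.5]; default 0.05.
#' @return The profile with an added logical column `unique`.
#' @export
classify_unique <- function(profile, null, alpha = 0.05) {
    stopifnot(inherits(null, "cm_null"), alpha > 0, alpha <= 0.5)
    thr <- unname(quantile(null$null_cm, alpha, type = 7))
    ## inclusive at the threshold, robust to interpolation round-off
    profile$unique <- !is.na(profile$cm) & profile$cm - thr > -1e-9
    attr(profile, "alpha") <- alpha
    attr(profile, "cm_threshold") <- thr
    profile
}

#' Write / read a complexity profile (TSV, 0-based half-open)
#'
#' @param profile A `cm_profile`.
#' @param path File path.
#' @return `path` / the profile.
#' @export
write_profile <- function(profile, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# match-complexity profile; window=%d step=%d; 0-based half-open",
                       attr(profile, "window"), attr(profile, "step")), con)
    cols <- intersect(c("chrom", "start", "end", "mo", "cm", "unique"),
                      names(profile))
    write.table(profile[cols], con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
    out <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    class(out) <- c("cm_profile", "data.frame")
    out
}

#' Serialize / restore a null model as a key-value sidecar file
#'
#' @param null A `cm_null`.
#' @param path File path.
#' @return `path` / the `cm_null`.
#' @export
write_null_model <- function(null, path) {
    lines <- c(
        sprintf("me\t%.17g", null$me),
        sprintf("window\t%d", null$window),
        sprintf("step\t%d", null$step),
        sprintf("replicates\t%d", null$replicates),
        sprintf("seed\t%d", null$seed),
        sprintf("total_length\t%d", null$total_length),
        sprintf("composition\t%s", paste(format(null$composition, digits = 17),
                                         collapse = ",")),
        sprintf("null_cm\t%s", paste(format(null$null_cm, digits = 17),
                                     collapse = ",")))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname write_null_model
#' @export
read_null_model <- function(path) {
    lines <- readLines(path)
    kv <- strsplit(lines, "\t", fixed = TRUE)
    vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    structure(
        list(me = as.numeric(vals[["me"]]),
             null_cm = as.numeric(strsplit(vals[["null_cm"]], ",")[[1]]),
             window = as.integer(vals[["window"]]),
             step = as.integer(vals[["step"]]),
             replicates = as.integer(vals[["replicates"]]),
             seed = as.integer(vals[["seed"]]),
             total_length = as.integer(vals[["total_length"]]),
             composition = as.numeric(strsplit(vals[["composition"]], ",")[[1]])),
        class = "cm_null")
}
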