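## GO-term enrichment of genes annotated to a set of genomic intervals:
## per-term gene counts, interval shuffling across the genome, and the
## Monte Carlo test with Bonferroni correction.

#' Count distinct genes per GO term
#'
#' @param genes Character vector of gene ids (duplicates count once).
#' @param table A `gene2go` data.frame.
#' @return Named integer vector of distinct-gene counts per GO id, with
#'   attribute `total_genes` (number of distinct input genes).
#' @export
count_genes_per_term <- function(genes, table) {
    genes <- unique(genes)
    sub <- unique(table[table$gene_id %in% genes, c("gene_id", "go_id")])
    counts <- table(sub$go_id)
    out <- setNames(as.integer(counts), names(counts))
    attr(out, "total_genes") <- length(genes)
    out
}

#' Shuffle intervals uniformly across the genome
#'
#' Each interval is re-placed independently: a chromosome is chosen with
#' probability proportional to its number of valid start positions for the
#' interval's length, then a valid start is chosen uniformly. Lengths are
#' preserved exactly; placed intervals may overlap one another.
#'
#' @param intervals data.frame with chrom, start, end.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A data.frame of the same shape with new placements.
#' @export
shuffle_intervals <- function(intervals, chrom_lengths, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(intervals)
    if (n == 0L) return(intervals)
    len <- intervals$end - intervals$start
    chroms <- names(chrom_lengths)
    out_chrom <- character(n)
    out_start <- integer(n)
    for (i in seq_len(n)) {
        slots <- pmax(chrom_lengths - len[i] + 1L, 0L)
        if (sum(slots) == 0L)
            stop("placement error: interval of length ", len[i],
                 " (", intervals$chrom[i], ":", intervals$start[i], "-",
                 intervals$end[i], ") is longer than every chromosome")
        c_i <- sample.int(length(chroms), 1L, prob = slots)
        out_chrom[i] <- chroms[c_i]
        out_start[i] <- sample.int(slots[c_i], 1L) - 1L
    }
    data.frame(chrom = out_chrom, start = out_start,
               end = out_start + len, stringsAsFactors = FALSE)
}

## Precompute per-chromosome sorted feature tables for fast repeated overlap
## queries: for features sorted by start, a feature [fs, fe) overlaps some
## query iff among queries starting before fe there is one ending after fs.
.overlap_engine <- function(feats) {
    by_chrom <- split(seq_len(nrow(feats)), feats$chrom)
    lapply(by_chrom, function(idx) {
        list(idx = idx, start = feats$start[idx], end = feats$end[idx])
    })
}

## Returns indices (into the original feature table) of features overlapped
## by >= 1 query interval. Vectorized over features per chromosome.
.overlap_hits <- function(engine, q_chrom, q_start, q_end) {
    hits <- integer(0)
    for (ch in unique(q_chrom)) {
        e <- engine[[ch]]
        if (is.null(e)) next
        sel <- q_chrom == ch
        qs <- q_start[sel]
        qe <- q_end[sel]
        o <- order(qs)
        qs <- qs[o]
        cummax_qe <- cummax(qe[o])
        k <- findInterval(e$end - 1L, qs)  # queries with qs < feature end
        hit <- k > 0L & cummax_qe[pmax(k, 1L)] > e$start
        hits <- c(hits, e$idx[hit])
    }
    hits
}

#' Monte Carlo GO-term enrichment test by interval shuffling
#'
#' Counts, per GO term, the genes whose promoters (or transcripts) intersect
#' the observed intervals; then repeatedly shuffles the intervals across the
#' genome, re-annotates, and re-counts. The raw p-value of a term is the
#' add-one estimator `(1 + k) / (1 + iterations)`, where k is the number of
#' iterations with a null count at least equal to the observed count (so a
#' p-value is never exactly 0). Only terms with at least `min_genes` genes
#' genome-wide (in the whole gene2go table, within `category`) are tested;
#' p-values are Bonferroni-corrected by multiplication with the number of
#' tests and terms with corrected p <= `alpha` are flagged enriched.
#'
#' @param intervals A `ur_set` (or chrom/start/end data.frame).
#' @param models A `gene_models` object.
#' @param table A `gene2go` data.frame.
#' @param mode `"promoter"` or `"transcript"` (which feature must intersect).
#' @param iterations Number of shuffling iterations (default 10000; genome
#'   studies typically use 1e6).
#' @param min_genes Genome-wide minimum gene count per tested term
#'   (default 10).
#' @param alpha Significance level on the corrected p-value (default 0.01).
#' @param category GO namespace tested (default biological_process).
#' @param upstream Promoter length in bp.
#' @param seed Integer seed.
#' @return A data.frame (`enrichment_result`) with one row per tested term:
#'   go_id, go_term, category, observed_count, null_mean, enrichment_ratio,
#'   p_raw, p_bonferroni, enriched; test metadata in `attr(, "metadata")`.
#' @export
mc_enrichment <- function(intervals, models, table,
                          mode = c("promoter", "transcript"),
                          iterations = 10000L, min_genes = 10L,
                          alpha = 0.01, category = "biological_process",
                          upstream = 2000L, seed = 1L) {
    mode <- match.arg(mode)
    stopifnot(iterations >= 1L)
    .check_chroms(intervals, models)
    tab <- table[table$category == category, , drop = FALSE]
    genome_counts <- count_genes_per_term(unique(tab$gene_id), tab)
    tested <- names(genome_counts)[genome_counts >= min_genes]
    meta <- list(mode = mode, iterations = as.integer(iterations),
                 min_genes = as.integer(min_genes), alpha = alpha,
                 category = category, seed = as.integer(seed),
                 number_of_tests = length(tested))
    if (length(tested) == 0L) {
        warning("no GO term has >= ", min_genes, " genes; empty result")
        out <- data.frame(go_id = character(0), go_term = character(0),
                          category = character(0),
                          observed_count = integer(0), null_mean = numeric(0),
                          enrichment_ratio = numeric(0), p_raw = numeric(0),
                          p_bonferroni = numeric(0), enriched = logical(0))
        attr(out, "metadata") <- meta
        class(out) <- c("enrichment_result", "data.frame")
        return(out)
    }
    n_terms <- length(tested)
    term_names <- setNames(tab$go_term[match(tested, tab$go_id)], tested)

    feats <- if (mode == "promoter") promoter_set(models, upstream)
             else models$transcripts[c("gene_id", "chrom", "start", "end")]
    ## gene -> tested-term indices, features -> gene indices
    gene_ids <- unique(feats$gene_id)
    sub <- tab[tab$go_id %in% tested & tab$gene_id %in% gene_ids, ,
               drop = FALSE]
    gene2terms <- split(match(sub$go_id, tested), match(sub$gene_id, gene_ids))
    feat_gene <- match(feats$gene_id, gene_ids)
    engine <- .overlap_engine(feats)

    count_terms <- function(chrom, start, end) {
        f <- .overlap_hits(engine, chrom, start, end)
        g <- unique(feat_gene[f])
        idx <- unlist(gene2terms[as.character(g)], use.names = FALSE)
        tabulate(if (is.null(idx)) integer(0) else idx, nbins = n_terms)
    }

    observed <- count_terms(intervals$chrom, intervals$start, intervals$end)
    set.seed(seed)
    ge <- integer(n_terms)
    null_sum <- numeric(n_terms)
    for (it in seq_len(iterations)) {
        sh <- shuffle_intervals(intervals, models$chrom_lengths, seed = NULL)
        cnt <- count_terms(sh$chrom, sh$start, sh$end)
        ge <- ge + (cnt >= observed)
        null_sum <- null_sum + cnt
    }
    null_mean <- null_sum / iterations
    p_raw <- (1 + ge) / (1 + iterations)
    p_bonf <- pmin(1, p_raw * n_terms)
    out <- data.frame(go_id = tested,
                      go_term = unname(term_names),
                      category = category,
                      observed_count = observed,
                      null_mean = null_mean,
                      enrichment_ratio = ifelse(null_mean > 0,
                                                observed / null_mean,
                                                NA_real_),
                      p_raw = p_raw,
                      p_bonferroni = p_bonf,
                      enriched = p_bonf <= alpha,
                      stringsAsFactors = FALSE)
    out <- out[order(out$p_raw, -out$observed_count), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "metadata") <- meta
    class(out) <- c("enrichment_result", "data.frame")
    out
}

#' Enrichment ratio of tested terms
#'
#' `observed_count / null_mean`; missing where the null mean is 0.
#'
#' @param result An `enrichment_result`.
#' @return Named numeric vector of ratios (names = GO ids).
#' @export
enrichment_ratio <- function(result) {
    setNames(ifelse(result$null_mean > 0,
                    result$observed_count / result$null_mean, NA_real_),
             result$go_id)
}

#' Write an enrichment result as TSV with a metadata header
#'
#' @param result An `enrichment_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(result, path) {
    con <- file(path, "w")
    on.exit(close(con))
    meta <- attr(result, "metadata")
    for (k in names(meta))
        writeLines(sprintf("# %s=%s", k, format(meta[[k]])), con)
    write.table(result, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
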