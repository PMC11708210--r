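## GFF3 parsing into gene models, strand-aware promoter construction,
## intersection of unique regions with promoters/transcripts, and the
## identification of anonymous URs (URs without any annotation).

#' Parse a GFF3 annotation into gene models
#'
#' Reads an NCBI-dialect GFF3 (gene, mRNA/transcript, and CDS features; CDS
#' carry protein identifiers). Gene identity is the `Dbxref` GeneID when
#' present, the feature `ID` otherwise. 1-based inclusive GFF3 coordinates
#' are converted to 0-based half-open. `##sequence-region` pragmas provide
#' chromosome lengths; a named `chrom_lengths` argument overrides/completes
#' them.
#'
#' @param path Path to a GFF3 file.
#' @param chrom_lengths Optional named vector of chromosome lengths (bp).
#' @return An object of class `gene_models`: list with data.frames `genes`
#'   (gene_id, chrom, strand, start, end), `transcripts` (gene_id, chrom,
#'   strand, start, end, tss), `gene2protein` (gene_id, protein_id), and the
#'   named vector `chrom_lengths`.
#' @export
parse_gff3 <- function(path, chrom_lengths = NULL) {
    if (!file.exists(path)) stop("GFF3 file not found: ", path)
    gff <- rtracklayer::import(path, format = "gff3")
    ## chromosome lengths from the ##sequence-region pragmas
    pragma <- grep("^##sequence-region",
                   readLines(path, warn = FALSE), value = TRUE)
    sl <- integer(0)
    if (length(pragma) > 0L) {
        parts <- strsplit(trimws(pragma), "\\s+")
        sl <- setNames(vapply(parts, function(p) as.integer(p[4]), 0L),
                       vapply(parts, function(p) p[2], ""))
    }
    if (!is.null(chrom_lengths)) sl[names(chrom_lengths)] <- chrom_lengths
    meta <- S4Vectors::mcols(gff)
    type <- as.character(meta$type)
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gff)),
                     start = GenomicRanges::start(gff) - 1L,
                     end = GenomicRanges::end(gff),
                     strand = as.character(GenomicRanges::strand(gff)),
                     type = type,
                     id = if ("ID" %in% names(meta))
                         as.character(meta$ID) else NA_character_,
                     stringsAsFactors = FALSE)
    df$parent <- if ("Parent" %in% names(meta)) {
        vapply(meta$Parent, function(p)
            if (length(p) > 0) as.character(p[1]) else NA_character_, "")
    } else NA_character_

    gene_rows <- which(type == "gene")
    if (length(gene_rows) == 0L)
        warning("no gene features in ", path)
    gene_id <- df$id[gene_rows]
    if ("Dbxref" %in% names(meta)) {
        dbx <- vapply(meta$Dbxref[gene_rows], function(x) {
            g <- grep("^GeneID:", x, value = TRUE)
            if (length(g) > 0) sub("^GeneID:", "", g[1]) else NA_character_
        }, "")
        gene_id <- ifelse(is.na(dbx), gene_id, dbx)
    }
    genes <- data.frame(gene_id = gene_id,
                        chrom = df$chrom[gene_rows],
                        strand = df$strand[gene_rows],
                        start = df$start[gene_rows],
                        end = df$end[gene_rows],
                        stringsAsFactors = FALSE)
    id2gene <- setNames(genes$gene_id, df$id[gene_rows])

    tx_rows <- which(type %in% c("mRNA", "transcript"))
    tx_parent_gene <- id2gene[df$parent[tx_rows]]
    orphan <- is.na(tx_parent_gene)
    if (any(orphan)) {
        warning(sum(orphan), " transcript(s) with Parent not matching any ",
                "gene feature; skipped")
        tx_rows <- tx_rows[!orphan]
        tx_parent_gene <- tx_parent_gene[!orphan]
    }
    transcripts <- data.frame(gene_id = unname(tx_parent_gene),
                              chrom = df$chrom[tx_rows],
                              strand = df$strand[tx_rows],
                              start = df$start[tx_rows],
                              end = df$end[tx_rows],
                              stringsAsFactors = FALSE)
    transcripts$tss <- ifelse(transcripts$strand == "-",
                              transcripts$end, transcripts$start)
    id2tx_gene <- setNames(transcripts$gene_id, df$id[tx_rows])

    cds_rows <- which(type == "CDS")
    prot <- if ("protein_id" %in% names(meta))
        as.character(meta$protein_id[cds_rows]) else rep(NA_character_,
                                                         length(cds_rows))
    cds_gene <- id2tx_gene[df$parent[cds_rows]]
    keep <- !is.na(cds_gene) & !is.na(prot) & nzchar(prot)
    gene2protein <- unique(data.frame(gene_id = unname(cds_gene[keep]),
                                      protein_id = prot[keep],
                                      stringsAsFactors = FALSE))
    rownames(gene2protein) <- NULL

    if (length(sl) == 0L) {
        ## fall back to the furthest annotated coordinate per chromosome
        mx <- tapply(df$end, df$chrom, max)
        sl <- setNames(as.integer(mx), names(mx))
    }
    structure(list(genes = genes, transcripts = transcripts,
                   gene2protein = gene2protein,
                   chrom_lengths = sl),
              class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
    cat("gene_models:", nrow(x$genes), "genes,", nrow(x$transcripts),
        "transcripts,", nrow(x$gene2protein), "gene-protein links on",
        length(x$chrom_lengths), "chromosome(s)\n")
    invisible(x)
}

#' Strand-aware promoter construction
#'
#' A promoter is the `upstream` bp immediately 5' of each transcription
#' start site: `[max(0, s - upstream), s)` for a + strand transcript with
#' span `[s, e)`, and `[e, min(chrom_length, e + upstream))` on the - strand.
#' Promoters are truncated (not discarded) at chromosome edges; one promoter
#' per distinct TSS per gene; zero-length promoters are dropped.
#'
#' @param models A `gene_models` object.
#' @param upstream Promoter length in bp (default 2000).
#' @return A data.frame with columns gene_id, chrom, start, end.
#' @export
promoter_set <- function(models, upstream = 2000L) {
    tx <- models$transcripts
    if (nrow(tx) == 0L)
        return(data.frame(gene_id = character(0), chrom = character(0),
                          start = integer(0), end = integer(0)))
    len <- models$chrom_lengths[tx$chrom]
    plus <- tx$strand != "-"
    start <- ifelse(plus, pmax(0L, tx$start - upstream), tx$end)
    end <- ifelse(plus, tx$start,
                  pmin(ifelse(is.na(len), tx$end + upstream, len),
                       tx$end + upstream))
    out <- data.frame(gene_id = tx$gene_id, chrom = tx$chrom,
                      start = as.integer(start), end = as.integer(end),
                      stringsAsFactors = FALSE)
    out <- unique(out[out$end > out$start, , drop = FALSE])
    rownames(out) <- NULL
    out
}

.as_granges <- function(df) {
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(start = df$start + 1L,
                                            end = df$end))
}

.check_chroms <- function(intervals, models) {
    known <- unique(c(names(models$chrom_lengths), models$genes$chrom))
    unknown <- setdiff(unique(intervals$chrom), known)
    if (length(unknown) > 0L)
        stop("chromosome name(s) in the intervals not found in the ",
             "annotation: ", paste(unknown, collapse = ", "))
}

#' Genes whose promoters or transcripts intersect a set of intervals
#'
#' A gene is reported iff any of its promoters (promoter mode) or any of its
#' transcript spans (transcript mode) overlaps any interval by at least 1 bp
#' (half-open semantics: book-ended features do not overlap).
#'
#' @param intervals A data.frame of intervals (chrom, start, end), e.g. a
#'   `ur_set`.
#' @param models A `gene_models` object.
#' @param mode `"promoter"` or `"transcript"`.
#' @param upstream Promoter length (promoter mode only).
#' @return Sorted unique character vector of gene ids.
#' @export
annotate_intervals <- function(intervals, models,
                               mode = c("promoter", "transcript"),
                               upstream = 2000L) {
    mode <- match.arg(mode)
    .check_chroms(intervals, models)
    feats <- if (mode == "promoter") promoter_set(models, upstream)
             else models$transcripts
    if (nrow(feats) == 0L || nrow(intervals) == 0L) return(character(0))
    hits <- GenomicRanges::findOverlaps(.as_granges(feats),
                                        .as_granges(intervals))
    sort(unique(feats$gene_id[S4Vectors::queryHits(hits)]))
}

#' Unique regions without any annotation ("anonymous" URs)
#'
#' The subset of intervals overlapping neither any promoter nor any
#' transcript span of the annotation -- candidate locations of missing genes.
#'
#' @param intervals A `ur_set` (or any chrom/start/end data.frame).
#' @param models A `gene_models` object.
#' @param upstream Promoter length in bp.
#' @param sort_by_length If `TRUE`, sort the result by length, longest first
#'   (the longest anonymous UR is the usual object of interest).
#' @return The subset of `intervals`, same columns.
#' @export
anonymous_regions <- function(intervals, models, upstream = 2000L,
                              sort_by_length = FALSE) {
    .check_chroms(intervals, models)
    if (nrow(intervals) == 0L) return(intervals)
    feats <- rbind(promoter_set(models, upstream)[c("chrom", "start", "end")],
                   models$transcripts[c("chrom", "start", "end")])
    keep <- if (nrow(feats) == 0L) rep(TRUE, nrow(intervals)) else {
        hits <- GenomicRanges::findOverlaps(.as_granges(intervals),
                                            .as_granges(feats))
        !(seq_len(nrow(intervals)) %in% S4Vectors::queryHits(hits))
    }
    out <- intervals[keep, , drop = FALSE]
    if (sort_by_length)
        out <- out[order(out$end - out$start, decreasing = TRUE), ,
                   drop = FALSE]
    rownames(out) <- NULL
    out
}
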