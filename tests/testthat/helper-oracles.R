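## Independent oracles used across the suite. These deliberately avoid the
## package's own index/overlap machinery: reverse complement by character
## reversal, matching statistics by all-substring scanning, overlaps by a
## quadratic all-pairs check.

rc_oracle <- function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

## Brute-force matching statistics: MS[i] = longest substring starting at i
## (no N) occurring at another forward position of any record or anywhere in
## the reverse complement of any record.
brute_ms <- function(seqs) {
    texts_rc <- vapply(seqs, rc_oracle, "")
    lapply(seq_along(seqs), function(r) {
        s <- seqs[[r]]
        n <- nchar(s)
        vapply(seq_len(n), function(i) {
            best <- 0L
            repeat {
                l <- best + 1L
                if (i + l - 1L > n) break
                sub <- substr(s, i, i + l - 1L)
                if (grepl("N", sub, fixed = TRUE)) break
                found <- FALSE
                for (r2 in seq_along(seqs)) {
                    t2 <- seqs[[r2]]
                    n2 <- nchar(t2)
                    if (n2 >= l) {
                        js <- which(substring(t2, 1:(n2 - l + 1L), l:n2) == sub)
                        if (r2 == r) js <- setdiff(js, i)
                        if (length(js) > 0L) { found <- TRUE; break }
                    }
                }
                if (!found) for (t2 in texts_rc) {
                    n2 <- nchar(t2)
                    if (n2 >= l &&
                        any(substring(t2, 1:(n2 - l + 1L), l:n2) == sub)) {
                        found <- TRUE
                        break
                    }
                }
                if (!found) break
                best <- l
            }
            best
        }, 0L)
    })
}

## Random genome with optional N's, as a named character vector.
random_genome <- function(seed, max_records = 3L, max_len = 80L,
                          n_prob = 0.04) {
    set.seed(seed)
    nrec <- sample.int(max_records, 1L)
    setNames(vapply(seq_len(nrec), function(i) {
        n <- sample(5:max_len, 1L)
        paste(sample(c("A", "C", "G", "T", "N"), n, TRUE,
                     prob = c(rep((1 - n_prob) / 4, 4), n_prob)),
              collapse = "")
    }, ""), paste0("c", seq_len(nrec)))
}

## Quadratic all-pairs overlap of 0-based half-open intervals.
brute_overlap_genes <- function(intervals, feats) {
    hit <- vapply(seq_len(nrow(feats)), function(i) {
        any(intervals$chrom == feats$chrom[i] &
            intervals$start < feats$end[i] &
            intervals$end > feats$start[i])
    }, TRUE)
    sort(unique(feats$gene_id[hit]))
}

## Minimal gene_models constructor for tests (transcript span = gene span).
toy_models <- function(genes, chrom_lengths) {
    genes$tss <- ifelse(genes$strand == "-", genes$end, genes$start)
    structure(list(
        genes = genes[c("gene_id", "chrom", "strand", "start", "end")],
        transcripts = genes[c("gene_id", "chrom", "strand", "start", "end",
                              "tss")],
        gene2protein = data.frame(gene_id = character(0),
                                  protein_id = character(0)),
        chrom_lengths = chrom_lengths), class = "gene_models")
}

## gene2go table from a named list: term id -> character vector of gene ids.
toy_gene2go <- function(term_genes, category = "biological_process") {
    out <- data.frame(
        gene_id = unlist(term_genes, use.names = FALSE),
        go_id = rep(names(term_genes), lengths(term_genes)),
        stringsAsFactors = FALSE)
    out$go_term <- paste("term", out$go_id)
    out$category <- category
    class(out) <- c("gene2go", "data.frame")
    out
}

write_tmp_fasta <- function(lines) {
    path <- tempfile(fileext = ".fa")
    writeLines(lines, path)
    path
}
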