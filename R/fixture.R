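## Synthetic end-to-end fixture: a small genome with planted repeat-dense
## and repeat-free (unique) stretches, gene models whose promoters fall in
## the unique stretches for a designated "developmental-like" GO term, and
## all mapping files -- plus a truth table for end-to-end tests.

#' Generate a synthetic pipeline fixture
#'
#' Builds a genome of `n_chrom` chromosomes, each a sequence of `block_size`
#' bp blocks: most blocks are concatenations of units drawn from a small
#' repeat library (so they recur many times across the genome and score low
#' match complexity), while the blocks listed in `unique_blocks` are i.i.d.
#' random (the planted unique regions). Signal genes -- all annotated to one
#' "developmental-like" GO term -- get promoters inside the unique blocks;
#' background genes are placed uniformly and annotated to background terms.
#' Writes genome FASTA, NCBI-dialect GFF3, a go-basic-style OBO ontology, a
#' protein-to-GO TSV, and truth tables into `dir`.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed; the fixture is fully deterministic given it.
#' @param n_chrom Number of chromosomes (default 2).
#' @param n_blocks Blocks per chromosome (default 10).
#' @param block_size Block length in bp (default 10000).
#' @param unique_blocks 0-based indices of the random (unique) blocks within
#'   each chromosome (default blocks 2 and 6).
#' @param signal_genes_per_block Signal genes placed per unique block.
#' @param n_background_genes Background genes placed uniformly.
#' @param plant_signal If `FALSE`, the signal genes are placed uniformly like
#'   the background (no enrichment signal; for calibration tests).
#' @return Invisibly, a list with `paths` (fasta, gff3, obo, pro2go, truth)
#'   and `truth` (data.frame `unique_regions`, the `signal_term` GO id, the
#'   character vector `signal_genes`, and `chrom_lengths`).
#' @export
make_fixture <- function(dir, seed = 1L, n_chrom = 2L, n_blocks = 10L,
                         block_size = 10000L, unique_blocks = c(2L, 6L),
                         signal_genes_per_block = 3L,
                         n_background_genes = 48L,
                         plant_signal = TRUE) {
    stopifnot(max(unique_blocks) < n_blocks, block_size >= 5000L)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(seed)

    ## repeat library: 5 units; repeat blocks are unit concatenations
    unit_len <- 500L
    library_units <- replicate(5, random_sequence(unit_len, seed = NULL))
    chrom_length <- n_blocks * block_size
    chroms <- setNames(vector("list", n_chrom), paste0("chr", seq_len(n_chrom)))
    truth_ur <- list()
    for (c_i in seq_len(n_chrom)) {
        blocks <- character(n_blocks)
        for (b in seq_len(n_blocks) - 1L) {
            if (b %in% unique_blocks) {
                blocks[b + 1L] <- random_sequence(block_size, seed = NULL)
                truth_ur[[length(truth_ur) + 1L]] <-
                    data.frame(chrom = names(chroms)[c_i],
                               start = b * block_size,
                               end = (b + 1L) * block_size)
            } else {
                picks <- sample.int(5L, block_size %/% unit_len, replace = TRUE)
                blocks[b + 1L] <- paste(library_units[picks], collapse = "")
            }
        }
        chroms[[c_i]] <- paste(blocks, collapse = "")
    }
    genome <- unlist(chroms)
    chrom_lengths <- setNames(rep(chrom_length, n_chrom), names(chroms))

    ## GO structure: 1 root, 1 signal term, 6 background terms
    signal_term <- "GO:0007389"   # pattern specification-like
    bg_terms <- sprintf("GO:%07d", 1:6)
    term_names <- c(setNames("pattern specification process", signal_term),
                    setNames(paste("background process", 1:6), bg_terms),
                    "GO:0008150" = "biological_process")

    ## signal genes: promoters inside unique blocks (or uniform if no signal)
    genes <- list()
    gid <- 0L
    add_gene <- function(chrom, tss, strand, terms) {
        gid <<- gid + 1L
        tx_len <- 1000L
        if (strand == "+") {
            s <- tss; e <- tss + tx_len
        } else {
            s <- tss - tx_len; e <- tss
        }
        genes[[gid]] <<- data.frame(
            gene_id = as.character(100L + gid), chrom = chrom,
            strand = strand, start = s, end = e,
            protein_id = sprintf("P%04d", gid),
            terms = paste(terms, collapse = ","), stringsAsFactors = FALSE)
    }
    signal_ids <- character(0)
    for (c_i in seq_len(n_chrom)) {
        for (b in unique_blocks) {
            bs <- b * block_size
            for (k in seq_len(signal_genes_per_block)) {
                if (plant_signal) {
                    ## + strand: promoter [tss-2000, tss) inside the block
                    tss <- bs + 2000L + (k - 1L) * 2600L
                } else {
                    tss <- sample.int(chrom_length - 4000L, 1L) + 2000L
                }
                extra <- sample(bg_terms, 1L)
                add_gene(names(chroms)[c_i], tss, "+",
                         c(signal_term, extra))
                signal_ids <- c(signal_ids, as.character(100L + gid))
            }
        }
    }
    for (k in seq_len(n_background_genes)) {
        chrom <- sample(names(chroms), 1L)
        strand <- sample(c("+", "-"), 1L)
        tss <- sample.int(chrom_length - 6000L, 1L) + 3000L
        add_gene(chrom, tss, strand,
                 sample(bg_terms, sample.int(2L, 1L) + 1L))
    }
    genes <- do.call(rbind, genes)

    ## write FASTA
    fasta <- file.path(dir, "genome.fa")
    write_fasta(genome, fasta)

    ## write GFF3 (NCBI dialect: gene/mRNA/CDS, Dbxref GeneID, protein_id)
    gff3 <- file.path(dir, "annotation.gff3")
    con <- file(gff3, "w")
    writeLines("##gff-version 3", con)
    for (ch in names(chrom_lengths))
        writeLines(sprintf("##sequence-region %s 1 %d", ch,
                           chrom_lengths[[ch]]), con)
    for (i in seq_len(nrow(genes))) {
        g <- genes[i, ]
        s1 <- g$start + 1L   # GFF3 is 1-based inclusive
        writeLines(c(
            sprintf("%s\tfixture\tgene\t%d\t%d\t.\t%s\t.\tID=gene-%s;Dbxref=GeneID:%s",
                    g$chrom, s1, g$end, g$strand, g$gene_id, g$gene_id),
            sprintf("%s\tfixture\tmRNA\t%d\t%d\t.\t%s\t.\tID=rna-%s;Parent=gene-%s",
                    g$chrom, s1, g$end, g$strand, g$gene_id, g$gene_id),
            sprintf("%s\tfixture\tCDS\t%d\t%d\t.\t%s\t0\tID=cds-%s;Parent=rna-%s;protein_id=%s",
                    g$chrom, s1 + 99L, g$end - 100L, g$strand, g$gene_id,
                    g$gene_id, g$protein_id)), con)
    }
    close(con)

    ## write OBO
    obo <- file.path(dir, "go-basic.obo")
    con <- file(obo, "w")
    writeLines(c("format-version: 1.2", "ontology: go"), con)
    for (id in names(term_names)) {
        writeLines(c("", "[Term]", paste0("id: ", id),
                     paste0("name: ", term_names[[id]]),
                     "namespace: biological_process"), con)
        if (id != "GO:0008150")
            writeLines("is_a: GO:0008150 ! biological_process", con)
    }
    close(con)

    ## write pro2go (protein \t comma-separated GO ids)
    pro2go <- file.path(dir, "pro2go.tsv")
    writeLines(paste(genes$protein_id, genes$terms, sep = "\t"), pro2go)

    truth_ur <- do.call(rbind, truth_ur)
    truth_path <- file.path(dir, "truth_unique_regions.bed")
    write_bed(truth_ur, truth_path)
    writeLines(c(paste0("signal_term\t", signal_term),
                 paste0("signal_genes\t", paste(signal_ids, collapse = ","))),
               file.path(dir, "truth_enrichment.tsv"))

    invisible(list(
        paths = list(fasta = fasta, gff3 = gff3, obo = obo, pro2go = pro2go,
                     truth_ur = truth_path),
        truth = list(unique_regions = truth_ur, signal_term = signal_term,
                     signal_genes = signal_ids,
                     chrom_lengths = chrom_lengths)))
}
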