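write_toy_gff3 <- function() {
    p <- tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        "##sequence-region chr1 1 100000",
        "##sequence-region chr2 1 50000",
        # + strand gene, GFF3 5001..7000 -> internal [5000,7000)
        "chr1\ttoy\tgene\t5001\t7000\t.\t+\t.\tID=gene-g1;Dbxref=GeneID:101",
        "chr1\ttoy\tmRNA\t5001\t7000\t.\t+\t.\tID=rna-g1;Parent=gene-g1",
        "chr1\ttoy\tCDS\t5101\t6000\t.\t+\t0\tID=cds-g1a;Parent=rna-g1;protein_id=P1",
        "chr1\ttoy\tCDS\t6101\t6900\t.\t+\t0\tID=cds-g1b;Parent=rna-g1;protein_id=P1",
        # - strand gene on chr1
        "chr1\ttoy\tgene\t20001\t22000\t.\t-\t.\tID=gene-g2;Dbxref=GeneID:102",
        "chr1\ttoy\tmRNA\t20001\t22000\t.\t-\t.\tID=rna-g2;Parent=gene-g2",
        "chr1\ttoy\tCDS\t20101\t21900\t.\t-\t0\tID=cds-g2;Parent=rna-g2;protein_id=P2",
        # + strand gene with TSS near the chromosome start (promoter truncated)
        "chr2\ttoy\tgene\t501\t1500\t.\t+\t.\tID=gene-g3",
        "chr2\ttoy\tmRNA\t501\t1500\t.\t+\t.\tID=rna-g3;Parent=gene-g3",
        # non-coding gene: no mRNA children
        "chr2\ttoy\tgene\t30001\t31000\t.\t+\t.\tID=gene-g4;Dbxref=GeneID:104",
        # orphan transcript: Parent points at a missing gene
        "chr2\ttoy\tmRNA\t40001\t41000\t.\t+\t.\tID=rna-orphan;Parent=gene-missing"
    ), p)
    p
}

test_that("GFF3 parses into 0-based gene models with NCBI gene ids", {
    expect_warning(models <- parse_gff3(write_toy_gff3()), "orphan|skip")
    expect_s3_class(models, "gene_models")
    g1 <- models$genes[models$genes$gene_id == "101", ]
    expect_equal(g1$start, 5000L)   # 1-based inclusive -> 0-based half-open
    expect_equal(g1$end, 7000L)
    expect_equal(sort(models$genes$gene_id),
                 sort(c("101", "102", "gene-g3", "104")))  # ID fallback
    expect_equal(models$chrom_lengths[["chr1"]], 100000)

    # two CDS sharing a protein id give that id once
    g2p <- extract_gene2pro(models)
    expect_equal(g2p$protein_id[g2p$gene_id == "101"], "P1")
    # non-coding gene contributes no protein rows
    expect_false("104" %in% g2p$gene_id)

    # TSS is the strand-appropriate 5' end
    tx <- models$transcripts
    expect_equal(tx$tss[tx$gene_id == "101"], 5000L)
    expect_equal(tx$tss[tx$gene_id == "102"], 22000L)
})

test_that("promoters are strand-aware, truncated, and upstream of the TSS", {
    suppressWarnings(models <- parse_gff3(write_toy_gff3()))
    pr <- promoter_set(models, upstream = 2000)
    p1 <- pr[pr$gene_id == "101", ]
    expect_equal(c(p1$start, p1$end), c(3000L, 5000L))   # + strand
    p2 <- pr[pr$gene_id == "102", ]
    expect_equal(c(p2$start, p2$end), c(22000L, 24000L)) # - strand reflection
    p3 <- pr[pr$gene_id == "gene-g3", ]
    expect_equal(c(p3$start, p3$end), c(0L, 500L))       # truncated at edge
    # gene without transcript contributes no promoter; count bound holds
    expect_false("104" %in% pr$gene_id)
    expect_lte(nrow(pr), nrow(models$transcripts))
})

test_that("annotation uses >=1 bp overlap with half-open semantics", {
    suppressWarnings(models <- parse_gff3(write_toy_gff3()))
    # 1 bp overlap with g1's promoter [3000,5000)
    ur <- data.frame(chrom = "chr1", start = 4999L, end = 5001L)
    expect_equal(annotate_intervals(ur, models, "promoter"), "101")
    # book-ended: [5000,6000) abuts the promoter, overlaps the transcript
    ur <- data.frame(chrom = "chr1", start = 5000L, end = 6000L)
    expect_equal(annotate_intervals(ur, models, "promoter"), character(0))
    expect_equal(annotate_intervals(ur, models, "transcript"), "101")
    # unknown chromosome is an error naming the culprit
    expect_error(
        annotate_intervals(data.frame(chrom = "chrX", start = 0, end = 10),
                           models, "promoter"),
        "chrX")
})

test_that("annotate matches a quadratic all-pairs oracle on random toys", {
    for (seed in 1:8) {
        set.seed(seed)
        n_genes <- 30
        genes <- data.frame(
            gene_id = paste0("g", 1:n_genes),
            chrom = sample(c("c1", "c2"), n_genes, TRUE),
            strand = sample(c("+", "-"), n_genes, TRUE),
            start = sample(2000:80000, n_genes))
        genes$end <- genes$start + sample(500:3000, n_genes, TRUE)
        models <- toy_models(genes, c(c1 = 100000, c2 = 100000))
        urs <- data.frame(chrom = sample(c("c1", "c2"), 10, TRUE),
                          start = sample(0:90000, 10))
        urs$end <- urs$start + sample(1000:8000, 10, TRUE)

        expect_equal(annotate_intervals(urs, models, "transcript"),
                     brute_overlap_genes(urs, models$transcripts))
        pr <- promoter_set(models)
        expect_equal(annotate_intervals(urs, models, "promoter"),
                     brute_overlap_genes(urs, pr))

        # anonymous URs are exactly those missed by both oracles
        anon <- anonymous_regions(urs, models)
        feats <- rbind(pr[c("chrom", "start", "end")],
                       models$transcripts[c("chrom", "start", "end")])
        feats$gene_id <- seq_len(nrow(feats))
        hit_any <- vapply(seq_len(nrow(urs)), function(i)
            length(brute_overlap_genes(urs[i, ], feats)) > 0, TRUE)
        expect_equal(anon, urs[!hit_any, , drop = FALSE],
                     ignore_attr = TRUE)
    }
})

test_that("anonymous URs on an unannotated chromosome are kept and sortable", {
    suppressWarnings(models <- parse_gff3(write_toy_gff3()))
    urs <- data.frame(chrom = c("chr1", "chr1"),
                      start = c(3500L, 50000L), end = c(4000L, 70000L))
    anon <- anonymous_regions(urs, models, sort_by_length = TRUE)
    # first interval hits g1's promoter; second hits nothing
    expect_equal(anon$start, 50000L)
    a2 <- anonymous_regions(urs, models)
    expect_equal(nrow(a2), 1L)
})
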