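test_that("gene counts per term are over distinct genes", {
    tab <- toy_gene2go(list("GO:A" = "g1", "GO:B" = "g1"))
    cnt <- count_genes_per_term(c("g1", "g1"), tab)   # duplicate counts once
    expect_equal(unname(cnt[c("GO:A", "GO:B")]), c(1L, 1L))
    expect_equal(attr(cnt, "total_genes"), 1L)
    expect_length(count_genes_per_term(character(0), tab), 0L)
    # genes absent from the table contribute nothing
    expect_length(count_genes_per_term("nope", tab), 0L)
})

test_that("shuffling preserves lengths and respects forced placements", {
    # only one placement exists: output equals input
    iv <- data.frame(chrom = "c1", start = 0L, end = 5L)
    sh <- shuffle_intervals(iv, c(c1 = 5L), seed = 3)
    expect_equal(sh, iv)

    set.seed(10)
    iv <- data.frame(chrom = "c1", start = sample(0:500, 50))
    iv$end <- iv$start + sample(1:400, 50, TRUE)
    sh <- shuffle_intervals(iv, c(c1 = 1000L, c2 = 2000L), seed = 4)
    expect_equal(sort(sh$end - sh$start), sort(iv$end - iv$start))
    expect_true(all(sh$start >= 0))
    lens <- c(c1 = 1000L, c2 = 2000L)
    expect_true(all(sh$end <= lens[sh$chrom]))

    # an interval longer than every chromosome cannot be placed
    expect_error(shuffle_intervals(data.frame(chrom = "c1", start = 0,
                                              end = 5000),
                                   c(c1 = 1000L), seed = 1),
                 "placement error")
})

test_that("placement follows the slot-proportional chromosome law", {
    # lengths 100 and 300: a 1 bp interval lands on c2 with prob 300/400
    iv <- data.frame(chrom = rep("c1", 10000), start = 0L, end = 1L)
    sh <- shuffle_intervals(iv, c(c1 = 100L, c2 = 300L), seed = 11)
    frac <- mean(sh$chrom == "c2")
    expect_lt(abs(frac - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))
    # starts on c2 roughly uniform over [0, 300)
    expect_gt(min(sh$start[sh$chrom == "c2"]), -1)
    expect_lt(mean(sh$start[sh$chrom == "c2"]) / 300, 0.55)
})

test_that("Monte Carlo p-values match exhaustive enumeration on a tiny genome", {
    ## one chromosome of 50 bp, one 10 bp interval: 41 possible placements
    genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                        chrom = "c1", strand = "+",
                        start = c(0L, 20L, 35L), end = c(10L, 30L, 50L))
    models <- toy_models(genes, c(c1 = 50L))
    tab <- toy_gene2go(list("GO:A" = c("g1", "g2"), "GO:B" = "g3"))
    iv <- data.frame(chrom = "c1", start = 18L, end = 28L)  # hits g2 only

    ## exact null by enumerating every placement
    exact_p <- function(term_genes, observed) {
        counts <- vapply(0:40, function(s) {
            hit <- genes$start < s + 10 & genes$end > s
            sum(genes$gene_id[hit] %in% term_genes)
        }, 0L)
        mean(counts >= observed)
    }
    obs_A <- 1L   # g2
    obs_B <- 0L
    pA <- exact_p(c("g1", "g2"), obs_A)
    pB <- exact_p("g3", obs_B)
    expect_equal(pB, 1)   # observed 0 is always tied or exceeded

    res <- mc_enrichment(iv, models, tab, mode = "transcript",
                         iterations = 10000, min_genes = 1, seed = 5)
    expect_equal(res$observed_count[res$go_id == "GO:A"], obs_A)
    got_pA <- res$p_raw[res$go_id == "GO:A"]
    se <- sqrt(pA * (1 - pA) / 10000)
    expect_lt(abs(got_pA - pA), 3 * se + 2 / 10001)
    expect_equal(res$p_raw[res$go_id == "GO:B"], 1)

    ## null means agree with the enumerated expectation
    exact_mean <- function(term_genes) {
        mean(vapply(0:40, function(s) {
            hit <- genes$start < s + 10 & genes$end > s
            sum(genes$gene_id[hit] %in% term_genes)
        }, 0L))
    }
    expect_equal(res$null_mean[res$go_id == "GO:A"], exact_mean(c("g1", "g2")),
                 tolerance = 0.05)
})

test_that("Bonferroni correction and the add-one estimator behave", {
    genes <- data.frame(gene_id = paste0("g", 1:6), chrom = "c1",
                        strand = "+", start = seq(0, 500, 100))
    genes$end <- genes$start + 50L
    models <- toy_models(genes, c(c1 = 1000L))
    tab <- toy_gene2go(split(genes$gene_id, rep(c("GO:A", "GO:B", "GO:C"), 2)))
    iv <- data.frame(chrom = "c1", start = c(0L, 100L), end = c(50L, 150L))
    res <- mc_enrichment(iv, models, tab, mode = "transcript",
                         iterations = 200, min_genes = 2, seed = 6)
    expect_equal(res$p_bonferroni,
                 pmin(1, res$p_raw * attr(res, "metadata")$number_of_tests))
    expect_true(all(res$p_bonferroni >= res$p_raw))
    expect_true(all(res$p_raw > 0))          # never exactly 0
    expect_true(all(res$p_raw >= 1 / 201))   # add-one floor
    expect_lte(sum(res$p_bonferroni <= 0.01), sum(res$p_bonferroni <= 0.05))
    # reproducibility: same seed, same result
    res2 <- mc_enrichment(iv, models, tab, mode = "transcript",
                          iterations = 200, min_genes = 2, seed = 6)
    expect_identical(res, res2)
    # enrichment_ratio accessor agrees with the columns
    expect_equal(unname(enrichment_ratio(res)),
                 res$observed_count / res$null_mean)
})

test_that("intervals covering the whole genome saturate the test", {
    genes <- data.frame(gene_id = c("g1", "g2"), chrom = "c1", strand = "+",
                        start = c(5L, 20L), end = c(15L, 28L))
    models <- toy_models(genes, c(c1 = 30L))
    tab <- toy_gene2go(list("GO:A" = c("g1", "g2")))
    iv <- data.frame(chrom = "c1", start = 0L, end = 30L)
    res <- mc_enrichment(iv, models, tab, mode = "transcript",
                         iterations = 50, min_genes = 1, seed = 7)
    expect_equal(res$p_raw, 1)
    expect_equal(res$enrichment_ratio, 1)
    expect_false(any(res$enriched))
})

test_that("genome-wide min_genes filter selects the tested terms", {
    tab <- toy_gene2go(list("GO:A" = paste0("g", 1:12),
                            "GO:B" = paste0("g", 1:3)))
    genes <- data.frame(gene_id = paste0("g", 1:12), chrom = "c1",
                        strand = "+", start = seq(0, 1100, 100))
    genes$end <- genes$start + 50L
    models <- toy_models(genes, c(c1 = 2000L))
    iv <- data.frame(chrom = "c1", start = 0L, end = 100L)
    res <- mc_enrichment(iv, models, tab, mode = "transcript",
                         iterations = 20, min_genes = 10, seed = 8)
    expect_equal(res$go_id, "GO:A")   # GO:B has < 10 genes genome-wide
    expect_equal(attr(res, "metadata")$number_of_tests, 1L)
    expect_warning(
        mc_enrichment(iv, models, tab, mode = "transcript", iterations = 5,
                      min_genes = 50, seed = 8),
        "no GO term")
})

test_that("with no planted signal, raw p-values are not anti-conservative", {
    set.seed(99)
    n_genes <- 120
    genes <- data.frame(gene_id = paste0("g", seq_len(n_genes)),
                        chrom = sample(c("c1", "c2"), n_genes, TRUE),
                        strand = "+",
                        start = sample(0:48000, n_genes))
    genes$end <- genes$start + 1000L
    models <- toy_models(genes, c(c1 = 50000L, c2 = 50000L))
    term_genes <- lapply(setNames(nm = sprintf("GO:%04d", 1:30)),
                         function(t) sample(genes$gene_id, 12))
    tab <- toy_gene2go(term_genes)
    ## intervals themselves drawn from the shuffling null
    iv <- shuffle_intervals(
        data.frame(chrom = "c1", start = 0L, end = rep(4000L, 5)),
        c(c1 = 50000L, c2 = 50000L), seed = 123)
    res <- mc_enrichment(iv, models, tab, mode = "transcript",
                         iterations = 400, min_genes = 10, seed = 124)
    frac_small <- mean(res$p_raw <= 0.05)
    expect_lte(frac_small, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(res)) + 1e-9)
    expect_gte(mean(res$p_raw), 0.35)   # stochastically >= uniform, roughly
    expect_false(any(res$enriched))
})
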