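test_that("load_fasta reads, orders, and normalizes records", {
    p <- write_tmp_fasta(c(">c1", "ACGT"))
    expect_equal(load_fasta(p), c(c1 = "ACGT"))

    p <- write_tmp_fasta(c(">c1", "acgn"))
    expect_equal(load_fasta(p), c(c1 = "ACGN"))

    p <- write_tmp_fasta(c(">b", "AC", "GT", ">a desc here", "TTRY"))
    got <- load_fasta(p)
    expect_equal(names(got), c("b", "a"))      # file order, id cut at space
    expect_equal(unname(got), c("ACGT", "TTNN"))  # wrapped lines, IUPAC -> N
})

test_that("load_fasta rejects malformed input with the offending line", {
    p <- tempfile(); file.create(p)
    expect_error(load_fasta(p), "empty")
    p <- write_tmp_fasta(c("ACGT", ">c1"))
    expect_error(load_fasta(p), "line 1")
    p <- write_tmp_fasta(c(">c1", "ACGT", "AC GT"))
    expect_error(load_fasta(p), "line 3")
    expect_error(load_fasta(tempfile()), "not found")
})

test_that("fasta round-trips through write_fasta", {
    seqs <- c(chrA = "ACGTACGTNN", chrB = "TTTTGGGG")
    p <- tempfile(fileext = ".fa")
    write_fasta(seqs, p)
    expect_equal(load_fasta(p), seqs)
})

test_that("build_index computes composition and rejects degenerate input", {
    idx <- build_index(c(c1 = "ACGT", c2 = "A"))
    expect_s3_class(idx, "match_index")
    expect_equal(idx$total_length, 5L)
    expect_equal(unname(idx$composition), c(2, 1, 1, 1) / 5)
    expect_error(build_index(c(c1 = "NNNN")), "degenerate")

    # single-residue genome: nothing can match
    expect_equal(unname(matching_statistics(build_index(c(c1 = "A")))[[1]]), 0L)
})

test_that("matching statistics match the spec's worked example", {
    ms <- matching_statistics(build_index(c(c1 = "AAAA")))
    expect_equal(unname(ms$c1), c(3L, 3L, 2L, 1L))
})

test_that("no match crosses a chromosome boundary", {
    # as one record, ACGT matches its own reverse complement fully;
    # split as ACG | T, the boundary truncates every such match
    ms_split <- matching_statistics(build_index(c(a = "ACG", b = "T")))
    expect_equal(ms_split, setNames(brute_ms(c(a = "ACG", b = "T")),
                                    c("a", "b")))
    ms_joint <- matching_statistics(build_index(c(a = "ACGT")))
    expect_equal(unname(ms_joint$a[1]), 4L)  # palindromic self-match survives
})

test_that("matching statistics equal the brute-force scan on random genomes", {
    for (seed in 1:20) {
        g <- random_genome(seed)
        got <- matching_statistics(build_index(g))
        want <- setNames(brute_ms(g), names(g))
        expect_equal(lapply(got, as.integer), lapply(want, as.integer),
                     info = paste("seed", seed))
    }
    # one larger dense case
    set.seed(99)
    g <- c(c1 = paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""))
    expect_equal(as.integer(matching_statistics(build_index(g))[[1]]),
                 as.integer(brute_ms(g)[[1]]))
})

test_that("matching-statistic invariants hold on random genomes", {
    for (seed in 21:35) {
        g <- random_genome(seed)
        ms <- matching_statistics(build_index(g))
        for (r in seq_along(g)) {
            v <- ms[[r]]
            n <- length(v)
            expect_true(all(v <= n - seq_len(n) + 1L))
            isn <- strsplit(g[[r]], "")[[1]] == "N"
            expect_true(all(v[isn] == 0L))
            # suffix-overlap property between adjacent non-N positions
            if (n > 1) {
                both <- !isn[-n] & !isn[-1]
                expect_true(all((v[-1] >= v[-n] - 1L)[both]))
            }
        }
        # reverse-complement symmetry: MS multiset is invariant
        g_rc <- setNames(vapply(g, rc_oracle, ""), names(g))
        ms_rc <- matching_statistics(build_index(g_rc))
        expect_equal(sort(unlist(ms)), sort(unlist(ms_rc)),
                     ignore_attr = TRUE)
    }
})

test_that("factorize applies the greedy rule and tiles the region", {
    f <- factorize(c(3L, 3L, 2L, 1L))
    expect_equal(f$start, c(0L, 3L))
    expect_equal(f$length, c(3L, 1L))

    expect_equal(nrow(factorize(c(3L, 3L), 1, 1)), 0L)  # empty region

    # zero-match position is its own factor
    f <- factorize(c(0L, 5L, 4L), 0, 1)
    expect_equal(f, data.frame(start = 0L, length = 1L))

    # tiling: contiguous, non-overlapping, exact cover
    for (seed in 1:10) {
        g <- random_genome(seed, max_records = 1L, max_len = 150L)
        ms <- matching_statistics(build_index(g))[[1]]
        f <- factorize(ms)
        expect_equal(f$start, cumsum(c(0L, f$length[-nrow(f)])))
        expect_equal(sum(f$length), length(ms))
    }
})

test_that("factor-in-window counts agree with a naive intersection scan", {
    set.seed(5)
    g <- c(c1 = paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = ""))
    ms <- matching_statistics(build_index(g))[[1]]
    f <- factorize(ms)
    ws <- seq(0L, 350L, by = 13L)
    got <- urscan:::count_factors_in_windows(f, ws, ws + 50L)
    naive <- vapply(ws, function(s)
        sum(f$start < s + 50L & f$start + f$length > s), 0L)
    expect_equal(got, naive)
})
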