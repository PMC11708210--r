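## End-to-end pipeline: genome FASTA + GFF3 + OBO + pro2go in, unique
## regions, gene lists, gene2go table, and enrichment results out.

#' Default pipeline configuration
#'
#' @param ... Named overrides of any configuration entry.
#' @return A named list: input paths (`fasta`, `gff3`, `obo`, `pro2go`,
#'   `out_dir`) and parameters (`window`, `step`, `alpha_unique`,
#'   `min_ur_length`, `mode`, `iterations`, `min_genes`, `alpha_enrich`,
#'   `category`, `upstream`, `null_replicates`, `propagate`, `seed`).
#' @export
default_config <- function(...) {
    cfg <- list(fasta = NULL, gff3 = NULL, obo = NULL, pro2go = NULL,
                out_dir = NULL,
                window = 10000L, step = 1000L, alpha_unique = 0.05,
                min_ur_length = 10000L, mode = "promoter",
                iterations = 10000L, min_genes = 10L, alpha_enrich = 0.01,
                category = "biological_process", upstream = 2000L,
                null_replicates = 20L, propagate = FALSE, seed = 1L)
    over <- list(...)
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) > 0L)
        stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
    cfg
}

#' Read / write a pipeline configuration (key = value text)
#'
#' @param path File path.
#' @param cfg A configuration list.
#' @return The configuration list / `path`.
#' @export
read_config <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    kv <- regmatches(lines, regexec("^\\s*([^=\\s]+)\\s*=\\s*(.*?)\\s*$",
                                    lines, perl = TRUE))
    bad <- which(lengths(kv) != 3L)
    if (length(bad) > 0L)
        stop("config format error at line ", bad[1], ": ", lines[bad[1]])
    keys <- vapply(kv, `[`, "", 2L)
    vals <- vapply(kv, `[`, "", 3L)
    defaults <- default_config()
    cfg <- defaults
    for (i in seq_along(keys)) {
        k <- keys[i]
        if (!k %in% names(defaults)) stop("unknown configuration key: ", k)
        v <- vals[i]
        proto <- defaults[[k]]
        cfg[[k]] <- if (is.null(proto) || is.character(proto)) v
                    else if (is.logical(proto)) as.logical(v)
                    else if (is.integer(proto)) as.integer(v)
                    else as.numeric(v)
    }
    cfg
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
    keep <- !vapply(cfg, is.null, TRUE)
    writeLines(sprintf("%s = %s", names(cfg)[keep],
                       vapply(cfg[keep], function(v) format(v), "")), path)
    invisible(path)
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full unique-region annotation pipeline
#'
#' Stages, each written to `out_dir` as it completes: null-model sidecar,
#' complexity profile, unique-region BED, annotated gene lists (promoter and
#' transcript modes), anonymous-UR BED, gene2go table, enrichment TSV, and a
#' run log recording every parameter and seed. Stage seeds are derived
#' deterministically from the global seed.
#'
#' @param config A configuration list (see [default_config()]); `fasta`,
#'   `gff3`, `obo`, `pro2go`, and `out_dir` must be set.
#' @return Invisibly, a named list of output paths plus the in-memory
#'   results (`urs`, `enrichment`).
#' @export
run_pipeline <- function(config = default_config()) {
    for (k in c("fasta", "gff3", "obo", "pro2go", "out_dir"))
        if (is.null(config[[k]])) stop("config entry '", k, "' is required")
    for (k in c("fasta", "gff3", "obo", "pro2go"))
        if (!file.exists(config[[k]]))
            stop("input path not readable: ", k, " = ", config[[k]])
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$out_dir, f)
    log_lines <- c(sprintf("# urscan run log"),
                   sprintf("%s = %s", names(config),
                           vapply(config, function(v)
                               paste(format(v), collapse = ","), "")))

    genome <- .stage("load_fasta", load_fasta(config$fasta))
    index <- .stage("build_index", build_index(genome))

    null <- .stage("calibrate_null", calibrate_null(
        total_length = index$total_length,
        composition = index$composition,
        window = config$window, step = config$step,
        replicates = config$null_replicates,
        seed = config$seed))
    write_null_model(null, out("null_model.txt"))

    profile <- .stage("window_complexity",
                      window_complexity(index, null, step = config$step))
    profile <- classify_unique(profile, null, alpha = config$alpha_unique)
    write_profile(profile, out("complexity.tsv"))

    urs <- .stage("extract_unique_regions",
                  extract_unique_regions(profile, config$min_ur_length))
    write_bed(urs, out("urs.bed"))

    models <- .stage("parse_gff3",
                     parse_gff3(config$gff3,
                                chrom_lengths = index$lengths))
    genes_prom <- .stage("annotate",
                         annotate_intervals(urs, models, "promoter",
                                            upstream = config$upstream))
    writeLines(genes_prom, out("genes_promoter.txt"))
    genes_tx <- annotate_intervals(urs, models, "transcript")
    writeLines(genes_tx, out("genes_transcript.txt"))

    anon <- .stage("anonymous_regions",
                   anonymous_regions(urs, models, upstream = config$upstream))
    write_bed(anon, out("anonymous_urs.bed"))

    dag <- .stage("parse_obo", parse_obo(config$obo))
    gene2go <- .stage("build_gene2go", build_gene2go(
        extract_gene2pro(models), read_pro2go(config$pro2go), dag))
    if (isTRUE(config$propagate))
        gene2go <- propagate_gene2go(gene2go, dag)
    write_gene2go(gene2go, out("gene2go.tsv"))

    enr <- .stage("mc_enrichment", mc_enrichment(
        urs, models, gene2go, mode = config$mode,
        iterations = config$iterations, min_genes = config$min_genes,
        alpha = config$alpha_enrich, category = config$category,
        upstream = config$upstream, seed = config$seed + 1L))
    write_enrichment(enr, out("enrichment.tsv"))

    log_lines <- c(log_lines,
                   sprintf("me = %.6f", null$me),
                   sprintf("cm_threshold = %.6f", attr(profile, "cm_threshold")),
                   sprintf("n_urs = %d", nrow(urs)),
                   sprintf("n_genes_promoter = %d", length(genes_prom)),
                   sprintf("n_genes_transcript = %d", length(genes_tx)),
                   sprintf("n_anonymous = %d", nrow(anon)),
                   sprintf("number_of_tests = %d",
                           attr(enr, "metadata")$number_of_tests),
                   sprintf("propagate = %s", isTRUE(config$propagate)),
                   sprintf("n_enriched = %d", sum(enr$enriched)))
    writeLines(log_lines, out("run_log.txt"))

    invisible(list(
        null_model = out("null_model.txt"),
        complexity = out("complexity.tsv"),
        urs_bed = out("urs.bed"),
        genes_promoter = out("genes_promoter.txt"),
        genes_transcript = out("genes_transcript.txt"),
        anonymous_bed = out("anonymous_urs.bed"),
        gene2go = out("gene2go.tsv"),
        enrichment_tsv = out("enrichment.tsv"),
        run_log = out("run_log.txt"),
        urs = urs, enrichment = enr))
}
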