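## Gene -> GO mapping: OBO ontology parsing, the gene2pro and pro2go input
## tables, their join into a gene2go table (NCBI column dialect), and
## optional propagation of annotations to is_a/part_of ancestors.

#' Parse a GO ontology in OBO 1.2 (go-basic) format
#'
#' Loads every non-obsolete `[Term]` stanza with its id, name, namespace,
#' `is_a` parents, and `relationship: part_of` parents. Terms without a
#' namespace are skipped with a warning; a cycle over is_a/part_of edges is
#' a format error.
#'
#' @param path Path to an OBO file.
#' @return An object of class `go_dag`: list with `terms` (data.frame id,
#'   name, namespace) and `edges` (data.frame child, parent, rel).
#' @export
parse_obo <- function(path) {
    if (!file.exists(path)) stop("OBO file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    stanza_at <- which(lines == "[Term]")
    boundaries <- c(grep("^\\[", lines), length(lines) + 1L)
    ids <- names <- namespaces <- character(0)
    edges_child <- edges_parent <- edges_rel <- character(0)
    skipped <- 0L
    for (s in stanza_at) {
        stop_at <- boundaries[boundaries > s][1]
        block <- lines[(s + 1L):(stop_at - 1L)]
        getval <- function(key) {
            v <- sub(paste0("^", key, ": "), "",
                     grep(paste0("^", key, ": "), block, value = TRUE))
            sub("\\s*!.*$", "", v)  # strip trailing '! comment'
        }
        if (any(grepl("^is_obsolete: true", block))) next
        id <- getval("id")[1]
        ns <- getval("namespace")[1]
        if (is.na(ns) || length(ns) == 0L) {
            skipped <- skipped + 1L
            next
        }
        ids <- c(ids, id)
        names <- c(names, getval("name")[1])
        namespaces <- c(namespaces, ns)
        isa <- getval("is_a")
        po <- sub("^part_of ", "",
                  grep("^part_of ", getval("relationship"), value = TRUE))
        edges_child <- c(edges_child, rep(id, length(isa) + length(po)))
        edges_parent <- c(edges_parent, isa, po)
        edges_rel <- c(edges_rel, rep("is_a", length(isa)),
                       rep("part_of", length(po)))
    }
    if (skipped > 0L)
        warning(skipped, " term(s) without a namespace skipped")
    ## drop edges to unknown (e.g. obsolete) terms
    known <- edges_parent %in% ids
    edges <- data.frame(child = edges_child[known],
                        parent = edges_parent[known],
                        rel = edges_rel[known], stringsAsFactors = FALSE)
    dag <- structure(list(terms = data.frame(id = ids, name = names,
                                             namespace = namespaces,
                                             stringsAsFactors = FALSE),
                          edges = edges),
                     class = "go_dag")
    if (.has_cycle(dag))
        stop("OBO format error: cycle detected over is_a/part_of edges")
    dag
}

## Kahn's algorithm: TRUE iff the is_a/part_of graph has a cycle.
.has_cycle <- function(dag) {
    ids <- dag$terms$id
    if (nrow(dag$edges) == 0L) return(FALSE)
    child <- match(dag$edges$child, ids)
    parent <- match(dag$edges$parent, ids)
    outdeg <- tabulate(child, nbins = length(ids))  # edges child -> parent
    incoming <- split(child, parent)                # who points at me
    queue <- which(outdeg == 0L)
    seen <- 0L
    while (length(queue) > 0L) {
        v <- queue[[1]]
        queue <- queue[-1]
        seen <- seen + 1L
        for (u in incoming[[as.character(v)]]) {
            outdeg[u] <- outdeg[u] - 1L
            if (outdeg[u] == 0L) queue <- c(queue, u)
        }
    }
    seen < length(ids)
}

#' @export
print.go_dag <- function(x, ...) {
    cat("go_dag:", nrow(x$terms), "terms,", nrow(x$edges), "edges (",
        paste(names(table(x$terms$namespace)), collapse = ", "), ")\n")
    invisible(x)
}

#' All is_a/part_of ancestors of a GO term
#'
#' @param dag A `go_dag`.
#' @param id A GO id.
#' @return Character vector of ancestor ids (excluding `id` itself).
#' @export
go_ancestors <- function(dag, id) {
    parents <- split(dag$edges$parent, dag$edges$child)
    out <- character(0)
    frontier <- id
    while (length(frontier) > 0L) {
        nxt <- unique(unlist(parents[frontier], use.names = FALSE))
        nxt <- setdiff(nxt, out)
        out <- c(out, nxt)
        frontier <- nxt
    }
    setdiff(out, id)
}

#' Extract the gene -> protein table from gene models
#'
#' @param models A `gene_models` object (see [parse_gff3()]).
#' @return A data.frame with one row per distinct (gene_id, protein_id) pair.
#' @export
extract_gene2pro <- function(models) {
    unique(models$gene2protein)
}

#' Read a protein -> GO mapping table
#'
#' Two tab-separated columns: protein id, comma-separated GO ids (the
#' annotations-column convention of homology-transfer tools). Lines starting
#' with `#` are ignored.
#'
#' @param path Path to the TSV.
#' @return A data.frame with columns protein_id, go_id (one row per pair).
#' @export
read_pro2go <- function(path) {
    if (!file.exists(path)) stop("pro2go file not found: ", path)
    d <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
    if (ncol(d) < 2L) stop("pro2go format error: need 2 tab-separated columns")
    gos <- strsplit(as.character(d[[2]]), ",", fixed = TRUE)
    out <- data.frame(protein_id = rep(as.character(d[[1]]), lengths(gos)),
                      go_id = trimws(unlist(gos)), stringsAsFactors = FALSE)
    unique(out[nzchar(out$go_id), , drop = FALSE])
}

#' Build the gene2go table by joining gene2pro, pro2go, and the ontology
#'
#' Inner join of gene2pro and pro2go on protein id, then of the result and
#' the ontology on GO id, attaching term name and category (the namespace).
#' GO ids absent from the ontology are dropped with a warning; duplicate
#' (gene, GO) pairs are collapsed.
#'
#' @param gene2pro data.frame (gene_id, protein_id), see [extract_gene2pro()].
#' @param pro2go data.frame (protein_id, go_id), see [read_pro2go()].
#' @param dag A `go_dag`.
#' @return A data.frame (`gene2go`) with columns gene_id, go_id, go_term,
#'   category.
#' @export
build_gene2go <- function(gene2pro, pro2go, dag) {
    j <- merge(gene2pro, pro2go, by = "protein_id")
    unknown <- setdiff(unique(j$go_id), dag$terms$id)
    if (length(unknown) > 0L) {
        warning(length(unknown), " GO id(s) absent from the ontology dropped: ",
                paste(utils::head(unknown, 5), collapse = ", "),
                if (length(unknown) > 5) ", ..." else "")
        j <- j[!(j$go_id %in% unknown), , drop = FALSE]
    }
    j <- merge(j, dag$terms, by.x = "go_id", by.y = "id")
    out <- unique(data.frame(gene_id = j$gene_id, go_id = j$go_id,
                             go_term = j$name, category = j$namespace,
                             stringsAsFactors = FALSE))
    if (nrow(out) == 0L) warning("empty gene2go join result")
    out <- out[order(out$gene_id, out$go_id), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("gene2go", "data.frame")
    out
}

#' Propagate annotations to is_a/part_of ancestors
#'
#' Adds, for every (gene, term) row, rows annotating the gene to every
#' ancestor of the term. Idempotent; never removes rows. Off by default in
#' the pipeline because reference counting tools differ on whether counts
#' are over directly annotated terms or the ancestor closure.
#'
#' @param table A `gene2go` data.frame.
#' @param dag The `go_dag` the table was built against.
#' @return The propagated `gene2go` table.
#' @export
propagate_gene2go <- function(table, dag) {
    anc <- lapply(setNames(nm = unique(table$go_id)),
                  function(id) go_ancestors(dag, id))
    extra_n <- lengths(anc[table$go_id])
    new_go <- unlist(anc[table$go_id], use.names = FALSE)
    if (length(new_go) > 0L) {
        add <- data.frame(gene_id = rep(table$gene_id, extra_n),
                          go_id = new_go, stringsAsFactors = FALSE)
        add <- merge(add, dag$terms, by.x = "go_id", by.y = "id")
        add <- data.frame(gene_id = add$gene_id, go_id = add$go_id,
                          go_term = add$name, category = add$namespace,
                          stringsAsFactors = FALSE)
        table <- rbind(as.data.frame(table), add)
    }
    out <- unique(table)
    out <- out[order(out$gene_id, out$go_id), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("gene2go", "data.frame")
    out
}

#' Write / read a gene2go table in the NCBI 8-column dialect
#'
#' Columns: tax_id, GeneID, GO_ID, Evidence, Qualifier, GO_term, PubMed,
#' Category. Only GeneID, GO_ID, GO_term, and Category are populated; the
#' other columns are written as `-` (tax_id as 0) for drop-in compatibility.
#'
#' @param table A `gene2go` data.frame.
#' @param path File path.
#' @param tax_id Value for the tax_id column (default 0).
#' @return `path` / the `gene2go` table.
#' @export
write_gene2go <- function(table, path, tax_id = 0L) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste("#tax_id", "GeneID", "GO_ID", "Evidence", "Qualifier",
                     "GO_term", "PubMed", "Category", sep = "\t"), con)
    if (nrow(table) > 0L)
        writeLines(paste(tax_id, table$gene_id, table$go_id, "-", "-",
                         table$go_term, "-", table$category, sep = "\t"), con)
    invisible(path)
}

#' @rdname write_gene2go
#' @export
read_gene2go <- function(path) {
    d <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE,
                    col.names = c("tax_id", "GeneID", "GO_ID", "Evidence",
                                  "Qualifier", "GO_term", "PubMed",
                                  "Category"))
    out <- data.frame(gene_id = as.character(d$GeneID), go_id = d$GO_ID,
                      go_term = d$GO_term, category = d$Category,
                      stringsAsFactors = FALSE)
    class(out) <- c("gene2go", "data.frame")
    out
}
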