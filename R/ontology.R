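#' Construct an ontology DAG from child-parent edges
#'
#' Terms form a directed acyclic graph through `is_a` links (child points to
#' parent). Term annotation frequencies, needed for information-content
#' similarity, are attached later by [set_term_frequencies()].
#'
#' @param terms Character vector of term identifiers.
#' @param edges Tibble/data frame with columns `child`, `parent`.
#' @return An `ssmoc_ontology` object: term set, parent lists, and ancestor
#'   sets (each term is its own ancestor).
#' @export
ontology_graph <- function(terms, edges) {
  terms <- unique(as.character(terms))
  edges <- tibble::tibble(child = as.character(edges$child),
                          parent = as.character(edges$parent))
  unknown <- setdiff(c(edges$child, edges$parent), terms)
  if (length(unknown) > 0L) {
    stop("edge endpoint(s) not in term set: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = terms)
  if (!igraph::is_dag(g)) {
    # any nontrivial strongly connected component sits on a cycle
    comp <- igraph::components(g, mode = "strong")
    on_cycle <- names(comp$membership)[comp$membership %in%
                                         which(comp$csize > 1)]
    if (length(on_cycle) == 0L) on_cycle <- edges$child[edges$child == edges$parent]
    stop("ontology contains a cycle through term '", on_cycle[1], "'")
  }
  parents <- split(edges$parent, factor(edges$child, levels = terms))
  # ancestors include the term itself; fill in reverse topological order
  topo <- names(igraph::topo_sort(g, mode = "in"))  # parents first
  anc <- stats::setNames(vector("list", length(terms)), terms)
  for (t in topo) {
    anc[[t]] <- unique(c(t, unlist(anc[parents[[t]]], use.names = FALSE)))
  }
  structure(
    list(terms = terms, parents = parents, ancestors = anc,
         edges = edges, term_frequency = NULL),
    class = "ssmoc_ontology"
  )
}

#' Read an ontology from an OBO 1.2 file
#'
#' Parses `[Term]` stanzas, honoring `id:`, `is_a:` and `is_obsolete:` tags.
#' Obsolete terms are skipped; `is_a` targets not defined by their own stanza
#' are added as bare terms so that every edge endpoint exists. Only `is_a`
#' relations are used.
#'
#' @param path Path to an OBO file.
#' @return An `ssmoc_ontology` object.
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur_id <- NA_character_
  cur_parents <- character()
  obsolete <- FALSE
  ids <- character()
  child <- character()
  parent <- character()
  flush <- function() {
    if (in_term && !is.na(cur_id) && !obsolete) {
      ids <<- c(ids, cur_id)
      if (length(cur_parents) > 0L) {
        child <<- c(child, rep(cur_id, length(cur_parents)))
        parent <<- c(parent, cur_parents)
      }
    }
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (startsWith(ln, "[")) {
      flush()
      in_term <- identical(ln, "[Term]")
      cur_id <- NA_character_
      cur_parents <- character()
      obsolete <- FALSE
    } else if (in_term) {
      if (startsWith(ln, "id:")) {
        cur_id <- trimws(sub("^id:", "", ln))
      } else if (startsWith(ln, "is_a:")) {
        p <- trimws(sub("^is_a:", "", ln))
        if (nzchar(p)) cur_parents <- c(cur_parents, p)
      } else if (startsWith(ln, "is_obsolete:")) {
        obsolete <- isTRUE(trimws(sub("^is_obsolete:", "", ln)) == "true")
      }
    }
  }
  flush()
  if (length(ids) == 0L) stop("no [Term] stanzas found in ", path)
  terms <- unique(c(ids, parent))
  keep <- !duplicated(paste(child, parent))
  ontology_graph(terms, tibble::tibble(child = child[keep],
                                       parent = parent[keep]))
}

#' Read gene-to-term annotations
#'
#' @param path Two-column TSV: `gene_id`, `term_id` (no header needed; a
#'   header row matching these names is allowed).
#' @param ontology The `ssmoc_ontology` the terms must belong to.
#' @return A tibble with columns `gene_id`, `term_id` (distinct rows).
#' @export
read_annotations <- function(path, ontology) {
  tb <- readr::read_tsv(path, col_names = c("gene_id", "term_id"),
                        show_col_types = FALSE, progress = FALSE,
                        col_types = "cc")
  if (nrow(tb) > 0L && tb$gene_id[1] == "gene_id") tb <- tb[-1, ]
  as_annotations(tb, ontology)
}

#' Validate an annotation table against an ontology
#'
#' @param anno Data frame with columns `gene_id`, `term_id`.
#' @param ontology An `ssmoc_ontology`.
#' @return A distinct annotation tibble.
#' @export
as_annotations <- function(anno, ontology) {
  tb <- tibble::tibble(gene_id = as.character(anno$gene_id),
                       term_id = as.character(anno$term_id))
  bad <- which(!(tb$term_id %in% ontology$terms))
  if (length(bad) > 0L) {
    stop("annotation term(s) not in ontology (rows ",
         paste(utils::head(bad, 5), collapse = ", "), "): ",
         paste(utils::head(unique(tb$term_id[bad]), 5), collapse = ", "))
  }
  dplyr::distinct(tb)
}

#' Attach annotation frequencies to an ontology
#'
#' The frequency of a term is the fraction of annotated genes annotated to
#' the term or to any of its descendants (true-path rule), relative to the
#' number of genes carrying at least one annotation in `anno`. Frequencies
#' are therefore monotone non-decreasing from child to parent, and the root
#' always has frequency 1.
#'
#' @param ontology An `ssmoc_ontology`.
#' @param anno Annotation tibble (see [as_annotations()]).
#' @return The ontology with `term_frequency` populated (named numeric).
#' @export
set_term_frequencies <- function(ontology, anno) {
  anno <- as_annotations(anno, ontology)
  genes <- unique(anno$gene_id)
  n_ann <- length(genes)
  if (n_ann == 0L) stop("no annotated genes")
  # each gene's effective term set = ancestors of its direct annotations
  counts <- stats::setNames(numeric(length(ontology$terms)), ontology$terms)
  per_gene <- split(anno$term_id, anno$gene_id)
  for (ts in per_gene) {
    eff <- unique(unlist(ontology$ancestors[ts], use.names = FALSE))
    counts[eff] <- counts[eff] + 1
  }
  ontology$term_frequency <- counts / n_ann
  ontology
}

#' @export
print.ssmoc_ontology <- function(x, ...) {
  cat("ontology DAG:", length(x$terms), "terms,", nrow(x$edges), "is_a edges")
  if (!is.null(x$term_frequency)) {
    cat(";", sum(x$term_frequency > 0), "terms with annotation frequency")
  }
  cat("\n")
  invisible(x)
}
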