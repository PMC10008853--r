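#' Build a canonical pairwise constraint set
#'
#' A pairwise constraint asserts that two genes must share a cluster
#' (must-link, `"ML"`) or must not (`"CL"`). Constraints carry a `source`
#' tag recording whether they were mined from the expression matrix
#' (`"expression"`) or from ontology annotations (`"ontology"`).
#'
#' Pairs are unordered: rows are stored with `gene_a < gene_b`
#' lexicographically, so `(g2, g1)` and `(g1, g2)` are the same constraint.
#' Duplicate rows per `(pair, kind, source)` are collapsed.
#'
#' @param gene_a,gene_b Character vectors of gene identifiers.
#' @param kind `"ML"` or `"CL"`, recycled as needed.
#' @param source `"expression"` or `"ontology"`, recycled as needed.
#' @return A tibble with columns `gene_a`, `gene_b`, `kind`, `source`.
#' @export
constraint_set <- function(gene_a = character(), gene_b = character(),
                           kind = character(), source = character()) {
  tb <- tibble::tibble(
    gene_a = as.character(gene_a), gene_b = as.character(gene_b),
    kind = as.character(kind), source = as.character(source)
  )
  if (nrow(tb) == 0L) return(tb)
  if (any(tb$gene_a == tb$gene_b)) {
    bad <- tb$gene_a[tb$gene_a == tb$gene_b][1]
    stop("self-pair constraint on gene '", bad, "'")
  }
  if (!all(tb$kind %in% c("ML", "CL"))) {
    stop("constraint kind must be 'ML' or 'CL', got: ",
         paste(setdiff(unique(tb$kind), c("ML", "CL")), collapse = ", "))
  }
  if (!all(tb$source %in% c("expression", "ontology"))) {
    stop("constraint source must be 'expression' or 'ontology'")
  }
  a <- pmin(tb$gene_a, tb$gene_b)
  b <- pmax(tb$gene_a, tb$gene_b)
  tb$gene_a <- a
  tb$gene_b <- b
  dplyr::distinct(tb)
}

#' Read a 4-column constraint TSV
#'
#' @param path TSV with columns `gene_a`, `gene_b`, `kind`, `source`.
#' @return A canonical constraint tibble (see [constraint_set()]).
#' @export
read_constraints <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = "cccc")
  need <- c("gene_a", "gene_b", "kind", "source")
  if (!all(need %in% names(tb))) {
    stop("constraint file must have columns: ", paste(need, collapse = ", "))
  }
  constraint_set(tb$gene_a, tb$gene_b, tb$kind, tb$source)
}

#' Write a constraint set as TSV
#'
#' Round-trips with [read_constraints()] on the canonical form.
#'
#' @param cs Constraint tibble.
#' @param path Output path.
#' @export
write_constraints <- function(cs, path) {
  cs <- constraint_set(cs$gene_a, cs$gene_b, cs$kind, cs$source)
  readr::write_tsv(cs, path, progress = FALSE)
  invisible(path)
}

# canonical "a|b" pair keys, used throughout for set membership tests
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
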