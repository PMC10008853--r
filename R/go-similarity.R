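#' Aggregate-information-content term semantics
#'
#' For each term t with annotation frequency p(t), the information content
#' is IC(t) = -log p(t) (nats). The semantic weight
#' SW(t) = 1 / (1 + exp(-1 / IC(t))) squashes 1/IC into (0.5, 1]; at IC = 0
#' (the root, p = 1) SW is defined as its continuity limit 1. The semantic
#' value SV(t) sums SW over all ancestors of t, t included.
#'
#' @param ontology An `ssmoc_ontology` with `term_frequency` set
#'   (see [set_term_frequencies()]).
#' @return An `ssmoc_semantics` object holding per-term `sw` and `sv`
#'   lookups, the ancestor sets, and a tidy `table` tibble
#'   (`term`, `p`, `ic`, `sw`, `sv`).
#' @export
term_semantics <- function(ontology) {
  p <- ontology$term_frequency
  if (is.null(p)) stop("ontology has no term frequencies; run set_term_frequencies() first")
  p <- p[ontology$terms]
  if (any(p <= 0)) {
    stop("term frequency must be positive for all terms; zero at: ",
         paste(utils::head(ontology$terms[p <= 0], 5), collapse = ", "))
  }
  if (any(p > 1)) stop("term frequency must be <= 1")
  ic <- -log(p)
  sw <- ifelse(ic == 0, 1, 1 / (1 + exp(-1 / ic)))
  names(sw) <- ontology$terms
  sv <- vapply(ontology$terms,
               function(t) sum(sw[ontology$ancestors[[t]]]), numeric(1))
  structure(
    list(sw = sw, sv = sv, ancestors = ontology$ancestors,
         table = tibble::tibble(term = ontology$terms, p = unname(p),
                                ic = unname(ic), sw = unname(sw),
                                sv = unname(sv))),
    class = "ssmoc_semantics"
  )
}

#' Semantic similarity between two ontology terms
#'
#' sim(t1, t2) = 2 * sum of SW over the shared ancestors of t1 and t2,
#' divided by SV(t1) + SV(t2). Symmetric, in \[0, 1\], and 1 for t1 == t2.
#'
#' @param sem An `ssmoc_semantics` object.
#' @param t1,t2 Term identifiers.
#' @return Similarity in \[0, 1\].
#' @export
term_similarity <- function(sem, t1, t2) {
  for (t in c(t1, t2)) {
    if (is.null(sem$ancestors[[t]])) stop("unknown term: ", t)
  }
  shared <- intersect(sem$ancestors[[t1]], sem$ancestors[[t2]])
  2 * sum(sem$sw[shared]) / (sem$sv[[t1]] + sem$sv[[t2]])
}

#' Functional similarity between two genes from their annotations
#'
#' Best-match average over the two annotation sets: each term of one gene is
#' matched to its most similar term of the other gene, the matches are
#' summed in both directions and divided by the total number of annotations.
#'
#' @param sem An `ssmoc_semantics` object.
#' @param anno Annotation tibble (`gene_id`, `term_id`).
#' @param g1,g2 Gene identifiers; both must carry at least one annotation.
#' @return Similarity in \[0, 1\].
#' @export
gene_similarity <- function(sem, anno, g1, g2) {
  t1 <- anno$term_id[anno$gene_id == g1]
  t2 <- anno$term_id[anno$gene_id == g2]
  if (length(t1) == 0L) stop("gene '", g1, "' is unannotated")
  if (length(t2) == 0L) stop("gene '", g2, "' is unannotated")
  simmat <- outer(t1, t2, Vectorize(function(a, b) term_similarity(sem, a, b)))
  (sum(apply(simmat, 1, max)) + sum(apply(simmat, 2, max))) /
    (length(t1) + length(t2))
}

#' Pairwise gene functional similarity for all annotated genes
#'
#' @param sem An `ssmoc_semantics` object.
#' @param anno Annotation tibble.
#' @param genes Optional subset of gene ids to consider.
#' @return Tibble `gene_a`, `gene_b`, `sim` over all unordered pairs of
#'   annotated genes (canonical order `gene_a < gene_b`).
#' @export
gene_similarity_all <- function(sem, anno, genes = NULL) {
  if (!is.null(genes)) anno <- anno[anno$gene_id %in% genes, ]
  per_gene <- split(anno$term_id, anno$gene_id)
  ids <- names(per_gene)
  n <- length(ids)
  if (n < 2L) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          sim = numeric()))
  }
  # precompute the term-term similarity over the terms actually used
  used <- unique(anno$term_id)
  tsim <- matrix(0, length(used), length(used), dimnames = list(used, used))
  for (i in seq_along(used)) {
    for (j in i:length(used)) {
      s <- term_similarity(sem, used[i], used[j])
      tsim[i, j] <- s
      tsim[j, i] <- s
    }
  }
  idx <- utils::combn(n, 2)
  sims <- vapply(seq_len(ncol(idx)), function(c) {
    t1 <- per_gene[[idx[1, c]]]
    t2 <- per_gene[[idx[2, c]]]
    sm <- tsim[t1, t2, drop = FALSE]
    (sum(apply(sm, 1, max)) + sum(apply(sm, 2, max))) /
      (length(t1) + length(t2))
  }, numeric(1))
  a <- ids[idx[1, ]]
  b <- ids[idx[2, ]]
  tibble::tibble(gene_a = pmin(a, b), gene_b = pmax(a, b), sim = sims)
}

#' Mine ontology-derived pairwise constraints
#'
#' Over all pairs of annotated genes, functional similarity strictly above
#' `hi` yields a must-link constraint and strictly below `lo` a cannot-link
#' constraint; intermediate pairs yield nothing. Unannotated genes
#' contribute no pairs.
#'
#' @param sem An `ssmoc_semantics` object.
#' @param anno Annotation tibble.
#' @param hi,lo Similarity thresholds, defaults 0.9 and 0.1.
#' @param genes Optional subset of gene ids.
#' @return Constraint tibble with `source = "ontology"`.
#' @export
go_constraints <- function(sem, anno, hi = 0.9, lo = 0.1, genes = NULL) {
  stopifnot(lo >= 0, hi <= 1, lo < hi)
  sims <- gene_similarity_all(sem, anno, genes)
  ml <- sims[sims$sim > hi, ]
  cl <- sims[sims$sim < lo, ]
  constraint_set(
    gene_a = c(ml$gene_a, cl$gene_a),
    gene_b = c(ml$gene_b, cl$gene_b),
    kind = c(rep("ML", nrow(ml)), rep("CL", nrow(cl))),
    source = "ontology"
  )
}
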