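#' Silhouette index of a crisp clustering
#'
#' For each gene, a(i) is the mean Euclidean distance to the other members
#' of its cluster and b(i) the smallest mean distance to any other cluster;
#' the silhouette width is S(i) = (b - a) / max(a, b). Members of singleton
#' clusters get width 0 (the width is undefined there). The index SI is the
#' mean width, in \[-1, 1\]; larger means tighter, better-separated
#' clusters.
#'
#' @param expr Expression tibble.
#' @param labels Integer cluster labels, one per gene.
#' @return A tibble with one row per gene (`gene_id`, `label`, `width`),
#'   carrying the scalar index as attribute `si` (also returned by
#'   [silhouette_index()]'s companion accessor `attr(x, "si")`).
#' @export
silhouette_widths <- function(expr, labels) {
  X <- expr_values(expr)
  n <- nrow(X)
  stopifnot(length(labels) == n)
  cl <- unique(labels)
  if (length(cl) < 2L) stop("silhouette needs at least 2 non-empty clusters")
  D <- as.matrix(stats::dist(X))
  sizes <- table(factor(labels, levels = cl))
  # mean distance from each gene to each cluster
  M <- vapply(cl, function(g) rowSums(D[, labels == g, drop = FALSE]),
              numeric(n))
  colnames(M) <- as.character(cl)
  widths <- vapply(seq_len(n), function(i) {
    g <- as.character(labels[i])
    m <- sizes[[g]]
    if (m == 1L) return(0)
    a <- M[i, g] / (m - 1)
    others <- setdiff(as.character(cl), g)
    b <- min(M[i, others] / as.numeric(sizes[others]))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  out <- tibble::tibble(gene_id = expr$gene_id, label = labels,
                        width = widths)
  attr(out, "si") <- mean(widths)
  out
}

#' @rdname silhouette_widths
#' @return `silhouette_index()` returns the scalar mean width.
#' @export
silhouette_index <- function(expr, labels) {
  attr(silhouette_widths(expr, labels), "si")
}

#' Select the final solution from a Pareto front by silhouette
#'
#' Every front member's crisp labelling is scored by silhouette index; the
#' best one wins. Ties break toward lower Xie-Beni, then lower penalized
#' objective. Members whose crisp labelling collapses to a single cluster
#' are skipped (no silhouette is defined for them).
#'
#' @param fit An `mscc_fit` (or a bare list of individuals with `U` and
#'   `fitness` fields).
#' @param expr Expression tibble the fit was computed on.
#' @return List with `labels`, `si`, `widths` tibble, and `index` of the
#'   chosen front member, or `NULL` if no member yields >= 2 clusters.
#' @export
select_final_solution <- function(fit, expr) {
  front <- if (inherits(fit, "mscc_fit")) fit$front else fit
  if (length(front) == 0L) stop("empty Pareto front")
  scored <- lapply(seq_along(front), function(i) {
    labels <- crisp_assignment(front[[i]]$U)
    if (length(unique(labels)) < 2L) return(NULL)
    w <- silhouette_widths(expr, labels)
    list(index = i, labels = labels, si = attr(w, "si"), widths = w,
         fitness = front[[i]]$fitness)
  })
  scored <- scored[!vapply(scored, is.null, logical(1))]
  if (length(scored) == 0L) return(NULL)
  si <- vapply(scored, `[[`, numeric(1), "si")
  xb <- vapply(scored, function(s) s$fitness[[1]], numeric(1))
  jp <- vapply(scored, function(s) s$fitness[[2]], numeric(1))
  best <- order(-si, xb, jp)[1]
  scored[[best]]
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement computed from the contingency
#' table; 1 for identical partitions (up to label names), about 0 for
#' independent ones.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Scalar ARI (<= 1).
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("labelings differ in length")
  }
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(labels_a))
  expected <- sum_a * sum_b / n2
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}

#' Fraction of constraints consistent with ground-truth labels
#'
#' A must-link pair is consistent when both genes share a true label, a
#' cannot-link pair when they differ.
#'
#' @param cs Constraint tibble.
#' @param labels Named vector (names = gene ids) of true labels.
#' @return Proportion in \[0, 1\] (`NaN` for an empty set).
#' @export
constraint_consistency <- function(cs, labels) {
  if (nrow(cs) == 0L) return(NaN)
  same <- labels[cs$gene_a] == labels[cs$gene_b]
  mean(ifelse(cs$kind == "ML", same, !same))
}
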