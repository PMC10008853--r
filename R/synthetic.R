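#' Simulate a labeled Gaussian expression matrix
#'
#' Generates k isotropic Gaussian clusters in d dimensions whose means are
#' at pairwise distance >= `separation * sigma`, then min-max normalizes
#' the columns. Genes are assigned to clusters in a balanced round-robin,
#' so every cluster holds floor(n/k) or ceiling(n/k) genes.
#'
#' @param n Number of genes (>= k).
#' @param d Number of features.
#' @param k Number of clusters.
#' @param separation Minimum distance between cluster means, in units of
#'   the within-cluster standard deviation.
#' @param sigma Within-cluster standard deviation.
#' @param seed Optional integer seed.
#' @return List: `expr` (normalized expression tibble), `labels` (named
#'   integer vector in 1..k), `means` (k x d matrix, pre-normalization).
#' @export
simulate_expression <- function(n = 200, d = 10, k = 4, separation = 6,
                                sigma = 1, seed = NULL) {
  stopifnot(n >= k, separation > 0, sigma > 0)
  if (!is.null(seed)) set.seed(seed)
  mu <- matrix(stats::rnorm(k * d), k, d)
  if (k > 1) {
    min_gap <- min(stats::dist(mu))
    mu <- mu * (separation * sigma / min_gap)
  }
  labels <- rep(seq_len(k), length.out = n)
  X <- mu[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * d, sd = sigma), n, d)
  rownames(X) <- sprintf("g%03d", seq_len(n))
  names(labels) <- rownames(X)
  expr <- normalize_minmax(as_expression(X))
  list(expr = expr, labels = labels, means = mu)
}

#' Simulate an ontology concordant with cluster labels
#'
#' Builds a small DAG: one root, one branch term per cluster, and several
#' leaf terms under each branch. Each gene is annotated to 2-4 terms drawn
#' from its own cluster's branch; a fraction `annotation_noise` of genes is
#' instead annotated within another cluster's branch. Term frequencies are
#' computed from the generated annotations, so the ontology is ready for
#' [term_semantics()].
#'
#' @param labels Named integer vector of true cluster labels (names = gene
#'   ids).
#' @param leaves_per_branch Leaf terms under each cluster branch (>= 3).
#' @param annotation_noise Fraction of genes annotated to a wrong branch.
#' @param seed Optional integer seed.
#' @return List: `ontology` (with frequencies set), `annotations` tibble.
#' @export
simulate_ontology <- function(labels, leaves_per_branch = 4,
                              annotation_noise = 0, seed = NULL) {
  stopifnot(leaves_per_branch >= 3, annotation_noise >= 0,
            annotation_noise <= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- max(labels)
  branches <- sprintf("T:%02d", seq_len(k))
  leaves <- lapply(seq_len(k), function(c) {
    sprintf("T:%02d.%02d", c, seq_len(leaves_per_branch))
  })
  terms <- c("T:root", branches, unlist(leaves))
  edges <- tibble::tibble(
    child = c(branches, unlist(leaves)),
    parent = c(rep("T:root", k),
               rep(branches, each = leaves_per_branch))
  )
  onto <- ontology_graph(terms, edges)

  genes <- names(labels)
  n_noisy <- round(annotation_noise * length(genes))
  noisy <- if (n_noisy > 0) sample(genes, n_noisy) else character(0)
  anno <- purrr::map_dfr(genes, function(g) {
    cl <- labels[[g]]
    if (g %in% noisy && k > 1) {
      cl <- sample(setdiff(seq_len(k), cl), 1)
    }
    branch_terms <- c(branches[cl], leaves[[cl]])
    m <- sample(2:4, 1)
    tibble::tibble(gene_id = g,
                   term_id = sample(branch_terms, min(m, length(branch_terms))))
  })
  # every leaf must be annotated at least once so IC is defined everywhere
  unused <- setdiff(unlist(leaves), anno$term_id)
  if (length(unused) > 0L) {
    extra <- purrr::map_dfr(unused, function(t) {
      cl <- match(sub("\\..*$", "", t), branches)
      pool_genes <- genes[labels == cl]
      if (length(pool_genes) == 0L) pool_genes <- genes
      tibble::tibble(gene_id = sample(pool_genes, 1), term_id = t)
    })
    anno <- dplyr::bind_rows(anno, extra)
  }
  anno <- as_annotations(anno, onto)
  list(ontology = set_term_frequencies(onto, anno), annotations = anno)
}

#' Simulate a label-consistent pairwise constraint set
#'
#' Draws `n_ml` distinct within-cluster pairs (must-link) and `n_cl`
#' distinct between-cluster pairs (cannot-link) uniformly from the ground
#' truth. Combine with [inject_constraint_noise()] for a controlled
#' fraction of label-inconsistent constraints.
#'
#' @param labels Named integer vector of true cluster labels.
#' @param n_ml,n_cl Number of must-link / cannot-link constraints.
#' @param source Source tag to stamp on the records.
#' @param seed Optional integer seed.
#' @return Constraint tibble, fully consistent with `labels`.
#' @export
simulate_constraints <- function(labels, n_ml = 10, n_cl = 10,
                                 source = "expression", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- names(labels)
  draw <- function(n_want, want_same) {
    keys <- character(0)
    a <- character(0); b <- character(0)
    guard <- 0
    while (length(a) < n_want) {
      guard <- guard + 1
      if (guard > 1000 * n_want) stop("cannot draw enough distinct pairs")
      p <- sample(genes, 2)
      if ((labels[[p[1]]] == labels[[p[2]]]) != want_same) next
      k <- pair_key(p[1], p[2])
      if (k %in% keys) next
      keys <- c(keys, k)
      a <- c(a, p[1]); b <- c(b, p[2])
    }
    list(a = a, b = b)
  }
  ml <- draw(n_ml, TRUE)
  cl <- draw(n_cl, FALSE)
  constraint_set(c(ml$a, cl$a), c(ml$b, cl$b),
                 rep(c("ML", "CL"), c(n_ml, n_cl)), source)
}

#' Replace a fraction of constraints with label-inconsistent ones
#'
#' Exactly `round(rate * nrow(cs))` constraints (chosen at random) are
#' replaced: a replaced must-link pair spans two different true clusters, a
#' replaced cannot-link pair stays within one. Kind and source tags are
#' preserved, so the noisy set is indistinguishable from the clean one
#' without the labels.
#'
#' @param cs Constraint tibble.
#' @param labels Named integer vector of true labels.
#' @param rate Fraction in \[0, 1\] to corrupt.
#' @param seed Optional integer seed.
#' @return Constraint tibble of the same size.
#' @export
inject_constraint_noise <- function(cs, labels, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(cs)
  n_bad <- round(rate * m)
  if (n_bad == 0L) return(cs)
  genes <- names(labels)
  idx <- sample.int(m, n_bad)
  keys <- pair_key(cs$gene_a, cs$gene_b)
  for (i in idx) {
    repeat {
      a <- sample(genes, 1)
      b <- sample(genes, 1)
      if (a == b) next
      if (pair_key(a, b) %in% keys) next   # keep the set size exact
      same <- labels[[a]] == labels[[b]]
      ok <- if (cs$kind[i] == "ML") !same else same
      if (ok) break
    }
    cs$gene_a[i] <- min(a, b)
    cs$gene_b[i] <- max(a, b)
    keys[i] <- pair_key(a, b)
  }
  constraint_set(cs$gene_a, cs$gene_b, cs$kind, cs$source)
}
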