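# shared fixture builders; all data built in code at test time

expr_from <- function(M, normalized = TRUE) {
  if (is.null(rownames(M))) rownames(M) <- paste0("g", seq_len(nrow(M)))
  as_expression(M, normalized = normalized)
}

# a 5-term DAG: root r with children a, b; a with children c, d
tiny_dag <- function() {
  ontology_graph(
    c("r", "a", "b", "c", "d"),
    tibble::tibble(child = c("a", "b", "c", "d"),
                   parent = c("r", "r", "a", "a"))
  )
}

# random DAG: term i (i >= 2) gets 1-2 parents among terms 1..(i-1)
random_dag <- function(n_terms, seed) {
  set.seed(seed)
  terms <- paste0("t", seq_len(n_terms))
  child <- character(); parent <- character()
  for (i in 2:n_terms) {
    np <- sample(1:2, 1)
    ps <- sample(seq_len(i - 1), min(np, i - 1))
    child <- c(child, rep(terms[i], length(ps)))
    parent <- c(parent, terms[ps])
  }
  onto <- ontology_graph(terms, tibble::tibble(child = child, parent = parent))
  # count-based frequencies from random annotations covering every term
  genes <- paste0("g", 1:12)
  anno <- tibble::tibble(
    gene_id = c(rep(genes, each = 2), sample(genes, n_terms, replace = TRUE)),
    term_id = c(sample(terms, 24, replace = TRUE), terms)
  )
  onto <- set_term_frequencies(onto, anno)
  list(ontology = onto, annotations = dplyr::distinct(anno))
}

# independent ancestor-set oracle for term similarity (brute-force DFS)
brute_ancestors <- function(onto, t) {
  res <- character()
  stack <- t
  while (length(stack) > 0L) {
    cur <- stack[1]
    stack <- stack[-1]
    if (cur %in% res) next
    res <- c(res, cur)
    stack <- c(stack, onto$parents[[cur]])
  }
  sort(res)
}

brute_sim_aic <- function(onto, sem, t1, t2) {
  sw <- function(t) {
    ic <- -log(onto$term_frequency[[t]])
    if (ic == 0) 1 else 1 / (1 + exp(-1 / ic))
  }
  sv <- function(t) sum(vapply(brute_ancestors(onto, t), sw, numeric(1)))
  shared <- intersect(brute_ancestors(onto, t1), brute_ancestors(onto, t2))
  2 * sum(vapply(shared, sw, numeric(1))) / (sv(t1) + sv(t2))
}

# O(N^2) dominance-based rank oracle (minimization, both objectives)
brute_ranks <- function(fit) {
  n <- nrow(fit)
  dominates <- function(i, j) {
    all(fit[i, ] <= fit[j, ]) && any(fit[i, ] < fit[j, ])
  }
  rank <- integer(n)
  left <- seq_len(n)
  r <- 0L
  while (length(left) > 0L) {
    r <- r + 1L
    nd <- left[vapply(left, function(j) {
      !any(vapply(left, function(i) i != j && dominates(i, j), logical(1)))
    }, logical(1))]
    rank[nd] <- r
    left <- setdiff(left, nd)
  }
  rank
}

write_temp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

pair_keys <- function(tb) paste(tb$gene_a, tb$gene_b)
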