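#' Density-tracking model of an expression matrix
#'
#' Computes, for every gene: its local density (reciprocal of the distance
#' to the farthest of its `b` nearest neighbours), its density chain (the
#' path obtained by repeatedly stepping to the closest neighbour of strictly
#' greater density within the current gene's b-neighbourhood), the chain
#' endpoint, the density group (chains sharing an endpoint form one group),
#' the centrality (number of chains, one per gene, in which the gene
#' appears — a gene's own chain counts), the chain centrality (sum of member
#' centralities along the gene's chain), and the impurity
#'
#'   Impurity(x) = (1 - sum_g p_g^2) * (1 - Density(x) / Density(endpoint)),
#'
#' where p_g is the fraction of the (b+1)-point neighbourhood
#' S = \{x\} U N_b(x) lying in group g. High impurity marks sparse genes on
#' group boundaries; chain endpoints and group-pure neighbourhoods score 0.
#'
#' @param expr Expression tibble (normalized recommended).
#' @param b Neighbourhood size, 1 <= b <= n-1.
#' @return An `ssmoc_density` object with a per-gene `tbl`
#'   (`gene_id`, `density`, `endpoint`, `group`, `centrality`,
#'   `chain_centrality`, `impurity`), the chains (integer index vectors),
#'   the neighbour lists, and the distance matrix.
#' @export
density_model <- function(expr, b = 10) {
  X <- expr_values(expr)
  n <- nrow(X)
  stopifnot(b >= 1, b <= n - 1)
  D <- as.matrix(stats::dist(X))
  dup <- which(D == 0 & upper.tri(D), arr.ind = TRUE)
  if (nrow(dup) > 0L) {
    stop("coincident genes: '", rownames(X)[dup[1, 1]], "' and '",
         rownames(X)[dup[1, 2]], "'")
  }
  # b nearest neighbours; ties broken by lowest index (order() is stable)
  nb <- lapply(seq_len(n), function(i) {
    ord <- order(D[i, -i])  # indices into 1..n-1 skipping i
    cand <- seq_len(n)[-i]
    cand[ord][seq_len(b)]
  })
  dens <- vapply(seq_len(n), function(i) 1 / max(D[i, nb[[i]]]), numeric(1))

  # successor: closest in-neighbourhood gene of strictly greater density
  succ <- vapply(seq_len(n), function(i) {
    cand <- nb[[i]][dens[nb[[i]]] > dens[i]]
    if (length(cand) == 0L) return(NA_integer_)
    cand[order(D[i, cand], cand)[1]]
  }, integer(1))

  chains <- lapply(seq_len(n), function(i) {
    path <- i
    while (!is.na(succ[path[length(path)]])) {
      nxt <- succ[path[length(path)]]
      if (nxt %in% path) stop("density chain cycle detected")  # cannot happen: density strictly increases
      path <- c(path, nxt)
    }
    path
  })
  endpoint <- vapply(chains, function(p) p[length(p)], integer(1))
  group <- match(endpoint, sort(unique(endpoint)))
  centrality <- tabulate(unlist(chains), nbins = n)
  chain_centrality <- vapply(chains, function(p) sum(centrality[p]), numeric(1))

  impurity <- vapply(seq_len(n), function(i) {
    S <- c(i, nb[[i]])
    pg <- tabulate(group[S], nbins = max(group)) / (b + 1)
    gini <- 1 - sum(pg^2)
    ratio <- dens[i] / dens[endpoint[i]]
    min(max(gini * (1 - ratio), 0), 1)
  }, numeric(1))

  structure(
    list(
      tbl = tibble::tibble(
        gene_id = rownames(X), density = dens, endpoint = endpoint,
        group = group, centrality = centrality,
        chain_centrality = chain_centrality, impurity = impurity
      ),
      chains = chains, neighbors = nb, dist = D, b = b
    ),
    class = "ssmoc_density"
  )
}

#' @export
print.ssmoc_density <- function(x, ...) {
  cat("density-tracking model:", nrow(x$tbl), "genes, b =", x$b, ",",
      length(unique(x$tbl$group)), "density group(s)\n")
  invisible(x)
}

#' Mine expression-derived pairwise constraints by density tracking
#'
#' Three passes over the density model build the constraint set:
#' \enumerate{
#'   \item Cannot-link: genes in descending impurity order are paired with
#'     their nearest gene outside their own density group, until `n_cl`
#'     pairs are collected or candidates are exhausted.
#'   \item Must-link (boundary): genes in descending impurity order are
#'     paired with their chain successor x_j whenever
#'     Density(x_j) >= epsilon * Density(endpoint).
#'   \item Must-link (skeleton): chains in descending chain-centrality order
#'     are walked from their start with step `stride`, pairing consecutive
#'     visited genes.
#' }
#' Passes 2 and 3 share the `n_ml` quota (pass 2 first). Duplicates are
#' emitted once; a pair already emitted as cannot-link is never re-emitted
#' as must-link. Ties in any ordering break toward the lowest gene index.
#'
#' @param model An `ssmoc_density` model.
#' @param epsilon Density drop rate (> 0), default 0.8.
#' @param n_cl,n_ml Quotas; default `max(10, floor(n / 20))` each.
#' @param stride Skeleton sampling interval (>= 1), default 2.
#' @return Constraint tibble with `source = "expression"`. When only one
#'   density group exists the cannot-link part is empty and a warning is
#'   raised.
#' @export
expression_constraints <- function(model, epsilon = 0.8,
                                   n_cl = NULL, n_ml = NULL, stride = 2) {
  stopifnot(inherits(model, "ssmoc_density"), epsilon > 0, stride >= 1)
  tbl <- model$tbl
  n <- nrow(tbl)
  if (is.null(n_cl)) n_cl <- max(10L, floor(n / 20))
  if (is.null(n_ml)) n_ml <- max(10L, floor(n / 20))
  stopifnot(n_cl >= 0, n_ml >= 0)
  ids <- tbl$gene_id
  D <- model$dist
  imp_order <- order(-tbl$impurity, seq_len(n))

  seen <- character()
  cl_a <- integer(); cl_b <- integer()
  if (length(unique(tbl$group)) < 2L) {
    warning("single density group: cannot-link set is empty")
  } else {
    for (i in imp_order) {
      if (length(cl_a) >= n_cl) break
      out <- which(tbl$group != tbl$group[i])
      j <- out[order(D[i, out], out)[1]]
      key <- pair_key(ids[i], ids[j])
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        cl_a <- c(cl_a, i); cl_b <- c(cl_b, j)
      }
    }
  }

  ml_a <- integer(); ml_b <- integer()
  add_ml <- function(i, j) {
    key <- pair_key(ids[i], ids[j])
    if (!(key %in% seen)) {
      seen <<- c(seen, key)
      ml_a <<- c(ml_a, i); ml_b <<- c(ml_b, j)
    }
  }
  # pass 2: boundary must-links along chains
  succ1 <- vapply(model$chains, function(p) {
    if (length(p) >= 2L) p[2] else NA_integer_
  }, integer(1))
  for (i in imp_order) {
    if (length(ml_a) >= n_ml) break
    j <- succ1[i]
    if (is.na(j)) next
    e <- tbl$endpoint[i]
    if (tbl$density[j] >= epsilon * tbl$density[e]) add_ml(i, j)
  }
  # pass 3: skeleton must-links, chains by descending chain centrality
  if (length(ml_a) < n_ml) {
    for (i in order(-tbl$chain_centrality, seq_len(n))) {
      if (length(ml_a) >= n_ml) break
      p <- model$chains[[i]]
      pos <- seq(1, length(p), by = stride)
      if (length(pos) < 2L) next
      for (t in seq_len(length(pos) - 1L)) {
        if (length(ml_a) >= n_ml) break
        add_ml(p[pos[t]], p[pos[t + 1L]])
      }
    }
  }

  constraint_set(
    gene_a = ids[c(ml_a, cl_a)],
    gene_b = ids[c(ml_b, cl_b)],
    kind = c(rep("ML", length(ml_a)), rep("CL", length(cl_a))),
    source = "expression"
  )
}
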