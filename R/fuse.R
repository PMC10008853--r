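#' Fuse expression and ontology constraints into penalty weights
#'
#' Agreement between the two sources strengthens a constraint, silence of
#' the ontology weakens it, and contradiction removes the pair entirely.
#' With GO action parameter theta > 0, a pair present in the expression
#' must-link set gets weight `1 + theta` if the ontology must-link set
#' agrees and `1 - theta` otherwise; a pair in the expression cannot-link
#' set gets `-(1 + theta)` with ontology agreement and `-(1 - theta)`
#' without. A pair whose two sources disagree (ML vs CL) is contradictory:
#' it is deleted from both sets and carries weight 0. Ontology-only pairs
#' remain selectable but carry weight 0.
#'
#' @param omega Expression constraint tibble (`source = "expression"`).
#' @param omega_star Ontology constraint tibble (`source = "ontology"`).
#' @param theta GO action parameter, > 0. Values in (0, 1) keep must-link
#'   weights positive and cannot-link weights negative; theta >= 1 is
#'   allowed with a warning.
#' @param gene_ids Character vector fixing the gene universe and matrix
#'   order.
#' @return An `ssmoc_weights` object: `pairs` (tibble `gene_a`, `gene_b`,
#'   `kind`, `source`, `w` over the pruned union), `removed` (contradictory
#'   pairs), `theta`, `gene_ids`.
#' @export
fuse_constraints <- function(omega, omega_star, theta, gene_ids) {
  if (theta <= 0) stop("theta must be > 0")
  if (theta >= 1) warning("theta >= 1 flips the sign of unconfirmed weights")
  omega <- constraint_set(omega$gene_a, omega$gene_b, omega$kind, omega$source)
  omega_star <- constraint_set(omega_star$gene_a, omega_star$gene_b,
                               omega_star$kind, omega_star$source)
  stopifnot(all(omega$source == "expression"),
            all(omega_star$source == "ontology"))
  unknown <- setdiff(c(omega$gene_a, omega$gene_b,
                       omega_star$gene_a, omega_star$gene_b), gene_ids)
  if (length(unknown) > 0L) {
    stop("constraint gene(s) not in gene_ids: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }

  key_e <- pair_key(omega$gene_a, omega$gene_b)
  key_o <- pair_key(omega_star$gene_a, omega_star$gene_b)
  kind_o <- stats::setNames(omega_star$kind, key_o)

  star_kind <- kind_o[key_e]                      # NA when ontology is silent
  contradictory <- !is.na(star_kind) & star_kind != omega$kind
  confirmed <- !is.na(star_kind) & star_kind == omega$kind

  w <- unname(ifelse(omega$kind == "ML", 1, -1) *
                ifelse(confirmed, 1 + theta, 1 - theta))
  w[contradictory] <- 0

  removed <- omega[contradictory, ]
  kept_e <- omega[!contradictory, ]
  kept_e$w <- w[!contradictory]
  kept_o <- omega_star[!(key_o %in% key_e[contradictory]) &
                         !(key_o %in% key_e), ]
  if (nrow(kept_o) > 0L) kept_o$w <- 0

  structure(
    list(pairs = dplyr::bind_rows(kept_e, kept_o),
         removed = removed, theta = theta, gene_ids = gene_ids),
    class = "ssmoc_weights"
  )
}

#' Dense/sparse penalty-weight matrix from fused constraints
#'
#' @param fw An `ssmoc_weights` object (or its `pairs` subset).
#' @param pairs Optional subset of `fw$pairs` rows to include (defaults to
#'   all); used to restrict the matrix to an individual's selected
#'   constraints.
#' @return Sparse symmetric n x n `Matrix::dgCMatrix` with zero diagonal.
#' @export
weight_matrix <- function(fw, pairs = NULL) {
  if (is.null(pairs)) pairs <- fw$pairs
  ids <- fw$gene_ids
  n <- length(ids)
  pairs <- pairs[pairs$w != 0, , drop = FALSE]
  i <- match(pairs$gene_a, ids)
  j <- match(pairs$gene_b, ids)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = rep(pairs$w, 2),
                       dims = c(n, n))
}

#' @export
print.ssmoc_weights <- function(x, ...) {
  cat("fused constraint weights: theta =", x$theta, "\n")
  print(dplyr::count(x$pairs, .data$kind, .data$source, .data$w))
  if (nrow(x$removed) > 0L) {
    cat(nrow(x$removed), "contradictory pair(s) removed\n")
  }
  invisible(x)
}
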