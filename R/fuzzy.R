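#' Constrained quadratic-regularized fuzzy membership update
#'
#' Memberships combine three parts: the uniform share 1/k, a data-driven
#' deviation proportional to how much closer the gene is to prototype c than
#' to the average prototype, and a constraint-driven deviation that pulls
#' membership rows of positively-weighted (must-link) pairs together and
#' pushes negatively-weighted (cannot-link) pairs apart:
#'
#'   u_ic     = 1/k + (1/eta) uFCM_ic + beta uP_ic
#'   uFCM_ic  = (1/k) sum_f (d_if^2 - d_ic^2)
#'   uP_ic    = sum_j w_ij u_jc - (1/k) sum_f sum_j w_ij u_jf
#'
#' The constraint part depends on U itself, so it is iterated as a fixed
#' point starting from uP = 0 until the largest membership change falls
#' below `tol` or `passes` sweeps are done. Both deviation parts sum to zero
#' over clusters, so every row of U sums to exactly 1 analytically;
#' memberships are deliberately not clipped (small eta makes them signed)
#' and crisp labels use the row argmax.
#'
#' @param X Numeric matrix n x d (genes in rows, values in \[0, 1\]).
#' @param V Numeric matrix k x d of cluster prototypes.
#' @param W Sparse/dense n x n symmetric penalty-weight matrix, or `NULL`
#'   for the unconstrained update.
#' @param eta Fuzziness parameter (> 0), default 0.001.
#' @param beta Constraint-penalty parameter (>= 0), default 0.1.
#' @param passes Maximum fixed-point sweeps, default 10.
#' @param tol Convergence tolerance on max |change|, default 1e-6.
#' @return Membership matrix U (n x k), rows summing to 1.
#' @export
update_memberships <- function(X, V, W = NULL, eta = 0.001, beta = 0.1,
                               passes = 10, tol = 1e-6) {
  stopifnot(eta > 0, beta >= 0)
  k <- nrow(V)
  n <- nrow(X)
  d2 <- sq_dist(X, V)                       # n x k squared distances
  ufcm <- rowMeans(d2) - d2
  base <- 1 / k + ufcm / eta
  U <- base
  if (is.null(W) || beta == 0 || k == 1L) {
    if (k == 1L) U <- matrix(1, n, 1)
    return(U)
  }
  for (pass in seq_len(passes)) {
    WU <- as.matrix(W %*% U)
    uP <- WU - rowMeans(WU)
    Unew <- base + beta * uP
    if (max(abs(Unew - U)) < tol) {
      U <- Unew
      break
    }
    U <- Unew
  }
  U
}

#' Recompute cluster prototypes from memberships
#'
#' v_c is the membership-weighted mean of the data, clamped to \[0, 1\]. A
#' cluster with zero total membership keeps its incoming prototype.
#'
#' The quadratic-regularized update leaves memberships unclipped, so rows
#' can carry negative entries; the prototype step uses the positive part
#' of U (the active-set projection standard for quadratic-regularized
#' c-means). For non-negative memberships — every crisp or classical fuzzy
#' partition — this is exactly the weighted mean.
#'
#' @param U Membership matrix n x k (entries may be signed).
#' @param X Data matrix n x d.
#' @param V_old Incoming prototypes, used for zero-mass clusters.
#' @return Prototype matrix k x d in \[0, 1\].
#' @export
recompute_prototypes <- function(U, X, V_old = NULL) {
  Up <- pmax(U, 0)
  mass <- colSums(Up)
  zero <- mass < 1e-12
  mass[zero] <- 1
  V <- crossprod(Up, X) / mass
  if (any(zero)) {
    if (is.null(V_old)) stop("zero membership mass and no incoming prototype")
    V[zero, ] <- V_old[zero, ]
  }
  pmin(pmax(V, 0), 1)
}

#' Xie-Beni cluster validity index
#'
#' Ratio of the fuzzy within-cluster scatter sum_c sum_i u_ic^2 d_ic^2 to
#' n times the minimum squared distance between two prototypes. Smaller is
#' better. Coincident prototypes make the index degenerate and return
#' `Inf` so the evolutionary search discards such solutions.
#'
#' @param U Membership matrix n x k (k >= 2).
#' @param V Prototype matrix k x d.
#' @param X Data matrix n x d.
#' @return Non-negative scalar, possibly `Inf`.
#' @export
objective_xb <- function(U, V, X) {
  stopifnot(nrow(V) >= 2L)
  sep <- min(stats::dist(V))^2
  if (sep == 0) return(Inf)
  sum(U^2 * sq_dist(X, V)) / (nrow(X) * sep)
}

#' Penalized quadratic-regularized fuzzy c-means objective
#'
#' J = sum_c sum_i u_ic d_ic^2 + (eta/2) sum u^2
#'     - (beta/2) sum_ij w_ij <u_i, u_j>,
#' the last term rewarding agreement of membership rows across must-link
#' pairs (w > 0) and disagreement across cannot-link pairs (w < 0).
#'
#' @inheritParams update_memberships
#' @param U Membership matrix n x k.
#' @return Scalar objective value (minimized).
#' @export
objective_jp <- function(U, V, X, W = NULL, eta = 0.001, beta = 0.1) {
  j <- sum(U * sq_dist(X, V)) + eta / 2 * sum(U^2)
  if (!is.null(W) && beta > 0) {
    j <- j - beta / 2 * sum(as.matrix(W %*% U) * U)
  }
  j
}

#' Crisp labels from a membership matrix
#'
#' @param U Membership matrix n x k (entries may be signed).
#' @return Integer labels in 1..k; ties go to the lowest cluster index.
#' @export
crisp_assignment <- function(U) {
  max.col(U, ties.method = "first")
}

# squared Euclidean distances between rows of X (n x d) and V (k x d)
sq_dist <- function(X, V) {
  d2 <- outer(rowSums(X^2), rowSums(V^2), "+") - 2 * tcrossprod(X, V)
  pmax(d2, 0)
}
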