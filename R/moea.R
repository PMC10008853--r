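#' Density-peak cluster prototypes
#'
#' Ranks genes by the product of local density (rho, reciprocal of the
#' distance to the farthest of the b nearest neighbours) and delta, the
#' distance to the nearest gene of higher density (for the global density
#' maximum, the largest pairwise distance). The k top-ranked genes serve as
#' initial cluster prototypes.
#'
#' @param expr Expression tibble.
#' @param k Number of prototypes, k <= n.
#' @param b Neighbourhood size for the density estimate.
#' @return k x d matrix of prototypes (rows are gene value vectors).
#' @export
density_peak_centers <- function(expr, k, b = 10) {
  X <- expr_values(expr)
  n <- nrow(X)
  if (k > n) stop("k (", k, ") exceeds the number of genes (", n, ")")
  model <- density_model(expr, b = min(b, n - 1))
  rho <- model$tbl$density
  D <- model$dist
  delta <- vapply(seq_len(n), function(i) {
    higher <- which(rho > rho[i])
    if (length(higher) == 0L) max(D) else min(D[i, higher])
  }, numeric(1))
  top <- order(-(rho * delta), seq_len(n))[seq_len(k)]
  X[top, , drop = FALSE]
}

#' Default run configuration
#'
#' Bundles the evolutionary and clustering parameters with their standard
#' values: density drop rate `epsilon = 0.8`, neighbourhood `b = 10`,
#' fuzziness `eta = 0.001`, penalty `beta = 0.1`, population `n_pop = 100`,
#' generations `n_gen = 300`, selection pressure `alpha = 0.3`, mutation
#' distribution index `eta_m = 5`, crossover probability `p_c = 0.8`,
#' mutation probability `p_m = 0.1`, GO action parameter `theta = 0.5`.
#'
#' @param k Number of clusters (required downstream).
#' @param s Number of constraints each individual selects.
#' @param ... Overrides for any listed field.
#' @return A named list of parameters.
#' @export
run_config <- function(k = NULL, s = 15, ...) {
  cfg <- list(k = k, s = s, epsilon = 0.8, b = 10, eta = 0.001, beta = 0.1,
              n_pop = 100, n_gen = 300, alpha = 0.3, eta_m = 5,
              p_c = 0.8, p_m = 0.1, theta = 0.5, seed = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Initialize the mixed-encoding population
#'
#' Half the individuals (rounded up) carry the density-peak prototypes, the
#' rest uniform-random prototypes in \[0, 1\]; every individual draws s
#' distinct constraint indices uniformly from the 2s-element candidate
#' pool.
#'
#' @param expr Expression tibble.
#' @param k Cluster count.
#' @param s Constraints selected per individual (0 disables selection).
#' @param n_pop Population size.
#' @param b Neighbourhood size for the density-peak half.
#' @return List of chromosomes, each `list(V = k x d matrix, sel = integer s)`.
#' @export
initialize_population <- function(expr, k, s, n_pop, b = 10) {
  X <- expr_values(expr)
  d <- ncol(X)
  n_dp <- ceiling(n_pop / 2)
  Vdp <- density_peak_centers(expr, k, b)
  lapply(seq_len(n_pop), function(r) {
    V <- if (r <= n_dp) Vdp else matrix(stats::runif(k * d), k, d)
    sel <- if (s > 0) sort(sample.int(2L * s, s)) else integer(0)
    list(V = V, sel = sel)
  })
}

#' Non-dominated sorting with crowding distances
#'
#' Both objectives are minimized. Rank 1 holds the individuals dominated by
#' no one; rank r+1 those dominated only by ranks <= r. Crowding distance
#' is the usual per-front normalized objective gap, with boundary points at
#' `Inf`.
#'
#' @param fitness Numeric matrix N x 2 (columns: the two objectives).
#' @return List with integer `rank` and numeric `crowding` (length N).
#' @export
nondominated_sort <- function(fitness) {
  N <- nrow(fitness)
  f1 <- fitness[, 1]; f2 <- fitness[, 2]
  le1 <- outer(f1, f1, "<="); le2 <- outer(f2, f2, "<=")
  lt1 <- outer(f1, f1, "<");  lt2 <- outer(f2, f2, "<")
  dom <- le1 & le2 & (lt1 | lt2)        # dom[i, j]: i dominates j
  rank <- integer(N)
  remaining <- rep(TRUE, N)
  r <- 0L
  while (any(remaining)) {
    r <- r + 1L
    idx <- which(remaining)
    nd <- idx[colSums(dom[idx, idx, drop = FALSE]) == 0L]
    rank[nd] <- r
    remaining[nd] <- FALSE
  }
  crowding <- numeric(N)
  for (fr in unique(rank)) {
    idx <- which(rank == fr)
    m <- length(idx)
    if (m <= 2L) {
      crowding[idx] <- Inf
      next
    }
    cd <- numeric(m)
    for (o in 1:2) {
      v <- fitness[idx, o]
      v[!is.finite(v)] <- if (any(is.finite(v))) max(v[is.finite(v)]) + 1 else 1
      ord <- order(v)
      cd[ord[1]] <- cd[ord[m]] <- Inf
      rng <- v[ord[m]] - v[ord[1]]
      if (rng > 0) {
        inner <- 2:(m - 1)
        cd[ord[inner]] <- cd[ord[inner]] + (v[ord[inner + 1]] - v[ord[inner - 1]]) / rng
      }
    }
    crowding[idx] <- cd
  }
  list(rank = rank, crowding = crowding)
}

#' Rank-based roulette-wheel parent selection
#'
#' An individual of non-domination rank r receives unnormalized score
#' alpha * (1 - alpha)^(r - 1); sampling uses the scores normalized over
#' the population, so equal ranks mean uniform sampling.
#'
#' @param rank Integer vector of non-domination ranks.
#' @param alpha Selection parameter in (0, 1).
#' @param n_draws Number of parents to draw (with replacement).
#' @return Integer indices of the selected parents.
#' @export
roulette_select <- function(rank, alpha = 0.3, n_draws = 1) {
  stopifnot(alpha > 0, alpha < 1)
  score <- alpha * (1 - alpha)^(rank - 1)
  sample.int(length(rank), n_draws, replace = TRUE, prob = score / sum(score))
}

#' Normal-distribution crossover for prototype blocks
#'
#' Per coordinate, one |N(0,1)| draw z is shared by the two offspring:
#' off1 = mid + 1.481 |a - b|/2 z, off2 = mid - 1.481 |a - b|/2 z, with
#' mid = (a + b)/2; offspring are clamped to \[0, 1\]. Before clamping
#' off1 + off2 = a + b exactly.
#'
#' @param a,b Parent prototype matrices (k x d).
#' @param clamp Clamp offspring to \[0, 1\] (the search space); `FALSE`
#'   exposes the raw symmetric construction.
#' @return List of two offspring matrices.
#' @export
crossover_prototypes <- function(a, b, clamp = TRUE) {
  z <- abs(matrix(stats::rnorm(length(a)), nrow(a), ncol(a)))
  mid <- (a + b) / 2
  spread <- 1.481 * abs(a - b) / 2 * z
  off <- list(mid + spread, mid - spread)
  if (clamp) off <- lapply(off, function(m) pmin(pmax(m, 0), 1))
  off
}

#' Single-point crossover for constraint-selection blocks
#'
#' Tails after a uniform cut point in \[1, s\] are swapped; any duplicate
#' index so introduced is replaced by a uniform draw from the pool indices
#' \[1, 2s\] not yet present in the offspring.
#'
#' @param a,b Parent selection blocks (s distinct integers in 1..2s).
#' @param two_s Candidate-pool size 2s.
#' @param cut Optional fixed cut point in 1..s (drawn uniformly when `NULL`).
#' @return List of two offspring blocks.
#' @export
crossover_selection <- function(a, b, two_s, cut = NULL) {
  s <- length(a)
  if (s == 0L) return(list(a, b))
  if (is.null(cut)) cut <- sample.int(s, 1)
  off1 <- c(a[seq_len(cut)], if (cut < s) b[(cut + 1):s])
  off2 <- c(b[seq_len(cut)], if (cut < s) a[(cut + 1):s])
  list(repair_selection(off1, two_s), repair_selection(off2, two_s))
}

repair_selection <- function(sel, two_s) {
  dup <- duplicated(sel)
  if (any(dup)) {
    unused <- setdiff(seq_len(two_s), sel)
    repl <- if (length(unused) == 1L) unused else sample(unused, sum(dup))
    sel[dup] <- repl
  }
  sel
}

#' Polynomial mutation for prototype blocks
#'
#' Each site mutates independently with probability p_m. With bounds
#' \[0, 1\] and distribution index eta_m, a uniform draw r gives
#' perturbation delta = (2r + (1 - 2r)(1 - v)^(eta_m+1))^(1/(eta_m+1)) - 1
#' for r < 0.5 and delta = 1 - (2(1 - r) + 2(r - 0.5) v^(eta_m+1))^(1/(eta_m+1))
#' otherwise; the new value v + delta is clamped to \[0, 1\].
#'
#' @param V Prototype matrix.
#' @param p_m Per-site mutation probability.
#' @param eta_m Distribution index (larger = smaller perturbations).
#' @return Mutated prototype matrix.
#' @export
mutate_prototypes <- function(V, p_m = 0.1, eta_m = 5) {
  hit <- stats::runif(length(V)) < p_m
  if (any(hit)) {
    v <- V[hit]
    r <- stats::runif(sum(hit))
    V[hit] <- pmin(pmax(v + polynomial_delta(r, v, eta_m), 0), 1)
  }
  V
}

# Eq.-style polynomial-mutation perturbation on [0, 1]-bounded sites
polynomial_delta <- function(r, v, eta_m) {
  e <- eta_m + 1
  lower <- (2 * r + (1 - 2 * r) * (1 - v)^e)^(1 / e) - 1
  upper <- 1 - (2 * (1 - r) + 2 * (r - 0.5) * v^e)^(1 / e)
  ifelse(r < 0.5, lower, upper)
}

#' Random mutation for constraint-selection blocks
#'
#' With probability p_m one uniformly chosen position is replaced by a
#' uniform draw from the pool indices not already present.
#'
#' @param sel Selection block (distinct integers in 1..2s).
#' @param p_m Mutation probability (per individual).
#' @param two_s Candidate-pool size 2s.
#' @return Mutated selection block.
#' @export
mutate_selection <- function(sel, p_m = 0.1, two_s = 2 * length(sel)) {
  s <- length(sel)
  if (s == 0L || stats::runif(1) >= p_m) return(sel)
  pos <- if (s == 1L) 1L else sample.int(s, 1)
  unused <- setdiff(seq_len(two_s), sel)
  if (length(unused) == 0L) return(sel)
  sel[pos] <- if (length(unused) == 1L) unused else sample(unused, 1)
  sel
}

# fitness of one chromosome: constrained membership update, one Lamarckian
# prototype write-back, then (XB, J_P) on the consistent (U, V) pair
evaluate_chromosome <- function(chrom, X, fw, pool, cfg, beta, restrict = TRUE) {
  W <- NULL
  if (!is.null(pool) && nrow(pool) > 0L) {
    active <- if (restrict) pool[chrom$sel, , drop = FALSE] else pool
    W <- weight_matrix(fw, active)
  }
  U <- update_memberships(X, chrom$V, W, eta = cfg$eta, beta = beta)
  V <- recompute_prototypes(U, X, chrom$V)
  chrom$V <- V
  chrom$fitness <- c(xb = objective_xb(U, V, X),
                     jp = objective_jp(U, V, X, W, eta = cfg$eta, beta = beta))
  chrom$U <- U
  chrom
}

#' Multi-objective semi-supervised clustering with constraint selection
#'
#' Co-optimizes k cluster prototypes and the choice of s active pairwise
#' constraints under NSGA-II, minimizing the Xie-Beni index and the
#' penalized quadratic-regularized fuzzy c-means objective. Each individual
#' is a mixed chromosome (real prototype block + integer constraint-index
#' block into a candidate pool of 2s fused constraints); only an
#' individual's selected constraints contribute penalty weights to its own
#' fitness, which is the mechanism by which noisy constraints can be
#' evolved away. Parents and offspring are merged each generation and the
#' best N survive by (rank, crowding); the penalty parameter beta doubles
#' at generations ceil(0.5 L) and ceil(0.8 L). With `s = 0` the penalty
#' term is identically zero and the run reduces to unsupervised
#' two-objective fuzzy clustering.
#'
#' @param expr Normalized expression tibble (values in \[0, 1\]).
#' @param k Number of clusters.
#' @param fused `ssmoc_weights` from [fuse_constraints()] (required when
#'   `s > 0`).
#' @param s Number of constraints each individual activates; the candidate
#'   pool holds 2s.
#' @param pool Optional explicit candidate pool (2s rows of `fused$pairs`);
#'   drawn uniformly without replacement from `fused$pairs` when `NULL`.
#' @param restrict If `FALSE`, every individual is evaluated with all 2s
#'   pool constraints active (selection disabled), for ablation runs.
#' @param seed Integer seed driving all randomness; `NULL` leaves the RNG
#'   state alone.
#' @param ... [run_config()] overrides (`n_pop`, `n_gen`, `eta`, `beta`,
#'   `alpha`, `p_c`, `p_m`, `eta_m`, `b`, ...).
#' @return An `mscc_fit` object: `front` (list of rank-1 individuals with
#'   prototypes, selected constraint indices and fitness), `best` (the
#'   silhouette-selected final solution: `labels`, `si`, `index`), `pool`,
#'   `config`, and the input `expr`.
#' @seealso [select_final_solution()], [tidy.mscc_fit()], [autoplot.mscc_fit()]
#' @export
mscc <- function(expr, k, fused = NULL, s = 15, pool = NULL,
                 restrict = TRUE, seed = NULL, ...) {
  cfg <- run_config(k = k, s = s, seed = seed, ...)
  if (!is_normalized(expr)) {
    warning("expression data not flagged as normalized; prototypes assume [0, 1]")
  }
  X <- expr_values(expr)
  if (!is.null(seed)) set.seed(seed)
  if (s > 0) {
    if (is.null(fused)) stop("s > 0 requires fused constraint weights")
    if (is.null(pool)) {
      if (nrow(fused$pairs) < 2 * s) {
        stop("candidate pool needs 2s = ", 2 * s, " constraints but only ",
             nrow(fused$pairs), " are available; reduce s")
      }
      pool <- fused$pairs[sample.int(nrow(fused$pairs), 2 * s), ]
    }
    if (nrow(pool) != 2 * s) stop("pool must hold exactly 2s constraints")
  } else {
    pool <- NULL
  }

  pop <- initialize_population(expr, k, s, cfg$n_pop, cfg$b)
  beta_cur <- cfg$beta
  double_at <- unique(c(ceiling(0.5 * cfg$n_gen), ceiling(0.8 * cfg$n_gen)))
  evaluate_all <- function(chroms) {
    lapply(chroms, function(ch) {
      evaluate_chromosome(ch, X = X, fw = fused, pool = pool,
                          cfg = cfg, beta = beta_cur, restrict = restrict)
    })
  }
  pop <- evaluate_all(pop)

  for (l in seq_len(cfg$n_gen)) {
    fit <- do.call(rbind, lapply(pop, `[[`, "fitness"))
    rk <- nondominated_sort(fit)
    offspring <- vector("list", 0)
    while (length(offspring) < cfg$n_pop) {
      pr <- roulette_select(rk$rank, cfg$alpha, 2)
      c1 <- pop[[pr[1]]]; c2 <- pop[[pr[2]]]
      if (stats::runif(1) < cfg$p_c) {
        vs <- crossover_prototypes(c1$V, c2$V)
        ss <- crossover_selection(c1$sel, c2$sel, 2L * s)
        o1 <- list(V = vs[[1]], sel = ss[[1]])
        o2 <- list(V = vs[[2]], sel = ss[[2]])
      } else {
        o1 <- list(V = c1$V, sel = c1$sel)
        o2 <- list(V = c2$V, sel = c2$sel)
      }
      for (o in list(o1, o2)) {
        o$V <- mutate_prototypes(o$V, cfg$p_m, cfg$eta_m)
        o$sel <- mutate_selection(o$sel, cfg$p_m, 2L * s)
        offspring[[length(offspring) + 1L]] <- o
      }
    }
    offspring <- evaluate_all(offspring[seq_len(cfg$n_pop)])

    merged <- c(pop, offspring)
    mfit <- do.call(rbind, lapply(merged, `[[`, "fitness"))
    mrk <- nondominated_sort(mfit)
    keep <- order(mrk$rank, -mrk$crowding)[seq_len(cfg$n_pop)]
    pop <- merged[keep]

    if (l %in% double_at) {
      beta_cur <- 2 * beta_cur
      pop <- evaluate_all(pop)   # fitness must reflect the new penalty scale
    }
  }

  fit <- do.call(rbind, lapply(pop, `[[`, "fitness"))
  rk <- nondominated_sort(fit)
  front <- pop[rk$rank == 1L]
  out <- structure(
    list(front = front, pool = pool, config = cfg, beta_final = beta_cur,
         expr = expr, restrict = restrict),
    class = "mscc_fit"
  )
  out$best <- select_final_solution(out, expr)
  out
}

#' @export
print.mscc_fit <- function(x, ...) {
  cat("multi-objective semi-supervised clustering fit\n")
  cat("  k =", x$config$k, ", s =", x$config$s,
      ", population", x$config$n_pop, "x", x$config$n_gen, "generations\n")
  cat("  Pareto front:", length(x$front), "solution(s)\n")
  if (!is.null(x$best)) {
    cat("  selected solution: SI =", format(x$best$si, digits = 4), "\n")
  }
  invisible(x)
}
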