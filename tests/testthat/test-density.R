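test_that("density is the reciprocal b-neighbourhood radius", {
  ex <- expr_from(matrix(c(0, 5), ncol = 1))
  m <- density_model(ex, b = 1)
  expect_equal(m$tbl$density, c(0.2, 0.2))

  ex3 <- expr_from(matrix(c(0, 1, 3), ncol = 1))
  m3 <- density_model(ex3, b = 2)
  expect_equal(m3$tbl$density, c(1 / 3, 1 / 2, 1 / 3))
})

test_that("coincident genes are reported by name", {
  ex <- expr_from(matrix(c(1, 1, 3, 1, 1, 4), ncol = 2,
                         dimnames = list(c("gA", "gB", "gC"), NULL)))
  expect_error(density_model(ex, b = 1), "gA.*gB")
})

test_that("chains, groups and centrality match hand enumeration", {
  # collinear 0, 1, 3 with b = 2: middle gene is the density peak
  m <- density_model(expr_from(matrix(c(0, 1, 3), ncol = 1)), b = 2)
  expect_equal(m$chains, list(c(1L, 2L), 2L, c(3L, 2L)))
  expect_equal(m$tbl$endpoint, c(2L, 2L, 2L))
  expect_equal(length(unique(m$tbl$group)), 1L)
  expect_equal(m$tbl$centrality, c(1L, 3L, 1L))
  expect_equal(m$tbl$chain_centrality, c(4, 3, 4))
})

test_that("well-separated tight blobs form one group each", {
  set.seed(7)
  blob <- function(center, n) {
    matrix(rep(center, each = n), n, 2) + matrix(rnorm(2 * n, sd = 0.01), n, 2)
  }
  M <- rbind(blob(c(0, 0), 6), blob(c(10, 10), 6))
  m <- density_model(expr_from(M), b = 3)
  grp <- m$tbl$group
  expect_equal(length(unique(grp)), 2L)
  expect_equal(length(unique(grp[1:6])), 1L)
  expect_equal(length(unique(grp[7:12])), 1L)
})

test_that("chain density increases strictly and endpoints are local maxima", {
  set.seed(11)
  ex <- expr_from(matrix(runif(40 * 3), 40, 3))
  m <- density_model(ex, b = 6)
  dens <- m$tbl$density
  for (i in seq_len(40)) {
    path <- m$chains[[i]]
    if (length(path) > 1) {
      expect_true(all(diff(dens[path]) > 0))
    }
    e <- path[length(path)]
    expect_true(all(dens[m$neighbors[[e]]] <= dens[e]))
  }
})

test_that("impurity matches a direct evaluation of its definition", {
  set.seed(13)
  ex <- expr_from(matrix(runif(30 * 2), 30, 2))
  b <- 5
  m <- density_model(ex, b = b)
  dens <- m$tbl$density; grp <- m$tbl$group; endp <- m$tbl$endpoint
  for (i in seq_len(30)) {
    S <- c(i, m$neighbors[[i]])
    pg <- table(grp[S]) / (b + 1)
    want <- (1 - sum(pg^2)) * (1 - dens[i] / dens[endp[i]])
    expect_equal(m$tbl$impurity[i], min(max(want, 0), 1))
  }
  # endpoints are pure by the density-ratio factor
  ends <- unique(endp)
  expect_equal(m$tbl$impurity[ends], rep(0, length(ends)))
})

test_that("single density group yields an empty cannot-link set", {
  m <- density_model(expr_from(matrix(c(0, 1, 3), ncol = 1)), b = 2)
  expect_warning(cs <- expression_constraints(m, n_cl = 5, n_ml = 0),
                 "single density group")
  expect_equal(nrow(cs), 0L)
})

test_that("skeleton pass pairs chain members at the stride interval", {
  # 1-D chain a -> b -> c with d joining at c; epsilon too high for pass 2
  ex <- expr_from(matrix(c(0, 2, 3.2, 4), ncol = 1))
  m <- density_model(ex, b = 2)
  expect_equal(m$chains[[1]], c(1L, 2L, 3L))
  expect_warning(cs <- expression_constraints(m, epsilon = 10, n_ml = 1,
                                              n_cl = 0, stride = 2))
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$kind, "ML")
  expect_setequal(c(cs$gene_a, cs$gene_b), c("g1", "g3"))
})

test_that("boundary must-links respect the density drop rate", {
  ex <- expr_from(matrix(c(0, 2, 3.2, 4), ncol = 1))
  m <- density_model(ex, b = 2)
  # epsilon small: every chain successor qualifies in pass 2
  expect_warning(cs <- expression_constraints(m, epsilon = 1e-6, n_ml = 10,
                                              n_cl = 0, stride = 100))
  succ_pairs <- pair_keys <- paste(cs$gene_a, cs$gene_b)
  expect_true(all(cs$kind == "ML"))
  # (g1,g2), (g2,g3), (g4,g3) are the chain successor steps
  expect_setequal(pair_keys, c("g1 g2", "g2 g3", "g3 g4"))
})

test_that("must-link and cannot-link sets are disjoint, quotas respected", {
  set.seed(17)
  sim <- simulate_expression(n = 60, d = 4, k = 3, separation = 8, seed = 17)
  m <- density_model(sim$expr, b = 6)
  cs <- expression_constraints(m, n_cl = 8, n_ml = 8)
  keys <- paste(cs$gene_a, cs$gene_b)
  expect_equal(anyDuplicated(keys), 0L)
  expect_lte(sum(cs$kind == "ML"), 8L)
  expect_lte(sum(cs$kind == "CL"), 8L)
  # must-links follow chains/skeletons, so they never cross density groups
  grp <- stats::setNames(m$tbl$group, m$tbl$gene_id)
  ml <- cs[cs$kind == "ML", ]
  expect_true(all(grp[ml$gene_a] == grp[ml$gene_b]))
  cl <- cs[cs$kind == "CL", ]
  expect_true(all(grp[cl$gene_a] != grp[cl$gene_b]))
})
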