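test_that("density-peak initialization puts one prototype per blob", {
  set.seed(3)
  blob <- function(center, n, d = 3) {
    matrix(rep(center, each = n), n, d) + matrix(rnorm(n * d, sd = 0.02), n, d)
  }
  M <- rbind(blob(rep(0.2, 3), 8), blob(rep(0.5, 3), 8), blob(rep(0.8, 3), 8))
  ex <- expr_from(M)
  V <- density_peak_centers(ex, k = 3, b = 4)
  which_blob <- function(v) which.min(c(sum((v - 0.2)^2), sum((v - 0.5)^2),
                                        sum((v - 0.8)^2)))
  expect_setequal(apply(V, 1, which_blob), 1:3)
  # k = 1: the globally densest gene
  V1 <- density_peak_centers(ex, k = 1, b = 4)
  m <- density_model(ex, b = 4)
  expect_equal(unname(V1[1, ]), unname(M[which.max(m$tbl$density), ]))
  # n = k returns every gene
  ex4 <- expr_from(matrix(runif(8), 4, 2))
  expect_equal(nrow(density_peak_centers(ex4, k = 4, b = 2)), 4L)
  expect_error(density_peak_centers(ex4, k = 5), "exceeds")
})

test_that("population initialization splits density-peak and random halves", {
  ex <- expr_from(matrix(runif(40), 20, 2))
  set.seed(8)
  pop <- initialize_population(ex, k = 3, s = 4, n_pop = 5, b = 4)
  expect_length(pop, 5L)
  Vdp <- density_peak_centers(ex, 3, 4)
  expect_equal(pop[[1]]$V, Vdp)
  expect_equal(pop[[3]]$V, Vdp)         # ceiling(5/2) = 3 density-peak
  expect_false(isTRUE(all.equal(pop[[4]]$V, Vdp)))
  for (ch in pop) {
    expect_length(ch$sel, 4L)
    expect_equal(anyDuplicated(ch$sel), 0L)
    expect_true(all(ch$sel >= 1 & ch$sel <= 8))
    expect_true(all(ch$V >= 0 & ch$V <= 1))
  }
  set.seed(8)
  pop2 <- initialize_population(ex, k = 3, s = 4, n_pop = 5, b = 4)
  expect_identical(pop, pop2)           # seeded reproducibility
})

test_that("non-dominated sorting matches the brute-force dominance oracle", {
  # trivial structures
  expect_equal(nondominated_sort(matrix(c(1, 1), 1, 2)),
               list(rank = 1L, crowding = Inf))
  chain <- rbind(c(1, 1), c(2, 2), c(3, 3))
  expect_equal(nondominated_sort(chain)$rank, c(1L, 2L, 3L))
  # 200 random fitness pairs, including ties and an Inf sentinel
  set.seed(33)
  fit <- cbind(sample(c(runif(195), rep(0.5, 4), Inf)), runif(200))
  got <- nondominated_sort(fit)
  expect_equal(got$rank, brute_ranks(fit))
  # boundary points of each front carry infinite crowding
  f1 <- which(got$rank == 1)
  expect_true(is.infinite(got$crowding[f1[which.min(fit[f1, 1])]]))
})

test_that("elite survivors retain every rank-1 individual", {
  set.seed(44)
  fit <- cbind(runif(60), runif(60))
  rk <- nondominated_sort(fit)
  keep <- order(rk$rank, -rk$crowding)[1:30]
  r1 <- which(rk$rank == 1)
  if (length(r1) <= 30) expect_true(all(r1 %in% keep))
})

test_that("roulette selection follows the rank-geometric scores", {
  rank <- c(1L, 1L, 2L, 3L)
  alpha <- 0.3
  score <- alpha * (1 - alpha)^(rank - 1)
  expect_equal(score[1] / score[3], 1 / (1 - alpha))
  set.seed(12)
  draws <- roulette_select(rank, alpha, 1e5)
  freq <- tabulate(draws, 4) / 1e5
  p <- score / sum(score)
  sigma <- sqrt(p * (1 - p) / 1e5)
  expect_true(all(abs(freq - p) < 3 * sigma + 1e-4))
  # all ranks equal: uniform
  set.seed(13)
  d2 <- roulette_select(rep(1L, 4), alpha, 1e5)
  expect_true(all(abs(tabulate(d2, 4) / 1e5 - 0.25) < 0.01))
})

test_that("prototype crossover conserves the parent sum pre-clamp", {
  set.seed(21)
  for (trial in 1:25) {
    a <- matrix(runif(6), 2, 3); b <- matrix(runif(6), 2, 3)
    off <- crossover_prototypes(a, b, clamp = FALSE)
    expect_equal(off[[1]] + off[[2]], a + b, tolerance = 1e-12)
  }
  # identical parents reproduce themselves
  off <- crossover_prototypes(a, a)
  expect_equal(off[[1]], a); expect_equal(off[[2]], a)
  # clamped offspring stay in bounds
  offc <- crossover_prototypes(matrix(0.01, 2, 3), matrix(0.99, 2, 3))
  expect_true(all(offc[[1]] >= 0 & offc[[1]] <= 1))
})

test_that("selection crossover swaps tails and repairs duplicates", {
  off <- crossover_selection(c(1L, 2L, 3L), c(3L, 4L, 5L), two_s = 6, cut = 1)
  expect_equal(off[[1]], c(1L, 4L, 5L))
  expect_equal(off[[2]][1:2], c(3L, 2L))
  expect_true(off[[2]][3] %in% c(1L, 4L, 5L, 6L))   # repaired from unused
  expect_equal(anyDuplicated(off[[2]]), 0L)
  # cut at s leaves parents unchanged
  off2 <- crossover_selection(c(1L, 2L), c(3L, 4L), two_s = 4, cut = 2)
  expect_equal(off2, list(c(1L, 2L), c(3L, 4L)))
  set.seed(2)
  for (trial in 1:20) {
    a <- sample(10, 5); b <- sample(10, 5)
    off <- crossover_selection(a, b, two_s = 10)
    for (o in off) {
      expect_equal(anyDuplicated(o), 0L)
      expect_true(all(o >= 1 & o <= 10))
    }
  }
})

test_that("polynomial mutation perturbations stay within one box width", {
  delta <- ssmoc:::polynomial_delta
  expect_equal(delta(0.5, 0.3, 5), 0)               # continuity at r = 0.5
  expect_equal(delta(0, 0.7, 5), -0.7)              # lower branch at r = 0
  expect_equal(delta(1, 0.7, 5), 0.3)               # upper branch at r = 1
  grid <- expand.grid(r = seq(0, 1, length.out = 100),
                      v = seq(0, 1, length.out = 100))
  d <- delta(grid$r, grid$v, 5)
  expect_true(all(d >= -1 - 1e-12 & d <= 1 + 1e-12))
  expect_true(all(grid$v + d >= -1e-12 & grid$v + d <= 1 + 1e-12))
})

test_that("selection mutation replaces one site with an unused index", {
  set.seed(31)
  expect_equal(mutate_selection(c(1L, 3L), p_m = 0, two_s = 4), c(1L, 3L))
  got <- mutate_selection(1L, p_m = 1, two_s = 2)
  expect_equal(got, 2L)                              # only unused value
  for (trial in 1:20) {
    sel <- sample(8, 4)
    out <- mutate_selection(sel, p_m = 1, two_s = 8)
    expect_equal(anyDuplicated(out), 0L)
    expect_true(all(out >= 1 & out <= 8))
    expect_equal(sum(out != sel), 1L)                # exactly one site changed
  }
})

test_that("short evolutionary runs are reproducible and respect invariants", {
  sim <- simulate_expression(n = 40, d = 3, k = 2, separation = 8, seed = 2)
  cs <- simulate_constraints(sim$labels, 4, 4, seed = 3)
  fused <- fuse_constraints(cs, constraint_set(), 0.5, sim$expr$gene_id)
  fit1 <- mscc(sim$expr, k = 2, fused = fused, s = 4, seed = 9,
               n_pop = 10, n_gen = 8, beta = 0.1)
  fit2 <- mscc(sim$expr, k = 2, fused = fused, s = 4, seed = 9,
               n_pop = 10, n_gen = 8, beta = 0.1)
  expect_identical(lapply(fit1$front, `[[`, "fitness"),
                   lapply(fit2$front, `[[`, "fitness"))
  expect_identical(fit1$best$labels, fit2$best$labels)
  # beta doubled at 0.5 and 0.8 of the run
  expect_equal(fit1$beta_final, 0.4)
  for (ch in fit1$front) {
    expect_true(all(ch$V >= 0 & ch$V <= 1))
    expect_equal(anyDuplicated(ch$sel), 0L)
    expect_true(all(ch$sel >= 1 & ch$sel <= 8))
  }
  # the front is mutually non-dominating
  ffit <- do.call(rbind, lapply(fit1$front, `[[`, "fitness"))
  expect_true(all(nondominated_sort(ffit)$rank == 1L))
})
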