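# independent triple-loop oracles for the two objectives
xb_brute <- function(U, V, X) {
  n <- nrow(X); k <- nrow(V)
  num <- 0
  for (c in 1:k) for (i in 1:n) {
    num <- num + U[i, c]^2 * sum((X[i, ] - V[c, ])^2)
  }
  sep <- Inf
  for (c in 1:k) for (f in 1:k) {
    if (f != c) sep <- min(sep, sum((V[f, ] - V[c, ])^2))
  }
  num / (n * sep)
}

jp_brute <- function(U, V, X, W, eta, beta) {
  n <- nrow(X); k <- nrow(V)
  j <- 0
  for (c in 1:k) for (i in 1:n) {
    j <- j + U[i, c] * sum((X[i, ] - V[c, ])^2) + eta / 2 * U[i, c]^2
  }
  for (i in 1:n) for (jj in 1:n) {
    j <- j - beta / 2 * W[i, jj] * sum(U[i, ] * U[jj, ])
  }
  j
}

rand_weights <- function(n, m, seed) {
  set.seed(seed)
  W <- matrix(0, n, n)
  for (r in seq_len(m)) {
    ij <- sample(n, 2)
    w <- sample(c(-1.4, -0.6, 0.6, 1.4), 1)
    W[ij[1], ij[2]] <- W[ij[2], ij[1]] <- w
  }
  W
}

test_that("membership rows always sum to one and deviations to zero", {
  set.seed(5)
  for (trial in 1:20) {
    n <- sample(5:30, 1); d <- sample(2:6, 1); k <- sample(2:5, 1)
    X <- matrix(runif(n * d), n, d)
    V <- matrix(runif(k * d), k, d)
    W <- rand_weights(n, 8, trial)
    U <- update_memberships(X, V, W, eta = 0.01, beta = 0.05)
    expect_equal(rowSums(U), rep(1, n), tolerance = 1e-9)
    # the two deviation parts each sum to zero over clusters
    d2 <- ssmoc:::sq_dist(X, V)
    ufcm <- rowMeans(d2) - d2
    expect_equal(rowSums(ufcm), rep(0, n), tolerance = 1e-9)
    WU <- W %*% U
    uP <- WU - rowMeans(WU)
    expect_equal(rowSums(uP), rep(0, n), tolerance = 1e-9)
  }
})

test_that("degenerate membership cases reduce to the uniform share", {
  X <- matrix(c(0.1, 0.9, 0.4), ncol = 1)
  # k = 1: all mass on the single cluster
  expect_equal(update_memberships(X, matrix(0.5), NULL), matrix(1, 3, 1))
  # equidistant prototypes, no constraints: exactly 1/k
  Xe <- matrix(c(0.5, 0.5), 1, 2)
  Ve <- rbind(c(0.4, 0.5), c(0.6, 0.5), c(0.5, 0.4))
  U <- update_memberships(Xe, Ve, NULL, eta = 0.001)
  expect_equal(U, matrix(1 / 3, 1, 3))
})

test_that("beta is inert without constraints", {
  set.seed(9)
  X <- matrix(runif(20), 10, 2)
  V <- matrix(runif(6), 3, 2)
  U1 <- update_memberships(X, V, NULL, eta = 0.01, beta = 0)
  U2 <- update_memberships(X, V, matrix(0, 10, 10), eta = 0.01, beta = 7)
  expect_equal(U1, U2)
})

test_that("prototypes are membership-weighted means with guard rails", {
  X <- matrix(c(0, 1), ncol = 1)
  # crisp memberships: per-cluster means
  Uc <- rbind(c(1, 0), c(0, 1))
  expect_equal(recompute_prototypes(Uc, X), rbind(0, 1), ignore_attr = TRUE)
  # uniform memberships: every prototype at the global mean
  Uu <- matrix(0.5, 2, 2)
  expect_equal(recompute_prototypes(Uu, X), rbind(0.5, 0.5),
               ignore_attr = TRUE)
  # weighted mean example
  Uw <- matrix(c(0.75, 0.25), 2, 1)
  expect_equal(recompute_prototypes(Uw, X)[1, 1], 0.25)
  # zero column mass keeps the incoming prototype
  Uz <- rbind(c(1, 0), c(1, 0))
  V_old <- rbind(0.5, 0.77)
  expect_equal(recompute_prototypes(Uz, X, V_old)[2, 1], 0.77)
})

test_that("objectives match brute-force evaluation to 1e-12", {
  set.seed(21)
  for (trial in 1:20) {
    n <- sample(4:15, 1); d <- sample(1:4, 1); k <- sample(2:4, 1)
    X <- matrix(runif(n * d), n, d)
    V <- matrix(runif(k * d), k, d)
    U <- matrix(rnorm(n * k), n, k)
    W <- rand_weights(n, 5, trial + 50)
    eta <- runif(1, 0.001, 0.1); beta <- runif(1, 0, 0.5)
    expect_equal(objective_xb(U, V, X), xb_brute(U, V, X),
                 tolerance = 1e-12)
    expect_equal(objective_jp(U, V, X, W, eta, beta),
                 jp_brute(U, V, X, W, eta, beta), tolerance = 1e-12)
  }
})

test_that("degenerate objective cases behave as specified", {
  X <- rbind(c(0, 0), c(1, 1))
  V <- rbind(c(0, 0), c(1, 1))
  Uc <- diag(2)
  expect_equal(objective_xb(Uc, V, X), 0)          # points at prototypes
  expect_equal(objective_jp(Uc, V, X, NULL, eta = 0.4, beta = 0),
               0.4 / 2 * 2)                        # only the regularizer
  Vdup <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(objective_xb(Uc, Vdup, X), Inf)     # coincident prototypes
  # beta = 0 makes J_P independent of W
  W <- rand_weights(2, 2, 1)
  expect_equal(objective_jp(Uc, V, X, W, 0.4, 0),
               objective_jp(Uc, V, X, NULL, 0.4, 0))
})

test_that("the penalty rewards satisfied must-links", {
  X <- matrix(c(0.1, 0.12, 0.9, 0.88), ncol = 1)
  V <- matrix(c(0.11, 0.89), ncol = 1)
  W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- 1.4   # ML between genes 1, 2
  U_ok <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  U_bad2 <- U_ok; U_bad2[2, ] <- c(0, 1)   # membership rows swapped: ML violated
  expect_lt(objective_jp(U_ok, V, X, W, 0.001, 0.5),
            objective_jp(U_bad2, V, X, W, 0.001, 0.5))
})

test_that("crisp assignment takes the row argmax with low-index ties", {
  U <- rbind(c(0.2, 0.8), c(0.5, 0.5), c(1.2, -0.2))
  expect_equal(crisp_assignment(U), c(2L, 1L, 1L))
})
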