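test_that("category probabilities match the model definition", {
  # logistic symmetry at theta = beta
  expect_equal(gpcm_prob(0, 0, 1), c("0" = 0.5, "1" = 0.5))
  # all cumulative logits zero -> uniform, regardless of discrimination
  expect_equal(unname(gpcm_prob(0, c(0, 0), 7.3)), rep(1 / 3, 3))
  # dichotomous upper-category probability is the logistic function
  expect_equal(unname(gpcm_prob(1, 0, 1)[2]), 1 / (1 + exp(-1)),
               tolerance = 1e-12)

  # randomized parameters against the naive formula
  set.seed(42)
  for (r in 1:25) {
    m <- sample(1:5, 1)
    theta <- rnorm(1, sd = 2)
    beta <- rnorm(m)
    alpha <- exp(rnorm(1, sd = 0.7))
    expect_equal(unname(gpcm_prob(theta, beta, alpha)),
                 naive_gpcm_prob(theta, beta, alpha), tolerance = 1e-12)
  }
})

test_that("probabilities normalize, stay positive, and survive extreme logits", {
  set.seed(7)
  for (r in 1:30) {
    m <- sample(1:6, 1)
    p <- gpcm_prob(rnorm(1, sd = 3), rnorm(m, sd = 2), exp(rnorm(1)))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
  }
  # overflow-scale logits: alpha * (theta - beta) ~ 1e3
  p <- gpcm_prob(30, c(-30, -30), 20)
  expect_false(any(is.nan(p)))
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("with one threshold and unit discrimination the model is the Rasch model", {
  theta <- seq(-3, 3, by = 0.5)
  beta <- 0.7
  p <- gpcm_prob(theta, beta, 1)
  expect_equal(unname(p[, 2]), plogis(theta - beta), tolerance = 1e-12)
})

test_that("top-category probability increases strictly with ability", {
  theta <- seq(-4, 4, length.out = 40)
  for (alpha in c(0.3, 1, 2.5)) {
    p_top <- gpcm_prob(theta, c(-1, 0.5, 1.2), alpha)[, 4]
    expect_true(all(diff(p_top) > 0))
  }
})

test_that("invalid probability inputs are rejected", {
  expect_error(gpcm_prob(NA, 0, 1), "non-finite")
  expect_error(gpcm_prob(0, c(0, Inf), 1), "non-finite")
  expect_error(gpcm_prob(0, 0, -1), "positive")
  expect_error(gpcm_prob(0, numeric(0), 1), "threshold")
})

test_that("itemset log likelihood sums per-cell log probabilities", {
  # single dichotomous cell at theta = beta
  r1 <- response_matrix(matrix(c(1L, 0L), ncol = 1), n_categories = 2)
  expect_equal(gpcm_loglik(r1, 1, c(0, 0), list(0), 1), 2 * log(0.5),
               tolerance = 1e-12)
  # empty itemset is an empty sum
  expect_identical(gpcm_loglik(r1, integer(0), c(0, 0), list(0), 1), 0)

  # 3 x 2 instance with missing cells against the brute-force oracle
  x <- matrix(c(0L, 2L, 1L, NA, 1L, 0L), nrow = 3)
  resp <- response_matrix(x, n_categories = c(3, 2))
  theta <- c(-0.5, 0.2, 1.1)
  beta <- list(c(-0.3, 0.4), 0.1)
  alpha <- c(0.8, 1.4)
  expect_equal(gpcm_loglik(resp, 1:2, theta, beta, alpha),
               naive_loglik(resp$values, 1:2, theta, beta, alpha),
               tolerance = 1e-10)
  expect_lt(gpcm_loglik(resp, 1:2, theta, beta, alpha), 0)
  expect_error(gpcm_loglik(resp, 5, theta, beta, alpha), "out of range")
})

test_that("penalized objective subtracts the ridge terms", {
  s <- tiny_sim(N = 10, P = 3, seed = 5)
  ll <- gpcm_loglik(s$responses, 1:3, s$theta, s$beta, s$alpha)
  # unit discriminations and zero abilities: penalties vanish
  th0 <- rep(0, 10)
  expect_equal(gpcm_objective(s$responses, 1:3, th0, s$beta, rep(1, 3),
                              0.05, 50),
               gpcm_loglik(s$responses, 1:3, th0, s$beta, rep(1, 3)))
  # theta = (1, -1, 0, ...) with lambda_theta = .05 subtracts exactly 0.1
  th <- c(1, -1, rep(0, 8))
  expect_equal(gpcm_objective(s$responses, 1:3, th, s$beta, rep(1, 3),
                              0.05, 50),
               gpcm_loglik(s$responses, 1:3, th, s$beta, rep(1, 3)) - 0.1,
               tolerance = 1e-12)
  # random instance: recompute both penalty terms independently
  expect_equal(gpcm_objective(s$responses, 1:3, s$theta, s$beta, s$alpha,
                              0.07, 3),
               ll - 0.07 * sum(s$theta^2) - 3 * sum(log(s$alpha)^2),
               tolerance = 1e-10)
  # excluded-set convention drops the ability ridge
  expect_equal(gpcm_objective(s$responses, 1:3, s$theta, s$beta, s$alpha,
                              0.07, 3, penalize_theta = FALSE),
               ll - 3 * sum(log(s$alpha)^2), tolerance = 1e-10)
})

test_that("analytic gradient matches central finite differences", {
  s <- tiny_sim(N = 5, P = 3, m = 3, seed = 11)
  N <- 5
  mlen <- lengths(s$beta)
  pack <- function(theta, beta, alpha) c(theta, unlist(beta), log(alpha))
  unpack <- function(par) {
    theta <- par[1:N]
    beta <- split(par[N + seq_len(sum(mlen))], rep(seq_along(mlen), mlen))
    alpha <- exp(par[N + sum(mlen) + seq_along(mlen)])
    list(theta = theta, beta = beta, alpha = alpha)
  }
  f <- function(par) {
    u <- unpack(par)
    gpcm_objective(s$responses, 1:3, u$theta, u$beta, u$alpha, 0.05, 2)
  }
  p0 <- pack(s$theta, s$beta, s$alpha)
  g <- gpcm_gradient(s$responses, 1:3, s$theta, s$beta, s$alpha, 0.05, 2)
  expect_lt(max(abs(c(g$theta, unlist(g$beta), g$log_alpha) -
                      fd_gradient(f, p0))), 1e-5)

  # fixed-theta mode: no theta block, FD over item parameters only
  g2 <- gpcm_gradient(s$responses, 1:3, s$theta, s$beta, s$alpha, 0.05, 2,
                      penalize_theta = FALSE,
                      free_blocks = c("beta", "log_alpha"))
  expect_null(g2$theta)
  f2 <- function(par) {
    u <- unpack(c(s$theta, par))
    gpcm_objective(s$responses, 1:3, s$theta, u$beta, u$alpha, 0.05, 2,
                   penalize_theta = FALSE)
  }
  expect_lt(max(abs(c(unlist(g2$beta), g2$log_alpha) -
                      fd_gradient(f2, p0[-(1:N)]))), 1e-5)
})

test_that("theta gradient respects subject relabeling", {
  s <- tiny_sim(N = 6, P = 2, seed = 13)
  g <- gpcm_gradient(s$responses, 1:2, s$theta, s$beta, s$alpha, 0.05, 2)
  perm <- c(3, 1, 2, 6, 4, 5)
  rp <- response_matrix(s$responses$values[perm, ],
                        n_categories = lengths(s$beta) + 1L)
  gp <- gpcm_gradient(rp, 1:2, s$theta[perm], s$beta, s$alpha, 0.05, 2)
  expect_equal(gp$theta, g$theta[perm], tolerance = 1e-12)
})

test_that("expected score and variance are the distribution moments", {
  # Bernoulli(1/2) at theta = beta
  mom <- gpcm_moments(0, 0, 1)
  expect_equal(mom$E, 0.5)
  expect_equal(mom$W, 0.25)
  # three equiprobable categories: uniform moments
  mom3 <- gpcm_moments(0, c(0, 0), 2)
  expect_equal(mom3$E, 1, tolerance = 1e-12)
  expect_equal(mom3$W, 2 / 3, tolerance = 1e-12)
  # random parameters against direct enumeration
  set.seed(3)
  for (r in 1:10) {
    beta <- rnorm(3); alpha <- exp(rnorm(1)); theta <- rnorm(1)
    p <- naive_gpcm_prob(theta, beta, alpha)
    mom <- gpcm_moments(theta, beta, alpha)
    expect_equal(mom$E, sum((0:3) * p), tolerance = 1e-10)
    expect_equal(mom$W, sum(((0:3) - sum((0:3) * p))^2 * p), tolerance = 1e-10)
  }
})
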