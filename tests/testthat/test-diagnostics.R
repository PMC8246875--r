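test_that("outfit and infit are zero for perfectly expected responses", {
  # abilities chosen so the expected score is exactly integer: E = 2 at the
  # symmetry point of a 5-category item, E = 1 and 3 at +-theta_star
  beta <- c(-1.5, -0.5, 0.5, 1.5)
  theta_star <- uniroot(function(t) gpcm_moments(t, beta, 1)$E - 1,
                        c(-6, 0), tol = 1e-14)$root
  theta <- c(theta_star, 0, -theta_star)
  x <- matrix(rep(1:3, 2), ncol = 2)
  resp <- response_matrix(x, n_categories = 5)
  fit <- make_fit(resp, theta, list(beta, beta), c(1, 1))
  it <- item_fit(fit)
  expect_equal(it$outfit, c(0, 0), tolerance = 1e-8)
  expect_equal(it$infit, c(0, 0), tolerance = 1e-8)
})

test_that("fit statistics are near 1 for data drawn from the model", {
  for (seed in 1:3) {
    set.seed(seed)
    theta <- seq(-3, 3, length.out = 301)
    beta <- replicate(6, c(-1, 0, 1), simplify = FALSE)
    alpha <- rep(1, 6)
    resp <- sim_gpcm(theta, beta, alpha, seed = seed + 10)
    it <- item_fit(make_fit(resp, theta, beta, alpha))
    # item means concentrate near 1; single items are noisier (outfit's
    # squared residuals have heavy tails at extreme abilities)
    expect_true(all(abs(it$outfit - 1) < 0.35))
    expect_true(all(abs(it$infit - 1) < 0.35))
    expect_true(mean(it$outfit) > 0.85 && mean(it$outfit) < 1.15)
    expect_true(mean(it$infit) > 0.85 && mean(it$infit) < 1.15)
  }
})

test_that("fitted discrimination and infit are strongly inversely related", {
  sim <- sim_inhomogeneous(seed = 12)
  fit <- gpcm_fit(sim$responses)
  it <- item_fit(fit)
  expect_lt(cor(it$alpha, it$infit, method = "spearman"), -0.8)
})

test_that("a constant item yields missing fit statistics with a warning", {
  x <- cbind(rep(1L, 20), rep(c(0L, 1L, 2L), length.out = 20))
  resp <- response_matrix(x, n_categories = 3)
  fit <- make_fit(resp, rnorm(20), list(c(-1, 1), c(-1, 1)), c(1, 1))
  expect_warning(it <- item_fit(fit), "zero observed variance")
  expect_true(is.na(it$outfit[1]))
  expect_false(is.na(it$outfit[2]))
})

test_that("duplicated items are flagged by the residual correlation screen", {
  set.seed(31)
  theta <- rnorm(150)
  col <- sim_gpcm(theta, list(c(-0.5, 0.5)), 1, seed = 32)$values[, 1]
  other <- sim_gpcm(theta, list(c(-0.5, 0.5)), 1, seed = 33)$values[, 1]
  resp <- response_matrix(cbind(col, col, other), n_categories = 3,
                          item_ids = c("a", "a_copy", "b"))
  fit <- make_fit(resp, theta, replicate(3, c(-0.5, 0.5), simplify = FALSE),
                  rep(1, 3))
  rc <- residual_correlations(fit)
  expect_equal(rc$matrix["a", "a_copy"], 1, tolerance = 1e-9)
  expect_true(rc$max_abs > 0.3)
  expect_true(any(rc$flagged$item_a == "a" & rc$flagged$item_b == "a_copy"))
  # symmetric with unit diagonal
  expect_equal(rc$matrix, t(rc$matrix))
  expect_equal(unname(diag(rc$matrix)), rep(1, 3))
})

test_that("independent model-consistent items show only sampling-noise correlations", {
  set.seed(41)
  theta <- rnorm(301)
  beta <- replicate(6, c(-1, 0, 1), simplify = FALSE)
  resp <- sim_gpcm(theta, beta, rep(1, 6), seed = 42)
  rc <- residual_correlations(make_fit(resp, theta, beta, rep(1, 6)))
  expect_lt(rc$mean_abs, 2 / sqrt(301))
})

test_that("ability standard errors follow the test information", {
  # single dichotomous item at theta = beta: I = 0.25, se = 2
  resp <- response_matrix(matrix(c(0L, 1L), ncol = 1))
  fit <- make_fit(resp, c(0, 0), list(0), 1)
  pd <- suppressWarnings(ability_se(fit))
  expect_equal(pd$se, c(2, 2), tolerance = 1e-12)
  # duplicating every item doubles information: se shrinks by 1/sqrt(2)
  s <- tiny_sim(N = 30, P = 2, seed = 51)
  f1 <- make_fit(s$responses, s$theta, s$beta, s$alpha)
  dbl <- response_matrix(cbind(s$responses$values, s$responses$values),
                         n_categories = rep(lengths(s$beta) + 1L, 2),
                         item_ids = paste0("I", 1:4))
  f2 <- make_fit(dbl, s$theta, c(s$beta, s$beta), rep(s$alpha, 2))
  expect_equal(suppressWarnings(ability_se(f2))$se,
               suppressWarnings(ability_se(f1))$se / sqrt(2),
               tolerance = 1e-12)
})

test_that("information matches the curvature of the unpenalized log likelihood", {
  s <- tiny_sim(N = 12, P = 3, seed = 61)
  fit <- gpcm_fit(s$responses)
  pd <- ability_se(fit)
  h <- 1e-3
  for (n in c(1, 5, 12)) {
    ll_at <- function(t) {
      th <- fit$theta; th[n] <- t
      gpcm_loglik(s$responses, 1:3, th, fit$beta, fit$alpha)
    }
    curv <- -(ll_at(fit$theta[n] + h) - 2 * ll_at(fit$theta[n]) +
                ll_at(fit$theta[n] - h)) / h^2
    expect_equal(pd$info[n], curv, tolerance = 1e-4)
  }
})

test_that("person separation reliability behaves like a variance ratio", {
  theta <- c(-1.2, -0.3, 0.4, 1.4)
  expect_equal(person_separation(theta, rep(0, 4)), 1)
  # var_obs = 1, mean(se^2) = 0.25 -> 0.75
  th <- c(-1, 1) * sqrt(0.5)          # sample variance exactly 1
  expect_equal(person_separation(th, rep(0.5, 2)), 0.75)
  expect_warning(p0 <- person_separation(th, rep(2, 2)), "clipped")
  expect_identical(p0, 0)
  expect_error(person_separation(rep(1, 3), rep(0.1, 3)), "zero observed")
  # invariant to shifting all abilities
  expect_equal(person_separation(theta + 5, rep(0.4, 4)),
               person_separation(theta, rep(0.4, 4)))
})

test_that("random-instrument baselines are seeded and rank a reference", {
  s <- tiny_sim(N = 60, P = 4, seed = 71, alpha = c(2, 1.8, 0.1, 0.1))
  b1 <- random_baseline(s$responses, size = 2, n_draws = 5, seed = 9)
  b2 <- random_baseline(s$responses, size = 2, n_draws = 5, seed = 9)
  expect_identical(b1$draws, b2$draws)
  expect_identical(nrow(b1$draws), 5L)
  tr <- ipoq_search(s$responses)
  ref <- best_itemset(tr, 2)
  b3 <- random_baseline(s$responses, size = 2, n_draws = 8, seed = 10,
                        reference = ref)
  expect_equal(unname(b3$percentile[["ipoq_ll"]]), 100)
})

test_that("chance overlap probabilities match enumeration and Monte Carlo", {
  expect_identical(overlap_probability(10, 3, 4, 0), 1)
  # pool of 4, two 2-subsets: only 1 of the 6 second subsets overlaps fully
  expect_equal(overlap_probability(4, 2, 2, 2), 1 / 6, tolerance = 1e-12)
  # full enumeration oracle on a small configuration
  pool <- 7; a <- 3; b <- 4; k <- 2
  A <- seq_len(a)
  Bs <- combn(pool, b, simplify = FALSE)
  expect_equal(overlap_probability(pool, a, b, k),
               mean(vapply(Bs, function(B) length(intersect(A, B)) >= k,
                           logical(1))),
               tolerance = 1e-12)
  # Monte-Carlo cross-check within 3 standard errors
  set.seed(81)
  ndr <- 20000
  hits <- mean(replicate(ndr, sum(sample.int(9, 4) <= 4) >= 2))
  p <- overlap_probability(9, 4, 4, 2)
  expect_lt(abs(hits - p), 3 * sqrt(p * (1 - p) / ndr))
  expect_error(overlap_probability(10, 3, 4, 5), "0..min")
})
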