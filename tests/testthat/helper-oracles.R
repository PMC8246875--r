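# Independent brute-force oracles, kept free of the package's numerics.

# GPCM probabilities straight from the definition (no log-sum-exp).
naive_gpcm_prob <- function(theta, beta, alpha) {
  m <- length(beta)
  num <- c(1, vapply(seq_len(m), function(x)
    exp(alpha * sum(theta - beta[seq_len(x)])), numeric(1)))
  num / sum(num)
}

# Cell-by-cell log likelihood from the naive probabilities.
naive_loglik <- function(values, items, theta, beta, alpha) {
  ll <- 0
  for (k in seq_along(items)) {
    i <- items[k]
    for (n in seq_len(nrow(values))) {
      x <- values[n, i]
      if (is.na(x)) next
      ll <- ll + log(naive_gpcm_prob(theta[n], beta[[k]], alpha[k])[x + 1L])
    }
  }
  ll
}

# Central finite differences of a scalar function.
fd_gradient <- function(f, par, h = 1e-6) {
  vapply(seq_along(par), function(i) {
    e <- rep(0, length(par)); e[i] <- h
    (f(par + e) - f(par - e)) / (2 * h)
  }, numeric(1))
}

# Small seeded GPCM dataset with known parameters.
tiny_sim <- function(N = 30, P = 4, m = 2, seed = 1, alpha = NULL) {
  set.seed(seed)
  theta <- rnorm(N)
  beta <- replicate(P, sort(rnorm(m, sd = 0.8)), simplify = FALSE)
  if (is.null(alpha)) alpha <- exp(rnorm(P, sd = 0.3))
  resp <- sim_gpcm(theta, beta, alpha, seed = seed + 1000)
  list(responses = resp, theta = theta, beta = beta, alpha = alpha)
}

# Assemble a gpcm_fit-shaped object from explicit parameters, for
# closed-form diagnostics checks that do not need an optimizer run.
make_fit <- function(responses, theta, beta, alpha) {
  resp <- as_response_matrix(responses)
  ids <- resp$item_ids
  names(beta) <- ids
  structure(list(theta = theta, beta = beta,
                 alpha = stats::setNames(alpha, ids),
                 items = ids, item_index = seq_along(ids),
                 loglik = NA_real_, objective = NA_real_, converged = TRUE,
                 n_iterations = 0L, gradient_norm = 0,
                 theta_fixed = FALSE, lambda_theta = 0.05, lambda_alpha = 50,
                 responses = resp, n_subjects = length(theta)),
            class = "gpcm_fit")
}
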