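#' Penalized joint maximum likelihood fit of the GPCM
#'
#' Fits abilities, thresholds and discriminations of the generalized partial
#' credit model to an itemset by maximizing the ridge-penalized joint log
#' likelihood (see [gpcm_objective()]) with a quasi-Newton method (L-BFGS-B)
#' and analytic gradients in the `(theta, beta, log alpha)` parameterization
#' (so `alpha > 0` by construction).
#'
#' Two fit flavours share this interface:
#' * **included-itemset fit** (default): `theta` is free and carries the ridge
#'   `lambda_theta * sum(theta^2)`; discriminations carry
#'   `lambda_alpha * sum(log(alpha)^2)` with the strong default 50.
#' * **ability-fixed fit**: pass `theta` to hold abilities constant (as when
#'   evaluating excluded items at abilities estimated from the included set);
#'   only thresholds and discriminations are optimized, usually under a weak
#'   `lambda_alpha` (0.05).
#'
#' Abilities are initialized from the standardized raw sum scores on the
#' itemset, thresholds at 0 and discriminations at 1, unless `init` provides
#' warm-start values. Subjects with no observed response on the itemset are
#' reported; their ability is determined by the ridge alone (hence 0).
#'
#' @param responses a [response_matrix()] (or matrix coercible to one).
#' @param items item ids or indices to fit; default all items.
#' @param lambda_theta ridge weight on `sum(theta^2)`; default 0.05.
#' @param lambda_alpha ridge weight on `sum(log(alpha)^2)`; default 50, the
#'   strong shrinkage used for included itemsets (use 0.05 for excluded sets).
#' @param theta optional fixed ability vector (one per subject). When given,
#'   abilities are not estimated and no ability penalty applies.
#' @param init optional warm start: a list with any of `theta`, `beta` (list
#'   per item, named by item id), `alpha` (named). Missing pieces fall back to
#'   the defaults.
#' @param multistart number of optimizer starts; starts beyond the first
#'   jitter the initialization (seeded) and the best objective wins. Single
#'   start is the deterministic default.
#' @param seed RNG seed for the jittered restarts (ignored for
#'   `multistart = 1`).
#' @param control optimizer settings: `maxit` (500), `pgtol` (1e-5, gradient
#'   inf-norm) and `rel_tol` (1e-9, relative objective change).
#' @return An object of class `"gpcm_fit"`: list with `theta`, `beta`
#'   (named list), `alpha` (named), `items`, `loglik` (unpenalized log
#'   likelihood at the optimum), `objective` (penalized), `converged`,
#'   `n_iterations`, `gradient_norm`, `theta_fixed` flag, the penalty weights
#'   and the fitted `responses` subset. Methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `simulate`, `plot`, `logLik`.
#' @examples
#' sim <- sim_inhomogeneous(n_categories = 2, seed = 1)
#' fit <- gpcm_fit(sim$responses, items = 13:18)
#' fit
#' cor(coef(fit, "theta"), sim$theta)
#' @export
gpcm_fit <- function(responses, items = NULL, lambda_theta = 0.05,
                     lambda_alpha = 50, theta = NULL, init = NULL,
                     multistart = 1L, seed = NULL, control = list()) {
  resp <- as_response_matrix(responses)
  if (is.null(items)) items <- seq_len(ncol(resp$values))
  if (length(items) == 0L) stop("`items` must name at least one item")
  if (lambda_theta < 0 || lambda_alpha < 0) stop("penalty weights must be >= 0")
  idx <- resolve_items(resp, items)
  ids <- resp$item_ids[idx]
  X <- resp$values[, idx, drop = FALSE]
  N <- nrow(X)
  m <- resp$m[idx]
  theta_free <- is.null(theta)
  if (!theta_free && length(theta) != N)
    stop("fixed `theta` must have one entry per subject")

  ctrl <- utils::modifyList(list(maxit = 500L, pgtol = 1e-5, rel_tol = 1e-9),
                            control)

  no_resp <- rowSums(!is.na(X)) == 0L
  if (theta_free && any(no_resp))
    message(sum(no_resp), " subject(s) have no observed response on this itemset;",
            " their ability is set by the penalty alone")

  init0 <- default_init(X, m, ids, theta_free, init)
  par0 <- pack_par(init0, theta_free)

  run1 <- function(par) {
    if (theta_free)
      return(fit_lbfgsb(par, X, m, theta_fixed = numeric(0),
                        theta_free = TRUE, lambda_theta = lambda_theta,
                        lambda_alpha = lambda_alpha, penalize_theta = TRUE,
                        ctrl = ctrl))
    # with abilities fixed the items are independent: fit one small
    # optimization per item (much better conditioned than the joint block)
    off <- c(0L, cumsum(m))
    pieces <- lapply(seq_along(idx), function(k) {
      pk <- c(par[off[k] + seq_len(m[k])], par[sum(m) + k])
      fit_lbfgsb(pk, X[, k, drop = FALSE], m[k], theta_fixed = theta,
                 theta_free = FALSE, lambda_theta = lambda_theta,
                 lambda_alpha = lambda_alpha, penalize_theta = FALSE,
                 ctrl = ctrl)
    })
    list(par = c(unlist(lapply(pieces, function(p) p$par[seq_len(length(p$par) - 1L)])),
                 vapply(pieces, function(p) p$par[length(p$par)], numeric(1))),
         value = sum(vapply(pieces, function(p) p$value, numeric(1))),
         converged = all(vapply(pieces, function(p) p$converged, logical(1))),
         iterations = sum(vapply(pieces, function(p) p$iterations, numeric(1))),
         gradient_norm = max(vapply(pieces, function(p) p$gradient_norm,
                                    numeric(1))))
  }
  best <- run1(par0)
  if (multistart > 1L) {
    runif_jitter <- local_rng(seed, {
      lapply(seq_len(multistart - 1L), function(k)
        par0 + stats::rnorm(length(par0), sd = 0.3))
    })
    for (p0 in runif_jitter) {
      cand <- run1(p0)
      if (cand$value < best$value) best <- cand
    }
  }

  out <- unpack_par(best$par, N, m, ids, theta_free)
  theta_hat <- if (theta_free) out$theta else theta
  ll <- gpcm_loglik(resp, idx, theta_hat, out$beta, out$alpha)
  structure(list(
    theta = theta_hat,
    beta = out$beta,
    alpha = out$alpha,
    items = ids,
    item_index = idx,
    loglik = ll,
    objective = -best$value,
    converged = best$converged,
    n_iterations = best$iterations,
    gradient_norm = best$gradient_norm,
    theta_fixed = !theta_free,
    lambda_theta = lambda_theta,
    lambda_alpha = lambda_alpha,
    responses = subset_items(resp, idx),
    n_subjects = N
  ), class = "gpcm_fit")
}

default_init <- function(X, m, ids, theta_free, init) {
  N <- nrow(X)
  theta0 <- NULL
  if (theta_free) {
    raw <- rowSums(X, na.rm = TRUE)
    raw[rowSums(!is.na(X)) == 0L] <- NA
    s <- stats::sd(raw, na.rm = TRUE)
    theta0 <- if (is.na(s) || s == 0) rep(0, N) else
      (raw - mean(raw, na.rm = TRUE)) / s
    theta0[is.na(theta0)] <- 0
  }
  beta0 <- stats::setNames(lapply(m, function(mi) rep(0, mi)), ids)
  alpha0 <- stats::setNames(rep(1, length(ids)), ids)
  if (!is.null(init)) {
    if (!is.null(init$theta) && theta_free) {
      stopifnot(length(init$theta) == N)
      theta0 <- init$theta
    }
    if (!is.null(init$beta)) {
      for (id in intersect(names(init$beta), ids))
        if (length(init$beta[[id]]) == length(beta0[[id]]))
          beta0[[id]] <- init$beta[[id]]
    }
    if (!is.null(init$alpha)) {
      hit <- intersect(names(init$alpha), ids)
      alpha0[hit] <- init$alpha[hit]
    }
  }
  list(theta = theta0, beta = beta0, alpha = alpha0)
}

pack_par <- function(init, theta_free) {
  c(if (theta_free) init$theta,
    unlist(init$beta, use.names = FALSE),
    log(unlist(init$alpha, use.names = FALSE)))
}

unpack_par <- function(par, N, m, ids, theta_free) {
  pos <- 0L
  theta <- NULL
  if (theta_free) { theta <- par[seq_len(N)]; pos <- N }
  beta <- split(par[pos + seq_len(sum(m))], rep(seq_along(m), m))
  names(beta) <- ids
  alpha <- stats::setNames(exp(par[pos + sum(m) + seq_along(ids)]), ids)
  list(theta = theta, beta = beta, alpha = alpha)
}

fit_lbfgsb <- function(par0, X, m, theta_fixed, theta_free, lambda_theta,
                       lambda_alpha, penalize_theta, ctrl) {
  cache_par <- NULL
  cache_val <- NULL
  ev <- function(par) {
    if (is.null(cache_par) || !identical(par, cache_par)) {
      cache_val <<- gpcm_negobj(par, X, as.integer(m), theta_fixed, theta_free,
                                lambda_theta, lambda_alpha, penalize_theta)
      cache_par <<- par
    }
    cache_val
  }
  res <- stats::optim(par0, fn = function(p) ev(p)$value,
                      gr = function(p) ev(p)$gradient,
                      method = "L-BFGS-B",
                      control = list(maxit = ctrl$maxit,
                                     pgtol = ctrl$pgtol,
                                     factr = ctrl$rel_tol / .Machine$double.eps))
  gnorm <- max(abs(gpcm_negobj(res$par, X, as.integer(m), theta_fixed,
                               theta_free, lambda_theta, lambda_alpha,
                               penalize_theta)$gradient))
  conv <- res$convergence == 0L
  if (!conv)
    warning("GPCM fit did not converge in ", ctrl$maxit, " iterations (",
            res$message, ")", call. = FALSE)
  list(par = res$par, value = res$value, converged = conv,
       iterations = res$counts[["function"]], gradient_norm = gnorm)
}

# evaluate `expr` under a temporary seed, restoring the caller's RNG state
local_rng <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}
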