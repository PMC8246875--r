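#' GPCM category probabilities
#'
#' Response probabilities of the generalized partial credit model. For an
#' item with thresholds `beta = (b_1, ..., b_m)` and discrimination
#' `alpha > 0`, the probability of category `x` at ability `theta` is
#' proportional to `exp(alpha * sum_{j<=x} (theta - b_j))`, with the empty sum
#' for `x = 0`. With `alpha = 1` this is the partial credit model; with one
#' threshold it is the two-parameter logistic and, at `alpha = 1`, the
#' dichotomous Rasch model.
#'
#' Computation subtracts the maximum cumulative logit before exponentiating,
#' so extreme `alpha * (theta - beta)` cannot overflow.
#'
#' @param theta ability value(s), logit scale.
#' @param beta numeric vector of `m >= 1` thresholds.
#' @param alpha positive discrimination.
#' @return For scalar `theta`, a probability vector of length `m + 1`
#'   (categories `0..m`); for vector `theta`, a matrix with one row per
#'   ability. Rows sum to 1 and every entry is strictly positive.
#' @examples
#' gpcm_prob(0, 0, 1)                   # 0.5 / 0.5
#' gpcm_prob(1, 0, 1)[2]                # plogis(1)
#' gpcm_prob(0, c(-1, 0, 1), 1.7)
#' @export
gpcm_prob <- function(theta, beta, alpha) {
  if (!all(is.finite(theta)) || !all(is.finite(beta)) || !all(is.finite(alpha)))
    stop("non-finite parameter passed to gpcm_prob()")
  if (length(alpha) != 1L || alpha <= 0) stop("`alpha` must be a single positive value")
  m <- length(beta)
  if (m < 1L) stop("`beta` needs at least one threshold")
  # cumulative logits C_k = alpha * (k * theta - sum_{j<=k} beta_j), C_0 = 0
  k <- seq_len(m)
  C <- cbind(0, alpha * (outer(theta, k) -
                           matrix(cumsum(beta), length(theta), m, byrow = TRUE)))
  C <- C - apply(C, 1L, max)
  p <- exp(C)
  p <- p / rowSums(p)
  colnames(p) <- as.character(0:m)
  if (length(theta) == 1L) drop(p) else p
}

#' GPCM expected score and score variance
#'
#' Conditional moments `E = sum_x x p_x` and `W = sum_x (x - E)^2 p_x` of a
#' response at ability `theta`, the ingredients of the outfit/infit mean
#' squares and of the test information `alpha^2 * W`.
#'
#' @inheritParams gpcm_prob
#' @return list with numeric `E` and `W`, each of `length(theta)`.
#' @examples
#' gpcm_moments(0, 0, 1)   # E = 0.5, W = 0.25
#' @export
gpcm_moments <- function(theta, beta, alpha) {
  p <- gpcm_prob(theta, beta, alpha)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  x <- 0:(ncol(p) - 1L)
  E <- drop(p %*% x)
  W <- drop(p %*% (x^2)) - E^2
  list(E = E, W = W)
}

#' Log likelihood of an itemset
#'
#' Joint log likelihood `L_S = sum_{i in S} sum_n log P(X = x_ni)` of the
#' observed responses on the items in `items` under GPCM parameters. Missing
#' cells contribute nothing; an empty itemset has log likelihood 0.
#'
#' @param responses a [response_matrix()] (or coercible).
#' @param items item ids or indices (may be empty).
#' @param theta ability vector, one per subject.
#' @param beta list of threshold vectors, one per *selected* item (in the
#'   order of `items`), or a full per-item list named by item id.
#' @param alpha discrimination vector matching `beta`.
#' @return scalar log likelihood (<= 0).
#' @export
gpcm_loglik <- function(responses, items, theta, beta, alpha) {
  resp <- as_response_matrix(responses)
  if (length(items) == 0L) return(0)
  idx <- resolve_items(resp, items)
  if (length(theta) != nrow(resp$values))
    stop("`theta` must have one entry per subject")
  beta <- align_item_params(beta, resp$item_ids[idx], length(idx))
  alpha <- align_item_params(alpha, resp$item_ids[idx], length(idx), scalar = TRUE)
  ll <- 0
  for (k in seq_along(idx)) {
    i <- idx[k]
    x <- resp$values[, i]
    obs <- !is.na(x)
    if (!any(obs)) next
    p <- gpcm_prob(theta[obs], beta[[k]], alpha[k])
    if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
    ll <- ll + sum(log(p[cbind(seq_len(sum(obs)), x[obs] + 1L)]))
  }
  ll
}

# Accept item parameters either positionally (length = number of selected
# items) or as a named full-length structure keyed by item id.
align_item_params <- function(par, ids, n, scalar = FALSE) {
  if (scalar) {
    if (!is.null(names(par)) && all(ids %in% names(par))) return(unname(par[ids]))
    if (length(par) == 1L) return(rep(par, n))
    if (length(par) != n) stop("`alpha` length does not match the itemset")
    return(par)
  }
  if (!is.list(par)) par <- list(par)
  if (!is.null(names(par)) && all(ids %in% names(par))) return(par[ids])
  if (length(par) != n) stop("`beta` must have one threshold vector per item")
  par
}

#' Ridge-penalized GPCM objective
#'
#' The criterion maximized by the penalized joint fit:
#' `F_S = L_S - lambda_theta * sum(theta^2) - lambda_alpha * sum(log(alpha)^2)`,
#' with the ability penalty dropped when `penalize_theta = FALSE` (the
#' excluded-itemset fit, where abilities are held fixed). The ridge terms
#' resolve the translation/scale non-identifiability of joint estimation and
#' keep perfect-score parameters finite; the log-alpha penalty shrinks
#' discriminations toward 1 (the partial credit model).
#'
#' @inheritParams gpcm_loglik
#' @param lambda_theta,lambda_alpha nonnegative penalty weights.
#' @param penalize_theta include the ability ridge term?
#' @return scalar penalized objective.
#' @export
gpcm_objective <- function(responses, items, theta, beta, alpha,
                           lambda_theta = 0.05, lambda_alpha = 50,
                           penalize_theta = TRUE) {
  if (lambda_theta < 0 || lambda_alpha < 0) stop("penalty weights must be >= 0")
  resp <- as_response_matrix(responses)
  idx <- resolve_items(resp, items)
  alpha_s <- align_item_params(alpha, resp$item_ids[idx], length(idx), scalar = TRUE)
  ll <- gpcm_loglik(resp, items, theta, beta, alpha)
  pen <- lambda_alpha * sum(log(alpha_s)^2)
  if (penalize_theta) pen <- pen + lambda_theta * sum(theta^2)
  ll - pen
}

#' Gradient of the penalized GPCM objective
#'
#' Analytic partial derivatives of [gpcm_objective()] in the internal
#' `(theta, beta, log alpha)` parameterization, as used by the quasi-Newton
#' fits. Blocks not listed in `free_blocks` are omitted from the result.
#'
#' @inheritParams gpcm_objective
#' @param free_blocks subset of `c("theta", "beta", "log_alpha")`.
#' @return list with one numeric element per requested block; `beta` is a
#'   list of per-item gradients in itemset order.
#' @export
gpcm_gradient <- function(responses, items, theta, beta, alpha,
                          lambda_theta = 0.05, lambda_alpha = 50,
                          penalize_theta = TRUE,
                          free_blocks = c("theta", "beta", "log_alpha")) {
  free_blocks <- match.arg(free_blocks, c("theta", "beta", "log_alpha"),
                           several.ok = TRUE)
  resp <- as_response_matrix(responses)
  idx <- resolve_items(resp, items)
  ids <- resp$item_ids[idx]
  beta <- align_item_params(beta, ids, length(idx))
  alpha <- align_item_params(alpha, ids, length(idx), scalar = TRUE)
  theta_free <- "theta" %in% free_blocks
  X <- resp$values[, idx, drop = FALSE]
  m <- lengths(beta)
  par <- c(if (theta_free) theta, unlist(beta, use.names = FALSE), log(alpha))
  res <- gpcm_negobj(par, X, as.integer(m),
                     if (theta_free) numeric(0) else theta,
                     theta_free, lambda_theta, lambda_alpha, penalize_theta)
  g <- -res$gradient  # back to ascent direction
  out <- list()
  pos <- 0L
  if (theta_free) {
    out$theta <- g[seq_len(nrow(X))]
    pos <- nrow(X)
  }
  gb <- g[pos + seq_len(sum(m))]
  out$beta <- split(gb, rep(seq_along(m), m))
  names(out$beta) <- ids
  out$log_alpha <- stats::setNames(g[pos + sum(m) + seq_along(idx)], ids)
  out[free_blocks[free_blocks %in% names(out)]]
}
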