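#' In-plus-out-of-questionnaire log likelihood of an itemset split
#'
#' Scores a split of the survey into an included itemset `s_in` and its
#' complement `s_out` by the IPOQ-LL criterion:
#'
#' 1. fit abilities, thresholds and discriminations jointly on `s_in` with
#'    the strong discrimination ridge `lambda_in`;
#' 2. evaluate the *unpenalized* log likelihood of those parameters on
#'    `s_in` (IQ-LL);
#' 3. holding the step-1 abilities fixed, refit thresholds and
#'    discriminations of the excluded items under the weak ridge
#'    `lambda_out`;
#' 4. evaluate their unpenalized log likelihood (OQ-LL);
#' 5. IPOQ-LL = IQ-LL + OQ-LL.
#'
#' Every item contributes to exactly one of the two terms, so splits of the
#' same survey are comparable. A good instrument earns a high IQ-LL (its
#' items are mutually predictable through a common ability) *and* a high
#' OQ-LL (the abilities it yields still explain the left-out items). The
#' asymmetric penalties matter: excluded items may freely shrink their
#' discrimination, so unpredictable items are cheap to leave out but
#' expensive to keep in.
#'
#' @param responses a [response_matrix()] (or coercible).
#' @param items the included itemset `s_in` (ids or indices); must be
#'   non-empty, since abilities can only be estimated from included items.
#' @param lambda_theta ability ridge for the included fit (default .05).
#' @param lambda_in discrimination ridge on included items (default 50).
#' @param lambda_out discrimination ridge on excluded items (default .05).
#' @param warm optional warm start: an `ipoq_ll` object of a neighbouring
#'   split whose fitted parameters seed both fits (results are still polished
#'   to full tolerance, so scores do not depend on the warm start).
#' @param multistart,seed optional multi-start control passed to the included
#'   fit (see [gpcm_fit()]).
#' @param control optimizer settings forwarded to both fits (see
#'   [gpcm_fit()]); property checks on hard instances may need a higher
#'   `maxit`.
#' @return object of class `"ipoq_ll"`: list with `s_in`, `s_out` (item ids),
#'   `iq_ll`, `oq_ll`, `ipoq_ll`, and the two fits `fit_in`, `fit_out`
#'   (`fit_out` is `NULL` for the full itemset, whose OQ-LL is 0).
#' @examples
#' sim <- sim_inhomogeneous(n_categories = 2, seed = 1)
#' ipoq_ll(sim$responses, items = 13:18)
#' @export
ipoq_ll <- function(responses, items, lambda_theta = 0.05, lambda_in = 50,
                    lambda_out = 0.05, warm = NULL, multistart = 1L,
                    seed = NULL, control = list()) {
  resp <- as_response_matrix(responses)
  if (length(items) == 0L)
    stop("`items` (the included itemset) must be non-empty: abilities cannot be estimated from zero items")
  idx_in <- sort(resolve_items(resp, items))
  idx_out <- setdiff(seq_len(ncol(resp$values)), idx_in)

  init_in <- init_out <- NULL
  if (!is.null(warm)) {
    stopifnot(inherits(warm, "ipoq_ll"))
    prev <- warm_params(warm)
    init_in <- list(theta = prev$theta, beta = prev$beta, alpha = prev$alpha)
    init_out <- list(beta = prev$beta, alpha = prev$alpha)
  }

  fit_in <- gpcm_fit(resp, items = idx_in, lambda_theta = lambda_theta,
                     lambda_alpha = lambda_in, init = init_in,
                     multistart = multistart, seed = seed, control = control)
  iq <- fit_in$loglik

  if (length(idx_out)) {
    fit_out <- gpcm_fit(resp, items = idx_out, lambda_alpha = lambda_out,
                        theta = fit_in$theta, init = init_out,
                        control = control)
    oq <- fit_out$loglik
  } else {
    fit_out <- NULL
    oq <- 0
  }

  structure(list(s_in = resp$item_ids[idx_in], s_out = resp$item_ids[idx_out],
                 index_in = idx_in, index_out = idx_out,
                 iq_ll = iq, oq_ll = oq, ipoq_ll = iq + oq,
                 fit_in = fit_in, fit_out = fit_out,
                 lambda_theta = lambda_theta, lambda_in = lambda_in,
                 lambda_out = lambda_out),
            class = "ipoq_ll")
}

# pool fitted item parameters of both sides (for warm starts)
warm_params <- function(sc) {
  beta <- c(sc$fit_in$beta,
            if (!is.null(sc$fit_out)) sc$fit_out$beta)
  alpha <- c(sc$fit_in$alpha,
             if (!is.null(sc$fit_out)) sc$fit_out$alpha)
  list(theta = sc$fit_in$theta, beta = beta, alpha = alpha)
}

#' @export
print.ipoq_ll <- function(x, ...) {
  cat(sprintf("IPOQ-LL split: %d included / %d excluded items\n",
              length(x$s_in), length(x$s_out)))
  cat(sprintf("  IQ-LL   = %12.3f\n", x$iq_ll))
  cat(sprintf("  OQ-LL   = %12.3f\n", x$oq_ll))
  cat(sprintf("  IPOQ-LL = %12.3f\n", x$ipoq_ll))
  invisible(x)
}

#' Per-item log-likelihood contributions of a scored split
#'
#' Splits IQ-LL and OQ-LL into one term per item (at the already-fitted
#' parameters). The contributions sum to the corresponding totals; useful
#' for seeing which items pay for their place in the instrument.
#'
#' @param score an [ipoq_ll()] object.
#' @param responses the response matrix the split was scored on.
#' @return data frame with `item`, `side` (`"in"`/`"out"`) and `loglik`.
#' @export
ipoq_contributions <- function(score, responses) {
  stopifnot(inherits(score, "ipoq_ll"))
  resp <- as_response_matrix(responses)
  one <- function(fit, side, ids) {
    if (is.null(fit) || !length(ids)) return(NULL)
    ll <- vapply(ids, function(id)
      gpcm_loglik(resp, id, fit$theta, fit$beta[id], fit$alpha[id]),
      numeric(1))
    data.frame(item = ids, side = side, loglik = unname(ll),
               stringsAsFactors = FALSE)
  }
  rbind(one(score$fit_in, "in", score$s_in),
        one(score$fit_out, "out", score$s_out))
}
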