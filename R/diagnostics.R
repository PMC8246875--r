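#' Item fit statistics (outfit / infit mean squares)
#'
#' Standard polytomous Rasch fit statistics from standardized residuals
#' `z_ni = (x_ni - E_ni) / sqrt(W_ni)` under the fitted model (with the
#' fitted discriminations, not forced to 1):
#' * outfit (unweighted mean square): `mean(z^2)` over observed responses;
#' * infit (information-weighted): `sum((x - E)^2) / sum(W)`.
#'
#' Values near 1 indicate model-consistent noise; values well above 1 flag
#' unpredictable (noisy) items, values well below 1 overly deterministic
#' ones. Under the GPCM fit these track the discrimination parameter
#' closely: low-discrimination items fit noisily.
#'
#' @param fit a [gpcm_fit()] object.
#' @return data frame with one row per item: `item`, `alpha`, `outfit`,
#'   `infit`, `n` (observed responses). Items whose observed responses have
#'   zero variance get `NA` statistics with a warning.
#' @export
item_fit <- function(fit) {
  stopifnot(inherits(fit, "gpcm_fit"))
  X <- fit$responses$values
  out <- data.frame(item = fit$items,
                    alpha = unname(fit$alpha),
                    outfit = NA_real_, infit = NA_real_,
                    n = colSums(!is.na(X)),
                    stringsAsFactors = FALSE)
  degen <- character(0)
  for (k in seq_along(fit$items)) {
    x <- X[, k]
    obs <- !is.na(x)
    if (sum(obs) == 0L) next
    if (stats::var(x[obs]) == 0) { degen <- c(degen, fit$items[k]); next }
    mom <- gpcm_moments(fit$theta[obs], fit$beta[[k]], fit$alpha[[k]])
    r2 <- (x[obs] - mom$E)^2
    out$outfit[k] <- mean(r2 / mom$W)
    out$infit[k] <- sum(r2) / sum(mom$W)
  }
  if (length(degen))
    warning("zero observed variance, fit statistics undefined for item(s): ",
            paste(degen, collapse = ", "))
  out
}

#' Residual correlations (local-dependence screen)
#'
#' Pairwise Pearson correlations of the standardized residuals across
#' subjects. Under local independence residuals are uncorrelated up to
#' sampling noise of order `1/sqrt(N)`; a pair correlating strongly (the
#' conventional flag is |r| > .3) indicates a dependence not explained by the
#' common ability, and usually one of the two items is dropped.
#'
#' @param fit a [gpcm_fit()] object with at least 2 items.
#' @param flag_threshold absolute correlation above which a pair is flagged.
#' @return list with `matrix` (P x P, unit diagonal, `NA` for pairs with a
#'   constant residual vector), `mean_abs` and `max_abs` over off-diagonal
#'   entries, `mean_signed`, and `flagged` (data frame of flagged pairs).
#' @export
residual_correlations <- function(fit, flag_threshold = 0.3) {
  stopifnot(inherits(fit, "gpcm_fit"))
  if (length(fit$items) < 2L) stop("need at least 2 items")
  Z <- residuals(fit, type = "standardized")
  R <- suppressWarnings(stats::cor(Z, use = "pairwise.complete.obs"))
  off <- R[upper.tri(R)]
  pairs <- which(upper.tri(R) & abs(R) > flag_threshold, arr.ind = TRUE)
  flagged <- data.frame(item_a = fit$items[pairs[, 1]],
                        item_b = fit$items[pairs[, 2]],
                        correlation = R[pairs],
                        stringsAsFactors = FALSE)
  list(matrix = R,
       mean_abs = mean(abs(off), na.rm = TRUE),
       max_abs = if (all(is.na(off))) NA_real_ else max(abs(off), na.rm = TRUE),
       mean_signed = mean(off, na.rm = TRUE),
       flagged = flagged)
}

#' Ability standard errors
#'
#' Information-based standard errors `se_n = 1 / sqrt(I_n)` with test
#' information `I_n = sum_i alpha_i^2 W_ni` over the subject's observed
#' items, evaluated at the fitted parameters. The information is that of the
#' unpenalized log likelihood (the ridge shrinks the point estimate but is
#' not counted as information about the subject).
#'
#' @param fit a [gpcm_fit()] object.
#' @return list of class `"person_diag"` with `theta_hat`, `se`, `info`,
#'   `rms_se` (root mean squared SE), and `psr` (person separation
#'   reliability, see [person_separation()]). Subjects with zero information
#'   get `NA` with a warning.
#' @export
ability_se <- function(fit) {
  stopifnot(inherits(fit, "gpcm_fit"))
  X <- fit$responses$values
  info <- numeric(fit$n_subjects)
  for (k in seq_along(fit$items)) {
    obs <- !is.na(X[, k])
    if (!any(obs)) next
    W <- gpcm_moments(fit$theta[obs], fit$beta[[k]], fit$alpha[[k]])$W
    info[obs] <- info[obs] + fit$alpha[[k]]^2 * W
  }
  se <- 1 / sqrt(info)
  if (any(info == 0)) {
    warning(sum(info == 0), " subject(s) with zero test information; SE undefined")
    se[info == 0] <- NA_real_
  }
  psr <- tryCatch(person_separation(fit$theta, se), error = function(e) NA_real_)
  structure(list(theta_hat = fit$theta, se = se, info = info,
                 rms_se = sqrt(mean(se^2, na.rm = TRUE)), psr = psr),
            class = "person_diag")
}

#' @export
print.person_diag <- function(x, ...) {
  cat(sprintf("Person diagnostics: %d subjects\n", length(x$theta_hat)))
  cat(sprintf("  rms standard error: %.3f\n", x$rms_se))
  cat(sprintf("  person separation reliability: %.3f\n", x$psr))
  invisible(x)
}

#' Person separation reliability
#'
#' `PSR = (var(theta_hat) - mean(se^2)) / var(theta_hat)`: the estimated
#' share of observed ability variance that is true variance rather than
#' measurement error — the Rasch analogue of Cronbach's alpha. Clipped to
#' `[0, 1]`; values >= .8 are conventionally considered good.
#'
#' @param theta_hat estimated abilities (>= 2 subjects with defined SE).
#' @param se their standard errors.
#' @return scalar in `[0, 1]`.
#' @examples
#' person_separation(c(-1, 0, 1), rep(0.5, 3))
#' @export
person_separation <- function(theta_hat, se) {
  ok <- !is.na(se)
  if (sum(ok) < 2L) stop("need at least 2 subjects with defined SE")
  v <- stats::var(theta_hat[ok])
  if (v == 0) stop("zero observed ability variance; PSR undefined")
  psr <- (v - mean(se[ok]^2)) / v
  if (psr < 0) {
    warning("mean squared SE exceeds observed variance; PSR clipped to 0")
    psr <- 0
  }
  min(psr, 1)
}

#' Random-instrument baseline distributions
#'
#' Draws random instruments of a fixed size uniformly from the survey and
#' computes, for each, the statistics used to benchmark a candidate
#' instrument: mean outfit, mean infit, mean absolute residual correlation,
#' PSR, and IPOQ-LL. A selected instrument should beat this chance
#' distribution at least on IPOQ-LL.
#'
#' @param responses a [response_matrix()] (or coercible).
#' @param size instrument size, `1 <= size < P`.
#' @param n_draws number of random instruments.
#' @param lambda_theta,lambda_in,lambda_out penalties, as in [ipoq_ll()].
#' @param seed RNG seed for the draws (caller's RNG state restored).
#' @param reference optional itemset (ids or indices) whose statistics and
#'   percentiles within the baseline distributions are reported.
#' @return list with `draws` (data frame, one row per draw), and when a
#'   reference is given `reference` (its statistics) and `percentile`
#'   (percent of draws at or below the reference, per statistic).
#' @export
random_baseline <- function(responses, size, n_draws = 100,
                            lambda_theta = 0.05, lambda_in = 50,
                            lambda_out = 0.05, seed = NULL,
                            reference = NULL) {
  resp <- as_response_matrix(responses)
  P <- ncol(resp$values)
  if (size < 1L || size >= P) stop("`size` must satisfy 1 <= size < P")
  draws <- local_rng(seed, {
    lapply(seq_len(n_draws), function(d) sort(sample.int(P, size)))
  })
  stat_row <- function(itemset) {
    sc <- ipoq_ll(resp, itemset, lambda_theta = lambda_theta,
                  lambda_in = lambda_in, lambda_out = lambda_out)
    it <- suppressWarnings(item_fit(sc$fit_in))
    rc <- residual_correlations(sc$fit_in)
    pd <- suppressWarnings(ability_se(sc$fit_in))
    data.frame(items = paste(resp$item_ids[resolve_items(resp, itemset)],
                             collapse = ";"),
               mean_outfit = mean(it$outfit, na.rm = TRUE),
               mean_infit = mean(it$infit, na.rm = TRUE),
               mean_abs_resid_corr = rc$mean_abs,
               psr = pd$psr,
               ipoq_ll = sc$ipoq_ll,
               stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, lapply(draws, stat_row))
  out <- list(draws = tab)
  if (!is.null(reference)) {
    ref <- stat_row(reference)
    stats_cols <- c("mean_outfit", "mean_infit", "mean_abs_resid_corr",
                    "psr", "ipoq_ll")
    pct <- vapply(stats_cols, function(cl)
      100 * mean(tab[[cl]] <= ref[[cl]]), numeric(1))
    out$reference <- ref
    out$percentile <- pct
  }
  out
}

#' Chance overlap probability of two item subsets
#'
#' Probability that two independently, uniformly drawn subsets of sizes
#' `size_a` and `size_b` from a pool of `pool` items share at least `k`
#' items. Conditional on one subset, the overlap is hypergeometric, so the
#' tail is `P(H >= k)` with `H ~ Hypergeometric(size_a, pool - size_a,
#' size_b)`. Used to judge whether the agreement between two instruments
#' (e.g. an automatically selected and a manually built one) could be luck.
#'
#' @param pool total number of items.
#' @param size_a,size_b subset sizes.
#' @param k overlap threshold, `0 <= k <= min(size_a, size_b)`.
#' @return scalar probability.
#' @examples
#' overlap_probability(36, 17, 17, 14)   # far below 1e-4
#' @export
overlap_probability <- function(pool, size_a, size_b, k) {
  if (any(c(pool, size_a, size_b, k) != round(c(pool, size_a, size_b, k))))
    stop("all arguments must be integers")
  if (size_a > pool || size_b > pool) stop("subset sizes cannot exceed `pool`")
  if (k < 0 || k > min(size_a, size_b))
    stop("`k` must lie in 0..min(size_a, size_b)")
  if (k == 0) return(1)
  stats::phyper(k - 1, size_a, pool - size_a, size_b, lower.tail = FALSE)
}
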