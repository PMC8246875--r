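#' @export
print.gpcm_fit <- function(x, ...) {
  cat(sprintf("Penalized joint GPCM fit: %d items, %d subjects\n",
              length(x$items), x$n_subjects))
  cat(sprintf("  abilities: %s\n",
              if (x$theta_fixed) "fixed" else "estimated"))
  cat(sprintf("  log likelihood: %.3f   penalized objective: %.3f\n",
              x$loglik, x$objective))
  cat(sprintf("  converged: %s (grad inf-norm %.2e, %d evaluations)\n",
              x$converged, x$gradient_norm, x$n_iterations))
  invisible(x)
}

#' Extract GPCM parameters
#'
#' @param object a [gpcm_fit()] object.
#' @param which one of `"all"`, `"theta"`, `"beta"`, `"alpha"`.
#' @param ... unused.
#' @return For `"theta"` a numeric vector, `"alpha"` a named vector,
#'   `"beta"` a named list of threshold vectors, `"all"` a list of the three.
#' @export
coef.gpcm_fit <- function(object, which = c("all", "theta", "beta", "alpha"),
                          ...) {
  which <- match.arg(which)
  switch(which,
         all = list(theta = object$theta, beta = object$beta,
                    alpha = object$alpha),
         theta = object$theta,
         beta = object$beta,
         alpha = object$alpha)
}

#' @export
logLik.gpcm_fit <- function(object, ...) {
  npar <- (!object$theta_fixed) * object$n_subjects +
    sum(lengths(object$beta)) + length(object$alpha)
  structure(object$loglik, df = npar, class = "logLik")
}

#' Predicted category probabilities or expected scores
#'
#' @param object a [gpcm_fit()] object.
#' @param newtheta abilities at which to predict; default the fitted ones.
#' @param type `"prob"` for per-category probabilities (a list of matrices,
#'   one per item) or `"expected"` for the expected-score matrix.
#' @param ... unused.
#' @export
predict.gpcm_fit <- function(object, newtheta = NULL,
                             type = c("expected", "prob"), ...) {
  type <- match.arg(type)
  th <- if (is.null(newtheta)) object$theta else newtheta
  if (type == "prob") {
    out <- lapply(seq_along(object$items), function(k) {
      p <- gpcm_prob(th, object$beta[[k]], object$alpha[[k]])
      if (is.null(dim(p))) p <- matrix(p, nrow = 1L,
                                       dimnames = list(NULL, names(p)))
      p
    })
    names(out) <- object$items
    return(out)
  }
  E <- vapply(seq_along(object$items), function(k)
    gpcm_moments(th, object$beta[[k]], object$alpha[[k]])$E,
    numeric(length(th)))
  if (is.null(dim(E))) E <- matrix(E, nrow = length(th))
  colnames(E) <- object$items
  E
}

#' @export
fitted.gpcm_fit <- function(object, ...) predict(object, type = "expected")

#' Residuals of a GPCM fit
#'
#' Score residuals `x - E` or standardized residuals `(x - E) / sqrt(W)`,
#' with `E` and `W` the model's conditional response mean and variance at the
#' fitted parameters. Standardized residuals are the building block of the
#' outfit/infit mean squares and of the residual-correlation screen for
#' local dependence.
#'
#' @param object a [gpcm_fit()] object.
#' @param type `"standardized"` (default) or `"score"`.
#' @param ... unused.
#' @return subjects-by-items matrix with `NA` where responses were missing.
#' @export
residuals.gpcm_fit <- function(object, type = c("standardized", "score"),
                               ...) {
  type <- match.arg(type)
  X <- object$responses$values
  R <- matrix(NA_real_, nrow(X), ncol(X), dimnames = dimnames(X))
  for (k in seq_along(object$items)) {
    mom <- gpcm_moments(object$theta, object$beta[[k]], object$alpha[[k]])
    r <- X[, k] - mom$E
    if (type == "standardized") r <- r / sqrt(mom$W)
    R[, k] <- r
  }
  R[is.na(X)] <- NA_real_
  R
}

#' Simulate responses from a fitted GPCM
#'
#' @param object a [gpcm_fit()] object.
#' @param nsim number of replicate response matrices.
#' @param seed optional RNG seed (caller's RNG state is restored).
#' @param ... unused.
#' @return a list of `nsim` [response_matrix()] objects.
#' @export
simulate.gpcm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  local_rng(seed, {
    lapply(seq_len(nsim), function(r)
      sim_gpcm(object$theta, object$beta, object$alpha,
               item_ids = object$items))
  })
}

#' @export
summary.gpcm_fit <- function(object, ...) {
  it <- item_fit(object)
  pd <- suppressWarnings(ability_se(object))
  structure(list(fit = object, item_table = it, person = pd),
            class = "summary.gpcm_fit")
}

#' @export
print.summary.gpcm_fit <- function(x, digits = 3, ...) {
  print(x$fit)
  cat("\nItem diagnostics:\n")
  print(format(x$item_table, digits = digits), row.names = FALSE)
  if (!is.null(x$person$psr))
    cat(sprintf("\nPerson separation reliability: %.3f (rms SE %.3f)\n",
                x$person$psr, x$person$rms_se))
  invisible(x)
}

#' Expected score curves of a fitted GPCM
#'
#' Plots each item's expected score as a function of ability, the polytomous
#' analogue of an item characteristic curve; steeper curves belong to more
#' discriminating items.
#'
#' @param x a [gpcm_fit()] object.
#' @param theta_range ability range to draw.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gpcm_fit <- function(x, theta_range = c(-4, 4), ...) {
  th <- seq(theta_range[1], theta_range[2], length.out = 101)
  E <- predict(x, newtheta = th, type = "expected")
  graphics::matplot(th, E, type = "l", lty = 1,
                    xlab = expression(theta),
                    ylab = "expected score", ...)
  invisible(x)
}
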