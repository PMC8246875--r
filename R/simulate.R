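#' Sample a GPCM response matrix
#'
#' Draws every cell independently from the GPCM category probabilities at the
#' given parameters. Deterministic for a fixed `seed` (the caller's RNG
#' state is restored).
#'
#' @param theta ability vector (one per subject) *or* an N x P matrix giving
#'   each subject a per-item ability (used by the multidimensional designs,
#'   where different item blocks load on different ability vectors).
#' @param beta list of threshold vectors, one per item.
#' @param alpha discrimination vector, one per item.
#' @param seed optional RNG seed.
#' @param item_ids,subject_ids optional labels.
#' @return a [response_matrix()] whose declared category counts come from
#'   `beta` (so rare categories absent by chance are still represented).
#' @examples
#' r <- sim_gpcm(seq(-2, 2, length.out = 50), list(0, 0), c(1, 1), seed = 1)
#' dim(r)
#' @export
sim_gpcm <- function(theta, beta, alpha, seed = NULL, item_ids = NULL,
                     subject_ids = NULL) {
  P <- length(beta)
  if (length(alpha) != P) stop("`alpha` and `beta` must have one entry per item")
  if (is.matrix(theta)) {
    if (ncol(theta) != P) stop("matrix `theta` needs one column per item")
    TH <- theta
  } else {
    TH <- matrix(theta, length(theta), P)
  }
  N <- nrow(TH)
  if (is.null(item_ids)) item_ids <- names(beta)
  if (is.null(item_ids)) item_ids <- paste0("I", seq_len(P))
  X <- matrix(NA_integer_, N, P)
  local_rng(seed, {
    for (i in seq_len(P)) {
      p <- gpcm_prob(TH[, i], beta[[i]], alpha[i])
      if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
      u <- stats::runif(N)
      cum <- t(apply(p, 1L, cumsum))
      X[, i] <- rowSums(u > cum)  # count of cumulative bins below u
    }
  })
  response_matrix(X, n_categories = lengths(beta) + 1L,
                  item_ids = item_ids, subject_ids = subject_ids)
}

# shared defaults of the simulated survey designs: 18 items in three 6-item
# blocks, 301 subjects, thresholds evenly spaced and centered
design_thresholds <- function(n_categories) {
  if (!n_categories %in% c(2L, 5L))
    stop("designs are defined for 2 or 5 response categories")
  if (n_categories == 2L) 0 else c(-1.5, -0.5, 0.5, 1.5)
}

theta_grid <- function(n_subjects, range = c(-3, 3))
  seq(range[1], range[2], length.out = n_subjects)

#' Inhomogeneous survey design
#'
#' Simulates a unidimensional survey whose three 6-item blocks differ
#' sharply in discrimination: items 1-6 have alpha in
#' {.04, .045, .05, .055, .06, .065} (responses close to noise), items 7-12
#' in {.2, .25, .3, .35, .4, .45}, and items 13-18 in
#' {2.6, 2.65, 2.7, 2.75, 2.8, 2.85} (highly predictable). Abilities sit on
#' an even grid over \[-3, 3\]; thresholds are evenly spaced and centered
#' (0 for dichotomous items, (-1.5, -.5, .5, 1.5) for 5-category items).
#' An item-selection procedure should discard the low-discrimination blocks
#' first and peak with the third block retained.
#'
#' @param n_categories 2 (dichotomous) or 5 (polytomous); default 5.
#' @param n_subjects number of subjects; default 301.
#' @param seed RNG seed.
#' @return list with `responses` ([response_matrix()]), the true `theta`,
#'   `beta`, `alpha`, and `block` labels (1-3 per item).
#' @export
sim_inhomogeneous <- function(n_categories = 5, n_subjects = 301, seed = NULL) {
  alpha <- c(seq(0.040, 0.065, by = 0.005),
             seq(0.20, 0.45, by = 0.05),
             seq(2.60, 2.85, by = 0.05))
  P <- length(alpha)
  beta <- rep(list(design_thresholds(n_categories)), P)
  names(beta) <- paste0("I", seq_len(P))
  theta <- theta_grid(n_subjects)
  resp <- sim_gpcm(theta, beta, alpha, seed = seed)
  list(responses = resp, theta = theta, beta = beta,
       alpha = stats::setNames(alpha, names(beta)),
       block = rep(1:3, each = P %/% 3L))
}

#' Uncorrelated multidimensional survey design
#'
#' Simulates a survey whose three 6-item blocks measure three unrelated
#' dimensions: the first block's abilities sit on an even grid over
#' \[-3, 3\] and the other two blocks use independent random permutations of
#' the same values (so the three ability vectors are uncorrelated by
#' construction). All items share the same discrimination. A unidimensional
#' selection procedure should keep one complete block and discard the other
#' two, block by block.
#'
#' @inheritParams sim_inhomogeneous
#' @param alpha common discrimination of all items; default 1 (partial
#'   credit model).
#' @return list with `responses`, `theta` (N x 3 matrix of block abilities),
#'   `beta`, `alpha`, and `block` labels.
#' @export
sim_multidimensional <- function(n_categories = 5, n_subjects = 301,
                                 alpha = 1, seed = NULL) {
  base <- theta_grid(n_subjects)
  TH3 <- local_rng(seed, cbind(base, sample(base), sample(base)))
  colnames(TH3) <- paste0("dim", 1:3)
  block <- rep(1:3, each = 6L)
  beta <- rep(list(design_thresholds(n_categories)), 18L)
  names(beta) <- paste0("I", 1:18)
  alpha_vec <- rep(alpha, 18L)
  seed2 <- if (is.null(seed)) NULL else seed + 1L
  resp <- sim_gpcm(TH3[, block], beta, alpha_vec, seed = seed2)
  list(responses = resp, theta = TH3, beta = beta,
       alpha = stats::setNames(alpha_vec, names(beta)), block = block)
}

#' Correlated two-dimensional survey design
#'
#' Simulates a polytomous survey with two 6-item blocks measuring two
#' correlated dimensions. The two ability vectors are built from a bivariate
#' normal construction with the *empirical* Pearson correlation equal to
#' `rho` exactly (the second vector is assembled from the standardized first
#' vector plus its orthogonalized residual), then each is linearly mapped
#' onto \[-4, 4\]; affine maps per vector leave the correlation unchanged.
#' At low correlation a unidimensional selection procedure keeps one block;
#' as the correlation grows the two dimensions become mutually predictive
#' and the selected set starts to mix items from both.
#'
#' @param rho target correlation between the two ability vectors, in (-1, 1)
#'   (the simulations of interest use .2 to .6).
#' @inheritParams sim_multidimensional
#' @return list with `responses` (12 items), `theta` (N x 2), `beta`,
#'   `alpha`, `block` labels (1-2), and `rho`.
#' @export
sim_correlated <- function(rho, n_categories = 5, n_subjects = 301,
                           alpha = 1, seed = NULL) {
  if (rho <= -1 || rho >= 1) stop("`rho` must lie in (-1, 1)")
  TH2 <- local_rng(seed, {
    z1 <- stats::rnorm(n_subjects)
    z2 <- stats::rnorm(n_subjects)
    z1s <- as.numeric(scale(z1))
    e <- stats::residuals(stats::lm(z2 ~ z1s))     # exactly orthogonal to z1s
    es <- as.numeric(scale(e))
    cbind(z1s, rho * z1s + sqrt(1 - rho^2) * es)
  })
  to_range <- function(v, lo = -4, hi = 4)
    (v - min(v)) / (max(v) - min(v)) * (hi - lo) + lo
  TH2 <- apply(TH2, 2L, to_range)
  colnames(TH2) <- paste0("dim", 1:2)
  block <- rep(1:2, each = 6L)
  beta <- rep(list(design_thresholds(n_categories)), 12L)
  names(beta) <- paste0("I", 1:12)
  alpha_vec <- rep(alpha, 12L)
  seed2 <- if (is.null(seed)) NULL else seed + 1L
  resp <- sim_gpcm(TH2[, block], beta, alpha_vec, seed = seed2)
  list(responses = resp, theta = TH2, beta = beta,
       alpha = stats::setNames(alpha_vec, names(beta)), block = block,
       rho = rho)
}
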