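#' BayesC-pi marker-effect model via Gibbs sampling
#'
#' Bayesian variable-selection model in which marker `j` is excluded with
#' probability `pi` and, when included, its effect is drawn from a single
#' normal distribution `N(0, sigma_u2)` shared by all included markers.
#' `pi` has a Uniform(0, 1) prior and is updated from its conjugate Beta
#' posterior; `sigma_u2` has a scaled-inverse-chi-squared prior with `nu_u`
#' degrees of freedom and scale `S_u2 = (nu_u - 2) sigma_tilde_u2 / nu_u`,
#' where `sigma_tilde_u2` spreads the phenotypic variance of the line means
#' over the expected number of included markers:
#' `sigma_tilde_u2 = var(y) / (m (1 - pi) mean_marker_variance)`, with
#' `(1 - pi)` floored at `1/m`. The residual variance has a flat
#' scaled-inverse-chi-squared prior (`nu = -2`, scale 0). A single chain is
#' run; the update order per sweep is the intercept, then loci in index order
#' with `(delta_j, u_j)` sampled jointly, then `sigma_u2`, `sigma_e2`, `pi`.
#'
#' Returned effects are posterior means of `delta_j u_j` over post-burn-in
#' samples, and `pip` gives posterior inclusion probabilities.
#'
#' The `fix_*` arguments freeze parts of the sampler: with `fix_delta = TRUE`
#' (all markers always included) and fixed variances, the posterior mean
#' converges to the RR-BLUP solution at `lambda = sigma_e2 / sigma_u2`, which
#' is used as a cross-check in the test suite.
#'
#' @inheritParams fit_rrblup
#' @param n_iter total Gibbs iterations (default 3000).
#' @param burn_in iterations discarded (default 1000).
#' @param nu_u prior degrees of freedom for the marker-effect variance
#'   (default 4).
#' @param pi_init initial (or fixed) exclusion probability.
#' @param fix_pi if `TRUE`, `pi` stays at `pi_init`.
#' @param fix_delta if `TRUE`, all markers are always included.
#' @param sigma_u2,sigma_e2 optional fixed variance components; when both are
#'   supplied the variance updates are skipped.
#' @return a `gs_fit` with `method = "bayescpi"`, posterior-mean `mu` and
#'   `effects`, `pip`, and posterior means `pi`, `sigma_u2`, `sigma_e2`.
#' @export
fit_bayescpi <- function(Z, y, n_iter = 3000, burn_in = 1000, nu_u = 4,
                         pi_init = 0.5, fix_pi = FALSE, fix_delta = FALSE,
                         sigma_u2 = NULL, sigma_e2 = NULL) {
  Z <- as.matrix(Z)
  storage.mode(Z) <- "double"
  n <- nrow(Z)
  if (length(y) != n) stop("length(y) must equal nrow(Z)", call. = FALSE)
  if (any(!is.finite(y))) stop("phenotypes must be finite", call. = FALSE)
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in", call. = FALSE)
  fixed_vars <- !is.null(sigma_u2) && !is.null(sigma_e2)
  res <- cpp_bayescpi(Z, as.numeric(y), as.integer(n_iter),
                      as.integer(burn_in), nu_u, pi_init,
                      update_pi = !fix_pi, update_delta = !fix_delta,
                      update_vars = !fixed_vars,
                      sigma_u2_init = if (is.null(sigma_u2)) -1 else sigma_u2,
                      sigma_e2_init = if (is.null(sigma_e2)) -1 else sigma_e2)
  new_gs_fit("bayescpi", mu = res$mu, effects = res$effects, pip = res$pip,
             pi = res$pi, sigma_u2 = res$sigma_u2, sigma_e2 = res$sigma_e2,
             n_samples = res$n_samples)
}
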