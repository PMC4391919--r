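#' Sampler configuration
#'
#' Bundle the MCMC schedule and model choices for [gibbs_blasso()] /
#' [gibbs_bridge()].  The default schedule (burn-in 25000, thinning 4, 10000
#' retained draws for a fixed tuning parameter; burn-in 70000, thinning 10,
#' 15000 draws when the tuning parameter is random) mirrors the long chains
#' used in published line-cross analyses; much shorter chains are adequate for
#' exploratory scans.
#'
#' @param model `"lasso"` (scale-mixture Laplace prior) or `"ridge"`
#'   (Gaussian prior `beta | sigma2, lambda ~ N(0, sigma2/lambda I)`).
#' @param lambda fixed tuning parameter (> 0), or `NULL` for a random tuning
#'   parameter with improper prior `p(lambda) ~ 1/lambda`.
#' @param burn_in,thin,n_draws MCMC schedule; `NULL` picks the defaults above.
#' @param seed integer seed; every draw of the chain flows from it.
#' @param center_y if `TRUE`, the phenotype is centered and the intercept is
#'   fixed at zero; by default the intercept is sampled under a flat prior.
#' @param standardize if `TRUE`, columns of the design are scaled to unit
#'   sample standard deviation before fitting (off by default: -1/+1 genotype
#'   codings are conventionally left unstandardized).
#' @param keep_tau2 retain the tau^2 augmentation draws (lasso only).
#' @return list of class `sampler_config`.
#' @export
sampler_config <- function(model = c("lasso", "ridge"), lambda = NULL,
                           burn_in = NULL, thin = NULL, n_draws = NULL,
                           seed = 1L, center_y = FALSE, standardize = FALSE,
                           keep_tau2 = FALSE) {
  model <- match.arg(model)
  lambda_random <- is.null(lambda)
  if (!lambda_random) {
    if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
        lambda <= 0)
      stop("sampler_config: fixed lambda must be a positive number")
  }
  if (is.null(burn_in)) burn_in <- if (lambda_random) 70000L else 25000L
  if (is.null(thin))    thin    <- if (lambda_random) 10L else 4L
  if (is.null(n_draws)) n_draws <- if (lambda_random) 15000L else 10000L
  burn_in <- as.integer(burn_in); thin <- as.integer(thin)
  n_draws <- as.integer(n_draws)
  if (burn_in < 0L) stop("sampler_config: burn_in must be >= 0")
  if (thin < 1L) stop("sampler_config: thin must be >= 1")
  if (n_draws < 1L) stop("sampler_config: n_draws must be >= 1")
  structure(list(model = model, lambda = lambda,
                 lambda_random = lambda_random, burn_in = burn_in,
                 thin = thin, n_draws = n_draws, seed = as.integer(seed),
                 center_y = isTRUE(center_y),
                 standardize = isTRUE(standardize),
                 keep_tau2 = isTRUE(keep_tau2)),
            class = "sampler_config")
}

validate_xy <- function(X, y) {
  X <- as_plain_matrix(X)
  if (ncol(X) == 0L) stop("gibbs sampler: design matrix has no markers")
  check_complete(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X))
    stop("gibbs sampler: phenotype length does not match design rows")
  if (any(!is.finite(y)))
    stop("gibbs sampler: phenotype contains non-finite values")
  list(X = X, y = y)
}

run_gibbs <- function(X, y, config, ridge) {
  d <- validate_xy(X, y)
  X <- d$X; y <- d$y
  if (config$standardize) {
    s <- apply(X, 2L, stats::sd)
    s[s == 0] <- 1
    X <- sweep(X, 2L, s, "/")
  }
  sample_mu <- !config$center_y
  if (config$center_y) y <- y - mean(y)
  lam0 <- if (config$lambda_random) 1 else config$lambda
  set.seed(config$seed)
  res <- gibbs_shrinkage_cpp(X, y, lam0, config$lambda_random,
                             config$burn_in, config$thin, config$n_draws,
                             ridge, config$keep_tau2, sample_mu)
  colnames(res$beta) <- colnames(X)
  out <- list(beta = res$beta, mu = res$mu, sigma2 = res$sigma2,
              tau2 = res$tau2, lambda = res$lambda,
              config = config, model = if (ridge) "ridge" else "lasso",
              marker_names = colnames(X), n = nrow(X), m = ncol(X),
              seed = config$seed)
  class(out) <- "posterior_draws"
  out
}

#' Gibbs sampler for the Bayesian LASSO
#'
#' Samples the hierarchical Bayesian LASSO: Gaussian likelihood, conditional
#' Laplace prior on the marker effects expressed through the usual
#' exponential scale mixture, improper prior `1/sigma2` on the noise
#' variance, flat prior on the intercept, and (optionally) the improper prior
#' `1/lambda` on the tuning parameter.  All full conditionals are conjugate:
#' normal for each effect and the intercept, inverse-gamma for the noise
#' variance, inverse-Gaussian for the reciprocal mixture scales, and gamma
#' for `lambda^2` when the tuning parameter is random.
#'
#' @param X a [genotype_matrix()] or numeric design matrix without missing
#'   entries (apply [impute_missing()] first).
#' @param y numeric phenotype vector, one value per design row.
#' @param config a [sampler_config()].
#' @return object of class `posterior_draws`: retained draws of `beta`
#'   (`n_draws` x m), `mu`, `sigma2`, optionally `tau2` and `lambda`, plus
#'   the configuration and seed.
#' @examples
#' X <- simulate_linecross_genotypes(40, 3, r = 0.5, seed = 1)
#' y <- make_phenotype(X, c(2, 0, 0), noise_sd = 1, seed = 2)
#' fit <- gibbs_blasso(X, y, sampler_config(lambda = 2, burn_in = 200,
#'                                          thin = 1, n_draws = 200))
#' posterior_summary(fit)
#' @seealso [gibbs_bridge()], [posterior_summary()], [ss_scan()]
#' @export
gibbs_blasso <- function(X, y, config = sampler_config()) {
  stopifnot(inherits(config, "sampler_config"))
  run_gibbs(X, y, config, ridge = FALSE)
}

#' Gibbs sampler for Bayesian ridge regression
#'
#' Same hierarchy as [gibbs_blasso()] but with the Gaussian prior
#' `beta | sigma2, lambda ~ N(0, sigma2/lambda I)`, so `lambda` plays the
#' same penalty role as in the LASSO (larger values shrink harder).  With a
#' random tuning parameter, `lambda | rest` is gamma with shape m/2 and rate
#' `sum(beta^2)/(2 sigma2)`.
#'
#' @inheritParams gibbs_blasso
#' @return object of class `posterior_draws`.
#' @export
gibbs_bridge <- function(X, y, config = sampler_config(model = "ridge")) {
  stopifnot(inherits(config, "sampler_config"))
  run_gibbs(X, y, config, ridge = TRUE)
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws: %s model, %d draws x %d markers (n = %d)%s\n",
              x$model, nrow(x$beta), x$m, x$n,
              if (is.null(x$lambda))
                sprintf(", lambda = %g", x$config$lambda)
              else ", random lambda"))
  invisible(x)
}

#' Per-coefficient posterior summaries
#'
#' Column means, standard deviations and sign proportions of the retained
#' effect draws.  Draws exactly equal to zero (possible only for degenerate
#' input) count toward neither sign.
#'
#' @param draws a `posterior_draws` object from [gibbs_blasso()] /
#'   [gibbs_bridge()], or a draws matrix (S x m).
#' @return data frame with one row per coefficient: `mean`, `sd`, `p_pos`,
#'   `p_neg`.
#' @export
posterior_summary <- function(draws) {
  B <- if (inherits(draws, "posterior_draws")) draws$beta else as.matrix(draws)
  if (nrow(B) < 1L || length(B) == 0L)
    stop("posterior_summary: no draws")
  data.frame(
    marker = colnames(B) %||% paste0("M", seq_len(ncol(B))),
    mean = colMeans(B),
    sd = apply(B, 2L, stats::sd),
    p_pos = colMeans(B > 0),
    p_neg = colMeans(B < 0),
    row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Full-conditional parameter bookkeeping for the Bayesian LASSO hierarchy.
# These mirror the updates the C++ sampler performs and are used to verify
# conjugacy in unit tests; they are not part of the fitting path.
cond_beta_j <- function(xj, r_minus_j, sigma2, prior_prec) {
  prec <- sum(xj^2) + prior_prec
  list(mean = sum(xj * r_minus_j) / prec, var = sigma2 / prec)
}

cond_sigma2 <- function(resid, beta, invtau2) {
  list(shape = (length(resid) + length(beta)) / 2,
       rate = (sum(resid^2) + sum(beta^2 * invtau2)) / 2)
}

cond_invtau2 <- function(beta_j, sigma2, lambda) {
  list(mean = lambda * sqrt(sigma2) / max(abs(beta_j), 1e-10),
       shape = lambda^2)
}

cond_lambda2 <- function(tau2) {
  list(shape = length(tau2), rate = sum(tau2) / 2)
}
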