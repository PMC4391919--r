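#' Count false positives in a credibility-type vector
#'
#' A locus counts as a (potential) false positive when its credibility type
#' is `1`, `-1`, `0.75` or `-0.75`: either its own effect is credible or it
#' is the stronger member of a credible combined effect.  Weaker members
#' (types `+/-0.25`) are not counted, because one real association can make
#' many combined effects credible.
#'
#' @param types numeric credibility-type vector (see [credibility_types()]).
#' @return integer count.
#' @export
false_positive_count <- function(types) {
  sum(abs(types) >= 0.75)
}

# Shared permutation engine: builds the full credibility map for every
# (permutation, lambda) pair once, and records PW/HPW false-positive counts
# and the maximum marginal sign probability.  The same permutation set is
# reused across lambda so per-lambda comparisons share their nulls.
#
# inference_fn, when supplied, replaces the sampler+inference pipeline for
# testing; contract: inference_fn(X, y_perm, lambda) returns a
# credibility-type vector, or a list(types=, max_q=).
permutation_null_scan <- function(X, y, grid, config, n_perm,
                                  alpha_pw = 0.975, alpha_hpw = 0.95,
                                  rho = 0.8, use_combined = TRUE,
                                  seed = config$seed, inference_fn = NULL) {
  if (n_perm < 1L) stop("calibration: n_perm must be >= 1")
  if (length(grid) < 1L || any(diff(grid) <= 0) || any(grid <= 0))
    stop("calibration: grid must be increasing and positive")
  Xp <- as_plain_matrix(X)
  y <- as.numeric(y)
  L <- length(grid); P <- as.integer(n_perm)
  set.seed(seed)
  perms <- replicate(P, sample.int(length(y)), simplify = FALSE)
  catalog <- if (use_combined && is.null(inference_fn))
    enumerate_pairs(Xp, rho) else NULL
  fp_pw <- matrix(NA_integer_, L, P)
  fp_hpw <- matrix(NA_integer_, L, P)
  max_q <- matrix(NA_real_, L, P)
  for (p in seq_len(P)) {
    yp <- y[perms[[p]]]
    for (i in seq_len(L)) {
      if (!is.null(inference_fn)) {
        res <- inference_fn(Xp, yp, grid[i])
        if (is.list(res)) {
          types <- res$types
          max_q[i, p] <- res$max_q %||% NA_real_
        } else {
          types <- res
        }
        fp_pw[i, p] <- false_positive_count(types)
        fp_hpw[i, p] <- fp_pw[i, p]
      } else {
        cfg <- config
        cfg$lambda <- grid[i]
        cfg$lambda_random <- FALSE
        cfg$seed <- scan_chain_seed(seed, (p - 1L) * L + i)
        fit <- run_gibbs(Xp, yp, cfg, ridge = (config$model == "ridge"))
        es <- combined_effect_draws(fit, catalog)
        pw <- pw_detect(es, alpha_pw)
        hpw <- hpw_select(es, alpha_hpw)
        fp_pw[i, p] <- false_positive_count(credibility_types(pw, ncol(Xp)))
        fp_hpw[i, p] <- false_positive_count(credibility_types(hpw, ncol(Xp)))
        max_q[i, p] <- max(pw$q)
      }
    }
  }
  list(grid = grid, n_perm = P, seed = seed,
       fp_pw = fp_pw, fp_hpw = fp_hpw, max_q = max_q)
}

# smallest grid value from which on the zero-false-positive fraction stays
# at or above `level`; NA (with a warning) if even the largest value fails
lambda_threshold_from_fp <- function(fp, grid, level) {
  zero_frac <- rowMeans(fp == 0)
  ok <- zero_frac >= level
  if (!ok[length(ok)]) {
    warning("no tuning-parameter value reaches the requested null level; ",
            "consider extending the grid upward")
    return(NA_real_)
  }
  # smallest index i such that ok[i:L] are all TRUE
  idx <- max(c(0L, which(!ok))) + 1L
  grid[idx]
}

alpha_from_maxima <- function(maxima, level) {
  # conservative, interpolation-free empirical quantile: the smallest
  # observed maximum m_(i) with i/n >= level
  s <- sort(maxima)
  s[ceiling(level * length(s))]
}

#' Permutation-based lower bound for the tuning parameter
#'
#' Repeatedly permutes the phenotype (destroying any marker association),
#' rebuilds the full credibility map for every permutation, and reports the
#' smallest grid value of the tuning parameter from which on at least
#' `level` of the permutations produce *no* false detections (loci of
#' credibility type `+/-1` or `+/-0.75`).
#'
#' @inheritParams ss_scan
#' @param n_perm number of phenotype permutations (100 in full-scale
#'   analyses; 20 is a practical scaled-down default).
#' @param level required fraction of clean permutations (default 0.95).
#' @param mode `"pw"` or `"hpw"` inference for the null maps.
#' @param inference_fn optional stub replacing the sampling pipeline, for
#'   testing: `function(X, y_perm, lambda)` returning a credibility-type
#'   vector.
#' @return object of class `ss_calibration`: `lambda_threshold` (a grid
#'   element, or `NA` if even the largest grid value fails), the
#'   lambda x permutation false-positive count matrix `fp`, `grid`,
#'   `n_perm`, `level`, `mode`, `seed`.
#' @export
permutation_lambda_threshold <- function(X, y, grid,
                                         config = sampler_config(lambda = 1),
                                         n_perm = 20L, level = 0.95,
                                         mode = c("pw", "hpw"),
                                         alpha_pw = 0.975, alpha_hpw = 0.95,
                                         rho = 0.8, use_combined = TRUE,
                                         seed = config$seed,
                                         inference_fn = NULL) {
  mode <- match.arg(mode)
  ns <- permutation_null_scan(X, y, grid, config, n_perm, alpha_pw,
                              alpha_hpw, rho, use_combined, seed,
                              inference_fn)
  fp <- if (mode == "pw") ns$fp_pw else ns$fp_hpw
  structure(list(mode = mode,
                 lambda_threshold = lambda_threshold_from_fp(fp, grid, level),
                 fp = fp, grid = grid, n_perm = ns$n_perm, level = level,
                 seed = seed),
            class = "ss_calibration")
}

#' Tuning-parameter-dependent credibility level from permutations
#'
#' For each tuning-parameter grid value, permuting the phenotype gives the
#' null distribution of the *maximum* marginal sign probability over all
#' effects (and combined effects); `alpha(lambda)` is its empirical
#' `level`-quantile (the smallest observed maximum whose rank fraction
#' reaches `level`).  Detection then uses the threshold
#' `max(alpha(lambda), 0.975)`; see [detect_with_alpha_curve()].
#'
#' @inheritParams permutation_lambda_threshold
#' @return object of class `ss_calibration` with the `alpha` curve (one
#'   value per grid element), the lambda x permutation maxima matrix
#'   `max_q`, `grid`, `n_perm`, `level`, `seed`.
#' @export
alpha_curve <- function(X, y, grid, config = sampler_config(lambda = 1),
                        n_perm = 20L, level = 0.95, alpha_pw = 0.975,
                        rho = 0.8, use_combined = TRUE, seed = config$seed,
                        inference_fn = NULL) {
  ns <- permutation_null_scan(X, y, grid, config, n_perm, alpha_pw,
                              alpha_hpw = 0.95, rho, use_combined, seed,
                              inference_fn)
  if (anyNA(ns$max_q))
    stop("alpha_curve: the inference stub must supply max_q")
  alpha <- apply(ns$max_q, 1L, alpha_from_maxima, level = level)
  alpha <- pmin(pmax(alpha, 0.5), 1)
  structure(list(mode = "alpha", alpha = alpha, max_q = ns$max_q,
                 grid = grid, n_perm = ns$n_perm, level = level,
                 seed = seed),
            class = "ss_calibration")
}

#' @export
print.ss_calibration <- function(x, ...) {
  if (!is.null(x$alpha)) {
    cat(sprintf("alpha(lambda) curve over %d grid values, %d permutations\n",
                length(x$grid), x$n_perm))
  } else {
    cat(sprintf("%s permutation threshold: lambda* = %s (%d permutations, level %g)\n",
                toupper(x$mode),
                if (is.na(x$lambda_threshold)) "none"
                else format(x$lambda_threshold, digits = 4),
                x$n_perm, x$level))
  }
  invisible(x)
}

#' Detection with a tuning-parameter-dependent credibility level
#'
#' Re-flags the effects of a scale-space scan using, at each grid value, the
#' threshold `max(alpha(lambda), floor)`: an effect is credible when its
#' marginal sign probability strictly exceeds it.  Credibility types are
#' recomputed accordingly.
#'
#' @param maps a `scale_space` from [ss_scan()].
#' @param curve an `ss_calibration` from [alpha_curve()] on the same grid.
#' @param floor lower bound for the threshold (default 0.975, the
#'   conventional point-wise level).
#' @return list with `types` (lambda x locus credibility-type matrix),
#'   `threshold` (per-lambda applied level) and the grid.
#' @export
detect_with_alpha_curve <- function(maps, curve, floor = 0.975) {
  stopifnot(inherits(maps, "scale_space"), inherits(curve, "ss_calibration"))
  if (is.null(curve$alpha))
    stop("detect_with_alpha_curve: 'curve' carries no alpha curve")
  if (length(curve$grid) != length(maps$grid) ||
      any(abs(log10(curve$grid) - log10(maps$grid)) > 1e-8))
    stop("detect_with_alpha_curve: curve and maps grids do not match")
  L <- length(maps$grid)
  m <- ncol(maps$mean_beta)
  threshold <- pmax(curve$alpha, floor)
  types <- matrix(0, L, m)
  for (i in seq_len(L)) {
    det <- data.frame(label = maps$effects$label, kind = maps$effects$kind,
                      j = maps$effects$j, k = maps$effects$k,
                      q = maps$q[i, ], sign = maps$sign[i, ],
                      credible = maps$q[i, ] > threshold[i],
                      stringsAsFactors = FALSE)
    types[i, ] <- credibility_types(det, m)
  }
  list(types = types, threshold = threshold, grid = maps$grid)
}
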