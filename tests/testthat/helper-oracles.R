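# Independent oracles and small utilities shared across the test files.
# Everything here is deliberately written as plainly as possible (loops,
# direct counting, dense grids) and never calls back into the code paths it
# is used to check.

# Monte-Carlo standard error of a chain mean by batch means (accounts for
# autocorrelation of the Gibbs draws).
mcse_mean <- function(x, n_batches = 40L) {
  n <- length(x)
  b <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(i) mean(x[((i - 1L) * b + 1L):(i * b)]),
                  numeric(1))
  sd(means) / sqrt(n_batches)
}

# Dense-grid quadrature of the Bayesian LASSO posterior for m = 1 or 2
# markers: likelihood N(y; mu 1 + X b, s2 I) with the intercept integrated
# analytically under its flat prior, conditional Laplace prior with rate
# lambda/sqrt(s2) per coefficient (the analytic integral of the exponential
# scale mixture), and p(s2) ~ 1/s2.  Returns posterior means and positive
# sign probabilities per coefficient.
quad_blasso <- function(X, y, lambda, n_b = 241L, n_s = 161L, span = 6) {
  X <- as.matrix(X)
  n <- length(y); m <- ncol(X)
  stopifnot(m %in% c(1L, 2L))
  ls_fit <- lm.fit(cbind(1, X), y)
  bhat <- ls_fit$coefficients[-1L]
  s2hat <- sum(ls_fit$residuals^2) / max(n - m - 1, 1)
  se <- sqrt(s2hat * diag(solve(crossprod(cbind(1, X)))))[-1L]
  grids <- lapply(seq_len(m), function(j) {
    half <- span * max(se[j], 0.2) + abs(bhat[j])
    seq(-half, half, length.out = n_b) + 0 # symmetric around 0 keeps the
  })                                       # sign integral exact at b = 0
  s2 <- exp(seq(log(s2hat / 60), log(s2hat * 60), length.out = n_s))
  # log posterior over the grid; s2 integrated on the log scale, whose
  # jacobian cancels one power of the 1/s2 prior
  log_post <- function(b) {
    r <- y - X %*% b
    Sc <- sum((r - mean(r))^2)
    -((n - 1) / 2 + m / 2) * log(s2) - Sc / (2 * s2) -
      lambda * sum(abs(b)) / sqrt(s2)
  }
  if (m == 1L) {
    lp <- t(vapply(grids[[1L]], function(b) log_post(b), numeric(n_s)))
    w <- exp(lp - max(lp))
    pb <- rowSums(w); pb <- pb / sum(pb)
    list(mean = sum(grids[[1L]] * pb),
         p_pos = sum(pb[grids[[1L]] > 0]))
  } else {
    lp <- array(NA_real_, c(n_b, n_b, n_s))
    for (i in seq_len(n_b)) for (j in seq_len(n_b))
      lp[i, j, ] <- log_post(c(grids[[1L]][i], grids[[2L]][j]))
    w <- exp(lp - max(lp))
    pb1 <- apply(w, 1L, sum); pb1 <- pb1 / sum(pb1)
    pb2 <- apply(w, 2L, sum); pb2 <- pb2 / sum(pb2)
    list(mean = c(sum(grids[[1L]] * pb1), sum(grids[[2L]] * pb2)),
         p_pos = c(sum(pb1[grids[[1L]] > 0]), sum(pb2[grids[[2L]] > 0])))
  }
}

# Exact posterior mean of the Bayesian ridge effects: with the prior
# variance proportional to s2, the conditional mean (X'CX + lambda I)^-1
# X'Cy (C the centering projector from the flat intercept prior) does not
# depend on s2, so it is also the marginal posterior mean.
ridge_exact_mean <- function(X, y, lambda) {
  X <- as.matrix(X); n <- length(y)
  C <- diag(n) - matrix(1 / n, n, n)
  drop(solve(crossprod(X, C %*% X) + lambda * diag(ncol(X)),
             crossprod(X, C %*% y)))
}

# Brute-force re-implementation of greedy HPW selection by exhaustive draw
# counting.  `kind`, `j`, `k` describe the effect columns as in an
# effect_set.  Returns the selected column indices.
brute_hpw <- function(draws, kind, j, k, alpha) {
  ne <- ncol(draws)
  q <- numeric(ne); sgn <- character(ne)
  for (e in seq_len(ne)) {
    pp <- sum(draws[, e] > 0) / nrow(draws)
    pn <- sum(draws[, e] < 0) / nrow(draws)
    q[e] <- max(pp, pn)
    sgn[e] <- if (pp >= pn) "+" else "-"
  }
  ord <- order(-q, kind == "single", seq_len(ne))
  sel <- integer(0)
  for (e in ord) {
    markers_of <- function(i) if (kind[i] == "single") j[i] else c(j[i], k[i])
    blocked <- FALSE
    for (s in sel) {
      if (kind[e] == "single" && kind[s] != "single" &&
          j[e] %in% markers_of(s)) blocked <- TRUE
      if (kind[e] != "single" &&
          length(intersect(markers_of(e), markers_of(s)))) blocked <- TRUE
    }
    if (blocked) next
    trial <- c(sel, e)
    count <- 0L
    for (d in seq_len(nrow(draws))) {
      all_ok <- TRUE
      for (s in trial) {
        v <- draws[d, s]
        if (sgn[s] == "+" && v <= 0) all_ok <- FALSE
        if (sgn[s] == "-" && v >= 0) all_ok <- FALSE
      }
      if (all_ok) count <- count + 1L
    }
    if (count / nrow(draws) > alpha) sel <- trial else break
  }
  sort(sel)
}

# Brute-force combined-effect pair enumeration with the missing-as-zero
# agreement rules, by explicit elementwise counting.
brute_pairs <- function(X, rho) {
  n <- nrow(X); m <- ncol(X)
  out <- data.frame(j = integer(0), k = integer(0), kind = character(0),
                    prop = numeric(0))
  for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
    agree <- 0L; disagree <- 0L
    for (i in seq_len(n)) {
      u <- X[i, a]; v <- X[i, b]
      if (u != 0 && u == v) agree <- agree + 1L
      else if (!(u == 0 && v == 0)) disagree <- disagree + 1L
    }
    if (agree / n > rho)
      out <- rbind(out, data.frame(j = a, k = b, kind = "sum",
                                   prop = agree / n))
    if (disagree / n > rho)
      out <- rbind(out, data.frame(j = a, k = b, kind = "difference",
                                   prop = disagree / n))
  }
  out
}

# quick +/-1 design helper
pm1 <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ifelse(runif(n) < 0.5, 1, -1)
}

test_schedule <- function(lambda = NULL, seed = 1L, n_draws = 2000L) {
  sampler_config(lambda = lambda, burn_in = 2000L, thin = 2L,
                 n_draws = n_draws, seed = seed)
}
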