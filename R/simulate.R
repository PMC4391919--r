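#' Simulate line-cross genotypes with Markov-correlated markers
#'
#' Each individual's marker sequence is an independent two-state \{-1, +1\}
#' Markov chain along the genome: the first marker is uniform and each
#' subsequent marker flips with probability `r` (a recombination-like rate).
#' The correlation between adjacent marker columns is `1 - 2r`, so `r = 0.1`
#' emulates a dense line-cross map with adjacent correlation about 0.8 and
#' `r = 0.5` gives mutually independent markers.
#'
#' @param n individuals (>= 2).
#' @param m markers (>= 1).
#' @param r flip probability between adjacent markers, in \[0, 0.5\].
#' @param seed optional integer seed.
#' @param p_first probability of +1 at the first marker, per column chain
#'   start (length 1; default 0.5).
#' @return a [genotype_matrix()] with entries in \{-1, +1\}.
#' @export
simulate_linecross_genotypes <- function(n, m, r = 0.1, seed = NULL,
                                         p_first = 0.5) {
  if (!is.numeric(r) || length(r) != 1L || r < 0 || r > 0.5)
    stop("simulate_linecross_genotypes: r must lie in [0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  first <- ifelse(stats::runif(n) < p_first, 1, -1)
  X <- matrix(0, n, m)
  X[, 1L] <- first
  if (m > 1L) {
    flips <- matrix(stats::runif(n * (m - 1L)) < r, n, m - 1L)
    for (j in 2:m) X[, j] <- X[, j - 1L] * ifelse(flips[, j - 1L], -1, 1)
  }
  genotype_matrix(X)
}

#' Inject missing genotypes uniformly at random
#'
#' @param X a [genotype_matrix()].
#' @param rate per-entry missingness probability in \[0, 1).
#' @param seed optional integer seed.
#' @return the genotype matrix with entries set to `NA`.
#' @export
inject_missing <- function(X, rate, seed = NULL) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    stop("inject_missing: rate must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  mask <- matrix(stats::runif(length(X)) < rate, nrow(X), ncol(X))
  X[mask] <- NA
  X
}

#' Resolve missing genotypes
#'
#' `"impute_random_pm1"` draws -1/+1 with equal probability, once per missing
#' entry (a single imputation for the whole analysis, not one per chain);
#' `"set_zero"` applies the missing-as-neutral policy, setting missing
#' entries to 0.
#'
#' @param X a [genotype_matrix()] possibly containing `NA`.
#' @param policy `"impute_random_pm1"` or `"set_zero"`.
#' @param seed optional integer seed (random policy).
#' @return a complete [genotype_matrix()].
#' @export
impute_missing <- function(X, policy = c("impute_random_pm1", "set_zero"),
                           seed = NULL) {
  policy <- match.arg(policy)
  na <- is.na(X)
  if (!any(na)) return(X)
  if (policy == "set_zero") {
    X[na] <- 0
  } else {
    if (!is.null(seed)) set.seed(seed)
    X[na] <- ifelse(stats::runif(sum(na)) < 0.5, 1, -1)
  }
  X
}

#' Remove markers and record flanking loci
#'
#' Deletes the given marker columns (e.g. markers with too many missing
#' values, or QTL markers removed deliberately so that only their flanking
#' markers carry the signal) and records, for every removed locus with a
#' nonzero true effect, the nearest kept neighbors on each side in
#' *post-removal* indexing, and for every kept locus with nonzero effect its
#' adjusted index.
#'
#' @param X a [genotype_matrix()].
#' @param beta_true length-m true effect vector (zeros at non-QTL loci).
#' @param removal_set integer indices of columns to delete.
#' @return list with `X` (columns deleted), `beta` (effects of the kept
#'   loci), and `map`: a data frame with one row per QTL locus (nonzero
#'   `beta_true`), columns `original`, `effect`, `removed`, `adj1`, `adj2`
#'   (`adj2` is `NA` for kept loci and for boundary loci with a single
#'   neighbor).
#' @export
remove_markers <- function(X, beta_true, removal_set) {
  m <- ncol(X)
  removal_set <- unique(as.integer(removal_set))
  if (length(beta_true) != m)
    stop("remove_markers: beta_true length must equal the marker count")
  if (length(removal_set) &&
      (any(removal_set < 1L) || any(removal_set > m)))
    stop("remove_markers: removal_set indices out of range")
  kept <- setdiff(seq_len(m), removal_set)
  adj <- match(seq_len(m), kept)         # post-removal index of kept loci
  qtl <- which(beta_true != 0)
  rows <- lapply(qtl, function(loc) {
    if (loc %in% removal_set) {
      left <- kept[kept < loc]
      right <- kept[kept > loc]
      flank <- c(if (length(left)) adj[max(left)],
                 if (length(right)) adj[min(right)])
      if (!length(flank))
        stop(sprintf("remove_markers: removed locus %d has no kept neighbor", loc))
      data.frame(original = loc, effect = beta_true[loc], removed = TRUE,
                 adj1 = flank[1L],
                 adj2 = if (length(flank) > 1L) flank[2L] else NA_integer_)
    } else {
      data.frame(original = loc, effect = beta_true[loc], removed = FALSE,
                 adj1 = adj[loc], adj2 = NA_integer_)
    }
  })
  Xk <- X[, kept, drop = FALSE]
  Xk <- genotype_matrix(Xk, marker_names = colnames(X)[kept],
                        individual_ids = rownames(X))
  list(X = Xk, beta = beta_true[kept],
       map = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Simulate phenotypes from genotypes and true effects
#'
#' `y = X beta + e` with `e ~ N(0, noise_sd^2)` i.i.d., drawn once per data
#' set.  The phenotype is computed on the *complete* design, before any
#' marker removal.
#'
#' @param X complete [genotype_matrix()] (no `NA`).
#' @param beta_true length-m effect vector.
#' @param noise_sd noise standard deviation (>= 0), in trait units.
#' @param seed optional integer seed.
#' @return numeric phenotype vector of length n.
#' @export
make_phenotype <- function(X, beta_true, noise_sd, seed = NULL) {
  Xp <- as_plain_matrix(X)
  check_complete(Xp)
  if (length(beta_true) != ncol(Xp))
    stop("make_phenotype: beta_true length must equal the marker count")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("make_phenotype: noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  drop(Xp %*% beta_true) + stats::rnorm(nrow(Xp), 0, noise_sd)
}

#' Realized heritability
#'
#' Sample variance of the genetic values divided by the sample variance of
#' the phenotype: `Var(X beta) / Var(y)`.
#'
#' @inheritParams make_phenotype
#' @param y realized phenotype vector.
#' @return heritability estimate in \[0, +\].
#' @export
heritability <- function(X, beta_true, y) {
  g <- drop(as_plain_matrix(X) %*% beta_true)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0)
    stop("heritability: phenotype variance is zero or undefined")
  stats::var(g) / vy
}

# Table of true effects for the collinear line-cross (barley-like) design
barley_effects <- function() {
  data.frame(locus = c(3L, 10L, 20L, 34L, 51L, 72L, 84L, 108L),
             effect = c(3, 3.5, 4, -2.5, -3, -2, 3, -3))
}

# Table of true effects for the larger uncorrelated (wheat-like) design
wheat_effects <- function() {
  data.frame(locus = c(7L, 76L, 118L, 162L, 181L, 218L, 273L, 344L, 395L),
             effect = c(1.75, 2, 2.5, -2.25, 1.5, -2.25, -1.75, 2.5, -2.25))
}

#' Barley-like collinear line-cross fixture
#'
#' A full synthetic data set with the statistical structure of a classic
#' line-cross QTL design: 145 individuals, 127 Markov-correlated markers
#' (adjacent correlation about 0.8), eight QTLs (effects 3, 3.5, 4, -2.5,
#' -3, -2, 3, -3 at loci 3, 10, 20, 34, 51, 72, 84, 108), 3.4% genotypes
#' missing at random and singly imputed with random -1/+1, five designated
#' "high-missingness" markers removed, and four of the QTL markers (3, 51,
#' 84, 108) removed before analysis so that only their flanking markers
#' carry the signal.  Noise is Gaussian with standard deviation `sqrt(8)`,
#' which puts the realized heritability near 0.9, the regime of the design
#' this fixture emulates (see the package vignette for the reasoning).
#'
#' The removal bookkeeping reproduces the canonical adjusted indexing: kept
#' QTLs map to loci 9, 19, 33, 67 and the removed QTLs to flanking pairs
#' (2,3), (48,49), (78,79), (100,101).
#'
#' @param seed integer seed driving every random step.
#' @param noise_sd noise standard deviation (default `sqrt(8)`).
#' @param missing_rate uniform missingness rate (default 0.034).
#' @param r adjacent-marker flip probability (default 0.1).
#' @return list with `X` (145 x 118 analysis design), `y`, and `truth`:
#'   `beta_full` (length 127), `effects` table, `removed_high_missing`,
#'   `removed_qtl`, `map` (flanking bookkeeping from [remove_markers()]),
#'   `regions` (list of adjusted locus sets, one per QTL), `h2`, `noise_sd`,
#'   `seed`; plus `X_complete` (the imputed 127-column design used to form
#'   `y`).
#' @export
barley_fixture <- function(seed = 1L, noise_sd = sqrt(8),
                           missing_rate = 0.034, r = 0.1) {
  n <- 145L; m <- 127L
  high_missing <- c(40L, 60L, 65L, 95L, 115L)
  eff <- barley_effects()
  beta <- numeric(m); beta[eff$locus] <- eff$effect
  set.seed(seed)
  X0 <- simulate_linecross_genotypes(n, m, r)
  Xm <- inject_missing(X0, missing_rate)
  Xi <- impute_missing(Xm, "impute_random_pm1")
  y <- make_phenotype(Xi, beta, noise_sd)
  h2 <- heritability(Xi, beta, y)
  removal <- c(high_missing, c(3L, 51L, 84L, 108L))
  rem <- remove_markers(Xi, beta, removal)
  map <- rem$map
  regions <- lapply(seq_len(nrow(map)), function(i)
    stats::na.omit(c(map$adj1[i], map$adj2[i])))
  names(regions) <- map$original
  list(X = rem$X, y = y,
       truth = list(beta_full = beta, effects = eff,
                    removed_high_missing = high_missing,
                    removed_qtl = c(3L, 51L, 84L, 108L),
                    map = map, regions = regions, h2 = h2,
                    noise_sd = noise_sd, seed = seed),
       X_complete = Xi)
}

#' Wheat-like uncorrelated association-panel fixture
#'
#' 300 individuals, 400 mutually independent markers, nine QTLs (effects
#' 1.75, 2, 2.5, -2.25, 1.5, -2.25, -1.75, 2.5, -2.25 at loci 7, 76, 118,
#' 162, 181, 218, 273, 344, 395).  A set of 40 non-QTL loci is forced to
#' strong allele-frequency imbalance (majority frequency 0.95), and the QTL
#' loci 7 and 76 are deliberately imbalanced (frequencies 0.86 of +1 and
#' 0.87 of -1 respectively) to make them hard to detect; all other loci are
#' balanced.  No markers are removed and no genotypes are missing.  Noise SD
#' defaults to `sqrt(8)` (realized heritability near 0.8).
#'
#' @param seed integer seed.
#' @param noise_sd noise standard deviation (default `sqrt(8)`).
#' @return list with `X` (300 x 400), `y`, `truth` (`beta`, `effects`,
#'   `imbalanced_loci`, `h2`, `noise_sd`, `seed`).
#' @export
wheat_fixture <- function(seed = 1L, noise_sd = sqrt(8)) {
  n <- 300L; m <- 400L
  eff <- wheat_effects()
  beta <- numeric(m); beta[eff$locus] <- eff$effect
  p <- rep(0.5, m)
  imb <- setdiff(seq(10L, 400L, by = 10L), eff$locus)[1:40]
  p[imb] <- rep(c(0.95, 0.05), length.out = 40L)
  p[7L] <- 0.86   # majority +1
  p[76L] <- 0.13  # majority -1
  set.seed(seed)
  X <- matrix(ifelse(stats::runif(n * m) < rep(p, each = n), 1, -1), n, m)
  X <- genotype_matrix(X)
  y <- make_phenotype(X, beta, noise_sd)
  list(X = X, y = y,
       truth = list(beta = beta, effects = eff, imbalanced_loci = imb,
                    h2 = heritability(X, beta, y), noise_sd = noise_sd,
                    seed = seed))
}
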