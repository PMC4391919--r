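#' Enumerate collinear marker pairs for combined effects
#'
#' Finds the candidate pairs whose combined effect (sum or difference of the
#' two regression coefficients) is worth testing.  A pair (j, k), j < k, is a
#' *sum* candidate when the proportion of individuals with identical nonzero
#' genotype codes strictly exceeds `rho`, and a *difference* candidate when
#' the proportion of disagreeing codes strictly exceeds `rho`.  Pairs need
#' not be adjacent markers.
#'
#' Under the missing-as-zero policy a 0 entry agrees with nothing and
#' disagrees with every nonzero code; two zeros count as neither agreement
#' nor disagreement.  Zero-imputed data can therefore produce extra
#' difference candidates, mirroring what happens in real data sets with
#' many zeroed genotypes.
#'
#' @param X a [genotype_matrix()] or matrix with entries in \{-1, 0, 1\}
#'   (no `NA`).
#' @param rho agreement threshold, strictly between 0.5 and 1 (default 0.8).
#' @return a `pair_catalog`: data frame with columns `j`, `k` (j < k),
#'   `kind` (`"sum"` or `"difference"`) and `prop` (the agreement or
#'   disagreement proportion), with `rho` as an attribute.
#' @examples
#' X <- genotype_matrix(cbind(c(1, 1, -1, 1), c(1, 1, -1, 1), c(-1, -1, 1, -1)))
#' enumerate_pairs(X, rho = 0.8)
#' @export
enumerate_pairs <- function(X, rho = 0.8) {
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0.5 || rho >= 1)
    stop("enumerate_pairs: rho must lie strictly between 0.5 and 1")
  X <- as_plain_matrix(X)
  check_complete(X)
  n <- nrow(X); m <- ncol(X)
  entries <- data.frame(j = integer(0), k = integer(0),
                        kind = character(0), prop = numeric(0))
  if (m >= 2L) {
    A <- abs(X)                       # 1 where nonzero
    dot <- crossprod(X)               # +1 equal nonzero, -1 opposite nonzero
    nz <- crossprod(A)                # both nonzero
    zerozero <- crossprod(1 - A)      # both zero
    agree <- (nz + dot) / 2
    disagree <- n - agree - zerozero  # opposite nonzero or exactly one zero
    p_agree <- agree / n
    p_dis <- disagree / n
    ut <- upper.tri(p_agree)
    sum_sel <- which(ut & p_agree > rho, arr.ind = TRUE)
    dif_sel <- which(ut & p_dis > rho, arr.ind = TRUE)
    entries <- rbind(
      if (nrow(sum_sel))
        data.frame(j = sum_sel[, 1L], k = sum_sel[, 2L], kind = "sum",
                   prop = p_agree[sum_sel]),
      if (nrow(dif_sel))
        data.frame(j = dif_sel[, 1L], k = dif_sel[, 2L], kind = "difference",
                   prop = p_dis[dif_sel]),
      entries)
    entries <- entries[order(entries$kind, entries$j, entries$k), ,
                       drop = FALSE]
    rownames(entries) <- NULL
  }
  structure(entries, rho = rho, marker_names = colnames(X),
            class = c("pair_catalog", "data.frame"))
}

#' @export
print.pair_catalog <- function(x, ...) {
  cat(sprintf("pair_catalog: %d sum and %d difference candidates (rho = %g)\n",
              sum(x$kind == "sum"), sum(x$kind == "difference"),
              attr(x, "rho")))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}

#' Assemble single and combined effect draws
#'
#' Concatenates the single-effect posterior draws with one column per
#' catalogued combined effect: `beta_j + beta_k` for sum pairs and
#' `beta_j - beta_k` for difference pairs (canonical order j < k; a credibly
#' negative difference is interpreted as credible positivity of
#' `beta_k - beta_j` during inference).
#'
#' @param draws a `posterior_draws` object or an S x m matrix of effect
#'   draws.
#' @param catalog a `pair_catalog` from [enumerate_pairs()]; may have zero
#'   rows, or be `NULL` for singles only.
#' @return an `effect_set`: list with the S x (m + K) draw matrix `draws`,
#'   and per-column `labels`, `kind` (`"single"`, `"sum"`, `"difference"`),
#'   `j`, `k` (parent marker indices; `k` is `NA` for singles).
#' @export
combined_effect_draws <- function(draws, catalog = NULL) {
  B <- if (inherits(draws, "posterior_draws")) draws$beta else as.matrix(draws)
  m <- ncol(B)
  labels <- colnames(B) %||% paste0("M", seq_len(m))
  kind <- rep("single", m)
  j <- seq_len(m); k <- rep(NA_integer_, m)
  D <- B
  if (!is.null(catalog) && nrow(catalog)) {
    if (any(catalog$j < 1L | catalog$k > m | catalog$j >= catalog$k))
      stop("combined_effect_draws: catalog indices out of range")
    sgn <- ifelse(catalog$kind == "sum", 1, -1)
    comb <- B[, catalog$j, drop = FALSE] +
      sweep(B[, catalog$k, drop = FALSE], 2L, sgn, "*")
    op <- ifelse(catalog$kind == "sum", "+", "-")
    colnames(comb) <- paste0(labels[catalog$j], op, labels[catalog$k])
    D <- cbind(B, comb)
    labels <- c(labels, colnames(comb))
    kind <- c(kind, catalog$kind)
    j <- c(j, catalog$j); k <- c(k, catalog$k)
  }
  structure(list(draws = D, labels = labels, kind = kind, j = j, k = k,
                 m = m),
            class = "effect_set")
}

#' @export
print.effect_set <- function(x, ...) {
  cat(sprintf("effect_set: %d single + %d combined effects, %d draws\n",
              x$m, length(x$labels) - x$m, nrow(x$draws)))
  invisible(x)
}
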