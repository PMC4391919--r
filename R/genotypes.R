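#' Genotype design matrix
#'
#' Construct a validated genotype matrix for a line cross: individuals in
#' rows, markers in columns, entries coded -1 / +1 for the two genotype
#' classes, 0 for the "missing as neutral" policy, and \code{NA} for missing
#' genotypes that have not yet been imputed.
#'
#' @param values numeric matrix (n individuals x m markers) with entries in
#'   \{-1, 0, 1, NA\}.
#' @param marker_names optional unique marker labels (default \code{M1..Mm}).
#' @param individual_ids optional row labels (default \code{I1..In}).
#' @return a \code{genotype_matrix}: a numeric matrix with dimnames and class
#'   attribute.
#' @examples
#' X <- genotype_matrix(matrix(c(1, -1, -1, 1), 2, 2))
#' @export
genotype_matrix <- function(values, marker_names = NULL, individual_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); m <- ncol(values)
  if (n < 2L || m < 1L)
    stop("genotype_matrix: need at least 2 individuals and 1 marker")
  bad <- !(values %in% c(-1, 0, 1) | is.na(values))
  if (any(bad)) {
    idx <- which(bad)[1L]
    stop(sprintf(
      "genotype_matrix: entry %g at row %d, column %d not in {-1, 0, 1, NA}",
      values[idx], (idx - 1L) %% n + 1L, (idx - 1L) %/% n + 1L))
  }
  if (is.null(marker_names)) marker_names <- paste0("M", seq_len(m))
  if (anyDuplicated(marker_names)) stop("genotype_matrix: duplicate marker names")
  if (length(marker_names) != m) stop("genotype_matrix: marker_names length mismatch")
  if (is.null(individual_ids)) individual_ids <- paste0("I", seq_len(n))
  if (length(individual_ids) != n) stop("genotype_matrix: individual_ids length mismatch")
  dimnames(values) <- list(individual_ids, marker_names)
  class(values) <- c("genotype_matrix", "matrix", "array")
  values
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d markers, %d missing\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x object to test.
#' @export
is_genotype_matrix <- function(x) inherits(x, "genotype_matrix")

as_plain_matrix <- function(X) {
  Y <- as.matrix(X)
  attr(Y, "class") <- NULL
  Y
}

check_complete <- function(X, what = "design matrix") {
  if (anyNA(X))
    stop(sprintf("%s still contains missing entries; impute first (see impute_missing)",
                 what))
  invisible(X)
}
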