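#' Read a genotype table
#'
#' Reads a delimited text table (TSV by default) with a header row of marker
#' names and one row per individual; entries must parse as -1, 0, 1 or `NA`.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return a [genotype_matrix()]; `NA` cells are kept as missing.
#' @export
read_genotypes <- function(path, sep = "\t") {
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      colClasses = "numeric", na.strings = c("NA", "")),
    error = function(e)
      stop(sprintf("read_genotypes: cannot parse '%s': %s", path,
                   conditionMessage(e)), call. = FALSE))
  vals <- as.matrix(tab)
  bad <- !(vals %in% c(-1, 0, 1) | is.na(vals))
  if (any(bad)) {
    idx <- which(bad)[1L]
    stop(sprintf(
      "read_genotypes: invalid genotype code %g at line %d, column %d of '%s'",
      vals[idx], (idx - 1L) %% nrow(vals) + 2L,   # +1 header, +1 one-based
      (idx - 1L) %/% nrow(vals) + 1L, path))
  }
  genotype_matrix(vals, marker_names = colnames(tab))
}

#' Write a genotype table
#'
#' @param X a [genotype_matrix()].
#' @param path output file.
#' @param sep field separator.
#' @return invisibly, `path`.
#' @export
write_genotypes <- function(X, path, sep = "\t") {
  utils::write.table(as.data.frame(as_plain_matrix(X)), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write phenotypes
#'
#' One-column delimited table, aligned with the genotype rows by order; a
#' header line `y` is written and tolerated on reading.
#'
#' @param path file path.
#' @return numeric vector.
#' @export
read_phenotypes <- function(path) {
  lines <- readLines(path)
  if (length(lines) && identical(tolower(trimws(lines[1L])), "y"))
    lines <- lines[-1L]
  y <- suppressWarnings(as.numeric(trimws(lines)))
  if (anyNA(y))
    stop(sprintf("read_phenotypes: line %d of '%s' is not a number",
                 which(is.na(y))[1L], path))
  y
}

#' @rdname read_phenotypes
#' @param y numeric phenotype vector.
#' @export
write_phenotypes <- function(y, path) {
  writeLines(c("y", format(y, digits = 17, trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}

#' Write posterior draws as a columnar text archive
#'
#' One TSV per parameter block (`beta`, `mu`, `sigma2`, optionally `tau2`,
#' `lambda`) plus a JSON sidecar recording the configuration and seed.
#'
#' @param fit a `posterior_draws` object.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
write_draws <- function(fit, dir) {
  stopifnot(inherits(fit, "posterior_draws"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  blocks <- list(beta = fit$beta, mu = fit$mu, sigma2 = fit$sigma2,
                 tau2 = fit$tau2, lambda = fit$lambda)
  for (nm in names(blocks)) {
    if (is.null(blocks[[nm]])) next
    utils::write.table(as.data.frame(blocks[[nm]]),
                       file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  cfg <- fit$config
  sidecar <- list(model = fit$model, lambda = cfg$lambda,
                  lambda_random = cfg$lambda_random, burn_in = cfg$burn_in,
                  thin = cfg$thin, n_draws = cfg$n_draws, seed = fit$seed,
                  n = fit$n, m = fit$m)
  jsonlite::write_json(sidecar, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run manifest
#'
#' Collects everything needed to reproduce a run bit-identically: the
#' configuration snapshot, master seed, per-stage seeds, package version,
#' timestamp and digests of the input files.
#'
#' @param config named list (configuration snapshot).
#' @param seed master seed.
#' @param stage_seeds named list/vector of derived seeds.
#' @param inputs character vector of input file paths to digest.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(config, seed, stage_seeds = list(),
                         inputs = character(0)) {
  digests <- vapply(inputs, function(p) {
    con <- file(p, "rb")
    on.exit(close(con))
    # cheap content digest: length + sum of bytes (no digest pkg dependency)
    bytes <- readBin(con, "raw", n = file.size(p))
    sprintf("%d:%.0f", length(bytes), sum(as.integer(bytes)))
  }, character(1))
  structure(list(config = config, seed = seed, stage_seeds = stage_seeds,
                 inputs = as.list(digests),
                 version = as.character(utils::packageVersion("ssblasso")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path output JSON file.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Save / load a scale-space scan as text tables
#'
#' @param maps a `scale_space` from [ss_scan()].
#' @param dir directory.
#' @return `save_scan` invisibly returns `dir`; `load_scan` returns a
#'   `scale_space` object (without retained draws).
#' @export
save_scan <- function(maps, dir) {
  stopifnot(inherits(maps, "scale_space"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(data.frame(lambda = maps$grid), "grid.tsv")
  wt(as.data.frame(maps$mean_beta), "mean_beta.tsv")
  wt(as.data.frame(maps$pw_types), "pw_types.tsv")
  wt(as.data.frame(maps$hpw_types), "hpw_types.tsv")
  wt(as.data.frame(maps$q), "q.tsv")
  wt(as.data.frame(maps$sign), "sign.tsv")
  wt(maps$effects, "effects.tsv")
  if (!is.null(maps$catalog)) wt(as.data.frame(maps$catalog), "catalog.tsv")
  meta <- list(B = maps$B, alpha_pw = maps$alpha_pw,
               alpha_hpw = maps$alpha_hpw, use_combined = maps$use_combined,
               seed = maps$seed, model = maps$config$model,
               burn_in = maps$config$burn_in, thin = maps$config$thin,
               n_draws = maps$config$n_draws)
  jsonlite::write_json(meta, file.path(dir, "scan.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_scan
#' @export
load_scan <- function(dir) {
  rt <- function(f, ...) utils::read.table(file.path(dir, f), header = TRUE,
                                           sep = "\t", check.names = FALSE,
                                           ...)
  meta <- jsonlite::read_json(file.path(dir, "scan.json"),
                              simplifyVector = TRUE)
  grid <- rt("grid.tsv")$lambda
  mean_beta <- as.matrix(rt("mean_beta.tsv"))
  effects <- rt("effects.tsv", colClasses = c("character", "character",
                                              "integer", "integer"))
  catalog <- NULL
  if (file.exists(file.path(dir, "catalog.tsv"))) {
    catalog <- rt("catalog.tsv")
    catalog <- structure(catalog, rho = NULL,
                         class = c("pair_catalog", "data.frame"))
  }
  cfg <- sampler_config(model = meta$model, lambda = 1,
                        burn_in = meta$burn_in, thin = meta$thin,
                        n_draws = meta$n_draws, seed = meta$seed)
  structure(list(grid = grid, mean_beta = mean_beta,
                 quant = quantize_effects(mean_beta), B = meta$B,
                 pw_types = as.matrix(rt("pw_types.tsv")),
                 hpw_types = as.matrix(rt("hpw_types.tsv")),
                 q = as.matrix(rt("q.tsv")),
                 sign = as.matrix(rt("sign.tsv", colClasses = "character")),
                 effects = effects, catalog = catalog,
                 alpha_pw = meta$alpha_pw, alpha_hpw = meta$alpha_hpw,
                 use_combined = meta$use_combined, config = cfg,
                 seed = meta$seed, draws = NULL),
            class = "scale_space")
}
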