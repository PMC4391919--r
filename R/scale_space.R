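#' Logarithmically spaced tuning-parameter grid
#'
#' @param lo_exp,hi_exp base-10 exponents of the endpoints (`lo_exp < hi_exp`).
#' @param n number of grid values (>= 2).
#' @return increasing numeric vector of length `n`; first value
#'   `10^lo_exp`, last `10^hi_exp`, exponents equispaced.
#' @examples
#' lambda_grid(-0.7, 2, 80)  # the canonical line-cross scan grid
#' @export
lambda_grid <- function(lo_exp, hi_exp, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2L)
    stop("lambda_grid: n must be at least 2")
  if (!(lo_exp < hi_exp)) stop("lambda_grid: need lo_exp < hi_exp")
  10^seq(lo_exp, hi_exp, length.out = as.integer(n))
}

#' Quantize posterior-mean effects to seven categories
#'
#' Maps every posterior-mean effect to one of the categories
#' `-L, -M, -S, 0, S, M, L` by sign and magnitude band, with
#' `B = max |effect|` over the *entire* map so colors are comparable across
#' tuning-parameter rows: `0` when `|b| <= B/20`, `S` when
#' `B/20 < |b| <= B/5`, `M` when `B/5 < |b| <= 2B/5`, `L` when
#' `2B/5 < |b| <= B`.  Values exactly on a band edge take the lower band.
#'
#' @param mean_matrix numeric matrix (rows = tuning-parameter values,
#'   columns = loci) or vector of posterior means.
#' @param B band scale; default the maximum absolute value of the input.
#' @return integer matrix of the same shape with entries in -3..3
#'   (0 = category 0, 1 = S, 2 = M, 3 = L, signed), with `B` and the category
#'   labels as attributes.
#' @export
quantize_effects <- function(mean_matrix, B = NULL) {
  x <- as.matrix(mean_matrix)
  if (is.null(B)) B <- max(abs(x), 0)
  q <- matrix(0L, nrow(x), ncol(x))
  if (B > 0) {
    a <- abs(x) / B
    q <- (a > 1 / 20) + (a > 1 / 5) + (a > 2 / 5)
    q <- q * sign(x)
    storage.mode(q) <- "integer"
  }
  dimnames(q) <- dimnames(x)
  structure(q, B = B,
            categories = c(`-3` = "-L", `-2` = "-M", `-1` = "-S", `0` = "0",
                           `1` = "S", `2` = "M", `3` = "L"))
}

scan_chain_seed <- function(master_seed, index) {
  # distinct, order-independent per-chain seeds below 2^31
  (as.integer(master_seed) + 7919L * as.integer(index)) %% 2147483647L
}

#' Scale-space scan over a tuning-parameter grid
#'
#' Fits the Bayesian LASSO (or ridge) independently at every grid value of
#' the tuning parameter with one seeded chain per value, and assembles the
#' scale-space maps: posterior-mean effects, their 7-level quantization,
#' and per-locus credibility types from PW and HPW inference (with combined
#' effects of collinear pairs when `use_combined`).
#'
#' Chains use seeds derived from `(seed, grid index)`, so results do not
#' depend on evaluation order.
#'
#' @param X design ([genotype_matrix()]), no missing entries.
#' @param y phenotype vector.
#' @param grid increasing vector of tuning-parameter values
#'   (see [lambda_grid()]).
#' @param config [sampler_config()]; its `lambda` is ignored (each grid value
#'   is fitted as a fixed tuning parameter).
#' @param alpha_pw,alpha_hpw credibility levels for PW and HPW inference.
#' @param rho collinearity threshold for [enumerate_pairs()].
#' @param use_combined include combined effects in the inference.
#' @param seed master seed for the per-chain seeds (default `config$seed`).
#' @param keep_draws retain the full effect draws per grid value (needed to
#'   re-run inference afterwards; memory grows with the grid).
#' @return object of class `scale_space`: list with `grid`, `mean_beta`
#'   (L x m), `quant` (L x m quantized categories), `B`, `pw_types` and
#'   `hpw_types` (L x m credibility-type matrices), `q` and `sign`
#'   (L x E marginal sign-probability and sign matrices over all effects),
#'   `effects` (per-column label/kind/parents), `catalog`, and the
#'   configuration.
#' @export
ss_scan <- function(X, y, grid, config = sampler_config(lambda = 1),
                    alpha_pw = 0.975, alpha_hpw = 0.95, rho = 0.8,
                    use_combined = TRUE, seed = config$seed,
                    keep_draws = FALSE) {
  Xp <- as_plain_matrix(X)
  check_complete(Xp)
  if (length(grid) < 1L || any(diff(grid) <= 0) || any(grid <= 0))
    stop("ss_scan: grid must be increasing and positive")
  m <- ncol(Xp)
  L <- length(grid)
  catalog <- if (use_combined) enumerate_pairs(Xp, rho) else NULL
  K <- if (is.null(catalog)) 0L else nrow(catalog)
  ne <- m + K
  mean_beta <- matrix(NA_real_, L, m,
                      dimnames = list(NULL, colnames(Xp)))
  qmat <- matrix(NA_real_, L, ne)
  smat <- matrix(NA_character_, L, ne)
  pw_types <- matrix(0, L, m)
  hpw_types <- matrix(0, L, m)
  draws <- if (keep_draws) vector("list", L) else NULL
  effects_info <- NULL
  for (i in seq_len(L)) {
    cfg <- config
    cfg$lambda <- grid[i]
    cfg$lambda_random <- FALSE
    cfg$seed <- scan_chain_seed(seed, i)
    fit <- tryCatch(
      run_gibbs(Xp, y, cfg, ridge = (config$model == "ridge")),
      error = function(e)
        stop(sprintf("ss_scan: sampler failed at lambda = %g (grid row %d): %s",
                     grid[i], i, conditionMessage(e)), call. = FALSE))
    es <- combined_effect_draws(fit, catalog)
    if (is.null(effects_info))
      effects_info <- data.frame(label = es$labels, kind = es$kind,
                                 j = es$j, k = es$k)
    pw <- pw_detect(es, alpha_pw)
    hpw <- hpw_select(es, alpha_hpw)
    mean_beta[i, ] <- colMeans(fit$beta)
    qmat[i, ] <- pw$q
    smat[i, ] <- pw$sign
    pw_types[i, ] <- credibility_types(pw, m)
    hpw_types[i, ] <- credibility_types(hpw, m)
    if (keep_draws) draws[[i]] <- es
  }
  colnames(qmat) <- colnames(smat) <- effects_info$label
  quant <- quantize_effects(mean_beta)
  structure(list(grid = grid, mean_beta = mean_beta, quant = quant,
                 B = attr(quant, "B"), pw_types = pw_types,
                 hpw_types = hpw_types, q = qmat, sign = smat,
                 effects = effects_info, catalog = catalog,
                 alpha_pw = alpha_pw, alpha_hpw = alpha_hpw,
                 use_combined = use_combined, config = config, seed = seed,
                 draws = draws),
            class = "scale_space")
}

#' @export
print.scale_space <- function(x, ...) {
  cat(sprintf(
    "scale_space: %d lambda values in [%.4g, %.4g], %d loci, %d combined effects\n",
    length(x$grid), min(x$grid), max(x$grid), ncol(x$mean_beta),
    nrow(x$effects) - ncol(x$mean_beta)))
  invisible(x)
}

# diverging palette for the seven quantization categories (-L..L)
quant_palette <- function() {
  c("-L" = "#2166AC", "-M" = "#67A9CF", "-S" = "#D1E5F0", "0" = "#F7F7F7",
    "S" = "#FDDBC7", "M" = "#EF8A62", "L" = "#B2182B")
}

# palette for credibility types 0, +/-0.25, +/-0.75, +/-1
type_palette <- function() {
  c("-1" = "#053061", "-0.75" = "#2166AC", "-0.25" = "#92C5DE",
    "0" = "#BDBDBD",
    "0.25" = "#F4A582", "0.75" = "#B2182B", "1" = "#67001F")
}

draw_map <- function(mat, grid, levels, palette, main, qtl = NULL,
                     hline = NULL) {
  z <- matrix(match(as.character(mat), names(palette)), nrow(mat), ncol(mat))
  graphics::image(x = seq_len(ncol(mat)), y = log10(grid), z = t(z),
                  col = palette, zlim = c(1, length(palette)),
                  xlab = "locus", ylab = "log10(lambda)", main = main,
                  useRaster = FALSE)
  if (!is.null(qtl))
    graphics::points(qtl, rep(min(log10(grid)), length(qtl)), pch = 16,
                     cex = 0.6)
  if (!is.null(hline))
    graphics::abline(h = log10(hline), lwd = 2)
}

#' Render scale-space maps to image files and tables
#'
#' Writes one PNG per map (quantized posterior means, PW credibility types,
#' HPW credibility types) plus the underlying matrices as TSV tables and a
#' small JSON manifest.
#'
#' @param maps a `scale_space` object from [ss_scan()].
#' @param path output directory (created if absent).
#' @param qtl optional integer vector of locus positions to dot-annotate.
#' @param lambda_threshold optional tuning-parameter value drawn as a
#'   horizontal line (e.g. a permutation threshold).
#' @return invisibly, the vector of files written.
#' @export
render_maps <- function(maps, path, qtl = NULL, lambda_threshold = NULL) {
  stopifnot(inherits(maps, "scale_space"))
  if (length(maps$grid) < 1L) stop("render_maps: empty maps")
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("render_maps: cannot create '%s'", path))
  files <- character(0)
  qlab <- attr(maps$quant, "categories")[as.character(maps$quant)]
  qlab <- matrix(qlab, nrow(maps$quant), ncol(maps$quant))
  specs <- list(
    list(file = "map_quantized.png", mat = qlab, pal = quant_palette(),
         main = "Quantized posterior mean effects"),
    list(file = "map_pw_types.png", mat = maps$pw_types, pal = type_palette(),
         main = "PW credibility types"),
    list(file = "map_hpw_types.png", mat = maps$hpw_types,
         pal = type_palette(), main = "HPW credibility types"))
  for (sp in specs) {
    f <- file.path(path, sp$file)
    grDevices::png(f, width = 900, height = 600)
    draw_map(sp$mat, maps$grid, names(sp$pal), sp$pal, sp$main, qtl,
             lambda_threshold)
    grDevices::dev.off()
    files <- c(files, f)
  }
  tabs <- list(grid = data.frame(lambda = maps$grid),
               mean_beta = as.data.frame(maps$mean_beta),
               quantized = as.data.frame(unclass(maps$quant)),
               pw_types = as.data.frame(maps$pw_types),
               hpw_types = as.data.frame(maps$hpw_types),
               q = as.data.frame(maps$q))
  for (nm in names(tabs)) {
    f <- file.path(path, paste0(nm, ".tsv"))
    utils::write.table(tabs[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- list(seed = maps$seed, B = maps$B,
                   alpha_pw = maps$alpha_pw, alpha_hpw = maps$alpha_hpw,
                   use_combined = maps$use_combined,
                   model = maps$config$model,
                   burn_in = maps$config$burn_in, thin = maps$config$thin,
                   n_draws = maps$config$n_draws,
                   grid = range(maps$grid), grid_n = length(maps$grid))
  f <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}
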