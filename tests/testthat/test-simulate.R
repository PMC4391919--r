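test_that("line-cross generator produces +/-1 Markov chains", {
  X <- simulate_linecross_genotypes(50, 10, r = 0.2, seed = 1)
  expect_true(all(X %in% c(-1, 1)))
  expect_s3_class(X, "genotype_matrix")
  # determinism
  X2 <- simulate_linecross_genotypes(50, 10, r = 0.2, seed = 1)
  expect_identical(unclass(X), unclass(X2))
  expect_error(simulate_linecross_genotypes(10, 5, r = 0.6), "r must")
})

test_that("adjacent-marker correlation converges to 1 - 2r", {
  for (r in c(0.1, 0.5)) {
    X <- simulate_linecross_genotypes(10000, 2, r = r, seed = 7)
    cc <- cor(X[, 1], X[, 2])
    expect_lt(abs(cc - (1 - 2 * r)), 0.03)   # MC tolerance at n = 10^4
  }
})

test_that("missing injection and both imputation policies", {
  X <- simulate_linecross_genotypes(145, 122, r = 0.1, seed = 3)
  expect_identical(inject_missing(X, 0), X)
  Xm <- inject_missing(X, 0.034, seed = 4)
  nmiss <- sum(is.na(Xm))
  expected <- 0.034 * length(X)
  expect_lt(abs(nmiss - expected), 4 * sqrt(expected))  # binomial tolerance
  # set_zero: masked entries become exactly 0, others untouched
  Xz <- impute_missing(Xm, "set_zero")
  expect_true(all(Xz[is.na(Xm)] == 0))
  expect_identical(Xz[!is.na(Xm)], Xm[!is.na(Xm)])
  # random +/-1 imputation is balanced
  Xbig <- inject_missing(simulate_linecross_genotypes(200, 100, 0.5, 5),
                         0.5, seed = 6)
  Xi <- impute_missing(Xbig, "impute_random_pm1", seed = 7)
  expect_false(anyNA(Xi))
  filled <- Xi[is.na(Xbig)]
  expect_lt(abs(mean(filled == 1) - 0.5), 4 * sqrt(0.25 / length(filled)))
  # no missing: identity
  expect_identical(impute_missing(X, "set_zero"), X)
  expect_error(impute_missing(Xm, "nonsense"), "arg")
  expect_error(inject_missing(X, 1), "rate")
})

test_that("marker removal reproduces the canonical adjusted indexing", {
  # the flanking bookkeeping of the collinear line-cross design: five
  # high-missingness markers plus the four QTL markers removed
  m <- 127
  beta <- numeric(m)
  beta[c(3, 10, 20, 34, 51, 72, 84, 108)] <- c(3, 3.5, 4, -2.5, -3, -2, 3, -3)
  X <- simulate_linecross_genotypes(10, m, r = 0.5, seed = 8)
  rem <- remove_markers(X, beta, c(40, 60, 65, 95, 115, 3, 51, 84, 108))
  expect_equal(ncol(rem$X), 118)
  map <- rem$map
  kept <- map[!map$removed, ]
  expect_equal(kept$original, c(10, 20, 34, 72))
  expect_equal(kept$adj1, c(9, 19, 33, 67))
  removed <- map[map$removed, ]
  expect_equal(removed$original, c(3, 51, 84, 108))
  expect_equal(removed$adj1, c(2, 48, 78, 100))
  expect_equal(removed$adj2, c(3, 49, 79, 101))
})

test_that("marker removal handles toy cases and boundaries", {
  X <- simulate_linecross_genotypes(5, 6, r = 0.5, seed = 9)
  beta <- c(1, 0, 2, 0, 0, -1)
  # empty removal: identity
  rem0 <- remove_markers(X, beta, integer(0))
  expect_identical(unclass(rem0$X), unclass(X))
  expect_equal(rem0$map$adj1, c(1, 3, 6))
  # remove loci 3 and 4: QTL 3 flanked by kept 2 and 5 -> adjusted (2, 3)
  rem <- remove_markers(X, beta, c(3, 4))
  expect_equal(ncol(rem$X), 4)
  expect_equal(rem$map$adj1[rem$map$original == 3], 2)
  expect_equal(rem$map$adj2[rem$map$original == 3], 3)
  expect_equal(rem$map$adj1[rem$map$original == 6], 4)
  # boundary: removing the first locus leaves a single right neighbor
  beta1 <- c(2, rep(0, 5))
  rem1 <- remove_markers(X, beta1, 1L)
  expect_equal(rem1$map$adj1, 1)
  expect_true(is.na(rem1$map$adj2))
  expect_error(remove_markers(X, beta, 99), "out of range")
})

test_that("phenotype simulation: exact at zero noise, calibrated otherwise", {
  X <- simulate_linecross_genotypes(145, 10, r = 0.5, seed = 10)
  beta <- c(2, rep(0, 8), -1)
  y0 <- make_phenotype(X, beta, noise_sd = 0)
  expect_equal(y0, drop(unclass(X) %*% beta))
  y1 <- make_phenotype(X, beta, noise_sd = 8, seed = 11)
  y2 <- make_phenotype(X, beta, noise_sd = 8, seed = 11)
  expect_identical(y1, y2)
  # sample SD of the realized noise is near its nominal value
  s <- sd(y1 - drop(unclass(X) %*% beta))
  ci <- 8 * sqrt(c(qchisq(0.0005, 144), qchisq(0.9995, 144)) / 144)
  expect_gt(s, ci[1]); expect_lt(s, ci[2])
})

test_that("heritability is the genetic variance fraction", {
  X <- genotype_matrix(matrix(c(1, -1, 1, -1), ncol = 1))
  expect_equal(heritability(X, 2, drop(unclass(X) * 2)), 1)
  set.seed(12)
  Xb <- simulate_linecross_genotypes(100, 5, r = 0.5)
  beta <- c(1, 2, 0, 0, -1)
  y <- make_phenotype(Xb, beta, noise_sd = 2)
  g <- drop(unclass(Xb) %*% beta)
  expect_equal(heritability(Xb, beta, y), var(g) / var(y))
  expect_error(heritability(X, 2, rep(1, 4)), "variance")
})

test_that("barley fixture matches its design", {
  fx <- barley_fixture(seed = 1)
  expect_equal(dim(fx$X), c(145L, 118L))
  expect_equal(dim(fx$X_complete), c(145L, 127L))
  eff <- fx$truth$effects
  expect_equal(eff$effect, c(3, 3.5, 4, -2.5, -3, -2, 3, -3))
  expect_equal(eff$locus, c(3, 10, 20, 34, 51, 72, 84, 108))
  expect_equal(fx$truth$beta_full[eff$locus], eff$effect)
  expect_equal(sum(fx$truth$beta_full != 0), 8)
  expect_equal(length(fx$truth$regions), 8)
  expect_equal(fx$truth$regions[["51"]], c(48, 49), ignore_attr = TRUE)
  expect_false(anyNA(fx$X))
  # determinism
  fx2 <- barley_fixture(seed = 1)
  expect_identical(fx$y, fx2$y)
  expect_identical(unclass(fx$X), unclass(fx2$X))
})

test_that("barley fixture heritability sits in the design regime", {
  # the target regime is h2 near 0.9; individual seeds scatter around it
  # because the realized genetic variance depends on the drawn design
  h2 <- vapply(1:8, function(s) barley_fixture(seed = s)$truth$h2, numeric(1))
  expect_gt(median(h2), 0.80)
  expect_lt(median(h2), 0.95)
  expect_true(all(h2 > 0.70 & h2 < 1.1))
})

test_that("wheat fixture matches its design", {
  fx <- wheat_fixture(seed = 2)
  expect_equal(dim(fx$X), c(300L, 400L))
  eff <- fx$truth$effects
  expect_equal(eff$locus, c(7, 76, 118, 162, 181, 218, 273, 344, 395))
  expect_equal(eff$effect,
               c(1.75, 2, 2.5, -2.25, 1.5, -2.25, -1.75, 2.5, -2.25))
  expect_equal(fx$truth$beta[eff$locus], eff$effect)
  # deliberate imbalance at loci 7 and 76, strong imbalance elsewhere
  f7 <- mean(fx$X[, 7] == 1)
  expect_gt(f7, 0.78); expect_lt(f7, 0.93)
  f76 <- mean(fx$X[, 76] == -1)
  expect_gt(f76, 0.79); expect_lt(f76, 0.94)
  imb <- fx$truth$imbalanced_loci
  expect_equal(length(imb), 40)
  fr <- colMeans(fx$X[, imb] == 1)
  expect_true(all(fr > 0.9 | fr < 0.1))
  # remaining QTL loci are balanced
  others <- setdiff(eff$locus, c(7, 76))
  fo <- colMeans(fx$X[, others] == 1)
  expect_true(all(fo > 0.35 & fo < 0.65))
  expect_gt(fx$truth$h2, 0.7)
})
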