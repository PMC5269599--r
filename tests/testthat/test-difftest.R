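test_that("resampling t-test handles degenerate and separated groups", {
  r0 <- permuted_t_test(c(5, 5, 5), c(5, 5))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  ## clearly separated groups reach far below 0.01
  r1 <- permuted_t_test(c(10, 10.1, 9.9), c(20, 20.2),
                        n_resamples = 1e4, seed = 5L)
  expect_lt(r1$p, 0.01)
  expect_lt(r1$statistic, 0)
  expect_warning(permuted_t_test(rnorm(3), rnorm(2), n_resamples = 50L),
                 "coarse")
})

test_that("resampled p-values are reproducible under a seed", {
  a <- c(1.2, 0.8, 1.5); b <- c(2.2, 2.6)
  p1 <- permuted_t_test(a, b, n_resamples = 2000L, seed = 42L)$p
  p2 <- permuted_t_test(a, b, n_resamples = 2000L, seed = 42L)$p
  p3 <- permuted_t_test(a, b, n_resamples = 2000L, seed = 43L)$p
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
})

test_that("exhaustive permutation enumerates all label splits", {
  r <- permuted_t_test(c(1, 2, 3), c(10, 11), method = "exhaustive")
  expect_equal(r$n_resamples, 10L)
  expect_equal(r$p, 0.1)      # observed split is the most extreme of 10
  ## exact permutation p-values are provably super-uniform
  set.seed(7)
  p <- replicate(400, {
    v <- rnorm(5)
    permuted_t_test(v[1:3], v[4:5], method = "exhaustive")$p
  })
  expect_true(all(p >= 0.1))
  for (x in c(0.1, 0.2, 0.5)) expect_lte(mean(p <= x), x + 0.05)
})

test_that("bootstrap null p-values are calibrated in the rejection region", {
  set.seed(8)
  p <- replicate(600, {
    v <- log2(rnbinom(5, mu = 2000, size = 20) + 0.5)
    permuted_t_test(v[1:3], v[4:5], n_resamples = 400L)$p
  })
  expect_gte(mean(p < 0.05), 0.02)
  expect_lte(mean(p < 0.05), 0.08)
  expect_lte(mean(p < 0.01), 0.03)
})

test_that("pattern taxonomy reproduces the canonical single-gene patterns", {
  ## Fos-like: RNA and RF up, TE unchanged
  expect_equal(classify_pattern(TRUE, TRUE, FALSE, 1, 1.1, 0.1),
               "forwarded_up")
  expect_equal(classify_pattern(TRUE, TRUE, FALSE, -1, -1.1, -0.1),
               "forwarded_down")
  ## Fth1-like: TE up without transcript change
  expect_equal(classify_pattern(FALSE, TRUE, TRUE, 0.1, 1, 1),
               "te_only_up")
  expect_equal(classify_pattern(FALSE, TRUE, TRUE, 0.1, -1, -1),
               "te_only_down")
  ## Srf-like: RNA up countered by TE down, RF flat
  expect_equal(classify_pattern(TRUE, FALSE, TRUE, 1, 0.1, -1),
               "homeostatic")
  ## Nfat5-like amplification
  expect_equal(classify_pattern(TRUE, TRUE, TRUE, 1, 2, 1),
               "synergistic_up")
  expect_equal(classify_pattern(TRUE, TRUE, TRUE, -1, -2, -1),
               "synergistic_down")
  expect_equal(classify_pattern(FALSE, FALSE, FALSE, 1, 1, 1),
               "unclassified")
})

test_that("every flag/sign combination receives exactly one valid label", {
  grid <- expand.grid(sr = c(TRUE, FALSE), sf = c(TRUE, FALSE),
                      st = c(TRUE, FALSE), dr = c(-1, 1), df = c(-1, 1),
                      dt = c(-1, 1))
  labs <- with(grid, classify_pattern(sr, sf, st, dr, df, dt))
  valid <- c("forwarded_up", "forwarded_down", "te_only_up", "te_only_down",
             "homeostatic", "synergistic_up", "synergistic_down",
             "unclassified")
  expect_true(all(labs %in% valid))
  expect_length(labs, nrow(grid))
  ## direction consistency of te_only labels
  te_only <- grepl("^te_only", labs)
  expect_true(all(ifelse(grid$dt[te_only] > 0, "te_only_up",
                         "te_only_down") == labs[te_only]))
})

test_that("differential table computes fold changes and the TE identity", {
  set.seed(31)
  n <- 12
  base <- matrix(2^rnorm(n * 5, 7, 0.2), n, 5,
                 dimnames = list(sprintf("tx%02d", 1:n), paste0("s", 1:5)))
  rna <- base
  rna[1, 4:5] <- rna[1, 4:5] * 4               # planted RNA up
  rf <- base * 2^matrix(rnorm(n * 5, 0, 0.05), n, 5)
  rf[2, 4:5] <- rf[2, 4:5] * 4                 # planted TE up
  expr <- manual_expression_table(rna, rf)
  dt <- differential_table(expr, n_resamples = 2000L, seed = 9L)
  expect_equal(nrow(dt), n)
  ## identity: TE fold change is the RF minus RNA fold change
  expect_equal(dt$log2fc_te, dt$log2fc_rf - dt$log2fc_rna, tolerance = 1e-9)
  i1 <- which(dt$transcript_id == "tx01")
  i2 <- which(dt$transcript_id == "tx02")
  expect_gt(dt$log2fc_rna[i1], 1.5)
  expect_true(dt$sig_rna[i1])
  expect_gt(dt$log2fc_te[i2], 1.5)
  expect_true(dt$sig_te[i2])
  expect_false(dt$sig_rna[i2])
  ## patterns follow the flags
  expect_equal(dt$pattern[i2], "te_only_up")
  ## empty input gives an empty table
  e <- differential_table(expr[0, ])
  expect_s3_class(e, "differential_table")
  expect_equal(nrow(e), 0)
})

test_that("q-values are BH-monotone in the p-values", {
  set.seed(32)
  rna <- matrix(2^rnorm(100, 7, 0.5), 20, 5,
                dimnames = list(sprintf("t%02d", 1:20), paste0("s", 1:5)))
  rf <- rna * 2^matrix(rnorm(100, 0, 0.3), 20, 5)
  dt <- differential_table(manual_expression_table(rna, rf),
                           n_resamples = 500L, seed = 2L)
  o <- order(dt$p_te)
  expect_true(all(diff(dt$q_te[o]) >= -1e-12))
  expect_true(all(dt$q_te >= dt$p_te - 1e-12))
})

test_that("variance explained in fold changes follows the planted split", {
  set.seed(33)
  x <- rnorm(5000)
  ## planted 60:40 variance split
  y <- x * sqrt(0.6) + rnorm(5000, 0, sqrt(0.4))
  r <- fc_variance_explained(x, y)
  expect_lt(abs(r$r_squared - 0.6), 0.03)
  expect_lt(r$p, 1e-10)
  ## perfect fit and null
  expect_equal(suppressWarnings(
    fc_variance_explained(x, 2 * x + 1)$r_squared), 1)
  expect_lt(fc_variance_explained(x, rnorm(5000))$r_squared, 0.01)
  expect_error(fc_variance_explained(rep(1, 10), rnorm(10)),
               "constant predictor")
  expect_error(fc_variance_explained(c(1, 2), c(1, 2)), "at least 3")
})

test_that("Gamma-GLM pseudo-R2 recovers planted response-scale splits", {
  set.seed(34)
  x <- exp(rnorm(5000, 2, 0.6))
  mu <- 3 * x
  ## exact relationship
  expect_equal(baseline_variance_explained(x, mu)$pseudo_r_squared, 1,
               tolerance = 1e-8)
  ## planted 60:40 split on the response scale via Gamma noise
  k <- mean(mu^2) / (var(mu) * (1 / 0.6 - 1))
  y <- mu * rgamma(5000, shape = k, rate = k)
  r <- baseline_variance_explained(x, y)
  expect_lt(abs(r$pseudo_r_squared - 0.6), 0.05)
  ## independence gives ~0
  y0 <- exp(rnorm(5000, 1, 0.3))
  expect_lt(abs(baseline_variance_explained(x, y0)$pseudo_r_squared), 0.02)
  expect_error(baseline_variance_explained(c(-1, 2, 3), c(1, 2, 3)),
               "positive")
})
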