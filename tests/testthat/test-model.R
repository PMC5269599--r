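## Synthetic feature frames for model-level tests (independent of the
## sequence machinery: cheap, exactly controlled).
synth_features <- function(n, seed = 1L) {
  set.seed(seed)
  data.frame(
    n_upstream_kozak = rpois(n, 0.7),
    norm_ss_utr5 = rnorm(n, -0.9, 0.12),
    ss_cds = rnorm(n, -120, 25),
    short_utr3 = rbinom(n, 1, 0.6),
    utr5_gc = runif(n, 0.3, 0.7),
    norm_ss_utr3 = rnorm(n, -0.85, 0.1))
}

## Response with planted variance shares on three predictors, total
## variance 1.
planted_response <- function(fe, shares = c(n_upstream_kozak = 0.07,
                                            norm_ss_utr5 = 0.06,
                                            short_utr3 = 0.04)) {
  xb <- rep(0, nrow(fe))
  for (p in names(shares)) {
    x <- fe[[p]]
    xb <- xb + sqrt(shares[[p]]) * (x - mean(x)) / sd(x)
  }
  xb + rnorm(nrow(fe), 0, sqrt(1 - sum(shares)))
}

test_that("univariate scan recovers planted R2 and ranks predictors", {
  set.seed(101)
  n <- 2000
  x <- rnorm(n)
  y <- 3 * x + rnorm(n, 0, 3)    # true R2 = 0.5
  fe <- data.frame(x = x, z = rnorm(n))
  sc <- univariate_scan(fe, y, predictors = c("x", "z"))
  expect_equal(sc$predictor[1], "x")
  expect_lt(abs(sc$adj_r_squared[1] - 0.5), 0.04)
  expect_lte(sc$adj_r_squared[2], 0.01)
  ## a predictor identical to the response fits perfectly
  sc2 <- suppressWarnings(
    univariate_scan(data.frame(y = y), y, predictors = "y"))
  expect_equal(sc2$r_squared, 1)
  expect_warning(univariate_scan(data.frame(k = rep(1, n)), y,
                                 predictors = "k"), "constant")
})

test_that("stepwise selection finds planted predictors and rejects noise", {
  n <- 600
  hit <- 0
  for (r in 1:20) {
    fe <- synth_features(n, seed = 200L + r)
    y <- planted_response(fe)
    fit <- stepwise_select(fe, y)
    planted <- c("n_upstream_kozak", "norm_ss_utr5", "short_utr3")
    ok <- all(planted %in% fit$selected) &&
      length(setdiff(fit$selected, planted)) == 0
    hit <- hit + ok
  }
  expect_gte(hit, 18)
})

test_that("stepwise keeps the intercept-only model under pure noise", {
  n <- 600
  empty <- 0
  for (r in 1:20) {
    fe <- synth_features(n, seed = 300L + r)
    y <- rnorm(n)
    fit <- stepwise_select(fe, y)
    empty <- empty + (length(fit$selected) == 0)
  }
  expect_gte(empty, 16)
})

test_that("a single planted predictor reduces stepwise to the univariate fit", {
  fe <- synth_features(500, seed = 401L)
  y <- 0.8 * fe$norm_ss_utr5 + rnorm(500, 0, 0.05)
  fit <- stepwise_select(fe, y)
  expect_identical(fit$selected, "norm_ss_utr5")
  uni <- univariate_scan(fe, y, predictors = "norm_ss_utr5")
  expect_equal(fit$adj_r_squared, uni$adj_r_squared, tolerance = 1e-12)
})

test_that("stepwise never materially underperforms its best input", {
  for (r in 1:5) {
    fe <- synth_features(400, seed = 500L + r)
    y <- planted_response(fe)
    fit <- stepwise_select(fe, y)
    uni <- univariate_scan(fe, y, predictors = names(fe))
    expect_gte(fit$adj_r_squared, max(uni$r_squared) - 0.02)
  }
})

test_that("noise-free planted coefficients are recovered exactly", {
  fe <- synth_features(300, seed = 601L)
  y <- 2 - 0.4 * fe$n_upstream_kozak + 3 * fe$norm_ss_utr5
  fit <- suppressWarnings(stepwise_select(fe, y))
  expect_setequal(fit$selected, c("n_upstream_kozak", "norm_ss_utr5"))
  co <- coef(fit$fit)
  expect_equal(unname(co["n_upstream_kozak"]), -0.4, tolerance = 1e-6)
  expect_equal(unname(co["norm_ss_utr5"]), 3, tolerance = 1e-6)
})

test_that("collinearity report flags redundant predictor pairs", {
  set.seed(71)
  fe <- data.frame(a = rnorm(5000), b = rnorm(5000))
  fe$dup <- fe$a
  cr <- collinearity_report(fe)
  top <- cr[1, ]
  expect_setequal(c(top$var1, top$var2), c("a", "dup"))
  expect_equal(top$r, 1)
  expect_true(top$flagged)
  expect_true(all(abs(cr$r[cr$var1 == "a" & cr$var2 == "b" |
                           cr$var1 == "b" & cr$var2 == "a"]) < 0.05))
  expect_error(collinearity_report(fe[1:2, ]), ">= 3 complete rows")
})

test_that("structure score and length are strongly correlated on transcripts", {
  cfg <- simulation_config(n_transcripts = 40L, seed = 81L)
  ts <- simulate_transcriptome(cfg)
  ft <- feature_table(ts, features = c("ss_utr3", "utr3_len"))
  cr <- collinearity_report(ft, predictors = c("ss_utr3", "utr3_len"))
  expect_lt(cr$r[1], -0.9)
  expect_true(cr$flagged[1])
})

test_that("quartile ANOVA detects planted monotone bin effects", {
  set.seed(91)
  n <- 600
  x <- runif(n)
  bin_mean <- c(0, -0.2, -0.4, -0.6)[findInterval(x, c(0.25, 0.5, 0.75)) + 1]
  y <- bin_mean + rnorm(n, 0, 0.3)
  qa <- quartile_anova(x, y)
  expect_lt(qa$p, 1e-4)
  expect_true(all(diff(qa$bin_means) < 0.2))
  expect_equal(sum(qa$bin_counts), n)
})

test_that("quartile ANOVA is exact on degenerate and null inputs", {
  set.seed(92)
  x <- runif(100)
  qa0 <- quartile_anova(x, rep(1.5, 100))
  expect_equal(qa0$f, 0)
  expect_equal(qa0$p, 1)
  ## null calibration: shuffled response gives uniform p
  p <- replicate(150, quartile_anova(x, rnorm(100))$p)
  expect_gt(suppressWarnings(
    ks.test(p, "punif", alternative = "greater")$p.value), 0.01)
  expect_error(quartile_anova(x[1:6], rnorm(6)), "n >= 8")
  expect_error(quartile_anova(rep(c(1, 2, 3), 10), rnorm(30)),
               "distinct values")
})

test_that("tied quartiles collapse to fewer bins matching the pooled t-test", {
  set.seed(95)
  x <- c(1, rep(2, 20), 3, 4)
  y <- c(rnorm(21, 0), rnorm(2, 1))
  expect_warning(qa <- quartile_anova(x, y), "merged")
  expect_equal(length(qa$bin_means), 2L)
  ## two-bin ANOVA F equals the squared pooled-variance t statistic
  tt <- t.test(y[as.integer(qa$bins) == 1L], y[as.integer(qa$bins) == 2L],
               var.equal = TRUE)
  expect_equal(qa$f, unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("direction chi-square responds to planted Kozak-direction bias", {
  set.seed(93)
  n <- 600
  koz <- rpois(n, 1.2)
  p_down <- plogis(-0.6 + 0.8 * pmin(koz, 3))
  dir <- ifelse(runif(n) < p_down, "down", "up")
  dc <- direction_chisq(koz, dir)
  expect_lt(dc$p, 0.001)
  expect_equal(sum(dc$table), n)
  ## null calibration over repetitions
  p <- replicate(150, {
    direction_chisq(rpois(200, 1.2),
                    sample(c("up", "down"), 200, TRUE))$p
  })
  expect_gt(suppressWarnings(
    ks.test(p, "punif", alternative = "greater")$p.value), 0.01)
})

test_that("degenerate contingency tables error or collapse with a warning", {
  expect_error(direction_chisq(rep(0L, 50),
                               sample(c("up", "down"), 50, TRUE)),
               "fewer than 2")
  set.seed(94)
  koz <- c(rep(0L, 60), rep(1L, 40), 3L)   # >=3 bin nearly empty
  dir <- sample(c("up", "down"), 101, TRUE)
  expect_warning(dc <- direction_chisq(koz, dir), "collapsing")
  expect_lt(ncol(dc$table), 4L)
})
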