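test_that("configuration invariants are enforced", {
  expect_error(simulation_config(utr5_length_range = c(100L, 50L)),
               "degenerate")
  expect_error(simulation_config(cds_length_range = c(4L, 5L)),
               "no usable length")
  expect_error(simulation_config(n_treated = 1L), "replicates")
  expect_error(simulation_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(simulation_config(gc_range = c(0.7, 0.3)), "gc_range")
  ## a degenerate-by-value but ordered CDS range is allowed
  cfg <- simulation_config(n_transcripts = 5L,
                           cds_length_range = c(300L, 300L), seed = 1L)
  expect_s3_class(cfg, "simulation_config")
})

test_that("uaug_rate zero yields AUG-free 5'UTRs", {
  cfg <- simulation_config(n_transcripts = 40L, uaug_rate = 0, seed = 3L)
  ts <- simulate_transcriptome(cfg)
  ann <- ts$annotation
  for (i in seq_len(nrow(ann))) {
    utr5 <- substr(as.character(ts$sequences[[i]]), 1, ann$utr5_end[i])
    expect_false(grepl("ATG", utr5, fixed = TRUE), info = ann$transcript_id[i])
  }
  expect_true(all(feature_table(ts, features = "n_uaug")$n_uaug == 0L))
})

test_that("identical config and seed give byte-identical fixtures", {
  cfg <- simulation_config(n_transcripts = 100L, mean_depth = 200,
                           seed = 1L)
  d1 <- file.path(tempdir(), "simrep1"); d2 <- file.path(tempdir(), "simrep2")
  ex1 <- simulate_experiment(cfg)
  write_fixtures(ex1$transcripts, list(rf = ex1$rf, rna = ex1$rna), d1)
  ex2 <- simulate_experiment(cfg)
  write_fixtures(ex2$transcripts, list(rf = ex2$rf, rna = ex2$rna), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("fixed CDS length places AUG and a stop codon at the boundaries", {
  cfg <- simulation_config(n_transcripts = 25L,
                           cds_length_range = c(300L, 300L), seed = 9L)
  ts <- simulate_transcriptome(cfg)
  ann <- ts$annotation
  expect_true(all(ann$cds_end - ann$cds_start == 300L))
  for (i in seq_len(nrow(ann))) {
    s <- as.character(ts$sequences[[i]])
    expect_identical(substr(s, ann$cds_start[i] + 1, ann$cds_start[i] + 3),
                     "ATG")
    expect_true(substr(s, ann$cds_end[i] - 2, ann$cds_end[i]) %in%
                  c("TAA", "TAG", "TGA"))
  }
})

test_that("ground truth is internally consistent and recomputable", {
  cfg <- simulation_config(n_transcripts = 50L, seed = 17L)
  ts <- simulate_transcriptome(cfg)
  tr <- ts$truth
  expect_equal(tr$log2fc_rf, tr$log2fc_rna + tr$log2fc_te)
  ## recorded feature values equal a fresh feature_table pass
  ft <- feature_table(ts, features = names(cfg$planted_te_coefficients))
  for (f in names(cfg$planted_te_coefficients)) {
    expect_equal(tr[[f]], ft[[f]], info = f)
  }
  ## planted RNA-change fractions are as configured
  expect_equal(sum(tr$log2fc_rna > 0), round(0.165 * 50))
  expect_equal(sum(tr$log2fc_rna < 0), round(0.095 * 50))
})

test_that("planted coefficients are recovered exactly in the noise-free limit", {
  cfg <- simulation_config(n_transcripts = 120L, te_noise_sd = 0,
                           te_target_r2 = NULL, seed = 23L)
  ts <- simulate_transcriptome(cfg)
  tr <- ts$truth
  fit <- lm(log2fc_te ~ norm_ss_utr5 + n_upstream_kozak + short_utr3,
            data = tr)
  expect_equal(unname(coef(fit)[-1]),
               unname(cfg$planted_te_coefficients[
                 c("norm_ss_utr5", "n_upstream_kozak", "short_utr3")]),
               tolerance = 1e-6)
  expect_lt(sigma(fit), 1e-8)
})

test_that("RF coverage is confined to 5'UTR + CDS", {
  se <- small_experiment(seed = 31L)
  ann <- se$ex$transcripts$annotation
  for (i in seq_len(nrow(ann))) {
    m <- se$ex$rf$depth[[ann$transcript_id[i]]]
    utr3 <- sum(m[(ann$utr3_start[i] + 1):ann$utr3_end[i], ])
    cds <- sum(m[(ann$cds_start[i] + 1):ann$cds_end[i], ])
    expect_lte(utr3, 0.01 * max(cds, 1))
  }
})

test_that("null TE planting gives near-zero mean estimated TE change", {
  ## deep-coverage, low-dispersion limit of the null case; baseline
  ## spread is kept modest so heavy-tailed library weights do not add
  ## compositional noise to the mean
  cfg <- simulation_config(n_transcripts = 100L, mean_depth = 1e4,
                           nb_dispersion = 1e-3,
                           baseline_log2_abundance_sd = 0.3,
                           baseline_log2_te_sd = 0.3,
                           planted_te_coefficients = c(short_utr3 = 0),
                           te_target_r2 = NULL, te_noise_sd = 0,
                           seed = 41L)
  ex <- simulate_experiment(cfg)
  expr <- quantify_expression(ex$transcripts, rf = ex$rf, rna = ex$rna)
  rna <- riboTE:::.expr_matrix(expr, "rna", "exonic")
  rf <- riboTE:::.expr_matrix(expr, "rf", "cds")
  te <- compute_te(rf, rna)
  trt <- grepl("^trt", colnames(te))
  est <- log2(condition_te(te[, trt]) / condition_te(te[, !trt]))
  expect_lt(abs(mean(est)), 0.05)
})

test_that("a planted four-fold TE change is recovered across NB draws", {
  ## the changed transcript sits in a pool of 50 stable ones so that the
  ## library-size (compositional) shift from its own RF change is small
  cfg <- simulation_config(n_transcripts = 50L, mean_depth = 5e3,
                           planted_te_coefficients = c(short_utr3 = 0),
                           te_target_r2 = NULL, te_noise_sd = 0,
                           frac_rna_up = 0, frac_rna_down = 0,
                           baseline_log2_abundance_sd = 0,
                           baseline_log2_te_sd = 0, seed = 43L)
  ts <- simulate_transcriptome(cfg)
  truth <- ts$truth
  truth$log2fc_te[1] <- 2
  truth$log2fc_rf <- truth$log2fc_rna + truth$log2fc_te
  ests <- vapply(1:50, function(r) {
    cov <- simulate_coverage(ts, truth, cfg, seed = 1000L + r)
    expr <- quantify_expression(ts, rf = cov$rf, rna = cov$rna)
    rna <- riboTE:::.expr_matrix(expr, "rna", "exonic")
    rf <- riboTE:::.expr_matrix(expr, "rf", "cds")
    te <- compute_te(rf, rna)
    trt <- grepl("^trt", colnames(te))
    log2(condition_te(te[1, trt]) / condition_te(te[1, !trt]))
  }, numeric(1))
  expect_lt(abs(mean(ests) - 2), 0.2)
})

test_that("coverage simulation rejects mismatched ground truth", {
  se <- small_experiment(seed = 51L, n = 5L)
  truth <- se$ex$truth
  truth$transcript_id <- rev(truth$transcript_id)
  expect_error(simulate_coverage(se$ex$transcripts, truth, se$cfg),
               "identical transcript ids")
})

test_that("an empty transcript set round-trips through fixtures", {
  ann <- data.frame(transcript_id = character(0), gene_id = character(0),
                    length = integer(0), utr5_start = integer(0),
                    utr5_end = integer(0), cds_start = integer(0),
                    cds_end = integer(0), utr3_start = integer(0),
                    utr3_end = integer(0), stringsAsFactors = FALSE)
  ts <- transcript_set(ann, setNames(character(0), character(0)))
  d <- file.path(tempdir(), "simempty")
  write_fixtures(ts, NULL, d)
  back <- read_annotation(file.path(d, "annotation.tsv"))
  expect_equal(nrow(back), 0)
  expect_identical(names(back), names(ann))
})
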