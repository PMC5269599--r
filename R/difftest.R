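## Differential testing between conditions: bootstrap permutation t-tests
## on log2 expression and TE, fold changes, regulatory-pattern labels, and
## variance-explained summaries.

#' @noRd
.welch_t <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  den <- sqrt(var(a) / length(a) + var(b) / length(b))
  if (is.na(den)) return(NA_real_)
  if (den == 0) {
    if (ma == mb) return(0)
    return(sign(ma - mb) * Inf)
  }
  (ma - mb) / den
}

#' Resampling t-test for tiny replicate groups
#'
#' Welch t-statistic for the observed grouping, with a resampled null
#' distribution: under `method = "bootstrap"` both groups are redrawn
#' `n_resamples` times, with replacement, from the fitted null — i.i.d.
#' normal at the common (pooled) mean with each group's own plug-in
#' standard deviation — and the Welch t recomputed. The p-value uses the
#' small-sample correction
#' `p = (1 + #(|t*| >= |t|)) / (1 + n_resamples)`. With replicate counts as
#' small as 3 vs 2 there are only 10 distinct label permutations, too few
#' for p < 0.05; this parametric resampling keeps the null fine-grained
#' while reproducing the heavy tails of the observed statistic, and is
#' calibrated near the working significance level (see the methods
#' vignette for the calibration study; nonparametric value-resampling
#' variants are badly miscalibrated at these group sizes).
#' `method = "exhaustive"` instead enumerates all label permutations
#' without replacement and reports the exact (coarse-grained, provably
#' valid) permutation p-value.
#'
#' Values are expected on a log scale (log2 RPKM or log2 TE, with a
#' pseudocount) so that the t-statistic is comparing fold changes.
#'
#' @param values_a,values_b Numeric vectors (>= 2 values each).
#' @param n_resamples Number of resamples (default 10000; < 100 warns).
#' @param seed Optional integer seed (`set.seed` is called when non-NULL).
#' @param method `"bootstrap"` (default) or `"exhaustive"`.
#' @return List with `statistic` (Welch t), `p`, `n_resamples`, `method`.
#' @export
permuted_t_test <- function(values_a, values_b, n_resamples = 10000L,
                            seed = NULL, method = c("bootstrap",
                                                    "exhaustive")) {
  method <- match.arg(method)
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  if (!is.null(seed)) set.seed(seed)
  t_obs <- .welch_t(values_a, values_b)
  if (var(values_a) == 0 && var(values_b) == 0 &&
      mean(values_a) == mean(values_b)) {
    return(list(statistic = 0, p = 1, n_resamples = 0L, method = method))
  }
  pooled <- c(values_a, values_b)
  na <- length(values_a)
  if (method == "exhaustive") {
    idx <- utils::combn(length(pooled), na)
    tstars <- apply(idx, 2L, function(ia) {
      .welch_t(pooled[ia], pooled[-ia])
    })
    tstars[is.na(tstars)] <- 0
    p <- mean(abs(tstars) >= abs(t_obs) - 1e-12)
    return(list(statistic = t_obs, p = p, n_resamples = ncol(idx),
                method = method))
  }
  n_resamples <- as.integer(n_resamples)
  if (n_resamples < 100L) {
    warning("n_resamples < 100 gives a very coarse p-value")
  }
  cnt <- .boot_t_count(sd(values_a), sd(values_b), length(values_a),
                       length(values_b), n_resamples,
                       abs(ifelse(is.finite(t_obs), t_obs, Inf)))
  list(statistic = t_obs, p = (1 + cnt) / (1 + n_resamples),
       n_resamples = n_resamples, method = method)
}

#' Regulatory pattern taxonomy
#'
#' Classifies a transcript's joint RNA / RF / TE significance calls:
#' * `forwarded_up` / `forwarded_down`: RNA and RF significant in the same
#'   direction, TE not significant — translation passively follows the
#'   transcript level (the *Fos* / *Tgfb1i1* patterns).
#' * `te_only_up` / `te_only_down`: TE significant while RNA is not — pure
#'   translational control (the *Fth1* / *Ccni* patterns).
#' * `homeostatic`: RNA and TE significant in opposite directions with RF
#'   not significant — TE buffers the transcript change (the *Srf*
#'   pattern).
#' * `synergistic_up` / `synergistic_down`: RNA and TE significant in the
#'   same direction — amplified response (the *Nfat5* / *Ccl2* patterns).
#' * `unclassified`: anything else.
#'
#' @param sig_rna,sig_rf,sig_te Logical significance flags.
#' @param fc_rna,fc_rf,fc_te log2 fold changes (only signs are used).
#' @return Character vector of pattern labels.
#' @export
classify_pattern <- function(sig_rna, sig_rf, sig_te,
                             fc_rna, fc_rf, fc_te) {
  n <- length(sig_rna)
  out <- rep("unclassified", n)
  dr <- sign(fc_rna); df <- sign(fc_rf); dt <- sign(fc_te)
  sig_rna <- sig_rna & !is.na(fc_rna)
  sig_rf <- sig_rf & !is.na(fc_rf)
  sig_te <- sig_te & !is.na(fc_te)
  te_only <- sig_te & !sig_rna
  out[te_only & dt > 0] <- "te_only_up"
  out[te_only & dt < 0] <- "te_only_down"
  fwd <- sig_rna & sig_rf & !sig_te & dr == df
  out[fwd & dr > 0] <- "forwarded_up"
  out[fwd & dr < 0] <- "forwarded_down"
  homeo <- sig_rna & sig_te & dr * dt < 0 & !sig_rf
  out[homeo] <- "homeostatic"
  syn <- sig_rna & sig_te & dr * dt > 0
  out[syn & dr > 0] <- "synergistic_up"
  out[syn & dr < 0] <- "synergistic_down"
  out
}

#' Differential table: RNA, RF and TE changes per transcript
#'
#' For each transcript computes the log2 fold change (mean log2 treated
#' minus mean log2 control, pseudocount added to RPKM) and a bootstrap
#' permutation p-value for three measures: RNA abundance (exonic RNA-seq
#' RPKM), ribosomal occupancy (CDS RF RPKM) and TE (per-sample
#' `log2(RF + pc) - log2(RNA + pc)` over samples present in both assays).
#' Significance is called at unadjusted `p < alpha`; Benjamini-Hochberg
#' q-values are reported alongside but not used for the pattern labels.
#'
#' By construction `log2fc_te = log2fc_rf_cds - log2fc_rna` when the same
#' samples carry both assays; `log2fc_rf` reported in the table is the CDS
#' RF fold change.
#'
#' @param expr `expression_table` (ideally pre-filtered with
#'   [filter_expressed()]).
#' @param alpha Unadjusted significance level (default 0.05).
#' @param n_resamples Resamples per test (default 10000).
#' @param seed Integer seed for reproducible p-values.
#' @param pseudocount RPKM pseudocount before log2 (default 0.5).
#' @param rna_region,rf_region Regions measured for the RNA and RF tests.
#' @param method Passed to [permuted_t_test()].
#' @return `data.frame` of class `differential_table`: `transcript_id`,
#'   `gene_id`, `log2fc_*`, `p_*`, `q_*`, `sig_*` for rna/rf/te, and
#'   `pattern`.
#' @export
differential_table <- function(expr, alpha = 0.05, n_resamples = 10000L,
                               seed = NULL, pseudocount = 0.5,
                               rna_region = "exonic", rf_region = "cds",
                               method = "bootstrap") {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(expr) == 0L) {
    out <- data.frame(transcript_id = character(0), gene_id = character(0))
    class(out) <- c("differential_table", "data.frame")
    return(out)
  }
  rna <- .expr_matrix(expr, "rna", rna_region)
  rf <- .expr_matrix(expr, "rf", rf_region)
  cond <- function(assay) {
    sub <- unique(expr[expr$assay == assay, c("sample", "condition")])
    setNames(sub$condition, sub$sample)
  }
  cond_rna <- cond("rna"); cond_rf <- cond("rf")
  shared <- intersect(colnames(rf), colnames(rna))
  if (length(shared) < 4L) {
    stop("TE requires paired samples across assays (>= 2 per condition)")
  }
  txs <- intersect(rownames(rna), rownames(rf))
  gmap <- unique(expr[, c("transcript_id", "gene_id")])
  genes <- setNames(gmap$gene_id, gmap$transcript_id)[txs]

  l2 <- function(m) log2(m + pseudocount)
  lrna <- l2(rna[txs, , drop = FALSE])
  lrf <- l2(rf[txs, , drop = FALSE])
  lte <- lrf[, shared, drop = FALSE] - lrna[, shared, drop = FALSE]

  one_measure <- function(lv, condv) {
    trt <- names(condv)[condv == "treated"]
    ctl <- names(condv)[condv == "control"]
    trt <- intersect(trt, colnames(lv)); ctl <- intersect(ctl, colnames(lv))
    if (length(trt) < 2L || length(ctl) < 2L) {
      stop("need >= 2 replicates per condition")
    }
    fc <- rowMeans(lv[, trt, drop = FALSE]) -
      rowMeans(lv[, ctl, drop = FALSE])
    p <- vapply(seq_len(nrow(lv)), function(i) {
      permuted_t_test(lv[i, trt], lv[i, ctl], n_resamples = n_resamples,
                      method = method)$p
    }, numeric(1))
    list(fc = fc, p = p)
  }

  m_rna <- one_measure(lrna, cond_rna)
  m_rf <- one_measure(lrf, cond_rf)
  m_te <- one_measure(lte, cond_rna[shared])

  ## flag TE missing where one condition has no RNA signal at all
  rna_zero <- {
    trt <- shared[cond_rna[shared] == "treated"]
    ctl <- shared[cond_rna[shared] == "control"]
    rowSums(rna[txs, trt, drop = FALSE]) == 0 |
      rowSums(rna[txs, ctl, drop = FALSE]) == 0
  }
  m_te$fc[rna_zero] <- NA_real_
  m_te$p[rna_zero] <- NA_real_

  out <- data.frame(
    transcript_id = txs, gene_id = unname(genes),
    log2fc_rna = unname(m_rna$fc), p_rna = m_rna$p,
    log2fc_rf = unname(m_rf$fc), p_rf = m_rf$p,
    log2fc_te = unname(m_te$fc), p_te = m_te$p,
    stringsAsFactors = FALSE)
  out$q_rna <- p.adjust(out$p_rna, "BH")
  out$q_rf <- p.adjust(out$p_rf, "BH")
  out$q_te <- p.adjust(out$p_te, "BH")
  out$sig_rna <- !is.na(out$p_rna) & out$p_rna < alpha
  out$sig_rf <- !is.na(out$p_rf) & out$p_rf < alpha
  out$sig_te <- !is.na(out$p_te) & out$p_te < alpha
  out$pattern <- classify_pattern(out$sig_rna, out$sig_rf, out$sig_te,
                                  out$log2fc_rna, out$log2fc_rf,
                                  out$log2fc_te)
  rownames(out) <- NULL
  class(out) <- c("differential_table", "data.frame")
  out
}

#' Variance in RF fold change explained by RNA fold change
#'
#' Ordinary least squares of the RF log2 fold change on the RNA log2 fold
#' change; the R-squared answers how much of the change in translation
#' level is accounted for by the change in transcript level.
#'
#' @param rna_log2fc,rf_log2fc Paired numeric vectors (n >= 3; NA pairs
#'   dropped).
#' @return List with `r_squared`, `p` (overall F-test), `slope`, `n`.
#' @export
fc_variance_explained <- function(rna_log2fc, rf_log2fc) {
  ok <- is.finite(rna_log2fc) & is.finite(rf_log2fc)
  x <- rna_log2fc[ok]; y <- rf_log2fc[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (var(x) == 0) stop("constant predictor")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(r_squared = sm$r.squared,
       p = unname(pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)),
       slope = unname(coef(fit)[2L]), n = length(x))
}

#' Baseline variance in RF levels explained by RNA levels
#'
#' Generalized linear model of RF RPKM on log RNA RPKM under a Gamma
#' response with log link (RF levels are positive and right-skewed); the
#' fit is summarised by the pseudo-R-squared
#' `1 - SS_error / SS_total` computed on the response scale.
#'
#' @param rna_rpkm,rf_rpkm Strictly positive paired numeric vectors.
#' @return List with `pseudo_r_squared`, `n`, and the fitted `glm` object.
#' @export
baseline_variance_explained <- function(rna_rpkm, rf_rpkm) {
  ok <- is.finite(rna_rpkm) & is.finite(rf_rpkm)
  x <- rna_rpkm[ok]; y <- rf_rpkm[ok]
  if (any(x <= 0) || any(y <= 0)) {
    stop("Gamma model requires strictly positive values")
  }
  fit <- glm(y ~ log(x), family = Gamma(link = "log"),
             control = list(maxit = 100))
  mu <- fitted(fit)
  r2 <- 1 - sum((y - mu)^2) / sum((y - mean(y))^2)
  list(pseudo_r_squared = r2, n = length(y), fit = fit)
}
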