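## Synthetic transcriptomes and RF/RNA-seq coverage with planted
## transcriptional and translational effects. The generator emulates the
## replicate structure of a depolarisation experiment (3 control vs 2
## treated cultures), negative-binomial count noise, RF coverage restricted
## to 5'UTR + CDS with start/stop-codon pause peaks, and planted TE changes
## that are linear functions of 5'UTR/3'UTR sequence features plus noise.

#' Simulation configuration
#'
#' Defaults define the reference synthetic experiment used throughout the
#' package tests: 3 control vs 2 treated replicates, NB dispersion 0.05,
#' mean depth 1e4 reads per transcript, planted TE effects on
#' `norm_ss_utr5`, `n_upstream_kozak` and `short_utr3` calibrated to 17%
#' of the TE-change variance, and transcriptional changes in ~16.5% (up)
#' and ~9.5% (down) of transcripts.
#'
#' @param n_transcripts Number of transcripts.
#' @param utr5_length_range,cds_length_range,utr3_length_range Inclusive nt
#'   ranges; CDS lengths are drawn from the multiples of 3 (>= 6) inside
#'   the range.
#' @param gc_range Per-transcript GC fraction range.
#' @param uaug_rate Expected (Poisson) number of injected uAUGs per 5'UTR.
#' @param kozak_fraction Fraction of injected uAUGs given strong Kozak
#'   context (purine at -3, G at +4).
#' @param n_control,n_treated Replicate counts (>= 2 each).
#' @param mean_depth Expected reads per transcript for a transcript at
#'   baseline log2 abundance 0.
#' @param nb_dispersion NB dispersion phi (variance `mu + phi mu^2`).
#' @param planted_te_coefficients Named numeric map predictor -> per-unit
#'   effect on log2 TE change in the treated condition.
#' @param te_noise_sd Residual sd of the planted log2 TE change.
#' @param te_target_r2 Optional: jointly rescale the planted coefficients
#'   so the feature term explains this fraction of the variance of the
#'   log2 TE change *as measured by the pipeline* — planted residual
#'   variance plus the analytic counting-noise variance of the fold-change
#'   estimate under the configured dispersion and replicate counts
#'   (`NULL` uses the coefficients as given).
#' @param frac_rna_up,frac_rna_down Fractions of transcripts with planted
#'   transcriptional up-/down-regulation.
#' @param rna_fc_mean,rna_fc_sd Mean and sd of |planted RNA log2 FC|.
#' @param baseline_log2_abundance_sd Between-transcript sd of baseline log2
#'   abundance.
#' @param baseline_log2_te_sd Between-transcript sd of baseline log2 TE.
#' @param start_stop_pause Multiplicative RF enrichment over the start and
#'   stop codon windows.
#' @param pause_width Width (nt) of each pause window (default 3, the
#'   codon).
#' @param utr5_rf_weight RF density of the 5'UTR relative to the CDS.
#' @param footprint_length_range Footprint lengths (nt) recorded as
#'   metadata; coverage stores per-nucleotide depth of footprint 5' ends.
#' @param seed Integer seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_transcripts = 2000L,
                              utr5_length_range = c(50L, 250L),
                              cds_length_range = c(150L, 450L),
                              utr3_length_range = c(90L, 690L),
                              gc_range = c(0.35, 0.65),
                              uaug_rate = 1,
                              kozak_fraction = 0.5,
                              n_control = 3L,
                              n_treated = 2L,
                              mean_depth = 1e4,
                              nb_dispersion = 0.05,
                              planted_te_coefficients =
                                c(norm_ss_utr5 = 3.2,
                                  n_upstream_kozak = -0.33,
                                  short_utr3 = 0.40),
                              te_noise_sd = 0.911,
                              te_target_r2 = 0.17,
                              frac_rna_up = 0.165,
                              frac_rna_down = 0.095,
                              rna_fc_mean = 1.5,
                              rna_fc_sd = 0.5,
                              baseline_log2_abundance_sd = 1.5,
                              baseline_log2_te_sd = 1,
                              start_stop_pause = 5,
                              pause_width = 3L,
                              utr5_rf_weight = 0.5,
                              footprint_length_range = c(26L, 34L),
                              seed = NULL) {
  cfg <- as.list(environment())
  ranges <- list(utr5 = utr5_length_range, cds = cds_length_range,
                 utr3 = utr3_length_range)
  for (r in names(ranges)) {
    rg <- ranges[[r]]
    if (length(rg) != 2L || any(rg < 1L) || rg[1L] > rg[2L]) {
      stop("degenerate ", r, "_length_range")
    }
  }
  cds_ok <- seq.int(cds_length_range[1L], cds_length_range[2L])
  cds_ok <- cds_ok[cds_ok %% 3L == 0L & cds_ok >= 6L]
  if (length(cds_ok) == 0L) {
    stop("cds_length_range contains no usable length (multiple of 3, >= 6)")
  }
  if (gc_range[1L] < 0 || gc_range[2L] > 1 || gc_range[1L] > gc_range[2L]) {
    stop("degenerate gc_range")
  }
  if (n_control < 2L || n_treated < 2L) {
    stop("need >= 2 replicates per condition")
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (uaug_rate < 0) stop("uaug_rate must be >= 0")
  structure(cfg, class = "simulation_config")
}

## Random sequence at a given GC, optionally free of an alphabet letter.
#' @noRd
.rand_seq <- function(n, gc) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## Replace the T of every ATG occurrence not in `keep` (0-based A positions)
## with C. T -> C can never create a new ATG, so one pass converges.
#' @noRd
.scrub_atg <- function(chars, keep = integer(0)) {
  repeat {
    hits <- which(chars == "A" &
                    c(chars[-1L], "") == "T" &
                    c(chars[-(1:2)], "", "") == "G")
    hits <- setdiff(hits - 1L, keep)       # 0-based
    if (length(hits) == 0L) return(chars)
    chars[hits + 2L] <- "C"
  }
}

#' Simulate an annotated transcriptome with planted effects
#'
#' Generates transcripts with contiguous 5'UTR | CDS | 3'UTR structure
#' (CDS starting with ATG and ending with a stop codon), injects a
#' Poisson(`uaug_rate`) number of uAUGs per 5'UTR (a `kozak_fraction` of
#' them in strong Kozak context, the rest with a pyrimidine at -3 so they
#' never count as Kozak matches), and draws the planted ground truth:
#' baseline abundance and TE, transcriptional log2 fold changes for the
#' configured fractions of transcripts, and a planted log2 TE change that
#' is a linear function of the configured sequence features plus Gaussian
#' noise. By construction the planted RF change is the sum of the RNA and
#' TE changes, and the recorded feature values are recomputed with the
#' package's own feature extractors.
#'
#' @param config A [simulation_config()].
#' @return A [transcript_set()] whose `truth` element holds the planted
#'   values; the realised coefficient vector is in
#'   `attr(truth, "planted_coefficients")`.
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- as.integer(config$n_transcripts)

  l5 <- sample(seq.int(config$utr5_length_range[1L],
                       config$utr5_length_range[2L]), n, replace = TRUE)
  cds_ok <- seq.int(config$cds_length_range[1L], config$cds_length_range[2L])
  cds_ok <- cds_ok[cds_ok %% 3L == 0L & cds_ok >= 6L]
  lc <- cds_ok[sample.int(length(cds_ok), n, replace = TRUE)]
  l3 <- sample(seq.int(config$utr3_length_range[1L],
                       config$utr3_length_range[2L]), n, replace = TRUE)
  gc <- runif(n, config$gc_range[1L], config$gc_range[2L])
  stops <- c("TAA", "TAG", "TGA")

  seqs <- character(n)
  for (i in seq_len(n)) {
    ## 5'UTR: uAUG-free background, then controlled injection
    u5 <- strsplit(.rand_seq(l5[i], gc[i]), "", fixed = TRUE)[[1L]]
    if (l5[i] >= 3L) u5 <- .scrub_atg(u5)
    k <- if (config$uaug_rate > 0) rpois(1L, config$uaug_rate) else 0L
    sites <- integer(0)
    if (k > 0L && l5[i] >= 8L) {
      avail <- seq.int(3L, l5[i] - 5L)     # 0-based A positions, contexts fit
      while (length(sites) < k && length(avail) > 0L) {
        s <- if (length(avail) == 1L) avail else sample(avail, 1L)
        sites <- c(sites, s)
        avail <- avail[abs(avail - s) >= 7L]
      }
      sites <- sort(sites)
      is_kozak <- runif(length(sites)) < config$kozak_fraction
      for (j in seq_along(sites)) {
        s <- sites[j]                       # 0-based
        u5[s + 1L] <- "A"; u5[s + 2L] <- "T"; u5[s + 3L] <- "G"
        if (is_kozak[j]) {
          u5[s - 2L] <- sample(c("A", "G"), 1L)   # -3 purine
          u5[s + 4L] <- "G"                       # +4 G
        } else {
          u5[s - 2L] <- sample(c("C", "T"), 1L)   # -3 pyrimidine
        }
      }
      u5 <- .scrub_atg(u5, keep = sites)
    }
    ## CDS: ATG + random codons + stop
    body_len <- lc[i] - 6L
    cds <- paste0("ATG", .rand_seq(body_len, gc[i]),
                  stops[sample.int(3L, 1L)])
    seqs[i] <- paste0(paste(u5, collapse = ""), cds, .rand_seq(l3[i], gc[i]))
  }

  tx_ids <- sprintf("tx%05d", seq_len(n))
  gene_ids <- sprintf("g%05d", ceiling(seq_len(n) / 1.4))
  ann <- data.frame(
    transcript_id = tx_ids, gene_id = gene_ids,
    length = l5 + lc + l3,
    utr5_start = 0L, utr5_end = l5,
    cds_start = l5, cds_end = l5 + lc,
    utr3_start = l5 + lc, utr3_end = l5 + lc + l3,
    stringsAsFactors = FALSE)
  ts <- transcript_set(ann, setNames(seqs, tx_ids))

  ## ground truth: features driving the planted TE change
  beta <- config$planted_te_coefficients
  feats <- feature_table(ts, features = names(beta))
  X <- as.matrix(feats[, names(beta), drop = FALSE])
  if (anyNA(X)) X[is.na(X)] <- 0
  ## Planted TE changes are centered across the transcriptome: depth
  ## normalisation makes a global TE shift unidentifiable (it cancels from
  ## every RPKM ratio), so only relative TE regulation is planted.
  xb <- drop(X %*% beta)
  xb <- xb - mean(xb)
  if (!is.null(config$te_target_r2)) {
    ## Target is the share of the *measured* TE-change variance: the
    ## pipeline estimates log2 TE change with counting noise of analytic
    ## variance 2*phi/ln(2)^2 * (1/n_treated + 1/n_control) (NB dispersion
    ## phi dominating depth at high coverage), which must be added to the
    ## planted residual variance when scaling the feature term.
    vxb <- var(xb)
    if (vxb > 0) {
      v_meas <- 2 * config$nb_dispersion / log(2)^2 *
        (1 / config$n_treated + 1 / config$n_control)
      r2 <- config$te_target_r2
      scale <- sqrt(r2 / (1 - r2) *
                      (config$te_noise_sd^2 + v_meas) / vxb)
      beta <- beta * scale
      xb <- xb * scale
    }
  }
  te_fc <- xb + rnorm(n, 0, config$te_noise_sd)

  rna_fc <- numeric(n)
  n_up <- round(config$frac_rna_up * n)
  n_dn <- round(config$frac_rna_down * n)
  moved <- sample.int(n, n_up + n_dn)
  rna_fc[moved[seq_len(n_up)]] <-
    abs(rnorm(n_up, config$rna_fc_mean, config$rna_fc_sd))
  rna_fc[moved[n_up + seq_len(n_dn)]] <-
    -abs(rnorm(n_dn, config$rna_fc_mean, config$rna_fc_sd))

  truth <- data.frame(
    transcript_id = tx_ids, gene_id = gene_ids,
    log2_baseline_abundance = rnorm(n, 0, config$baseline_log2_abundance_sd),
    log2_baseline_te = rnorm(n, 0, config$baseline_log2_te_sd),
    log2fc_rna = rna_fc,
    log2fc_te = te_fc,
    log2fc_rf = rna_fc + te_fc,
    stringsAsFactors = FALSE)
  truth <- cbind(truth, feats[, names(beta), drop = FALSE])
  attr(truth, "planted_coefficients") <- beta
  ts$truth <- truth
  ts
}

#' Simulate RF and RNA-seq coverage with planted fold changes
#'
#' RNA-seq reads are spread over the full transcript; RF reads (5' ends of
#' 26-34 nt footprints) are restricted to the 5'UTR + CDS, with the 5'UTR
#' at `utr5_rf_weight` of the CDS density and multiplicative pause peaks of
#' `start_stop_pause` over the start and stop codon windows. Per sample,
#' the expected read total follows the planted baseline and (for treated
#' samples) fold changes; realised totals are negative-binomial with the
#' configured dispersion, and read positions are multinomial in the weight
#' profile.
#'
#' @param transcripts A [transcript_set()] from [simulate_transcriptome()].
#' @param truth Ground-truth `data.frame` (defaults to
#'   `transcripts$truth`).
#' @param config The [simulation_config()] used to generate `transcripts`.
#' @param seed Optional seed; defaults to `config$seed + 1` so that
#'   transcriptome and coverage generation are independently reproducible.
#' @return List with elements `rf` and `rna`, both [coverage_set()]s.
#' @export
simulate_coverage <- function(transcripts, truth = transcripts$truth,
                              config, seed = NULL) {
  stopifnot(inherits(transcripts, "transcript_set"),
            inherits(config, "simulation_config"))
  ann <- transcripts$annotation
  if (is.null(truth) ||
      !identical(truth$transcript_id, ann$transcript_id)) {
    stop("truth and transcripts must cover identical transcript ids")
  }
  if (is.null(seed) && !is.null(config$seed)) {
    seed <- (config$seed + 1L) %% 2147483647L
  }
  if (!is.null(seed)) set.seed(seed)

  samples <- data.frame(
    sample = c(sprintf("ctrl_%d", seq_len(config$n_control)),
               sprintf("trt_%d", seq_len(config$n_treated))),
    condition = rep(c("control", "treated"),
                    c(config$n_control, config$n_treated)),
    stringsAsFactors = FALSE)
  treated <- samples$condition == "treated"
  nsamp <- nrow(samples)
  size <- 1 / config$nb_dispersion

  depth_rna <- vector("list", nrow(ann))
  depth_rf <- vector("list", nrow(ann))
  names(depth_rna) <- names(depth_rf) <- ann$transcript_id

  for (i in seq_len(nrow(ann))) {
    len <- ann$length[i]
    s <- ann$cds_start[i]
    e <- ann$cds_end[i]
    w_rna <- rep(1, len)
    w_rf <- numeric(len)
    w_rf[.iv_idx(0L, s)] <- config$utr5_rf_weight
    w_rf[.iv_idx(s, e)] <- 1
    pw <- config$pause_width
    w_rf[.iv_idx(s, min(s + pw, e))] <- config$start_stop_pause
    w_rf[.iv_idx(max(e - pw, s), e)] <- config$start_stop_pause

    b <- truth$log2_baseline_abundance[i]
    bte <- truth$log2_baseline_te[i]
    mu_rna <- config$mean_depth *
      2^(b + truth$log2fc_rna[i] * treated)
    mu_rf <- config$mean_depth *
      2^(b + bte + (truth$log2fc_rna[i] + truth$log2fc_te[i]) * treated)

    m_rna <- matrix(0L, len, nsamp)
    m_rf <- matrix(0L, len, nsamp)
    for (j in seq_len(nsamp)) {
      n_rna <- rnbinom(1L, mu = mu_rna[j], size = size)
      n_rf <- rnbinom(1L, mu = mu_rf[j], size = size)
      if (n_rna > 0L) m_rna[, j] <- rmultinom(1L, n_rna, w_rna)
      if (n_rf > 0L) m_rf[, j] <- rmultinom(1L, n_rf, w_rf)
    }
    depth_rna[[i]] <- m_rna
    depth_rf[[i]] <- m_rf
  }

  list(rf = coverage_set(depth_rf, samples, "rf"),
       rna = coverage_set(depth_rna, samples, "rna"))
}

#' One-call synthetic experiment
#'
#' Runs [simulate_transcriptome()] then [simulate_coverage()] under the
#' config's seed.
#'
#' @param config A [simulation_config()].
#' @return List with `transcripts`, `rf`, `rna`, `truth`, `config`.
#' @export
simulate_experiment <- function(config) {
  ts <- simulate_transcriptome(config)
  cov <- simulate_coverage(ts, ts$truth, config)
  list(transcripts = ts, rf = cov$rf, rna = cov$rna, truth = ts$truth,
       config = config)
}

#' Write a synthetic experiment to plain-text fixture files
#'
#' Emits `transcripts.fa`, `annotation.tsv`, `design.tsv`, `truth.tsv`
#' (when ground truth is present) and one `<assay>_<sample>.bedgraph` per
#' sample and assay, all round-trippable through the package readers.
#'
#' @param transcripts A [transcript_set()].
#' @param coverages List with `rf` and/or `rna` [coverage_set()]s (may be
#'   `NULL` to write sequences and annotation only).
#' @param out_dir Output directory (created if needed).
#' @param truth Optional ground-truth `data.frame`.
#' @return Invisibly, the vector of written paths.
#' @export
write_fixtures <- function(transcripts, coverages = NULL, out_dir,
                           truth = transcripts$truth) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir)
  }
  paths <- character(0)
  fa <- file.path(out_dir, "transcripts.fa")
  Biostrings::writeXStringSet(transcripts$sequences, fa)
  paths <- c(paths, fa)
  ann_path <- file.path(out_dir, "annotation.tsv")
  write_annotation(transcripts$annotation, ann_path)
  paths <- c(paths, ann_path)
  if (!is.null(truth)) {
    tp <- file.path(out_dir, "truth.tsv")
    write.table(truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, tp)
  }
  design <- NULL
  for (assay in names(coverages)) {
    cs <- coverages[[assay]]
    if (is.null(cs)) next
    design <- cs$samples
    for (j in seq_len(nrow(cs$samples))) {
      bg <- file.path(out_dir,
                      paste0(assay, "_", cs$samples$sample[j], ".bedgraph"))
      write_bedgraph(lapply(cs$depth, function(m) m[, j]), bg)
      paths <- c(paths, bg)
    }
  }
  if (!is.null(design)) {
    dp <- file.path(out_dir, "design.tsv")
    write.table(design, dp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, dp)
  }
  invisible(paths)
}
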