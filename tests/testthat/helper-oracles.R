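## Independent oracles and small fixture builders used across the suite.

## Pair weight used by the folding model (kept in sync with the spec of
## fold_energy, but implemented independently of the DP).
.pair_w <- function(a, b) {
  p <- paste0(a, b)
  if (p %in% c("GC", "CG")) return(3)
  if (p %in% c("AT", "TA")) return(2)
  if (p %in% c("GT", "TG")) return(1)
  0
}

## Brute-force optimum over ALL non-crossing structures with hairpin loops
## of >= min_loop unpaired bases: enumerate candidate pairs, then explore
## every compatible subset. Exponential; only for short sequences.
brute_fold_score <- function(seq, min_loop = 3) {
  chars <- strsplit(chartr("Uu", "TT", toupper(seq)), "", fixed = TRUE)[[1]]
  n <- length(chars)
  cand <- list()
  if (n >= min_loop + 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (j - i > min_loop && .pair_w(chars[i], chars[j]) > 0) {
          cand[[length(cand) + 1L]] <- c(i, j)
        }
      }
    }
  }
  best <- 0
  recurse <- function(idx, used, score) {
    if (score > best) best <<- score
    if (idx > length(cand)) return(invisible())
    recurse(idx + 1L, used, score)          # skip this pair
    p <- cand[[idx]]
    for (q in used) {
      if (length(intersect(p, q)) > 0L) return(invisible())
      crossing <- (q[1] < p[1] && p[1] < q[2] && q[2] < p[2]) ||
        (p[1] < q[1] && q[1] < p[2] && p[2] < q[2])
      if (crossing) return(invisible())
    }
    recurse(idx + 1L, c(used, list(p)),
            score + .pair_w(chars[p[1]], chars[p[2]]))
  }
  recurse(1L, list(), 0)
  -best
}

## Hypergeometric upper-tail oracle for the one-sided Fisher test:
## P(overlap >= a) for query size nq, target size nt, universe N.
hyper_tail_p <- function(a, nq, nt, N) {
  kmax <- min(nq, nt)
  if (a > kmax) return(0)
  sum(vapply(a:kmax, function(k) {
    choose(nt, k) * choose(N - nt, nq - k) / choose(N, nq)
  }, numeric(1)))
}

## Random DNA string.
rand_dna <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

## A tiny deterministic transcript set built by hand.
tiny_transcript_set <- function() {
  seqs <- c(
    txA = paste0(strrep("C", 30), "ATG", strrep("GAA", 30), "TAA",
                 strrep("T", 40)),
    txB = paste0(strrep("A", 12), "ATG", strrep("CCG", 40), "TGA",
                 strrep("G", 20)))
  ann <- data.frame(
    transcript_id = c("txA", "txB"), gene_id = c("gA", "gB"),
    length = unname(nchar(seqs)),
    utr5_start = 0L, utr5_end = c(30L, 12L),
    cds_start = c(30L, 12L), cds_end = c(30L + 96L, 12L + 126L),
    utr3_start = c(126L, 138L), utr3_end = unname(nchar(seqs)),
    stringsAsFactors = FALSE)
  transcript_set(ann, seqs)
}

## Long-format expression table assembled directly from RPKM matrices
## (transcripts x samples), bypassing coverage quantification.
manual_expression_table <- function(rna_rpkm, rf_rpkm,
                                    conditions = c("control", "control",
                                                   "control", "treated",
                                                   "treated"),
                                    gene_ids = NULL) {
  txs <- rownames(rna_rpkm)
  if (is.null(gene_ids)) gene_ids <- paste0("g_", txs)
  samples <- colnames(rna_rpkm)
  block <- function(m, assay, region) {
    data.frame(transcript_id = rep(txs, times = ncol(m)),
               gene_id = rep(gene_ids, times = ncol(m)),
               region = region,
               sample = rep(samples, each = nrow(m)),
               condition = rep(conditions, each = nrow(m)),
               assay = assay, count = as.vector(m) * 10,
               effective_length = 1000L,
               cpm = as.vector(m), rpkm = as.vector(m),
               stringsAsFactors = FALSE)
  }
  out <- rbind(block(rna_rpkm, "rna", "exonic"),
               block(rf_rpkm, "rf", "cds"))
  class(out) <- c("expression_table", "data.frame")
  out
}

## Small simulated experiment shared by coverage-level tests.
small_experiment <- function(seed = 421L, n = 40L, depth = 3000) {
  cfg <- simulation_config(n_transcripts = n, mean_depth = depth,
                           seed = seed)
  list(cfg = cfg, ex = simulate_experiment(cfg))
}
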