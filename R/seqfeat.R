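## Sequence-feature extraction: GC content, uAUG and upstream-Kozak
## scanning, and a built-in RNA secondary-structure score.

#' GC content of a nucleotide sequence
#'
#' Fraction of G+C among non-N bases. `N` bases are excluded from both the
#' numerator and the denominator.
#'
#' @param seq Character vector of nucleotide sequences (DNA or RNA alphabet).
#' @return Numeric vector of fractions in `[0, 1]`; `NA` for empty or all-N
#'   sequences.
#' @examples
#' gc_content(c("GGCC", "ATAT", "GCAT"))
#' @export
gc_content <- function(seq) {
  vapply(seq, function(s) {
    s <- .norm_seq(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    chars <- chars[chars != "N"]
    if (length(chars) == 0L) return(NA_real_)
    mean(chars %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Count upstream AUGs in a 5'UTR sequence
#'
#' Number of AUG (ATG) trinucleotides in the 5'UTR, in any reading frame.
#' AUG cannot overlap itself, so every occurrence is counted exactly once.
#'
#' @param utr5_seq Character vector of 5'UTR sequences (may be empty strings).
#' @return Integer vector of counts.
#' @examples
#' count_uaugs(c("", "GATGCATGG", "ATGATG"))
#' @export
count_uaugs <- function(utr5_seq) {
  vapply(utr5_seq, function(s) {
    if (nchar(s) < 3L) return(0L)
    hits <- gregexpr("ATG", .norm_seq(s), fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) 0L else length(hits)
  }, integer(1), USE.NAMES = FALSE)
}

#' Count upstream AUGs in strong Kozak context
#'
#' An upstream AUG counts as a Kozak match when the base at position -3
#' (relative to the A of the AUG at 0) is a purine (A/G) and the base at +4
#' (the base immediately 3' of the G) is G. uAUGs with fewer than 3 nt of
#' upstream context are never counted. For uAUGs near the 3' end of the UTR
#' the +4 base may fall in the CDS; supply its first bases as
#' `downstream_context`.
#'
#' @param utr5_seq 5'UTR sequence (single string).
#' @param downstream_context First bases of the CDS (>= 1 nt is enough;
#'   default `""` means no downstream context is available).
#' @return Integer count of Kozak-context uAUGs (always `<=`
#'   [count_uaugs()]).
#' @examples
#' count_upstream_kozak("AAAACCATGGTT")  # 1
#' count_upstream_kozak("CCCCCCATGCTT")  # 0: +4 base is C
#' @export
count_upstream_kozak <- function(utr5_seq, downstream_context = "") {
  stopifnot(length(utr5_seq) == 1L, length(downstream_context) == 1L)
  utr <- .norm_seq(utr5_seq)
  L <- nchar(utr)
  if (L < 3L) return(0L)
  ctx <- paste0(utr, .norm_seq(downstream_context))
  chars <- strsplit(ctx, "", fixed = TRUE)[[1L]]
  starts <- which(vapply(seq_len(L - 2L), function(i) {
    chars[i] == "A" && chars[i + 1L] == "T" && chars[i + 2L] == "G"
  }, logical(1)))
  n <- 0L
  for (i in starts) {                      # i is 1-based position of the A
    if (i - 3L < 1L) next                  # -3 context missing
    if (i + 3L > length(chars)) next       # +4 context missing
    if (chars[i - 3L] %in% c("A", "G") && chars[i + 3L] == "G") n <- n + 1L
  }
  n
}

#' Secondary-structure score of a nucleotide sequence
#'
#' The built-in engine runs a weighted Nussinov dynamic program that
#' maximises the total weight of non-crossing base pairs (GC = 3, AU = 2,
#' GU = 1) subject to a minimum hairpin loop of `min_loop` unpaired
#' nucleotides, and returns the negated optimal weight as a pseudo
#' free-energy: always `<= 0`, more negative meaning more stable structure.
#' It is a base-pair maximisation model, not a thermodynamic nearest-
#' neighbour model, and is exactly testable against exhaustive structure
#' enumeration.
#'
#' The external engine delegates to a user-supplied function (for example a
#' wrapper around ViennaRNA's `RNAfold`) expected to return a minimum free
#' energy in kcal/mol. Scores from different engines live on different
#' scales; record which engine produced a feature table.
#'
#' @param seq Character vector of sequences.
#' @param engine `"builtin"` (default) or `"external"`.
#' @param min_loop Minimum number of unpaired nucleotides in a hairpin loop
#'   (builtin engine; default 3).
#' @param external_fn For `engine = "external"`: function taking one
#'   sequence and returning one numeric energy.
#' @return Numeric vector of scores, `<= 0`; 0 for sequences admitting no
#'   pair (including empty sequences).
#' @examples
#' fold_energy("AAAAAA")     # 0, nothing can pair
#' fold_energy("GGGAAACCC")  # -9: three GC pairs around a 3-nt loop
#' @export
fold_energy <- function(seq, engine = c("builtin", "external"), min_loop = 3L,
                        external_fn = NULL) {
  engine <- match.arg(engine)
  if (engine == "external") {
    if (!is.function(external_fn)) {
      stop("engine = 'external' requires an `external_fn` folding backend")
    }
    return(vapply(seq, function(s) as.numeric(external_fn(s)), numeric(1),
                  USE.NAMES = FALSE))
  }
  vapply(seq, function(s) {
    s <- .norm_seq(s)
    if (grepl("N", s, fixed = TRUE)) s <- gsub("N", "A", s)  # N never pairs
    -as.numeric(.nussinov_score(s, as.integer(min_loop)))
  }, numeric(1), USE.NAMES = FALSE)
}

## Features that can be requested from feature_table(), with the ss_* and
## derived columns they require.
.FEATURE_COLS <- c("utr5_gc", "cds_gc", "utr3_gc",
                   "utr5_len", "cds_len", "utr3_len",
                   "n_uaug", "n_upstream_kozak",
                   "ss_utr5", "ss_cds", "ss_utr3",
                   "norm_ss_utr5", "norm_ss_cds", "norm_ss_utr3",
                   "short_utr3")

#' Per-transcript sequence feature table
#'
#' Extracts the primary-sequence predictors used for modelling TE change:
#' GC content, length and secondary-structure score of 5'UTR, CDS and
#' 3'UTR, length-normalised structure scores, uAUG and upstream-Kozak
#' counts, and the short-3'UTR indicator (`utr3_len < short_utr3_cutoff`).
#'
#' Zero-length regions get length 0, structure score 0, and `NA` GC and
#' normalised-structure values.
#'
#' @param transcripts A `transcript_set` (see [simulate_transcriptome()] or
#'   [transcript_set()]).
#' @param engine,external_fn Folding engine passed to [fold_energy()].
#' @param features Character vector of feature columns to compute (default
#'   all). Folding is the expensive step; restrict this when only a few
#'   predictors are needed.
#' @param short_utr3_cutoff Length (nt) below which a 3'UTR counts as
#'   short; default 492.
#' @return `data.frame` with one row per transcript: `transcript_id`,
#'   `gene_id`, the requested feature columns, and an `engine` attribute
#'   recording the folding backend.
#' @export
feature_table <- function(transcripts, engine = c("builtin", "external"),
                          external_fn = NULL, features = .FEATURE_COLS,
                          short_utr3_cutoff = 492L) {
  engine <- match.arg(engine)
  stopifnot(inherits(transcripts, "transcript_set"))
  features <- match.arg(features, .FEATURE_COLS, several.ok = TRUE)
  ann <- transcripts$annotation
  seqs <- as.character(transcripts$sequences)[ann$transcript_id]

  region_seq <- function(i, from, to) substr(seqs[i], from + 1L, to)
  n <- nrow(ann)
  utr5 <- vapply(seq_len(n), function(i)
    region_seq(i, ann$utr5_start[i], ann$utr5_end[i]), character(1))
  cds <- vapply(seq_len(n), function(i)
    region_seq(i, ann$cds_start[i], ann$cds_end[i]), character(1))
  utr3 <- vapply(seq_len(n), function(i)
    region_seq(i, ann$utr3_start[i], ann$utr3_end[i]), character(1))

  out <- data.frame(transcript_id = ann$transcript_id,
                    gene_id = ann$gene_id,
                    stringsAsFactors = FALSE)
  lens <- list(utr5 = nchar(utr5), cds = nchar(cds), utr3 = nchar(utr3))
  regs <- list(utr5 = utr5, cds = cds, utr3 = utr3)

  need <- function(col) col %in% features
  for (r in c("utr5", "cds", "utr3")) {
    if (need(paste0(r, "_gc"))) out[[paste0(r, "_gc")]] <- gc_content(regs[[r]])
    if (need(paste0(r, "_len"))) out[[paste0(r, "_len")]] <- lens[[r]]
    ss_col <- paste0("ss_", r)
    norm_col <- paste0("norm_ss_", r)
    if (need(ss_col) || need(norm_col)) {
      ss <- fold_energy(regs[[r]], engine = engine, external_fn = external_fn)
      if (need(ss_col)) out[[ss_col]] <- ss
      if (need(norm_col)) {
        out[[norm_col]] <- ifelse(lens[[r]] > 0L, ss / lens[[r]], NA_real_)
      }
    }
  }
  if (need("n_uaug")) out$n_uaug <- count_uaugs(utr5)
  if (need("n_upstream_kozak")) {
    out$n_upstream_kozak <- vapply(seq_len(n), function(i) {
      count_upstream_kozak(utr5[i], substr(cds[i], 1L, 4L))
    }, integer(1))
  }
  if (need("short_utr3")) {
    out$short_utr3 <- as.integer(lens$utr3 < short_utr3_cutoff)
  }
  attr(out, "engine") <- engine
  out
}
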