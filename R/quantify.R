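## Region quantification: position masks around start/stop codons, masked
## region counts, CPM/RPKM normalisation, expression filter, and TE.

#' Positions masked around the start and stop codons
#'
#' For TE calculation, positions adjacent to the start and stop codons are
#' excluded because initiating and terminating ribosomes pile up there: the
#' 9 nt before the first nt of the start codon, the 15 nt after the last nt
#' of the start codon, the 15 nt before the first nt of the stop codon, and
#' the 15 nt after the last nt of the stop codon. The start and stop codon
#' trinucleotides themselves are kept. With `s` the first nt of the start
#' codon and `t` the first nt of the stop codon (the final in-frame codon of
#' the CDS interval), the mask is
#' `[s-9, s) U [s+3, s+18) U [t-15, t) U [t+3, t+18)`, clipped to the
#' transcript. For very short CDS (< 21 nt) the segments anchored at one
#' codon can reach the other; codon positions are excluded from the mask
#' in that case too.
#'
#' @param model One row of a transcript annotation (list or single-row
#'   `data.frame` with `cds_start`, `cds_end`, `length`).
#' @return Sorted integer vector of 0-based masked positions.
#' @export
build_mask <- function(model) {
  s <- as.integer(model$cds_start)
  e <- as.integer(model$cds_end)
  len <- as.integer(model$length)
  if (e - s < 6L) stop("CDS shorter than 6 nt: cannot place start/stop mask")
  t0 <- e - 3L                      # first nt of the stop codon
  clip <- function(from, to) {
    from <- max(from, 0L)
    to <- min(to, len)
    if (to <= from) integer(0) else seq.int(from, to - 1L)
  }
  mask <- sort(unique(c(clip(s - 9L, s), clip(s + 3L, s + 18L),
                        clip(t0 - 15L, t0), clip(t0 + 3L, t0 + 18L))))
  ## For a CDS shorter than ~21 nt the segments anchored at one codon can
  ## reach the other codon; the codons themselves are never masked.
  setdiff(mask, c(s:(s + 2L), t0:(t0 + 2L)))
}

## Region -> 0-based half-open interval for one annotation row.
#' @noRd
.region_interval <- function(model, region) {
  switch(region,
         utr5 = c(model$utr5_start, model$utr5_end),
         cds = c(model$cds_start, model$cds_end),
         utr3 = c(model$utr3_start, model$utr3_end),
         exonic = c(0L, model$length),
         stop("unknown region: ", region))
}

#' Count coverage over one transcript region
#'
#' Sums nucleotide depth over the region, optionally excluding masked
#' positions; the effective length (for RPKM) is the number of positions
#' actually counted.
#'
#' @param coverage Numeric depth vector (length = transcript length) or a
#'   depth matrix (positions x samples).
#' @param model Annotation row (as in [build_mask()]).
#' @param region One of `"utr5"`, `"cds"`, `"utr3"`, `"exonic"`.
#' @param mask Integer vector of 0-based masked positions (see
#'   [build_mask()]); ignored unless `apply_mask`.
#' @param apply_mask Whether to exclude masked positions.
#' @return List with `count` (scalar or per-sample vector) and
#'   `effective_length`.
#' @export
count_region <- function(coverage, model, region, mask = NULL,
                         apply_mask = TRUE) {
  iv <- .region_interval(model, region)
  pos <- .iv_idx(iv[1L], iv[2L])
  if (apply_mask && length(mask) > 0L) pos <- setdiff(pos, mask + 1L)
  if (is.matrix(coverage)) {
    cnt <- if (length(pos) > 0L) colSums(coverage[pos, , drop = FALSE])
           else numeric(ncol(coverage))
  } else {
    cnt <- sum(coverage[pos])
  }
  list(count = cnt, effective_length = length(pos))
}

#' CPM and RPKM normalisation
#'
#' `CPM = count * 1e6 / library_size`; `RPKM = CPM / (effective_length /
#' 1000)`. Library size defaults to the per-sample column sum of `counts`,
#' i.e. normalisation is over the counted units supplied.
#'
#' @param counts Matrix (units x samples) or vector of raw counts.
#' @param effective_lengths Effective region lengths (nt), recycled over
#'   units.
#' @param library_size Optional per-sample totals; must be positive.
#' @return List of matrices/vectors `cpm` and `rpkm`.
#' @export
normalize_counts <- function(counts, effective_lengths, library_size = NULL) {
  m <- as.matrix(counts)
  if (is.null(library_size)) library_size <- colSums(m)
  if (any(library_size <= 0)) stop("zero library size")
  cpm <- sweep(m, 2L, library_size, "/") * 1e6
  rpkm <- cpm / (effective_lengths / 1000)
  if (!is.matrix(counts)) {
    cpm <- drop(cpm)
    rpkm <- drop(rpkm)
  }
  list(cpm = cpm, rpkm = rpkm)
}

#' Quantify region-level expression from coverage
#'
#' Converts RF and RNA-seq coverage into a long-format expression table:
#' per transcript x region x sample x assay, the raw count, effective
#' length, CPM and RPKM. Per assay and sample, the library size is the
#' total exonic count over all transcripts in the set (so exonic CPM sums
#' to 1e6), and the same library size normalises the sub-region counts.
#'
#' @param transcripts A [transcript_set()].
#' @param rf,rna [coverage_set()] objects for the two assays (either may be
#'   `NULL` to quantify a single assay).
#' @param apply_mask Apply the start/stop-codon mask of [build_mask()] to
#'   the counts (default `TRUE`, as used for TE).
#' @param regions Regions to quantify.
#' @return `data.frame` of class `expression_table` with columns
#'   `transcript_id`, `gene_id`, `region`, `sample`, `condition`, `assay`,
#'   `count`, `effective_length`, `cpm`, `rpkm`.
#' @export
quantify_expression <- function(transcripts, rf = NULL, rna = NULL,
                                apply_mask = TRUE,
                                regions = c("utr5", "cds", "utr3", "exonic")) {
  stopifnot(inherits(transcripts, "transcript_set"))
  ann <- transcripts$annotation
  covs <- list(rf = rf, rna = rna)
  covs <- covs[!vapply(covs, is.null, logical(1))]
  if (length(covs) == 0L) stop("supply at least one coverage_set")
  masks <- lapply(seq_len(nrow(ann)), function(i) {
    if (apply_mask) build_mask(ann[i, ]) else integer(0)
  })

  blocks <- list()
  for (assay in names(covs)) {
    cs <- covs[[assay]]
    missing_tx <- setdiff(ann$transcript_id, names(cs$depth))
    if (length(missing_tx) > 0L) {
      stop("coverage for assay '", assay, "' lacks transcripts: ",
           paste(head(missing_tx, 3L), collapse = ", "))
    }
    nsamp <- nrow(cs$samples)
    for (region in regions) {
      cnts <- matrix(0, nrow(ann), nsamp)
      efflen <- integer(nrow(ann))
      for (i in seq_len(nrow(ann))) {
        cr <- count_region(cs$depth[[ann$transcript_id[i]]], ann[i, ],
                           region, masks[[i]], apply_mask = apply_mask)
        cnts[i, ] <- cr$count
        efflen[i] <- cr$effective_length
      }
      blocks[[paste(assay, region)]] <-
        list(assay = assay, region = region, counts = cnts, efflen = efflen,
             samples = cs$samples)
    }
  }

  ## per assay+sample library size = total exonic count
  libsize <- lapply(names(covs), function(assay) {
    ex <- blocks[[paste(assay, "exonic")]]
    if (is.null(ex)) {  # exonic not among requested regions: compute it
      cs <- covs[[assay]]
      Reduce(`+`, lapply(ann$transcript_id,
                         function(tx) colSums(cs$depth[[tx]])))
    } else {
      colSums(ex$counts)
    }
  })
  names(libsize) <- names(covs)

  rows <- lapply(blocks, function(b) {
    ls <- libsize[[b$assay]]
    if (any(ls <= 0)) stop("zero library size for assay ", b$assay)
    nz <- normalize_counts(b$counts, pmax(b$efflen, 1L), library_size = ls)
    data.frame(
      transcript_id = rep(ann$transcript_id, times = nrow(b$samples)),
      gene_id = rep(ann$gene_id, times = nrow(b$samples)),
      region = b$region,
      sample = rep(b$samples$sample, each = nrow(ann)),
      condition = rep(b$samples$condition, each = nrow(ann)),
      assay = b$assay,
      count = as.vector(b$counts),
      effective_length = rep(b$efflen, times = nrow(b$samples)),
      cpm = as.vector(nz$cpm),
      rpkm = as.vector(nz$rpkm),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("expression_table", "data.frame")
  out
}

## rpkm (or another value column) as transcripts x samples matrix.
#' @noRd
.expr_matrix <- function(expr, assay, region, value = "rpkm") {
  sub <- expr[expr$assay == assay & expr$region == region, ]
  if (nrow(sub) == 0L) {
    stop("expression table has no rows for assay '", assay,
         "', region '", region, "'")
  }
  samples <- unique(sub$sample)
  txs <- unique(sub$transcript_id)
  m <- matrix(NA_real_, length(txs), length(samples),
              dimnames = list(txs, samples))
  m[cbind(match(sub$transcript_id, txs), match(sub$sample, samples))] <-
    sub[[value]]
  m
}

#' Expression filter for robustly measured transcripts
#'
#' Keeps a transcript when its RNA-seq RPKM and its RF RPKM are both
#' `>= threshold` in at least `min_samples` samples (each assay judged on
#' its own samples). Defaults reproduce the robust-expression rule of
#' RPKM >= 10 in >= 2 samples.
#'
#' @param expr An `expression_table` from [quantify_expression()].
#' @param threshold RPKM threshold (default 10).
#' @param min_samples Minimum number of samples at or above threshold per
#'   assay (default 2).
#' @param rna_region,rf_region Regions whose RPKM is tested (defaults:
#'   exonic RNA, CDS RF).
#' @return Character vector of retained transcript ids (possibly empty).
#' @export
filter_expressed <- function(expr, threshold = 10, min_samples = 2L,
                             rna_region = "exonic", rf_region = "cds") {
  rna <- .expr_matrix(expr, "rna", rna_region)
  rf <- .expr_matrix(expr, "rf", rf_region)
  ok_rna <- rowSums(rna >= threshold, na.rm = TRUE) >= min_samples
  ok_rf <- rowSums(rf >= threshold, na.rm = TRUE) >= min_samples
  txs <- intersect(names(ok_rna)[ok_rna], names(ok_rf)[ok_rf])
  txs[order(match(txs, rownames(rna)))]
}

#' Translation efficiency
#'
#' `TE = RF RPKM / RNA RPKM`, per sample. Undefined (returned as `NA`, not
#' zero) where the RNA RPKM is 0.
#'
#' @param rf_rpkm,rna_rpkm Numeric vectors or matrices of matching shape.
#' @return TE values with the same shape.
#' @export
compute_te <- function(rf_rpkm, rna_rpkm) {
  te <- rf_rpkm / rna_rpkm
  te[rna_rpkm == 0] <- NA_real_
  te
}

#' Condition-level TE from replicate TEs
#'
#' Geometric mean across replicates, respecting the log scale on which TE
#' is analysed downstream. `NA` replicates are dropped; all-`NA` or
#' non-positive input gives `NA`.
#'
#' @param te Numeric vector of replicate TE values, or a matrix
#'   (transcripts x replicates).
#' @return Scalar (or per-row vector) geometric-mean TE.
#' @export
condition_te <- function(te) {
  if (is.matrix(te)) return(apply(te, 1L, .geomean))
  .geomean(te)
}
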