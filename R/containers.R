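## Core containers: transcript_set (sequences + region annotation) and
## coverage_set (per-sample nucleotide depth vectors for one assay).

#' Build a transcript set
#'
#' Couples transcript sequences with a region annotation in transcript
#' coordinates. All intervals are 0-based, half-open, and the three regions
#' must tile the transcript contiguously: `[utr5_start, utr5_end)`,
#' `[cds_start, cds_end)`, `[utr3_start, utr3_end)` with
#' `utr5_end == cds_start`, `cds_end == utr3_start`, CDS length a multiple
#' of 3, and `utr3_end` equal to the sequence length.
#'
#' @param annotation `data.frame` with columns `transcript_id`, `gene_id`,
#'   `length`, `utr5_start`, `utr5_end`, `cds_start`, `cds_end`,
#'   `utr3_start`, `utr3_end`.
#' @param sequences Named character vector or `Biostrings::DNAStringSet`,
#'   names matching `annotation$transcript_id`.
#' @param truth Optional ground-truth `data.frame` (synthetic data only).
#' @return Object of class `transcript_set` with elements `annotation`,
#'   `sequences` (a `DNAStringSet`), and optionally `truth`.
#' @export
transcript_set <- function(annotation, sequences, truth = NULL) {
  req <- c("transcript_id", "gene_id", "length", "utr5_start", "utr5_end",
           "cds_start", "cds_end", "utr3_start", "utr3_end")
  missing_cols <- setdiff(req, names(annotation))
  if (length(missing_cols) > 0L) {
    stop("annotation lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.character(sequences)) {
    sequences <- Biostrings::DNAStringSet(vapply(sequences, .norm_seq,
                                                 character(1)))
  }
  if (length(sequences) > 0L &&
      (is.null(names(sequences)) ||
       !all(annotation$transcript_id %in% names(sequences)))) {
    stop("sequences must be named by transcript_id")
  }
  sequences <- sequences[annotation$transcript_id]
  with(annotation, {
    if (any(utr5_start != 0L) || any(utr5_end != cds_start) ||
        any(cds_end != utr3_start) || any(utr3_end != length)) {
      stop("regions must tile the transcript: utr5 | cds | utr3")
    }
    if (any((cds_end - cds_start) %% 3L != 0L)) {
      stop("CDS lengths must be multiples of 3")
    }
  })
  if (!all(Biostrings::width(sequences) == annotation$length)) {
    stop("sequence widths disagree with annotation lengths")
  }
  structure(list(annotation = annotation, sequences = sequences,
                 truth = truth),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", nrow(x$annotation), "transcripts",
      if (!is.null(x$truth)) "(with ground truth)" else "", "\n")
  invisible(x)
}

#' Build a coverage set
#'
#' Per-sample nucleotide depth vectors for one assay (ribosome footprints
#' or RNA-seq) over a transcript set.
#'
#' @param depth Named list; one element per transcript, an integer or
#'   numeric matrix of dimension transcript length x number of samples.
#' @param samples `data.frame` with columns `sample` and `condition`
#'   (rows in matrix column order).
#' @param assay `"rf"` or `"rna"`.
#' @return Object of class `coverage_set`.
#' @export
coverage_set <- function(depth, samples, assay = c("rf", "rna")) {
  assay <- match.arg(assay)
  stopifnot(is.list(depth), !is.null(names(depth)),
            all(c("sample", "condition") %in% names(samples)))
  ncol_ok <- vapply(depth, function(m) ncol(m) == nrow(samples), logical(1))
  if (!all(ncol_ok)) stop("each depth matrix needs one column per sample")
  structure(list(depth = depth, samples = samples, assay = assay),
            class = "coverage_set")
}

#' @export
print.coverage_set <- function(x, ...) {
  cat("coverage_set [", x$assay, "]: ", length(x$depth), " transcripts x ",
      nrow(x$samples), " samples\n", sep = "")
  invisible(x)
}
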