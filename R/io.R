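## Plain-text readers and writers: annotation TSV, 4-column bedGraph
## coverage in transcript coordinates, count tables, gene-set TSVs.

#' Read a transcript annotation table
#'
#' @param path TSV with the columns documented in [transcript_set()]
#'   (0-based half-open transcript coordinates).
#' @return `data.frame`.
#' @export
read_annotation <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("transcript_id", "gene_id", "length", "utr5_start", "utr5_end",
           "cds_start", "cds_end", "utr3_start", "utr3_end")
  missing_cols <- setdiff(req, names(ann))
  if (length(missing_cols) > 0L) {
    stop("annotation file ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  ann
}

#' @rdname read_annotation
#' @param annotation Annotation `data.frame` to write.
#' @export
write_annotation <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write one sample's coverage as a bedGraph file
#'
#' Transcript-coordinate bedGraph: `transcript_id`, `start`, `end`, `depth`
#' (0-based half-open). Zero-depth runs are omitted, so the line count
#' equals the number of nonzero-depth runs.
#'
#' @param depth Named list of per-transcript depth vectors (or a
#'   single-sample column pulled from a [coverage_set()]).
#' @param path Output file.
#' @export
write_bedgraph <- function(depth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph", con)
  for (tx in names(depth)) {
    v <- as.numeric(depth[[tx]])
    if (length(v) == 0L) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths       # 0-based starts
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(paste(tx, starts[keep], ends[keep], r$values[keep],
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a bedGraph coverage file back into depth vectors
#'
#' @param path bedGraph file written by [write_bedgraph()] (or compatible).
#' @param annotation Annotation `data.frame`; transcripts absent from the
#'   file get all-zero vectors.
#' @return Named list of numeric depth vectors.
#' @export
read_bedgraph <- function(path, annotation) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines) & nzchar(lines)]
  depth <- lapply(setNames(annotation$length, annotation$transcript_id),
                  numeric)
  if (length(lines) > 0L) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (p in parts) {
      tx <- p[[1L]]
      if (is.null(depth[[tx]])) next
      from <- as.integer(p[[2L]])
      to <- as.integer(p[[3L]])
      depth[[tx]][.iv_idx(from, to)] <- as.numeric(p[[4L]])
    }
  }
  depth
}

#' Read a directory of bedGraph files into a coverage set
#'
#' Expects files named `<assay>_<sample>.bedgraph` as written by
#' [write_fixtures()].
#'
#' @param dir Directory containing the files.
#' @param annotation Annotation `data.frame`.
#' @param design `data.frame` with columns `sample`, `condition`.
#' @param assay `"rf"` or `"rna"`.
#' @return A [coverage_set()].
#' @export
read_coverage_set <- function(dir, annotation, design, assay = c("rf", "rna")) {
  assay <- match.arg(assay)
  per_sample <- lapply(design$sample, function(s) {
    path <- file.path(dir, paste0(assay, "_", s, ".bedgraph"))
    if (!file.exists(path)) stop("missing coverage file: ", path)
    read_bedgraph(path, annotation)
  })
  depth <- lapply(setNames(annotation$transcript_id, annotation$transcript_id),
                  function(tx) {
                    do.call(cbind, lapply(per_sample, function(d) d[[tx]]))
                  })
  coverage_set(depth, design, assay)
}

#' Read a precomputed region count table
#'
#' Long-format TSV with columns `transcript_id`, `region`, `sample`,
#' `assay`, `count`, `effective_length`, as accepted by
#' [normalize_counts()]-based quantification.
#'
#' @param path TSV path.
#' @return `data.frame`.
#' @export
read_counts_table <- function(path) {
  cnt <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("transcript_id", "region", "sample", "assay", "count",
           "effective_length")
  missing_cols <- setdiff(req, names(cnt))
  if (length(missing_cols) > 0L) {
    stop("count table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  cnt
}

#' Read gene sets from a 2- or 3-column TSV
#'
#' @param path TSV with columns `set_name`, `gene_id`, and optionally
#'   `confidence`.
#' @return `data.frame` with those columns (confidence `NA` when absent).
#' @export
read_gene_sets <- function(path) {
  gs <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("set_name", "gene_id") %in% names(gs))) {
    stop("gene-set file needs set_name and gene_id columns")
  }
  if (is.null(gs$confidence)) gs$confidence <- NA_real_
  gs
}
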