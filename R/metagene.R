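## Metagene profiles: average footprint density at nucleotide resolution,
## anchored at the start or stop codon.

#' Metagene profile anchored at the start or stop codon
#'
#' For every retained transcript, depth is pooled across samples and
#' normalised per transcript to counts-per-million of that transcript's
#' reads, so each transcript contributes with equal weight regardless of
#' expression level. Offset 0 is the first nucleotide of the anchor codon
#' (for `anchor = "stop"`, the first nt of the stop codon, i.e. the last
#' in-frame codon of the CDS interval). At each offset the profile reports
#' the mean normalised depth over the transcripts whose extent covers that
#' offset, together with how many contributed.
#'
#' Transcripts with CDS shorter than `min_cds_length` are excluded; the
#' default of 2000 nt restricts the profile to long CDS where the window
#' around the anchor is unambiguous.
#'
#' @param coverages A [coverage_set()] (typically the RF assay).
#' @param transcripts A [transcript_set()] (or bare annotation
#'   `data.frame`).
#' @param anchor `"start"` or `"stop"`.
#' @param window Integer length-2 vector of offsets relative to the anchor,
#'   default `c(-50, 200)` for start and `c(-200, 50)` for stop.
#' @param min_cds_length Minimum CDS length (nt); default 2000.
#' @return `data.frame` of class `metagene_profile` with columns `anchor`,
#'   `offset`, `mean_cpm`, `n`.
#' @export
metagene_profile <- function(coverages, transcripts,
                             anchor = c("start", "stop"), window = NULL,
                             min_cds_length = 2000L) {
  anchor <- match.arg(anchor)
  ann <- if (inherits(transcripts, "transcript_set")) {
    transcripts$annotation
  } else {
    transcripts
  }
  if (is.null(window)) {
    window <- if (anchor == "start") c(-50L, 200L) else c(-200L, 50L)
  }
  keep <- (ann$cds_end - ann$cds_start) >= min_cds_length
  if (!any(keep)) stop("no transcripts retained at min_cds_length = ",
                       min_cds_length)
  ann <- ann[keep, , drop = FALSE]
  offsets <- seq.int(window[1L], window[2L])
  acc <- numeric(length(offsets))
  nn <- integer(length(offsets))
  for (i in seq_len(nrow(ann))) {
    m <- coverages$depth[[ann$transcript_id[i]]]
    if (is.null(m)) stop("coverage missing transcript ",
                         ann$transcript_id[i])
    v <- if (is.matrix(m)) rowSums(m) else as.numeric(m)
    tot <- sum(v)
    if (tot == 0) next
    v <- v / tot * 1e6
    a <- if (anchor == "start") ann$cds_start[i] else ann$cds_end[i] - 3L
    pos <- a + offsets                       # 0-based
    inside <- pos >= 0L & pos < ann$length[i]
    acc[inside] <- acc[inside] + v[pos[inside] + 1L]
    nn[inside] <- nn[inside] + 1L
  }
  if (all(nn == 0L)) stop("no transcript contributed coverage to the window")
  out <- data.frame(anchor = anchor, offset = offsets,
                    mean_cpm = ifelse(nn > 0L, acc / pmax(nn, 1L), NA_real_),
                    n = nn, stringsAsFactors = FALSE)
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' Peak enrichment score of a metagene profile
#'
#' Ratio of the mean profile value inside a peak window to the mean inside
#' a disjoint background window; quantifies, e.g., the start-codon pause.
#'
#' @param profile A [metagene_profile()].
#' @param peak_window,background_window Length-2 offset ranges (inclusive);
#'   must be disjoint and non-empty within the profile.
#' @return Scalar enrichment ratio.
#' @export
peak_score <- function(profile, peak_window, background_window) {
  in_win <- function(w) {
    profile$offset >= w[1L] & profile$offset <= w[2L]
  }
  pk <- in_win(peak_window)
  bg <- in_win(background_window)
  if (!any(pk)) stop("peak window is empty within the profile")
  if (!any(bg)) stop("background window is empty within the profile")
  if (any(pk & bg)) stop("peak and background windows must be disjoint")
  bg_mean <- mean(profile$mean_cpm[bg], na.rm = TRUE)
  if (!is.finite(bg_mean) || bg_mean == 0) stop("zero background signal")
  mean(profile$mean_cpm[pk], na.rm = TRUE) / bg_mean
}
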