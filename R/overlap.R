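## Gene-set overlap testing: one-tailed Fisher enrichment against a
## measurable universe, multi-set scans with BH correction, and
## length/expression bias diagnostics.

#' One-tailed Fisher overlap test against a universe
#'
#' Tests whether a query gene set is enriched in a target set within a
#' fixed universe of measurable genes. Both sets are intersected with the
#' universe before testing (restricting to the measurable universe
#' prevents the statistical inflation that arises when target lists
#' contain unmeasurable genes). The odds ratio is the conditional maximum
#' likelihood estimate, with the one-sided 95% confidence bound
#' `[lower, Inf)` matching the usual enrichment reporting style.
#'
#' @param query,target Character vectors of gene ids.
#' @param universe Character vector of measurable gene ids.
#' @param alternative `"greater"` (enrichment, default), `"less"`, or
#'   `"two.sided"`.
#' @return List: `odds_ratio`, `p`, `conf_int`, `overlap`, `n_query`,
#'   `n_target`, `n_universe`, `table`. Empty query or target within the
#'   universe gives `p = 1` and an `NA` odds ratio.
#' @export
fisher_overlap <- function(query, target, universe,
                           alternative = "greater") {
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  target <- intersect(unique(target), universe)
  a <- length(intersect(query, target))
  tab <- matrix(c(a,
                  length(query) - a,
                  length(target) - a,
                  length(universe) - length(query) - length(target) + a),
                2L, 2L,
                dimnames = list(query = c("in", "out"),
                                target = c("in", "out")))
  if (length(query) == 0L || length(target) == 0L) {
    return(list(odds_ratio = NA_real_, p = 1, conf_int = c(NA_real_, Inf),
                overlap = a, n_query = length(query),
                n_target = length(target),
                n_universe = length(universe), table = tab))
  }
  ft <- fisher.test(tab, alternative = alternative)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value,
       conf_int = as.numeric(ft$conf.int), overlap = a,
       n_query = length(query), n_target = length(target),
       n_universe = length(universe), table = tab)
}

#' Overlap scan across many target sets (e.g. miRNA predictions)
#'
#' Filters target predictions to the measurable universe and to a minimum
#' confidence, tests each set's overlap with the query via
#' [fisher_overlap()], and corrects across sets with Benjamini-Hochberg.
#' By default only sets retaining at least one measurable target after
#' filtering enter the correction.
#'
#' @param predictions `data.frame` with columns `set_name`, `gene_id`, and
#'   optionally `confidence` (`NA` confidence passes any threshold).
#' @param query Character vector of regulated gene ids.
#' @param universe Character vector of measurable gene ids.
#' @param confidence_min Minimum confidence retained (default 80; a
#'   prediction at 79.9 is excluded, one at 80 kept).
#' @param fdr_method Passed to [stats::p.adjust()] (default `"BH"`).
#' @param min_targets Minimum measurable targets for a set to be tested.
#' @return `data.frame`: `set_name`, `n_query`, `n_target`, `overlap`,
#'   `odds_ratio`, `p`, `q`, sorted by `p`.
#' @export
mirna_scan <- function(predictions, query, universe, confidence_min = 80,
                       fdr_method = "BH", min_targets = 1L) {
  stopifnot(all(c("set_name", "gene_id") %in% names(predictions)))
  conf <- predictions$confidence %||% rep(NA_real_, nrow(predictions))
  keep <- (is.na(conf) | conf >= confidence_min) &
    predictions$gene_id %in% universe
  preds <- predictions[keep, , drop = FALSE]
  sets <- split(preds$gene_id, preds$set_name)
  sets <- sets[lengths(lapply(sets, unique)) >= min_targets]
  if (length(sets) == 0L) {
    return(data.frame(set_name = character(0), n_query = integer(0),
                      n_target = integer(0), overlap = integer(0),
                      odds_ratio = numeric(0), p = numeric(0),
                      q = numeric(0)))
  }
  rows <- lapply(names(sets), function(nm) {
    fo <- fisher_overlap(query, sets[[nm]], universe)
    data.frame(set_name = nm, n_query = fo$n_query,
               n_target = fo$n_target, overlap = fo$overlap,
               odds_ratio = fo$odds_ratio, p = fo$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, fdr_method)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Length and expression bias diagnostics for an overlap query
#'
#' Known target lists (FMRP targets in particular) are biased toward long,
#' highly expressed genes; a query sharing that bias can overlap them
#' spuriously. This compares the query against the background with
#' two-sample Kolmogorov-Smirnov tests on log10 CDS length and log10
#' expression.
#'
#' @param query Character vector of gene ids.
#' @param background Character vector of background gene ids (the
#'   measurable universe, possibly minus the query).
#' @param lengths Named numeric vector of per-gene CDS lengths (nt).
#' @param expression Named numeric vector of per-gene expression (RPKM).
#' @return `data.frame`: `covariate`, `ks_d`, `p`, `n_query`,
#'   `n_background`, `biased` (p < 0.05).
#' @export
bias_diagnostics <- function(query, background, lengths, expression) {
  covs <- list(log10_cds_length = lengths, log10_expression = expression)
  if (length(query) < 5L || length(background) < 5L) {
    warning("fewer than 5 genes in query or background")
  }
  rows <- lapply(names(covs), function(nm) {
    v <- covs[[nm]]
    q <- log10(v[intersect(query, names(v))])
    b <- log10(v[intersect(background, names(v))])
    q <- q[is.finite(q)]; b <- b[is.finite(b)]
    kt <- suppressWarnings(ks.test(q, b))
    data.frame(covariate = nm, ks_d = unname(kt$statistic), p = kt$p.value,
               n_query = length(q), n_background = length(b),
               biased = kt$p.value < 0.05, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Baseline variance explained within each gene set
#'
#' Runs [baseline_variance_explained()] (Gamma GLM of RF on RNA) inside
#' each gene set, reporting the per-set pseudo-R-squared and, for set
#' pairs, the difference — e.g. contrasting how predictable ribosomal
#' occupancy is from mRNA abundance for glial vs neuronal transcripts.
#'
#' @param gene_sets Named list of character vectors of gene ids.
#' @param rna,rf Named numeric vectors (names = gene ids) of positive
#'   expression values.
#' @return List with `per_set` (`data.frame`: `set`, `pseudo_r_squared`,
#'   `n`) and `delta` (named differences for consecutive set pairs, `NULL`
#'   for a single set).
#' @export
per_set_variance_explained <- function(gene_sets, rna, rf) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  rows <- lapply(names(gene_sets), function(nm) {
    ids <- intersect(gene_sets[[nm]], intersect(names(rna), names(rf)))
    if (length(ids) < 10L) {
      warning("gene set '", nm, "' has fewer than 10 measurable genes")
    }
    if (length(ids) < 3L) {
      return(data.frame(set = nm, pseudo_r_squared = NA_real_,
                        n = length(ids), stringsAsFactors = FALSE))
    }
    bv <- baseline_variance_explained(rna[ids], rf[ids])
    data.frame(set = nm, pseudo_r_squared = bv$pseudo_r_squared,
               n = bv$n, stringsAsFactors = FALSE)
  })
  per_set <- do.call(rbind, rows)
  delta <- NULL
  if (nrow(per_set) >= 2L) {
    r2 <- per_set$pseudo_r_squared
    delta <- setNames(diff(r2),
                      paste(per_set$set[-1L], "-",
                            per_set$set[-nrow(per_set)]))
  }
  list(per_set = per_set, delta = delta)
}
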