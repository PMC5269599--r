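## Relating TE change to sequence features: univariate scans, stepwise
## multivariate selection, quartile-bin ANOVA and direction chi-square.

.DEFAULT_CANDIDATES <- c("n_upstream_kozak", "norm_ss_utr5", "ss_cds",
                         "short_utr3", "utr5_gc", "norm_ss_utr3")

## Assemble the model frame: response + candidate predictors (+ product
## columns for interaction terms written "a:b"), listwise-complete.
## Interaction products are formed from mean-centered components so the
## product is not aliased with its main effects (an uncentered product of
## a low-variation and a count variable is nearly collinear with the
## count).
#' @noRd
.model_frame <- function(features, response, predictors) {
  df <- data.frame(.response = response)
  for (p in predictors) {
    if (grepl(":", p, fixed = TRUE)) {
      parts <- strsplit(p, ":", fixed = TRUE)[[1L]]
      missing_parts <- setdiff(parts, names(features))
      if (length(missing_parts) > 0L) {
        stop("feature table lacks columns: ",
             paste(missing_parts, collapse = ", "))
      }
      df[[p]] <- Reduce(`*`, lapply(features[parts], function(v) {
        v - mean(v, na.rm = TRUE)
      }))
    } else {
      if (!p %in% names(features)) stop("feature table lacks column: ", p)
      df[[p]] <- features[[p]]
    }
  }
  df[complete.cases(df), , drop = FALSE]
}

#' Univariate regressions of TE change on each predictor
#'
#' One ordinary-least-squares fit per predictor, reporting adjusted
#' R-squared and the overall F-test p-value, sorted by adjusted R-squared
#' descending. The response is typically the log2 TE fold change of the
#' TE-significant transcripts.
#'
#' @param features Feature `data.frame` (see [feature_table()]), rows
#'   aligned with `response`.
#' @param response Numeric response vector.
#' @param predictors Feature column names (interaction terms `"a:b"`
#'   allowed).
#' @return `data.frame`: `predictor`, `estimate`, `se`, `r_squared`,
#'   `adj_r_squared`, `p`, `n`; constant predictors are skipped with a
#'   warning.
#' @export
univariate_scan <- function(features, response,
                            predictors = .DEFAULT_CANDIDATES) {
  rows <- lapply(predictors, function(p) {
    df <- .model_frame(features, response, p)
    x <- df[[p]]
    if (nrow(df) < 3L || var(x) == 0) {
      warning("skipping constant predictor: ", p)
      return(NULL)
    }
    fit <- lm(.response ~ x, data = df)
    sm <- summary(fit)
    fstat <- sm$fstatistic
    data.frame(predictor = p,
               estimate = unname(coef(fit)[2L]),
               se = sm$coefficients[2L, 2L],
               r_squared = sm$r.squared,
               adj_r_squared = sm$adj.r.squared,
               p = unname(pf(fstat[1L], fstat[2L], fstat[3L],
                             lower.tail = FALSE)),
               n = nrow(df), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out <- out[order(-out$adj_r_squared), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @noRd
.ic_value <- function(fit, criterion, n) {
  switch(criterion,
         aic = AIC(fit),
         bic = BIC(fit),
         aicc = {
           k <- attr(logLik(fit), "df")
           AIC(fit) + 2 * k * (k + 1) / max(n - k - 1, 1)
         })
}

#' Bidirectional stepwise selection of a multivariate TE-change model
#'
#' Starting from the intercept-only model, repeatedly adds or removes the
#' single candidate term that most improves the information criterion,
#' stopping when no move improves it. The default candidate set contains
#' the decorrelated predictors plus the interaction between length-
#' normalised 5'UTR secondary structure and the number of upstream Kozak
#' matches. The default criterion is BIC: with several candidate terms the
#' small-sample AIC variants admit at least one noise predictor far too
#' often for a selection procedure meant to isolate real sequence effects
#' (both remain available).
#'
#' @param features,response As in [univariate_scan()].
#' @param candidates Candidate terms; interactions written `"a:b"`.
#' @param criterion `"bic"` (default), `"aic"` or `"aicc"`.
#' @return List of class `model_fit`: `selected` (character), `coefficients`
#'   (matrix from `summary.lm`), `r_squared`, `adj_r_squared`, `p` (overall
#'   F), `n`, `criterion`, and the final `fit`.
#' @export
stepwise_select <- function(features, response,
                            candidates = c(.DEFAULT_CANDIDATES,
                                           "norm_ss_utr5:n_upstream_kozak"),
                            criterion = c("bic", "aic", "aicc")) {
  criterion <- match.arg(criterion)
  df <- .model_frame(features, response, candidates)
  n <- nrow(df)
  if (n <= length(candidates)) {
    stop("need more complete rows than candidate terms")
  }
  ## drop constant candidates up front
  usable <- candidates[vapply(candidates,
                              function(p) var(df[[p]]) > 0, logical(1))]
  fit_terms <- function(terms) {
    if (length(terms) == 0L) return(lm(.response ~ 1, data = df))
    lm(stats::reformulate(sprintf("`%s`", terms), ".response"), data = df)
  }
  current <- character(0)
  current_fit <- fit_terms(current)
  current_ic <- .ic_value(current_fit, criterion, n)
  repeat {
    moves <- c(lapply(setdiff(usable, current),
                      function(p) union(current, p)),
               lapply(current, function(p) setdiff(current, p)))
    if (length(moves) == 0L) break
    ics <- vapply(moves, function(tm) {
      .ic_value(fit_terms(tm), criterion, n)
    }, numeric(1))
    best <- which.min(ics)
    if (ics[best] >= current_ic - 1e-8) break
    current <- moves[[best]]
    current_fit <- fit_terms(current)
    current_ic <- ics[best]
  }
  sm <- summary(current_fit)
  fstat <- sm$fstatistic
  structure(list(
    selected = current,
    coefficients = sm$coefficients,
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    p = if (is.null(fstat)) NA_real_ else
      unname(pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)),
    n = n, criterion = criterion, fit = current_fit),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("model_fit (", x$criterion, "): ",
      if (length(x$selected)) paste(x$selected, collapse = " + ")
      else "(intercept only)",
      "\n  adj R^2 = ", signif(x$adj_r_squared, 4),
      ", p = ", format(x$p, digits = 3), ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Pairwise correlations among candidate predictors
#'
#' Pearson correlations between all candidate predictor pairs on
#' listwise-complete rows, flagging strongly collinear pairs (such as
#' secondary structure vs region length, which track each other closely).
#'
#' @param features Feature `data.frame`.
#' @param predictors Columns to correlate (default: all numeric columns).
#' @param flag_threshold |r| above which a pair is flagged (default 0.9).
#' @return `data.frame`: `var1`, `var2`, `r`, `flagged`.
#' @export
collinearity_report <- function(features, predictors = NULL,
                                flag_threshold = 0.9) {
  if (is.null(predictors)) {
    predictors <- names(features)[vapply(features, is.numeric, logical(1))]
  }
  X <- features[predictors]
  X <- X[complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3L) stop("need >= 3 complete rows")
  cm <- cor(as.matrix(X))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  out <- data.frame(var1 = predictors[idx[, 1L]],
                    var2 = predictors[idx[, 2L]],
                    r = cm[idx], stringsAsFactors = FALSE)
  out$flagged <- abs(out$r) > flag_threshold
  out[order(-abs(out$r)), , drop = FALSE]
}

#' Quartile-bin ANOVA of TE change against a predictor
#'
#' Bins the predictor at its sample quartiles (values equal to a boundary
#' go to the lower bin) and runs a one-way ANOVA of the response across
#' the bins. Duplicate quartile boundaries (heavy ties) collapse the
#' affected bins with a warning.
#'
#' @param x Predictor values (>= 4 distinct values, n >= 8).
#' @param response Response values.
#' @return List: `f`, `p`, `bin_means`, `bin_counts`, `bins` (factor).
#' @export
quartile_anova <- function(x, response) {
  ok <- is.finite(x) & is.finite(response)
  x <- x[ok]; response <- response[ok]
  if (length(x) < 8L) stop("need n >= 8")
  if (length(unique(x)) < 4L) stop("predictor needs >= 4 distinct values")
  br <- quantile(x, probs = seq(0, 1, 0.25), names = FALSE)
  if (anyDuplicated(br)) {
    warning("tied quartile boundaries: bins merged")
    br <- unique(br)
  }
  bins <- cut(x, breaks = br, include.lowest = TRUE)
  bin_means <- tapply(response, bins, mean)
  bin_counts <- as.integer(table(bins))
  fit <- aov(response ~ bins)
  tab <- summary(fit)[[1L]]
  f <- tab[1L, "F value"]
  p <- tab[1L, "Pr(>F)"]
  if (tab[1L, "Sum Sq"] < 1e-12) { f <- 0; p <- 1 }
  list(f = unname(f), p = unname(p), bin_means = bin_means,
       bin_counts = bin_counts, bins = bins)
}

#' Chi-square test of TE direction against upstream-Kozak count
#'
#' Cross-tabulates the direction of TE change (up/down) against the
#' upstream-Kozak count binned as {0, 1, 2, >=3} and applies Pearson's
#' chi-square test. Bins with expected count below 1 are collapsed into
#' their neighbour with a warning.
#'
#' @param kozak_counts Integer vector of upstream Kozak matches.
#' @param direction Character/factor vector, `"up"` or `"down"`.
#' @param breaks Right-open bin lower bounds (default `c(0, 1, 2, 3)`,
#'   the last bin unbounded).
#' @return List: `statistic`, `p`, `df`, `table`.
#' @export
direction_chisq <- function(kozak_counts, direction,
                            breaks = c(0L, 1L, 2L, 3L)) {
  ok <- !is.na(kozak_counts) & !is.na(direction)
  kozak_counts <- kozak_counts[ok]
  direction <- as.character(direction[ok])
  stopifnot(all(direction %in% c("up", "down")))
  labs <- c(head(breaks, -1L), paste0(">=", breaks[length(breaks)]))
  labs[-length(labs)] <- as.character(head(breaks, -1L))
  bin <- cut(kozak_counts, breaks = c(breaks, Inf), right = FALSE,
             labels = labs)
  tab <- table(direction = factor(direction, c("up", "down")), bin = bin)
  tab <- tab[, colSums(tab) > 0L, drop = FALSE]
  if (ncol(tab) < 2L) stop("fewer than 2 populated Kozak bins")
  repeat {
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(expd >= 1) || ncol(tab) <= 2L) break
    j <- which.min(apply(expd, 2L, min))
    nb <- if (j == ncol(tab)) j - 1L else j + 1L
    warning("collapsing sparse Kozak bin '", colnames(tab)[j], "'")
    tab[, nb] <- tab[, nb] + tab[, j]
    tab <- tab[, -j, drop = FALSE]
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = ct$p.value,
       df = unname(ct$parameter), table = tab)
}
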