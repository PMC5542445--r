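## Study statistics: mean +/- SEM summaries, unpaired two-tailed
## Mann-Whitney tests (exact for small tie-free groups), and Pearson
## correlation with the conventional strength categories.

#' Pearson correlation with a strength category
#'
#' @slot r product-moment correlation coefficient.
#' @slot p two-sided p-value (t-transform, n - 2 df).
#' @slot n number of pairs.
#' @slot category strength label from [classifyCorrelation()].
#' @export
setClass("CorrelationResult", representation(
  r = "numeric", p = "numeric", n = "integer", category = "character"
))

setValidity("CorrelationResult", function(object) {
  if (abs(object@r) > 1 + 1e-12) return("r must lie in [-1, 1]")
  TRUE
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("Pearson r = %.3f (%s), p = %.4g, n = %d\n",
              object@r, object@category, object@p, object@n))
})

#' Mean and standard error of the mean
#'
#' @param values numeric vector, NA dropped; at least 2 non-missing
#'   values required.
#' @return Named numeric `c(mean, sem)` with `sem = sd / sqrt(n)`.
#' @export
#' @examples
#' meanSEM(c(2, 4, 6))  # mean 4, sem 2/sqrt(3)
meanSEM <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("meanSEM needs at least 2 values")
  c(mean = mean(values), sem = stats::sd(values) / sqrt(n))
}

#' Unpaired two-tailed Mann-Whitney test
#'
#' Exact U-distribution enumeration when the smaller group has at most
#' `exactMax` observations and there are no ties; otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param a,b numeric vectors (both nonempty).
#' @param exactMax largest min-group size for which the exact branch is
#'   used (default 8; the study's groups of 5 fall well inside it).
#' @return List with `U` (the statistic for `a`), `p` (two-tailed) and
#'   `exact` (logical branch indicator).
#' @export
#' @examples
#' mannWhitney(1:5, 6:10)$p  # complete separation: 2/252
mannWhitney <- function(a, b, exactMax = 8L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0L
  useExact <- !ties && min(length(a), length(b)) <= exactMax
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = useExact,
                                            correct = TRUE,
                                            alternative = "two.sided"))
  list(U = unname(wt$statistic), p = min(wt$p.value, 1), exact = useExact)
}

#' Classify a correlation coefficient by strength
#'
#' Conventional bands on `|r|`: strong above 0.8, substantial (0.6, 0.8],
#' moderate (0.4, 0.6], fair (0.2, 0.4], almost non-existent at or below
#' 0.2.  The bands are half-open with the boundary assigned to the lower
#' band (so `|r| = 0.4` is "fair"), matching how boundary values are used
#' in practice.
#'
#' @param r correlation coefficient, `|r| <= 1`.
#' @return One of `"strong"`, `"substantial"`, `"moderate"`, `"fair"`,
#'   `"almost non-existent"`.
#' @export
#' @examples
#' classifyCorrelation(0.85)   # strong
#' classifyCorrelation(-0.3)   # fair
classifyCorrelation <- function(r) {
  if (abs(r) > 1 + 1e-12) stop("|r| must not exceed 1")
  a <- abs(r)
  if (a > 0.8) "strong"
  else if (a > 0.6) "substantial"
  else if (a > 0.4) "moderate"
  else if (a > 0.2) "fair"
  else "almost non-existent"
}

#' Pearson correlation with p-value and strength category
#'
#' @param x,y paired numeric vectors; pairs with any NA are dropped;
#'   at least 3 complete pairs and nonzero variance in both variables
#'   are required.
#' @return A [CorrelationResult].
#' @export
#' @examples
#' pearsonCorrelation(1:10, 2 * (1:10) + 1)  # r = 1, strong
pearsonCorrelation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  new("CorrelationResult", r = r, p = ct$p.value, n = length(x),
      category = classifyCorrelation(r))
}

#' Per-week group trajectory with tests against the preceding time point
#'
#' Summarizes one measure per group and week as mean +/- SEM and applies
#' an unpaired two-tailed Mann-Whitney test between each week and the
#' preceding week of the same group (significance flagged at p < 0.05).
#'
#' @param table data.frame with columns `group`, `week` and the measure;
#'   one row per animal per time point.
#' @param measure column name of the measure to summarize.
#' @return data.frame with columns `group`, `week`, `n`, `mean`, `sem`,
#'   `p_vs_prev`, `significant`.
#' @export
groupTrajectory <- function(table, measure) {
  if (!measure %in% names(table))
    stop(sprintf("measure '%s' not found in table", measure))
  if (length(unique(table$week)) < 2L)
    stop("need at least 2 time points")
  out <- do.call(rbind, lapply(split(table, table$group), function(g) {
    wk <- sort(unique(g$week))
    prev <- NULL
    rows <- lapply(wk, function(w) {
      v <- g[[measure]][g$week == w]
      v <- v[!is.na(v)]
      ms <- if (length(v) >= 2) meanSEM(v) else c(mean = mean(v), sem = NA_real_)
      p <- if (!is.null(prev) && length(v) && length(prev))
        mannWhitney(prev, v)$p else NA_real_
      prev <<- v
      data.frame(group = g$group[1], week = w, n = length(v),
                 mean = ms[["mean"]], sem = ms[["sem"]], p_vs_prev = p)
    })
    do.call(rbind, rows)
  }))
  rownames(out) <- NULL
  out$significant <- !is.na(out$p_vs_prev) & out$p_vs_prev < 0.05
  out
}
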