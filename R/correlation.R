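#' Pairwise correlation matrix with p-values and effective n
#'
#' Pairwise-complete Pearson (or Spearman) correlations over the columns of
#' a samples-by-metabolites matrix. Two-sided p-values come from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` against the t distribution with
#' `n - 2` degrees of freedom, using each pair's own complete-observation
#' count (the same large-sample approximation is applied to Spearman rho).
#' Pairs with fewer than `min_n` complete observations, and pairs involving
#' a constant column, are missing with a notice.
#'
#' @param values Samples-by-metabolites numeric matrix.
#' @param method `"pearson"` or `"spearman"`.
#' @param min_n Minimum complete observations per pair, default 3.
#' @return Object of class `cor_matrix`: list with `r`, `p`, `n` matrices
#'   and `method`.
#' @export
correlation_matrix <- function(values, method = c("pearson", "spearman"),
                               min_n = 3) {
  method <- match.arg(method)
  values <- as.matrix(values)
  r <- suppressWarnings(stats::cor(values, use = "pairwise.complete.obs",
                                   method = method))
  n <- crossprod(!is.na(values))
  low <- n < min_n
  if (any(low[upper.tri(low)])) {
    message(sum(low[upper.tri(low)]),
            " pair(s) with fewer than ", min_n,
            " complete observations set missing")
  }
  r[low] <- NA_real_
  degenerate <- is.na(r) & !low
  if (any(degenerate[upper.tri(degenerate)])) {
    message("correlation undefined (constant column) for ",
            sum(degenerate[upper.tri(degenerate)]), " pair(s)")
  }
  rr <- pmin(pmax(r, -1), 1)
  tt <- rr * sqrt(pmax(n - 2, 0)) / sqrt(pmax(1 - rr^2, 0))
  p <- 2 * stats::pt(-abs(tt), df = pmax(n - 2, 1))
  p[abs(rr) >= 1] <- 0
  p[is.na(r)] <- NA_real_
  diag(r) <- 1
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n, method = method), class = "cor_matrix")
}

#' Count metabolite pairs above absolute-correlation cutoffs
#'
#' Number of unordered off-diagonal pairs with `|r|` strictly greater than
#' each cutoff (the census style `|r| > 0.75 / 0.85 / 0.93`).
#'
#' @param c A `cor_matrix` (or a plain correlation matrix).
#' @param thresholds Numeric cutoffs in (0, 1).
#' @return Named integer vector of counts.
#' @export
threshold_counts <- function(c, thresholds = c(0.75, 0.85, 0.93)) {
  r <- if (inherits(c, "cor_matrix")) c$r else as.matrix(c)
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie in (0, 1)")
  }
  up <- abs(r[upper.tri(r)])
  stats::setNames(vapply(thresholds, function(th) sum(up > th, na.rm = TRUE),
                         integer(1)),
                  paste0("|r|>", format(thresholds)))
}

#' Hierarchical clustering of correlation profiles
#'
#' Agglomerative clustering of the metabolites using the city-block (L1)
#' distance between their rows of correlation coefficients and average
#' (UPGMA) linkage. Rows containing missing correlations are dropped with
#' a notice.
#'
#' @param c A `cor_matrix` (or a plain correlation matrix).
#' @return List with `order` (leaf labels in dendrogram order), `merge`,
#'   `height`, and the underlying `hclust` object.
#' @export
hca_order <- function(c) {
  r <- if (inherits(c, "cor_matrix")) c$r else as.matrix(c)
  diag(r) <- 1
  ok <- !apply(r, 1, anyNA)
  if (any(!ok)) {
    message("dropped from clustering (missing correlations): ",
            paste(rownames(r)[!ok], collapse = ", "))
  }
  r <- r[ok, ok, drop = FALSE]
  if (nrow(r) < 2) stop("need at least 2 complete rows to cluster")
  h <- stats::hclust(stats::dist(r, method = "manhattan"), method = "average")
  list(order = h$labels[h$order], merge = h$merge, height = h$height,
       hclust = h)
}
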