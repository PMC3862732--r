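feature_coords <- function(m) {
  co <- attr(m, "coords")
  if (is.null(co)) co <- suppressWarnings(as.numeric(colnames(m)))
  if (length(co) != ncol(m) || anyNA(co)) {
    stop("feature coordinates unavailable: supply a `coords` attribute or numeric column names")
  }
  if (is.unsorted(co, strictly = TRUE)) {
    stop("feature coordinates must be strictly increasing")
  }
  co
}

#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution: each sample is divided by the median of
#' its feature-wise quotients against a reference profile (the median
#' spectrum by default). Leaves a matrix of identical rows unchanged.
#'
#' @param m Samples-by-features intensity matrix, values >= 0.
#' @param reference `"median_sample"` (feature-wise median over samples), a
#'   row index, or a numeric reference profile of length `ncol(m)`.
#' @return List with `matrix` (normalized) and `factors` (per-sample
#'   dilution factors that were divided out).
#' @export
pqn_normalize <- function(m, reference = "median_sample") {
  m <- as.matrix(m)
  if (any(m < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  ref <- if (is.character(reference) && reference == "median_sample") {
    apply(m, 2, stats::median, na.rm = TRUE)
  } else if (length(reference) == 1 && is.numeric(reference)) {
    m[reference, ]
  } else if (is.numeric(reference) && length(reference) == ncol(m)) {
    as.numeric(reference)
  } else {
    stop("invalid `reference`")
  }
  used <- !is.na(ref) & ref != 0
  if (!any(used)) stop("reference has no usable (nonzero) features")
  q <- sweep(m[, used, drop = FALSE], 2, ref[used], "/")
  factors <- apply(q, 1, stats::median, na.rm = TRUE)
  if (anyNA(factors) || any(factors == 0)) {
    stop("sample(s) with no usable signal: dilution factor undefined")
  }
  list(matrix = m / factors, factors = factors)
}

#' Bin features into fixed-width windows along the coordinate axis
#'
#' Features falling inside any exclusion interval (solvent/reference
#' regions) are dropped first; the rest are partitioned into contiguous
#' half-open bins `[a, a + width)` anchored at the minimum kept coordinate,
#' and summed within each bin (conserving integrated intensity). Non-empty
#' bins are returned, named and coordinated by their left edge.
#'
#' @param m Samples-by-features matrix with coordinates (a `coords`
#'   attribute or numeric column names).
#' @param width Bin width in coordinate units (> 0), e.g. 0.005 ppm.
#' @param exclusions List of length-2 numeric vectors `c(lo, hi)`; features
#'   with `lo <= coord <= hi` are removed.
#' @return Binned matrix with a `coords` attribute (bin left edges).
#' @export
bin_features <- function(m, width, exclusions = list()) {
  m <- as.matrix(m)
  if (width <= 0) stop("`width` must be > 0")
  co <- feature_coords(m)
  keep <- rep(TRUE, length(co))
  for (ex in exclusions) {
    if (length(ex) != 2 || ex[1] > ex[2]) stop("exclusions must be c(lo, hi)")
    keep <- keep & !(co >= ex[1] & co <= ex[2])
  }
  m <- m[, keep, drop = FALSE]
  co <- co[keep]
  if (!length(co)) {
    out <- m[, 0, drop = FALSE]
    attr(out, "coords") <- numeric(0)
    return(out)
  }
  idx <- floor((co - min(co)) / width)
  bins <- sort(unique(idx))
  out <- vapply(bins, function(b) {
    rowSums(m[, idx == b, drop = FALSE], na.rm = FALSE)
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), format(min(co) + bins * width)))
  attr(out, "coords") <- min(co) + bins * width
  out
}

#' Generalized log transform
#'
#' Elementwise `g(y) = ln((y + sqrt(y^2 + lambda^2)) / 2)`, the
#' variance-stabilizing transform for intensity data; strictly increasing
#' in `y`, and equal to `ln(y)` when `lambda = 0`.
#'
#' @param m Matrix of intensities >= 0.
#' @param lambda Transform parameter >= 0; with `lambda = 0` any zero
#'   intensity is an error (would map to -Inf). See [glog_lambda()] for the
#'   default selection rule.
#' @return Transformed matrix.
#' @export
glog_transform <- function(m, lambda) {
  m <- as.matrix(m)
  if (lambda < 0) stop("`lambda` must be >= 0")
  if (any(m < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  if (lambda == 0 && any(m == 0, na.rm = TRUE)) {
    stop("lambda = 0 with zero intensities maps to -Inf; use lambda > 0")
  }
  out <- log((m + sqrt(m^2 + lambda^2)) / 2)
  attributes(out) <- attributes(m)
  out
}

#' Default glog lambda: 5th percentile of the nonzero intensities
#' @param m Intensity matrix.
#' @return A scalar lambda.
#' @export
glog_lambda <- function(m) {
  v <- m[!is.na(m) & m > 0]
  if (!length(v)) stop("no nonzero intensities to choose lambda from")
  unname(stats::quantile(v, 0.05))
}
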