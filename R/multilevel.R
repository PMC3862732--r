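#' Multilevel (within/between-subject) decomposition of a paired matrix
#'
#' Splits a samples-by-features matrix into the between-subject part (one
#' row of subject means per subject) and the within-subject part (each
#' sample minus its subject mean). The two parts reconstruct the input
#' exactly, and a subject's within rows sum to zero.
#'
#' @param x Samples-by-features numeric matrix.
#' @param subject Subject identifier per row; every subject must have the
#'   same number (>= 2) of samples.
#' @return List with `between` (subjects x features), `within`
#'   (samples x features) and `subject`.
#' @export
multilevel_split <- function(x, subject) {
  x <- as.matrix(x)
  subject <- as.character(subject)
  if (length(subject) != nrow(x)) stop("`subject` length must match rows of `x`")
  counts <- table(subject)
  if (any(counts < 2)) {
    stop("subject(s) with a single sample: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  if (length(unique(counts)) != 1) {
    stop("every subject must have the same number of samples")
  }
  between <- rowsum(x, subject) / as.vector(counts[sort(unique(subject))])
  within <- x - between[subject, , drop = FALSE]
  list(between = between, within = within, subject = subject)
}

#' Multilevel principal component analysis
#'
#' PCA of the column-centered within-subject matrix via the singular value
#' decomposition; between-subject variation is removed first, so the model
#' captures the paired (e.g. marrow-vs-blood) contrast. Variance fractions
#' are percentages of the within-matrix variance.
#'
#' @param x Samples-by-features matrix.
#' @param subject Subject identifier per row (see [multilevel_split()]).
#' @param k Number of components (truncated at the matrix rank, with a
#'   notice, if larger).
#' @param scale Divide columns by their standard deviation first
#'   (default `FALSE`, the spectra convention).
#' @return Object of class `mpca`: `scores`, `loadings` (orthonormal
#'   columns), `variance_fraction` (percent, all components), `center`,
#'   `k`.
#' @export
mpca <- function(x, subject, k = 2, scale = FALSE) {
  sp <- multilevel_split(x, subject)
  w <- scale(sp$within, center = TRUE, scale = scale)
  s <- svd(w)
  tol <- max(dim(w)) * .Machine$double.eps * s$d[1]
  rank <- sum(s$d > tol)
  if (k > rank) {
    message("k = ", k, " exceeds the within-matrix rank ", rank,
            "; truncating")
    k <- rank
  }
  if (k < 1) stop("within matrix has rank 0")
  varfrac <- 100 * s$d[seq_len(rank)]^2 / sum(s$d[seq_len(rank)]^2)
  structure(list(
    scores = s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k),
    loadings = s$v[, seq_len(k), drop = FALSE],
    variance_fraction = varfrac,
    center = attr(w, "scaled:center"),
    subject = sp$subject, k = k), class = "mpca")
}

#' @export
print.mpca <- function(x, ...) {
  cat(sprintf("Multilevel PCA: %d component(s); variance captured: %s\n",
              x$k, paste(sprintf("%.2f%%", x$variance_fraction[seq_len(x$k)]),
                         collapse = ", ")))
  invisible(x)
}

# NIPALS PLS1 on an already-centered matrix against a +/-1 class code.
pls1_fit <- function(x, y, n_lv) {
  n <- nrow(x); pdim <- ncol(x)
  W <- matrix(0, pdim, n_lv); P <- matrix(0, pdim, n_lv)
  Tm <- matrix(0, n, n_lv); b <- numeric(n_lv)
  ss0 <- sum(x^2)
  xr <- x
  varfrac <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    wv <- crossprod(xr, y)
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12 * max(1, sqrt(ss0))) {
      stop("class code has (numerically) zero covariance with the data; ",
           "weight vector undefined at component ", a)
    }
    wv <- wv / nw
    tv <- xr %*% wv
    tt <- sum(tv^2)
    pv <- crossprod(xr, tv) / tt
    b[a] <- sum(y * tv) / tt
    xr <- xr - tv %*% t(pv)
    W[, a] <- wv; P[, a] <- pv; Tm[, a] <- tv
    varfrac[a] <- 100 * tt * sum(pv^2) / ss0
  }
  B <- W %*% solve(crossprod(P, W), b)
  list(weights = W, loadings = P, scores = Tm, b = b, coef = B,
       variance_fraction = varfrac)
}

#' Multilevel PLS discriminant analysis for paired two-class data
#'
#' Fits a PLS model (NIPALS with sequential deflation) on the
#' within-subject matrix against a +/-1 class code, reports per-latent-
#' variable captured variance, and evaluates predictions by
#' leave-one-subject-out cross-validation (both of a subject's samples held
#' out together; the held-out pair is centered on its own mean, which
#' requires no labels). Sensitivity and specificity come from the
#' Youden-optimal threshold on the cross-validated scores via [cv_roc()].
#'
#' @param x Samples-by-features matrix.
#' @param subject Subject identifier per row; each subject must carry
#'   exactly one sample of each class.
#' @param class Two-level class labels; the second sorted level is coded
#'   +1.
#' @param n_lv Number of latent variables, default 2.
#' @param cv Run leave-one-subject-out cross-validation (default `TRUE`).
#' @return Object of class `mplsda`: model matrices, `variance_fraction`,
#'   `cv_predictions` (data frame with per-sample cross-validated scores
#'   `yhat`), `sensitivity`, `specificity` (percent), `levels`.
#' @export
mplsda <- function(x, subject, class, n_lv = 2, cv = TRUE) {
  x <- as.matrix(x)
  cls <- factor(class)
  if (nlevels(cls) != 2) stop("exactly two classes are required")
  subject <- as.character(subject)
  tab <- table(subject, cls)
  if (any(tab != 1)) {
    stop("each subject must have exactly one sample per class (paired design)")
  }
  y <- ifelse(cls == levels(cls)[2], 1, -1)
  sp <- multilevel_split(x, subject)
  center <- colMeans(sp$within)
  xw <- sweep(sp$within, 2, center)
  fit <- pls1_fit(xw, y, n_lv)

  cvp <- NULL; sens <- NA_real_; spec <- NA_real_
  if (cv) {
    yhat <- numeric(nrow(x))
    for (s in unique(subject)) {
      test <- subject == s
      spt <- multilevel_split(x[!test, , drop = FALSE], subject[!test])
      ctr <- colMeans(spt$within)
      ft <- pls1_fit(sweep(spt$within, 2, ctr), y[!test], n_lv)
      xh <- x[test, , drop = FALSE]
      xh <- sweep(xh, 2, colMeans(xh))     # the held-out pair's own mean
      xh <- sweep(xh, 2, ctr)
      yhat[test] <- as.numeric(xh %*% ft$coef)
    }
    cvp <- data.frame(subject = subject, class = cls, y = y, yhat = yhat,
                      stringsAsFactors = FALSE)
    roc <- cv_roc(cvp)
    sens <- roc$sensitivity; spec <- roc$specificity
  }
  structure(c(fit, list(levels = levels(cls), center = center,
                        subject = subject, class = cls, n_lv = n_lv,
                        cv_predictions = cvp,
                        sensitivity = sens, specificity = spec)),
            class = "mplsda")
}

#' @export
print.mplsda <- function(x, ...) {
  cat(sprintf("Multilevel PLS-DA: %d LV(s); variance captured: %s\n",
              x$n_lv, paste(sprintf("%.2f%%", x$variance_fraction),
                            collapse = ", ")))
  if (!is.null(x$cv_predictions)) {
    cat(sprintf("  LOSO CV sensitivity %.1f%%, specificity %.1f%%\n",
                x$sensitivity, x$specificity))
  }
  invisible(x)
}

#' Sensitivity and specificity of cross-validated scores
#'
#' Scans the Youden index `sensitivity + specificity - 1` over the
#' midpoints of the observed cross-validated scores. The orientation is
#' fixed by the class code (+1 = positive class must score higher); scores
#' ranked against the code are reported as the poor classifier they are,
#' not sign-flipped.
#'
#' @param result An `mplsda` fit with CV predictions, or the
#'   `cv_predictions` data frame itself (columns `y`, `yhat`).
#' @return List with `sensitivity`, `specificity` (percent) and
#'   `threshold`.
#' @export
cv_roc <- function(result) {
  cvp <- if (inherits(result, "mplsda")) result$cv_predictions else result
  if (is.null(cvp)) stop("no cross-validated predictions available")
  y <- cvp$y; yhat <- cvp$yhat
  if (length(unique(y)) < 2) stop("cross-validated predictions cover a single class")
  su <- sort(unique(yhat))
  thr <- if (length(su) > 1) (su[-1] + su[-length(su)]) / 2 else su
  best <- NULL
  for (th in thr) {
    sens <- mean(yhat[y > 0] > th)
    spec <- mean(yhat[y < 0] <= th)
    if (is.null(best) || sens + spec > best$sens + best$spec) {
      best <- list(sens = sens, spec = spec, th = th)
    }
  }
  list(sensitivity = 100 * best$sens, specificity = 100 * best$spec,
       threshold = best$th)
}

cv_margin <- function(cvp) mean(cvp$y * cvp$yhat)

#' Permutation validation of a multilevel PLS-DA model
#'
#' The observed statistic is the mean cross-validated prediction margin
#' `mean(y * yhat)` under leave-one-subject-out CV. Null models are built
#' by swapping the class labels within a random subset of subjects
#' (respecting the pairing); masks are drawn uniformly over non-degenerate
#' subsets, because swapping no subject reproduces the observed model and
#' swapping all subjects merely inverts the +/-1 code and reproduces the
#' observed statistic exactly. The p-value is
#' `(1 + #permutations >= observed) / (n_perm + 1)`, never 0.
#'
#' @param x,subject,class As in [mplsda()].
#' @param n_perm Number of permutations (>= 19), default 99.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param n_lv Latent variables, default 2.
#' @return List with `p`, `observed`, `perm_stats`.
#' @export
permutation_validate <- function(x, subject, class, n_perm = 99, seed = NULL,
                                 n_lv = 2) {
  if (n_perm < 19) stop("`n_perm` must be >= 19")
  if (!is.null(seed)) set.seed(seed)
  subject <- as.character(subject)
  subs <- unique(subject)
  if (length(subs) < 3) stop("at least 3 subjects are required")
  obs_fit <- mplsda(x, subject, class, n_lv = n_lv)
  observed <- cv_margin(obs_fit$cv_predictions)
  cls <- factor(class)
  perm_stats <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    repeat {
      mask <- stats::runif(length(subs)) < 0.5
      if (any(mask) && !all(mask)) break
    }
    swap_sub <- subs[mask]
    cls_p <- cls
    sw <- subject %in% swap_sub
    cls_p[sw] <- factor(ifelse(cls[sw] == levels(cls)[1],
                               levels(cls)[2], levels(cls)[1]),
                        levels = levels(cls))
    ft <- mplsda(x, subject, cls_p, n_lv = n_lv)
    perm_stats[i] <- cv_margin(ft$cv_predictions)
  }
  list(p = (1 + sum(perm_stats >= observed)) / (n_perm + 1),
       observed = observed, perm_stats = perm_stats)
}
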