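#' Per-patient compartment differences at a fixed day
#'
#' For each patient with both a marrow (BM) and a blood (PB) sample at
#' `day`, computes `BM - PB` per metabolite (missing if either side is
#' missing), plus per-metabolite summaries: the mean difference and the
#' mean fold difference `mean(BM) / mean(PB)`.
#'
#' @param t A `conc_table`.
#' @param day Day (0, 8 or 29).
#' @return List with `differences` (patients x metabolites matrix),
#'   `bm`, `pb` (the paired compartment matrices) and `summary` (data
#'   frame: metabolite, mean_bm, mean_pb, mean_diff, fold).
#' @export
paired_differences <- function(t, day) {
  bm <- ct_matrix(t, "BM", day)
  pb <- ct_matrix(t, "PB", day)
  patients <- intersect(rownames(bm), rownames(pb))
  if (!length(patients)) {
    stop("no patient has both compartments at day ", day)
  }
  bm <- bm[patients, , drop = FALSE]
  pb <- pb[patients, , drop = FALSE]
  d <- bm - pb
  mean_bm <- colMeans(bm, na.rm = TRUE)
  mean_pb <- colMeans(pb, na.rm = TRUE)
  list(differences = d, bm = bm, pb = pb, day = day,
       summary = data.frame(metabolite = colnames(d),
                            mean_bm = unname(mean_bm),
                            mean_pb = unname(mean_pb),
                            mean_diff = unname(mean_bm - mean_pb),
                            fold = unname(mean_bm / mean_pb),
                            row.names = NULL, stringsAsFactors = FALSE))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact by enumeration when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie
#' correction is used.
#'
#' @param x,y Numeric samples (missing values removed; both must remain
#'   non-empty).
#' @return List with `statistic` (the Mann-Whitney U for `x`), `p`
#'   (two-sided) and `exact`.
#' @export
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty sample after removing missing values")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= 20
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value, exact = exact)
}

#' Benjamini-Hochberg step-up adjusted values
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of BH q-values (capped at 1).
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

significance_tier <- function(q) {
  ifelse(q < 0.05, "pFDR<5%", ifelse(q < 0.10, "5%<=pFDR<10%", "ns"))
}

#' Compartment comparison at a day: rank-sum tests with FDR tiers
#'
#' For every metabolite with at least `min_pairs` patients carrying both
#' compartments, tests marrow against blood values with the two-sided
#' rank-sum test, adjusts across the tested metabolites with
#' Benjamini-Hochberg, and assigns the significance tiers used for
#' reporting (`pFDR<5%`, `5%<=pFDR<10%`, `ns`).
#'
#' @param t A `conc_table`.
#' @param day Day (0, 8 or 29).
#' @param min_pairs Minimum complete pairs to test a metabolite, default 3.
#' @return Data frame with the paired summary plus `n_pairs`, `statistic`,
#'   `p`, `q`, `tier`, ordered by `p`.
#' @export
compartment_comparison <- function(t, day, min_pairs = 3) {
  pd <- paired_differences(t, day)
  res <- pd$summary
  res$n_pairs <- NA_integer_
  res$statistic <- NA_real_
  res$p <- NA_real_
  for (i in seq_len(nrow(res))) {
    b <- pd$bm[, i]
    pbv <- pd$pb[, i]
    ok <- !is.na(b) & !is.na(pbv)
    res$n_pairs[i] <- sum(ok)
    if (sum(ok) < min_pairs) next
    ht <- rank_sum_test(b[ok], pbv[ok])
    res$statistic[i] <- ht$statistic
    res$p[i] <- ht$p
  }
  dropped <- res$metabolite[is.na(res$p)]
  if (length(dropped)) {
    message("not tested (fewer than ", min_pairs, " complete pairs): ",
            paste(dropped, collapse = ", "))
  }
  res <- res[!is.na(res$p), , drop = FALSE]
  if (!nrow(res)) stop("no metabolite has enough complete pairs at day ", day)
  res$q <- bh_adjust(res$p)
  res$tier <- significance_tier(res$q)
  res <- res[order(res$p, res$metabolite), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Append the five derived ratio/sum features
#'
#' Adds, when the constituents exist in the panel: glutamate/glutamine,
#' aspartate/asparagine, choline/creatine, unsaturated/saturated fatty
#' acids (ratio of sums), and glutamine + pyroglutamate. A zero (or
#' missing) denominator yields a missing value, never infinity; features
#' whose constituents are absent are skipped with a notice.
#'
#' @param t A `conc_table`.
#' @param unsaturated,saturated Fatty-acid name lists used for the
#'   unsaturated/saturated ratio.
#' @return The table with the derived columns appended.
#' @export
ratio_features <- function(t,
                           unsaturated = c("palmitoleic acid", "cis-9-palmitoleic acid",
                                           "oleic acid", "linoleic acid",
                                           "linolenic acid", "arachidonic acid",
                                           "eicosadienoic acid"),
                           saturated = c("myristic acid", "palmitic acid",
                                         "stearic acid", "heptanoic acid")) {
  mets <- ct_metabolites(t)
  find <- function(name) mets[match(tolower(name), tolower(mets))]
  col <- function(name) {
    m <- find(name)
    if (is.na(m)) NULL else t[[m]]
  }
  safe_ratio <- function(num, den) {
    out <- num / den
    out[!is.na(den) & den == 0] <- NA_real_
    out
  }
  add <- function(tab, name, value) {
    if (is.null(value)) {
      message("ratio feature skipped (constituent missing): ", name)
      return(tab)
    }
    tab[[name]] <- value
    tab
  }
  pair_ratio <- function(a, b) {
    ca <- col(a); cb <- col(b)
    if (is.null(ca) || is.null(cb)) NULL else safe_ratio(ca, cb)
  }
  group_sum <- function(names) {
    present <- stats::na.omit(vapply(names, find, character(1)))
    if (!length(present)) return(NULL)
    rowSums(as.matrix(as.data.frame(t, check.names = FALSE)[present]),
            na.rm = FALSE)
  }
  out <- t
  out <- add(out, "glutamate/glutamine", pair_ratio("glutamate", "glutamine"))
  out <- add(out, "aspartate/asparagine", pair_ratio("aspartate", "asparagine"))
  out <- add(out, "choline/creatine", pair_ratio("choline", "creatine"))
  us <- group_sum(unsaturated); ss <- group_sum(saturated)
  out <- add(out, "unsaturated/saturated fatty acids",
             if (is.null(us) || is.null(ss)) NULL else safe_ratio(us, ss))
  gl <- col("glutamine"); pg <- col("pyroglutamate")
  out <- add(out, "glutamine+pyroglutamate",
             if (is.null(gl) || is.null(pg)) NULL else gl + pg)
  class(out) <- class(t)
  out
}
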