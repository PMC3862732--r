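#' Gaussian-copula mutual information from a correlation coefficient
#'
#' `mi = -1/2 * ln(1 - r^2)` (nats), the mutual information of a bivariate
#' Gaussian with correlation `r`; symmetric in the sign of `r` and strictly
#' increasing in `|r|`. Correlations with `|r| >= 1` are clamped to
#' `1 - 1e-12` with a notice.
#'
#' @param r Correlation coefficient(s); Pearson r or Spearman rho.
#' @return Mutual information in nats.
#' @export
mi_from_correlation <- function(r) {
  clamp <- !is.na(r) & abs(r) >= 1
  if (any(clamp)) {
    message(sum(clamp), " correlation(s) with |r| >= 1 clamped to 1 - 1e-12")
    r[clamp] <- sign(r[clamp]) * (1 - 1e-12)
  }
  -0.5 * log(1 - r^2)
}

#' Benjamini-Hochberg p-value cutoff at an FDR level
#'
#' The largest order statistic `p_(k)` with `p_(k) <= fdr * k / m`
#' (step-up); admitting all p-values at or below the cutoff is exactly the
#' BH selection at level `fdr`.
#'
#' @param p Numeric vector of p-values.
#' @param fdr FDR level in (0, 1).
#' @return The cutoff p-value, or `NA` if no p-value passes (or `p` is
#'   empty).
#' @export
fdr_pvalue_cutoff <- function(p, fdr) {
  if (fdr <= 0 || fdr >= 1) stop("`fdr` must be in (0, 1)")
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  ps <- sort(p)
  m <- length(ps)
  ok <- which(ps <= fdr * seq_len(m) / m)
  if (!length(ok)) NA_real_ else ps[max(ok)]
}

#' Build a metabolite relevance network from paired differences
#'
#' Metabolites with at least `min_nonzero` nonzero (and non-missing) values
#' become nodes. For every pair, the Pearson correlation `r` and its
#' two-sided p-value (pairwise complete n) are computed; the mutual
#' information uses the Gaussian-copula form on the chosen estimator's
#' correlation (Spearman rho by default at this stage). Edges are admitted
#' when their p-value passes the BH cutoff over all candidate pairs at
#' `fdr_admit` (FDR < 50% in the study, giving p-cutoffs of ~0.06-0.08),
#' then classified: `lipid` if both endpoints are lipid-metabolism
#' metabolites, `amino` if both are amino acids/derivatives, else `other`;
#' `sign` is `anticorrelated` iff `r < 0`.
#'
#' @param diff Patients-by-metabolites matrix (typically the BM-PB
#'   differences from [paired_differences()], whose `differences` element
#'   is also accepted directly).
#' @param ann Annotation map covering the metabolites.
#' @param fdr_admit Edge-admission FDR level, default 0.5.
#' @param min_nonzero Minimum nonzero values per metabolite, default 5.
#' @param estimator Correlation feeding the MI: `"spearman"` (default) or
#'   `"pearson"`.
#' @param space,day Optional provenance labels.
#' @return A `relevance_network`; empty (with a warning) if no edge passes.
#' @export
build_relevance_network <- function(diff, ann, fdr_admit = 0.5,
                                    min_nonzero = 5,
                                    estimator = c("spearman", "pearson"),
                                    space = "BM_minus_PB", day = NA) {
  estimator <- match.arg(estimator)
  if (is.list(diff) && !is.data.frame(diff) && !is.null(diff$differences)) {
    if (is.na(day) && !is.null(diff$day)) day <- diff$day
    diff <- diff$differences
  }
  m <- as.matrix(diff)
  nz <- colSums(!is.na(m) & m != 0)
  keep <- nz >= min_nonzero
  if (sum(keep) < 2) stop("fewer than 2 metabolites pass the nonzero filter")
  m <- m[, keep, drop = FALSE]
  mets <- colnames(m)
  cls <- check_annotation(ann, mets)
  cp <- correlation_matrix(m, "pearson")
  mi_r <- if (estimator == "spearman") correlation_matrix(m, "spearman")$r else cp$r
  mi <- suppressMessages(mi_from_correlation(mi_r))

  ut <- which(upper.tri(cp$r), arr.ind = TRUE)
  cand <- data.frame(node_a = mets[ut[, 1]], node_b = mets[ut[, 2]],
                     r = cp$r[ut], mi = mi[ut], p = cp$p[ut],
                     stringsAsFactors = FALSE)
  cand <- cand[!is.na(cand$p), , drop = FALSE]
  cand$q <- if (nrow(cand)) bh_adjust(cand$p) else numeric(0)
  cutoff <- fdr_pvalue_cutoff(cand$p, fdr_admit)
  nodes <- data.frame(metabolite = mets, class = unname(cls),
                      stringsAsFactors = FALSE)
  prov <- list(space = space, day = day, fdr_admit = fdr_admit,
               p_cutoff = cutoff, min_nonzero = min_nonzero,
               estimator = estimator, stage = "relevance")
  if (is.na(cutoff)) {
    warning("no edge passes the FDR-based cutoff; returning an empty network")
    return(relevance_network(nodes, empty_edges(), prov))
  }
  adm <- cand[cand$p <= cutoff, , drop = FALSE]
  adm$sign <- ifelse(adm$r < 0, "anticorrelated", "correlated")
  adm$edge_class <- classify_edge(cls[adm$node_a], cls[adm$node_b])
  relevance_network(nodes, adm, prov)
}

#' Smoothed distribution of a class's edge p-values
#'
#' Gaussian kernel density of the edge p-values of one edge class,
#' restricted to the unit interval by reflecting the kernel mass at both
#' boundaries so no density lies at p <= 0 and the density integrates to 1.
#' Bandwidth defaults to Silverman's rule on the p-values.
#'
#' @param net A `relevance_network`.
#' @param which Edge class: `"lipid"`, `"amino"` or `"other"`.
#' @param bandwidth Kernel bandwidth, or `"auto"` for Silverman's rule.
#' @param n_grid Evaluation grid size on (0, 1].
#' @return Object of class `smoothed_pdf`: `x` (grid), `density`,
#'   `bandwidth`, `n`.
#' @export
edge_pdf <- function(net, which = c("lipid", "amino", "other"),
                     bandwidth = "auto", n_grid = 512) {
  which <- match.arg(which)
  p <- net$edges$p[net$edges$edge_class == which]
  if (!length(p)) stop("no edges of class '", which, "'")
  bw <- if (identical(bandwidth, "auto")) {
    if (length(p) >= 2 && stats::sd(p) > 0) stats::bw.nrd0(p) else 0.05
  } else {
    if (bandwidth <= 0) stop("`bandwidth` must be > 0")
    bandwidth
  }
  x <- seq(1e-6, 1, length.out = n_grid)
  dens <- vapply(x, function(xx) {
    mean(stats::dnorm(xx, p, bw) + stats::dnorm(xx, -p, bw) +
           stats::dnorm(xx, 2 - p, bw))
  }, numeric(1))
  structure(list(x = x, density = dens, bandwidth = bw, n = length(p),
                 edge_class = which), class = "smoothed_pdf")
}

#' Edge-class enrichment test (Mann-Whitney on edge p-values)
#'
#' Tests whether the named edge class has stochastically smaller p-values
#' (i.e. stronger correlations) than the rest of the network's edges
#' (one-sided), or differs from the same class in another network
#' (two-sided; used for the cancer-vs-remission lipid comparison). The
#' exact null distribution of U is used whenever the pooled edge p-values
#' are tie-free and total at most 50 -- a small class group against a large
#' rest group is the common case here, and the normal approximation is too
#' coarse at the extreme ranks it produces; with ties or larger families
#' the tie-corrected normal approximation is used.
#'
#' @param net A `relevance_network`.
#' @param group Edge class: `"lipid"`, `"amino"` or `"other"`.
#' @param versus `"rest"` or `"same_class_other_network"`.
#' @param other The other `relevance_network` when comparing across
#'   networks.
#' @return Object of class `enrichment_result`: `contrast`, `U`, `p`,
#'   `direction` (which side has the smaller p-values), `n_group`,
#'   `n_other`, `alternative`.
#' @export
enrichment_test <- function(net, group = c("lipid", "amino", "other"),
                            versus = c("rest", "same_class_other_network"),
                            other = NULL) {
  group <- match.arg(group)
  versus <- match.arg(versus)
  gp <- net$edges$p[net$edges$edge_class == group]
  if (versus == "rest") {
    op <- net$edges$p[net$edges$edge_class != group]
    alternative <- "less"
    contrast <- paste0(group, " vs rest")
  } else {
    if (is.null(other)) stop("`other` network required")
    op <- other$edges$p[other$edges$edge_class == group]
    alternative <- "two.sided"
    contrast <- paste0(group, " vs ", group, " (other network)")
  }
  if (!length(gp)) stop("no edges of class '", group, "' in `net`")
  if (!length(op)) stop("comparison group has no edges")
  exact <- (length(gp) + length(op)) <= 50 && !anyDuplicated(c(gp, op))
  ht <- suppressWarnings(stats::wilcox.test(gp, op, alternative = alternative,
                                            exact = exact))
  structure(list(contrast = contrast, U = unname(ht$statistic),
                 p = ht$p.value,
                 direction = if (mean(rank(c(gp, op))[seq_along(gp)]) <
                                 mean(rank(c(gp, op))[-seq_along(gp)]))
                   group else "comparison group",
                 n_group = length(gp), n_other = length(op),
                 alternative = alternative, exact = exact),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment (%s): U = %.1f, %s p = %.3g (smaller p-values: %s; n = %d vs %d)\n",
              x$contrast, x$U,
              if (x$alternative == "less") "one-sided" else "two-sided",
              x$p, x$direction, x$n_group, x$n_other))
  invisible(x)
}

aracne_marked <- function(nodes, edges, tol) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\t")
  mi <- stats::setNames(edges$mi, key(edges$node_a, edges$node_b))
  g <- igraph::graph_from_data_frame(edges[, c("node_a", "node_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  tri <- matrix(igraph::V(g)$name[igraph::triangles(g)], nrow = 3)
  marked <- character(0)
  if (ncol(tri)) {
    for (i in seq_len(ncol(tri))) {
      v <- tri[, i]
      ks <- c(key(v[1], v[2]), key(v[1], v[3]), key(v[2], v[3]))
      ms <- mi[ks]
      for (e in 1:3) {
        if (ms[e] <= min(ms[-e]) - tol) marked <- c(marked, ks[e])
      }
    }
  }
  unique(marked)
}

#' ARACNE pruning by the data processing inequality
#'
#' For every triangle in the network, the edge with the smallest mutual
#' information is marked (at tolerance 0, an edge is marked when its MI is
#' less than or equal to the minimum of the other two, so ties among the
#' weakest edges remove all of them and the output is guaranteed
#' triangle-free). All marks are computed on the original network and
#' removed in one sweep -- never sequentially, which would be
#' order-dependent.
#'
#' @param net A `relevance_network`.
#' @param dpi_tolerance Tolerance subtracted from the comparison (0 removes
#'   every triangle; larger values spare edges whose MI deficit is within
#'   the tolerance).
#' @return The pruned `relevance_network`.
#' @export
aracne_prune <- function(net, dpi_tolerance = 0) {
  if (dpi_tolerance < 0) stop("`dpi_tolerance` must be >= 0")
  if (!nrow(net$edges)) return(net)
  marked <- aracne_marked(net$nodes$metabolite, net$edges, dpi_tolerance)
  key <- paste(net$edges$node_a, net$edges$node_b, sep = "\t")
  edges <- net$edges[!key %in% marked, , drop = FALSE]
  prov <- net$provenance
  prov$stage <- "aracne"
  prov$dpi_tolerance <- dpi_tolerance
  relevance_network(net$nodes, edges, prov)
}

#' Retain the significant edges after ARACNE (FDR < 1%)
#'
#' Benjamini-Hochberg is applied to the surviving edges' p-values as their
#' own family; by default the edges with `q <= fdr` are retained,
#' highlighting the regions of higher-than-average correlation. The
#' literal complementary reading (drop those edges) is available as
#' `mode = "remove"`.
#'
#' @param net A `relevance_network` (typically post-ARACNE).
#' @param fdr FDR level, default 0.01.
#' @param mode `"retain"` (default) or `"remove"`.
#' @return The filtered `relevance_network`; edge `q` values are updated to
#'   this family's BH values.
#' @export
fdr_retain <- function(net, fdr = 0.01, mode = c("retain", "remove")) {
  mode <- match.arg(mode)
  edges <- net$edges
  if (nrow(edges)) {
    edges$q <- bh_adjust(edges$p)
    keep <- if (mode == "retain") edges$q <= fdr else edges$q > fdr
    edges <- edges[keep, , drop = FALSE]
  }
  prov <- net$provenance
  prov$stage <- "fdr_retain"
  prov$fdr_retain <- fdr
  prov$retain_mode <- mode
  relevance_network(net$nodes, edges, prov)
}

#' Connected components of a relevance network
#'
#' Maximal connected components with at least `min_nodes` nodes, ordered by
#' node count (descending), then edge count (descending), then the
#' lexicographically smallest member.
#'
#' @param net A `relevance_network`.
#' @param min_nodes Minimum component size, default 4 ("more than three
#'   nodes").
#' @return List of `relevance_network` sub-networks.
#' @export
connected_components <- function(net, min_nodes = 4) {
  if (!nrow(net$edges)) return(list())
  g <- net_igraph(net)
  comp <- igraph::components(g)
  out <- list()
  for (ci in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == ci]
    if (length(members) < min_nodes) next
    keep_e <- net$edges$node_a %in% members
    sub <- relevance_network(
      net$nodes[net$nodes$metabolite %in% members, , drop = FALSE],
      net$edges[keep_e, , drop = FALSE],
      c(net$provenance, list(component = ci)))
    out[[length(out) + 1]] <- sub
  }
  if (!length(out)) return(out)
  nn <- vapply(out, function(s) nrow(s$nodes), integer(1))
  ne <- vapply(out, function(s) nrow(s$edges), integer(1))
  first <- vapply(out, function(s) min(s$nodes$metabolite), character(1))
  out[order(-nn, -ne, first)]
}

#' Summary statistics of one connected component
#'
#' Node and edge counts plus the edge-wise means of `r^2`, `p` and mutual
#' information (the component statistics reported for the study networks).
#'
#' @param c A `relevance_network` component with at least one edge.
#' @return Data frame with `n_nodes`, `n_edges`, `mean_r2`, `mean_p`,
#'   `mean_mi`.
#' @export
component_summary <- function(c) {
  if (!nrow(c$edges)) stop("component has no edges")
  data.frame(n_nodes = nrow(c$nodes), n_edges = nrow(c$edges),
             mean_r2 = mean(c$edges$r^2), mean_p = mean(c$edges$p),
             mean_mi = mean(c$edges$mi))
}
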