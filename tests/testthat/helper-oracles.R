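# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition (full enumeration, step-up by
# hand, triple enumeration) and never call the implementation under test.

# Exact two-sided rank-sum p by enumerating all C(n1+n2, n1) assignments.
oracle_ranksum_p <- function(x, y, alternative = "two.sided") {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  ranks <- seq_len(n1 + n2)
  u_all <- apply(combs, 2, function(idx) sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  pl <- mean(u_all <= u_obs)
  pg <- mean(u_all >= u_obs)
  switch(alternative,
         less = pl,
         greater = pg,
         two.sided = min(1, 2 * min(pl, pg)))
}

# BH step-up q-values from the definition q_(i) = min(1, min_{j>=i} p_(j) m/j).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# BH p-cutoff from the step-up definition.
oracle_bh_cutoff <- function(p, fdr) {
  ps <- sort(p)
  m <- length(ps)
  ok <- which(ps <= fdr * seq_len(m) / m)
  if (!length(ok)) NA_real_ else ps[max(ok)]
}

# DPI pruning by enumerating every node triple on an adjacency matrix.
# Returns the logical keep-mask over the rows of `edges`.
oracle_aracne_keep <- function(nodes, edges, tol = 0) {
  nn <- length(nodes)
  mi <- matrix(NA_real_, nn, nn, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    mi[edges$node_a[i], edges$node_b[i]] <- edges$mi[i]
    mi[edges$node_b[i], edges$node_a[i]] <- edges$mi[i]
  }
  drop <- matrix(FALSE, nn, nn, dimnames = dimnames(mi))
  if (nn >= 3) {
    for (tr in utils::combn(nn, 3, simplify = FALSE)) {
      a <- nodes[tr[1]]; b <- nodes[tr[2]]; cc <- nodes[tr[3]]
      ms <- c(mi[a, b], mi[a, cc], mi[b, cc])
      if (anyNA(ms)) next
      pairs <- list(c(a, b), c(a, cc), c(b, cc))
      for (e in 1:3) {
        if (ms[e] <= min(ms[-e]) - tol) {
          drop[pairs[[e]][1], pairs[[e]][2]] <- TRUE
          drop[pairs[[e]][2], pairs[[e]][1]] <- TRUE
        }
      }
    }
  }
  keep <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    keep[i] <- !drop[edges$node_a[i], edges$node_b[i]]
  }
  keep
}

has_triangle <- function(edges) {
  if (nrow(edges) < 3) return(FALSE)
  adj <- split(c(edges$node_b, edges$node_a), c(edges$node_a, edges$node_b))
  for (i in seq_len(nrow(edges))) {
    if (length(intersect(adj[[edges$node_a[i]]], adj[[edges$node_b[i]]])) > 0) {
      return(TRUE)
    }
  }
  FALSE
}

# Random relevance network on <= n_nodes nodes with random MI weights.
random_network <- function(n_nodes, edge_prob = 0.5, tie_mi = FALSE) {
  nodes <- sprintf("m%02d", seq_len(n_nodes))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < edge_prob
  k <- sum(keep)
  if (k == 0) {
    return(relevance_network(data.frame(metabolite = nodes, class = "other")))
  }
  mi <- stats::runif(k, 0.1, 2)
  if (tie_mi) mi <- round(mi, 1)  # induce ties among triangle edges
  edges <- data.frame(node_a = pairs[1, keep], node_b = pairs[2, keep],
                      r = stats::runif(k, -1, 1) * 0.9, mi = mi,
                      p = stats::runif(k), q = NA_real_,
                      sign = "correlated", edge_class = "other",
                      stringsAsFactors = FALSE)
  relevance_network(data.frame(metabolite = nodes, class = "other"), edges)
}

# Small concentration table fixture: 3 patients paired at day 0.
tiny_table <- function() {
  as_concentration_table(data.frame(
    patient_id = rep(c("a", "b", "c"), each = 2),
    compartment = rep(c("BM", "PB"), 3),
    day = 0L,
    glutamate = c(400, 150, 420, 160, 450, 155),
    glutamine = c(350, 440, 360, 450, 340, 430),
    check.names = FALSE))
}
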