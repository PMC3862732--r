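test_that("Gaussian-copula MI has the closed-form values and symmetries", {
  expect_equal(mi_from_correlation(0), 0)
  expect_equal(mi_from_correlation(0.9), -0.5 * log(0.19), tolerance = 1e-12)
  expect_equal(mi_from_correlation(0.9), 0.83037, tolerance = 1e-5)
  set.seed(30)
  r <- runif(50, -0.99, 0.99)
  expect_equal(mi_from_correlation(r), mi_from_correlation(-r))
  rs <- sort(abs(r))
  expect_true(all(diff(mi_from_correlation(rs)) > 0))
  expect_message(mi1 <- mi_from_correlation(1), "clamped")
  expect_true(is.finite(mi1))
})

test_that("FDR p-value cutoff follows the step-up rule", {
  expect_equal(fdr_pvalue_cutoff(c(0.01, 0.02, 0.3, 0.6), 0.5), 0.3)
  expect_true(is.na(fdr_pvalue_cutoff(rep(1, 4), 0.5)))
  expect_true(is.na(fdr_pvalue_cutoff(numeric(0), 0.5)))
  set.seed(31)
  for (rep in 1:50) {
    p <- runif(sample(1:30, 1))^2
    expect_equal(fdr_pvalue_cutoff(p, 0.25), oracle_bh_cutoff(p, 0.25))
    # admission by cutoff == BH selection at the same level
    cut <- fdr_pvalue_cutoff(p, 0.25)
    sel_cut <- if (is.na(cut)) rep(FALSE, length(p)) else p <= cut
    expect_identical(sel_cut, bh_adjust(p) <= 0.25)
  }
})

test_that("relevance network admits the collinear pair and filters sparse metabolites", {
  set.seed(32)
  n <- 10
  a <- rnorm(n, 10, 1)
  m <- cbind(a = a, b = a * 1.5 + rnorm(n, 0, 1e-6), c = rnorm(n, 5, 1))
  ann <- annotation_map(c("a", "b", "c"),
                        c("lipid_metabolism", "lipid_metabolism", "other"))
  net <- build_relevance_network(m, ann, fdr_admit = 0.5)
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$node_a, "a")
  expect_identical(net$edges$node_b, "b")
  expect_identical(net$edges$edge_class, "lipid")
  expect_identical(net$edges$sign, "correlated")
  expect_equal(net$edges$mi,
               mi_from_correlation(cor(m[, "a"], m[, "b"], method = "spearman")),
               tolerance = 1e-9)

  # metabolite with only 4 nonzero values among 10 is excluded from the nodes
  m2 <- m
  m2[5:10, "c"] <- 0
  net2 <- build_relevance_network(m2, ann, min_nonzero = 5)
  expect_false("c" %in% net2$nodes$metabolite)

  # anticorrelation is flagged by sign
  m3 <- cbind(a = a, b = -2 * a + rnorm(n, 0, 1e-6), c = rnorm(n))
  net3 <- build_relevance_network(m3, ann)
  expect_identical(net3$edges$sign[net3$edges$node_a == "a"], "anticorrelated")
})

test_that("admitted edge count is nonincreasing in stricter admission FDR", {
  set.seed(33)
  m <- matrix(rnorm(10 * 12), 10, 12,
              dimnames = list(NULL, sprintf("met%02d", 1:12)))
  m[, 2] <- m[, 1] + rnorm(10, 0, 0.3)
  ann <- annotation_map(colnames(m), rep("other", 12))
  counts <- vapply(c(0.6, 0.5, 0.3, 0.1), function(f) {
    nrow(suppressWarnings(build_relevance_network(m, ann, fdr_admit = f))$edges)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("edge p-value PDFs integrate to 1 with no mass at p <= 0", {
  nodes <- data.frame(metabolite = c("a", "b"), class = "lipid_metabolism")
  e <- data.frame(node_a = "a", node_b = "b", r = 0.9, mi = 0.83, p = 0.02,
                  q = 0.02, sign = "correlated", edge_class = "lipid")
  net <- relevance_network(nodes, e)
  sp <- edge_pdf(net, "lipid")
  integral <- sum(diff(sp$x) * (head(sp$density, -1) + tail(sp$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-3)
  # closed form of the boundary-reflected kernel for a single observation
  closed <- function(xx) dnorm(xx, 0.02, sp$bandwidth) +
    dnorm(xx, -0.02, sp$bandwidth) + dnorm(xx, 2 - 0.02, sp$bandwidth)
  at <- c(0.02, 0.1, 0.5)
  expect_equal(sapply(at, function(v) sp$density[which.min(abs(sp$x - v))]),
               closed(at), tolerance = 1e-2)
  expect_lt(sp$x[which.max(sp$density)], 0.1)  # mass concentrated at small p
  expect_true(all(sp$density >= 0))
  expect_error(edge_pdf(net, "amino"), "no edges")

  set.seed(34)
  rn <- random_network(10, 0.7)
  sp2 <- edge_pdf(rn, "other")
  int2 <- sum(diff(sp2$x) * (head(sp2$density, -1) + tail(sp2$density, -1)) / 2)
  expect_equal(int2, 1, tolerance = 1e-3)
})

test_that("enrichment tests match exact Mann-Whitney enumeration", {
  mk_net <- function(p_lipid, p_other) {
    nn <- length(p_lipid) + length(p_other)
    nodes <- data.frame(metabolite = sprintf("m%02d", seq_len(2 * nn)),
                        class = rep(c("lipid_metabolism", "other"),
                                    times = c(2 * length(p_lipid),
                                              2 * length(p_other))))
    e <- data.frame(
      node_a = nodes$metabolite[seq(1, 2 * nn, 2)],
      node_b = nodes$metabolite[seq(2, 2 * nn, 2)],
      r = 0.5, mi = 0.1, p = c(p_lipid, p_other), q = NA_real_,
      sign = "correlated",
      edge_class = rep(c("lipid", "other"),
                       times = c(length(p_lipid), length(p_other))))
    relevance_network(nodes, e)
  }
  # group entirely below the rest: exact one-sided p = 1 / C(5,3)
  net <- mk_net(c(0.001, 0.002, 0.003), c(0.5, 0.6))
  e1 <- enrichment_test(net, "lipid", "rest")
  expect_equal(e1$p, 1 / choose(5, 3), tolerance = 1e-12)
  expect_identical(e1$direction, "lipid")
  expect_equal(e1$p, oracle_ranksum_p(c(0.001, 0.002, 0.003), c(0.5, 0.6),
                                      "less"), tolerance = 1e-12)

  # single edge against a single larger p: exact p = 0.5
  e2 <- enrichment_test(mk_net(0.01, 0.5), "lipid", "rest")
  expect_equal(e2$p, 0.5)

  # random small instances against the enumeration oracle
  set.seed(35)
  for (rep in 1:20) {
    ng <- sample(1:5, 1); no <- sample(1:5, 1)
    ps <- sample(seq(0.01, 0.99, by = 0.01), ng + no)
    ee <- enrichment_test(mk_net(ps[seq_len(ng)], ps[-seq_len(ng)]),
                          "lipid", "rest")
    expect_equal(ee$p, oracle_ranksum_p(ps[seq_len(ng)], ps[-seq_len(ng)],
                                        "less"), tolerance = 1e-12)
  }

  # cross-network comparison is two-sided
  net_a <- mk_net(c(0.001, 0.002, 0.003), 0.5)
  net_b <- mk_net(c(0.4, 0.5, 0.6), 0.5)
  e3 <- enrichment_test(net_a, "lipid", "same_class_other_network", net_b)
  expect_identical(e3$alternative, "two.sided")
  expect_equal(e3$p, oracle_ranksum_p(c(0.001, 0.002, 0.003),
                                      c(0.4, 0.5, 0.6), "two.sided"),
               tolerance = 1e-12)
  expect_error(enrichment_test(net_a, "amino", "rest"), "no edges")
})

test_that("ARACNE removes the weakest edge of each triangle, mark-then-sweep", {
  nodes <- data.frame(metabolite = c("A", "B", "C"), class = "other")
  tri <- data.frame(node_a = c("A", "B", "A"), node_b = c("B", "C", "C"),
                    r = 0.5, mi = c(0.9, 0.8, 0.5), p = 0.01, q = 0.01,
                    sign = "correlated", edge_class = "other")
  net <- relevance_network(nodes, tri)
  pruned <- aracne_prune(net)
  keys <- paste(pruned$edges$node_a, pruned$edges$node_b)
  expect_setequal(keys, c("A B", "B C"))

  # a path with no closing edge is untouched
  path <- relevance_network(nodes, tri[1:2, ])
  expect_identical(nrow(aracne_prune(path)$edges), 2L)

  # tied weakest edges are both removed (triangle-free guarantee)
  tie <- tri; tie$mi <- c(0.5, 0.5, 0.9)
  pt <- aracne_prune(relevance_network(nodes, tie))
  expect_identical(paste(pt$edges$node_a, pt$edges$node_b), "A C")
})

test_that("ARACNE equals the brute-force triple oracle on random graphs", {
  set.seed(36)
  for (rep in 1:300) {
    net <- random_network(sample(4:8, 1), edge_prob = 0.6,
                          tie_mi = rep %% 3 == 0)
    pruned <- aracne_prune(net)
    keep <- oracle_aracne_keep(net$nodes$metabolite, net$edges)
    expect_identical(paste(pruned$edges$node_a, pruned$edges$node_b),
                     paste(net$edges$node_a[keep], net$edges$node_b[keep]))
    expect_false(has_triangle(pruned$edges))
  }
})

test_that("positive DPI tolerance spares edges within the tolerance", {
  nodes <- data.frame(metabolite = c("A", "B", "C"), class = "other")
  tri <- data.frame(node_a = c("A", "B", "A"), node_b = c("B", "C", "C"),
                    r = 0.5, mi = c(0.9, 0.8, 0.75), p = 0.01, q = 0.01,
                    sign = "correlated", edge_class = "other")
  net <- relevance_network(nodes, tri)
  expect_identical(nrow(aracne_prune(net, dpi_tolerance = 0.1)$edges), 3L)
  expect_identical(nrow(aracne_prune(net, dpi_tolerance = 0)$edges), 2L)
})

test_that("fdr_retain reproduces brute-force BH selection on the edge family", {
  set.seed(37)
  net <- random_network(12, 0.6)
  kept <- fdr_retain(net, 0.05)
  qs <- oracle_bh(net$edges$p)
  expect_setequal(paste(kept$edges$node_a, kept$edges$node_b),
                  paste(net$edges$node_a[qs <= 0.05],
                        net$edges$node_b[qs <= 0.05]))
  # literal complementary reading
  dropped <- fdr_retain(net, 0.05, mode = "remove")
  expect_identical(nrow(kept$edges) + nrow(dropped$edges), nrow(net$edges))

  tiny <- net
  tiny$edges$p <- rep(1e-9, nrow(tiny$edges))
  expect_identical(nrow(fdr_retain(tiny, 0.01)$edges), nrow(tiny$edges))
  tiny$edges$p <- rep(0.5, nrow(tiny$edges))
  expect_identical(nrow(fdr_retain(tiny, 0.01)$edges), 0L)
})

test_that("connected components are filtered, ordered, and summarized", {
  nodes <- data.frame(metabolite = c("A", "B", "C", "D", "E", "F", "G"),
                      class = "other")
  e <- data.frame(node_a = c("A", "B", "C", "E", "F"),
                  node_b = c("B", "C", "D", "F", "G"),
                  r = c(0.9, 0.8, 0.7, 0.6, 0.5),
                  mi = c(0.83, 0.5, 0.4, 0.3, 0.2),
                  p = c(0.001, 0.002, 0.003, 0.004, 0.005), q = NA_real_,
                  sign = "correlated", edge_class = "other")
  net <- relevance_network(nodes, e)
  comps <- connected_components(net, min_nodes = 4)
  expect_length(comps, 1)  # the 3-node E-F-G component is filtered out
  expect_setequal(comps[[1]]$nodes$metabolite, c("A", "B", "C", "D"))
  comps2 <- connected_components(net, min_nodes = 3)
  expect_length(comps2, 2)
  expect_gte(nrow(comps2[[1]]$nodes), nrow(comps2[[2]]$nodes))
  expect_true(all(paste(comps2[[1]]$edges$node_a, comps2[[1]]$edges$node_b)
                  %in% paste(net$edges$node_a, net$edges$node_b)))

  empty <- relevance_network(nodes)
  expect_identical(connected_components(empty), list())

  s <- component_summary(comps[[1]])
  expect_identical(s$n_nodes, 4L)
  expect_identical(s$n_edges, 3L)
  expect_equal(s$mean_r2, mean(c(0.9, 0.8, 0.7)^2))
  expect_equal(s$mean_p, 0.002)
  single <- comps2[[2]]
  expect_equal(component_summary(single)$mean_r2, mean(c(0.6, 0.5)^2))
  expect_error(component_summary(relevance_network(nodes)), "no edges")

  # two edges r = 0.8 / 0.6 average to mean r^2 = (0.64 + 0.36)/2 = 0.5
  e2 <- e[4:5, ]
  e2$r <- c(0.8, 0.6)
  two <- relevance_network(nodes, e2)
  expect_equal(component_summary(two)$mean_r2, 0.5)
})
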