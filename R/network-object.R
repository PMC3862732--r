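EDGE_COLS <- c("node_a", "node_b", "r", "mi", "p", "q", "sign", "edge_class")

empty_edges <- function() {
  data.frame(node_a = character(), node_b = character(),
             r = numeric(), mi = numeric(), p = numeric(), q = numeric(),
             sign = character(), edge_class = character(),
             stringsAsFactors = FALSE)
}

#' Construct a relevance network
#'
#' Nodes are metabolites with a class annotation; edges carry the Pearson
#' correlation `r`, mutual information `mi` (nats), the two-sided
#' correlation p-value, its BH-adjusted value `q` within the network's edge
#' family, a `sign` (`correlated` / `anticorrelated`), and an `edge_class`:
#' `lipid` when both endpoints are lipid-metabolism metabolites, `amino`
#' when both are amino acids (incl. derivatives and analogues), `other`
#' for every remaining pair.
#'
#' @param nodes Data frame with columns `metabolite`, `class`.
#' @param edges Data frame with columns
#'   `node_a, node_b, r, mi, p, q, sign, edge_class`; endpoints are stored
#'   with `node_a < node_b` lexicographically.
#' @param provenance Named list recording how the network was built
#'   (space, day, FDR levels, estimator, p-value cutoff, ...).
#' @return An object of class `relevance_network`.
#' @export
relevance_network <- function(nodes, edges = empty_edges(),
                              provenance = list()) {
  stopifnot(is.data.frame(nodes), all(c("metabolite", "class") %in% names(nodes)))
  nodes <- data.frame(metabolite = as.character(nodes$metabolite),
                      class = as.character(nodes$class),
                      stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    miss <- setdiff(EDGE_COLS, names(edges))
    if (length(miss)) stop("edges missing column(s): ", paste(miss, collapse = ", "))
    edges <- edges[EDGE_COLS]
    swap <- edges$node_a > edges$node_b
    if (any(swap)) {
      tmp <- edges$node_a[swap]
      edges$node_a[swap] <- edges$node_b[swap]
      edges$node_b[swap] <- tmp
    }
    if (any(edges$node_a == edges$node_b)) stop("self-edges are not allowed")
    unknown <- setdiff(c(edges$node_a, edges$node_b), nodes$metabolite)
    if (length(unknown)) {
      stop("edge endpoint(s) not in node set: ", paste(unknown, collapse = ", "))
    }
    edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- empty_edges()
  }
  structure(list(nodes = nodes, edges = edges, provenance = provenance),
            class = "relevance_network")
}

#' @export
print.relevance_network <- function(x, ...) {
  cat(sprintf("Relevance network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    cat("  edge classes:",
        paste(sprintf("%s=%d", names(table(x$edges$edge_class)),
                      table(x$edges$edge_class)), collapse = ", "), "\n")
  }
  if (length(x$provenance)) {
    keep <- vapply(x$provenance, function(v) is.atomic(v) && length(v) == 1,
                   logical(1))
    cat("  provenance:",
        paste(sprintf("%s=%s", names(x$provenance)[keep],
                      unlist(x$provenance[keep])), collapse = ", "), "\n")
  }
  invisible(x)
}

classify_edge <- function(class_a, class_b) {
  ifelse(class_a == "lipid_metabolism" & class_b == "lipid_metabolism", "lipid",
  ifelse(class_a == "amino_acid" & class_b == "amino_acid", "amino", "other"))
}

net_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    d = net$edges[, intersect(EDGE_COLS, names(net$edges)), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = net$nodes$metabolite,
                          class = net$nodes$class,
                          stringsAsFactors = FALSE))
  g
}

#' Serialize a relevance network
#'
#' `edge_tsv` writes one row per edge (columns
#' `node_a, node_b, r, mi, p, q, sign, edge_class`, endpoints in
#' lexicographic order); `graphml` writes standard GraphML with the node
#' `class` and all edge attributes, readable by [read_network()] and by
#' common graph tools.
#'
#' @param net A `relevance_network`.
#' @param path Output path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @export
write_network <- function(net, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    igraph::write_graph(net_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read a relevance network written by [write_network()]
#'
#' The edge-TSV form carries edges only; nodes are reconstructed from edge
#' endpoints (classes inferred from `edge_class` are not recoverable for
#' mixed edges, so node classes are `NA` unless `ann` is supplied). The
#' GraphML form restores node classes exactly.
#'
#' @param path Input path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @param ann Optional annotation map to reattach node classes.
#' @return A `relevance_network`.
#' @export
read_network <- function(path, format = c("edge_tsv", "graphml"), ann = NULL) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    edges <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                               stringsAsFactors = FALSE, check.names = FALSE)
    if (!nrow(edges)) edges <- empty_edges()
    mets <- sort(unique(c(edges$node_a, edges$node_b)))
    cls <- if (is.null(ann)) rep(NA_character_, length(mets)) else
      check_annotation(ann, mets)
    nodes <- data.frame(metabolite = mets, class = unname(cls),
                        stringsAsFactors = FALSE)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(metabolite = igraph::V(g)$name,
                        class = igraph::V(g)$class,
                        stringsAsFactors = FALSE)
    el <- igraph::as_data_frame(g, what = "edges")
    if (nrow(el)) {
      edges <- data.frame(node_a = el$from, node_b = el$to,
                          r = el$r, mi = el$mi, p = el$p, q = el$q,
                          sign = el$sign, edge_class = el$edge_class,
                          stringsAsFactors = FALSE)
    } else {
      edges <- empty_edges()
    }
  }
  relevance_network(nodes, edges)
}
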