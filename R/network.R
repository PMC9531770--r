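#' Build the undirected substance graph
#'
#' Nodes are the concepts incident to at least one surviving PPMI edge
#' (isolated concepts are excluded), minus an optional manual exclusion
#' list for known false-positive nodes; edges carry the PPMI weights.
#'
#' @param ppmi a (filtered) [compute_ppmi()] result.
#' @param exclusions concept ids to remove together with their edges.
#' @param lex optional [lexicon]; when given, vertices carry `label`
#'   (canonical name) and `class` attributes.
#' @return an [igraph][igraph::graph_from_data_frame] graph, vertices
#'   sorted by concept id.
#' @export
build_graph <- function(ppmi, exclusions = character(), lex = NULL) {
  edges <- as.data.frame(ppmi)[, c("x", "y", "weight")]
  keep <- !(edges$x %in% exclusions) & !(edges$y %in% exclusions)
  edges <- edges[keep, , drop = FALSE]
  ids <- sort(unique(c(edges$x, edges$y)))
  verts <- data.frame(name = ids, stringsAsFactors = FALSE)
  if (!is.null(lex)) {
    idx <- match(ids, lex$concepts$concept_id)
    verts$label <- ifelse(is.na(idx), ids, lex$concepts$canonical_name[idx])
    verts$class <- ifelse(is.na(idx), NA_character_,
                          lex$concepts$substance_class[idx])
  } else {
    verts$label <- ids
    verts$class <- rep(NA_character_, length(ids))
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Unweighted degree centrality
#'
#' The number of linkages of a node; edge weights are deliberately
#' ignored, matching the study's importance measure.
#'
#' @param graph an igraph graph.
#' @return named integer vector.
#' @export
degree_centrality <- function(graph) {
  d <- igraph::degree(graph, loops = FALSE)
  stats::setNames(as.integer(d), names(d))
}

#' Average clustering coefficient
#'
#' Arithmetic mean over nodes of the unweighted local clustering
#' coefficient, with 0 for nodes of degree < 2.
#'
#' @param graph an igraph graph.
#' @return value in \[0, 1\] (0 for an empty graph).
#' @export
avg_clustering_coefficient <- function(graph) {
  if (igraph::vcount(graph) == 0) return(0)
  igraph::transitivity(graph, type = "localaverage", isolates = "zero")
}

# weights, 2m and per-node strength of a graph; shared by modularity and
# leiden internals
graph_arrays <- function(graph) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  n <- igraph::vcount(graph)
  k <- numeric(n)
  for (r in seq_len(nrow(el))) {
    k[el[r, 1]] <- k[el[r, 1]] + w[r]
    k[el[r, 2]] <- k[el[r, 2]] + w[r]
  }
  list(n = n, el = el, w = w, k = k, m = sum(w),
       names = igraph::V(graph)$name)
}

#' Weighted modularity with resolution
#'
#' `Q = (1/2m) * sum_ij (A_ij - gamma * k_i * k_j / (2m)) * delta(c_i, c_j)`
#' over the weighted adjacency, equivalently
#' `sum_c (w_in_c / m - gamma * (d_c / 2m)^2)` with `w_in_c` the total
#' intra-community edge weight and `d_c` the community strength.
#'
#' @param graph an igraph graph with optional `weight` edge attribute.
#' @param membership community labels: named vector covering every vertex,
#'   or a `substance_partition`.
#' @param resolution gamma > 0.
#' @return Q.
#' @export
modularity_q <- function(graph, membership, resolution = 1) {
  abort_if(resolution <= 0, "resolution must be positive")
  if (inherits(membership, "substance_partition")) {
    membership <- membership$membership
  }
  g <- graph_arrays(graph)
  if (g$n == 0) return(0)
  mem <- membership[g$names]
  abort_if(anyNA(mem), "membership does not cover every node")
  if (g$m == 0) return(0)
  modularity_from_arrays(as.integer(factor(mem)), g$el, g$w, g$k, g$m,
                         resolution)
}

# membership: integer vector over nodes 1..n
modularity_from_arrays <- function(mem, el, w, k, m, gamma) {
  inside <- sum(w[mem[el[, 1]] == mem[el[, 2]]])
  d <- tapply(k, mem, sum)
  inside / m - gamma * sum((d / (2 * m))^2)
}

#' Per-cluster network summary
#'
#' The reporting analogue of a cluster characteristics table: per
#' community, its share of all graph nodes and its top-k substances by
#' degree centrality (ties broken by higher weighted degree, then
#' lexicographically), annotated with substance classes; plus global
#' statistics (nodes, edges, Q, average clustering coefficient).
#'
#' @param graph an igraph graph.
#' @param partition a `substance_partition` from [leiden()].
#' @param lex optional [lexicon] for class annotations.
#' @param k list length per community (>= 1); default 10.
#' @return An object of class `network_summary`.
#' @export
cluster_summary <- function(graph, partition, lex = NULL, k = 10L) {
  abort_if(k < 1, "k must be >= 1")
  mem <- partition$membership
  deg <- degree_centrality(graph)
  strength <- igraph::strength(graph)
  n <- igraph::vcount(graph)
  communities <- sort(unique(unname(mem)))
  per <- lapply(communities, function(cm) {
    nodes <- names(mem)[mem == cm]
    ord <- order(-deg[nodes], -strength[nodes], nodes)
    top <- nodes[utils::head(ord, k)]
    cls <- if (!is.null(lex)) {
      idx <- match(top, lex$concepts$concept_id)
      ifelse(is.na(idx), NA_character_, lex$concepts$substance_class[idx])
    } else rep(NA_character_, length(top))
    list(community = cm, n_nodes = length(nodes),
         share_pct = 100 * length(nodes) / n,
         top = data.frame(concept_id = top, degree = unname(deg[top]),
                          substance_class = cls, stringsAsFactors = FALSE))
  })
  structure(list(n_nodes = n, n_edges = igraph::ecount(graph),
                 modularity = partition$modularity %||% partition$quality,
                 resolution = partition$resolution,
                 avg_clustering = avg_clustering_coefficient(graph),
                 communities = per),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("<network_summary> %d nodes, %d edges, Q = %.3f (gamma = %g), avg clustering = %.3f\n",
              x$n_nodes, x$n_edges, x$modularity, x$resolution,
              x$avg_clustering))
  for (cm in x$communities) {
    cat(sprintf("  community %d: %d nodes (%.2f%%): %s\n",
                cm$community, cm$n_nodes, cm$share_pct,
                paste(cm$top$concept_id, collapse = ", ")))
  }
  invisible(x)
}

# flat data.frame view of a network summary, for CSV export
summary_table <- function(x) {
  do.call(rbind, lapply(x$communities, function(cm) {
    data.frame(community = cm$community, n_nodes = cm$n_nodes,
               share_pct = cm$share_pct, rank = seq_len(nrow(cm$top)),
               concept_id = cm$top$concept_id, degree = cm$top$degree,
               substance_class = cm$top$substance_class,
               stringsAsFactors = FALSE)
  }))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Export the graph for external visualisation
#'
#' Writes GEXF 1.2 or GraphML with node attributes `label`, `community`
#' and `degree` and edge attribute `weight`. Node and edge ordering is
#' sorted by id, so identical inputs produce byte-identical files.
#'
#' @param graph an igraph graph.
#' @param partition optional `substance_partition`; when omitted all nodes
#'   get community 0.
#' @param path output path.
#' @param format `"gexf"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, partition = NULL, path,
                         format = c("gexf", "graphml")) {
  format <- match.arg(format)
  ids <- igraph::V(graph)$name
  ord <- order(ids)
  labels <- igraph::V(graph)$label
  if (is.null(labels)) labels <- ids
  mem <- if (!is.null(partition)) partition$membership[ids] else
    stats::setNames(rep(0L, length(ids)), ids)
  deg <- degree_centrality(graph)
  el <- igraph::as_edgelist(graph, names = TRUE)
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  flip <- el[, 1] > el[, 2]
  tmp <- el[flip, 1]; el[flip, 1] <- el[flip, 2]; el[flip, 2] <- tmp
  eord <- order(el[, 1], el[, 2])
  el <- el[eord, , drop = FALSE]; w <- w[eord]
  wfmt <- function(v) sub("\\.?0+$", "", sprintf("%.10f", v))
  lines <- character(0)
  if (format == "gexf") {
    lines <- c(lines,
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<gexf xmlns=\"http://www.gexf.net/1.2draft\" version=\"1.2\">",
      "  <graph mode=\"static\" defaultedgetype=\"undirected\">",
      "    <attributes class=\"node\">",
      "      <attribute id=\"0\" title=\"community\" type=\"integer\"/>",
      "      <attribute id=\"1\" title=\"degree\" type=\"integer\"/>",
      "    </attributes>",
      "    <nodes>")
    for (i in ord) {
      lines <- c(lines, sprintf(
        "      <node id=\"%s\" label=\"%s\"><attvalues><attvalue for=\"0\" value=\"%d\"/><attvalue for=\"1\" value=\"%d\"/></attvalues></node>",
        xml_escape(ids[i]), xml_escape(labels[i]),
        as.integer(mem[ids[i]]), as.integer(deg[ids[i]])))
    }
    lines <- c(lines, "    </nodes>", "    <edges>")
    if (nrow(el) > 0) {
      for (r in seq_len(nrow(el))) {
        lines <- c(lines, sprintf(
          "      <edge id=\"%d\" source=\"%s\" target=\"%s\" weight=\"%s\"/>",
          r - 1L, xml_escape(el[r, 1]), xml_escape(el[r, 2]), wfmt(w[r])))
      }
    }
    lines <- c(lines, "    </edges>", "  </graph>", "</gexf>")
  } else {
    lines <- c(lines,
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
      "  <key id=\"label\" for=\"node\" attr.name=\"label\" attr.type=\"string\"/>",
      "  <key id=\"community\" for=\"node\" attr.name=\"community\" attr.type=\"int\"/>",
      "  <key id=\"degree\" for=\"node\" attr.name=\"degree\" attr.type=\"int\"/>",
      "  <key id=\"weight\" for=\"edge\" attr.name=\"weight\" attr.type=\"double\"/>",
      "  <graph id=\"G\" edgedefault=\"undirected\">")
    for (i in ord) {
      lines <- c(lines, sprintf(
        "    <node id=\"%s\"><data key=\"label\">%s</data><data key=\"community\">%d</data><data key=\"degree\">%d</data></node>",
        xml_escape(ids[i]), xml_escape(labels[i]),
        as.integer(mem[ids[i]]), as.integer(deg[ids[i]])))
    }
    if (nrow(el) > 0) {
      for (r in seq_len(nrow(el))) {
        lines <- c(lines, sprintf(
          "    <edge source=\"%s\" target=\"%s\"><data key=\"weight\">%s</data></edge>",
          xml_escape(el[r, 1]), xml_escape(el[r, 2]), wfmt(w[r])))
      }
    }
    lines <- c(lines, "  </graph>", "</graphml>")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
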