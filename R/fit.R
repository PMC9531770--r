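#' Fit a substance co-mention network to a corpus
#'
#' The package's high-level entry point: runs extraction, co-occurrence
#' counting, PPMI filtering, graph construction and Leiden community
#' detection on an (already flair-filtered) corpus, and returns one
#' object holding every intermediate product. This is the programmatic
#' analogue of the full study workflow; [run_pipeline()] wraps it with
#' file input/output.
#'
#' @param x a [corpus] of analyzed posts.
#' @param lex a [lexicon]; default [default_lexicon()].
#' @param rules a [negation_rules] object.
#' @param link_threshold fuzzy entity-linking threshold (default 0.85).
#' @param min_count minimum post-level substance frequency (default 10).
#' @param resolution Leiden resolution gamma (default 0.6).
#' @param seed RNG seed for community detection (default 42).
#' @param exclusions concept ids to drop from the graph (known
#'   false-positive nodes).
#' @param top_k substances listed per community in summaries.
#' @return An object of class `substance_network` with components
#'   `mentions`, `mention_table`, `frequencies`, `pairs`, `ppmi`
#'   (post-filter), `graph`, `partition`, `summary` and `call` metadata.
#' @examples
#' \donttest{
#' lex <- generate_lexicon(generator_config(n_posts = 300))
#' syn <- generate_corpus(generator_config(n_posts = 300), lex)
#' kept <- filter_by_flair(syn$corpus)
#' fit <- substance_network(kept, lex, min_count = 5)
#' print(fit)
#' }
#' @export
substance_network <- function(x, lex = default_lexicon(),
                              rules = default_negation_rules(),
                              link_threshold = 0.85, min_count = 10L,
                              resolution = 0.6, seed = 42L,
                              exclusions = character(), top_k = 10L) {
  stopifnot(inherits(x, "corpus"))
  mentions <- extract_corpus(x, lex, rules, link_threshold)
  active <- mentions[!mentions$negated, , drop = FALSE]
  mt <- build_mention_table(x, active)
  freq <- count_frequencies(mt)
  pairs <- count_pairs(mt)
  retained <- frequency_filter(freq, min_count)
  # an empty corpus has no pairs; keep the degenerate run total
  ppmi <- compute_ppmi(pairs, freq, max(mt$n_posts, 1L), retained)
  ppmi <- mean_weight_filter(ppmi)
  graph <- build_graph(ppmi, exclusions = exclusions, lex = lex)
  partition <- leiden(graph, resolution = resolution, seed = seed)
  summ <- cluster_summary(graph, partition, lex, k = top_k)
  structure(list(mentions = mentions, mention_table = mt,
                 frequencies = freq, pairs = pairs, ppmi = ppmi,
                 graph = graph, partition = partition, summary = summ,
                 params = list(link_threshold = link_threshold,
                               min_count = min_count,
                               resolution = resolution, seed = seed,
                               exclusions = exclusions, top_k = top_k)),
            class = "substance_network")
}

#' @export
print.substance_network <- function(x, ...) {
  cat("Substance co-mention network\n")
  cat(sprintf("  posts analyzed: %d (%d with substances)\n",
              x$mention_table$n_posts,
              length(unique(x$mention_table$rows$post_id))))
  cat(sprintf("  mentions: %d (%d negated, excluded)\n",
              nrow(x$mentions), sum(x$mentions$negated)))
  cat(sprintf("  network: %d nodes, %d edges after PPMI filters\n",
              x$summary$n_nodes, x$summary$n_edges))
  cat(sprintf("  communities: %d, Q = %.3f (detected at gamma = %g)\n",
              x$partition$n_communities, x$partition$modularity,
              x$partition$resolution))
  invisible(x)
}

#' @export
summary.substance_network <- function(object, ...) {
  object$summary
}

#' @export
plot.substance_network <- function(x, ...) {
  g <- x$graph
  if (igraph::vcount(g) == 0) {
    warning("empty network; nothing to plot")
    return(invisible(NULL))
  }
  mem <- x$partition$membership[igraph::V(g)$name]
  deg <- degree_centrality(g)
  igraph::plot.igraph(
    g,
    vertex.color = mem + 1L,
    vertex.size = 3 + 12 * deg / max(1L, max(deg)),
    vertex.label = igraph::V(g)$label,
    vertex.label.cex = 0.6,
    edge.width = 0.5 + igraph::E(g)$weight,
    ...)
  invisible(x)
}
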