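#' Pipeline configuration
#'
#' All tunables of the end-to-end run in one place. Every study constant
#' is a named key, never hard-coded: the 0.85 linking threshold, the
#' minimum substance frequency 10, the Leiden resolution 0.6 and the
#' top-10 report length are the defaults.
#'
#' @param corpus path to a JSONL post dump (or `NULL` when a corpus
#'   object is passed to [run_pipeline()] directly).
#' @param out_dir output directory.
#' @param lexicon,brands,stops paths for [load_lexicon()]; `NULL` uses
#'   the packaged default lexicon.
#' @param negation path for [load_negation_rules()]; `NULL` uses the
#'   packaged triggers.
#' @param exclusions path to a plain-text list of concept ids to drop
#'   from the graph (one per line), or a character vector.
#' @param excluded_flairs flair tags to exclude.
#' @param drop_untagged drop posts without a flair?
#' @param link_threshold,min_count,resolution,top_k,seed study tunables.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(corpus = NULL, out_dir = "ppminet_out",
                            lexicon = NULL, brands = NULL, stops = NULL,
                            negation = NULL, exclusions = character(),
                            excluded_flairs = default_excluded_flairs(),
                            drop_untagged = TRUE, link_threshold = 0.85,
                            min_count = 10L, resolution = 0.6,
                            top_k = 10L, seed = 42L) {
  abort_if(link_threshold <= 0 || link_threshold > 1,
           "link_threshold must be in (0, 1]")
  abort_if(min_count < 1, "min_count must be >= 1")
  abort_if(resolution <= 0, "resolution must be positive")
  abort_if(top_k < 1, "top_k must be >= 1")
  structure(list(corpus = corpus, out_dir = out_dir, lexicon = lexicon,
                 brands = brands, stops = stops, negation = negation,
                 exclusions = exclusions,
                 excluded_flairs = excluded_flairs,
                 drop_untagged = isTRUE(drop_untagged),
                 link_threshold = link_threshold,
                 min_count = as.integer(min_count),
                 resolution = resolution, top_k = as.integer(top_k),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  abort_if(!file.exists(path), "no such config file: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  abort_if(length(unknown) > 0, "unknown config keys: %s",
           paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

config_lexicon <- function(config) {
  if (is.null(config$lexicon)) default_lexicon() else
    load_lexicon(config$lexicon, config$brands, config$stops)
}

config_rules <- function(config) {
  if (is.null(config$negation)) default_negation_rules() else
    load_negation_rules(config$negation)
}

config_exclusions <- function(config) {
  x <- config$exclusions
  if (length(x) == 1 && file.exists(x)) {
    lines <- trimws(sub("#.*$", "", readLines(x, warn = FALSE)))
    lines[nzchar(lines)]
  } else {
    as.character(x)
  }
}

#' Run the end-to-end pipeline
#'
#' Ingestion, flair filtering, extraction, co-occurrence, PPMI filtering,
#' community detection and reporting in one deterministic run. Writes to
#' `config$out_dir`:
#' \describe{
#'   \item{frequencies.csv}{post-level substance frequencies}
#'   \item{top_pairs.csv}{most frequent co-occurrence pairs}
#'   \item{cluster_summary.csv / cluster_summary.json}{per-community
#'     shares and top-k substances by degree centrality}
#'   \item{network.gexf / network.graphml}{the graph with community,
#'     degree and weight attributes}
#'   \item{mentions.tsv / negated_mentions.tsv}{the extraction audit}
#'   \item{manifest.json}{all counts, per-stage, plus the exact config}
#' }
#' Outputs are byte-identical across runs with the same config and seed.
#' On any stage failure the partial outputs are removed.
#'
#' @param config a [pipeline_config()] or path to its YAML form.
#' @param corpus optional [corpus] object, bypassing `config$corpus`.
#' @return The run manifest (named list), invisibly; also written as
#'   JSON.
#' @export
run_pipeline <- function(config, corpus = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  outputs <- file.path(out, c("frequencies.csv", "top_pairs.csv",
                              "cluster_summary.csv", "cluster_summary.json",
                              "network.gexf", "network.graphml",
                              "mentions.tsv", "negated_mentions.tsv",
                              "manifest.json"))
  ok <- FALSE
  on.exit(if (!ok) unlink(outputs))
  stage <- "ingest"
  manifest <- tryCatch({
    raw <- if (!is.null(corpus)) corpus else read_posts(config$corpus)
    stage <- "filter"
    kept <- filter_by_flair(raw, config$excluded_flairs,
                            config$drop_untagged)
    stage <- "analysis"
    lex <- config_lexicon(config)
    fit <- substance_network(
      kept, lex, config_rules(config),
      link_threshold = config$link_threshold,
      min_count = config$min_count, resolution = config$resolution,
      seed = config$seed, exclusions = config_exclusions(config),
      top_k = config$top_k)
    stage <- "report"
    write_pipeline_outputs(fit, lex, out, config,
                           kept$meta$flair_filter)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  ok <- TRUE
  invisible(manifest)
}

write_pipeline_outputs <- function(fit, lex, out, config, flair_counts) {
  freq_df <- data.frame(concept_id = names(fit$frequencies),
                        count = unname(fit$frequencies),
                        stringsAsFactors = FALSE)
  freq_df <- freq_df[order(-freq_df$count, freq_df$concept_id), ,
                     drop = FALSE]
  utils::write.csv(freq_df, file.path(out, "frequencies.csv"),
                   row.names = FALSE)
  tp <- if (nrow(fit$pairs) > 0) top_pairs(fit$pairs, config$top_k) else
    fit$pairs
  utils::write.csv(tp, file.path(out, "top_pairs.csv"), row.names = FALSE)
  st <- if (fit$summary$n_nodes > 0) summary_table(fit$summary) else
    data.frame(community = integer(), n_nodes = integer(),
               share_pct = numeric(), rank = integer(),
               concept_id = character(), degree = integer(),
               substance_class = character(), stringsAsFactors = FALSE)
  utils::write.csv(st, file.path(out, "cluster_summary.csv"),
                   row.names = FALSE)
  summ <- fit$summary
  jsonlite::write_json(
    list(n_nodes = summ$n_nodes, n_edges = summ$n_edges,
         modularity = summ$modularity, resolution = summ$resolution,
         avg_clustering = summ$avg_clustering,
         communities = lapply(summ$communities, function(cm) {
           list(community = cm$community, n_nodes = cm$n_nodes,
                share_pct = cm$share_pct, top = cm$top)
         })),
    file.path(out, "cluster_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  export_graph(fit$graph, fit$partition, file.path(out, "network.gexf"),
               "gexf")
  export_graph(fit$graph, fit$partition, file.path(out, "network.graphml"),
               "graphml")
  men <- fit$mentions
  utils::write.table(men[!men$negated, , drop = FALSE],
                     file.path(out, "mentions.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(men[men$negated, , drop = FALSE],
                     file.path(out, "negated_mentions.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  mt <- fit$mention_table
  manifest <- list(
    config = config[setdiff(names(config), "out_dir")],
    posts_in = flair_counts$n_in,
    posts_removed_excluded_flair = flair_counts$removed_excluded,
    posts_removed_untagged = flair_counts$removed_untagged,
    posts_analyzed = mt$n_posts,
    posts_with_substances = length(unique(mt$rows$post_id)),
    mentions_total = nrow(men),
    mentions_negated = sum(men$negated),
    entities_after_dedup = nrow(mt$rows),
    concepts_observed = length(fit$frequencies),
    concepts_retained = length(attr(fit$ppmi, "retained")),
    pairs_observed = nrow(fit$pairs),
    edges_after_filters = nrow(fit$ppmi),
    n_nodes = summ$n_nodes, n_edges = summ$n_edges,
    n_communities = fit$partition$n_communities,
    modularity = fit$partition$modularity,
    leiden_objective = fit$partition$quality,
    avg_clustering = summ$avg_clustering)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  manifest
}

#' Sweep the Leiden resolution
#'
#' Runs community detection once per resolution value on the same graph
#' and seed, reporting the number of communities and modularity per
#' gamma — the tool for the iterative resolution selection the method
#' calls for, without choosing for the user.
#'
#' @param fit a [substance_network()] object (the graph is reused).
#' @param gammas non-empty numeric vector of resolutions; duplicates are
#'   kept (with a warning).
#' @param seed RNG seed shared by all runs.
#' @return data.frame with columns `gamma`, `n_communities`, `quality`.
#' @export
resolution_sweep <- function(fit, gammas, seed = 42L) {
  stopifnot(inherits(fit, "substance_network"))
  abort_if(length(gammas) == 0, "gammas must be non-empty")
  if (anyDuplicated(gammas)) warning("duplicate gamma values in sweep")
  rows <- lapply(gammas, function(g) {
    p <- leiden(fit$graph, resolution = g, seed = seed)
    data.frame(gamma = g, n_communities = p$n_communities,
               quality = p$quality, modularity = p$modularity)
  })
  do.call(rbind, rows)
}
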