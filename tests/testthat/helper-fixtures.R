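# Shared fixtures, built in code.

# minimal in-code lexicon: three drugs, a group term, a brand, a stop term
tiny_lexicon <- function() {
  concepts <- data.frame(
    concept_id = c("aspirin", "famotidine", "magnesium", "vitamins"),
    canonical_name = c("aspirin", "famotidine", "magnesium", "vitamins"),
    substance_class = c("nsaid", "antihistamine", "mineral", "vitamin"),
    synonyms = c("acetylsalicylic acid", "", "magnesium glycinate",
                 "vitamin"),
    stringsAsFactors = FALSE)
  lexicon(concepts,
          brand_map = c(pepcid = "famotidine"),
          stop_terms = "ethanol")
}

# corpus from bodies (+ optional flairs), ids p1, p2, ...
make_corpus <- function(bodies, flairs = rep("Symptoms", length(bodies))) {
  corpus(data.frame(
    post_id = sprintf("p%d", seq_along(bodies)),
    author_id = sprintf("u%d", seq_along(bodies)),
    created_utc = seq_along(bodies),
    flair = flairs,
    body = bodies,
    stringsAsFactors = FALSE))
}

# mention table straight from per-post concept sets (no text involved)
mention_table_from_sets <- function(sets, n_posts = length(sets)) {
  ids <- sprintf("p%03d", seq_along(sets))
  rows <- data.frame(
    post_id = rep(ids, lengths(sets)),
    concept_id = unlist(sets, use.names = FALSE),
    stringsAsFactors = FALSE)
  x <- make_corpus(rep("", n_posts))
  x$posts$post_id <- sprintf("p%03d", seq_len(n_posts))
  build_mention_table(x, rows)
}

# independent PPMI oracle: naive per-post double loop, no shared code with
# compute_ppmi / count_* (set algebra only)
naive_ppmi_oracle <- function(sets, n_posts, min_count) {
  all_concepts <- sort(unique(unlist(sets)))
  c_x <- vapply(all_concepts, function(cc) {
    sum(vapply(sets, function(s) cc %in% s, logical(1)))
  }, numeric(1))
  retained <- all_concepts[c_x >= min_count]
  out <- list()
  for (i in seq_along(retained)) {
    for (j in seq_along(retained)) {
      if (j <= i) next
      a <- retained[i]; b <- retained[j]
      c_ab <- 0
      for (s in sets) if ((a %in% s) && (b %in% s)) c_ab <- c_ab + 1
      if (c_ab == 0) next
      pmi <- log2((c_ab * n_posts) / (c_x[[a]] * c_x[[b]]))
      if (pmi > 0) out[[paste(a, b)]] <- pmi
    }
  }
  out
}

# seeded random weighted graph with n named nodes, p edge prob
random_test_graph <- function(n, p = 0.45) {
  nm <- sprintf("v%02d", seq_len(n))
  repeat {
    m <- matrix(stats::runif(n * n) < p, n, n)
    m[lower.tri(m, diag = TRUE)] <- FALSE
    if (sum(m) > 0) break
  }
  el <- which(m, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = nm[el[, 1]], to = nm[el[, 2]]),
    directed = FALSE,
    vertices = data.frame(name = nm))
  igraph::E(g)$weight <- round(stats::runif(igraph::ecount(g), 0.2, 2), 3)
  igraph::delete_vertices(g, which(igraph::degree(g) == 0))
}

# two unit-weight triangles joined by one bridge edge; optimum is the
# two-triangle split with Q = 5/14 at gamma = 1
bridged_triangles <- function() {
  g <- igraph::make_graph(~ a - b, a - c, b - c, d - e, d - f, e - f, c - d)
  igraph::E(g)$weight <- 1
  g
}

toy_corpus_path <- function() {
  system.file("extdata", "toy_posts.jsonl", package = "ppminet")
}
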