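#' Synthetic corpus generator configuration
#'
#' Describes a Reddit-like corpus with planted substance-cluster
#' structure: each post is attributed to one of `K` latent medication
#' strategies (clusters) and mentions each of that cluster's substances
#' independently with probability `p_in` and every other substance with
#' `p_out`; `p_in > p_out` plants co-mention enrichment the pipeline
#' should recover, `p_in = p_out` is the independence null it should not
#' hallucinate structure from. Mentions are rendered through canonical,
#' synonym, brand or out-of-lexicon (slang) surfaces, optionally negated,
#' and embedded in filler text with hyperlink/tab noise and flair tags
#' (some excludable) mirroring real subreddit dumps.
#'
#' The defaults are the reference study conditions used throughout the
#' package's own validation: 5000 posts over 3 clusters of 15 substances
#' with `p_in = 0.25`, `p_out = 0.01`.
#'
#' @param seed integer RNG seed (drives lexicon and corpus generation).
#' @param n_posts number of posts.
#' @param n_users number of distinct authors.
#' @param K number of planted clusters.
#' @param substances_per_cluster substances per cluster (>= 1).
#' @param n_background substances outside any cluster.
#' @param p_in,p_out per-substance mention probabilities (p_in >= p_out).
#' @param lambda_filler Poisson mean of filler tokens per sentence.
#' @param negation_rate fraction of mentions wrapped in a negation trigger.
#' @param brand_rate fraction rendered as brand surfaces.
#' @param synonym_rate fraction rendered as non-canonical synonyms.
#' @param oov_rate fraction rendered as out-of-lexicon slang (guaranteed
#'   recall failures).
#' @param excluded_flair_rate fraction of posts given an excludable flair.
#' @param untagged_rate fraction of posts with no flair.
#' @param url_rate,tab_rate text-noise injection probabilities.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 42L, n_posts = 5000L, n_users = 640L,
                             K = 3L, substances_per_cluster = 15L,
                             n_background = 5L, p_in = 0.25, p_out = 0.01,
                             lambda_filler = 8, negation_rate = 0.05,
                             brand_rate = 0.10, synonym_rate = 0.15,
                             oov_rate = 0, excluded_flair_rate = 0.10,
                             untagged_rate = 0.10, url_rate = 0.10,
                             tab_rate = 0.05) {
  cfg <- list(seed = as.integer(seed), n_posts = as.integer(n_posts),
              n_users = as.integer(n_users), K = as.integer(K),
              substances_per_cluster = as.integer(substances_per_cluster),
              n_background = as.integer(n_background),
              p_in = p_in, p_out = p_out, lambda_filler = lambda_filler,
              negation_rate = negation_rate, brand_rate = brand_rate,
              synonym_rate = synonym_rate, oov_rate = oov_rate,
              excluded_flair_rate = excluded_flair_rate,
              untagged_rate = untagged_rate, url_rate = url_rate,
              tab_rate = tab_rate)
  probs <- cfg[c("p_in", "p_out", "negation_rate", "brand_rate",
                 "synonym_rate", "oov_rate", "excluded_flair_rate",
                 "untagged_rate", "url_rate", "tab_rate")]
  abort_if(any(unlist(probs) < 0 | unlist(probs) > 1),
           "all rates must lie in [0, 1]")
  abort_if(cfg$K < 1, "K must be >= 1")
  abort_if(cfg$substances_per_cluster < 1,
           "substances_per_cluster must be >= 1")
  abort_if(cfg$n_background < 0, "n_background must be >= 0")
  abort_if(cfg$p_in < cfg$p_out, "p_in must be >= p_out")
  abort_if(cfg$n_posts < 0 || cfg$n_users < 1, "invalid corpus size")
  abort_if(cfg$excluded_flair_rate + cfg$untagged_rate > 1,
           "flair rates must sum to <= 1")
  structure(cfg, class = "generator_config")
}

# neutral filler vocabulary; curated to contain no negation triggers and
# nothing a 0.85-threshold linker could confuse with a generated substance
# name (enforced again at generation time)
filler_words <- function() {
  c("really", "helped", "today", "morning", "week", "months", "symptoms",
    "feeling", "better", "worse", "tried", "taking", "started", "daily",
    "doctor", "advice", "anyone", "else", "same", "issue", "fatigue",
    "brain", "fog", "heart", "rate", "sleep", "energy", "slowly",
    "improving", "update", "still", "struggling", "crash", "after",
    "exercise", "pacing", "helps", "somewhat", "noticed", "difference",
    "within", "days", "dose", "small", "large", "evening", "before",
    "breakfast", "dinner", "routine", "keeping", "journal", "track",
    "progress", "thanks", "everyone", "support", "community", "hope",
    "recovery", "soon", "hang", "there", "friends", "family", "work",
    "remote", "slowly", "walking", "minutes", "gentle", "stretching")
}

kept_flairs <- function() {
  c("Symptoms", "Question", "Vent", "Recovery", "Update", "Personal Story")
}

excludable_flairs <- function() {
  c("Humor", "Article", "Research Article")
}

# pronounceable CV-syllable name, e.g. "radebuso"
random_name <- function(n_syllables) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  paste0(paste0(sample(cons, n_syllables, replace = TRUE),
                sample(vow, n_syllables, replace = TRUE)), collapse = "")
}

# a fresh surface far (in similarity) from everything already taken
fresh_surface <- function(taken, threshold = 0.80, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    cand <- random_name(sample(3:5, 1))
    if (cand %in% taken) next
    ok <- TRUE
    for (t in taken) {
      if (similarity_possible(nchar(cand), nchar(t), threshold) &&
          jaro_winkler(cand, t) >= threshold) { ok <- FALSE; break }
    }
    if (ok) return(cand)
  }
  stop("could not generate a sufficiently distinct surface", call. = FALSE)
}

#' Generate a synthetic substance lexicon
#'
#' `K * substances_per_cluster + n_background` concepts with two synonyms
#' each (canonical plus one alternative surface) and a brand name for
#' every third concept. All surfaces are generated pronounceable names
#' kept mutually dissimilar (Jaro-Winkler < 0.80 across concepts, also
#' against the filler vocabulary), so exact matching is unambiguous and
#' fuzzy linking cannot cross concepts. Deterministic under
#' `config$seed`.
#'
#' @param config a [generator_config()].
#' @return A [lexicon]; concept ids are `s01 ...` in cluster order
#'   (background concepts last).
#' @export
generate_lexicon <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n_concepts <- config$K * config$substances_per_cluster + config$n_background
  classes <- c("nutritional supplements", "histamine antagonists",
               "steroids", "antidepressants", "minerals", "vitamins",
               "beta blockers", "analgesics")
  with_seed(config$seed, {
    taken <- filler_words()
    rows <- vector("list", n_concepts)
    brand_map <- character(0)
    for (i in seq_len(n_concepts)) {
      canonical <- fresh_surface(taken); taken <- c(taken, canonical)
      alt <- fresh_surface(taken); taken <- c(taken, alt)
      cid <- sprintf("s%02d_%s", i, canonical)
      rows[[i]] <- data.frame(
        concept_id = cid, canonical_name = canonical,
        substance_class = classes[(i - 1L) %% length(classes) + 1L],
        synonyms = paste(c(canonical, alt), collapse = "|"),
        stringsAsFactors = FALSE)
      if (i %% 3L == 1L) {
        brand <- fresh_surface(taken); taken <- c(taken, brand)
        brand_map[brand] <- cid
      }
    }
    lexicon(do.call(rbind, rows), brand_map = brand_map,
            stop_terms = character(0))
  })
}

# corrupt a surface beyond the fuzzy-linking radius: random edits until the
# matcher finds nothing in it (the "benzos" lexical-error mechanism)
corrupt_surface <- function(surface, lex, threshold, max_tries = 50L) {
  letters_pool <- letters
  for (i in seq_len(max_tries)) {
    chars <- strsplit(surface, "")[[1]]
    n_edits <- sample(2:4, 1)
    for (e in seq_len(n_edits)) {
      pos <- sample(length(chars), 1)
      op <- sample(c("sub", "del", "ins"), 1)
      if (op == "sub") chars[pos] <- sample(letters_pool, 1)
      else if (op == "del" && length(chars) > 4) chars <- chars[-pos]
      else chars <- append(chars, sample(letters_pool, 1), after = pos)
    }
    cand <- paste(chars, collapse = "")
    if (nchar(cand) >= 4 &&
        nrow(match_entities(cand, lex, threshold)) == 0) {
      return(cand)
    }
  }
  stop("could not corrupt surface beyond the linking radius", call. = FALSE)
}

#' Generate a synthetic corpus with gold annotations
#'
#' Draws posts under the planted-cluster model of [generator_config()],
#' renders mentions through the configured surface channels, injects
#' negations, filler text, hyperlinks, tabs, blank lines and flair tags,
#' and returns the corpus together with gold span annotations and the
#' planted community labels. Gold spans are 0-based half-open offsets on
#' the *cleaned* body and only cover posts that survive the default flair
#' filter (extraction is defined on the analyzed corpus).
#'
#' @param config a [generator_config()].
#' @param lex the [generate_lexicon()] output for the same config.
#' @return An object of class `synthetic_corpus`: list with `corpus`,
#'   `gold_mentions` (in-lexicon, non-negated), `gold_oov` (slang-rendered,
#'   non-negated; guaranteed extraction misses), `gold_negated`,
#'   `true_communities` (concept id -> planted cluster, background
#'   excluded) and `config`.
#' @export
generate_corpus <- function(config, lex) {
  stopifnot(inherits(config, "generator_config"), inherits(lex, "lexicon"))
  n_cluster_sub <- config$K * config$substances_per_cluster
  n_concepts <- n_cluster_sub + config$n_background
  abort_if(nrow(lex$concepts) < n_concepts,
           "lexicon too small for config (%d < %d)",
           nrow(lex$concepts), n_concepts)
  cids <- lex$concepts$concept_id[seq_len(n_concepts)]
  cluster_of <- c(rep(seq_len(config$K), each = config$substances_per_cluster),
                  rep(NA_integer_, config$n_background))
  brand_of <- stats::setNames(rep(NA_character_, n_concepts), cids)
  for (b in names(lex$brand_map)) {
    tgt <- lex$brand_map[[b]]
    if (tgt %in% cids && is.na(brand_of[tgt])) brand_of[tgt] <- b
  }
  synonyms_of <- stats::setNames(
    lex$concepts$synonyms[seq_len(n_concepts)], cids)
  canonical_of <- stats::setNames(
    lex$concepts$canonical_name[seq_len(n_concepts)], cids)
  fillers <- filler_words()
  pre_triggers <- c("no", "not", "never", "without", "stopped taking")

  with_seed(config$seed + 1L, {
    np <- config$n_posts
    p_id <- character(np); p_author <- character(np)
    p_flair <- character(np); p_body <- character(np)
    gold <- list(); oov <- list(); neg <- list()
    for (i in seq_len(config$n_posts)) {
      pid <- sprintf("p%06d", i)
      z <- sample.int(config$K, 1)
      p_vec <- ifelse(!is.na(cluster_of) & cluster_of == z,
                      config$p_in, config$p_out)
      chosen <- cids[stats::runif(n_concepts) < p_vec]
      if (length(chosen) > 1) chosen <- sample(chosen)
      # flair channel
      u <- stats::runif(1)
      flair <- if (u < config$excluded_flair_rate) {
        sample(excludable_flairs(), 1)
      } else if (u < config$excluded_flair_rate + config$untagged_rate) {
        NA_character_
      } else {
        sample(kept_flairs(), 1)
      }
      analyzed <- !is.na(flair) && !(norm_surface(flair) %in%
                                       norm_surface(excludable_flairs()))
      # sentences: one leading filler sentence, then one per mention
      sentences <- list(sample(fillers, 1 + stats::rpois(1, 2), replace = TRUE))
      mention_info <- list()
      for (cid in chosen) {
        negated <- stats::runif(1) < config$negation_rate
        r <- stats::runif(1)
        kind <- if (r < config$oov_rate) "oov"
        else if (r < config$oov_rate + config$brand_rate &&
                 !is.na(brand_of[cid])) "brand"
        else if (r < config$oov_rate + config$brand_rate +
                 config$synonym_rate) "synonym"
        else "canonical"
        surface <- switch(kind,
          canonical = canonical_of[[cid]],
          synonym = {
            syn <- setdiff(synonyms_of[[cid]], canonical_of[[cid]])
            if (length(syn) == 0) canonical_of[[cid]] else sample(syn, 1)
          },
          brand = brand_of[[cid]],
          oov = corrupt_surface(canonical_of[[cid]], lex, 0.85))
        toks <- character(0)
        if (negated) toks <- strsplit(sample(pre_triggers, 1), " ")[[1]]
        surface_idx <- length(toks) + 1L
        toks <- c(toks, surface,
                  sample(fillers, stats::rpois(1, config$lambda_filler),
                         replace = TRUE))
        sentences[[length(sentences) + 1L]] <- toks
        mention_info[[length(mention_info) + 1L]] <-
          list(sentence = length(sentences), idx = surface_idx,
               cid = cid, surface = surface, negated = negated, kind = kind)
      }
      # assemble the clean body and record spans
      body_parts <- character(length(sentences))
      offsets <- integer(length(sentences))
      off <- 0L
      for (s in seq_along(sentences)) {
        sent <- paste0(paste(sentences[[s]], collapse = " "), ".")
        body_parts[s] <- sent
        offsets[s] <- off
        off <- off + nchar(sent) + 1L  # joining space
      }
      body_clean <- paste(body_parts, collapse = " ")
      for (mi in mention_info) {
        toks <- sentences[[mi$sentence]]
        rel <- if (mi$idx == 1) 0L else
          sum(nchar(toks[seq_len(mi$idx - 1)])) + (mi$idx - 1L)
        start <- offsets[mi$sentence] + rel
        row <- list(post_id = pid, start = start,
                    end = start + nchar(mi$surface),
                    concept_id = mi$cid, surface = mi$surface)
        if (mi$negated) {
          neg[[length(neg) + 1L]] <- row
        } else if (analyzed) {
          if (mi$kind == "oov") oov[[length(oov) + 1L]] <- row
          else gold[[length(gold) + 1L]] <- row
        }
      }
      # raw body: inject removable noise (clean_text() restores body_clean)
      body <- body_clean
      if (stats::runif(1) < config$url_rate) {
        body <- sub(" ", sprintf(" https://redd.it/%s ", pid), body, fixed = TRUE)
      }
      if (stats::runif(1) < config$tab_rate && grepl(" ", body, fixed = TRUE)) {
        sp <- gregexpr(" ", body, fixed = TRUE)[[1]]
        at <- sp[sample(length(sp), 1)]
        substr(body, at, at) <- "\t"
      }
      if (stats::runif(1) < 0.2) body <- paste0(body, "\n\n")
      p_id[i] <- pid
      p_author[i] <- sprintf("u%04d", sample.int(config$n_users, 1))
      p_flair[i] <- flair
      p_body[i] <- body
    }
    bindg <- function(l) {
      pull <- function(f, cast) cast(unlist(lapply(l, `[[`, f),
                                            use.names = FALSE))
      data.frame(
        post_id = pull("post_id", as.character),
        start = pull("start", as.integer),
        end = pull("end", as.integer),
        concept_id = pull("concept_id", as.character),
        surface = pull("surface", as.character),
        stringsAsFactors = FALSE)
    }
    posts_df <- data.frame(post_id = p_id, author_id = p_author,
                           created_utc = 1598832000 + seq_len(np) * 60,
                           flair = p_flair, body = p_body,
                           stringsAsFactors = FALSE)
    if (np == 0) posts_df$created_utc <- numeric(0)
    truth <- stats::setNames(cluster_of[!is.na(cluster_of)],
                             cids[!is.na(cluster_of)])
    structure(list(corpus = corpus(posts_df, meta = list(source = "synthetic")),
                   gold_mentions = bindg(gold), gold_oov = bindg(oov),
                   gold_negated = bindg(neg), true_communities = truth,
                   config = config),
              class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus> %d posts, %d gold mentions (+%d oov, +%d negated), K=%d\n",
              nrow(x$corpus$posts), nrow(x$gold_mentions), nrow(x$gold_oov),
              nrow(x$gold_negated), x$config$K))
  invisible(x)
}

#' Closed-form expectations of the planted structure
#'
#' The binomial expectations the generator's draws should satisfy, used
#' as independent assertions in tests: per-substance post frequencies and
#' within/between-cluster pair probabilities, plus the implied PMI at the
#' expected counts. With `p_in = p_out` every joint probability
#' factorizes and the expected PMI is 0 for all pairs; with `p_out = 0`
#' the expected between-cluster pair count is 0. Expectations refer to
#' drawn mentions (before the negation/OOV rendering channels).
#'
#' @param config a [generator_config()].
#' @return list of expectations.
#' @export
expected_structure_report <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  K <- config$K; p_in <- config$p_in; p_out <- config$p_out
  n <- config$n_posts
  p_x_cluster <- (p_in + (K - 1) * p_out) / K
  p_pair_within <- (p_in^2 + (K - 1) * p_out^2) / K
  p_pair_between <- (2 * p_in * p_out + max(K - 2, 0) * p_out^2) / K
  list(
    expected_freq_cluster = n * p_x_cluster,
    sd_freq_cluster = sqrt(n * p_x_cluster * (1 - p_x_cluster)),
    expected_freq_background = n * p_out,
    p_pair_within = p_pair_within,
    p_pair_between = p_pair_between,
    expected_pairs_within = n * p_pair_within,
    expected_pairs_between = n * p_pair_between,
    expected_pmi_within = if (p_pair_within > 0)
      log2(p_pair_within / p_x_cluster^2) else -Inf,
    expected_pmi_between = if (p_pair_between > 0)
      log2(p_pair_between / p_x_cluster^2) else -Inf
  )
}

#' Write a synthetic corpus to disk
#'
#' Emits the JSONL post dump [read_posts()] ingests plus gold TSVs and a
#' truth JSON, for use as pipeline input fixtures.
#'
#' @param x a [generate_corpus()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_corpus <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_posts(x$corpus, file.path(dir, "posts.jsonl"))
  utils::write.table(x$gold_mentions, file.path(dir, "gold_mentions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(x$gold_oov, file.path(dir, "gold_oov.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(x$gold_negated, file.path(dir, "gold_negated.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(as.list(x$true_communities),
                       file.path(dir, "true_communities.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
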