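test_that("generated lexicons have the configured size and are seed-deterministic", {
  cfg <- generator_config(seed = 5, K = 3, substances_per_cluster = 5,
                          n_background = 5, n_posts = 10)
  lex <- generate_lexicon(cfg)
  expect_equal(nrow(lex$concepts), 20)
  expect_true(all(lengths(lex$concepts$synonyms) >= 2))
  expect_gte(length(lex$brand_map), 20 %/% 3)
  lex2 <- generate_lexicon(cfg)
  expect_identical(lex$concepts, lex2$concepts)
  expect_identical(lex$brand_map, lex2$brand_map)
  expect_error(generator_config(substances_per_cluster = 0), ">= 1")
})

test_that("generated surfaces cannot cross-link between concepts at 0.85", {
  cfg <- generator_config(seed = 8, K = 2, substances_per_cluster = 6,
                          n_background = 3, n_posts = 10)
  lex <- generate_lexicon(cfg)
  for (i in seq_len(nrow(lex$concepts))) {
    for (syn in lex$concepts$synonyms[[i]]) {
      expect_equal(link_entity(syn, lex), lex$concepts$concept_id[i])
    }
  }
  for (b in names(lex$brand_map)) {
    expect_equal(normalize_brand(b, lex), unname(lex$brand_map[b]))
  }
})

test_that("corpus generation is deterministic and respects degenerate limits", {
  cfg <- generator_config(seed = 21, n_posts = 120, n_users = 30)
  lex <- generate_lexicon(cfg)
  a <- generate_corpus(cfg, lex)
  b <- generate_corpus(cfg, lex)
  expect_identical(a$corpus$posts, b$corpus$posts)
  expect_identical(a$gold_mentions, b$gold_mentions)
  # n_posts = 0: empty corpus, empty gold
  cfg0 <- generator_config(seed = 21, n_posts = 0)
  z <- generate_corpus(cfg0, generate_lexicon(cfg0))
  expect_equal(nrow(z$corpus$posts), 0)
  expect_equal(nrow(z$gold_mentions), 0)
  # p_in = 1, p_out = 0, all channels off: every post mentions exactly its
  # cluster's substances
  cfg1 <- generator_config(seed = 4, n_posts = 30, K = 2,
                           substances_per_cluster = 3, n_background = 0,
                           p_in = 1, p_out = 0, negation_rate = 0,
                           brand_rate = 0, synonym_rate = 0, oov_rate = 0,
                           excluded_flair_rate = 0, untagged_rate = 0)
  lex1 <- generate_lexicon(cfg1)
  syn1 <- generate_corpus(cfg1, lex1)
  truth <- syn1$true_communities
  gold_sets <- split(syn1$gold_mentions$concept_id,
                     syn1$gold_mentions$post_id)
  expect_equal(length(gold_sets), 30)
  for (s in gold_sets) {
    expect_equal(length(s), 3)
    expect_equal(length(unique(truth[s])), 1)   # one full cluster
  }
})

test_that("gold spans slice the cleaned bodies exactly", {
  cfg <- generator_config(seed = 30, n_posts = 80, oov_rate = 0.1)
  lex <- generate_lexicon(cfg)
  syn <- generate_corpus(cfg, lex)
  bodies <- stats::setNames(clean_text(syn$corpus$posts$body),
                            syn$corpus$posts$post_id)
  gold <- rbind(syn$gold_mentions, syn$gold_oov,
                syn$gold_negated[syn$gold_negated$post_id %in%
                                   names(bodies), ])
  expect_gt(nrow(gold), 0)
  for (r in seq_len(nrow(gold))) {
    expect_equal(substring(bodies[[gold$post_id[r]]],
                           gold$start[r] + 1, gold$end[r]),
                 gold$surface[r])
  }
})

test_that("drawn frequencies match the binomial expectation within 4 standard deviations", {
  cfg <- generator_config(seed = 77, n_posts = 6000, K = 3,
                          substances_per_cluster = 5, n_background = 0,
                          p_in = 0.25, p_out = 0, negation_rate = 0,
                          brand_rate = 0, synonym_rate = 0, oov_rate = 0,
                          excluded_flair_rate = 0, untagged_rate = 0)
  lex <- generate_lexicon(cfg)
  syn <- generate_corpus(cfg, lex)
  rep <- expected_structure_report(cfg)
  expect_equal(rep$expected_freq_cluster, 500)     # 6000 * 0.25 / 3
  counts <- table(syn$gold_mentions$concept_id)
  for (cid in names(syn$true_communities)) {
    expect_lt(abs(counts[[cid]] - rep$expected_freq_cluster),
              4 * rep$sd_freq_cluster)
  }
})

test_that("structure expectations obey the closed forms", {
  base <- generator_config(n_posts = 1000, K = 3, p_in = 0.3, p_out = 0)
  expect_equal(expected_structure_report(base)$expected_pairs_between, 0)
  null <- generator_config(n_posts = 1000, K = 3, p_in = 0.2, p_out = 0.2)
  rep <- expected_structure_report(null)
  expect_equal(rep$expected_pmi_within, 0, tolerance = 1e-12)
  expect_equal(rep$expected_pmi_between, 0, tolerance = 1e-12)
  # doubling n doubles counts but leaves expected PMI unchanged
  small <- generator_config(n_posts = 1000, K = 3, p_in = 0.3, p_out = 0.05)
  big <- generator_config(n_posts = 2000, K = 3, p_in = 0.3, p_out = 0.05)
  rs <- expected_structure_report(small); rb <- expected_structure_report(big)
  expect_equal(rb$expected_pairs_within, 2 * rs$expected_pairs_within)
  expect_equal(rb$expected_pmi_within, rs$expected_pmi_within)
})

test_that("extraction reproduces generator gold exactly when all surfaces are in-lexicon", {
  cfg <- generator_config(seed = 61, n_posts = 250, n_users = 60,
                          oov_rate = 0)
  lex <- generate_lexicon(cfg)
  syn <- generate_corpus(cfg, lex)
  kept <- filter_by_flair(syn$corpus)
  men <- extract_corpus(kept, lex)
  pred <- men[!men$negated, c("post_id", "start", "end", "concept_id")]
  res <- evaluate_ner(pred, syn$gold_mentions)
  expect_equal(res$f1, 1.0)
  # negation channel: no gold-negated mention survives extraction
  key <- function(d) paste(d$post_id, d$start, d$end)
  expect_length(intersect(key(pred), key(syn$gold_negated)), 0)
})

test_that("synthetic corpora serialize to the ingestible JSONL dialect", {
  cfg <- generator_config(seed = 14, n_posts = 40)
  lex <- generate_lexicon(cfg)
  syn <- generate_corpus(cfg, lex)
  dir <- withr::local_tempdir()
  write_synthetic_corpus(syn, dir)
  back <- read_posts(file.path(dir, "posts.jsonl"))
  expect_equal(back$posts$post_id, syn$corpus$posts$post_id)
  expect_equal(back$posts$body, syn$corpus$posts$body)
  expect_equal(back$posts$flair, syn$corpus$posts$flair)
  gold <- utils::read.delim(file.path(dir, "gold_mentions.tsv"),
                            stringsAsFactors = FALSE)
  expect_equal(nrow(gold), nrow(syn$gold_mentions))
})
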