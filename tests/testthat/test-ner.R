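test_that("tokenizer lowercases, keeps internal hyphens, maps spans back to text", {
  toks <- tokenize("No famotidine today.")
  expect_equal(toks$token, c("no", "famotidine", "today"))
  # spans are 0-based half-open: slicing the input reproduces each token
  for (r in seq_len(nrow(toks))) {
    expect_equal(tolower(substring("No famotidine today.",
                                   toks$start[r] + 1, toks$end[r])),
                 toks$token[r])
  }
  expect_equal(nrow(tokenize("")), 0)
  expect_equal(tokenize("anti-histamines")$token, "anti-histamines")
  # sentence ids advance at ., !, ? and newline
  toks <- tokenize("no luck. aspirin helps")
  expect_equal(toks$sentence, c(0L, 0L, 1L, 1L))
})

test_that("dictionary matching finds synonyms, brands and group terms, never stop terms", {
  lex <- default_lexicon()
  men <- match_entities("took famotidine and zyrtec", lex)
  expect_equal(men$concept_id, c("famotidine", "cetirizine_hydrochloride"))
  # surfaces equal the text slice at the reported spans
  expect_equal(men$surface,
               substring("took famotidine and zyrtec",
                         men$start + 1, men$end))

  expect_equal(nrow(match_entities("drank ethanol", lex)), 0)

  men <- match_entities("vitamin d and vitamin d", lex)
  expect_equal(men$concept_id, rep("ergocalciferol", 2))

  # greedy longest match: the 2-token synonym wins over its head token
  men <- match_entities("cetirizine hydrochloride helped", lex)
  expect_equal(men$concept_id, "cetirizine_hydrochloride")
  expect_equal(men$surface, "cetirizine hydrochloride")

  # group term with hyphen, the classic compound-term miss avoided
  men <- match_entities("anti-histamines changed everything", lex)
  expect_equal(men$concept_id, "histamine_antagonists")
})

test_that("negation detection honours scope, sentence bounds and pseudo-triggers", {
  rules <- default_negation_rules()
  check <- function(text, negated) {
    toks <- tokenize(text)
    idx <- which(toks$token == "aspirin" | toks$token == "magnesium")
    expect_equal(detect_negation(toks, idx, idx, rules), negated,
                 label = sprintf("'%s'", text))
  }
  check("i do not take aspirin", TRUE)
  check("no luck. aspirin helps", FALSE)       # sentence boundary blocks scope
  check("not only magnesium helped", FALSE)    # pseudo-trigger suppression
  check("never took aspirin", TRUE)            # multi-word trigger
  check("took aspirin daily", FALSE)
  check("one two three four five six aspirin", FALSE)  # out of window
  # post-trigger
  toks <- tokenize("finally aspirin free")
  idx <- which(toks$token == "aspirin")
  expect_true(detect_negation(toks, idx, idx, rules))
})

test_that("per-post extraction collapses duplicates and drops negated mentions", {
  lex <- default_lexicon()
  expect_equal(extract_substances("famotidine, famotidine, and magnesium", lex),
               c("famotidine", "magnesium"))
  expect_equal(extract_substances("never took famotidine", lex), character(0))
  expect_equal(extract_substances("", lex), character(0))
})

test_that("adding a negation trigger before a mention never grows the extracted set", {
  lex <- default_lexicon()
  bodies <- c("magnesium in the morning", "took aspirin and famotidine",
              "zyrtec helps", "cetirizine hydrochloride plus zinc")
  for (b in bodies) {
    base <- extract_substances(b, lex)
    negd <- extract_substances(paste("never", b), lex)
    expect_true(all(negd %in% base), label = sprintf("'%s'", b))
  }
})

test_that("NER evaluation scores exact (span, concept) matches micro-averaged", {
  gold <- data.frame(post_id = c("p1", "p1", "p2", "p2"),
                     start = c(0L, 10L, 0L, 7L), end = c(4L, 19L, 5L, 15L),
                     concept_id = c("a", "b", "c", "d"),
                     stringsAsFactors = FALSE)
  # identity
  res <- evaluate_ner(gold, gold)
  expect_equal(res$precision, 1); expect_equal(res$recall, 1)
  expect_equal(res$f1, 1)
  # 2 TP, 2 FP, 2 FN -> P = R = F1 = 0.5 (hand-counted confusion cells)
  pred <- rbind(gold[1:2, ],
                data.frame(post_id = c("p3", "p3"), start = c(0L, 6L),
                           end = c(3L, 9L), concept_id = c("x", "y"),
                           stringsAsFactors = FALSE))
  res <- evaluate_ner(pred, gold)
  expect_equal(res$tp, 2); expect_equal(res$fp, 2); expect_equal(res$fn, 2)
  expect_equal(res$precision, 0.5)
  expect_equal(res$recall, 0.5)
  expect_equal(res$f1, 0.5)
  # degenerate convention: empty predictions
  res <- evaluate_ner(gold[0, ], gold)
  expect_equal(res$precision, 0)
  expect_equal(res$recall, 0)
  expect_equal(res$f1, 0)
  # swapping predicted and gold swaps precision and recall, F1 unchanged
  pred2 <- rbind(gold[1:3, ],
                 data.frame(post_id = "p9", start = 0L, end = 2L,
                            concept_id = "z", stringsAsFactors = FALSE))
  a <- evaluate_ner(pred2, gold)
  b <- evaluate_ner(gold, pred2)
  expect_equal(a$precision, b$recall)
  expect_equal(a$recall, b$precision)
  expect_equal(a$f1, b$f1)
})

test_that("intercoder reliability is Cohen's kappa over binary unit decisions", {
  units <- data.frame(post_id = sprintf("p%d", 1:100),
                      start = 0L, end = 5L, stringsAsFactors = FALSE)
  # identical annotations -> 1
  ann <- units[1:30, ]
  expect_equal(intercoder_reliability(ann, ann, units), 1)
  # agreement table (45, 5; 5, 45) over 100 units:
  # po = 0.9, pe = 0.5, kappa = (0.9 - 0.5) / 0.5 = 0.8
  ann_a <- units[1:50, ]
  ann_b <- units[c(1:45, 51:55), ]
  expect_equal(intercoder_reliability(ann_a, ann_b, units), 0.8)
  # statistically independent labels -> kappa near 0
  set.seed(13)
  big <- data.frame(post_id = sprintf("p%d", 1:4000),
                    start = 0L, end = 5L, stringsAsFactors = FALSE)
  ra <- big[sample(4000, 2000), ]
  rb <- big[sample(4000, 2000), ]
  expect_lt(abs(intercoder_reliability(ra, rb, big)), 0.08)
  # annotations outside the unit set are an error
  stray <- data.frame(post_id = "nope", start = 0L, end = 5L,
                      stringsAsFactors = FALSE)
  expect_error(intercoder_reliability(stray, ann, units), "outside")
})
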