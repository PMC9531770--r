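#' Tokenize cleaned text
#'
#' Lowercase tokens split on non-alphanumeric boundaries, except that
#' internal hyphens are kept (so "anti-histamines" is one token). Spans are
#' 0-based half-open character offsets into the input text. Sentence ids
#' increment at `.`, `!`, `?` and newline, so negation scope can be bounded
#' by sentence.
#'
#' @param text a single cleaned string (see [clean_text()]).
#' @return data.frame with columns `token`, `start`, `end`, `sentence`.
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1)
  empty <- data.frame(token = character(), start = integer(),
                      end = integer(), sentence = integer())
  if (is.na(text) || !nzchar(text)) return(empty)
  low <- tolower(text)
  m <- gregexpr("[a-z0-9]+(?:-[a-z0-9]+)*", low, perl = TRUE)[[1]]
  if (m[1] == -1) return(empty)
  start <- as.integer(m) - 1L                      # 0-based
  end <- start + attr(m, "match.length")           # half-open
  tok <- substring(low, start + 1L, end)
  b <- gregexpr("[.!?\n]", low, perl = TRUE)[[1]]
  sentence <- if (b[1] == -1) rep(0L, length(tok)) else
    findInterval(start, as.integer(b) - 1L)
  data.frame(token = tok, start = start, end = end,
             sentence = as.integer(sentence), stringsAsFactors = FALSE)
}

#' Negation rules
#'
#' Negex-style trigger lists. A substance mention is negated when a
#' pre-trigger occurs within `scope_window` tokens before it in the same
#' sentence (unless the trigger is the start of a pseudo-trigger such as
#' "not only"), or a post-trigger within `scope_window` tokens after it.
#'
#' @param pre_triggers,post_triggers,pseudo_triggers character vectors;
#'   multi-word triggers are given as space-separated token sequences.
#' @param scope_window token distance a trigger reaches; default 5, the
#'   classical Negex convention.
#' @return An object of class `negation_rules`.
#' @export
negation_rules <- function(pre_triggers, post_triggers = character(),
                           pseudo_triggers = character(), scope_window = 5L) {
  abort_if(scope_window < 1, "scope_window must be >= 1")
  split_tokens <- function(x) strsplit(norm_surface(x), " ", fixed = TRUE)
  structure(list(pre = split_tokens(pre_triggers),
                 post = split_tokens(post_triggers),
                 pseudo = split_tokens(pseudo_triggers),
                 scope_window = as.integer(scope_window)),
            class = "negation_rules")
}

#' Load negation rules from a trigger file
#'
#' One trigger per line with a role prefix `PRE:`, `POST:` or `PSEUDO:`;
#' `#` comments allowed.
#'
#' @param path trigger file.
#' @param scope_window see [negation_rules()].
#' @return A [negation_rules] object.
#' @export
load_negation_rules <- function(path, scope_window = 5L) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  pick <- function(prefix) {
    hits <- grep(paste0("^", prefix, ":"), lines, value = TRUE)
    trimws(sub(paste0("^", prefix, ":"), "", hits))
  }
  negation_rules(pick("PRE"), pick("POST"), pick("PSEUDO"), scope_window)
}

#' Shipped default negation rules
#' @return A [negation_rules] object with the packaged trigger lists.
#' @export
default_negation_rules <- function() {
  load_negation_rules(system.file("extdata", "negation_triggers.txt",
                                  package = "ppminet"))
}

# Does the token sequence `trig` occur with its last token at position
# `at` (for pre) or first token at `at` (for post)?
trigger_at <- function(tokens, trig, last_idx) {
  k <- length(trig)
  first <- last_idx - k + 1L
  if (first < 1L) return(FALSE)
  all(tokens[first:last_idx] == trig)
}

#' Detect whether a mention is negated
#'
#' @param tokens data.frame from [tokenize()].
#' @param first_idx,last_idx 1-based indices of the mention's first and
#'   last token within `tokens`.
#' @param rules a [negation_rules] object.
#' @return logical flag.
#' @export
detect_negation <- function(tokens, first_idx, last_idx = first_idx,
                            rules = default_negation_rules()) {
  stopifnot(inherits(rules, "negation_rules"))
  n <- nrow(tokens)
  sent <- tokens$sentence[first_idx]
  w <- rules$scope_window
  # pre-triggers: last trigger token within w tokens before the mention
  lo <- max(1L, first_idx - w)
  pre_idx <- if (first_idx - 1L >= lo) seq(first_idx - 1L, lo) else integer(0)
  for (j in pre_idx) {
    if (tokens$sentence[j] != sent) break
    for (trig in rules$pre) {
      if (trigger_at(tokens$token, trig, j)) {
        first <- j - length(trig) + 1L
        # pseudo suppression: trigger is the prefix of a pseudo sequence
        pseudo <- FALSE
        for (ps in rules$pseudo) {
          if (length(ps) >= length(trig) &&
              first + length(ps) - 1L <= n &&
              all(tokens$token[first:(first + length(ps) - 1L)] == ps)) {
            pseudo <- TRUE
            break
          }
        }
        if (!pseudo) return(TRUE)
      }
    }
  }
  # post-triggers: within w tokens after the mention, same sentence
  hi <- min(n, last_idx + w)
  post_idx <- if (last_idx + 1L <= hi) seq(last_idx + 1L, hi) else integer(0)
  for (j in post_idx) {
    if (tokens$sentence[j] != sent) break
    for (trig in rules$post) {
      last <- j + length(trig) - 1L
      if (last <= n && all(tokens$token[j:last] == trig)) return(TRUE)
    }
  }
  FALSE
}

empty_mentions <- function() {
  data.frame(post_id = character(), surface = character(),
             start = integer(), end = integer(),
             concept_id = character(), negated = logical(),
             first_idx = integer(), last_idx = integer(),
             stringsAsFactors = FALSE)
}

#' Match substance mentions in cleaned text
#'
#' Greedy longest-match over token n-grams (n <= 4), left to right and
#' non-overlapping. Exact synonym surfaces are matched first, then exact
#' brand surfaces (normalised to their ingredient). Single unmatched
#' alphabetic tokens of at least 4 characters are attempted fuzzily via
#' [link_entity()] and fuzzy brand normalisation. Stop-term surfaces are
#' consumed but never emitted. Negation is not evaluated here (all
#' `negated` flags are `FALSE`); see [extract_substances()].
#'
#' @param text one cleaned string.
#' @param lex a [lexicon].
#' @param threshold fuzzy link threshold; default 0.85.
#' @param post_id id recorded on the returned mentions.
#' @param fuzzy attempt fuzzy linking of unmatched tokens?
#' @param cache optional environment memoising fuzzy lookups across posts.
#' @return data.frame of mentions with 0-based half-open spans on `text`.
#' @export
match_entities <- function(text, lex, threshold = 0.85, post_id = NA_character_,
                           fuzzy = TRUE, cache = NULL) {
  stopifnot(inherits(lex, "lexicon"))
  toks <- tokenize(text)
  hits <- match_tokens(text, toks, lex, threshold, fuzzy, cache)
  if (length(hits$concept_id) == 0) return(empty_mentions())
  data.frame(post_id = post_id, surface = hits$surface,
             start = hits$start, end = hits$end,
             concept_id = hits$concept_id, negated = FALSE,
             first_idx = hits$first_idx, last_idx = hits$last_idx,
             stringsAsFactors = FALSE)
}

# vector-returning core of the matcher; `toks` from tokenize(text)
match_tokens <- function(text, toks, lex, threshold = 0.85, fuzzy = TRUE,
                         cache = NULL) {
  n <- nrow(toks)
  out_cid <- character(0); out_i <- integer(0); out_j <- integer(0)
  if (n > 0) {
    token <- toks$token
    sentence <- toks$sentence
    stop_terms <- lex$stop_terms
    has_stops <- length(stop_terms) > 0
    syn_env <- lex$syn_env
    brand_env <- lex$brand_env
    maxn <- lex$max_ngram
    nch <- nchar(token)
    alpha <- grepl("^[a-z][a-z-]*$", token)
    i <- 1L
    while (i <= n) {
      hit_cid <- NULL
      hit_n <- 0L
      for (len in rev(seq_len(min(maxn, n - i + 1L)))) {
        # n-grams never cross sentence boundaries
        if (sentence[i + len - 1L] != sentence[i]) next
        key <- if (len == 1L) token[i] else
          paste(token[i:(i + len - 1L)], collapse = " ")
        if (has_stops && key %in% stop_terms) {
          hit_cid <- NA_character_; hit_n <- len; break
        }
        cid <- get0(key, envir = syn_env)
        if (is.null(cid)) {
          b <- get0(key, envir = brand_env)
          if (!is.null(b)) cid <- b
        }
        if (!is.null(cid)) { hit_cid <- cid; hit_n <- len; break }
      }
      if (hit_n == 0L && fuzzy && nch[i] >= 4 && alpha[i]) {
        tok <- token[i]
        cid <- if (!is.null(cache)) get0(tok, envir = cache) else NULL
        if (is.null(cid)) {
          cid <- link_entity(tok, lex, threshold)
          if (is.na(cid)) {
            nb <- normalize_brand(tok, lex, threshold)
            cid <- if (!identical(nb, tok)) nb else NA_character_
          }
          if (!is.null(cache)) assign(tok, cid, envir = cache)
        }
        if (!is.na(cid)) { hit_cid <- cid; hit_n <- 1L }
      }
      if (hit_n > 0L) {
        if (!is.null(hit_cid) && !is.na(hit_cid)) {
          out_cid <- c(out_cid, hit_cid)
          out_i <- c(out_i, i)
          out_j <- c(out_j, i + hit_n - 1L)
        }
        i <- i + hit_n
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(out_cid) == 0) {
    return(list(concept_id = character(0), start = integer(0),
                end = integer(0), surface = character(0),
                first_idx = integer(0), last_idx = integer(0)))
  }
  list(concept_id = out_cid,
       start = toks$start[out_i], end = toks$end[out_j],
       surface = substring(text, toks$start[out_i] + 1L, toks$end[out_j]),
       first_idx = out_i, last_idx = out_j)
}

#' Extract the substance set of one post
#'
#' Cleans the body, matches mentions, drops negated ones, and collapses
#' duplicates: the result is the set of concept ids used for co-occurrence
#' counting (so longer posts do not weigh more).
#'
#' @param post one-row data.frame with `post_id` and `body` (a [corpus]
#'   posts row), or a single body string.
#' @param lex a [lexicon].
#' @param rules a [negation_rules] object.
#' @param threshold fuzzy link threshold.
#' @param cache optional fuzzy-lookup cache environment.
#' @return character vector of concept ids (possibly empty).
#' @export
extract_substances <- function(post, lex, rules = default_negation_rules(),
                               threshold = 0.85, cache = NULL) {
  body <- if (is.character(post)) post else post$body
  pid <- if (is.character(post)) NA_character_ else post$post_id
  men <- post_mentions(body, pid, lex, rules, threshold, cache)
  sort(unique(men$concept_id[!men$negated]))
}

# clean + match + negation-flag mentions of one body
post_mentions <- function(body, post_id, lex, rules, threshold = 0.85,
                          cache = NULL) {
  text <- clean_text(body)
  toks <- tokenize(text)
  hits <- match_tokens(text, toks, lex, threshold, cache = cache)
  k <- length(hits$concept_id)
  if (k == 0) return(empty_mentions())
  negated <- vapply(seq_len(k), function(r) {
    detect_negation(toks, hits$first_idx[r], hits$last_idx[r], rules)
  }, logical(1))
  data.frame(post_id = post_id, surface = hits$surface,
             start = hits$start, end = hits$end,
             concept_id = hits$concept_id, negated = negated,
             first_idx = hits$first_idx, last_idx = hits$last_idx,
             stringsAsFactors = FALSE)
}

#' Extract mentions for every post of a corpus
#'
#' Corpus-level driver used by the pipeline: returns all located mentions
#' (negated ones flagged, for the audit file) with fuzzy lookups memoised
#' across posts.
#'
#' @inheritParams extract_substances
#' @param x a [corpus].
#' @return data.frame of mentions (`post_id`, `surface`, `start`, `end`,
#'   `concept_id`, `negated`).
#' @export
extract_corpus <- function(x, lex, rules = default_negation_rules(),
                           threshold = 0.85) {
  stopifnot(inherits(x, "corpus"))
  cache <- new.env(parent = emptyenv())
  texts <- clean_text(x$posts$body)  # vectorised cleaning
  acc <- vector("list", nrow(x$posts))
  for (i in seq_len(nrow(x$posts))) {
    text <- texts[i]
    toks <- tokenize(text)
    hits <- match_tokens(text, toks, lex, threshold, cache = cache)
    k <- length(hits$concept_id)
    if (k == 0) next
    negated <- vapply(seq_len(k), function(r) {
      detect_negation(toks, hits$first_idx[r], hits$last_idx[r], rules)
    }, logical(1))
    acc[[i]] <- list(post_id = rep(x$posts$post_id[i], k),
                     surface = hits$surface, start = hits$start,
                     end = hits$end, concept_id = hits$concept_id,
                     negated = negated)
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  if (length(acc) == 0) {
    men <- empty_mentions()
    men$first_idx <- NULL; men$last_idx <- NULL
    return(men)
  }
  pull <- function(f) unlist(lapply(acc, `[[`, f), use.names = FALSE)
  data.frame(post_id = pull("post_id"), surface = pull("surface"),
             start = pull("start"), end = pull("end"),
             concept_id = pull("concept_id"), negated = pull("negated"),
             stringsAsFactors = FALSE)
}

#' Evaluate extraction against gold annotations
#'
#' Micro-averaged precision, recall and F1 over exact (post, span, concept)
#' matches. Undefined ratios (empty predicted or gold) fall back to 0.
#'
#' @param predicted data.frame with `post_id`, `start`, `end`, `concept_id`.
#' @param gold data.frame with the same columns.
#' @return named list with `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
evaluate_ner <- function(predicted, gold) {
  key <- function(d) paste(d$post_id, d$start, d$end, d$concept_id, sep = "\r")
  pk <- unique(key(predicted))
  gk <- unique(key(gold))
  tp <- length(intersect(pk, gk))
  fp <- length(setdiff(pk, gk))
  fn <- length(setdiff(gk, pk))
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn)
}

#' Intercoder reliability (Cohen's kappa)
#'
#' Agreement between two annotators over a shared set of candidate units,
#' each labelled substance / not-substance. A unit counts as labelled
#' "substance" by an annotator when it appears in their annotation table.
#' Chance-corrected: kappa = (po - pe) / (1 - pe), and 1 on identical
#' labels.
#'
#' @param ann_a,ann_b data.frames with `post_id`, `start`, `end`.
#' @param units data.frame of all candidate units (`post_id`, `start`,
#'   `end`) both annotators decided on.
#' @return kappa in \[-1, 1\].
#' @export
intercoder_reliability <- function(ann_a, ann_b, units) {
  ukey <- function(d) paste(d$post_id, d$start, d$end, sep = "\r")
  u <- unique(ukey(units))
  ka <- unique(ukey(ann_a)); kb <- unique(ukey(ann_b))
  abort_if(!all(ka %in% u) || !all(kb %in% u),
           "annotations reference units outside the shared unit set")
  a <- u %in% ka
  b <- u %in% kb
  n <- length(u)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (abs(1 - pe) < 1e-12) return(if (po >= 1 - 1e-12) 1 else 0)
  (po - pe) / (1 - pe)
}
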