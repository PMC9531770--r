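#' Substance lexicon
#'
#' The lexicon is the packaged knowledge base standing behind entity
#' normalisation: a set of substance concepts (canonical name, substance
#' class, synonyms), a brand-name map in the style of an FDA Orange Book
#' extract (brand surface -> active-ingredient concept), and stop terms —
#' chemical surfaces such as "ethanol" that are never emitted as treatment
#' substances.
#'
#' @param concepts data.frame with columns `concept_id`, `canonical_name`,
#'   `substance_class`, and `synonyms` (list column of character vectors, or
#'   pipe-separated strings).
#' @param brand_map named character vector: names are brand surfaces,
#'   values are concept ids.
#' @param stop_terms character vector of surfaces never emitted.
#' @return An object of class `lexicon`.
#' @export
lexicon <- function(concepts, brand_map = character(), stop_terms = character()) {
  abort_if(nrow(concepts) < 1, "a lexicon needs at least one concept")
  concepts$concept_id <- as.character(concepts$concept_id)
  dup <- concepts$concept_id[duplicated(concepts$concept_id)]
  abort_if(length(dup) > 0, "duplicate concept_id: %s", paste(dup, collapse = ", "))
  concepts$canonical_name <- norm_surface(concepts$canonical_name)
  if (is.null(concepts$synonyms)) concepts$synonyms <- rep("", nrow(concepts))
  if (!is.list(concepts$synonyms)) {
    syn <- as.character(concepts$synonyms)
    syn[is.na(syn)] <- ""
    concepts$synonyms <- strsplit(syn, "|", fixed = TRUE)
  }
  concepts$synonyms <- lapply(seq_len(nrow(concepts)), function(i) {
    syn <- norm_surface(concepts$synonyms[[i]])
    syn <- unique(c(concepts$canonical_name[i], syn[nzchar(syn)]))
    sort(syn)
  })
  stop_terms <- sort(unique(norm_surface(stop_terms)))
  stop_terms <- stop_terms[nzchar(stop_terms)]
  all_syn <- unlist(concepts$synonyms, use.names = FALSE)
  clash <- intersect(stop_terms, all_syn)
  abort_if(length(clash) > 0,
           "stop terms collide with concept synonyms: %s", paste(clash, collapse = ", "))
  if (length(brand_map) > 0) {
    names(brand_map) <- norm_surface(names(brand_map))
    brand_map <- vapply(brand_map, as.character, character(1))
    unknown <- setdiff(unname(brand_map), concepts$concept_id)
    abort_if(length(unknown) > 0,
             "brand map points at unknown concepts: %s", paste(unknown, collapse = ", "))
  }
  rownames(concepts) <- NULL
  # hash tables for O(1) exact lookup during matching
  syn_env <- new.env(parent = emptyenv(), size = max(64L, 2L * length(all_syn)))
  for (i in seq_len(nrow(concepts))) {
    for (s in concepts$synonyms[[i]]) {
      prev <- get0(s, envir = syn_env)
      # a surface shared by two concepts links to the lexicographically
      # smallest concept_id, matching the fuzzy tie-break
      if (is.null(prev) || concepts$concept_id[i] < prev) {
        assign(s, concepts$concept_id[i], envir = syn_env)
      }
    }
  }
  brand_env <- new.env(parent = emptyenv())
  for (b in names(brand_map)) assign(b, unname(brand_map[b]), envir = brand_env)
  syn_df <- data.frame(
    synonym = all_syn,
    concept_id = rep(concepts$concept_id, lengths(concepts$synonyms)),
    stringsAsFactors = FALSE
  )
  syn_df$nchar <- nchar(syn_df$synonym)
  # longest surface (in tokens) the matcher must consider, capped at 4
  n_tokens <- function(x) lengths(strsplit(x, " ", fixed = TRUE))
  max_ngram <- min(4L, max(1L, n_tokens(all_syn),
                           if (length(brand_map)) n_tokens(names(brand_map)),
                           if (length(stop_terms)) n_tokens(stop_terms)))
  structure(list(concepts = concepts, brand_map = brand_map,
                 stop_terms = stop_terms, syn_env = syn_env,
                 brand_env = brand_env, syn_df = syn_df,
                 max_ngram = max_ngram),
            class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon> %d concepts, %d synonyms, %d brands, %d stop terms\n",
              nrow(x$concepts), nrow(x$syn_df), length(x$brand_map),
              length(x$stop_terms)))
  invisible(x)
}

#' Load a lexicon from TSV files
#'
#' @param concepts_path TSV with columns `concept_id`, `canonical_name`,
#'   `substance_class`, `synonyms` (pipe-separated).
#' @param brands_path optional two-column TSV `brand_name`, `concept_id`.
#' @param stops_path optional plain-text stop list, one term per line,
#'   `#` comments allowed.
#' @return A [lexicon].
#' @export
load_lexicon <- function(concepts_path, brands_path = NULL, stops_path = NULL) {
  abort_if(!file.exists(concepts_path), "no such file: %s", concepts_path)
  concepts <- utils::read.delim(concepts_path, sep = "\t", header = TRUE,
                                quote = "", comment.char = "",
                                stringsAsFactors = FALSE)
  brand_map <- character()
  if (!is.null(brands_path)) {
    brands <- utils::read.delim(brands_path, sep = "\t", header = TRUE,
                                quote = "", comment.char = "",
                                stringsAsFactors = FALSE)
    brand_map <- stats::setNames(as.character(brands$concept_id),
                                 as.character(brands$brand_name))
  }
  stop_terms <- character()
  if (!is.null(stops_path)) {
    lines <- readLines(stops_path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    stop_terms <- lines[nzchar(lines)]
  }
  lexicon(concepts, brand_map, stop_terms)
}

#' The packaged default substance lexicon
#'
#' Roughly sixty substance concepts covering the supplements, OTC and
#' prescription medications most discussed in long-COVID self-medication
#' forums (antihistamines, steroids, antidepressants, vitamins, minerals,
#' ...), with common brand names and stop terms.
#'
#' @return A [lexicon].
#' @export
default_lexicon <- function() {
  dir <- system.file("extdata", package = "ppminet")
  load_lexicon(file.path(dir, "lexicon_concepts.tsv"),
               file.path(dir, "lexicon_brands.tsv"),
               file.path(dir, "lexicon_stops.txt"))
}

#' Link a surface string to a lexicon concept
#'
#' Returns the concept whose best synonym similarity to `surface` is
#' maximal and at least `threshold`; `NA` when nothing reaches the
#' threshold (the discard signal). Exact synonym matches short-circuit at
#' similarity 1. Ties on similarity are broken by the lexicographically
#' smallest concept id, for determinism.
#'
#' @param surface a surface string (normalised internally).
#' @param lex a [lexicon].
#' @param threshold minimum similarity in (0, 1\]; default 0.85.
#' @param method passed to [string_similarity()].
#' @return concept id, or `NA_character_`.
#' @export
link_entity <- function(surface, lex, threshold = 0.85,
                        method = c("jaro_winkler", "trigram_jaccard")) {
  method <- match.arg(method)
  stopifnot(inherits(lex, "lexicon"))
  s <- norm_surface(surface)
  if (!nzchar(s)) return(NA_character_)
  hit <- get0(s, envir = lex$syn_env)
  if (!is.null(hit)) return(hit)
  cand <- lex$syn_df
  if (method == "jaro_winkler") {
    cand <- cand[similarity_possible(nchar(s), cand$nchar, threshold), , drop = FALSE]
  }
  if (nrow(cand) == 0) return(NA_character_)
  sims <- vapply(cand$synonym, function(syn) string_similarity(s, syn, method),
                 numeric(1), USE.NAMES = FALSE)
  ok <- sims >= threshold
  if (!any(ok)) return(NA_character_)
  best <- max(sims[ok])
  ids <- cand$concept_id[ok & sims >= best - 1e-12]
  min(ids)
}

#' Normalise a brand surface to its active ingredient
#'
#' If the input matches a brand-map key exactly, or fuzzily at or above the
#' threshold, the mapped ingredient concept id is returned; otherwise the
#' input is returned unchanged. Idempotent: concept ids are not brand
#' surfaces, so a second application is the identity.
#'
#' @param x a surface string or concept id.
#' @inheritParams link_entity
#' @return concept id, or `x` unchanged.
#' @export
normalize_brand <- function(x, lex, threshold = 0.85,
                            method = c("jaro_winkler", "trigram_jaccard")) {
  method <- match.arg(method)
  stopifnot(inherits(lex, "lexicon"))
  s <- norm_surface(x)
  if (!nzchar(s) || length(lex$brand_map) == 0) return(x)
  hit <- get0(s, envir = lex$brand_env)
  if (!is.null(hit)) return(hit)
  keys <- names(lex$brand_map)
  if (method == "jaro_winkler") {
    keys <- keys[similarity_possible(nchar(s), nchar(keys), threshold)]
  }
  if (length(keys) == 0) return(x)
  sims <- vapply(keys, function(k) string_similarity(s, k, method),
                 numeric(1), USE.NAMES = FALSE)
  ok <- sims >= threshold
  if (!any(ok)) return(x)
  best <- max(sims[ok])
  ids <- unname(lex$brand_map[keys[ok & sims >= best - 1e-12]])
  min(ids)
}
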