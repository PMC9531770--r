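#' Per-post substance mention table
#'
#' The bridge between extraction and network construction: one row per
#' (post, concept) with duplicates already collapsed, plus `n_posts`, the
#' number of analyzed posts *including* substance-free ones — that count is
#' `N`, the denominator of every PMI probability.
#'
#' @param x a [corpus] (its size fixes `N`).
#' @param mentions data.frame with `post_id` and `concept_id` columns
#'   (typically non-negated rows of [extract_corpus()] output).
#' @return An object of class `mention_table`: list with `n_posts` and
#'   `rows` (data.frame `post_id`, `concept_id`).
#' @export
build_mention_table <- function(x, mentions) {
  stopifnot(inherits(x, "corpus"))
  rows <- unique(data.frame(post_id = as.character(mentions$post_id),
                            concept_id = as.character(mentions$concept_id),
                            stringsAsFactors = FALSE))
  extra <- setdiff(rows$post_id, x$posts$post_id)
  abort_if(length(extra) > 0,
           "mentions refer to posts outside the corpus: %s",
           paste(utils::head(extra, 3), collapse = ", "))
  rows <- rows[order(rows$post_id, rows$concept_id), , drop = FALSE]
  rownames(rows) <- NULL
  structure(list(n_posts = nrow(x$posts), rows = rows),
            class = "mention_table")
}

#' @export
print.mention_table <- function(x, ...) {
  cat(sprintf("<mention_table> N=%d posts, %d posts with substances, %d concepts\n",
              x$n_posts, length(unique(x$rows$post_id)),
              length(unique(x$rows$concept_id))))
  invisible(x)
}

#' Substance frequencies
#'
#' `c_x`: the number of posts in which concept `x` appears at least once
#' (per-post duplicates were already disregarded).
#'
#' @param table a [build_mention_table()] result.
#' @return named integer vector, sorted by concept id.
#' @export
count_frequencies <- function(table) {
  stopifnot(inherits(table, "mention_table"))
  if (nrow(table$rows) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(table$rows$concept_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Co-occurrence pair counts
#'
#' A co-occurrence is the mention of two or more substances in one post: a
#' post whose set holds k substances contributes all k(k-1)/2 unordered
#' pairs, each once. Pairs are stored with `x < y` lexicographically.
#'
#' @param table a [build_mention_table()] result.
#' @return data.frame with columns `x`, `y`, `count`.
#' @export
count_pairs <- function(table) {
  stopifnot(inherits(table, "mention_table"))
  empty <- data.frame(x = character(), y = character(), count = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(table$rows) == 0) return(empty)
  sets <- split(table$rows$concept_id, table$rows$post_id)
  sets <- sets[lengths(sets) >= 2]
  if (length(sets) == 0) return(empty)
  pair_list <- lapply(sets, function(s) {
    s <- sort(s)
    cmb <- utils::combn(s, 2)
    data.frame(x = cmb[1, ], y = cmb[2, ], stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pair_list)
  agg <- stats::aggregate(list(count = rep(1L, nrow(pairs))),
                          by = pairs[c("x", "y")], FUN = sum)
  agg <- agg[order(agg$x, agg$y), , drop = FALSE]
  agg$count <- as.integer(agg$count)
  rownames(agg) <- NULL
  agg
}

#' Minimum-frequency filter
#'
#' Concepts occurring in fewer than `min_count` posts are excluded before
#' the network is built (default 10).
#'
#' @param freq named vector from [count_frequencies()].
#' @param min_count minimum post-level frequency; >= 1.
#' @return character vector of retained concept ids.
#' @export
frequency_filter <- function(freq, min_count = 10L) {
  abort_if(min_count < 1, "min_count must be >= 1")
  sort(names(freq)[freq >= min_count])
}

#' Positive PMI matrix
#'
#' Pointwise mutual information per unordered concept pair,
#' `PMI(x, y) = log2(c_xy * N / (c_x * c_y))` with post-level probabilities
#' `p(x) = c_x / N`, `p(x, y) = c_xy / N`. Pairs with non-positive PMI
#' (co-occurring no more than expected under independence) are dropped;
#' only strictly positive weights are stored. Log base 2; the base only
#' rescales all weights uniformly.
#'
#' @param pairs data.frame from [count_pairs()].
#' @param freq named vector from [count_frequencies()].
#' @param n_posts total number of analyzed posts `N` (> 0).
#' @param retained concept ids surviving [frequency_filter()]; pairs with
#'   a member outside this set are ignored.
#' @return An object of class `ppmi_matrix`: data.frame `x`, `y`, `weight`
#'   with attributes `retained` and `n_posts`.
#' @export
compute_ppmi <- function(pairs, freq, n_posts,
                         retained = names(freq)) {
  abort_if(n_posts <= 0, "n_posts must be positive")
  keep <- pairs$x %in% retained & pairs$y %in% retained
  p <- pairs[keep, , drop = FALSE]
  if (nrow(p) > 0) {
    cx <- freq[p$x]; cy <- freq[p$y]
    bad <- is.na(cx) | is.na(cy) | p$count > pmin(cx, cy)
    abort_if(any(bad), "inconsistent counts: c_xy exceeds min(c_x, c_y) for %s-%s",
             p$x[which(bad)[1]], p$y[which(bad)[1]])
    p$weight <- log2(p$count * n_posts / (as.numeric(cx) * as.numeric(cy)))
    p <- p[p$weight > 0, c("x", "y", "weight"), drop = FALSE]
  } else {
    p <- data.frame(x = character(), y = character(), weight = numeric(),
                    stringsAsFactors = FALSE)
  }
  p <- p[order(p$x, p$y), , drop = FALSE]
  rownames(p) <- NULL
  structure(p, class = c("ppmi_matrix", "data.frame"),
            retained = sort(retained), n_posts = n_posts)
}

#' Mean-weight filter
#'
#' Drops node pairs whose PPMI weight lies below the arithmetic mean of
#' the stored (positive) weights; pairs exactly at the mean are kept, so a
#' matrix of equal weights passes unchanged.
#'
#' @param ppmi a [compute_ppmi()] result.
#' @return filtered `ppmi_matrix`.
#' @export
mean_weight_filter <- function(ppmi) {
  stopifnot(inherits(ppmi, "ppmi_matrix"))
  if (nrow(ppmi) == 0) return(ppmi)
  m <- mean(ppmi$weight)
  out <- ppmi[ppmi$weight >= m - 1e-12, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(ppmi), retained = attr(ppmi, "retained"),
            n_posts = attr(ppmi, "n_posts"))
}

#' Most frequent co-occurrence pairs
#'
#' @param pairs data.frame from [count_pairs()].
#' @param k number of pairs to report (>= 1); descending by count, ties
#'   broken by lexicographic pair name.
#' @return data.frame `x`, `y`, `count` with at most `k` rows.
#' @export
top_pairs <- function(pairs, k) {
  abort_if(k < 1, "k must be >= 1")
  ord <- order(-pairs$count, pairs$x, pairs$y)
  out <- pairs[utils::head(ord, k), , drop = FALSE]
  rownames(out) <- NULL
  out
}
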