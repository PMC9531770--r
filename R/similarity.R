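#' Fuzzy string similarity for entity linking
#'
#' Similarity between two surface strings on \[0, 1\], used to link free-text
#' substance mentions to lexicon concepts at the 0.85 threshold. Two metrics
#' are available behind one swappable interface:
#'
#' * `"jaro_winkler"` (default): the Jaro similarity with the Winkler common
#'   prefix bonus (p = 0.1, prefix capped at 4). Single-typo drug-name
#'   variants (transpositions, substitutions) stay at or above 0.85 while
#'   unrelated drug names fall well below it, which is the behaviour the
#'   linking threshold presumes.
#' * `"trigram_jaccard"`: multiset Jaccard overlap of padded character
#'   3-grams; order-free and cheap, but far stricter on short typo variants.
#'
#' Both metrics are symmetric, equal 1 exactly on equal normalised strings,
#' and operate on lowercased, whitespace-squished input.
#'
#' @param a,b non-empty strings (scalar).
#' @param method similarity metric.
#' @return a score in \[0, 1\].
#' @examples
#' string_similarity("magnesium", "magnesium")         # 1
#' string_similarity("cetirizine", "ceterizine")       # >= 0.85
#' string_similarity("famotidine", "loratadine")       # << 0.85
#' @export
string_similarity <- function(a, b, method = c("jaro_winkler", "trigram_jaccard")) {
  method <- match.arg(method)
  a <- norm_surface(a)
  b <- norm_surface(b)
  abort_if(!nzchar(a) || !nzchar(b),
           "string_similarity: inputs must be non-empty after normalization")
  if (a == b) return(1)
  switch(method,
         jaro_winkler = jaro_winkler(a, b),
         trigram_jaccard = trigram_jaccard(a, b))
}

# Jaro similarity: matches within the standard window, transpositions counted
# as half the out-of-order matched pairs.
jaro <- function(a, b) {
  s1 <- strsplit(a, "", fixed = TRUE)[[1]]
  s2 <- strsplit(b, "", fixed = TRUE)[[1]]
  l1 <- length(s1); l2 <- length(s2)
  window <- max(0L, floor(max(l1, l2) / 2) - 1L)
  used2 <- logical(l2)
  m1 <- integer(0)  # matched positions in s2, in s1 order
  for (i in seq_len(l1)) {
    lo <- max(1L, i - window); hi <- min(l2, i + window)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!used2[j] && s1[i] == s2[j]) {
        used2[j] <- TRUE
        m1 <- c(m1, j)
        break
      }
    }
  }
  m <- length(m1)
  if (m == 0) return(0)
  # transpositions: half the matched characters that are out of order
  matched1 <- s2[m1]        # matched chars in s1 order
  matched2 <- s2[sort(m1)]  # matched chars in s2 order
  t <- sum(matched1 != matched2) / 2
  (m / l1 + m / l2 + (m - t) / m) / 3
}

jaro_winkler <- function(a, b, p = 0.1, max_prefix = 4L) {
  j <- jaro(a, b)
  s1 <- strsplit(a, "", fixed = TRUE)[[1]]
  s2 <- strsplit(b, "", fixed = TRUE)[[1]]
  l <- 0L
  for (i in seq_len(min(length(s1), length(s2), max_prefix))) {
    if (s1[i] == s2[i]) l <- l + 1L else break
  }
  j + l * p * (1 - j)
}

# Multiset Jaccard of character 3-grams over '##'-padded strings; 0 when no
# 3-gram is shared.
trigram_jaccard <- function(a, b) {
  g <- function(s) {
    s <- paste0("##", s, "##")
    n <- nchar(s)
    substring(s, 1:(n - 2), 3:n)
  }
  ga <- g(a); gb <- g(b)
  ta <- table(ga); tb <- table(gb)
  keys <- union(names(ta), names(tb))
  ca <- as.integer(ta[keys]); ca[is.na(ca)] <- 0L
  cb <- as.integer(tb[keys]); cb[is.na(cb)] <- 0L
  inter <- sum(pmin(ca, cb))
  uni <- sum(pmax(ca, cb))
  if (uni == 0) 0 else inter / uni
}

# Cheap length prefilter: Jaro-Winkler cannot reach `threshold` when the
# shorter string is much shorter than the longer one.
similarity_possible <- function(len_a, len_b, threshold) {
  r <- pmin(len_a, len_b) / pmax(len_a, len_b)
  jmax <- (1 + 2 * r) / 3
  jmax + 0.4 * (1 - jmax) >= threshold - 1e-9
}
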