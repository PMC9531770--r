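#' Corpus of social-media posts
#'
#' A corpus is an ordered collection of posts (initial posts and comments
#' alike), each carrying an id, author, timestamp, optional flair tag and
#' free-text body. The post is the unit of analysis throughout the package:
#' co-occurrence is defined per post and the corpus size `N` is the
#' denominator of all PMI probabilities.
#'
#' @param posts data.frame with columns `post_id`, `author_id`,
#'   `created_utc`, `flair` (NA when untagged) and `body`.
#' @param meta list of ingestion/filter provenance counts.
#' @return An object of class `corpus`.
#' @export
corpus <- function(posts, meta = list()) {
  required <- c("post_id", "author_id", "created_utc", "flair", "body")
  missing <- setdiff(required, names(posts))
  abort_if(length(missing) > 0, "posts is missing columns: %s",
           paste(missing, collapse = ", "))
  abort_if(anyDuplicated(posts$post_id) > 0, "post_id values must be unique")
  rownames(posts) <- NULL
  meta$n_posts <- nrow(posts)
  structure(list(posts = posts, meta = meta), class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> %d posts, %d authors\n",
              nrow(x$posts), length(unique(x$posts$author_id))))
  invisible(x)
}

#' @export
length.corpus <- function(x) nrow(x$posts)

default_post_schema <- function() {
  list(post_id = "id", author_id = "author", created_utc = "created_utc",
       flair = "link_flair_text", body = c("body", "selftext"))
}

#' Read a JSONL post dump
#'
#' Reads one JSON record per line (the dialect of Pushshift-style subreddit
#' dumps). Records missing the id or body field, and lines that are not
#' valid JSON, are skipped and counted in the returned corpus meta.
#'
#' @param path path to a JSONL file.
#' @param schema named list mapping corpus fields to JSON field names; a
#'   field may list several candidate names tried in order (the default
#'   accepts both `body` and `selftext`).
#' @return A [corpus]. `meta$skipped` counts dropped records.
#' @export
read_posts <- function(path, schema = default_post_schema()) {
  abort_if(!file.exists(path), "cannot read posts: no such file '%s'", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  skipped <- 0L
  take <- function(rec, keys) {
    for (k in keys) {
      v <- rec[[k]]
      if (!is.null(v) && length(v) == 1 && !is.na(v)) return(v)
    }
    NULL
  }
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e) NULL)
    if (is.null(rec)) { skipped <- skipped + 1L; next }
    id <- take(rec, schema$post_id)
    body <- take(rec, schema$body)
    if (is.null(id) || is.null(body)) { skipped <- skipped + 1L; next }
    flair <- take(rec, schema$flair)
    rows[[i]] <- data.frame(
      post_id = as.character(id),
      author_id = as.character(take(rec, schema$author_id) %||% NA_character_),
      created_utc = as.numeric(take(rec, schema$created_utc) %||% NA_real_),
      flair = if (is.null(flair)) NA_character_ else as.character(flair),
      body = as.character(body),
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  posts <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(post_id = character(), author_id = character(),
               created_utc = numeric(), flair = character(),
               body = character(), stringsAsFactors = FALSE)
  corpus(posts, meta = list(source = path, n_lines = length(lines),
                            skipped = skipped))
}

#' Write a corpus back to JSONL
#'
#' Serialises posts in the same dialect [read_posts()] ingests, one JSON
#' object per line with fields `id`, `author`, `created_utc`,
#' `link_flair_text`, `body`. Output is deterministic (input order, fixed
#' field order).
#'
#' @param x a [corpus].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_posts <- function(x, path) {
  stopifnot(inherits(x, "corpus"))
  p <- x$posts
  lines <- vapply(seq_len(nrow(p)), function(i) {
    rec <- list(id = p$post_id[i], author = p$author_id[i],
                created_utc = p$created_utc[i],
                link_flair_text = p$flair[i], body = p$body[i])
    jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Filter posts by flair tag
#'
#' Applies the study's inclusion rule: posts whose flair tag is on the
#' exclusion list (e.g. article, research article, humor) are removed, and
#' optionally posts with no flair at all. Matching is case-insensitive
#' after whitespace trimming. The operation is idempotent and total:
#' `kept + removed_excluded + removed_untagged = input`.
#'
#' @param x a [corpus].
#' @param excluded_tags character vector of flair tags to exclude.
#' @param drop_untagged drop posts whose flair is missing/empty?
#' @return The filtered [corpus]; `meta$flair_filter` records the counts.
#' @export
filter_by_flair <- function(x, excluded_tags = default_excluded_flairs(),
                            drop_untagged = TRUE) {
  stopifnot(inherits(x, "corpus"))
  tags <- norm_surface(excluded_tags)
  flair <- x$posts$flair
  flair_norm <- ifelse(is.na(flair), NA_character_, norm_surface(flair))
  untagged <- is.na(flair_norm) | !nzchar(flair_norm)
  excluded <- !untagged & flair_norm %in% tags
  drop <- excluded | (untagged & drop_untagged)
  meta <- x$meta
  meta$flair_filter <- list(
    n_in = nrow(x$posts),
    removed_excluded = sum(excluded),
    removed_untagged = sum(untagged & drop_untagged),
    n_kept = sum(!drop)
  )
  corpus(x$posts[!drop, , drop = FALSE], meta = meta)
}

#' Default excluded flair tags
#'
#' The shipped exclusion list covers article, research-article and humor
#' tags; extend it per forum.
#' @return character vector.
#' @export
default_excluded_flairs <- function() {
  c("article", "research article", "humor")
}

#' Clean post text
#'
#' Removes hyperlinks (scheme or `www.` prefixed tokens), replaces tabs
#' with spaces, collapses blank lines and runs of whitespace to a single
#' space, and trims. Idempotent; never introduces characters beyond a
#' single space.
#'
#' @param x character vector of post bodies.
#' @return cleaned character vector of the same length.
#' @export
clean_text <- function(x) {
  x <- gsub("(?i)\\b(?:https?://|www\\.)[^[:space:]]+", " ", x, perl = TRUE)
  x <- gsub("\t", " ", x, fixed = TRUE)
  squish(x)
}
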