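#' Cleaning configuration
#'
#' @param noise_terms character vector of noise markers (stop-word-list
#'   entries whose presence marks a post as noisy, e.g. ad phrases or
#'   `"http"` link markers).
#' @param dedup_min_chars duplicates are removed only among posts whose
#'   normalized text is strictly longer than this (default 10).
#' @return an object of class `cleaning_config`.
#' @export
cleaning_config <- function(noise_terms, dedup_min_chars = 10) {
  noise_terms <- unique(as.character(noise_terms))
  if (length(noise_terms) == 0) stop("noise_terms must be non-empty")
  if (dedup_min_chars < 0) stop("dedup_min_chars must be >= 0")
  structure(list(noise_terms = noise_terms,
                 dedup_min_chars = as.integer(dedup_min_chars)),
            class = "cleaning_config")
}

#' Seed lexicon
#'
#' @param terms character vector of seed keywords/expressions.
#' @param name lexicon name.
#' @return an object of class `seed_lexicon`.
#' @export
seed_lexicon <- function(terms, name = "seeds") {
  terms <- as.character(terms)
  if (length(terms) == 0) stop("seed lexicon must be non-empty")
  if (anyDuplicated(terms)) stop("seed lexicon contains duplicate terms")
  structure(list(name = name, terms = terms), class = "seed_lexicon")
}

#' Load posts from a JSON-lines file
#'
#' One JSON object per line with keys `post_id`, `text` and optionally
#' `user_id`, `created_at`. Records missing `post_id` or a non-empty
#' `text`, and unparseable lines, are skipped with a warning that reports
#' the skip count.
#'
#' @param path file path.
#' @param format currently only `"jsonl"`.
#' @return data.frame: `post_id`, `user_id`, `text`, `created_at`.
#' @export
load_posts <- function(path, format = "jsonl") {
  format <- match.arg(format, "jsonl")
  if (!file.exists(path)) stop("post file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n_skip <- 0L
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(rec) || is.null(rec$post_id) || is.null(rec$text) ||
        !nzchar(trimws(as.character(rec$text)))) {
      n_skip <- n_skip + 1L
      next
    }
    recs[[i]] <- data.frame(
      post_id = as.character(rec$post_id),
      user_id = as.character(rec$user_id %||% NA_character_),
      text = as.character(rec$text),
      created_at = as.character(rec$created_at %||% NA_character_),
      stringsAsFactors = FALSE
    )
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (n_skip > 0) warning("skipped ", n_skip, " malformed record(s)")
  if (length(recs) == 0) {
    warning("no well-formed records in ", path)
    return(data.frame(post_id = character(), user_id = character(),
                      text = character(), created_at = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  if (anyDuplicated(out$post_id)) stop("duplicate post_id in ", path)
  rownames(out) <- NULL
  out
}

#' Write posts to a JSON-lines file
#'
#' @param posts posts data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_posts <- function(posts, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(posts))) {
    writeLines(jsonlite::toJSON(as.list(posts[i, , drop = FALSE]),
                                auto_unbox = TRUE, na = "null"), con)
  }
  invisible(path)
}

#' Clean a post collection
#'
#' Two rules, applied in order: (1) noise filtering drops every post whose
#' normalized text contains any noise term as a substring; (2) among the
#' survivors, posts whose normalized text is identical and strictly longer
#' than `dedup_min_chars` characters are deduplicated, keeping the first
#' occurrence.
#'
#' @param posts posts data.frame (`post_id`, `text`, ...).
#' @param cfg a [cleaning_config()].
#' @return list with `posts` (retained rows) and `report` (class
#'   `cleaning_report`): input/removed/retained counts per rule and total.
#' @export
clean_corpus <- function(posts, cfg) {
  stopifnot(inherits(cfg, "cleaning_config"))
  n_in <- nrow(posts)
  norm <- normalize_text(posts$text)
  noise <- normalize_text(cfg$noise_terms)
  noisy <- rep(FALSE, n_in)
  for (term in noise) {
    noisy <- noisy | grepl(term, norm, fixed = TRUE)
  }
  posts2 <- posts[!noisy, , drop = FALSE]
  norm2 <- norm[!noisy]
  long <- nchar(norm2) > cfg$dedup_min_chars
  dup <- long & duplicated(norm2)
  out <- posts2[!dup, , drop = FALSE]
  rownames(out) <- NULL
  report <- structure(list(
    n_input = n_in,
    n_removed_noise = sum(noisy),
    n_removed_duplicate = sum(dup),
    n_retained = nrow(out)
  ), class = "cleaning_report")
  list(posts = out, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Corpus cleaning report\n")
  cat(sprintf("  input:              %d\n", x$n_input))
  cat(sprintf("  removed (noise):    %d\n", x$n_removed_noise))
  cat(sprintf("  removed (dedup):    %d\n", x$n_removed_duplicate))
  cat(sprintf("  retained:           %d\n", x$n_retained))
  invisible(x)
}

#' Screen posts by seed keywords
#'
#' Retains exactly the posts whose normalized text contains at least one
#' lexicon term as a substring; input order is preserved.
#'
#' @param posts posts data.frame.
#' @param lexicon a [seed_lexicon()] or character vector of terms.
#' @return the retained subset of `posts`.
#' @export
screen_seeds <- function(posts, lexicon) {
  if (is.character(lexicon)) lexicon <- seed_lexicon(lexicon)
  stopifnot(inherits(lexicon, "seed_lexicon"))
  norm <- normalize_text(posts$text)
  terms <- normalize_text(lexicon$terms)
  hit <- rep(FALSE, nrow(posts))
  for (term in terms) hit <- hit | grepl(term, norm, fixed = TRUE)
  out <- posts[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Corpus accounting statistics
#'
#' @param posts posts data.frame.
#' @return list: `n_posts`, `n_users`, `mean_posts_per_user`,
#'   `mean_chars_per_post` (means rounded to 2 decimals). Per-user fields
#'   are NA with a warning when no user ids are present.
#' @export
corpus_stats <- function(posts) {
  n <- nrow(posts)
  chars <- nchar(posts$text)
  has_users <- "user_id" %in% names(posts) && any(!is.na(posts$user_id))
  if (!has_users) {
    warning("no user ids present; per-user statistics unavailable")
    n_users <- NA_integer_
    mppu <- NA_real_
  } else {
    uid <- posts$user_id[!is.na(posts$user_id)]
    n_users <- length(unique(uid))
    mppu <- round(length(uid) / n_users, 2)
  }
  list(n_posts = n, n_users = n_users,
       mean_posts_per_user = mppu,
       mean_chars_per_post = if (n > 0) round(mean(chars), 2) else NA_real_)
}
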