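# Mapping candidate factor terms onto closed-vocabulary lexicon
# categories, Top-k ranking, and per-group category proportions.
#
# The proprietary LIWC Chinese dictionary is not shipped; any dictionary
# in the two-file TSV format can be used. A 52-category toy lexicon with
# a 52 -> 9 grouping map ships for tests and examples.

#' Load a category lexicon
#'
#' @param lexicon_path TSV with columns `category`, `term`.
#' @param groups_path TSV with columns `category`, `group` mapping each
#'   category to a broader group.
#' @return an object of class `category_lexicon`: list with `categories`
#'   (named list of term vectors, normalized), `group_of` (named
#'   character).
#' @export
read_lexicon <- function(lexicon_path, groups_path) {
  lex <- read.delim(lexicon_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  grp <- read.delim(groups_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  stopifnot(all(c("category", "term") %in% names(lex)),
            all(c("category", "group") %in% names(grp)))
  categories <- lapply(split(normalize_text(lex$term), lex$category), unique)
  if (any(lengths(categories) == 0)) stop("lexicon has empty categories")
  group_of <- setNames(grp$group, grp$category)
  missing <- setdiff(names(categories), names(group_of))
  if (length(missing)) {
    stop("categories without a group: ", paste(missing, collapse = ", "))
  }
  structure(list(categories = categories,
                 group_of = group_of[names(categories)]),
            class = "category_lexicon")
}

#' The shipped toy lexicon (52 categories, 9 groups)
#'
#' A small stand-in dictionary over Latin tokens, aligned with the
#' synthetic post generator's vocabulary.
#'
#' @return a `category_lexicon`.
#' @export
toy_lexicon <- function() {
  read_lexicon(system.file("extdata", "toy_lexicon.tsv", package = "milscope"),
               system.file("extdata", "toy_groups.tsv", package = "milscope"))
}

#' @export
print.category_lexicon <- function(x, ...) {
  cat(sprintf("Category lexicon: %d categories in %d groups, %d terms\n",
              length(x$categories), length(unique(x$group_of)),
              sum(lengths(x$categories))))
  invisible(x)
}

#' Map candidate terms to lexicon categories
#'
#' Each candidate increments every category containing it (a word in two
#' categories increments both); unmatched candidates are recorded.
#'
#' @param candidates character vector of candidate terms.
#' @param lexicon a `category_lexicon`.
#' @return list with `counts` (named integer over hit categories),
#'   `matched` (data.frame `term`, `category`), `unmatched` (character).
#' @export
map_terms <- function(candidates, lexicon) {
  stopifnot(inherits(lexicon, "category_lexicon"))
  if (length(lexicon$categories) == 0) stop("empty lexicon")
  cand <- normalize_text(candidates)
  hits <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    in_cat <- vapply(lexicon$categories, function(terms) cand[i] %in% terms,
                     logical(1))
    if (any(in_cat)) {
      hits[[i]] <- data.frame(term = cand[i],
                              category = names(lexicon$categories)[in_cat],
                              stringsAsFactors = FALSE)
    }
  }
  matched <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(matched)) {
    matched <- data.frame(term = character(), category = character(),
                          stringsAsFactors = FALSE)
  }
  counts <- table(matched$category)
  list(counts = setNames(as.integer(counts), names(counts)),
       matched = matched,
       unmatched = cand[!cand %in% matched$term])
}

#' Rank the Top-k categories
#'
#' Deterministic ordering: count descending, then category name ascending.
#'
#' @param counts named numeric/integer vector of category counts.
#' @param k number of categories to return.
#' @return character vector of at most k category names.
#' @export
rank_topk <- function(counts, k) {
  stopifnot(k >= 1)
  if (length(counts) == 0) return(character(0))
  ord <- order(-as.numeric(counts), names(counts))
  head(names(counts)[ord], k)
}

#' Per-post factor assignments
#'
#' Maps each post's extracted factor terms to lexicon categories and
#' ranks the Top-k categories per post.
#'
#' @param terms data.frame `post_id`, `term` (as from
#'   [extract_factors()]).
#' @param lexicon a `category_lexicon`.
#' @param k Top-k depth (default 3).
#' @return list with `counts` (data.frame `post_id`, `category`,
#'   `count`), `topk` (data.frame `post_id`, `rank`, `category`),
#'   `unmatched` (data.frame `post_id`, `term`).
#' @export
factor_assignments <- function(terms, lexicon, k = 3) {
  ids <- unique(terms$post_id)
  cnt <- vector("list", length(ids))
  top <- vector("list", length(ids))
  unm <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    m <- map_terms(terms$term[terms$post_id == ids[i]], lexicon)
    if (length(m$counts)) {
      cnt[[i]] <- data.frame(post_id = ids[i], category = names(m$counts),
                             count = as.integer(m$counts),
                             stringsAsFactors = FALSE)
      tk <- rank_topk(m$counts, k)
      top[[i]] <- data.frame(post_id = ids[i], rank = seq_along(tk),
                             category = tk, stringsAsFactors = FALSE)
    }
    if (length(m$unmatched)) {
      unm[[i]] <- data.frame(post_id = ids[i], term = m$unmatched,
                             stringsAsFactors = FALSE)
    }
  }
  bind <- function(l, proto) {
    l <- l[!vapply(l, is.null, logical(1))]
    if (length(l)) do.call(rbind, l) else proto
  }
  list(
    counts = bind(cnt, data.frame(post_id = character(),
                                  category = character(), count = integer(),
                                  stringsAsFactors = FALSE)),
    topk = bind(top, data.frame(post_id = character(), rank = integer(),
                                category = character(),
                                stringsAsFactors = FALSE)),
    unmatched = bind(unm, data.frame(post_id = character(),
                                     term = character(),
                                     stringsAsFactors = FALSE))
  )
}

#' Post-by-category count matrix
#'
#' @param counts data.frame `post_id`, `category`, `count` (as from
#'   [factor_assignments()]).
#' @param categories column universe (default: all lexicon categories in
#'   `counts`); fixed column order across subgroups.
#' @param post_ids row universe (default: posts present in `counts`).
#' @return integer matrix posts x categories with dimnames.
#' @export
counts_matrix <- function(counts, categories = sort(unique(counts$category)),
                          post_ids = unique(counts$post_id)) {
  m <- matrix(0L, nrow = length(post_ids), ncol = length(categories),
              dimnames = list(post_ids, categories))
  keep <- counts$post_id %in% post_ids & counts$category %in% categories
  cc <- counts[keep, , drop = FALSE]
  m[cbind(match(cc$post_id, post_ids), match(cc$category, categories))] <-
    as.integer(cc$count)
  m
}

.subgroup_keys <- c("S1", "S0", "P1", "P0", "S1P1", "S1P0", "S0P1", "S0P0")

#' Category proportions per MIL subgroup
#'
#' For each subgroup, the percentage of its posts whose factor counts
#' include each category (multi-label: rows need not sum to 100).
#'
#' @param subgroups named list of post-by-category count matrices, keyed
#'   by the eight subgroup codes (as from [split_subgroups()]).
#' @return matrix subgroups x categories of percentages in \[0, 100\].
#' @export
group_proportions <- function(subgroups) {
  unknown <- setdiff(names(subgroups), .subgroup_keys)
  if (length(unknown)) {
    stop("unknown group tag(s): ", paste(unknown, collapse = ", "))
  }
  cats <- colnames(subgroups[[1]])
  out <- matrix(0, nrow = length(subgroups), ncol = length(cats),
                dimnames = list(names(subgroups), cats))
  for (g in names(subgroups)) {
    m <- subgroups[[g]]
    if (!identical(colnames(m), cats)) stop("column order differs across subgroups")
    if (nrow(m) == 0) {
      warning("empty subgroup: ", g)
      next
    }
    out[g, ] <- 100 * colMeans(m > 0)
  }
  out
}
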