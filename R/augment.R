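# Data augmentation: random deletion of noncritical tokens and
# similarity-gated synonym replacement, up to a task-specific target size.

#' Augmentation configuration
#'
#' @param target_size desired output size (>= input size).
#' @param sim_threshold cosine-similarity gate for synonym replacement;
#'   replacements must satisfy cosine > threshold (strict, default 0.80).
#' @param max_deletions 1 or 2 noncritical tokens removed per deletion op.
#' @param qc_fraction fraction of augmented posts emitted for manual
#'   review (default 0.10).
#' @param seed integer seed.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(target_size, sim_threshold = 0.80,
                           max_deletions = 2, qc_fraction = 0.10, seed = 1) {
  stopifnot(sim_threshold > 0, sim_threshold < 1, max_deletions %in% c(1, 2),
            qc_fraction >= 0, qc_fraction <= 1)
  structure(list(target_size = as.integer(target_size),
                 sim_threshold = sim_threshold,
                 max_deletions = as.integer(max_deletions),
                 qc_fraction = qc_fraction, seed = as.integer(seed)),
            class = "augment_config")
}

#' Deterministic character-n-gram embedding provider
#'
#' A lightweight stand-in for a sentence-embedding model: character
#' n-grams are hash-bucketed into a fixed-length count vector, L2
#' normalized. Same text always maps to the same vector. Morphological
#' near-variants of a word score high cosine similarity; unrelated words
#' score near zero.
#'
#' @param dim vector dimension (default 256).
#' @param n n-gram size (default 3).
#' @return a function `(text) -> numeric vector` of length `dim`.
#' @export
ngram_embedding <- function(dim = 256, n = 3) {
  force(dim); force(n)
  function(text) {
    text <- normalize_text(text)
    v <- numeric(dim)
    chars <- utf8ToInt(text)
    if (length(chars) < n) {
      grams <- if (length(chars) > 0) list(chars) else list()
    } else {
      grams <- lapply(seq_len(length(chars) - n + 1),
                      function(i) chars[i:(i + n - 1)])
    }
    for (g in grams) {
      h <- 7
      for (c in g) h <- (h * 131 + c) %% dim
      v[h + 1] <- v[h + 1] + 1
    }
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v / nrm else v
  }
}

#' Cosine similarity between two vectors
#'
#' @param u,v numeric vectors of equal length.
#' @return cosine similarity in \[-1, 1\]; 0 if either vector is zero.
#' @export
cosine_sim <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

#' Default noncritical-token tagger
#'
#' Tags adverbs/intensifiers/particles (a fixed function-word list) as
#' noncritical, i.e. deletable without altering the central meaning.
#'
#' @return a function `(tokens) -> logical vector` (TRUE = noncritical).
#' @export
default_noncritical <- function() {
  lst <- c("very", "really", "just", "so", "too", "quite", "again",
           "still", "also", "often", "rather", "pretty", "somewhat")
  function(tokens) normalize_text(tokens) %in% lst
}

#' Default near-synonym candidate table
#'
#' Morphological variants of generator vocabulary words; under the shipped
#' character-n-gram embedding each listed candidate passes the 0.80
#' cosine gate against its key.
#'
#' @return named list: word -> character vector of candidates.
#' @export
default_synonyms <- function() {
  list(
    meaning = "meanings", purpose = "purposes", dream = "dreams",
    sleepless = "sleeplessly", nightmare = "nightmares",
    searching = "searchings", fulfilled = "fulfilledness",
    grateful = "gratefulness", pointless = "pointlessness",
    insomnia = "insomniac", exploration = "explorations"
  )
}

#' Random deletion of noncritical tokens
#'
#' Removes `k` (1 or 2) noncritical tokens at random; critical tokens are
#' never removed. If no token is deletable the input is returned
#' unchanged with attribute `flagged = TRUE`; if fewer than `k` are
#' deletable, all deletable tokens are removed and the result flagged.
#'
#' @param tokens character vector.
#' @param k number of deletions (1 or 2).
#' @param noncritical logical vector marking deletable tokens, or a tagger
#'   function as from [default_noncritical()].
#' @return token vector, possibly with attribute `flagged`.
#' @export
random_deletion <- function(tokens, k = 1, noncritical = default_noncritical()) {
  stopifnot(k %in% c(1, 2))
  nc <- if (is.function(noncritical)) noncritical(tokens) else as.logical(noncritical)
  stopifnot(length(nc) == length(tokens))
  idx <- which(nc)
  if (length(idx) == 0) {
    attr(tokens, "flagged") <- TRUE
    return(tokens)
  }
  kk <- min(k, length(idx))
  drop <- if (length(idx) == 1) idx else sample(idx, kk)
  out <- tokens[-drop]
  if (kk < k) attr(out, "flagged") <- TRUE
  out
}

#' Similarity-gated synonym replacement
#'
#' Replaces one randomly chosen token with a candidate synonym whose
#' embedding cosine similarity with the original strictly exceeds
#' `threshold`. If no token has an acceptable candidate the input is
#' returned unchanged with attribute `flagged = TRUE`.
#'
#' @param tokens character vector.
#' @param synonyms named list word -> candidate vector.
#' @param provider embedding provider function (same text, same vector).
#' @param threshold cosine gate (default 0.80, strict inequality).
#' @return token vector, possibly with attribute `flagged`.
#' @export
synonym_replace <- function(tokens, synonyms = default_synonyms(),
                            provider = ngram_embedding(), threshold = 0.80) {
  key <- normalize_text(tokens)
  eligible <- which(key %in% names(synonyms))
  if (length(eligible) > 1) eligible <- sample(eligible)
  for (i in eligible) {
    cands <- synonyms[[key[i]]]
    if (length(cands) > 1) cands <- sample(cands)
    ev <- provider(tokens[i])
    for (cand in cands) {
      if (cosine_sim(ev, provider(cand)) > threshold) {
        tokens[i] <- cand
        return(tokens)
      }
    }
  }
  attr(tokens, "flagged") <- TRUE
  tokens
}

#' Expand a labeled post set to a target size
#'
#' Cycles over source posts round-robin within each label class
#' (allocation across classes is proportional to the input class mix),
#' alternating random deletion and synonym replacement, until the target
#' size is reached. Every augmented post carries its source label, a
#' `source_id` and an `aug_op` provenance tag; a `qc_fraction` sample of
#' the augmented posts is returned for manual review.
#'
#' @param posts data.frame: `post_id`, `text`, `label`.
#' @param cfg an [augment_config()].
#' @param synonyms,provider,noncritical see [synonym_replace()] and
#'   [random_deletion()].
#' @return list with `posts` (target_size rows; original rows carry
#'   `aug_op = "none"`) and `qc` (review sample of augmented rows).
#' @export
augment_to_target <- function(posts, cfg, synonyms = default_synonyms(),
                              provider = ngram_embedding(),
                              noncritical = default_noncritical()) {
  stopifnot(inherits(cfg, "augment_config"),
            all(c("post_id", "text", "label") %in% names(posts)))
  n_in <- nrow(posts)
  if (cfg$target_size < n_in) stop("target_size must be >= input size")
  n_need <- cfg$target_size - n_in
  set.seed(derive_seed(cfg$seed, "augment"))

  orig <- data.frame(post_id = posts$post_id, text = posts$text,
                     label = posts$label, source_id = posts$post_id,
                     aug_op = "none", stringsAsFactors = FALSE)
  if (n_need == 0) return(list(posts = orig, qc = orig[0, , drop = FALSE]))

  # proportional per-class allocation, largest remainder
  cls <- table(posts$label)
  share <- n_need * as.numeric(cls) / n_in
  alloc <- floor(share)
  rem <- n_need - sum(alloc)
  if (rem > 0) {
    ord <- order(share - alloc, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
  }
  names(alloc) <- names(cls)

  aug <- vector("list", n_need)
  ai <- 0L
  for (cl in names(alloc)) {
    src <- posts[posts$label == cl, , drop = FALSE]
    need <- alloc[[cl]]
    made <- 0L
    pos <- 0L
    fails <- 0L
    while (made < need) {
      pos <- pos %% nrow(src) + 1L
      op <- if ((made + fails) %% 2 == 0) "deletion" else "synonym"
      toks <- tokenize_ws(src$text[pos])
      out <- if (op == "deletion") {
        random_deletion(toks, k = sample(cfg$max_deletions, 1),
                        noncritical = noncritical)
      } else {
        synonym_replace(toks, synonyms, provider, cfg$sim_threshold)
      }
      if (isTRUE(attr(out, "flagged")) && identical(unname(out), toks)) {
        fails <- fails + 1L
        if (fails > 2L * nrow(src) + 4L) {
          stop("cannot reach target size: ", need - made,
               " post(s) short in class ", cl)
        }
        next
      }
      made <- made + 1L; ai <- ai + 1L
      aug[[ai]] <- data.frame(
        post_id = paste0(src$post_id[pos], "_aug", made),
        text = paste(out, collapse = " "), label = cl,
        source_id = src$post_id[pos], aug_op = op,
        stringsAsFactors = FALSE)
    }
  }
  aug <- do.call(rbind, aug[seq_len(ai)])
  n_qc <- ceiling(cfg$qc_fraction * nrow(aug))
  qc <- aug[sample.int(nrow(aug), n_qc), , drop = FALSE]
  rownames(qc) <- NULL
  out <- rbind(orig, aug)
  rownames(out) <- NULL
  list(posts = out, qc = qc)
}
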