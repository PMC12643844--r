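# Synthetic-data generators. Every downstream test fixture comes from
# these functions: class-conditional pseudo-text posts, annotator label
# tables, role-triple files, and Gaussian samples with planted sparse
# precision structure. Fixtures use Latin-token pseudo-text; the core
# operations are script-agnostic and the real-language path differs only
# in the tokenizer/parser adapters.

.mil_seed_terms <- c("meaning", "purpose", "value", "faith", "ideal",
                     "aspiration", "future", "pursuit", "quest", "seek",
                     "establish", "presence", "exploration")
.sleep_terms <- c("insomnia", "sleep", "sleepless", "night", "awake",
                  "dream", "nightmare", "sleepy")
.sfm_high_terms <- c("searching", "wondering", "questioning", "looking")
.sfm_low_terms <- c("settled", "content", "certain", "steady")
.pom_high_terms <- c("fulfilled", "grateful", "proud", "whole")
.pom_low_terms <- c("empty", "lost", "pointless", "hollow")
.filler_terms <- c("today", "really", "very", "just", "again", "morning",
                   "coffee", "weather", "bus", "work", "home", "phone")

#' Default vocabulary of the synthetic post generator
#'
#' @return named list of term vectors: `mil_seeds`, `sleep`, `sfm_high`,
#'   `sfm_low`, `pom_high`, `pom_low`, `filler`.
#' @export
synth_vocab <- function() {
  list(mil_seeds = .mil_seed_terms, sleep = .sleep_terms,
       sfm_high = .sfm_high_terms, sfm_low = .sfm_low_terms,
       pom_high = .pom_high_terms, pom_low = .pom_low_terms,
       filler = .filler_terms)
}

#' Generate class-conditional labeled posts
#'
#' Draws short whitespace-tokenized pseudo-posts. Every MIL-related post
#' contains at least one MIL seed term; SFM and POM levels inject
#' class-specific marker terms with probability `margin`, so the three
#' tasks are separable at a controllable margin (at `margin = 1` a
#' bag-of-words linear probe separates the classes perfectly).
#'
#' @param n number of posts.
#' @param seed integer seed.
#' @param rel_prior probability a post is MIL-related (default 0.5).
#' @param sfm_prior,pom_prior probability of the HIGH level given related.
#' @param margin probability a class marker term is injected (default 1).
#' @param n_users number of distinct users posts are spread over.
#' @param vocab vocabulary list as from [synth_vocab()].
#' @return data.frame: `post_id`, `user_id`, `text`, `created_at`,
#'   `rel` (`RELATED`/`NOT_RELATED`), `sfm`, `pom` (`HIGH`/`LOW`, NA when
#'   not related).
#' @export
gen_posts <- function(n, seed = 1, rel_prior = 0.5, sfm_prior = 0.5,
                      pom_prior = 0.5, margin = 1, n_users = max(1, n %/% 10),
                      vocab = synth_vocab()) {
  set.seed(derive_seed(seed, "posts"))
  rel <- runif(n) < rel_prior
  sfm <- ifelse(rel, ifelse(runif(n) < sfm_prior, "HIGH", "LOW"), NA)
  pom <- ifelse(rel, ifelse(runif(n) < pom_prior, "HIGH", "LOW"), NA)
  users <- paste0("u", sprintf("%04d", sample.int(n_users, n, replace = TRUE)))
  text <- character(n)
  for (i in seq_len(n)) {
    toks <- sample(vocab$filler, 4 + sample.int(4, 1), replace = TRUE)
    toks <- c(toks, sample(vocab$sleep, 1))
    if (rel[i]) {
      toks <- c(toks, sample(vocab$mil_seeds, 1))
      if (runif(1) < margin) {
        toks <- c(toks, sample(if (sfm[i] == "HIGH") vocab$sfm_high else vocab$sfm_low, 1))
        toks <- c(toks, sample(if (pom[i] == "HIGH") vocab$pom_high else vocab$pom_low, 1))
      }
    } else if (runif(1) < (1 - margin)) {
      toks <- c(toks, sample(vocab$mil_seeds, 1))
    }
    text[i] <- paste(sample(toks), collapse = " ")
  }
  data.frame(
    post_id = paste0("p", sprintf("%06d", seq_len(n))),
    user_id = users,
    text = text,
    created_at = format(as.POSIXct("2021-01-15", tz = "UTC") +
                          sample.int(86400 * 180, n, replace = TRUE),
                        "%Y-%m-%dT%H:%M:%SZ"),
    rel = ifelse(rel, "RELATED", "NOT_RELATED"),
    sfm = sfm, pom = pom,
    stringsAsFactors = FALSE
  )
}

#' Generate annotator label tables from gold labels
#'
#' Each annotator independently flips the gold label with probability
#' `error_rate` and emits UNABLE with probability `unable_rate`.
#'
#' @param gold data.frame with `post_id` and a gold label column
#'   (`POSITIVE`/`NEGATIVE`).
#' @param task task code (`REL`, `SFM`, `POM`).
#' @param error_rate per-annotator flip probability.
#' @param unable_rate per-annotator UNABLE probability.
#' @param n_annotators annotators per post (default 2).
#' @param seed integer seed.
#' @param label_col name of the gold label column (default `"label"`).
#' @return data.frame of annotation records: `post_id`, `annotator_id`,
#'   `task`, `label`.
#' @export
gen_annotations <- function(gold, task = "REL", error_rate = 0.1,
                            unable_rate = 0.05, n_annotators = 2, seed = 1,
                            label_col = "label") {
  stopifnot(error_rate >= 0, error_rate <= 1, unable_rate >= 0, unable_rate <= 1)
  set.seed(derive_seed(seed, paste0("ann", task)))
  n <- nrow(gold)
  out <- vector("list", n_annotators)
  flip <- function(l) ifelse(l == "POSITIVE", "NEGATIVE", "POSITIVE")
  for (a in seq_len(n_annotators)) {
    lab <- as.character(gold[[label_col]])
    do_flip <- runif(n) < error_rate
    lab[do_flip] <- flip(lab[do_flip])
    lab[runif(n) < unable_rate] <- "UNABLE"
    out[[a]] <- data.frame(post_id = gold$post_id,
                           annotator_id = paste0("a", a),
                           task = task, label = lab,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate sentence-level role triples for posts
#'
#' A fraction `reas_fraction` of units receives a reason-anchored chain of
#' role triples of the given depth (REAS at layer 0, then CONT/AGT/TIME
#' links outward); remaining units receive non-REAS triples only, so they
#' are unextractable by the reason-anchored expansion. Chain words are
#' drawn from `term_pool` so downstream lexicon mapping has targets.
#'
#' @param posts data.frame with `post_id` (one unit per post is emitted).
#' @param reas_fraction fraction of units given a REAS anchor.
#' @param depth chain depth (1-4): a depth-d chain populates layers
#'   0..(d-1) of the expansion.
#' @param seed integer seed.
#' @param term_pool words used for chain nodes (default: generator
#'   marker + filler terms).
#' @return data.frame of triples: `post_id`, `unit_id`, `word_a`,
#'   `word_b`, `role`.
#' @export
gen_triples <- function(posts, reas_fraction = 0.5, depth = 4, seed = 1,
                        term_pool = NULL) {
  stopifnot(depth >= 1, depth <= 4)
  set.seed(derive_seed(seed, "triples"))
  v <- synth_vocab()
  if (is.null(term_pool)) {
    term_pool <- unique(c(v$pom_high, v$pom_low, v$sfm_high, v$sfm_low,
                          v$sleep, v$filler))
  }
  chain_roles <- c("REAS", "CONT", "AGT", "TIME")
  other_roles <- c("AGT", "EXP", "PAT", "CONT", "DATV", "LINK", "TIME", "LOC")
  res <- vector("list", nrow(posts))
  for (i in seq_len(nrow(posts))) {
    pid <- posts$post_id[i]
    uid <- paste0(pid, "_u1")
    anchored <- runif(1) < reas_fraction
    words <- sample(term_pool, depth + 1)
    if (anchored) {
      roles <- chain_roles[seq_len(depth)]
    } else {
      roles <- sample(other_roles, depth, replace = TRUE)
    }
    res[[i]] <- data.frame(post_id = pid, unit_id = uid,
                           word_a = words[seq_len(depth)],
                           word_b = words[seq_len(depth) + 1],
                           role = roles, stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Build a planted sparse precision matrix
#'
#' @param p dimension (>= 2).
#' @param structure `"chain"` (off-diagonal `value` on the first
#'   off-diagonal), `"block"` (two dense blocks of size `p %/% 2`), or
#'   `"empty"` (identity).
#' @param value off-diagonal precision value (default -0.4).
#' @return list with `omega` (precision matrix) and `edges` (2-column
#'   matrix of true edge index pairs, i < j).
#' @export
make_precision <- function(p, structure = c("chain", "block", "empty"),
                           value = -0.4) {
  structure <- match.arg(structure)
  stopifnot(p >= 2)
  omega <- diag(p)
  if (structure == "chain") {
    for (i in seq_len(p - 1)) omega[i, i + 1] <- omega[i + 1, i] <- value
  } else if (structure == "block") {
    half <- p %/% 2
    for (i in seq_len(half)) for (j in seq_len(half)) {
      if (i != j) omega[i, j] <- value / 2
    }
    for (i in (half + 1):p) for (j in (half + 1):p) {
      if (i != j) omega[i, j] <- value / 2
    }
  }
  ut <- which(upper.tri(omega) & omega != 0, arr.ind = TRUE)
  colnames(omega) <- rownames(omega) <- paste0("V", seq_len(p))
  list(omega = omega, edges = ut)
}

#' Sample Gaussian data from a planted precision matrix
#'
#' @param precision list as returned by [make_precision()], or a precision
#'   matrix.
#' @param n sample size.
#' @param seed integer seed.
#' @return list with `x` (n x p sample matrix), `omega`, `edges`.
#' @export
gen_gaussian <- function(precision, n, seed = 1) {
  if (is.matrix(precision)) {
    omega <- precision
    ut <- which(upper.tri(omega) & omega != 0, arr.ind = TRUE)
    precision <- list(omega = omega, edges = ut)
  }
  omega <- precision$omega
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("precision matrix is not positive definite")
  sigma <- solve(omega)
  set.seed(derive_seed(seed, "gauss"))
  x <- MASS::mvrnorm(n, mu = rep(0, ncol(omega)), Sigma = sigma)
  colnames(x) <- colnames(omega)
  list(x = x, omega = omega, edges = precision$edges)
}

#' Score edge recovery of an estimated network against planted structure
#'
#' @param network a `mil_network` (or weight matrix).
#' @param edges true edge pairs (2-column matrix, i < j).
#' @return list with `precision`, `recall`, `n_true`, `n_est`.
#' @export
edge_recovery <- function(network, edges) {
  w <- if (inherits(network, "mil_network")) network$weights else as.matrix(network)
  est <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  key <- function(m) paste(m[, 1], m[, 2])
  tp <- length(intersect(key(est), key(edges)))
  list(
    precision = if (nrow(est) == 0) NA_real_ else tp / nrow(est),
    recall = if (nrow(edges) == 0) NA_real_ else tp / nrow(edges),
    n_true = nrow(edges), n_est = nrow(est)
  )
}
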