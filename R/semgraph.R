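# Semantic dependency graphs from role triples, and the reason-anchored
# layered expansion yielding candidate associated-factor terms.
#
# Triples come from any external semantic-role parser; this module
# consumes <(wordA, wordB), Role> triples, it does not parse.

.role_codes <- c("REAS", "AGT", "EXP", "PAT", "CONT", "DATV", "LINK",
                 "TIME", "LOC")

#' The nine semantic dependency role codes
#' @return character vector of role codes.
#' @export
role_codes <- function() .role_codes

#' Split text into linguistic units
#'
#' Units are sentences ending with a period, exclamation mark or question
#' mark (ASCII or CJK forms); trailing text without terminal punctuation
#' forms a final unit.
#'
#' @param text a single string.
#' @return character vector of unit strings (possibly empty).
#' @export
split_units <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  parts <- strsplit(text, "(?<=[.!?。！？])", perl = TRUE)[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Read role triples from a TSV file
#'
#' Columns: `post_id`, `unit_id`, `word_a`, `word_b`, `role`.
#'
#' @param path file path.
#' @return triples data.frame.
#' @export
read_triples <- function(path) {
  if (!file.exists(path)) stop("triple file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("post_id", "unit_id", "word_a", "word_b", "role")
  if (!all(need %in% names(df))) {
    stop("triple file must have columns: ", paste(need, collapse = ", "))
  }
  df[need]
}

#' Build a semantic dependency graph from role triples
#'
#' One node per normalized word (stop nodes and pure-punctuation tokens
#' excluded). Edges are stored undirected with the role set retained;
#' edge weight is the corpus count of links between the pair aggregated
#' across units and posts. Self-links are dropped, and edges with weight
#' below `min_edge_weight` are pruned.
#'
#' @param triples data.frame: `post_id`, `unit_id`, `word_a`, `word_b`,
#'   `role`.
#' @param min_edge_weight prune edges with lower corpus count (default 2).
#' @param stop_nodes character vector of words excluded as nodes.
#' @return an object of class `semantic_graph`: list with `nodes`
#'   (data.frame `node`, `freq`), `edges` (pruned: `node_a`, `node_b`,
#'   `roles`, `weight`), `edges_all` (pre-pruning), `n_triples_used`.
#' @export
build_graph <- function(triples, min_edge_weight = 2, stop_nodes = character()) {
  bad <- setdiff(unique(triples$role), .role_codes)
  if (length(bad)) stop("unknown role code(s): ", paste(bad, collapse = ", "))
  a <- normalize_text(triples$word_a)
  b <- normalize_text(triples$word_b)
  stop_nodes <- normalize_text(stop_nodes)
  is_punct <- function(x) grepl("^[[:punct:]]+$", x)
  keep <- nzchar(a) & nzchar(b) & a != b &
    !(a %in% stop_nodes) & !(b %in% stop_nodes) &
    !is_punct(a) & !is_punct(b)
  a <- a[keep]; b <- b[keep]; role <- triples$role[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (length(key) == 0) {
    edges <- data.frame(node_a = character(), node_b = character(),
                        roles = character(), weight = integer(),
                        stringsAsFactors = FALSE)
    return(structure(list(nodes = data.frame(node = character(),
                                             freq = integer(),
                                             stringsAsFactors = FALSE),
                          edges = edges, edges_all = edges,
                          n_triples_used = 0L,
                          min_edge_weight = min_edge_weight),
                     class = "semantic_graph"))
  }
  agg_w <- tapply(rep(1L, length(key)), key, sum)
  agg_r <- tapply(role, key, function(r) paste(sort(unique(r)), collapse = ","))
  ks <- names(agg_w)
  parts <- strsplit(ks, "\r", fixed = TRUE)
  edges_all <- data.frame(
    node_a = vapply(parts, `[`, "", 1),
    node_b = vapply(parts, `[`, "", 2),
    roles = as.character(agg_r[ks]),
    weight = as.integer(agg_w[ks]),
    stringsAsFactors = FALSE, row.names = NULL)
  edges_all <- edges_all[order(edges_all$node_a, edges_all$node_b), , drop = FALSE]
  rownames(edges_all) <- NULL
  edges <- edges_all[edges_all$weight >= min_edge_weight, , drop = FALSE]
  rownames(edges) <- NULL
  freq <- table(c(a, b))
  nodes <- data.frame(node = names(freq), freq = as.integer(freq),
                      stringsAsFactors = FALSE, row.names = NULL)
  nodes <- nodes[order(nodes$node), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, edges_all = edges_all,
                 n_triples_used = length(key),
                 min_edge_weight = min_edge_weight),
            class = "semantic_graph")
}

#' @export
print.semantic_graph <- function(x, ...) {
  cat(sprintf("Semantic dependency graph: %d nodes, %d edges (%d before pruning at weight >= %d)\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$edges_all),
              x$min_edge_weight))
  invisible(x)
}

#' Reason-anchored layered expansion
#'
#' Layer 0 is the set of endpoints of REAS-labeled edges; layer k
#' (1 <= k <= `max_layers`) contains nodes linked by any of the nine roles
#' to a layer k-1 node and not yet assigned (breadth-first, so a node is
#' assigned its smallest reachable layer). Nodes beyond `max_layers` are
#' excluded. Units without a REAS anchor are unextractable.
#'
#' @param graph a `semantic_graph`.
#' @param max_layers deepest layer (default 3).
#' @return list with `layer_of` (named integer vector over reached
#'   nodes), `layers` (list of node sets per layer), `extractable`
#'   (FALSE when no REAS edge exists).
#' @export
reason_expansion <- function(graph, max_layers = 3) {
  stopifnot(inherits(graph, "semantic_graph"))
  e <- graph$edges
  has_reas <- vapply(strsplit(e$roles, ","), function(r) "REAS" %in% r,
                     logical(1))
  if (!any(has_reas)) {
    return(list(layer_of = setNames(integer(0), character(0)),
                layers = list(), extractable = FALSE))
  }
  layer0 <- sort(unique(c(e$node_a[has_reas], e$node_b[has_reas])))
  layer_of <- setNames(rep(0L, length(layer0)), layer0)
  layers <- list(`0` = layer0)
  frontier <- layer0
  for (k in seq_len(max_layers)) {
    touch_a <- e$node_b[e$node_a %in% frontier]
    touch_b <- e$node_a[e$node_b %in% frontier]
    nxt <- sort(setdiff(unique(c(touch_a, touch_b)), names(layer_of)))
    if (length(nxt) == 0) break
    layer_of[nxt] <- k
    layers[[as.character(k)]] <- nxt
    frontier <- nxt
  }
  list(layer_of = layer_of, layers = layers, extractable = TRUE)
}

#' Extract candidate associated-factor terms
#'
#' Returns all layered nodes ordered by (layer ascending, corpus
#' frequency descending, term ascending).
#'
#' @param graph the `semantic_graph` the expansion ran on.
#' @param expansion result of [reason_expansion()].
#' @return data.frame: `term`, `layer`, `freq`.
#' @export
extract_factor_terms <- function(graph, expansion) {
  lo <- expansion$layer_of
  if (length(lo) == 0) {
    return(data.frame(term = character(), layer = integer(),
                      freq = integer(), stringsAsFactors = FALSE))
  }
  freq <- setNames(graph$nodes$freq, graph$nodes$node)
  out <- data.frame(term = names(lo), layer = as.integer(lo),
                    freq = as.integer(freq[names(lo)]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$layer, -out$freq, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-post factor-term extraction
#'
#' Convenience pipeline step: for each post, builds the within-post
#' semantic graph from its triples (no pruning within a single post),
#' runs the reason-anchored expansion, and collects factor terms. Posts
#' whose units carry no REAS anchor are flagged unextractable; the
#' extraction yield is the fraction of posts with at least one factor
#' term.
#'
#' @param triples triples data.frame (`post_id`, `unit_id`, `word_a`,
#'   `word_b`, `role`).
#' @param max_layers passed to [reason_expansion()].
#' @param stop_nodes passed to [build_graph()].
#' @return list with `terms` (data.frame `post_id`, `term`, `layer`,
#'   `freq`), `extractable` (named logical per post), `yield` (fraction
#'   extractable).
#' @export
extract_factors <- function(triples, max_layers = 3, stop_nodes = character()) {
  ids <- unique(triples$post_id)
  terms <- vector("list", length(ids))
  ok <- setNames(logical(length(ids)), ids)
  for (i in seq_along(ids)) {
    tr <- triples[triples$post_id == ids[i], , drop = FALSE]
    g <- build_graph(tr, min_edge_weight = 1, stop_nodes = stop_nodes)
    ex <- reason_expansion(g, max_layers = max_layers)
    ok[i] <- ex$extractable
    if (ex$extractable) {
      ft <- extract_factor_terms(g, ex)
      ft$post_id <- ids[i]
      terms[[i]] <- ft[c("post_id", "term", "layer", "freq")]
    }
  }
  terms <- terms[!vapply(terms, is.null, logical(1))]
  terms <- if (length(terms)) do.call(rbind, terms) else
    data.frame(post_id = character(), term = character(),
               layer = integer(), freq = integer(), stringsAsFactors = FALSE)
  rownames(terms) <- NULL
  list(terms = terms, extractable = ok,
       yield = if (length(ok)) mean(ok) else NA_real_)
}
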