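triples_df <- function(...) {
  rows <- list(...)
  data.frame(
    post_id = vapply(rows, function(r) r[[1]], ""),
    unit_id = vapply(rows, function(r) r[[2]], ""),
    word_a = vapply(rows, function(r) r[[3]], ""),
    word_b = vapply(rows, function(r) r[[4]], ""),
    role = vapply(rows, function(r) r[[5]], ""),
    stringsAsFactors = FALSE)
}

# the printed low-SFM/low-POM example sentence as role triples
lowlow_triples <- function() {
  triples_df(
    list("p1", "u1", "anxiety", "sleepless", "REAS"),
    list("p1", "u1", "belonging", "feeling", "CONT"),
    list("p1", "u1", "now", "leaves", "TIME"),
    list("p1", "u1", "loss", "leaves", "EXP"),
    list("p1", "u1", "nights", "leaves", "TIME"),
    list("p1", "u1", "me", "feeling", "AGT"))
}

test_that("split_units cuts at terminal punctuation", {
  expect_length(split_units("A. B! C?"), 3)
  expect_equal(split_units("no punctuation"), "no punctuation")
  expect_length(split_units(""), 0)
  expect_length(split_units("one. trailing tail"), 2)
  expect_length(split_units("CJK。second！"), 2)
})

test_that("build_graph aggregates weights, drops self-links, prunes", {
  g <- build_graph(lowlow_triples(), min_edge_weight = 1)
  expect_equal(nrow(g$edges), 6)
  reas <- g$edges[grepl("REAS", g$edges$roles), ]
  expect_equal(sort(c(reas$node_a, reas$node_b)), c("anxiety", "sleepless"))

  # identical triple in two sentences -> weight 2
  tr2 <- rbind(lowlow_triples(),
               triples_df(list("p2", "u1", "anxiety", "sleepless", "REAS")))
  g2 <- build_graph(tr2, min_edge_weight = 1)
  e <- g2$edges[g2$edges$node_a == "anxiety", ]
  expect_equal(e$weight, 2)
  # pruning at min weight 2 keeps only the repeated edge
  g3 <- build_graph(tr2, min_edge_weight = 2)
  expect_equal(nrow(g3$edges), 1)
  # edge-weight total equals non-self, non-stop triple count pre-pruning
  expect_equal(sum(g3$edges_all$weight), 7)

  # self-link dropped
  g4 <- build_graph(triples_df(list("p1", "u1", "x", "x", "LINK")))
  expect_equal(nrow(g4$edges_all), 0)

  # stop nodes and punctuation excluded
  g5 <- build_graph(triples_df(list("p1", "u1", "the", "meaning", "CONT"),
                               list("p1", "u1", "!", "meaning", "CONT")),
                    min_edge_weight = 1, stop_nodes = "the")
  expect_equal(nrow(g5$edges_all), 0)

  expect_error(build_graph(triples_df(list("p", "u", "a", "b", "BOGUS"))),
               "unknown role")
})

test_that("reason_expansion assigns BFS layers from the REAS anchor", {
  # chain a-REAS-b, b-CONT-c, c-AGT-d, d-TIME-e -> layers 0,0,1,2,3
  tr <- triples_df(list("p", "u", "a", "b", "REAS"),
                   list("p", "u", "b", "c", "CONT"),
                   list("p", "u", "c", "d", "AGT"),
                   list("p", "u", "d", "e", "TIME"))
  g <- build_graph(tr, min_edge_weight = 1)
  ex <- reason_expansion(g, max_layers = 3)
  expect_true(ex$extractable)
  expect_equal(ex$layer_of[c("a", "b", "c", "d", "e")],
               c(a = 0L, b = 0L, c = 1L, d = 2L, e = 3L))

  # node reachable at layers 1 and 3 gets the earlier layer
  tr2 <- rbind(tr, triples_df(list("p", "u", "b", "d", "LINK")))
  g2 <- build_graph(tr2, min_edge_weight = 1)
  ex2 <- reason_expansion(g2)
  expect_equal(unname(ex2$layer_of["d"]), 1L)

  # nodes beyond max_layers excluded
  ex1 <- reason_expansion(g, max_layers = 1)
  expect_false("d" %in% names(ex1$layer_of))

  # no REAS edge -> flagged unextractable, empty result
  ex0 <- reason_expansion(build_graph(
    triples_df(list("p", "u", "a", "b", "CONT")), min_edge_weight = 1))
  expect_false(ex0$extractable)
  expect_length(ex0$layer_of, 0)
})

test_that("expansion is invariant to triple input order", {
  tr <- lowlow_triples()
  tr2 <- rbind(tr, triples_df(list("p1", "u1", "sleepless", "feeling", "CONT")))
  g_fwd <- build_graph(tr2, min_edge_weight = 1)
  set.seed(3)
  g_rev <- build_graph(tr2[sample(nrow(tr2)), ], min_edge_weight = 1)
  expect_equal(reason_expansion(g_fwd)$layer_of, reason_expansion(g_rev)$layer_of)
})

test_that("extract_factor_terms orders by layer then frequency", {
  tr <- triples_df(list("p", "u", "a", "b", "REAS"),
                   list("p", "u", "b", "c", "CONT"),
                   list("p", "u", "b", "d", "CONT"),
                   list("p", "u", "d", "x", "LINK"),
                   list("p", "u", "d", "y", "LINK"))
  g <- build_graph(tr, min_edge_weight = 1)
  ft <- extract_factor_terms(g, reason_expansion(g))
  expect_equal(nrow(ft), 6)
  expect_equal(ft$term[1:2], c("b", "a"))  # layer 0, freq 3 then 1
  expect_equal(ft$layer, sort(ft$layer))
  # same layer: higher frequency first
  l1 <- ft[ft$layer == 1, ]
  expect_equal(l1$term[1], "d")
  # empty expansion -> empty list
  g0 <- build_graph(triples_df(list("p", "u", "a", "b", "CONT")),
                    min_edge_weight = 1)
  expect_equal(nrow(extract_factor_terms(g0, reason_expansion(g0))), 0)
})

test_that("extract_factors reports per-post yield matching REAS anchoring", {
  posts <- gen_posts(40, seed = 21)
  tr <- gen_triples(posts, reas_fraction = 0, seed = 1)
  expect_equal(extract_factors(tr)$yield, 0)
  tr1 <- gen_triples(posts, reas_fraction = 1, depth = 4, seed = 1)
  fx <- extract_factors(tr1)
  expect_equal(fx$yield, 1)
  # depth-4 chains populate layers 0..3
  expect_setequal(unique(fx$terms$layer), 0:3)
})
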