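test_that("stack_cls returns the configured L x d matrix, deterministically", {
  enc <- toy_enc()
  ids <- enc$tokenize("life has meaning tonight")
  M <- stack_cls(enc, ids)
  expect_equal(dim(M), c(4, 32))
  expect_identical(M, stack_cls(enc, ids))
  # wrong-shape encoder rejected
  bad <- enc
  bad$encode <- function(ids) matrix(0, 3, 32)
  expect_error(stack_cls(bad, ids), "shape")
})

test_that("conv head geometry and softmax normalization", {
  enc <- toy_enc()
  ccfg <- toy_ccfg(enc, m = 2, windows = c(2, 3))
  params <- init_head(ccfg, seed = 1)
  M <- stack_cls(enc, enc$tokenize("sleep meaning"))
  fw <- conv_head_forward(M, params, ccfg)
  # feature map lengths L - w + 1
  expect_equal(nrow(fw$cache$windows[["2"]]$pre), 3)
  expect_equal(nrow(fw$cache$windows[["3"]]$pre), 2)
  # fused vector length |windows| * m
  expect_length(fw$cache$z, 4)
  expect_equal(sum(fw$probs), 1, tolerance = 1e-6)
  expect_true(all(fw$probs >= 0 & fw$probs <= 1))
  # window larger than L rejected at config time
  expect_error(classifier_config(L = 4, d = 32, windows = c(3, 5)), "window")
})

test_that("head gradients match numerical differentiation", {
  enc <- toy_enc()
  ccfg <- toy_ccfg(enc, m = 2, windows = c(2, 3))
  params <- init_head(ccfg, seed = 3)
  M <- stack_cls(enc, enc$tokenize("sleepless night meaning purpose"))
  y <- 1L; wt <- 1.3
  loss_at <- function(p) {
    fw <- conv_head_forward(M, p, ccfg)
    wt * (-log(fw$probs[y]))
  }
  fw <- conv_head_forward(M, params, ccfg)
  g <- milscope:::conv_head_backward(fw$probs, fw$cache, y, wt, params, ccfg)
  for (k in c("U", "b", "Wf2", "bf3")) {
    idx <- which(abs(params[[k]]) == max(abs(params[[k]])))[1]
    eps <- 1e-5
    pp <- params; pp[[k]][idx] <- pp[[k]][idx] + eps
    pm <- params; pm[[k]][idx] <- pm[[k]][idx] - eps
    num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    expect_equal(g[[k]][idx], num, tolerance = 1e-4)
  }
})

test_that("class weights follow n/(K*n_c)", {
  y <- c(rep("A", 80), rep("B", 20))
  expect_equal(unname(class_weights(y)), c(0.625, 2.5))
})

test_that("training overfits separable data and reproduces under a seed", {
  posts <- separable_posts(40, seed = 7)
  labeled <- data.frame(post_id = posts$post_id, text = posts$text,
                        label = posts$rel, stringsAsFactors = FALSE)
  enc <- toy_enc()
  ccfg <- toy_ccfg(enc)
  tcfg <- fast_tcfg(split = c(1, 0, 0), folds = 1)
  m1 <- train_model(labeled, enc, ccfg, tcfg, task = "REL")
  expect_equal(m1$metrics$train_accuracy, 1)
  m2 <- train_model(labeled, enc, ccfg, tcfg, task = "REL")
  expect_identical(m1$params, m2$params)
  expect_equal(m1$metrics$train_accuracy, m2$metrics$train_accuracy)
  # single-class data rejected
  labeled1 <- labeled; labeled1$label <- "RELATED"
  expect_error(train_model(labeled1, enc, ccfg, tcfg), "single class")
})

test_that("fold metrics and held-out test metrics are reported", {
  posts <- gen_posts(60, seed = 17)
  labeled <- data.frame(post_id = posts$post_id, text = posts$text,
                        label = posts$rel, stringsAsFactors = FALSE)
  enc <- toy_enc()
  m <- train_model(labeled, enc, toy_ccfg(enc),
                   fast_tcfg(split = c(0.8, 0.1, 0.1), folds = 2))
  expect_equal(nrow(m$metrics$folds), 2)
  expect_true(all(c("accuracy", "precision", "recall", "f1") %in%
                    names(m$metrics$folds)))
  expect_true(m$metrics$test[["accuracy"]] >= 0 &&
                m$metrics$test[["accuracy"]] <= 1)
})

test_that("cascade gates SFM/POM behind relevance", {
  posts <- gen_posts(60, seed = 23)
  enc <- toy_enc()
  ccfg <- toy_ccfg(enc)
  tcfg <- fast_tcfg(split = c(0.9, 0.1, 0), folds = 1)
  lab <- function(col, rows = posts) {
    data.frame(post_id = rows$post_id, text = rows$text, label = rows[[col]],
               stringsAsFactors = FALSE)
  }
  m1 <- train_model(lab("rel"), enc, ccfg, tcfg, task = "REL")
  rel_posts <- posts[posts$rel == "RELATED", ]
  m2 <- train_model(lab("sfm", rel_posts), enc, ccfg, tcfg, task = "SFM")
  m3 <- train_model(lab("pom", rel_posts), enc, ccfg, tcfg, task = "POM")
  res <- predict_cascade(posts, m1, m2, m3)
  expect_equal(nrow(res), nrow(posts))
  expect_identical(res$post_id, posts$post_id)
  gated <- res$relevance == "NOT_RELATED"
  expect_true(all(is.na(res$sfm[gated])) && all(is.na(res$pom[gated])))
  expect_true(all(!is.na(res$sfm[!gated])) && all(!is.na(res$pom[!gated])))
  expect_true(all(res$p_relevance >= 0 & res$p_relevance <= 1))
})

test_that("stratified_sample enforces quadrant minima and determinism", {
  frame <- data.frame(
    id = seq_len(1200),
    quadrant = rep(c("S1P1", "S1P0", "S0P1", "S0P0"), c(500, 300, 250, 150)),
    stringsAsFactors = FALSE)
  s <- stratified_sample(frame, frac = 0.2, min_per_stratum = 100, seed = 4)
  tab <- table(s$quadrant)
  expect_true(all(tab >= 100))
  expect_equal(unname(tab[["S1P1"]]), 100)  # 0.2*500 = 100
  s2 <- stratified_sample(frame, frac = 0.2, min_per_stratum = 100, seed = 4)
  expect_identical(s$id, s2$id)
  # quadrant smaller than the minimum is a named error
  frame$quadrant[frame$quadrant == "S0P0"] <- "S0P1"
  frame$quadrant[1:50] <- "S0P0"
  expect_error(stratified_sample(frame, frac = 0.01, min_per_stratum = 100),
               "S0P0")
  # explicit per-stratum counts override the rule
  frame2 <- data.frame(quadrant = rep(c("A", "B"), c(200, 300)))
  s3 <- stratified_sample(frame2, n_per_stratum = c(A = 10, B = 20), seed = 1)
  expect_equal(as.vector(table(s3$quadrant)[c("A", "B")]), c(10L, 20L))
})

test_that("joint accuracy requires both labels simultaneously correct", {
  gold <- data.frame(post_id = paste0("p", 1:4),
                     sfm = c("HIGH", "HIGH", "LOW", "LOW"),
                     pom = c("HIGH", "LOW", "HIGH", "LOW"),
                     stringsAsFactors = FALSE)
  pred <- gold
  expect_equal(joint_accuracy(pred, gold), 1)
  pred$pom <- rev(gold$pom)  # POM wrong everywhere, SFM right
  expect_equal(joint_accuracy(pred, gold), 0)
  pred <- gold; pred$sfm[1] <- "LOW"
  expect_equal(joint_accuracy(pred, gold), 0.75)
  bad <- gold; bad$post_id[1] <- "zz"
  expect_error(joint_accuracy(bad, gold), "ids")
})

test_that("per-user MIL proportions and their correlation with scores", {
  res <- data.frame(user_id = rep(c("u1", "u2"), c(10, 5)),
                    relevance = c(rep("RELATED", 3), rep("NOT_RELATED", 7),
                                  rep("RELATED", 5)),
                    stringsAsFactors = FALSE)
  up <- user_mil_proportion(res)
  expect_equal(up$proportion[up$user_id == "u1"], 0.3)
  expect_equal(up$proportion[up$user_id == "u2"], 1)
  # proportions identical to scores -> r = 1
  pr <- c(0.1, 0.4, 0.8, 0.2, 0.6)
  expect_equal(correlate_mil(pr, pr)$r, 1)
  # anti-aligned ranks -> negative correlation
  cc <- correlate_mil(pr, -pr + 1)
  expect_lt(cc$r, 0)
  expect_error(correlate_mil(rep(0.5, 5), pr), "zero-variance")
  expect_error(correlate_mil(pr[1:2], pr[1:2]), "3 users")
})
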