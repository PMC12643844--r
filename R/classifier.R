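# Three-stage MIL classifier cascade.
#
# Stage architecture: a pluggable encoder produces one summary (CLS)
# vector per transformer block; the L stacked block vectors form an
# L x d matrix; convolution filters with several window sizes slide over
# the block axis, are max-pooled, concatenated, and fed to a dense
# softmax output. The head (convolution + pooling + fusion + output) and
# its training loop are implemented here in plain matrix code; the
# production encoder is an adapter boundary, and a small randomly
# initialized deterministic encoder ships for desk-scale use.

#' Classifier head configuration
#'
#' @param L encoder blocks (rows of the stacked CLS matrix), default 12.
#' @param d embedding dimension, default 768.
#' @param windows convolution window sizes over the block axis, default
#'   c(3, 4, 5); each must be <= L.
#' @param m filters per window size, default 128.
#' @param n_classes output classes, default 2.
#' @param max_len token sequence length after truncation/padding,
#'   default 164.
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(L = 12, d = 768, windows = c(3, 4, 5),
                              m = 128, n_classes = 2, max_len = 164) {
  if (max(windows) > L) stop("convolution window larger than block count L")
  stopifnot(m >= 1, max_len >= 1, n_classes >= 2)
  structure(list(L = as.integer(L), d = as.integer(d),
                 windows = as.integer(windows), m = as.integer(m),
                 n_classes = as.integer(n_classes),
                 max_len = as.integer(max_len)),
            class = "classifier_config")
}

#' Training configuration
#'
#' @param batch_size minibatch size, default 32.
#' @param learning_rate Adam learning rate, default 2e-5.
#' @param patience_steps early stopping after this many update steps
#'   without validation improvement, default 1000.
#' @param max_steps hard cap on update steps, default 2000.
#' @param folds cross-validation folds over the non-test data, default 10.
#' @param split train/validation/test fractions, must sum to 1.
#' @param eval_every validation-evaluation interval in steps, default 20.
#' @param seed integer seed.
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 32, learning_rate = 2e-5,
                         patience_steps = 1000, max_steps = 2000,
                         folds = 10, split = c(0.8, 0.1, 0.1),
                         eval_every = 20, seed = 1) {
  stopifnot(abs(sum(split) - 1) < 1e-8, patience_steps >= 1, folds >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience_steps = as.integer(patience_steps),
                 max_steps = as.integer(max_steps),
                 folds = as.integer(folds), split = split,
                 eval_every = as.integer(eval_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Toy deterministic encoder adapter
#'
#' A randomly initialized, frozen encoder for desk-scale testing: token
#' embeddings are mean-pooled and passed through L tanh blocks; the
#' hidden state of each block is that block's CLS vector. Same input,
#' same matrix. A production adapter wrapping a pretrained 12-block
#' encoder can be substituted; only `encode`, `tokenize`, `L`, `d` are
#' required of an adapter.
#'
#' @param vocab character vector of known tokens.
#' @param L number of blocks, default 4.
#' @param d embedding dimension, default 32.
#' @param max_len sequence length, default 32.
#' @param seed integer seed fixing the random weights.
#' @return an object of class `mil_encoder` with elements `encode(ids)`,
#'   `tokenize(text)`, `L`, `d`, `max_len`, `vocab`.
#' @export
toy_encoder <- function(vocab, L = 4, d = 32, max_len = 32, seed = 42) {
  set.seed(derive_seed(seed, "encoder"))
  vocab <- unique(normalize_text(vocab))
  V <- length(vocab)
  emb <- matrix(rnorm((V + 1) * d, sd = 1), nrow = V + 1)  # row 1 = <unk>
  blocks <- lapply(seq_len(L), function(i) {
    list(W = matrix(rnorm(d * d, sd = 1 / sqrt(d)), nrow = d),
         b = rnorm(d, sd = 0.1))
  })
  tokenize <- function(text) {
    toks <- normalize_text(tokenize_ws(text))
    ids <- match(toks, vocab, nomatch = 0L) + 1L  # 1 = <unk>
    length(ids) <- max_len  # truncate/pad with NA
    ids[seq_len(max_len)]
  }
  encode <- function(ids) {
    ids <- ids[!is.na(ids)]
    x <- if (length(ids)) colMeans(emb[ids, , drop = FALSE]) else numeric(d)
    out <- matrix(0, nrow = L, ncol = d)
    h <- x
    for (i in seq_len(L)) {
      h <- tanh(blocks[[i]]$W %*% h + blocks[[i]]$b)[, 1]
      out[i, ] <- h
    }
    out
  }
  structure(list(encode = encode, tokenize = tokenize, L = as.integer(L),
                 d = as.integer(d), max_len = as.integer(max_len),
                 vocab = vocab),
            class = "mil_encoder")
}

#' Stack per-block CLS vectors
#'
#' @param encoder an encoder adapter.
#' @param ids token id vector already truncated/padded to the adapter's
#'   `max_len`.
#' @return L x d matrix of stacked block-level summary vectors.
#' @export
stack_cls <- function(encoder, ids) {
  M <- encoder$encode(ids)
  if (!is.matrix(M) || nrow(M) != encoder$L || ncol(M) != encoder$d) {
    stop("encoder returned shape ", paste(dim(M), collapse = "x"),
         ", expected ", encoder$L, "x", encoder$d)
  }
  M
}

# flatten rows t..t+w-1 of M into the window design matrix
conv_design <- function(M, w) {
  L <- nrow(M)
  t(vapply(seq_len(L - w + 1),
           function(t) as.vector(t(M[t:(t + w - 1), , drop = FALSE])),
           numeric(w * ncol(M))))
}

#' Initialize convolution-head parameters
#'
#' @param ccfg a [classifier_config()].
#' @param seed integer seed.
#' @return named list of parameter matrices.
#' @export
init_head <- function(ccfg, seed = 1) {
  set.seed(derive_seed(seed, "head"))
  fused <- length(ccfg$windows) * ccfg$m
  params <- list()
  for (w in ccfg$windows) {
    params[[paste0("Wf", w)]] <- matrix(rnorm(ccfg$m * w * ccfg$d,
                                              sd = 1 / sqrt(w * ccfg$d)),
                                        nrow = ccfg$m)
    params[[paste0("bf", w)]] <- rep(0, ccfg$m)
  }
  params$U <- matrix(rnorm(ccfg$n_classes * fused, sd = 1 / sqrt(fused)),
                     nrow = ccfg$n_classes)
  params$b <- rep(0, ccfg$n_classes)
  params
}

#' Convolution-head forward pass
#'
#' For each window size w, filters slide over the L block rows producing
#' feature maps of length L - w + 1 (ReLU), which are max-pooled to one
#' scalar per filter; the pooled outputs of all window sizes are
#' concatenated and mapped to class probabilities by a dense softmax
#' layer.
#'
#' @param M L x d stacked CLS matrix.
#' @param params head parameters from [init_head()].
#' @param ccfg a [classifier_config()].
#' @return list with `probs` (length n_classes, sums to 1) and `cache`
#'   (intermediates for the backward pass).
#' @export
conv_head_forward <- function(M, params, ccfg) {
  if (nrow(M) != ccfg$L || ncol(M) != ccfg$d) {
    stop("matrix shape does not match config")
  }
  z <- numeric(0)
  cache <- list(windows = list())
  for (w in ccfg$windows) {
    X <- conv_design(M, w)
    pre <- X %*% t(params[[paste0("Wf", w)]])
    pre <- sweep(pre, 2, params[[paste0("bf", w)]], "+")
    act <- pmax(pre, 0)
    tmax <- apply(act, 2, which.max)
    pooled <- act[cbind(tmax, seq_len(ccfg$m))]
    z <- c(z, pooled)
    cache$windows[[as.character(w)]] <- list(X = X, pre = pre, tmax = tmax)
  }
  logits <- (params$U %*% z)[, 1] + params$b
  logits <- logits - max(logits)
  probs <- exp(logits) / sum(exp(logits))
  cache$z <- z
  list(probs = probs, cache = cache)
}

# gradient of the weighted cross-entropy loss for one example
conv_head_backward <- function(probs, cache, y, weight, params, ccfg) {
  dlogits <- weight * (probs - as.numeric(seq_along(probs) == y))
  grads <- list(U = dlogits %o% cache$z, b = dlogits)
  dz <- (t(params$U) %*% dlogits)[, 1]
  off <- 0
  for (w in ccfg$windows) {
    cw <- cache$windows[[as.character(w)]]
    dzw <- dz[off + seq_len(ccfg$m)]
    dpre <- matrix(0, nrow = nrow(cw$pre), ncol = ccfg$m)
    for (j in seq_len(ccfg$m)) {
      if (cw$pre[cw$tmax[j], j] > 0) dpre[cw$tmax[j], j] <- dzw[j]
    }
    grads[[paste0("Wf", w)]] <- t(dpre) %*% cw$X
    grads[[paste0("bf", w)]] <- colSums(dpre)
    off <- off + ccfg$m
  }
  grads
}

#' Class weights for imbalanced data
#'
#' `w_c = n / (K * n_c)` for K classes with class sizes n_c.
#'
#' @param y vector of class labels.
#' @param classes class universe (default observed).
#' @return named numeric vector of weights.
#' @export
class_weights <- function(y, classes = sort(unique(y))) {
  n_c <- table(factor(y, levels = classes))
  n <- length(y)
  setNames(n / (length(classes) * as.numeric(n_c)), classes)
}

# mean weighted cross-entropy over an index set
head_loss <- function(encs, yi, wts, params, ccfg, idx) {
  tot <- 0
  for (i in idx) {
    p <- conv_head_forward(encs[[i]], params, ccfg)$probs
    tot <- tot + wts[yi[i]] * (-log(max(p[yi[i]], 1e-12)))
  }
  tot / length(idx)
}

# Adam-driven minibatch training with early stopping on validation loss
fit_head <- function(encs, yi, ccfg, tcfg, wts, train_idx, val_idx = NULL,
                     params = NULL, stream = "fit") {
  if (is.null(val_idx)) val_idx <- train_idx
  if (is.null(params)) params <- init_head(ccfg, seed = derive_seed(tcfg$seed, stream))
  set.seed(derive_seed(tcfg$seed, paste0(stream, "-sgd")))
  mstate <- lapply(params, function(p) p * 0)
  vstate <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(loss = Inf, params = params, step = 0L)
  trace <- numeric(0)
  for (step in seq_len(tcfg$max_steps)) {
    bi <- if (length(train_idx) <= tcfg$batch_size) train_idx else
      sample(train_idx, tcfg$batch_size)
    g <- NULL
    for (i in bi) {
      fw <- conv_head_forward(encs[[i]], params, ccfg)
      gi <- conv_head_backward(fw$probs, fw$cache, yi[i], wts[yi[i]],
                               params, ccfg)
      g <- if (is.null(g)) gi else Map(`+`, g, gi)
    }
    g <- lapply(g, function(x) x / length(bi))
    for (k in names(params)) {
      mstate[[k]] <- b1 * mstate[[k]] + (1 - b1) * g[[k]]
      vstate[[k]] <- b2 * vstate[[k]] + (1 - b2) * g[[k]]^2
      mhat <- mstate[[k]] / (1 - b1^step)
      vhat <- vstate[[k]] / (1 - b2^step)
      params[[k]] <- params[[k]] - tcfg$learning_rate * mhat / (sqrt(vhat) + eps)
    }
    if (step %% tcfg$eval_every == 0 || step == tcfg$max_steps) {
      vl <- head_loss(encs, yi, wts, params, ccfg, val_idx)
      trace <- c(trace, vl)
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, params = params, step = step)
      } else if (step - best$step >= tcfg$patience_steps) {
        break
      }
    }
  }
  list(params = best$params, val_loss = best$loss, steps = best$step,
       trace = trace)
}

head_predict <- function(encs, params, ccfg, idx = seq_along(encs)) {
  t(vapply(idx, function(i) conv_head_forward(encs[[i]], params, ccfg)$probs,
           numeric(ccfg$n_classes)))
}

# accuracy / precision / recall / F1 with respect to the positive class
classification_metrics <- function(truth, pred, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  c(accuracy = mean(pred == truth), precision = prec, recall = rec, f1 = f1)
}

#' Train one cascade-stage classifier
#'
#' Protocol: the test split (`tcfg$split[3]`) is held out once; k-fold
#' cross-validation runs over the remainder, each fold training with
#' class-weighted loss, Adam, and early stopping on the fold's
#' validation loss; the final model is then trained on the full
#' non-test data with an internal validation split and evaluated on the
#' held-out test set. Seeded runs reproduce the metric trace exactly.
#'
#' @param posts data.frame with `post_id`, `text` and the label column.
#' @param encoder an encoder adapter (e.g. [toy_encoder()]).
#' @param ccfg a [classifier_config()] matching the encoder's L and d.
#' @param tcfg a [train_config()].
#' @param label_col label column name (default `"label"`; two classes
#'   required).
#' @param positive positive class for metrics and the 0.5 tie-break
#'   (default `"RELATED"` or `"HIGH"` when present, else the first
#'   class).
#' @param task task tag carried on the model (e.g. `"REL"`).
#' @return an object of class `mil_model`: list with `params`,
#'   `classes`, `positive`, `encoder`, `ccfg`, `tcfg`, `task`,
#'   `metrics` (`$folds` data.frame, `$test` named vector,
#'   `$train_accuracy`), `steps`.
#' @export
train_model <- function(posts, encoder, ccfg, tcfg = train_config(),
                        label_col = "label", positive = NULL, task = "REL") {
  y <- as.character(posts[[label_col]])
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("dataset has a single class")
  if (is.null(positive)) {
    positive <- if ("RELATED" %in% classes) "RELATED"
      else if ("HIGH" %in% classes) "HIGH" else classes[1]
  }
  yi <- match(y, classes)
  encs <- lapply(posts$text, function(tx) stack_cls(encoder, encoder$tokenize(tx)))
  n <- length(encs)

  set.seed(derive_seed(tcfg$seed, "split"))
  n_test <- round(tcfg$split[3] * n)
  test_idx <- if (n_test > 0) sample.int(n, n_test) else integer(0)
  rest <- setdiff(seq_len(n), test_idx)
  wts <- class_weights(y[rest], classes)
  wts_i <- setNames(as.numeric(wts), NULL)

  fold_metrics <- NULL
  if (tcfg$folds >= 2) {
    fold_of <- sample(rep(seq_len(tcfg$folds), length.out = length(rest)))
    fm <- vector("list", tcfg$folds)
    for (f in seq_len(tcfg$folds)) {
      tr <- rest[fold_of != f]; va <- rest[fold_of == f]
      fit <- fit_head(encs, yi, ccfg, tcfg, wts_i, tr, va,
                      stream = paste0("fold", f))
      pr <- head_predict(encs, fit$params, ccfg, va)
      pred <- cascade_decide(pr, classes, positive)
      fm[[f]] <- c(fold = f, classification_metrics(y[va], pred, positive),
                   val_loss = fit$val_loss)
    }
    fold_metrics <- as.data.frame(do.call(rbind, fm))
  }

  # final fit: internal validation carved out of the non-test data
  set.seed(derive_seed(tcfg$seed, "finalval"))
  n_val <- round(tcfg$split[2] / (tcfg$split[1] + tcfg$split[2]) *
                   length(rest))
  if (n_val >= 1 && length(rest) > n_val) {
    val_idx <- sample(rest, n_val)
    tr_idx <- setdiff(rest, val_idx)
  } else {
    # no validation share: early stopping tracks the training loss
    val_idx <- rest
    tr_idx <- rest
  }
  fit <- fit_head(encs, yi, ccfg, tcfg, wts_i, tr_idx, val_idx,
                  stream = "final")

  pred_tr <- cascade_decide(head_predict(encs, fit$params, ccfg, rest),
                            classes, positive)
  train_acc <- mean(pred_tr == y[rest])
  test_metrics <- NULL
  if (length(test_idx)) {
    pred_te <- cascade_decide(head_predict(encs, fit$params, ccfg, test_idx),
                              classes, positive)
    test_metrics <- classification_metrics(y[test_idx], pred_te, positive)
  }
  structure(list(params = fit$params, classes = classes, positive = positive,
                 encoder = encoder, ccfg = ccfg, tcfg = tcfg, task = task,
                 metrics = list(folds = fold_metrics, test = test_metrics,
                                train_accuracy = train_acc),
                 steps = fit$steps),
            class = "mil_model")
}

# label decisions from a probability matrix; exact 0.5 ties go positive
cascade_decide <- function(probs, classes, positive) {
  ppos <- probs[, match(positive, classes)]
  ifelse(ppos >= 0.5, positive, classes[classes != positive][1])
}

#' @export
print.mil_model <- function(x, ...) {
  cat(sprintf("MIL classifier [%s]: classes %s (positive: %s)\n", x$task,
              paste(x$classes, collapse = "/"), x$positive))
  cat(sprintf("  training accuracy: %.3f\n", x$metrics$train_accuracy))
  if (!is.null(x$metrics$test)) {
    cat(sprintf("  test accuracy: %.3f  F1: %.3f\n",
                x$metrics$test["accuracy"], x$metrics$test["f1"]))
  }
  invisible(x)
}

#' Predict with one trained stage
#'
#' @param object a `mil_model`.
#' @param posts data.frame with `post_id`, `text`.
#' @param ... unused.
#' @return data.frame: `post_id`, `label`, `prob` (probability of the
#'   positive class).
#' @export
predict.mil_model <- function(object, posts, ...) {
  encs <- lapply(posts$text,
                 function(tx) stack_cls(object$encoder, object$encoder$tokenize(tx)))
  probs <- head_predict(encs, object$params, object$ccfg)
  ppos <- probs[, match(object$positive, object$classes)]
  data.frame(post_id = posts$post_id,
             label = cascade_decide(probs, object$classes, object$positive),
             prob = ppos, stringsAsFactors = FALSE)
}

#' Three-stage cascade prediction
#'
#' The relevance model gates the two level models: SFM and POM are
#' assessed only for posts predicted RELATED; gated posts carry NA for
#' both levels.
#'
#' @param posts data.frame with `post_id`, `text`.
#' @param model_rel,model_sfm,model_pom trained `mil_model`s for
#'   relevance, SFM level and POM level.
#' @return data.frame of class `mil_cascade`: `post_id`, `relevance`,
#'   `p_relevance`, `sfm`, `p_sfm`, `pom`, `p_pom`.
#' @export
predict_cascade <- function(posts, model_rel, model_sfm, model_pom) {
  pr <- predict(model_rel, posts)
  out <- data.frame(post_id = posts$post_id,
                    relevance = ifelse(pr$label == model_rel$positive,
                                       "RELATED", "NOT_RELATED"),
                    p_relevance = pr$prob,
                    sfm = NA_character_, p_sfm = NA_real_,
                    pom = NA_character_, p_pom = NA_real_,
                    stringsAsFactors = FALSE)
  rel <- out$relevance == "RELATED"
  if (any(rel)) {
    ps <- predict(model_sfm, posts[rel, , drop = FALSE])
    pp <- predict(model_pom, posts[rel, , drop = FALSE])
    out$sfm[rel] <- ps$label
    out$p_sfm[rel] <- ps$prob
    out$pom[rel] <- pp$label
    out$p_pom[rel] <- pp$prob
  }
  class(out) <- c("mil_cascade", "data.frame")
  out
}

#' Stratified validation sample over SFM x POM quadrants
#'
#' @param frame data.frame with a stratum column (default `quadrant`).
#' @param frac target overall sampling fraction (default 0.01).
#' @param min_per_stratum minimum items per stratum (default 100).
#' @param seed integer seed.
#' @param stratum_col stratum column name.
#' @param n_per_stratum optional named vector of explicit per-stratum
#'   sample sizes, overriding the frac/min rule.
#' @return sampled subset of `frame`.
#' @export
stratified_sample <- function(frame, frac = 0.01, min_per_stratum = 100,
                              seed = 1, stratum_col = "quadrant",
                              n_per_stratum = NULL) {
  strata <- split(seq_len(nrow(frame)), frame[[stratum_col]])
  if (is.null(n_per_stratum)) {
    n_per_stratum <- vapply(strata, function(ix)
      max(min_per_stratum, round(frac * length(ix))), numeric(1))
  } else {
    n_per_stratum <- n_per_stratum[names(strata)]
  }
  short <- names(strata)[lengths(strata) < n_per_stratum]
  if (length(short)) {
    stop("stratum too small for requested sample: ",
         paste(short, collapse = ", "))
  }
  set.seed(derive_seed(seed, "stratified"))
  take <- unlist(lapply(names(strata), function(s)
    sample(strata[[s]], n_per_stratum[[s]])))
  out <- frame[sort(take), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Joint-label accuracy
#'
#' Fraction of posts whose SFM and POM labels are simultaneously
#' correct.
#'
#' @param predictions,gold data.frames with `post_id`, `sfm`, `pom`
#'   covering the same posts.
#' @return accuracy in \[0, 1\].
#' @export
joint_accuracy <- function(predictions, gold) {
  if (!setequal(predictions$post_id, gold$post_id)) {
    stop("prediction and gold post ids do not match")
  }
  g <- gold[match(predictions$post_id, gold$post_id), ]
  mean(predictions$sfm == g$sfm & predictions$pom == g$pom)
}

#' Per-user proportion of MIL-related posts
#'
#' @param results data.frame with `user_id` and `relevance`
#'   (`RELATED`/`NOT_RELATED`).
#' @return data.frame: `user_id`, `n_posts`, `n_related`, `proportion`.
#' @export
user_mil_proportion <- function(results) {
  sp <- split(results$relevance, results$user_id)
  data.frame(user_id = names(sp),
             n_posts = lengths(sp),
             n_related = vapply(sp, function(r) sum(r == "RELATED"), integer(1)),
             proportion = vapply(sp, function(r) mean(r == "RELATED"), numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Correlate per-user MIL proportions with questionnaire scores
#'
#' Pearson correlation with a two-sided test.
#'
#' @param proportions,scores numeric vectors (same users, same order).
#' @return list with `r` and `p`.
#' @export
correlate_mil <- function(proportions, scores) {
  if (length(proportions) != length(scores)) stop("length mismatch")
  if (length(proportions) < 3) stop("need at least 3 users")
  if (sd(proportions) == 0 || sd(scores) == 0) {
    stop("zero-variance vector; correlation undefined")
  }
  ct <- cor.test(proportions, scores, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
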