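# Shared fixture builders. All fixtures are generated in code.

write_jsonl <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (rec in records) {
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

# enumerate all set partitions of 1..n as membership vectors
# (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxb) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (b in seq_len(maxb + 1)) {
      rec(c(prefix, b), max(maxb, b))
    }
  }
  rec(integer(0), 0L)
  out
}

# brute-force maximum modularity over all partitions of a small graph
brute_force_best_q <- function(A) {
  parts <- all_partitions(nrow(A))
  best <- -Inf
  for (p in parts) {
    q <- modularity_q(A, p)
    if (q > best) best <- q
  }
  best
}

# random symmetric weighted adjacency with zero diagonal
random_adjacency <- function(n, density = 0.5, weighted = TRUE) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < density) {
        A[i, j] <- A[j, i] <- if (weighted) runif(1, 0.2, 1) else 1
      }
    }
  }
  A
}

# small labeled post set, linearly separable on all three tasks
separable_posts <- function(n = 40, seed = 7) {
  gen_posts(n, seed = seed, rel_prior = 0.5, margin = 1)
}

toy_ccfg <- function(enc, m = 8, windows = c(2, 3)) {
  classifier_config(L = enc$L, d = enc$d, windows = windows, m = m,
                    n_classes = 2, max_len = enc$max_len)
}

toy_enc <- function(seed = 42) {
  toy_encoder(unlist(synth_vocab()), L = 4, d = 32, max_len = 32, seed = seed)
}

fast_tcfg <- function(folds = 2, split = c(0.8, 0.1, 0.1)) {
  train_config(batch_size = 16, learning_rate = 0.02, patience_steps = 200,
               max_steps = 400, folds = folds, split = split,
               eval_every = 25, seed = 11)
}
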