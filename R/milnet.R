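#' Split factor assignments into the eight MIL subgroup matrices
#'
#' Posts labeled on both dimensions (search for meaning, SFM, and presence
#' of meaning, POM) are distributed into four marginal sub-datasets
#' (S1 = high SFM, S0 = low SFM, P1 = high POM, P0 = low POM) and four
#' joint quadrants (S1P1, S1P0, S0P1, S0P0). Every post appears in exactly
#' one quadrant and two marginal matrices; marginal matrices pool the
#' corresponding quadrants.
#'
#' @param labels data.frame with columns `post_id`, `sfm`, `pom`
#'   (values `"HIGH"`/`"LOW"`).
#' @param counts numeric matrix of per-post category counts with rownames
#'   equal to `post_id`; column order is preserved across subgroups.
#' @return named list of 8 matrices: S1, S0, P1, P0, S1P1, S1P0, S0P1, S0P0.
#' @export
split_subgroups <- function(labels, counts) {
  stopifnot(is.data.frame(labels), all(c("post_id", "sfm", "pom") %in% names(labels)))
  if (anyNA(labels$sfm) || anyNA(labels$pom)) {
    stop("every post must carry SFM and POM labels")
  }
  bad <- !(labels$sfm %in% c("HIGH", "LOW")) | !(labels$pom %in% c("HIGH", "LOW"))
  if (any(bad)) stop("SFM/POM labels must be HIGH or LOW")
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- as.character(labels$post_id)
  ids <- as.character(labels$post_id)
  if (!all(ids %in% rownames(counts))) stop("counts missing rows for some post_ids")
  pick <- function(keep) counts[ids[keep], , drop = FALSE]
  s1 <- labels$sfm == "HIGH"; p1 <- labels$pom == "HIGH"
  list(
    S1 = pick(s1), S0 = pick(!s1), P1 = pick(p1), P0 = pick(!p1),
    S1P1 = pick(s1 & p1), S1P0 = pick(s1 & !p1),
    S0P1 = pick(!s1 & p1), S0P0 = pick(!s1 & !p1)
  )
}

# glasso at one penalty; thin wrapper over the compiled solver
glasso_fit <- function(S, rho, beta_init = NULL) {
  .glasso_cpp(S, rho, beta_init)
}

#' Estimate a regularized partial-correlation network
#'
#' Computes the Pearson correlation matrix of the input, fits the graphical
#' lasso over a descending log-spaced penalty grid, and selects the penalty
#' minimizing the extended Bayesian information criterion
#' \deqn{EBIC(\lambda) = -2\,\ell + E \log n + 4 E \gamma \log p,}
#' where \eqn{\ell = (n/2)(\log\det\Theta - \mathrm{tr}(S\Theta))} and E is
#' the number of nonzero upper-triangle edges. Edges are reported as
#' regularized partial correlations
#' \eqn{-\theta_{ij}/\sqrt{\theta_{ii}\theta_{jj}}}.
#'
#' @param x numeric matrix or data.frame (rows = posts, columns = factors).
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param nlambda number of penalty grid points (default 100).
#' @param lambda_min_ratio smallest penalty as a fraction of the smallest
#'   penalty that yields an empty graph (default 0.01).
#' @param threshold if TRUE (default), partial correlations smaller in
#'   absolute value than `log(p (p - 1) / 2) / sqrt(n)` are set to zero
#'   before edge counting and in the reported network. This is the
#'   standard consistency threshold for regularized partial-correlation
#'   networks; without it the EBIC path admits weak spurious edges as n
#'   grows.
#' @param subgroup optional subgroup key carried on the result.
#' @return an object of class `mil_network`: list with `weights` (signed
#'   partial-correlation matrix, zero diagonal), `precision`, `pearson`,
#'   `lambda`, `lambda_grid`, `ebic`, `n`, `p`, `gamma`, `nodes`,
#'   `n_edges`, `dropped` (zero-variance columns removed).
#' @export
estimate_network <- function(x, gamma = 0.5, nlambda = 100,
                             lambda_min_ratio = 0.01, threshold = TRUE,
                             subgroup = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 rows to estimate a network")
  v <- apply(x, 2, sd)
  dropped <- colnames(x)[v == 0 | is.na(v)]
  if (length(dropped)) {
    warning("dropping zero-variance columns: ", paste(dropped, collapse = ", "))
    x <- x[, v > 0 & !is.na(v), drop = FALSE]
  }
  p <- ncol(x)
  if (p < 2) stop("need at least 2 non-constant columns")
  S <- cor(x)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    warning("singular correlation matrix; applying ridge adjustment")
    S <- (S + diag(1e-3, p)) / (1 + 1e-3)
  }
  lambda_max <- max(abs(S[upper.tri(S)]))
  if (lambda_max <= 0) lambda_max <- 1e-4
  grid <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                  length.out = nlambda))
  thr <- if (threshold) log(p * (p - 1) / 2) / sqrt(n) else 0
  to_pcor <- function(theta) {
    d <- sqrt(diag(theta))
    pc <- -theta / tcrossprod(d)
    diag(pc) <- 0
    pc[abs(pc) < thr] <- 0
    pc[pc > 1] <- 1; pc[pc < -1] <- -1
    pc
  }
  ebic <- numeric(nlambda)
  fits <- vector("list", nlambda)
  beta <- NULL
  for (i in seq_len(nlambda)) {
    fit <- glasso_fit(S, grid[i], beta_init = beta)
    beta <- fit$beta
    theta <- fit$wi
    pc <- to_pcor(theta)
    E <- sum(pc[upper.tri(pc)] != 0)
    ld <- determinant(theta, logarithm = TRUE)
    ll <- (n / 2) * (as.numeric(ld$modulus) - sum(S * theta))
    ebic[i] <- -2 * ll + E * log(n) + 4 * E * gamma * log(p)
    fits[[i]] <- list(theta = theta, E = E, pc = pc)
  }
  best <- which.min(ebic)
  theta <- fits[[best]]$theta
  pc <- fits[[best]]$pc
  dimnames(pc) <- dimnames(S)
  structure(list(
    weights = pc, precision = theta, pearson = S,
    lambda = grid[best], lambda_grid = grid, ebic = ebic,
    n = n, p = p, gamma = gamma, nodes = colnames(x),
    n_edges = fits[[best]]$E, dropped = dropped, subgroup = subgroup
  ), class = "mil_network")
}

#' @export
print.mil_network <- function(x, ...) {
  cat("MIL factor network", if (!is.null(x$subgroup)) paste0("[", x$subgroup, "]"), "\n")
  cat(sprintf("  nodes: %d  edges: %d  n: %d  gamma: %.2f  lambda: %.4g\n",
              x$p, x$n_edges, x$n, x$gamma, x$lambda))
  cat(sprintf("  density: %.3f  |  global strength: %.3f\n",
              network_density(x$p, x$n_edges),
              sum(abs(x$weights[upper.tri(x$weights)]))))
  invisible(x)
}

#' Expected-influence centrality
#'
#' One-step expected influence: the signed sum of a node's edge weights,
#' \eqn{EI_i = \sum_{j \ne i} w_{ij}}, plus its z-standardization across
#' nodes (the scale on which centrality indices are usually reported).
#'
#' @param network a `mil_network`, or a symmetric weight matrix with zero
#'   diagonal.
#' @return data.frame with columns `node`, `expected_influence_raw`,
#'   `expected_influence_z`.
#' @export
expected_influence <- function(network) {
  w <- if (inherits(network, "mil_network")) network$weights else as.matrix(network)
  stopifnot(isSymmetric(unname(w), tol = 1e-8))
  raw <- rowSums(w)
  s <- sd(raw)
  z <- if (is.na(s) || s == 0) rep(0, length(raw)) else (raw - mean(raw)) / s
  data.frame(
    node = colnames(w) %||% paste0("V", seq_along(raw)),
    expected_influence_raw = unname(raw),
    expected_influence_z = unname(z),
    stringsAsFactors = FALSE
  )
}

#' Network density
#'
#' Ratio of observed to possible edges: `2E / (N (N - 1))`.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param n_edges number of observed edges.
#' @return density in \[0, 1\].
#' @export
network_density <- function(n_nodes, n_edges) {
  if (n_nodes < 2) stop("density requires at least 2 nodes")
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

#' Modularity of a partition
#'
#' Standard (weighted) Newman modularity:
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \left(A_{ij} - \frac{k_i k_j}{2m}\right)
#'   \delta(c_i, c_j),}
#' with A the adjacency (edge-weight) matrix, k the node strengths and m
#' the total edge weight.
#'
#' @param adjacency symmetric non-negative matrix with zero diagonal.
#' @param membership integer/character vector of community ids, one per node.
#' @return modularity Q.
#' @export
modularity_q <- function(adjacency, membership) {
  A <- as.matrix(adjacency)
  if (length(membership) != nrow(A)) stop("partition must cover all nodes")
  if (anyNA(membership)) stop("partition must cover all nodes")
  m2 <- sum(A)  # 2m
  if (m2 == 0) return(0)
  k <- rowSums(A)
  same <- outer(membership, membership, "==")
  sum((A - tcrossprod(k) / m2) * same) / m2
}

# greedy single-node moves, repeated until modularity stops improving
refine_partition <- function(A, memb) {
  n <- nrow(A)
  repeat {
    improved <- FALSE
    for (i in sample.int(n)) {
      cand <- unique(c(memb[-i], max(memb) + 1L))
      q0 <- modularity_q(A, memb)
      for (cm in setdiff(cand, memb[i])) {
        trial <- memb
        trial[i] <- cm
        if (modularity_q(A, trial) > q0 + 1e-12) {
          memb <- trial
          q0 <- modularity_q(A, memb)
          improved <- TRUE
        }
      }
    }
    # community-merge pass
    comms <- unique(memb)
    if (length(comms) > 1) {
      q0 <- modularity_q(A, memb)
      for (a in seq_len(length(comms) - 1)) {
        for (b in (a + 1):length(comms)) {
          trial <- memb
          trial[trial == comms[b]] <- comms[a]
          if (modularity_q(A, trial) > q0 + 1e-12) {
            memb <- trial
            q0 <- modularity_q(A, memb)
            improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }
  match(memb, unique(memb))  # canonical labels
}

#' Louvain community detection
#'
#' Greedy modularity maximization (local moves, then community aggregation,
#' repeated until Q no longer improves), applied to the absolute edge
#' weights of a factor network. Runs several seeded restarts with random
#' node orders and keeps the partition with the highest modularity, which
#' makes the result deterministic given `seed`.
#'
#' @param network a `mil_network` or a symmetric weight matrix.
#' @param seed integer seed.
#' @param restarts number of restarts (default 10).
#' @return an object of class `mil_partition`: list with `membership`
#'   (named integer vector), `Q`, `n_communities`, `seed`.
#' @export
louvain_communities <- function(network, seed = 1, restarts = 10) {
  w <- if (inherits(network, "mil_network")) network$weights else as.matrix(network)
  if (nrow(w) == 0) stop("graph is empty")
  A <- abs(w)
  diag(A) <- 0
  n <- nrow(A)
  best <- NULL; best_q <- -Inf
  for (r in seq_len(restarts)) {
    set.seed(derive_seed(seed, paste0("louvain", r)))
    # randomize the greedy sweep order via a vertex permutation
    if (r %% 2 == 1) {
      perm <- if (r == 1) seq_len(n) else sample.int(n)
      g <- igraph::graph_from_adjacency_matrix(A[perm, perm, drop = FALSE],
                                               mode = "undirected",
                                               weighted = TRUE)
      cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
      memb <- integer(n)
      memb[perm] <- as.integer(igraph::membership(cl))
    } else {
      memb <- seq_len(n)  # local moves from the singleton partition
    }
    memb <- refine_partition(A, memb)
    q <- modularity_q(A, memb)
    if (q > best_q + 1e-12) { best_q <- q; best <- memb }
  }
  names(best) <- colnames(A) %||% paste0("V", seq_len(nrow(A)))
  structure(list(membership = best, Q = best_q,
                 n_communities = length(unique(best)), seed = seed),
            class = "mil_partition")
}

#' @export
print.mil_partition <- function(x, ...) {
  cat(sprintf("Louvain partition: %d communities, Q = %.4f\n",
              x$n_communities, x$Q))
  invisible(x)
}

#' Permutation-based network comparison
#'
#' Compares two factor networks on two indices: the global-strength
#' difference (absolute difference of the sums of absolute edge weights)
#' and the maximum edge-weight difference. The null distribution is built
#' by permuting the post-to-group assignment, re-estimating both networks,
#' and recomputing the statistics; p-values use the add-one estimator
#' `p = (1 + #(perm >= observed)) / (1 + n_perm)`.
#'
#' @param x_a,x_b count matrices with identical column sets.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param gamma,nlambda,lambda_min_ratio passed to [estimate_network()].
#' @return an object of class `mil_comparison`: list with
#'   `global_strength_diff`, `max_weight_diff`, `p_strength`, `p_weight`,
#'   `n_perm`, `seed`.
#' @export
compare_networks <- function(x_a, x_b, n_perm = 1000, seed = 1,
                             gamma = 0.5, nlambda = 100,
                             lambda_min_ratio = 0.01) {
  x_a <- as.matrix(x_a); x_b <- as.matrix(x_b)
  if (ncol(x_a) != ncol(x_b) ||
      !identical(colnames(x_a), colnames(x_b))) {
    stop("column sets of the two matrices must match")
  }
  stat <- function(a, b) {
    na <- suppressWarnings(estimate_network(a, gamma = gamma, nlambda = nlambda,
                                            lambda_min_ratio = lambda_min_ratio))
    nb <- suppressWarnings(estimate_network(b, gamma = gamma, nlambda = nlambda,
                                            lambda_min_ratio = lambda_min_ratio))
    gs <- abs(sum(abs(na$weights[upper.tri(na$weights)])) -
                sum(abs(nb$weights[upper.tri(nb$weights)])))
    # both networks keep full column order, so weights align entry-wise
    mw <- max(abs(na$weights - nb$weights))
    c(gs, mw)
  }
  obs <- stat(x_a, x_b)
  pooled <- rbind(x_a, x_b)
  na_rows <- nrow(x_a)
  set.seed(derive_seed(seed, "nct"))
  exceed <- c(0, 0)
  for (i in seq_len(n_perm)) {
    idx <- sample.int(nrow(pooled))
    pa <- pooled[idx[seq_len(na_rows)], , drop = FALSE]
    pb <- pooled[idx[-seq_len(na_rows)], , drop = FALSE]
    s <- stat(pa, pb)
    exceed <- exceed + (s >= obs - 1e-12)
  }
  p <- (1 + exceed) / (1 + n_perm)
  structure(list(global_strength_diff = obs[1], max_weight_diff = obs[2],
                 p_strength = p[1], p_weight = p[2],
                 n_perm = n_perm, seed = seed),
            class = "mil_comparison")
}

#' @export
print.mil_comparison <- function(x, ...) {
  cat("Network comparison (permutation test)\n")
  cat(sprintf("  global strength diff: %.4f  (p = %.4f)\n",
              x$global_strength_diff, x$p_strength))
  cat(sprintf("  max edge weight diff: %.4f  (p = %.4f)\n",
              x$max_weight_diff, x$p_weight))
  cat(sprintf("  permutations: %d\n", x$n_perm))
  invisible(x)
}
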