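#' Merge multi-annotator labels into consensus labels
#'
#' Binary labels with an unable-to-judge option are merged per post:
#' UNABLE if any annotator chose UNABLE; otherwise INCONSISTENT if the
#' labels differ; otherwise CONSISTENT with the shared label. Consensus
#' requires unanimity; the UNABLE precedence reproduces the exclusion
#' accounting in which unable and inconsistent posts are disjoint sets.
#'
#' @param records annotation data.frame: `post_id`, `annotator_id`,
#'   `task`, `label` (`POSITIVE`/`NEGATIVE`/`UNABLE`).
#' @param task task to merge (`REL`, `SFM` or `POM`).
#' @param n_annotators required annotations per post (default 2).
#' @return data.frame: `post_id`, `task`, `status`
#'   (`CONSISTENT`/`INCONSISTENT`/`UNABLE`), `label` (set only when
#'   CONSISTENT).
#' @export
merge_consensus <- function(records, task, n_annotators = 2) {
  stopifnot(all(c("post_id", "annotator_id", "task", "label") %in% names(records)))
  rec <- records[records$task == task, , drop = FALSE]
  if (nrow(rec) == 0) stop("no records for task ", task)
  if (anyDuplicated(rec[c("post_id", "annotator_id")])) {
    stop("duplicate (post_id, annotator_id) pairs for task ", task)
  }
  counts <- table(rec$post_id)
  short <- names(counts)[counts != n_annotators]
  if (length(short)) {
    stop("posts without exactly ", n_annotators, " annotations: ",
         paste(head(short, 10), collapse = ", "))
  }
  labs <- split(rec$label, rec$post_id)
  ids <- names(labs)
  status <- character(length(ids))
  label <- rep(NA_character_, length(ids))
  for (i in seq_along(ids)) {
    l <- labs[[i]]
    if (any(l == "UNABLE")) {
      status[i] <- "UNABLE"
    } else if (length(unique(l)) > 1) {
      status[i] <- "INCONSISTENT"
    } else {
      status[i] <- "CONSISTENT"
      label[i] <- l[1]
    }
  }
  data.frame(post_id = ids, task = task, status = status, label = label,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cohen's kappa
#'
#' Chance-corrected inter-annotator agreement,
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)}, with expected agreement from the
#' products of marginal proportions. When both raters use one category for
#' every item (`p_e = p_o = 1`) kappa is 1 by convention.
#'
#' @param labels_a,labels_b equal-length label vectors over the same
#'   alphabet.
#' @param drop_unable if TRUE, pairs where either rater chose `"UNABLE"`
#'   are removed before computing kappa (default FALSE: UNABLE is a third
#'   category, matching agreement computed on the task as performed).
#' @return kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(labels_a, labels_b, drop_unable = FALSE) {
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  if (length(labels_a) < 1) stop("need at least one pair")
  labels_a <- as.character(labels_a); labels_b <- as.character(labels_b)
  if (drop_unable) {
    keep <- labels_a != "UNABLE" & labels_b != "UNABLE"
    labels_a <- labels_a[keep]; labels_b <- labels_b[keep]
    if (length(labels_a) < 1) stop("no pairs left after dropping UNABLE")
  }
  lev <- sort(unique(c(labels_a, labels_b)))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    return(if (po >= 1 - .Machine$double.eps^0.5) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Dataset accounting for consensus labels
#'
#' @param consensus consensus data.frame from [merge_consensus()] (one
#'   task).
#' @return an object of class `filter_report`: `n_input`,
#'   `n_inconsistent`, `n_unable`, `n_retained`, `class_counts`,
#'   `class_percent` (1 decimal, sums to 100 within 0.1).
#' @export
accounting <- function(consensus) {
  if (length(unique(consensus$task)) > 1) stop("consensus must come from one task")
  n_input <- nrow(consensus)
  n_inc <- sum(consensus$status == "INCONSISTENT")
  n_un <- sum(consensus$status == "UNABLE")
  kept <- consensus[consensus$status == "CONSISTENT", , drop = FALSE]
  cc <- table(kept$label)
  cp <- if (nrow(kept) > 0) round(100 * as.numeric(cc) / nrow(kept), 1) else numeric(0)
  names(cp) <- names(cc)
  structure(list(n_input = n_input, n_inconsistent = n_inc, n_unable = n_un,
                 n_retained = nrow(kept),
                 class_counts = setNames(as.integer(cc), names(cc)),
                 class_percent = cp),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Annotation filter report\n")
  cat(sprintf("  input: %d  inconsistent: %d  unable: %d  retained: %d\n",
              x$n_input, x$n_inconsistent, x$n_unable, x$n_retained))
  if (length(x$class_counts)) {
    for (cl in names(x$class_counts)) {
      cat(sprintf("    %s: %d (%.1f%%)\n", cl, x$class_counts[[cl]],
                  x$class_percent[[cl]]))
    }
  }
  invisible(x)
}
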