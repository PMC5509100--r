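#' @importFrom rlang .data
NULL

# Coerce a label column to logical: TRUE = differential/positive.
as_binary_label <- function(x) {
  if (is.logical(x)) {
    return(x)
  }
  if (is.numeric(x)) {
    return(x != 0)
  }
  x <- as.character(x)
  lab <- x %in% c("differential", "positive", "TRUE", "1")
  if (!all(x %in% c(
    "differential", "non_differential", "positive", "negative",
    "TRUE", "FALSE", "1", "0"
  ))) {
    stop("unrecognized label values: ",
      paste(utils::head(setdiff(x, c(
        "differential", "non_differential", "positive", "negative",
        "TRUE", "FALSE", "1", "0"
      )), 3), collapse = ", "),
      call. = FALSE
    )
  }
  lab
}

pull_score_label <- function(data, score, label) {
  s <- rlang::eval_tidy(rlang::enquo(score), data)
  l <- as_binary_label(rlang::eval_tidy(rlang::enquo(label), data))
  keep <- is.finite(s) & !is.na(l)
  list(score = s[keep], label = l[keep])
}

# Average precision with tied scores processed jointly: every site in a tied
# block is assigned the precision at the end of the block.
average_precision_vec <- function(score, label) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  l <- label[ord]
  n <- length(s)
  block_end <- c(which(diff(s) != 0), n)
  cum_tp <- cumsum(l)[block_end]
  block_pos <- diff(c(0, cum_tp))
  prec <- cum_tp / block_end
  sum(block_pos * prec) / sum(l)
}

#' Precision-recall curve and average precision
#'
#' Builds the step-wise precision-recall curve of a ranked call set over all
#' score thresholds and summarizes it by average precision (AP): each
#' positive contributes the precision at its own threshold, and the AUPR is
#' the mean of these contributions. Tied scores are processed as one block,
#' every member receiving the block-end precision. Under extreme class
#' imbalance AP is the well-behaved area estimator: a random ranking has
#' expected AP close to the positive-class prevalence.
#'
#' @param data A data frame with one row per site.
#' @param score Column (unquoted) holding the ranking score; higher = more
#'   confidently differential.
#' @param label Column (unquoted) holding truth labels: logical, 0/1, or
#'   `"differential"`/`"non_differential"`.
#' @return Object of class `deltabind_pr`: list with `curve` (tibble
#'   `threshold`, `n_called`, `tp`, `precision`, `recall`, one row per tied
#'   block), `aupr`, `n_pos`, `n_neg`, `prevalence`.
#' @examples
#' d <- data.frame(s = c(0.9, 0.8, 0.3, 0.2), y = c(1, 0, 1, 0))
#' pr <- precision_recall(d, s, y)
#' pr$aupr
#' @export
precision_recall <- function(data, score, label) {
  v <- pull_score_label(data, {{ score }}, {{ label }})
  n_pos <- sum(v$label)
  n_neg <- sum(!v$label)
  if (n_pos == 0L) stop("no positive labels", call. = FALSE)
  if (n_neg == 0L) stop("no negative labels", call. = FALSE)

  ord <- order(v$score, decreasing = TRUE)
  s <- v$score[ord]
  l <- v$label[ord]
  n <- length(s)
  block_end <- c(which(diff(s) != 0), n)
  cum_tp <- cumsum(l)[block_end]
  curve <- tibble::tibble(
    threshold = s[block_end],
    n_called = block_end,
    tp = cum_tp,
    precision = cum_tp / block_end,
    recall = cum_tp / n_pos
  )
  block_pos <- diff(c(0, cum_tp))
  aupr <- sum(block_pos * curve$precision) / n_pos

  structure(
    list(
      curve = curve, aupr = aupr, n_pos = n_pos, n_neg = n_neg,
      prevalence = n_pos / (n_pos + n_neg)
    ),
    class = "deltabind_pr"
  )
}

#' Precision at a fixed recall level
#'
#' Reads the precision off a precision-recall curve at the first (highest)
#' threshold whose recall reaches the requested level — the "first
#' crossing", not the best precision anywhere beyond it. At `recall_level =
#' 0` this is the precision of the single top-ranked block.
#'
#' @param pr A `deltabind_pr` object from [precision_recall()].
#' @param recall_level Target recall in `[0, 1]` (default 0.10).
#' @return Precision (scalar) at the first crossing.
#' @export
precision_at_recall <- function(pr, recall_level = 0.10) {
  stopifnot(inherits(pr, "deltabind_pr"))
  if (recall_level > max(pr$curve$recall)) {
    stop("recall level ", recall_level, " exceeds the maximum achievable ",
      "recall ", max(pr$curve$recall),
      call. = FALSE
    )
  }
  i <- which(pr$curve$recall >= recall_level)[1L]
  pr$curve$precision[i]
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation with tie correction: the probability that a
#' uniformly chosen positive site outranks a uniformly chosen negative one
#' (ties counting one half). Invariant under strictly increasing transforms
#' of the score.
#'
#' @inheritParams precision_recall
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(data, score, label) {
  v <- pull_score_label(data, {{ score }}, {{ label }})
  n_pos <- sum(v$label)
  n_neg <- sum(!v$label)
  if (n_pos == 0L || n_neg == 0L) {
    stop("need at least one positive and one negative label", call. = FALSE)
  }
  r <- rank(v$score, ties.method = "average")
  (sum(r[v$label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Permutation p-value for a ranking metric
#'
#' Significance of an observed AUPR or AUROC against the label-permutation
#' null: labels are shuffled over sites (equivalently, the positive set is
#' re-drawn uniformly), the metric recomputed, and the p-value estimated
#' with the add-one estimator `p = (1 + #\{permuted >= observed\}) /
#' (1 + n_resamples)` — its minimum attainable value is
#' `1 / (1 + n_resamples)`.
#'
#' @inheritParams precision_recall
#' @param metric `"aupr"` or `"auroc"`.
#' @param n_resamples Number of label permutations (at least 100).
#' @param seed Integer seed for the permutations (local RNG scope).
#' @return Scalar p-value; the observed metric is attached as attribute
#'   `"observed"`.
#' @export
bootstrap_pvalue <- function(data, score, label, metric = c("aupr", "auroc"),
                             n_resamples = 9999L, seed = 1L) {
  metric <- match.arg(metric)
  v <- pull_score_label(data, {{ score }}, {{ label }})
  if (n_resamples < 100L) {
    stop("n_resamples must be at least 100; got ", n_resamples, call. = FALSE)
  }
  n <- length(v$score)
  n_pos <- sum(v$label)
  n_neg <- n - n_pos
  if (n_pos == 0L || n_neg == 0L) {
    stop("need at least one positive and one negative label", call. = FALSE)
  }

  has_ties <- anyDuplicated(v$score) > 0L
  r <- rank(v$score, ties.method = "average")
  # positions of sites in descending-score order (unique scores only)
  desc_pos <- integer(n)
  desc_pos[order(v$score, decreasing = TRUE)] <- seq_len(n)

  metric_at <- function(lab) {
    if (metric == "auroc") {
      (sum(r[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
    } else if (!has_ties) {
      k <- sort(desc_pos[lab])
      mean(seq_along(k) / k)
    } else {
      average_precision_vec(v$score, lab)
    }
  }

  observed <- metric_at(v$label)
  hits <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_resamples), function(i) {
      lab <- logical(n)
      lab[sample.int(n, n_pos)] <- TRUE
      metric_at(lab) >= observed - 1e-12
    }, logical(1)))
  })
  structure((1 + hits) / (1 + n_resamples), observed = observed)
}

#' Contingency statistics for signal-imbalance versus differential events
#'
#' Summarizes a 2x2 co-occurrence of an accessibility signal (e.g.
#' DNase-seq read imbalance at a SNP) and a differential-binding event
#' (e.g. ChIP-seq differential occupancy) over a set of candidate sites:
#' the positive and negative predictive value of the signal for the event,
#' and the marginal prevalences.
#'
#' @param counts Data frame (or named list) with single values `n_total`,
#'   `n_signal` (sites with the accessibility signal), `n_event` (sites
#'   with the differential event) and `n_both`.
#' @return Tibble with one row per statistic (`ppv`, `npv`,
#'   `prevalence_event`, `prevalence_signal`): `numerator`, `denominator`,
#'   `value` (exact fraction) and `percent` (rounded to the nearest whole
#'   percent).
#' @examples
#' contingency_stats(list(
#'   n_total = 11355, n_signal = 3079,
#'   n_event = 810, n_both = 566
#' ))
#' @export
contingency_stats <- function(counts) {
  counts <- as.list(counts)
  needed <- c("n_total", "n_signal", "n_event", "n_both")
  missing_cells <- setdiff(needed, names(counts))
  if (length(missing_cells) > 0L) {
    stop("missing counts: ", paste(missing_cells, collapse = ", "), call. = FALSE)
  }
  n_total <- counts$n_total
  n_signal <- counts$n_signal
  n_event <- counts$n_event
  n_both <- counts$n_both
  if (any(c(n_total, n_signal, n_event, n_both) < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  if (n_both > min(n_signal, n_event)) {
    stop("n_both exceeds min(n_signal, n_event)", call. = FALSE)
  }
  n_nosignal <- n_total - n_signal
  n_nosignal_noevent <- counts$n_nosignal_noevent %||%
    (n_nosignal - (n_event - n_both))
  for (cell in c("n_signal", "n_total")) {
    if (get(cell) == 0) stop("zero denominator: ", cell, call. = FALSE)
  }
  if (n_nosignal == 0 && n_nosignal_noevent > 0) {
    stop("zero denominator: n_nosignal", call. = FALSE)
  }
  out <- tibble::tibble(
    statistic = c("ppv", "npv", "prevalence_event", "prevalence_signal"),
    numerator = c(n_both, n_nosignal_noevent, n_event, n_signal),
    denominator = c(n_signal, n_nosignal, n_total, n_total),
    value = .data$numerator / .data$denominator
  )
  # a saturated table (every site carries the signal) leaves npv vacuous:
  # no signal-free site contradicts it, so it is reported as 1
  out$value[out$denominator == 0 & out$numerator == 0] <- 1
  out$percent <- round(100 * out$value)
  out
}

#' Read a packaged contingency-count table
#'
#' Reads a small TSV of named counts (columns `cell`, `count`; `#` comment
#' lines allowed) into the named list [contingency_stats()] consumes.
#'
#' @param path Path to the TSV. The fixture shipped with the package is at
#'   `system.file("extdata", "ctcf_snp_contingency.tsv", package =
#'   "deltabind")`.
#' @return Named list of counts.
#' @export
read_contingency <- function(path) {
  tab <- readr::read_tsv(path,
    comment = "#", show_col_types = FALSE,
    progress = FALSE
  )
  stats::setNames(as.list(tab$count), tab$cell)
}

#' Compare a per-factor metric between two factor classes
#'
#' Tests whether a performance metric (e.g. precision at 10% recall)
#' differs between two groups of transcription factors — typically pioneer
#' versus non-pioneer (settler/migrant) classes — with a permutation test
#' on the difference of group means. All reassignments of the group labels
#' are enumerated exactly when feasible, otherwise a seeded Monte-Carlo
#' sample is used. The test is one-sided in the direction named by
#' `higher` (default: the observed direction).
#'
#' @param data Data frame with one row per factor.
#' @param value Unquoted column of metric values.
#' @param group Unquoted column with exactly two group labels, each with
#'   at least 2 members.
#' @param higher Optional group label expected to have the larger mean;
#'   defaults to the group with the larger observed mean.
#' @param max_exact Enumerate exactly when the number of reassignments is
#'   at most this (default 2e5); otherwise sample `n_resamples` of them.
#' @param n_resamples,seed Monte-Carlo controls for the non-exact case.
#' @return One-row tibble: `group_high`, `group_low`, `mean_high`,
#'   `mean_low`, `mean_diff`, `p_value`, `n_perm`, `exact`.
#' @export
group_compare <- function(data, value, group, higher = NULL,
                          max_exact = 2e5, n_resamples = 1e4, seed = 1L) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- as.character(rlang::eval_tidy(rlang::enquo(group), data))
  lev <- sort(unique(g))
  if (length(lev) != 2L) {
    stop("group must have exactly 2 levels; got ", length(lev), call. = FALSE)
  }
  if (any(table(g) < 2L)) {
    stop("each group needs at least 2 members", call. = FALSE)
  }
  m1 <- mean(v[g == lev[1L]])
  m2 <- mean(v[g == lev[2L]])
  hi <- higher %||% lev[order(c(m1, m2), decreasing = TRUE)[1L]]
  if (!hi %in% lev) stop("'higher' must be one of the group labels", call. = FALSE)
  lo <- setdiff(lev, hi)
  obs <- mean(v[g == hi]) - mean(v[g == lo])

  n <- length(v)
  n_hi <- sum(g == hi)
  total <- choose(n, n_hi)
  stat_for <- function(idx) mean(v[idx]) - mean(v[-idx])
  if (total <= max_exact) {
    combos <- utils::combn(n, n_hi)
    stats_perm <- apply(combos, 2L, stat_for)
    exact <- TRUE
    n_perm <- total
  } else {
    stats_perm <- withr::with_seed(seed, {
      vapply(seq_len(n_resamples), function(i) {
        stat_for(sample.int(n, n_hi))
      }, numeric(1))
    })
    exact <- FALSE
    n_perm <- n_resamples
  }
  p <- mean(stats_perm >= obs - 1e-12)

  tibble::tibble(
    group_high = hi, group_low = lo,
    mean_high = mean(v[g == hi]), mean_low = mean(v[g == lo]),
    mean_diff = obs, p_value = p, n_perm = n_perm, exact = exact
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.deltabind_pr <- function(x, ...) {
  cat(sprintf(
    "Precision-recall: AUPR (average precision) = %.4g over %d positives / %d negatives (prevalence %.3g)\n",
    x$aupr, x$n_pos, x$n_neg, x$prevalence
  ))
  invisible(x)
}
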