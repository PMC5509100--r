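# independent threshold-sweep oracle for average precision:
# per-positive precision at its own threshold, tied blocks jointly
sweep_ap <- function(score, label) {
  thr <- sort(unique(score), decreasing = TRUE)
  total <- 0
  for (t in thr) {
    called <- score >= t
    block <- score == t
    n_pos_block <- sum(label[block])
    if (n_pos_block > 0) {
      total <- total + n_pos_block * sum(label[called]) / sum(called)
    }
  }
  total / sum(label)
}

# quadratic all-pairs AUROC oracle (ties count one half)
pairs_auroc <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

test_that("average precision has the right closed forms", {
  # perfect ranking
  d <- data.frame(s = 10:1, y = c(rep(1, 3), rep(0, 7)))
  expect_equal(precision_recall(d, s, y)$aupr, 1)

  # a single positive at rank k contributes precision 1/k
  n <- 100
  d2 <- data.frame(s = n:1, y = c(rep(0, n - 1), 1))
  expect_equal(precision_recall(d2, s, y)$aupr, 1 / n)
  d3 <- data.frame(s = n:1, y = c(rep(0, 9), 1, rep(0, n - 10)))
  expect_equal(precision_recall(d3, s, y)$aupr, 1 / 10)

  expect_error(precision_recall(data.frame(s = 1:3, y = 0), s, y), "no positive")
})

test_that("average precision and AUROC match brute-force oracles with ties", {
  withr::local_seed(41)
  for (i in 1:5) {
    score <- sample(seq(0, 1, by = 0.05), 200, replace = TRUE) # many ties
    label <- stats::runif(200) < 0.2
    d <- data.frame(s = score, y = label)
    expect_equal(precision_recall(d, s, y)$aupr, sweep_ap(score, label))
    expect_equal(auroc(d, s, y), pairs_auroc(score, label))
  }
})

test_that("AUROC has the right extremes and is transform-invariant", {
  d <- data.frame(s = 10:1, y = c(rep(1, 4), rep(0, 6)))
  expect_equal(auroc(d, s, y), 1)
  d$y <- rev(d$y)
  expect_equal(auroc(d, s, y), 0)
  withr::local_seed(42)
  d2 <- data.frame(s = rnorm(300), y = runif(300) < 0.3)
  expect_equal(auroc(d2, s, y), auroc(transform(d2, s = exp(5 * s)), s, y))
})

test_that("precision at recall reads the first crossing of the PR curve", {
  # perfect ranking: precision 1 at any recall
  d <- data.frame(s = 100:1, y = c(rep(1, 10), rep(0, 90)))
  pr <- precision_recall(d, s, y)
  for (r in c(0, 0.1, 0.5, 1)) expect_equal(precision_at_recall(pr, r), 1)

  # interleaved positives: compare with an exhaustive sweep
  withr::local_seed(43)
  y <- logical(1000)
  y[sample.int(1000, 10)] <- TRUE
  s <- stats::runif(1000)
  pr2 <- precision_recall(data.frame(s = s, y = y), s, y)
  # oracle: walk thresholds from the top, stop at the first recall >= r
  sweep_par <- function(score, label, r) {
    thr <- sort(unique(score), decreasing = TRUE)
    for (t in thr) {
      called <- score >= t
      if (sum(label[called]) / sum(label) >= r) {
        return(sum(label[called]) / sum(called))
      }
    }
  }
  for (r in c(0.1, 0.3, 0.8)) {
    expect_equal(precision_at_recall(pr2, r), sweep_par(s, y, r))
  }
  # recall 0 is the precision of the top-ranked block
  top <- which.max(s)
  expect_equal(precision_at_recall(pr2, 0), as.numeric(y[top]))
  expect_error(precision_at_recall(pr2, 1.5), "exceeds")
})

test_that("permutation p-value attains its minimum for a perfect ranking", {
  withr::local_seed(44)
  n <- 100000
  y <- logical(n)
  y[sample.int(n, 400)] <- TRUE
  s <- stats::runif(n) + 10 * y # positives strictly on top
  p <- bootstrap_pvalue(data.frame(s = s, y = y), s, y,
    metric = "aupr",
    n_resamples = 9999, seed = 7
  )
  expect_equal(as.numeric(p), 1e-4)
  expect_equal(attr(p, "observed"), 1)
})

test_that("permutation p-values are calibrated under the null", {
  ps <- vapply(1:50, function(sd) {
    withr::with_seed(sd, {
      y <- logical(500)
      y[sample.int(500, 25)] <- TRUE
      s <- stats::runif(500)
      as.numeric(bootstrap_pvalue(data.frame(s = s, y = y), s, y,
        metric = "auroc", n_resamples = 199, seed = sd
      ))
    })
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.90)
})

test_that("resample counts below the minimum are rejected", {
  d <- data.frame(s = runif(50), y = rep(c(TRUE, FALSE), 25))
  expect_error(bootstrap_pvalue(d, s, y, n_resamples = 0), "at least 100")
})

test_that("a random ranking's AUPR concentrates on the class prevalence", {
  aupr <- vapply(1:5, function(sd) {
    withr::with_seed(sd, {
      y <- logical(100000)
      y[sample.int(100000, 400)] <- TRUE
      precision_recall(data.frame(s = runif(100000), y = y), s, y)$aupr
    })
  }, numeric(1))
  expect_lt(abs(mean(aupr) - 0.004), 0.001)
})

test_that("contingency statistics summarize a saturated and a degenerate table", {
  sat <- contingency_stats(list(n_total = 50, n_signal = 50, n_event = 50, n_both = 50))
  expect_equal(sat$percent, c(100, 100, 100, 100))
  expect_error(
    contingency_stats(list(n_total = 10, n_signal = 0, n_event = 1, n_both = 0)),
    "n_signal"
  )
  expect_error(
    contingency_stats(list(n_total = 10, n_signal = 5, n_event = 2, n_both = 4)),
    "n_both"
  )
})

test_that("group comparison enumerates permutations exactly", {
  # identical groups: no difference, p at least one half
  d <- data.frame(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  res <- group_compare(d, v, g)
  expect_equal(res$mean_diff, 0)
  expect_gte(res$p_value, 0.5)

  # fully separated groups: the minimum attainable p for 3 vs 3
  d2 <- data.frame(v = c(1, 1, 1, 0, 0, 0), g = rep(c("hi", "lo"), each = 3))
  res2 <- group_compare(d2, v, g, higher = "hi")
  expect_equal(res2$mean_diff, 1)
  expect_equal(res2$p_value, 1 / choose(6, 3))
  expect_true(res2$exact)

  # independent bitmask enumeration oracle for n <= 8
  withr::local_seed(45)
  v <- stats::rnorm(8)
  g <- rep(c("x", "y"), each = 4)
  res3 <- group_compare(data.frame(v = v, g = g), v, g, higher = "x")
  obs <- mean(v[g == "x"]) - mean(v[g == "y"])
  stats_all <- c()
  for (mask in 0:(2^8 - 1)) {
    idx <- which(bitwAnd(bitwShiftR(mask, 0:7), 1L) == 1L)
    if (length(idx) != 4) next
    stats_all <- c(stats_all, mean(v[idx]) - mean(v[-idx]))
  }
  expect_equal(res3$p_value, mean(stats_all >= obs - 1e-12))
  expect_error(group_compare(data.frame(v = 1:3, g = c("a", "a", "b")), v, g), "at least 2")
})
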