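small_pipeline <- function(scores) {
  rt <- to_ranks(scores)
  rp <- fit_reproducibility(rt)
  dm <- fit_diff_mixture(rt, rp, n_windows = 5)
  call_differential(rt, rp, dm)
}

test_that("the call score is exactly the product of the two probabilities", {
  sim <- simulate_scores(sim_config(n_sites = 2000, seed = 21))
  calls <- small_pipeline(sim$scores)
  expect_identical(calls$deltabind_score, calls$pA * calls$pB)
  expect_true(all(calls$deltabind_score >= 0 & calls$deltabind_score <= 1))
  # the ranking is a permutation of the complete sites
  expect_setequal(calls$call_rank, seq_len(nrow(calls)))
})

test_that("tied scores rank deterministically by site key", {
  rt <- tibble::tibble(
    site_id = c("chr1:300-320:+", "chr1:100-120:+", "chr1:200-220:+"),
    meanrank_K = c(3, 3, 1),
    meanrank_G = c(1, 1, 3),
    rank_diff = c(2, 2, -2)
  )
  rp <- repro_model(0.5, 2, 1, 0.8)
  rp$pa_curve <- structure(list(x = c(1, 3), y = c(0.2, 0.8)),
    class = "deltabind_pa_curve"
  )
  dm <- manual_diffmix(0.8, 0.1, 0.1, delta = 2, sigma0 = 1, sigma1 = 1, center = 2)
  calls <- call_differential(rt, rp, dm)
  tied <- calls[calls$meanrank_K == 3, ]
  expect_equal(tied$deltabind_score[1], tied$deltabind_score[2])
  expect_lt(
    tied$call_rank[tied$site_id == "chr1:100-120:+"],
    tied$call_rank[tied$site_id == "chr1:300-320:+"]
  )
})

test_that("end-to-end calls are invariant under monotone raw-score transforms", {
  sim <- simulate_scores(sim_config(n_sites = 2000, seed = 22))
  f <- function(x) log(x + 1e-9) * 3 + 7 # strictly increasing on positives
  distorted <- sim$scores
  for (cl in c("K_rep1", "K_rep2", "G_rep1", "G_rep2")) {
    distorted[[cl]] <- f(distorted[[cl]])
  }
  attr(distorted, "score_cols") <- attr(sim$scores, "score_cols")
  c1 <- small_pipeline(sim$scores)
  c2 <- small_pipeline(distorted)
  expect_equal(c1$deltabind_score, c2$deltabind_score, tolerance = 1e-12)
  expect_identical(c1$call_rank, c2$call_rank)
})

test_that("swapping the bound-condition replicates leaves calls unchanged", {
  sim <- simulate_scores(sim_config(n_sites = 2000, seed = 23))
  swapped <- sim$scores
  swapped$K_rep1 <- sim$scores$K_rep2
  swapped$K_rep2 <- sim$scores$K_rep1
  attr(swapped, "score_cols") <- attr(sim$scores, "score_cols")
  c1 <- small_pipeline(sim$scores)
  c2 <- small_pipeline(swapped)
  expect_equal(c1$deltabind_score, c2$deltabind_score, tolerance = 1e-12)
})

test_that("a dimension mismatch between model and table is an error", {
  sim <- simulate_scores(sim_config(n_sites = 2000, seed = 24))
  rt <- to_ranks(sim$scores)
  rp <- fit_reproducibility(rt)
  dm <- suppressWarnings(fit_diff_mixture(rt, rp, n_windows = 5))
  expect_error(call_differential(rt[1:100, ], rp, dm), "2000")
})

test_that("score-difference baseline is the mean-replicate difference, ranked", {
  scores <- tiny_score_table(
    K1 = c(3, 1, 2), K2 = c(3, 1, 2),
    G1 = c(1, 1, 2), G2 = c(1, 1, 2)
  )
  bl <- baseline_score_diff(scores)
  expect_equal(bl$score_diff, c(2, 0, 0))
  expect_equal(bl$baseline_rank[1], 1L)

  # identical conditions: all differences zero
  eq <- baseline_score_diff(tiny_score_table(
    K1 = 1:3, K2 = 1:3, G1 = 1:3, G2 = 1:3
  ))
  expect_equal(eq$score_diff, c(0, 0, 0))

  # direct recomputation oracle on random rows
  withr::local_seed(25)
  n <- 100
  tab <- new_score_table(data.frame(
    chrom = "chr1", start = (seq_len(n) - 1L) * 50L,
    end = (seq_len(n) - 1L) * 50L + 20L,
    K_rep1 = rnorm(n), K_rep2 = rnorm(n),
    G_rep1 = rnorm(n), G_rep2 = rnorm(n)
  ))
  bl2 <- baseline_score_diff(tab)
  oracle <- (tab$K_rep1 + tab$K_rep2) / 2 - (tab$G_rep1 + tab$G_rep2) / 2
  expect_equal(bl2$score_diff, oracle)
})

test_that("read-count baseline subtracts counts and rejects negatives", {
  bl <- baseline_readcount_diff(c(10, 2), c(3, 2))
  expect_equal(bl$count_diff, c(7, 0))
  expect_equal(baseline_readcount_diff(c(5, 5), c(5, 5))$count_diff, c(0, 0))
  expect_error(baseline_readcount_diff(c(-1, 2), c(0, 0)), "nonnegative")

  withr::local_seed(26)
  cK <- rpois(200, 20)
  cG <- rpois(200, 20)
  expect_equal(baseline_readcount_diff(cK, cG)$count_diff, cK - cG)
})

test_that("the probabilistic score outranks the raw-difference baseline on planted data", {
  sim <- simulate_scores(sim_config(n_sites = 20000, seed = 27))
  calls <- small_pipeline(sim$scores)
  dat <- dplyr::inner_join(calls, sim$labels, by = "site_id")
  pr_db <- precision_recall(dat, deltabind_score, label)
  bl <- dplyr::inner_join(baseline_score_diff(sim$scores), sim$labels, by = "site_id")
  pr_bl <- precision_recall(bl, score_diff, label)
  expect_gt(pr_db$aupr, pr_bl$aupr)
})
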