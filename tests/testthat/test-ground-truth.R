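# independent loop oracle for the agreement walk
oracle_cutoff <- function(x, w) {
  m <- length(x)
  prop <- numeric(m)
  for (t in seq_len(m)) {
    prop[t] <- mean(x[max(1, t - w + 1):t])
  }
  max_so_far <- cummax(prop)
  for (t in seq_len(m)) {
    if (prop[t] < max_so_far[t] / 1.6) {
      return(t - 1L)
    }
  }
  m
}

test_that("the agreement walk stops at max proportion over 1.6", {
  # window 2: trailing proportions 1, 1, 1, .5, 0; threshold 1/1.6
  x <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(as.integer(agreement_cutoff(x, local_window = 2)), 3L)

  # full agreement: keep everything
  expect_message(
    all_in <- agreement_cutoff(rep(TRUE, 10), local_window = 3),
    "keeping all"
  )
  expect_equal(as.integer(all_in), 10L)

  # no agreement at all: threshold is 0, keep everything (degenerate case)
  expect_message(
    none <- agreement_cutoff(rep(FALSE, 10), local_window = 3),
    "keeping all"
  )
  expect_equal(as.integer(none), 10L)

  expect_error(agreement_cutoff(c(TRUE, FALSE), local_window = 5), "at least")
})

test_that("the agreement walk matches an independent loop oracle on random inputs", {
  withr::local_seed(31)
  for (i in 1:50) {
    x <- stats::runif(200) < seq(0.95, 0.05, length.out = 200)
    expect_equal(
      as.integer(suppressMessages(agreement_cutoff(x, local_window = 5))),
      oracle_cutoff(x, 5)
    )
  }
})

test_that("the threshold filter keeps exactly the jointly-significant sites", {
  stats <- tibble::tibble(
    site_id = c("a", "b", "c", "d", "e"),
    p_edger = c(0.01, 0.01, 0.1, 0.01, 0.04),
    q1 = c(1.0, 2.5, 1.0, 1.0, 2.0),
    q2 = c(5.0, 5.0, 5.0, 2.5, 2.4)
  )
  kept <- threshold_filter(stats)
  # a passes all four; b fails the strict q1 bound; c fails p; d fails the
  # strict q2 bound; e fails q2
  expect_equal(kept$site_id, "a")
})

test_that("the threshold filter equals a row-by-row boolean oracle on random tables", {
  withr::local_seed(32)
  n <- 1000
  stats <- tibble::tibble(
    site_id = sprintf("s%04d", seq_len(n)),
    p_edger = stats::runif(n),
    q1 = stats::rexp(n, 1 / 2),
    q2 = stats::rexp(n, 1 / 2)
  )
  kept <- threshold_filter(stats)
  oracle <- character(0)
  for (i in seq_len(n)) {
    if (stats$p_edger[i] < 0.05 && stats$q1[i] < 2.5 && stats$q2[i] > 2.5 &&
      (stats$q2[i] - stats$q1[i]) > 0.5) {
      oracle <- c(oracle, stats$site_id[i])
    }
  }
  expect_identical(kept$site_id, oracle)
})

test_that("events match the nearest motif within 20 bp, center to center", {
  motifs <- tibble::tibble(
    chrom = "chr1",
    start = c(975, 1040), end = c(995, 1060), # centers 985, 1050
    site_id = c("m985", "m1050")
  )
  ev <- tibble::tibble(chrom = "chr1", start = 990, end = 1010) # center 1000
  lab <- match_to_motifs(ev, motifs)
  expect_equal(lab$label[lab$site_id == "m985"], "differential")
  expect_equal(lab$label[lab$site_id == "m1050"], "non_differential")

  # 21 bp away: just outside
  far <- tibble::tibble(chrom = "chr1", start = 1011, end = 1031) # center 1021
  lab2 <- match_to_motifs(far, motifs[2, ])
  expect_equal(lab2$label, "non_differential")

  # exact distance tie resolved by site key, with a warning
  mid <- tibble::tibble(chrom = "chr1", start = 1007.5, end = 1027.5)
  expect_warning(lab3 <- match_to_motifs(mid, motifs, max_dist = 40), "site_id")
  expect_equal(lab3$label[lab3$site_id == "m1050"], "differential")
})

test_that("motif matching equals an all-pairs distance oracle on random coordinates", {
  withr::local_seed(33)
  n <- 500
  motifs <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = sample.int(50000, n)
  )
  motifs$end <- motifs$start + 20L
  motifs$site_id <- sprintf("m%04d", seq_len(n))
  events <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = sample.int(50000, n)
  )
  events$end <- events$start + 30L

  lab <- suppressWarnings(match_to_motifs(events, motifs))

  # quadratic oracle over every (event, motif) pair
  mc <- (motifs$start + motifs$end) / 2
  ec <- (events$start + events$end) / 2
  hit <- rep(FALSE, n)
  for (i in seq_len(n)) {
    same <- motifs$chrom == events$chrom[i]
    d <- abs(mc - ec[i])
    hit[same & d <= 20] <- hit[same & d <= 20] | TRUE
  }
  matched_ids <- sort(lab$site_id[lab$label == "differential"])
  # every matched motif is within 20 bp of some event and vice versa for
  # each event's nearest eligible motif
  expect_true(all(matched_ids %in% motifs$site_id[hit]))
  for (i in seq_len(n)) {
    same <- which(motifs$chrom == events$chrom[i])
    if (length(same) == 0) next
    d <- abs(mc[same] - ec[i])
    if (min(d) <= 20) {
      nearest <- motifs$site_id[same[order(d, motifs$site_id[same])[1]]]
      expect_equal(lab$label[lab$site_id == nearest], "differential")
    }
  }
})

test_that("the composed pipeline recovers planted truth from simulated statistics", {
  cfg <- sim_config(n_sites = 20000, seed = 3)
  sim <- simulate_scores(cfg)
  st <- simulate_sitestats(cfg, sim$labels)
  motifs <- dplyr::select(sim$scores, chrom, start, end, strand, site_id)
  truth <- build_truth_set(st, motifs)
  joined <- dplyr::inner_join(truth$labels, sim$labels,
    by = "site_id", suffix = c("_pred", "_true")
  )
  pos <- joined$label_true == "differential"
  expect_gte(mean(joined$label_pred[pos] == "differential"), 0.90)
  expect_lte(mean(joined$label_pred[!pos] == "differential"), 0.05)

  # stages only remove sites: each pass set nests inside the previous
  expect_true(all(truth$trace$pass_thresholds <= truth$trace$pass_agreement))
  expect_true(all(truth$trace$matched_motif <= truth$trace$pass_thresholds))
})
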