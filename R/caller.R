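#' Call differential binding sites
#'
#' Combines the two fitted stages into the final per-site differential-
#' binding probability: `score = pA * pB`, where `pA = P(A | R)` is the
#' bound-condition binding probability read off the reproducibility curve at
#' the site's mean bound-condition rank, and `pB = P(B | A, R)` is the
#' posterior of the "weaker in the unbound condition" category from the
#' rank-difference mixture. Sites are ranked by descending score; ties are
#' broken by `site_id` (lexicographic), so the ordering is deterministic
#' across runs and platforms.
#'
#' @param rank_table Tibble from [to_ranks()].
#' @param repro `deltabind_repro` from [fit_reproducibility()] (must carry
#'   the calibrated `pa_curve`).
#' @param diffmix `deltabind_diffmix` from [fit_diff_mixture()].
#' @return A tibble with the site columns plus `pA`, `pB`,
#'   `deltabind_score` and `call_rank` (1 = most confidently differential;
#'   `NA` probabilities and ranks for incomplete sites). Site order is the
#'   input order; the ranking lives in `call_rank`.
#' @examples
#' sim <- simulate_scores(sim_config(n_sites = 2000, seed = 1))
#' rt <- to_ranks(sim$scores)
#' rp <- fit_reproducibility(rt)
#' dm <- fit_diff_mixture(rt, rp, n_windows = 5)
#' calls <- call_differential(rt, rp, dm)
#' head(dplyr::arrange(calls, call_rank))
#' @export
call_differential <- function(rank_table, repro, diffmix) {
  stopifnot(inherits(repro, "deltabind_repro"), inherits(diffmix, "deltabind_diffmix"))
  if (is.null(repro$pa_curve)) {
    stop("repro model has no pa_curve; fit it with fit_reproducibility()",
      call. = FALSE
    )
  }
  if (!is.null(repro$n_sites) && !is.na(repro$n_sites) &&
    repro$n_sites != nrow(rank_table)) {
    stop("model fitted on ", repro$n_sites, " sites but rank table has ",
      nrow(rank_table),
      call. = FALSE
    )
  }
  pA <- pa_eval(repro$pa_curve, rank_table$meanrank_K)
  pA[!is.finite(rank_table$meanrank_K)] <- NA_real_
  pB <- posterior_B(diffmix, rank_table)
  out <- dplyr::select(
    tibble::as_tibble(rank_table),
    dplyr::any_of(c("chrom", "start", "end", "strand", "site_id",
                    "meanrank_K", "meanrank_G", "rank_diff"))
  )
  out$pA <- pA
  out$pB <- pB
  out$deltabind_score <- pA * pB
  ok <- which(is.finite(out$deltabind_score))
  out$call_rank <- NA_integer_
  out$call_rank[ok[order(-out$deltabind_score[ok], out$site_id[ok])]] <-
    seq_along(ok)
  out
}

#' Score-difference baseline ranker
#'
#' Ranks sites by the difference of mean raw scores between the two
#' conditions (bound minus unbound, replicates averaged) — the natural
#' single-number adaptation of a footprint score to the differential task,
#' against which the probabilistic caller is compared.
#'
#' @param scores A score table from [new_score_table()]/[read_score_table()].
#' @return Tibble with `site_id`, `score_diff` and `baseline_rank`
#'   (1 = largest difference; ties broken by `site_id`).
#' @export
baseline_score_diff <- function(scores) {
  cols <- score_cols(scores)
  sK <- rowMeans(as.matrix(scores[, cols$bound]))
  sG <- rowMeans(as.matrix(scores[, cols$unbound]))
  out <- tibble::tibble(
    site_id = scores$site_id,
    score_diff = sK - sG
  )
  ok <- which(is.finite(out$score_diff))
  out$baseline_rank <- NA_integer_
  out$baseline_rank[ok[order(-out$score_diff[ok], out$site_id[ok])]] <-
    seq_along(ok)
  out
}

#' Read-count-difference baseline ranker
#'
#' Ranks sites by the difference in (pre-normalized) read counts between
#' the two conditions, the counts having been extracted upstream over a
#' window (600 bp in the intended use) centered on each motif site.
#'
#' @param counts_K,counts_G Nonnegative per-site read counts in the bound
#'   and unbound condition.
#' @param site_id Optional site keys for deterministic tie-breaking;
#'   defaults to the position index.
#' @return Tibble with `site_id`, `count_diff` and `baseline_rank`.
#' @export
baseline_readcount_diff <- function(counts_K, counts_G, site_id = NULL) {
  stopifnot(length(counts_K) == length(counts_G))
  if (any(counts_K < 0, na.rm = TRUE) || any(counts_G < 0, na.rm = TRUE)) {
    stop("read counts must be nonnegative", call. = FALSE)
  }
  if (is.null(site_id)) {
    site_id <- sprintf("site_%06d", seq_along(counts_K))
  }
  out <- tibble::tibble(
    site_id = site_id,
    count_diff = counts_K - counts_G
  )
  ok <- which(is.finite(out$count_diff))
  out$baseline_rank <- NA_integer_
  out$baseline_rank[ok[order(-out$count_diff[ok], out$site_id[ok])]] <-
    seq_along(ok)
  out
}
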