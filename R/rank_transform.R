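#' Rank-transform a score table
#'
#' Replaces every raw score column by its within-column rank over the N
#' candidate sites. Rank N is the strongest binding signal. Ties receive the
#' average of the ranks they span, so each rank column sums to N(N+1)/2.
#' Working in rank space makes everything downstream invariant to monotone
#' distortions of the score scale, which is what lets the caller accept
#' scores from any footprinting algorithm.
#'
#' Per-condition mean ranks are added (`meanrank_K` over the two bound
#' replicates, `meanrank_G` over the unbound replicates — the single
#' replicate's rank when only one is available), together with the rank
#' difference `rank_diff = meanrank_K - meanrank_G`. Under this sign
#' convention a site bound in the bound condition and lost in the unbound
#' condition has `rank_diff` large and positive.
#'
#' Only rows flagged `complete` are ranked; incomplete rows get NA ranks and
#' are ignored by the model-fitting functions.
#'
#' @param scores A score table from [read_score_table()] or
#'   [new_score_table()].
#' @return The input tibble with added columns `rank_K1`, `rank_K2`,
#'   `rank_G1` (and `rank_G2` when present), `meanrank_K`, `meanrank_G`,
#'   `rank_diff`, plus attribute `n_ranked` (the N used for ranking).
#' @examples
#' tab <- new_score_table(
#'   data.frame(
#'     chrom = "chr1", start = 0:2 * 100, end = 0:2 * 100 + 20,
#'     K_rep1 = c(0.1, 3, 2), K_rep2 = c(0.2, 2.5, 2.6),
#'     G_rep1 = c(0.1, 0.2, 2.2), G_rep2 = c(0, 0.1, 2)
#'   )
#' )
#' to_ranks(tab)
#' @export
to_ranks <- function(scores) {
  cols <- score_cols(scores)
  ok <- scores$complete
  n <- sum(ok)
  if (n < 2L) stop("need at least 2 complete sites to rank", call. = FALSE)

  rank_col <- function(x) {
    out <- rep(NA_real_, length(x))
    if (length(unique(x[ok])) == 1L) {
      warning("constant score column: all ranks set to (N+1)/2", call. = FALSE)
    }
    out[ok] <- rank(x[ok], ties.method = "average")
    out
  }

  bound_ranks <- lapply(scores[cols$bound], rank_col)
  unbound_ranks <- lapply(scores[cols$unbound], rank_col)
  out <- scores
  out$rank_K1 <- bound_ranks[[1L]]
  out$rank_K2 <- bound_ranks[[2L]]
  out$rank_G1 <- unbound_ranks[[1L]]
  if (length(unbound_ranks) == 2L) out$rank_G2 <- unbound_ranks[[2L]]
  out$meanrank_K <- (out$rank_K1 + out$rank_K2) / 2
  out$meanrank_G <- if (length(unbound_ranks) == 2L) {
    (out$rank_G1 + out$rank_G2) / 2
  } else {
    out$rank_G1
  }
  out$rank_diff <- out$meanrank_K - out$meanrank_G
  attr(out, "score_cols") <- cols
  attr(out, "n_ranked") <- n
  out
}

#' Probit transform of ranks
#'
#' Maps ranks `r` in `1..N` to normal quantiles `qnorm(r / (N + 1))`. The
#' plotting position `r/(N+1)` is symmetric and keeps both extremes finite.
#' Applied to the ranks of an i.i.d. sample this yields an approximately
#' standard-normal column, the scale on which the reproducibility mixture
#' is fitted.
#'
#' @param ranks Numeric vector of (possibly tie-averaged) ranks in `[1, N]`.
#' @param n The number of ranked sites N.
#' @return Numeric vector of probit-transformed ranks.
#' @export
probit_rank <- function(ranks, n) {
  ok <- !is.na(ranks)
  if (any(ranks[ok] < 1 | ranks[ok] > n)) {
    stop("ranks must lie in [1, N]", call. = FALSE)
  }
  stats::qnorm(ranks / (n + 1))
}
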