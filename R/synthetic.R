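#' Configuration for the synthetic score generator
#'
#' Collects the parameters of the generative model the caller itself
#' assumes, so that simulated data constitute a fair test of the
#' implementation (parameter recovery, ranking order) rather than of the
#' model's biological adequacy. Defaults reflect the differential-binding
#' setting the method targets: 100,000 candidate motif sites of which 0.4%
#' are differentially bound (bound in the bound condition only), roughly
#' 10% bound at all, and replicate scores for bound sites drawn from a
#' correlated high-scoring cluster.
#'
#' @param n_sites Number of candidate sites (default 100,000; minimum 100).
#' @param prevalence_differential Fraction of sites bound in the bound
#'   condition and unbound in the other (default 0.004). Must not exceed
#'   `frac_bound_K`.
#' @param frac_bound_K Fraction of sites bound in the bound condition
#'   (default 0.10); the reproducible-cluster weight of the bound condition.
#' @param mu,sigma2,rho Bound-cluster parameters on the latent (probit-like)
#'   score scale: mean shift, marginal variance and replicate correlation
#'   (defaults 2, 1, 0.8). Unbound sites draw i.i.d. standard-normal scores.
#' @param shift_G Downward shift, on the latent scale, of the unbound-
#'   condition scores of differential sites (default `mu`: differential
#'   sites look like background in the unbound condition).
#' @param n_replicates_G Unbound-condition replicates, 1 or 2 (default 2).
#' @param count_base,count_slope,count_noise_sd Parameters of the noisy
#'   per-site read-count columns: counts are Poisson with rate
#'   `count_base * exp(count_slope * (latent mean + N(0, count_noise_sd)))`,
#'   a deliberately coarser readout than the scores (aggregate counts carry
#'   less information than footprint shape).
#' @param score_scale Scale on which raw scores are reported:
#'   `"log-normal"` (default) exponentiates the latent Gaussian, emulating
#'   the nonnegative, right-skewed, heteroscedastic distribution of real
#'   footprint scores; `"latent"` reports the Gaussian latent directly.
#'   The rank-based pipeline is invariant to this monotone choice; scale-
#'   sensitive baselines are not.
#' @param seed Integer seed; every draw is reproducible given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sites = 1e5, prevalence_differential = 0.004,
                       frac_bound_K = 0.10, mu = 2, sigma2 = 1, rho = 0.8,
                       shift_G = mu, n_replicates_G = 2L,
                       count_base = 20, count_slope = 0.5,
                       count_noise_sd = 1,
                       score_scale = c("log-normal", "latent"), seed = 1L) {
  score_scale <- match.arg(score_scale)
  if (n_sites < 100) stop("n_sites must be at least 100", call. = FALSE)
  if (prevalence_differential > frac_bound_K) {
    stop("prevalence_differential (", prevalence_differential, ") exceeds ",
      "frac_bound_K (", frac_bound_K, "): differential sites must be bound ",
      "in the bound condition",
      call. = FALSE
    )
  }
  stopifnot(
    prevalence_differential >= 0, frac_bound_K <= 1,
    sigma2 > 0, rho >= 0, rho < 1, n_replicates_G %in% c(1L, 2L)
  )
  structure(
    list(
      n_sites = as.integer(n_sites),
      prevalence_differential = prevalence_differential,
      frac_bound_K = frac_bound_K,
      mu = mu, sigma2 = sigma2, rho = rho, shift_G = shift_G,
      n_replicates_G = as.integer(n_replicates_G),
      count_base = count_base, count_slope = count_slope,
      count_noise_sd = count_noise_sd,
      score_scale = score_scale,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# correlated bivariate draw from the bound cluster
rbound_pair <- function(n, mu, sigma2, rho) {
  a <- stats::rnorm(n)
  b <- stats::rnorm(n)
  s <- sqrt(sigma2)
  cbind(
    mu + s * a,
    mu + s * (rho * a + sqrt(1 - rho^2) * b)
  )
}

#' Simulate replicate score tables with planted differential sites
#'
#' Draws a latent binding state per site — unbound, bound in both
#' conditions, or bound in the bound condition only (differential) — then
#' replicate scores: bound states draw correlated pairs from the
#' high-scoring cluster, unbound states i.i.d. standard normals, and
#' differential sites' unbound-condition scores are shifted down by
#' `shift_G` on the latent scale. Noisy read-count columns are added for
#' the count baseline. Every draw is recorded in the latent table.
#'
#' @param config A [sim_config()].
#' @return List with `scores` (a score table, see [new_score_table()], with
#'   extra columns `counts_K`, `counts_G`), `labels` (tibble `site_id`,
#'   `label`), `latent` (tibble of states and latent draws) and `config`.
#' @export
simulate_scores <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_sites
  withr::with_seed(config$seed, {
    state <- sample(
      c("unbound", "bound_both", "bound_K_only"),
      size = n, replace = TRUE,
      prob = c(
        1 - config$frac_bound_K,
        config$frac_bound_K - config$prevalence_differential,
        config$prevalence_differential
      )
    )
    bound_K <- state != "unbound"
    zK <- matrix(stats::rnorm(2 * n), ncol = 2)
    zK[bound_K, ] <- rbound_pair(sum(bound_K), config$mu, config$sigma2, config$rho)

    bound_G <- state == "bound_both"
    diff_G <- state == "bound_K_only"
    zG <- matrix(stats::rnorm(2 * n), ncol = 2)
    zG[bound_G, ] <- rbound_pair(sum(bound_G), config$mu, config$sigma2, config$rho)
    zG[diff_G, ] <- rbound_pair(sum(diff_G), config$mu, config$sigma2, config$rho) -
      config$shift_G

    latent_mean_K <- rowMeans(zK)
    latent_mean_G <- rowMeans(zG[, seq_len(config$n_replicates_G), drop = FALSE])
    counts_K <- stats::rpois(n, config$count_base *
      exp(config$count_slope *
        (latent_mean_K + stats::rnorm(n, 0, config$count_noise_sd))))
    counts_G <- stats::rpois(n, config$count_base *
      exp(config$count_slope *
        (latent_mean_G + stats::rnorm(n, 0, config$count_noise_sd))))

    on_scale <- if (config$score_scale == "log-normal") exp else identity
    tab <- tibble::tibble(
      chrom = "chr1",
      start = (seq_len(n) - 1L) * 1000L,
      end = (seq_len(n) - 1L) * 1000L + 20L,
      strand = "+",
      K_rep1 = on_scale(zK[, 1L]), K_rep2 = on_scale(zK[, 2L]),
      G_rep1 = on_scale(zG[, 1L]),
      counts_K = counts_K, counts_G = counts_G
    )
    unbound_cols <- "G_rep1"
    if (config$n_replicates_G == 2L) {
      tab$G_rep2 <- on_scale(zG[, 2L])
      unbound_cols <- c("G_rep1", "G_rep2")
    }
    scores <- new_score_table(tab,
      bound = c("K_rep1", "K_rep2"),
      unbound = unbound_cols
    )
    labels <- tibble::tibble(
      site_id = scores$site_id,
      label = ifelse(state == "bound_K_only", "differential", "non_differential")
    )
    latent <- tibble::tibble(
      site_id = scores$site_id,
      state = state,
      zK1 = zK[, 1L], zK2 = zK[, 2L],
      zG1 = zG[, 1L], zG2 = zG[, 2L]
    )
    list(scores = scores, labels = labels, latent = latent, config = config)
  })
}

#' Simulate upstream statistics tables for ground-truth construction
#'
#' Emulates the per-site outputs of the two upstream ChIP-seq tools the
#' ground-truth pipeline consumes: per-condition peak-caller significance
#' (`q1`, `q2` as `-log10 Q`), a count-test p-value (`p_edger`), the
#' caller's differential ordering (`gem_rank`), and event coordinates
#' jittered within a few bp of each motif site. Planted differential sites
#' receive small p-values (Beta-skewed) and strongly shifted bound-condition
#' significance, so they tend to pass the threshold filter; null sites draw
#' uniform p-values and background exponential significance, so they tend to
#' fail.
#'
#' @param config A [sim_config()]; draws use `config$seed + 1` so score and
#'   statistics tables are independently reproducible.
#' @param truth Labels tibble from [simulate_scores()] (`site_id`, `label`;
#'   coordinates are recovered from the `site_id` key).
#' @return Tibble with `site_id` (event key), `chrom`, `start`, `end`,
#'   `q1`, `q2`, `p_edger`, `gem_rank`, `in_edger_set`, `motif_site_id`,
#'   `label`.
#' @export
simulate_sitestats <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(truth)
  pos <- truth$label == "differential"
  coords <- parse_site_id(truth$site_id)
  withr::with_seed(config$seed + 1L, {
    p_edger <- ifelse(pos, stats::rbeta(n, 0.2, 30), stats::runif(n))
    q1 <- stats::rexp(n, rate = 2)
    q2 <- ifelse(pos, pmax(stats::rnorm(n, 6, 1), 0), stats::rexp(n, rate = 2))
    gem_score <- q2 - q1 + stats::rnorm(n, 0, 0.5)
    gem_rank <- rank(-gem_score, ties.method = "first")
    jitter <- sample(-10:10, n, replace = TRUE)
    tibble::tibble(
      site_id = sprintf("ev_%07d", seq_len(n)),
      chrom = coords$chrom,
      start = coords$start + jitter,
      end = coords$end + jitter,
      q1 = q1, q2 = q2, p_edger = p_edger,
      gem_rank = as.integer(gem_rank),
      in_edger_set = p_edger < 0.05,
      motif_site_id = truth$site_id,
      label = truth$label
    )
  })
}

parse_site_id <- function(site_id) {
  m <- regmatches(
    site_id,
    regexec("^(.+):([0-9]+)-([0-9]+):(.+)$", site_id)
  )
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) {
    stop("unparseable site_id: ", site_id[which(bad)[1L]], call. = FALSE)
  }
  tibble::tibble(
    chrom = vapply(m, `[[`, character(1), 2L),
    start = as.integer(vapply(m, `[[`, character(1), 3L)),
    end = as.integer(vapply(m, `[[`, character(1), 4L)),
    strand = vapply(m, `[[`, character(1), 5L)
  )
}
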