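# Shared fixture builders: everything is generated in code at test time.

# draw n pairs from the two-component reproducibility mixture
rmix_pairs <- function(n, pi1, mu, sigma2, rho, seed = 1) {
  withr::with_seed(seed, {
    lab <- stats::runif(n) < pi1
    a <- stats::rnorm(n)
    b <- stats::rnorm(n)
    s <- sqrt(sigma2)
    z1 <- ifelse(lab, mu + s * a, a)
    z2 <- ifelse(lab, mu + s * (rho * a + sqrt(1 - rho^2) * b), b)
    list(z1 = z1, z2 = z2, reproducible = lab)
  })
}

# draw n values from the three-component rank-difference mixture
rdiff_mix <- function(n, weights, delta, sigma0, sigma1, seed = 1) {
  withr::with_seed(seed, {
    comp <- sample(1:3, n, replace = TRUE, prob = weights)
    means <- c(0, delta, -delta)[comp]
    sds <- c(sigma0, sigma1, sigma1)[comp]
    stats::rnorm(n, means, sds)
  })
}

# minimal in-memory score table
tiny_score_table <- function(K1 = c(0.1, 3, 2), K2 = c(0.2, 2.5, 2.6),
                             G1 = c(0.1, 0.2, 2.2), G2 = c(0, 0.1, 2)) {
  n <- length(K1)
  new_score_table(data.frame(
    chrom = "chr1",
    start = (seq_len(n) - 1L) * 100L,
    end = (seq_len(n) - 1L) * 100L + 20L,
    K_rep1 = K1, K_rep2 = K2, G_rep1 = G1, G_rep2 = G2
  ))
}

# hand-built single-window rank-difference model
manual_diffmix <- function(pi_same, pi_lowerG, pi_higherG, delta,
                           sigma0, sigma1, center = 50) {
  structure(
    list(
      windows = tibble::tibble(
        window = 1L, center = center, lo = -Inf, hi = Inf,
        pi_same = pi_same, pi_lowerG = pi_lowerG, pi_higherG = pi_higherG,
        delta = delta, sigma0 = sigma0, sigma1 = sigma1,
        loglik = NA_real_, converged = TRUE, borrowed = FALSE
      ),
      control = list(), loglik = NULL, n = NA_integer_
    ),
    class = "deltabind_diffmix"
  )
}
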