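#' Fit the two-cluster reproducibility mixture
#'
#' Estimates the probability that a site produces a genuine, reproducible
#' signal in the bound condition from the agreement of its two replicate
#' ranks. On probit-transformed ranks `(z1, z2)` the model is a two-component
#' bivariate-normal mixture in the IDR (irreproducible discovery rate)
#' parameterization: an irreproducible cluster fixed at the standard
#' bivariate normal with correlation 0, and a reproducible cluster
#' `N((mu, mu), sigma2 * [[1, rho], [rho, 1]])` with weight `pi1` — genuine
#' sites score high and positively correlated across replicates, noise
#' scores low and uncorrelated.
#'
#' Fitting is by EM on the observed-data likelihood; the likelihood is
#' nondecreasing across iterations and the fit is flagged converged when
#' its relative change drops below `tol`.
#'
#' @param z1,z2 Probit-transformed replicate ranks (see [probit_rank()]),
#'   same length, at least 100 finite values.
#' @param init Named list of starting values; defaults
#'   `list(pi1 = 0.5, mu = 1, sigma2 = 1, rho = 0.5)`.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Relative log-likelihood change declaring convergence
#'   (default 1e-6).
#' @param min_n Minimum number of complete pairs to accept (default 100 —
#'   mixture fits on fewer sites are rarely stable; lower this only for
#'   deliberate toy analyses).
#' @return An object of class `deltabind_repro`: a list with elements
#'   `pi1`, `mu`, `sigma2`, `rho`, `loglik` (trace), `converged`,
#'   `n_iter`, `n`.
#' @seealso [posterior_repro()], [pA_from_mean_rank()],
#'   [fit_reproducibility()] for the one-call version operating on a rank
#'   table.
#' @export
fit_repro <- function(z1, z2,
                      init = list(pi1 = 0.5, mu = 1, sigma2 = 1, rho = 0.5),
                      max_iter = 500L, tol = 1e-6, min_n = 100L) {
  stopifnot(length(z1) == length(z2))
  keep <- is.finite(z1) & is.finite(z2)
  z1 <- z1[keep]
  z2 <- z2[keep]
  n <- length(z1)
  if (n < min_n) {
    stop("need at least ", min_n, " complete (z1, z2) pairs to fit the ",
      "reproducibility mixture; got ", n,
      call. = FALSE
    )
  }

  pi1 <- init$pi1
  mu <- init$mu
  sigma2 <- init$sigma2
  rho <- init$rho
  l0 <- dnorm2_log(z1, z2, 0, 1, 0) # fixed irreproducible component

  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    l1 <- dnorm2_log(z1, z2, mu, sigma2, rho)
    # E-step on the log scale for stability
    a <- log(pi1) + l1
    b <- log1p(-pi1) + l0
    m <- pmax(a, b)
    ll <- sum(m + log(exp(a - m) + exp(b - m)))
    loglik <- c(loglik, ll)
    g <- 1 / (1 + exp(b - a))

    # M-step; the weight is kept inside (0, 1) so a degenerate path
    # (all or no mass reproducible) cannot stall the remaining updates
    sg <- sum(g)
    pi1 <- min(max(sg / n, 1e-4), 1 - 1e-4)
    mu <- max(0, sum(g * (z1 + z2)) / (2 * sg))
    d1 <- z1 - mu
    d2 <- z2 - mu
    sigma2 <- max(1e-8, sum(g * (d1^2 + d2^2)) / (2 * sg))
    rho <- sum(g * d1 * d2) / (sigma2 * sg)
    rho <- min(max(rho, 0), 1 - 1e-6)

    if (it > 1L) {
      rel <- abs(ll - loglik[it - 1L]) / (abs(loglik[it - 1L]) + 1e-12)
      if (rel < tol) {
        converged <- TRUE
        break
      }
    }
  }

  if (pi1 <= 1e-4 || pi1 >= 1 - 1e-4) {
    warning("degenerate reproducibility fit (pi1 pinned at ",
      signif(pi1, 3), "); consider different starting values or more data",
      call. = FALSE
    )
  }
  structure(
    list(
      pi1 = pi1, mu = mu, sigma2 = sigma2, rho = rho,
      loglik = loglik, converged = converged,
      n_iter = length(loglik), n = n
    ),
    class = "deltabind_repro"
  )
}

#' Construct a reproducibility model from known parameters
#'
#' Mostly useful for scoring with externally chosen parameters and in
#' simulations; [fit_repro()] is the estimation route.
#'
#' @param pi1 Reproducible-cluster weight in `[0, 1]`.
#' @param mu Reproducible-cluster mean shift (probit units, both axes),
#'   `>= 0`.
#' @param sigma2 Reproducible-cluster marginal variance, `> 0`.
#' @param rho Reproducible-cluster replicate correlation in `[0, 1)`.
#' @return A `deltabind_repro` object.
#' @export
repro_model <- function(pi1, mu, sigma2, rho) {
  stopifnot(pi1 >= 0, pi1 <= 1, mu >= 0, sigma2 > 0, rho >= 0, rho < 1)
  structure(
    list(
      pi1 = pi1, mu = mu, sigma2 = sigma2, rho = rho,
      loglik = numeric(0), converged = NA, n_iter = 0L, n = NA_integer_
    ),
    class = "deltabind_repro"
  )
}

# log density of the bivariate normal with mean (m, m), marginal variance
# s2 and correlation r, evaluated at (z1, z2)
dnorm2_log <- function(z1, z2, m, s2, r) {
  d1 <- z1 - m
  d2 <- z2 - m
  q <- (d1^2 - 2 * r * d1 * d2 + d2^2) / (s2 * (1 - r^2))
  -log(2 * pi) - log(s2) - 0.5 * log1p(-r^2) - q / 2
}

#' Posterior probability of the reproducible cluster
#'
#' The Bayes posterior that a site belongs to the reproducible cluster given
#' its probit replicate ranks; this is the reproducibility score from which
#' the bound-condition binding probability curve is built.
#'
#' @param model A `deltabind_repro` object.
#' @param z1,z2 Probit replicate ranks.
#' @return Numeric vector of posteriors in `[0, 1]` (`NA` where either
#'   input is `NA`).
#' @export
posterior_repro <- function(model, z1, z2) {
  stopifnot(inherits(model, "deltabind_repro"))
  if (model$pi1 == 0) {
    return(ifelse(is.finite(z1) & is.finite(z2), 0, NA_real_))
  }
  if (model$pi1 == 1) {
    return(ifelse(is.finite(z1) & is.finite(z2), 1, NA_real_))
  }
  a <- log(model$pi1) + dnorm2_log(z1, z2, model$mu, model$sigma2, model$rho)
  b <- log1p(-model$pi1) + dnorm2_log(z1, z2, 0, 1, 0)
  1 / (1 + exp(b - a))
}

#' Calibrate binding probability against mean rank
#'
#' Turns per-site reproducibility posteriors into a monotone map from mean
#' bound-condition rank to binding probability P(A | R) by isotonic
#' regression (pool-adjacent-violators): deterministic, nondecreasing by
#' construction and free of a bin-width parameter. Sites sharing a mean rank
#' are pooled (weighted mean) before the fit. The fitted curve is evaluable
#' at any rank via linear interpolation between knots, constant beyond them.
#'
#' @param posteriors Reproducibility posteriors from [posterior_repro()].
#' @param mean_ranks Mean bound-condition ranks, aligned with `posteriors`.
#' @return An object of class `deltabind_pa_curve` with elements `x`
#'   (knot ranks) and `y` (fitted probabilities); use [predict()] or call
#'   [pa_eval()] to evaluate.
#' @export
pA_from_mean_rank <- function(posteriors, mean_ranks) {
  stopifnot(length(posteriors) == length(mean_ranks))
  keep <- is.finite(posteriors) & is.finite(mean_ranks)
  x <- mean_ranks[keep]
  p <- posteriors[keep]
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(x = x, p = p), .data$x),
    p = mean(.data$p), .groups = "drop"
  )
  fit <- stats::isoreg(agg$x, agg$p)
  y <- pmin(pmax(fit$yf, 0), 1)
  structure(list(x = agg$x[order(agg$x)], y = y), class = "deltabind_pa_curve")
}

#' Evaluate a binding-probability curve at given ranks
#'
#' @param curve A `deltabind_pa_curve` from [pA_from_mean_rank()].
#' @param ranks Ranks at which to evaluate.
#' @return Probabilities in `[0, 1]`.
#' @export
pa_eval <- function(curve, ranks) {
  stopifnot(inherits(curve, "deltabind_pa_curve"))
  if (length(curve$x) == 1L) {
    return(rep(curve$y, length(ranks)))
  }
  stats::approx(curve$x, curve$y, xout = ranks, rule = 2)$y
}

#' @export
predict.deltabind_pa_curve <- function(object, newdata, ...) {
  pa_eval(object, newdata)
}

#' Fit the full reproducibility stage on a rank table
#'
#' Convenience wrapper: probit-transforms the two bound-condition replicate
#' rank columns, fits the two-cluster mixture, computes per-site posteriors
#' and calibrates the P(A | mean rank) curve. Only the bound condition's
#' replicates enter this stage.
#'
#' @param rank_table A tibble from [to_ranks()].
#' @inheritParams fit_repro
#' @return A `deltabind_repro` object additionally carrying `posterior`
#'   (per-site, aligned with `rank_table`, `NA` for incomplete rows) and
#'   `pa_curve`.
#' @export
fit_reproducibility <- function(rank_table,
                                init = list(pi1 = 0.5, mu = 1, sigma2 = 1, rho = 0.5),
                                max_iter = 500L, tol = 1e-6) {
  n <- attr(rank_table, "n_ranked", exact = TRUE)
  if (is.null(n)) stop("rank_table must come from to_ranks()", call. = FALSE)
  z1 <- probit_rank(rank_table$rank_K1, n)
  z2 <- probit_rank(rank_table$rank_K2, n)
  model <- fit_repro(z1, z2, init = init, max_iter = max_iter, tol = tol)
  model$posterior <- posterior_repro(model, z1, z2)
  model$pa_curve <- pA_from_mean_rank(model$posterior, rank_table$meanrank_K)
  model$n_sites <- nrow(rank_table)
  model
}

#' @export
print.deltabind_repro <- function(x, ...) {
  cat("Reproducibility mixture (IDR-style two-cluster fit)\n")
  cat(sprintf(
    "  pi1 = %.4f  mu = %.3f  sigma2 = %.3f  rho = %.3f\n",
    x$pi1, x$mu, x$sigma2, x$rho
  ))
  if (x$n_iter > 0L) {
    cat(sprintf(
      "  %d EM iterations, %sconverged, log-likelihood %.2f, n = %d\n",
      x$n_iter, if (isTRUE(x$converged)) "" else "NOT ", utils::tail(x$loglik, 1), x$n
    ))
  }
  invisible(x)
}
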