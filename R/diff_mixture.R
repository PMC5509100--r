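#' Fit the windowed three-category mixture on rank differences
#'
#' Estimates P(B | A, R): the probability that a site, given it is bound in
#' the bound condition, is significantly more weakly bound in the unbound
#' condition. The statistic is the rank difference
#' `D = meanrank_K - meanrank_G`. Within sliding windows of bound-condition
#' mean rank, `D` is modeled as a three-component Gaussian mixture with
#' constrained means:
#'
#' * "same" — no significant rank difference, mean 0, spread `sigma0`;
#' * "lower in G" — mean `+delta` (the differential direction of interest);
#' * "higher in G" — mean `-delta` (fitted for symmetry, reported only).
#'
#' The shifted components share the spread `sigma1` and a common `delta > 0`.
#' Conditioning on the bound event is soft: each site enters the weighted EM
#' with its reproducibility posterior as case weight, so no arbitrary
#' bound/unbound cutoff is needed. Windowing lets the category weights and
#' shift vary with binding strength; spreads are floored at `sigma_min` and
#' the shift at `delta_min` (both 1 rank unit) to keep components
#' identifiable on degenerate inputs.
#'
#' @param rank_table A tibble from [to_ranks()].
#' @param repro Either a `deltabind_repro` object carrying a `posterior`
#'   element (from [fit_reproducibility()]) or a numeric vector of per-site
#'   reproducibility posteriors aligned with `rank_table`.
#' @param n_windows Number of overlapping windows over bound-condition mean
#'   rank (default 20; 1 fits a single global mixture).
#' @param window_frac Fraction of sites per window (default 0.1, i.e. N/10
#'   sites; consecutive windows overlap by roughly half).
#' @param min_weight Minimum effective (summed posterior) weight for a
#'   window to be fitted; lighter windows borrow the nearest fitted
#'   window's parameters with a warning (default 10).
#' @param init_weights Starting category weights (same, lowerG, higherG);
#'   default `c(0.8, 0.1, 0.1)`.
#' @param max_iter,tol EM control (defaults 500, 1e-6).
#' @param sigma_min,delta_min Floors, in rank units (defaults 1, 1).
#' @return Object of class `deltabind_diffmix`: list with `windows` (tibble
#'   of per-window parameters: `center`, `lo`, `hi`, `pi_same`, `pi_lowerG`,
#'   `pi_higherG`, `delta`, `sigma0`, `sigma1`, `loglik`, `converged`,
#'   `borrowed`) and the control settings.
#' @export
fit_diff_mixture <- function(rank_table, repro,
                             n_windows = 20L, window_frac = 0.10,
                             min_weight = 10,
                             init_weights = c(0.8, 0.1, 0.1),
                             max_iter = 500L, tol = 1e-6,
                             sigma_min = 1, delta_min = 1) {
  w_all <- if (inherits(repro, "deltabind_repro")) {
    if (is.null(repro$posterior)) {
      stop("repro model carries no posterior; use fit_reproducibility()",
        call. = FALSE
      )
    }
    repro$posterior
  } else {
    repro
  }
  stopifnot(length(w_all) == nrow(rank_table))
  ok <- is.finite(rank_table$rank_diff) & is.finite(rank_table$meanrank_K) &
    is.finite(w_all)
  d <- rank_table$rank_diff[ok]
  rk <- rank_table$meanrank_K[ok]
  w <- w_all[ok]
  n <- length(d)
  if (n < 10L) stop("too few complete sites to fit the mixture", call. = FALSE)

  ord <- order(rk)
  d <- d[ord]
  rk <- rk[ord]
  w <- w[ord]

  n_windows <- as.integer(n_windows)
  width <- max(10L, min(n, as.integer(ceiling(window_frac * n))))
  if (n_windows <= 1L || width >= n) {
    starts <- 1L
    ends <- n
    n_windows <- length(starts)
  } else {
    step <- (n - width) / (n_windows - 1L)
    starts <- pmin(as.integer(round((seq_len(n_windows) - 1L) * step)) + 1L, n - width + 1L)
    ends <- starts + width - 1L
  }

  # windows are fitted independently: a shared starting point would let a
  # low-signal window's local optimum leak into its neighbours
  fits <- vector("list", n_windows)
  for (k in seq_len(n_windows)) {
    idx <- starts[k]:ends[k]
    if (sum(w[idx]) >= min_weight) {
      fits[[k]] <- fit_diff_window(d[idx], w[idx],
        init_weights = init_weights, max_iter = max_iter, tol = tol,
        sigma_min = sigma_min, delta_min = delta_min
      )
    }
  }
  fitted_ks <- which(!vapply(fits, is.null, logical(1)))
  if (length(fitted_ks) == 0L) {
    stop("no window reached the minimum effective weight (", min_weight, ")",
      call. = FALSE
    )
  }
  borrowed <- setdiff(seq_len(n_windows), fitted_ks)
  if (length(borrowed) > 0L) {
    warning(length(borrowed), " window(s) below the minimum effective weight; ",
      "parameters borrowed from the nearest fitted window",
      call. = FALSE
    )
    for (k in borrowed) {
      fits[[k]] <- fits[[fitted_ks[which.min(abs(fitted_ks - k))]]]
    }
  }

  windows <- purrr::map2_dfr(fits, seq_len(n_windows), function(f, k) {
    tibble::tibble(
      window = k,
      center = mean(rk[starts[k]:ends[k]]),
      lo = rk[starts[k]], hi = rk[ends[k]],
      pi_same = f$pi[1L], pi_lowerG = f$pi[2L], pi_higherG = f$pi[3L],
      delta = f$delta, sigma0 = f$sigma0, sigma1 = f$sigma1,
      loglik = utils::tail(f$loglik, 1L), converged = f$converged,
      borrowed = k %in% borrowed
    )
  })

  structure(
    list(
      windows = windows,
      control = list(
        n_windows = n_windows, window_frac = window_frac,
        min_weight = min_weight, init_weights = init_weights,
        max_iter = max_iter, tol = tol,
        sigma_min = sigma_min, delta_min = delta_min
      ),
      loglik = lapply(fits, `[[`, "loglik"),
      n = n
    ),
    class = "deltabind_diffmix"
  )
}

# weighted EM for one window: 3 Gaussians on D with means (0, +delta, -delta),
# free sigma0, tied sigma1 for the shifted pair, case weights w
fit_diff_window <- function(d, w, init_weights, max_iter, tol,
                            sigma_min, delta_min) {
  pi_k <- init_weights / sum(init_weights)
  delta <- max(stats::sd(d), delta_min)
  if (!is.finite(delta)) delta <- delta_min
  sigma0 <- max(stats::sd(d), sigma_min)
  if (!is.finite(sigma0)) sigma0 <- sigma_min
  sigma1 <- sigma0
  sw <- sum(w)

  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    f0 <- stats::dnorm(d, 0, sigma0)
    fp <- stats::dnorm(d, delta, sigma1)
    fm <- stats::dnorm(d, -delta, sigma1)
    mix <- pi_k[1L] * f0 + pi_k[2L] * fp + pi_k[3L] * fm
    mix <- pmax(mix, 1e-300)
    ll <- sum(w * log(mix))
    loglik <- c(loglik, ll)

    g0 <- pi_k[1L] * f0 / mix
    gp <- pi_k[2L] * fp / mix
    gm <- pi_k[3L] * fm / mix

    pi_k <- c(sum(w * g0), sum(w * gp), sum(w * gm)) / sw
    s_pm <- sum(w * (gp + gm))
    if (s_pm > 1e-12) {
      delta <- max(sum(w * (gp - gm) * d) / s_pm, delta_min)
      sigma1 <- max(
        sqrt(sum(w * (gp * (d - delta)^2 + gm * (d + delta)^2)) / s_pm),
        sigma_min
      )
    }
    s_0 <- sum(w * g0)
    if (s_0 > 1e-12) {
      sigma0 <- max(sqrt(sum(w * g0 * d^2) / s_0), sigma_min)
    }

    if (it > 1L) {
      rel <- abs(ll - loglik[it - 1L]) / (abs(loglik[it - 1L]) + 1e-12)
      if (rel < tol) {
        converged <- TRUE
        break
      }
    }
  }
  list(
    pi = pi_k, delta = delta, sigma0 = sigma0, sigma1 = sigma1,
    loglik = loglik, converged = converged
  )
}

# per-window three-category posterior at rank differences d
window_posterior <- function(win, d) {
  f0 <- win$pi_same * stats::dnorm(d, 0, win$sigma0)
  fp <- win$pi_lowerG * stats::dnorm(d, win$delta, win$sigma1)
  fm <- win$pi_higherG * stats::dnorm(d, -win$delta, win$sigma1)
  tot <- pmax(f0 + fp + fm, 1e-300)
  cbind(same = f0 / tot, lowerG = fp / tot, higherG = fm / tot)
}

#' Per-site category posteriors under a fitted rank-difference mixture
#'
#' Evaluates, for every site, the posterior probability of the three rank-
#' difference categories using the window whose center brackets the site's
#' bound-condition mean rank; posteriors from the two bracketing windows are
#' blended linearly in mean rank, so the model varies smoothly over binding
#' strength. Sites beyond the outermost window centers use the nearest
#' window.
#'
#' @param model A `deltabind_diffmix` from [fit_diff_mixture()].
#' @param rank_table Tibble from [to_ranks()].
#' @return Tibble with columns `p_same`, `p_lowerG`, `p_higherG` (rows sum
#'   to 1; `NA` for incomplete sites), aligned with `rank_table`.
#' @export
posterior_categories <- function(model, rank_table) {
  stopifnot(inherits(model, "deltabind_diffmix"))
  d <- rank_table$rank_diff
  rk <- rank_table$meanrank_K
  ok <- is.finite(d) & is.finite(rk)
  win <- model$windows
  centers <- win$center

  out <- matrix(NA_real_, nrow = length(d), ncol = 3L)
  if (any(ok)) {
    dd <- d[ok]
    rr <- rk[ok]
    k_hi <- findInterval(rr, centers) + 1L
    k_lo <- k_hi - 1L
    k_lo <- pmin(pmax(k_lo, 1L), nrow(win))
    k_hi <- pmin(pmax(k_hi, 1L), nrow(win))
    frac <- ifelse(
      k_hi == k_lo, 0,
      (rr - centers[k_lo]) / (centers[k_hi] - centers[k_lo])
    )
    frac <- pmin(pmax(frac, 0), 1)
    post <- matrix(0, nrow = length(dd), ncol = 3L)
    for (k in sort(unique(c(k_lo, k_hi)))) {
      pk <- window_posterior(win[k, ], dd)
      sel_lo <- k_lo == k
      sel_hi <- k_hi == k
      post[sel_lo, ] <- post[sel_lo, ] + (1 - frac[sel_lo]) * pk[sel_lo, ]
      post[sel_hi, ] <- post[sel_hi, ] + frac[sel_hi] * pk[sel_hi, ]
    }
    out[ok, ] <- post
  }
  tibble::tibble(
    p_same = out[, 1L], p_lowerG = out[, 2L], p_higherG = out[, 3L]
  )
}

#' Posterior probability of condition-specific weakening
#'
#' Shortcut for the "lower in the unbound condition" column of
#' [posterior_categories()]: the per-site P(B | A, R) used by the caller.
#'
#' @inheritParams posterior_categories
#' @return Numeric vector in `[0, 1]`.
#' @export
posterior_B <- function(model, rank_table) {
  posterior_categories(model, rank_table)$p_lowerG
}

#' @export
print.deltabind_diffmix <- function(x, ...) {
  cat("Three-category rank-difference mixture\n")
  cat(sprintf(
    "  %d window(s) over bound-condition mean rank, %d sites\n",
    nrow(x$windows), x$n
  ))
  med <- dplyr::summarise(x$windows,
    pi_lowerG = stats::median(.data$pi_lowerG),
    delta = stats::median(.data$delta)
  )
  cat(sprintf(
    "  median across windows: pi_lowerG = %.3f, delta = %.1f rank units\n",
    med$pi_lowerG, med$delta
  ))
  invisible(x)
}
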