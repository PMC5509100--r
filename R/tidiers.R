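#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a reproducibility mixture fit
#'
#' @param x A `deltabind_repro` object.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`pi1`, `mu`, `sigma2`,
#'   `rho`) and its estimate.
#' @exportS3Method generics::tidy
tidy.deltabind_repro <- function(x, ...) {
  tibble::tibble(
    term = c("pi1", "mu", "sigma2", "rho"),
    estimate = c(x$pi1, x$mu, x$sigma2, x$rho)
  )
}

#' @rdname tidy.deltabind_repro
#' @return For `glance()`: a one-row tibble with `logLik`, `n_iter`,
#'   `converged`, `nobs`.
#' @exportS3Method generics::glance
glance.deltabind_repro <- function(x, ...) {
  tibble::tibble(
    logLik = if (length(x$loglik) > 0) utils::tail(x$loglik, 1) else NA_real_,
    n_iter = x$n_iter,
    converged = x$converged,
    nobs = x$n
  )
}

#' Tidy a rank-difference mixture fit
#'
#' @param x A `deltabind_diffmix` object.
#' @param ... Unused.
#' @return The per-window parameter tibble in long-friendly form (one row
#'   per window).
#' @exportS3Method generics::tidy
tidy.deltabind_diffmix <- function(x, ...) {
  x$windows
}

#' @rdname tidy.deltabind_diffmix
#' @return For `glance()`: one-row tibble with the number of windows,
#'   sites, and how many windows converged or were borrowed.
#' @exportS3Method generics::glance
glance.deltabind_diffmix <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x$windows),
    nobs = x$n,
    n_converged = sum(x$windows$converged),
    n_borrowed = sum(x$windows$borrowed)
  )
}

#' Export a fitted model to JSON
#'
#' Serializes a reproducibility or rank-difference mixture fit (parameters,
#' log-likelihood trace, and for the reproducibility model the calibration-
#' curve knots) for provenance alongside pipeline outputs.
#'
#' @param x A `deltabind_repro` or `deltabind_diffmix` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(x, path) {
  obj <- if (inherits(x, "deltabind_repro")) {
    list(
      type = "reproducibility",
      pi1 = x$pi1, mu = x$mu, sigma2 = x$sigma2, rho = x$rho,
      loglik_trace = x$loglik, converged = x$converged, n = x$n,
      pa_curve = if (!is.null(x$pa_curve)) {
        list(x = x$pa_curve$x, y = x$pa_curve$y)
      }
    )
  } else if (inherits(x, "deltabind_diffmix")) {
    list(
      type = "diff_mixture",
      windows = x$windows,
      control = x$control,
      n = x$n
    )
  } else {
    stop("unsupported model class: ", paste(class(x), collapse = "/"),
      call. = FALSE
    )
  }
  jsonlite::write_json(obj, path,
    auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(path)
}
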