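#' Tidy a single-trait GREML fit
#'
#' @param x A [reml_single()] fit.
#' @param ... Unused.
#' @return A tibble with one row per estimated component (`sigma2_a`,
#'   `sigma2_e`) and fixed effect.
#' @method tidy greml_fit
#' @export
tidy.greml_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = c("sigma2_a", "sigma2_e"),
                   type = "variance_component",
                   estimate = c(x$sigma2_a, x$sigma2_e)),
    tibble::tibble(term = names(x$beta), type = "fixed_effect",
                   estimate = unname(x$beta)))
}

#' @rdname tidy.greml_fit
#' @method glance greml_fit
#' @export
glance.greml_fit <- function(x, ...) {
  tibble::tibble(sigma2_a = x$sigma2_a, sigma2_e = x$sigma2_e,
                 h2 = x$sigma2_a / (x$sigma2_a + x$sigma2_e),
                 logLik = x$loglik, converged = x$converged,
                 iterations = x$iterations,
                 nobs = length(x$reference_ids))
}

#' Tidy a bivariate genetic-correlation fit
#'
#' @param x A [reml_genetic_correlation()] fit.
#' @param ... Unused.
#' @return A tibble with the estimated correlation and free components.
#' @method tidy greml_rg_fit
#' @export
tidy.greml_rg_fit <- function(x, ...) {
  tibble::tibble(term = c("r_G", "sigma2_a", "sigma2_e"),
                 type = c("correlation", "variance_component",
                          "variance_component"),
                 estimate = c(x$r_G, x$sigma2_a, x$sigma2_e),
                 fixed = FALSE) |>
    dplyr::bind_rows(tibble::tibble(
      term = c("sigma2_a_fixed", "sigma2_e_fixed"),
      type = "variance_component",
      estimate = c(x$fixed_components$sigma2_a,
                   x$fixed_components$sigma2_e),
      fixed = TRUE))
}

#' @rdname tidy.greml_rg_fit
#' @method glance greml_rg_fit
#' @export
glance.greml_rg_fit <- function(x, ...) {
  tibble::tibble(r_G = x$r_G, logLik = x$loglik, converged = x$converged,
                 boundary = x$boundary, iterations = x$iterations)
}

#' Tidy an accuracy report
#'
#' @param x An [run_scenario()] accuracy report.
#' @param ... Unused.
#' @return The per-method summary tibble of [summarize_replicates()].
#' @method tidy accuracy_report
#' @export
tidy.accuracy_report <- function(x, ...) summarize_replicates(x)
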