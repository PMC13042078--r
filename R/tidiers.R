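#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an admixture-model fit
#'
#' @param x a `qpadm_fit`.
#' @param ... unused.
#' @return tibble with one row per source: `source`, `weight`, `se`,
#'   `z`.
#' @method tidy qpadm_fit
#' @export
tidy.qpadm_fit <- function(x, ...) {
  dplyr::mutate(x$weights, z = .data$weight / .data$se)
}

#' @rdname tidy.qpadm_fit
#' @method glance qpadm_fit
#' @export
glance.qpadm_fit <- function(x, ...) {
  tibble::tibble(target = x$target, n_sources = length(x$sources),
                 chi2 = x$chi2, df = x$df, p = x$p,
                 feasible = x$feasible,
                 n_snps = x$n_snps, n_blocks = x$n_blocks)
}

#' Tidy an admixture-date fit
#'
#' @param x a `date_fit`.
#' @param ... unused.
#' @return one-row tibble of the fitted parameters.
#' @method tidy date_fit
#' @export
tidy.date_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "t", "c"),
                 estimate = c(x$A, x$t, x$c),
                 se = c(NA_real_, x$se, NA_real_))
}

#' @rdname tidy.date_fit
#' @method glance date_fit
#' @export
glance.date_fit <- function(x, ...) {
  tibble::tibble(t_generations = x$t, se = x$se, z = x$z,
                 years = x$years, years_se = x$years_se,
                 generation_time = x$generation_time,
                 signal = x$signal, converged = x$converged)
}

#' Tidy an effective-size fit
#'
#' @param x an `ne_fit`.
#' @param ... unused.
#' @return the likelihood grid as a tibble (`two_ne`, `loglik`).
#' @method tidy ne_fit
#' @export
tidy.ne_fit <- function(x, ...) x$grid

#' @rdname tidy.ne_fit
#' @method glance ne_fit
#' @export
glance.ne_fit <- function(x, ...) {
  tibble::tibble(ne = x$ne, ne_lo = x$ci_ne[1], ne_hi = x$ci_ne[2],
                 two_ne = x$two_ne, open_upper = x$open_upper,
                 n_ind = x$n_ind)
}
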