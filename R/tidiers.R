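#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Gaussian histogram fit
#'
#' @param x A `mixture_fit` from [fit_mixture_and_compare()].
#' @param ... Unused.
#' @return Tibble with one row per component: `component`, `amplitude`,
#'   `mean`, `sd`.
#' @exportS3Method generics::tidy
tidy.mixture_fit <- function(x, ...) x$parameters

#' @rdname tidy.mixture_fit
#' @return `glance()`: one-row tibble with `k`, `ss`, `n_bins`,
#'   `n_params`, `aicc`.
#' @exportS3Method generics::glance
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(k = x$k, ss = x$ss, n_bins = x$n_bins,
                 n_params = x$n_params, aicc = x$aicc)
}

#' Tidy a one- vs two-Gaussian model comparison
#'
#' @param x A `mixture_comparison` from [fit_mixture_and_compare()].
#' @param ... Unused.
#' @return `tidy()`: per-component parameters of both fits with a `model`
#'   column; `glance()`: the one-row comparison (`F`, `df_num`, `df_den`,
#'   `p_F`, `delta_aicc`, `akaike_weight_2`).
#' @exportS3Method generics::tidy
tidy.mixture_comparison <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$fit1$parameters, model = "one-Gaussian"),
    dplyr::mutate(x$fit2$parameters, model = "two-Gaussian")
  )
}

#' @rdname tidy.mixture_comparison
#' @exportS3Method generics::glance
glance.mixture_comparison <- function(x, ...) x$comparison

#' Tidy a GC3 heterogeneity analysis
#'
#' @param x A `gc_heterogeneity` from [heterogeneity_analysis()].
#' @param ... Unused.
#' @return `tidy()`: the per-class descriptive statistics; `glance()`: a
#'   one-row tibble with `n`, the class-comparison p-value, and the
#'   mixture comparison's `p_F` and `akaike_weight_2` (when computed).
#' @exportS3Method generics::tidy
tidy.gc_heterogeneity <- function(x, ...) x$class_stats

#' @rdname tidy.gc_heterogeneity
#' @exportS3Method generics::glance
glance.gc_heterogeneity <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    u_test_p = if (is.null(x$u_test)) NA_real_ else x$u_test$p_two_sided,
    mixture_p_F = if (is.null(x$mixture)) NA_real_ else x$mixture$comparison$p_F,
    akaike_weight_2 = if (is.null(x$mixture)) NA_real_
                      else x$mixture$comparison$akaike_weight_2
  )
}
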