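#' Broom-style tidiers for ssbkin fit objects
#'
#' `tidy()` returns one row per parameter with estimates and standard
#' errors; `glance()` returns a one-row model summary.
#'
#' @param x A fitted object (`hill_fit`, `two_site_fit`,
#'   `bimolecular_fit`, `gaussian_fit`).
#' @param ... Unused.
#' @return A tibble.
#' @name ssbkin-tidiers
NULL

#' @rdname ssbkin-tidiers
#' @export
tidy.hill_fit <- function(x, ...) x$params

#' @rdname ssbkin-tidiers
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(rss = x$rss, weighted_rss = x$weighted_rss,
         n = nrow(x$data),
         kd_nM = x$params$estimate[x$params$term == "kd"],
         hill_n = x$params$estimate[x$params$term == "n"])
}

#' @rdname ssbkin-tidiers
#' @export
tidy.two_site_fit <- function(x, ...) x$params

#' @rdname ssbkin-tidiers
#' @export
glance.two_site_fit <- function(x, ...) {
  tibble(rss = x$rss, weighted_rss = x$weighted_rss, n = nrow(x$data),
         k1_nM = x$params$estimate[x$params$term == "k1"],
         k2_nM = x$params$estimate[x$params$term == "k2"],
         cooperative = x$cooperative)
}

#' @rdname ssbkin-tidiers
#' @export
tidy.bimolecular_fit <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$slope, x$intercept),
         std_error = c(x$slope_se, x$intercept_se))
}

#' @rdname ssbkin-tidiers
#' @export
glance.bimolecular_fit <- function(x, ...) {
  tibble(slope = x$slope, slope_se = x$slope_se,
         intercept = x$intercept, intercept_se = x$intercept_se,
         r_squared = x$r_squared, n = x$n)
}

#' @rdname ssbkin-tidiers
#' @export
tidy.gaussian_fit <- function(x, ...) {
  x$components |>
    mutate(component = dplyr::row_number(), .before = 1)
}

#' @rdname ssbkin-tidiers
#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble(k = nrow(x$components), rss = x$rss)
}
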