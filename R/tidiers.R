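#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a persistent-random-walk fit
#'
#' @param x A [fit_prw()] result.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.prw_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mu_um2_per_min", "P_min"),
    estimate = c(x$mu_um2_per_min, x$P_min),
    std.error = c(x$stderr_mu, x$stderr_P)
  )
}

#' @rdname tidy.prw_fit
#' @return `glance()`: one-row tibble with fit-level summaries.
#' @export
glance.prw_fit <- function(x, ...) {
  tibble::tibble(
    rss = x$rss, n_lags = x$n_lags, n_d = x$n_d,
    converged = x$converged, identifiable_P = x$identifiable_P
  )
}

#' Tidy a Watson's U2 test result
#'
#' @param x A [watson_u2()] result.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `p.value`, `n1`, `n2`,
#'   `n_permutations`.
#' @export
tidy.watson_u2 <- function(x, ...) {
  tibble::tibble(
    statistic = x$u2, p.value = x$p_value,
    n1 = x$n1, n2 = x$n2, n_permutations = x$n_permutations
  )
}

#' Tidy a group comparison
#'
#' @param x A [compare_groups()] result.
#' @param ... Unused.
#' @return `tidy()`: the pairwise-test tibble. `glance()`: one-row tibble
#'   with the omnibus ANOVA p-value.
#' @export
tidy.group_comparison <- function(x, ...) {
  x$pairwise
}

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    metric = x$metric, anova_p = x$anova_p,
    n_groups = length(x$groups), alpha = x$alpha, welch = x$welch
  )
}

#' Tidy a fidelity result
#'
#' @param x A [fidelity_score()] result.
#' @param ... Unused.
#' @return One-row tibble with the three score components.
#' @export
tidy.fidelity_result <- function(x, ...) {
  tibble::tibble(
    spatial_overlap_pct = x$spatial_overlap_pct,
    intensity_corr = x$intensity_corr,
    fidelity_pct = x$fidelity_pct
  )
}

#' Tidy an angular distribution into a bin table
#'
#' @param x An [angular_distribution()].
#' @param ... Unused.
#' @return Tibble with `bin_start_deg`, `bin_end_deg`, `bin_mid_deg`,
#'   `density`.
#' @export
tidy.angular_distribution <- function(x, ...) {
  e <- x$bin_edges_deg
  tibble::tibble(
    bin_start_deg = e[-length(e)],
    bin_end_deg = e[-1],
    bin_mid_deg = (e[-1] + e[-length(e)]) / 2,
    density = x$density
  )
}
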