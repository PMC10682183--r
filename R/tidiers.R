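## broom-style access to simulation objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation into its per-cell census
#'
#' @param x a `prion_sim`.
#' @param ... unused.
#' @return the census tibble (see [colony_census()]).
#' @export
tidy.prion_sim <- function(x, ...) x$census

#' One-row summary of a simulation
#'
#' @param x a `prion_sim`.
#' @param ... unused.
#' @return a one-row tibble: cell counts, generation depth, total amyloid
#'   particle number and the fraction of prion-positive cells under the
#'   configured classifier.
#' @export
glance.prion_sim <- function(x, ...) {
  cen <- x$census
  tibble::tibble(
    clock_min = x$colony$clock,
    n_cells = nrow(cen),
    n_total_ever = length(x$colony$idx),
    max_generation = max(cen$generation),
    total_N_A1 = sum(cen$N_A1),
    total_N_A2 = sum(cen$N_A2),
    fraction_prion_positive = mean(classify_prion(cen, x$config$colour))
  )
}
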