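## R surface of the chemical layer.  The derivative and fine-loop code lives
## in src/kinetics.cpp; these wrappers validate inputs and present tidy
## output.  Times at this layer are in seconds, concentrations in molar.

chem_state <- function(C_M = 0, C_A1 = 0, C_MA1 = 0, C_A2 = 0, C_MA2 = 0) {
  c(C_M = C_M, C_A1 = C_A1, C_MA1 = C_MA1, C_A2 = C_A2, C_MA2 = C_MA2)
}

check_state <- function(state) {
  state <- state[CHEM_SPECIES]
  if (anyNA(state)) stop("state must contain ", paste(CHEM_SPECIES, collapse = ", "))
  if (any(state < 0)) stop("concentrations must be >= 0")
  state
}

#' Amino-acid resource pool
#'
#' The available amino-acid concentration shrinks with total amyloid load:
#' `C_AA = C_AA_basal * (1 - psi * S / (Omega + S))` with
#' `S = C_MA1 + C_MA2`.  With `psi < 1` the pool stays strictly positive;
#' the saturating form makes amyloid production self-limiting.
#'
#' @param C_MA1,C_MA2 fibril and clump mass concentrations (M).
#' @param params a [kinetic_params()].
#' @return amino-acid concentration (M); vectorised.
#' @export
amino_acid_pool <- function(C_MA1, C_MA2, params) {
  if (any(C_MA1 < 0) || any(C_MA2 < 0)) stop("inputs must be >= 0")
  S <- C_MA1 + C_MA2
  params$C_AA_basal * (1 - params$psi * S / (params$Omega + S))
}

#' Chemical rate vector
#'
#' Time derivatives of the five tracked concentrations under the
#' configured mechanism.  `derivs_standard()` and `derivs_munching()`
#' force the respective mechanism.  Average fibril sizes
#' `<i_A1> = C_MA1/C_A1` and `<i_A2> = C_MA2/C_A2` are taken as zero when
#' the number concentration is below a positivity floor (1e-30 M).  In
#' the munching model the nucleus (dimer) concentration is estimated from
#' an exponential length distribution, `C_2 = C_A1 (1 - exp(-k))` with
#' `k = 1 / (<i_A1> - 2)`, and equals `C_A1` when `<i_A1> <= 2`.
#'
#' @param state named numeric vector with entries `C_M`, `C_A1`, `C_MA1`,
#'   `C_A2`, `C_MA2` (M).
#' @param params a [kinetic_params()].
#' @return named numeric vector of time derivatives (M/s).
#' @export
amyloid_rates <- function(state, params) {
  state <- check_state(state)
  out <- chem_rates_cpp(state, unclass(params))
  names(out) <- CHEM_SPECIES
  out
}

#' @rdname amyloid_rates
#' @export
derivs_standard <- function(state, params) {
  params$mechanism <- "standard_breakage"
  amyloid_rates(state, params)
}

#' @rdname amyloid_rates
#' @export
derivs_munching <- function(state, params) {
  params$mechanism <- "munching"
  amyloid_rates(state, params)
}

#' Fixed-volume chemical integration
#'
#' Advances a cell's chemistry over `duration` seconds with `n_steps`
#' modified-midpoint steps (two derivative evaluations per step, fixed
#' step size).  Slightly negative excursions are clamped to zero.
#'
#' @param state named chemical state (M).
#' @param params a [kinetic_params()].
#' @param duration integration time (s, > 0).
#' @param n_steps number of fixed steps.
#' @return the final state, a named numeric vector.
#' @export
integrate_fixed_volume <- function(state, params, duration, n_steps) {
  state <- check_state(state)
  if (duration <= 0) stop("duration must be > 0")
  res <- chem_integrate_cpp(state, unclass(params), duration / n_steps,
                            as.integer(n_steps), 1, 1, 0L)
  stats::setNames(res$state, CHEM_SPECIES)
}

#' Single step with changing volume
#'
#' Applies the difference form of the changing-volume transform over one
#' step `dt`: concentrations are first rescaled by `V1/V2` (which exactly
#' conserves amounts `C * V`), then advanced by one reaction step at the
#' new concentration scale.
#'
#' @param state named chemical state (M).
#' @param V1,V2 volumes (micrometres^3, > 0) at the start and end of the
#'   step.
#' @param dt step length (s).
#' @param params a [kinetic_params()].
#' @return the final state, a named numeric vector.
#' @export
volume_step <- function(state, V1, V2, dt, params) {
  state <- check_state(state)
  if (V1 <= 0 || V2 <= 0) stop("volumes must be > 0")
  res <- chem_integrate_cpp(state, unclass(params), dt, 1L, V1, V2, 0L)
  stats::setNames(res$state, CHEM_SPECIES)
}

#' Mother/bud partition source terms
#'
#' First-order exchange of each species class between the mother (alpha)
#' and the open bud (beta).  The mother-side source carries the volume
#' factor `V_beta / V_alpha`, which makes the total amount
#' `C_alpha V_alpha + C_beta V_beta` exactly conserved by the exchange:
#' `alpha: (V_beta/V_alpha) (-k_ab C_alpha + k_ba C_beta)`,
#' `beta: -k_ba C_beta + k_ab C_alpha`.  Outside the division phase the
#' flux is zero.
#'
#' @param C_alpha,C_beta named chemical states (M) of mother and bud.
#' @param params a [partition_params()].
#' @param V_alpha,V_beta compartment volumes (micrometres^3, > 0).
#' @param dividing logical; fluxes are zero when `FALSE`.
#' @return list with named numeric vectors `alpha` and `beta` (M/s).
#' @export
partition_fluxes <- function(C_alpha, C_beta, params, V_alpha, V_beta,
                             dividing = TRUE) {
  C_alpha <- check_state(C_alpha); C_beta <- check_state(C_beta)
  if (V_alpha <= 0 || V_beta <= 0) stop("volumes must be > 0")
  zero <- stats::setNames(numeric(5), CHEM_SPECIES)
  if (!dividing) return(list(alpha = zero, beta = zero))
  kab <- params$k_ab[SPECIES_CLASS]
  kba <- params$k_ba[SPECIES_CLASS]
  fa <- (V_beta / V_alpha) * (-kab * C_alpha + kba * C_beta)
  fb <- -kba * C_beta + kab * C_alpha
  list(alpha = stats::setNames(as.numeric(fa), CHEM_SPECIES),
       beta = stats::setNames(as.numeric(fb), CHEM_SPECIES))
}

#' Single-cell "beaker mode" time series
#'
#' Integrates a scenario's kinetics in one cell of fixed volume and
#' returns the concentration time series, including derived average sizes
#' and the instantaneous amino-acid pool.  Reproduces the
#' fixed-geometry kinetic regimes of the `fig4*` presets.
#'
#' @param config a [scenario_config()] (or preset name).
#' @param duration run length in minutes; defaults to the scenario
#'   horizon.
#' @param n_record number of sample points in the returned series.
#' @return a tibble with columns `time_min`, the five concentrations,
#'   `i_A1_mean`, `i_A2_mean` and `C_AA`.
#' @examples
#' ts <- beaker_run(make_scenario("fig4A"), duration = 100)
#' @export
beaker_run <- function(config, duration = NULL, n_record = 200) {
  if (is.character(config)) config <- make_scenario(config)
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(duration)) duration <- config$scheduler$horizon
  sch <- config$scheduler
  dt_fine <- sch$dt_coarse * 60 / sch$n_steps
  n <- max(1L, as.integer(ceiling(duration * 60 / dt_fine)))
  res <- chem_integrate_cpp(check_state(config$init_chem),
                            unclass(config$kinetics),
                            dt_fine, n, 1, 1, as.integer(n_record))
  s <- res$samples
  colnames(s) <- c("t_s", CHEM_SPECIES, "volume")
  out <- tibble::as_tibble(s[, c("t_s", CHEM_SPECIES), drop = FALSE])
  out$time_min <- out$t_s / 60
  out$t_s <- NULL
  out$i_A1_mean <- ifelse(out$C_A1 > 1e-30, out$C_MA1 / out$C_A1, 0)
  out$i_A2_mean <- ifelse(out$C_A2 > 1e-30, out$C_MA2 / out$C_A2, 0)
  out$C_AA <- amino_acid_pool(out$C_MA1, out$C_MA2, config$kinetics)
  dplyr::relocate(out, "time_min")
}

## absolute particle numbers from concentration (M) and volume (um^3)
particle_number <- function(conc, volume_um3) {
  conc * volume_um3 * UM3_TO_L * N_AVOGADRO
}
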