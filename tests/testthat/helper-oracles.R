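# Independent reference implementations used as oracles.  These are written
# directly from the model's printed rate equations in plain R and never call
# the package's C++ kernel.

# time derivatives, standard breakage/clumping mechanism
ref_rates_standard <- function(y, p) {
  S <- y["C_MA1"] + y["C_MA2"]
  caa <- p$C_AA_basal * (1 - p$psi * S / (p$Omega + S))
  i1 <- if (y["C_A1"] > 1e-30) y["C_MA1"] / y["C_A1"] else 0
  i2 <- if (y["C_A2"] > 1e-30) y["C_MA2"] / y["C_A2"] else 0
  cm <- y["C_M"]; ca1 <- y["C_A1"]; ca2 <- y["C_A2"]
  c(C_M = unname(p$f_M * caa - p$b_M * cm - 2 * p$f_N * cm^2 +
                   2 * p$b_G * ca1 - p$f_G * ca1 * cm - 2 * p$f_G * ca2 * cm),
    C_A1 = unname(p$f_N * cm^2 + p$b_G * (y["C_MA1"] - 3 * ca1) -
                    2 * p$f_A1 * ca1^2 - 2 * p$f_A2 * ca1^2 + 2 * p$b_A2 * ca2),
    C_MA1 = unname(2 * p$f_N * cm^2 + p$f_G * ca1 * cm - 2 * p$b_G * ca1 -
                     2 * p$f_A2 * ca1^2 * i1 + p$b_A2 * ca2 * i2),
    C_A2 = unname(p$f_A2 * ca1^2 - p$b_A2 * ca2),
    C_MA2 = unname(2 * p$f_G * ca2 * cm + 2 * p$f_A2 * ca1^2 * i1 -
                     p$b_A2 * ca2 * i2))
}

# time derivatives, position-dependent breakage ("munching"), single filaments
ref_rates_munching <- function(y, p) {
  S <- y["C_MA1"] + y["C_MA2"]
  caa <- p$C_AA_basal * (1 - p$psi * S / (p$Omega + S))
  cm <- y["C_M"]; ca1 <- y["C_A1"]
  c2 <- 0
  if (ca1 > 1e-30) {
    i1 <- y["C_MA1"] / ca1
    c2 <- if (i1 <= 2 + 1e-9) ca1 else ca1 * (1 - exp(-1 / (i1 - 2)))
  }
  c(C_M = unname(p$f_M * caa - p$b_M * cm - 2 * p$f_N * cm^2 +
                   2 * p$b_G * ca1 - p$f_G * ca1 * cm),
    C_A1 = unname(p$f_N * cm^2 + c2 * (p$b_A1 - p$b_G) + p$b_A1 * y["C_MA1"] -
                    3 * p$b_A1 * ca1 - p$f_A1 * ca1^2),
    C_MA1 = unname(2 * p$f_N * cm^2 - 2 * p$b_G * ca1 + p$f_G * ca1 * cm),
    C_A2 = 0, C_MA2 = 0)
}

ref_rates <- function(y, p) {
  if (p$mechanism == "munching") ref_rates_munching(y, p) else ref_rates_standard(y, p)
}

# explicit-Euler reference integrator (fixed volume)
ref_euler <- function(y, p, duration, n) {
  dt <- duration / n
  for (i in seq_len(n)) {
    y <- y + dt * ref_rates(y, p)
    y[y < 0] <- 0
  }
  y
}

# direct Monte-Carlo oracle for the two-state life-cycle branching process:
# one founder mother; per coarse interval each mother buds (conditional
# hazard with delay) producing a daughter active from the next interval,
# each daughter matures into a mother.  Returns the final population size.
ref_branching <- function(n_intervals, dt, tau_M, delta_M, tau_D, delta_D) {
  haz <- function(age0, tau, delta) {
    eff <- max(0, (age0 + dt) - max(delta, age0))
    1 - exp(-log(2) * eff / tau)
  }
  stage <- "M"; age <- 0
  for (k in seq_len(n_intervals)) {
    new_stage <- character(0)
    for (i in seq_along(stage)) {
      if (stage[i] == "M") {
        if (runif(1) < haz(age[i], tau_M, delta_M)) {
          age[i] <- 0
          new_stage <- c(new_stage, "D")
        } else age[i] <- age[i] + dt
      } else {
        if (runif(1) < haz(age[i], tau_D, delta_D)) {
          stage[i] <- "M"; age[i] <- 0
        } else age[i] <- age[i] + dt
      }
    }
    stage <- c(stage, new_stage)
    age <- c(age, rep(0, length(new_stage)))
  }
  length(stage)
}

# small growth-only configuration for colony-level tests
growth_only_config <- function(horizon = 200, epsilon = 0, seed = 1,
                               n_steps = 1) {
  scenario_config(
    growth = growth_params(tau_DtoM = 20, delta_DtoM = 0,
                           tau_MtoD = 20, delta_MtoD = 50, epsilon = epsilon),
    kinetics = kinetic_params(f_M = 0, b_M = 0, f_N = 0, b_N = 0, f_G = 0,
                              b_G = 0, f_A1 = 0, b_A1 = 0, f_A2 = 0, b_A2 = 0),
    scheduler = scheduler_params(horizon = horizon, n_steps = n_steps,
                                 seed = seed))
}

# seeded-amyloid configuration with protein turnover off (conservation runs)
conserved_amyloid_config <- function(horizon = 700, seed = 1, n_steps = 1200) {
  scenario_config(
    growth = growth_params(tau_DtoM = 20, delta_DtoM = 0,
                           tau_MtoD = 20, delta_MtoD = 50, epsilon = 1e5),
    kinetics = kinetic_params(f_M = 0, b_M = 0, f_N = 0, b_N = 0.005,
                              b_G = 0.005, f_G = 5e5, b_A1 = 0.005,
                              f_A1 = 0, f_A2 = 0, b_A2 = 0),
    init_chem = c(C_M = 1e-7, C_A1 = 1e-7, C_MA1 = 5e-7),
    scheduler = scheduler_params(horizon = horizon, n_steps = n_steps,
                                 seed = seed))
}

# total protein amount (mol x 1e-15, arbitrary consistent unit) per colony
colony_protein_amount <- function(sim) {
  cen <- colony_census(sim, alive_only = TRUE)
  col <- sim$colony
  vol <- col$volume[match(cen$index, col$idx)]
  sum((cen$C_M + cen$C_MA1 + cen$C_MA2) * vol)
}
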