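test_that("amino-acid pool shrinks with amyloid load", {
  p <- kinetic_params(C_AA_basal = 2e-7, psi = 0.95, Omega = 1e-7)
  expect_equal(amino_acid_pool(0, 0, p), 2e-7)
  # S = Omega at psi = 0.95 halves the suppressible fraction
  expect_equal(amino_acid_pool(5e-8, 5e-8, p), 0.525 * 2e-7)
  # saturating limit 1 - psi
  expect_equal(amino_acid_pool(1, 1, p), 0.05 * 2e-7, tolerance = 1e-6)
  expect_gt(amino_acid_pool(1e3, 1e3, p), 0)
  expect_error(amino_acid_pool(-1e-9, 0, p), ">= 0")
})

test_that("rate vectors match an independent R transcription of the model", {
  set.seed(5)
  for (mech in c("standard_breakage", "munching")) {
    p <- kinetic_params(mechanism = mech, f_M = 0.01, b_M = 0.02,
                        f_N = 1e-3, b_N = 5e-3, f_G = 5e5, b_G = 4e-3,
                        f_A1 = 2e5, b_A1 = 6e-3, f_A2 = 1e5, b_A2 = 2e-3)
    for (r in 1:50) {
      y <- c(C_M = runif(1, 0, 2e-7), C_A1 = runif(1, 0, 1e-7),
             C_MA1 = 0, C_A2 = runif(1, 0, 1e-8), C_MA2 = 0)
      y["C_MA1"] <- y["C_A1"] * runif(1, 2, 30)
      y["C_MA2"] <- y["C_A2"] * runif(1, 4, 60)
      expect_equal(amyloid_rates(y, p), ref_rates(y, p), tolerance = 1e-12)
    }
  }
  expect_error(amyloid_rates(c(C_M = -1, C_A1 = 0, C_MA1 = 0, C_A2 = 0,
                               C_MA2 = 0), kinetic_params()), ">= 0")
})

test_that("feed-only system produces monomer at f_M * C_AA", {
  p <- kinetic_params(f_M = 0.01, b_M = 0, f_N = 0, b_N = 0, f_G = 0,
                      b_G = 0, f_A1 = 0, b_A1 = 0, f_A2 = 0, b_A2 = 0)
  r <- amyloid_rates(c(C_M = 0, C_A1 = 0, C_MA1 = 0, C_A2 = 0, C_MA2 = 0), p)
  expect_equal(unname(r["C_M"]), 0.01 * p$C_AA_basal)
  expect_equal(unname(r[-1]), rep(0, 4))
})

test_that("monomer-only system reaches the analytic steady state", {
  p <- kinetic_params(f_M = 0.01, b_M = 0.01, f_N = 0, b_N = 0, f_G = 0,
                      b_G = 0, f_A1 = 0, b_A1 = 0, f_A2 = 0, b_A2 = 0)
  target <- p$f_M * p$C_AA_basal / p$b_M
  y0 <- c(C_M = 0, C_A1 = 0, C_MA1 = 0, C_A2 = 0, C_MA2 = 0)
  yT <- integrate_fixed_volume(y0, p, duration = 10 / p$b_M, n_steps = 1000)
  expect_lt(abs(yT["C_M"] - target) / target, 1e-3)
})

test_that("closed-cell protein mass balance holds along all three kinetic presets", {
  for (nm in c("fig4A", "fig4B", "fig4C")) {
    cfg <- make_scenario(nm)
    p <- cfg$kinetics
    y <- cfg$init_chem
    dt <- 1
    for (step in 1:5000) {
      r <- amyloid_rates(y, p)
      resid <- sum(r[c("C_M", "C_MA1", "C_MA2")]) -
        (p$f_M * amino_acid_pool(y["C_MA1"], y["C_MA2"], p) - p$b_M * y["C_M"])
      if (abs(resid) >= 1e-12) {
        expect_lt(abs(resid), 1e-12, label = paste(nm, "step", step))
        break
      }
      y <- pmax(y + dt * r, 0)
    }
    expect_lt(abs(resid), 1e-12)
  }
})

test_that("munching reduces to standard breakage for single filaments with b_A1 = b_G", {
  set.seed(6)
  p <- kinetic_params(f_M = 0.01, b_M = 0.01, f_N = 1e-3, b_N = 4e-3,
                      f_G = 5e5, b_G = 4e-3, f_A1 = 0, b_A1 = 4e-3,
                      f_A2 = 0, b_A2 = 0)
  for (r in 1:100) {
    y <- c(C_M = runif(1, 0, 2e-7), C_A1 = runif(1, 1e-12, 1e-7),
           C_MA1 = 0, C_A2 = 0, C_MA2 = 0)
    y["C_MA1"] <- y["C_A1"] * runif(1, 2.5, 50)
    a <- derivs_standard(y, p)
    b <- derivs_munching(y, p)
    expect_equal(b[c("C_M", "C_A1", "C_MA1")], a[c("C_M", "C_A1", "C_MA1")],
                 tolerance = 1e-14)
  }
})

test_that("munching nucleus estimate follows the exponential length distribution", {
  # k = 1/(<i>-2); closed-form C_2 = C_A1 (1 - e^-k) equals the truncated
  # geometric sum C_A1 e^{-2k} / sum_{j=2}^z e^{-kj} for large z
  iA1 <- 3
  k <- 1 / (iA1 - 2)
  expect_equal(k, 1)
  z <- 4000
  num <- exp(-2 * k)
  den <- sum(exp(-k * (2:z)))
  ca1 <- 3e-8
  expect_equal(ca1 * num / den, ca1 * (1 - exp(-k)), tolerance = 1e-10)
  # the derivative uses exactly that estimate: isolate the C_2 (b_A1 - b_G) term
  p0 <- kinetic_params(mechanism = "munching", f_M = 0, b_M = 0, f_N = 0,
                       b_N = 0, f_G = 0, b_G = 0, f_A1 = 0, b_A1 = 0,
                       f_A2 = 0, b_A2 = 0)
  p1 <- p0; p1$b_A1 <- 0.005
  y <- c(C_M = 0, C_A1 = ca1, C_MA1 = iA1 * ca1, C_A2 = 0, C_MA2 = 0)
  d <- amyloid_rates(y, p1) - amyloid_rates(y, p0)
  c2 <- ca1 * (1 - exp(-k))
  expect_equal(unname(d["C_A1"]),
               0.005 * (c2 + y[["C_MA1"]] - 3 * ca1), tolerance = 1e-12)
  # no fibrils: every fibril term vanishes
  y0 <- c(C_M = 1e-7, C_A1 = 0, C_MA1 = 0, C_A2 = 0, C_MA2 = 0)
  expect_equal(unname(amyloid_rates(y0, p1)["C_A1"]), 0)
  # mean size at the dimer floor: all fibrils count as nuclei
  yd <- c(C_M = 0, C_A1 = ca1, C_MA1 = 2 * ca1, C_A2 = 0, C_MA2 = 0)
  dd <- amyloid_rates(yd, p1) - amyloid_rates(yd, p0)
  expect_equal(unname(dd["C_A1"]), 0.005 * (ca1 + 2 * ca1 - 3 * ca1),
               tolerance = 1e-12)
})

test_that("fixed-step integrator is inert at zero rates and errors on bad input", {
  p0 <- kinetic_params(f_M = 0, b_M = 0, f_N = 0, b_N = 0, f_G = 0, b_G = 0,
                       f_A1 = 0, b_A1 = 0, f_A2 = 0, b_A2 = 0)
  y <- c(C_M = 1e-7, C_A1 = 2e-9, C_MA1 = 1e-8, C_A2 = 0, C_MA2 = 0)
  expect_equal(integrate_fixed_volume(y, p0, 1000, 100), y)
  expect_error(integrate_fixed_volume(y, p0, -5, 10), "duration")
})

test_that("modified midpoint self-converges at order two or better", {
  cfg <- make_scenario("fig4A")
  y0 <- cfg$init_chem
  duration <- 100
  sol <- function(n) integrate_fixed_volume(y0, cfg$kinetics, duration, n)
  y1 <- sol(100); y2 <- sol(200); y4 <- sol(400)
  e12 <- sqrt(sum((y1 - y2)^2))
  e24 <- sqrt(sum((y2 - y4)^2))
  order <- log2(e12 / e24)
  expect_gte(order, 1.9)
})

test_that("integrator tracks a much finer explicit-Euler oracle", {
  for (nm in c("fig4A", "fig4B", "fig4C")) {
    cfg <- make_scenario(nm)
    y0 <- cfg$init_chem
    ymm <- integrate_fixed_volume(y0, cfg$kinetics, duration = 5,
                                  n_steps = 1000)
    yeu <- ref_euler(y0, cfg$kinetics, duration = 5, n = 100000)
    expect_lt(max(abs(ymm - yeu) / pmax(abs(yeu), 1e-12)), 1e-6,
              label = nm)
  }
})

test_that("Oosawa regime: irreversible nucleated growth never loses fibrils", {
  p <- kinetic_params(f_M = 0.01, b_M = 0.01, f_N = 1e-3, b_N = 0, f_G = 5e5,
                      b_G = 0, f_A1 = 0, b_A1 = 0, f_A2 = 0, b_A2 = 0)
  cfg <- scenario_config(kinetics = p, init_chem = c(C_M = 1e-7))
  ts <- beaker_run(cfg, duration = 300, n_record = 300)
  expect_true(all(diff(ts$C_A1) > -1e-22))
  expect_true(all(ts$C_A1 >= 0))
})

test_that("clumping converts single fibrils into pairs without losing mass", {
  p <- kinetic_params(f_M = 0, b_M = 0, f_N = 0, b_N = 0, f_G = 0, b_G = 0,
                      f_A1 = 0, b_A1 = 0, f_A2 = 1e5, b_A2 = 0)
  y0 <- c(C_M = 0, C_A1 = 1e-7, C_MA1 = 5e-7, C_A2 = 0, C_MA2 = 0)
  cfg <- scenario_config(kinetics = p, init_chem = y0)
  ts <- beaker_run(cfg, duration = 300, n_record = 50)
  expect_true(all(diff(ts$C_A1) <= 1e-22))       # singles are consumed
  expect_gt(dplyr::last(ts$C_A2), 0)             # clumps appear
  # two singles make one clump: C_A1 + 2 C_A2 is conserved
  expect_equal(ts$C_A1 + 2 * ts$C_A2, rep(1e-7, nrow(ts)), tolerance = 1e-9)
  # total polymerised mass is conserved
  expect_equal(ts$C_MA1 + ts$C_MA2, rep(5e-7, nrow(ts)), tolerance = 1e-9)
})

test_that("all kinetic presets run to their horizon without NaN or negatives", {
  for (nm in c("fig4A", "fig4B", "fig4C")) {
    ts <- beaker_run(make_scenario(nm), n_record = 100)
    expect_false(any(is.na(as.matrix(ts))), label = nm)
    expect_true(all(ts[c("C_M", "C_A1", "C_MA1", "C_A2", "C_MA2")] >= 0),
                label = nm)
    # average single-fibril size stays at or above the dimer nucleus
    expect_true(all(ts$i_A1_mean[ts$C_A1 > 1e-30] >= 2 - 1e-9), label = nm)
  }
})

test_that("standard-breakage kinetics show growth then plateau with depressed monomer", {
  ts <- beaker_run(make_scenario("fig4A"), n_record = 200)
  n <- nrow(ts)
  # C_MA1 rises from zero then flattens
  expect_gt(ts$C_MA1[n], ts$C_MA1[2])
  late <- abs(ts$C_MA1[n] - ts$C_MA1[n - 10]) / ts$C_MA1[n]
  expect_lt(late, 0.01)
  # free monomer ends below the aggregation-free steady state
  p <- make_scenario("fig4A")$kinetics
  expect_lt(ts$C_M[n], p$f_M * p$C_AA_basal / p$b_M)
})

test_that("volume change conserves amounts when chemistry is off", {
  p0 <- kinetic_params(f_M = 0, b_M = 0, f_N = 0, b_N = 0, f_G = 0, b_G = 0,
                       f_A1 = 0, b_A1 = 0, f_A2 = 0, b_A2 = 0)
  y <- c(C_M = 1e-7, C_A1 = 1e-9, C_MA1 = 5e-9, C_A2 = 1e-10, C_MA2 = 1e-9)
  # single step, volume doubling: concentrations halve exactly
  y2 <- volume_step(y, V1 = 10, V2 = 20, dt = 1, params = p0)
  expect_equal(y2, y / 2)
  # equal volumes: pure reaction step (identity at zero rates)
  expect_equal(volume_step(y, 10, 10, 1, p0), y)
  expect_error(volume_step(y, 0, 10, 1, p0), "> 0")
  # linear growth daughter -> mother volume over 20 min at 1 s steps
  Vd <- 4 / 3 * pi * 1.25^3; Vm <- 31.25
  res <- prioncolony:::chem_integrate_cpp(y, unclass(p0), 1, 1200, Vd, Vm, 0L)
  expect_equal(unname(res$state) * Vm, unname(y) * Vd, tolerance = 1e-6)
})
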