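test_that("temporal test follows the survival rule", {
  set.seed(1)
  # before the delay the survival term is >= 1: always failure
  expect_false(any(temporal_test(rep(25, 1000), tau = 10, delta = 50)))
  # at t - delta = tau the per-call success probability is exp(-ln 2) = 0.5
  n <- 1e5
  hits <- sum(temporal_test(rep(30, n), tau = 10, delta = 20))
  se <- sqrt(0.25 * n)
  expect_lt(abs(hits - 0.5 * n), 3 * se)
  # tau -> 0+ with t > delta: success with probability 1
  expect_true(all(temporal_test(rep(30, 1000), tau = 1e-12, delta = 20)))
  expect_error(temporal_test(10, tau = 0, delta = 0), "tau")
})

test_that("per-interval hazard is constant once the delay has passed", {
  # hazard for a window fully above delta is 1 - exp(-ln2 dt / tau)
  expect_equal(interval_hazard(100, 20, tau = 20, delta = 0),
               1 - exp(-log(2)))
  expect_equal(interval_hazard(0, 20, tau = 20, delta = 0),
               interval_hazard(200, 20, tau = 20, delta = 0))
  # window entirely below the delay: zero hazard
  expect_equal(interval_hazard(0, 20, tau = 20, delta = 50), 0)
  # partial overlap uses only the time above the delay
  expect_equal(interval_hazard(40, 20, tau = 20, delta = 50),
               1 - exp(-log(2) * 10 / 20))
})

test_that("first-success interval counts are geometric (chi-squared)", {
  set.seed(42)
  p <- interval_hazard(0, 20, tau = 20, delta = 0)  # 0.5
  expect_equal(p, 0.5)
  n_rep <- 1e4
  first <- replicate(n_rep, {
    k <- 1
    age <- 0
    # per-interval testing with accumulated (never reset) stage age
    while (runif(1) >= interval_hazard(age, 20, tau = 20, delta = 0)) {
      k <- k + 1
      age <- age + 20
    }
    k
  })
  kmax <- 8
  obs <- tabulate(pmin(first, kmax), nbins = kmax)
  probs <- c(dgeom(0:(kmax - 2), p), 1 - pgeom(kmax - 2, p))
  chi <- suppressWarnings(chisq.test(obs, p = probs))
  expect_gt(chi$p.value, 0.001)
})

test_that("candidate bud sites enumerate the six plane-adjacent segments", {
  sites <- candidate_bud_sites(0, 0, 1, 0)
  expect_equal(nrow(sites), 6)
  expected <- rbind(c(-1, 0), c(2, 0), c(0, 1), c(1, 1), c(0, -1), c(1, -1))
  expect_setequal(paste(sites[, 1], sites[, 2]),
                  paste(expected[, 1], expected[, 2]))
  # brute-force oracle: all segments 4-adjacent to the footprint
  foot <- rbind(c(0, 0), c(1, 0))
  adj <- unique(do.call(rbind, lapply(seq_len(nrow(foot)), function(r) {
    rbind(foot[r, ] + c(1, 0), foot[r, ] - c(1, 0),
          foot[r, ] + c(0, 1), foot[r, ] - c(0, 1))
  })))
  adj <- adj[!(paste(adj[, 1], adj[, 2]) %in% paste(foot[, 1], foot[, 2])), ]
  expect_setequal(paste(sites[, 1], sites[, 2]), paste(adj[, 1], adj[, 2]))
  # a vertical domino has six sites too
  v <- candidate_bud_sites(3, 7, 3, 8)
  expect_equal(nrow(v), 6)
  expect_equal(nrow(unique(v)), 6)
})

test_that("candidate expansion sites are the four axis neighbours", {
  sites <- candidate_expansion_sites(0, 0)
  expect_equal(nrow(sites), 4)
  expect_setequal(paste(sites[, 1], sites[, 2]),
                  c("1 0", "-1 0", "0 1", "0 -1"))
})

test_that("obstruction counts walk to the first empty segment or wall", {
  cfg <- growth_only_config()
  cfg$growth$plate_half <- 3
  col <- prioncolony:::new_colony(cfg)   # founder occupies (0,0), (1,0)
  # empty site with empty surroundings
  expect_equal(unname(obstruction_counts(col, c(0, 2), c(0, 1))), c(0, 0))
  # site on the founder: 2-segment chain then empty along +x; wall met at -x
  # after walking the chain and the empty segments beyond
  expect_equal(unname(obstruction_counts(col, c(0, 0), c(1, 0))), c(2, 1))
  # ignore the founder: both walks hit the immovable cell
  expect_equal(unname(obstruction_counts(col, c(0, 0), c(1, 0), ignore = 1)),
               c(Inf, Inf))
  # fully walled direction: fill the row from the founder to the +x boundary
  for (x in 2:3) prioncolony:::occ_set(col, x, 0L, 1L)
  cnt <- obstruction_counts(col, c(1, 0), c(1, 0))
  expect_equal(unname(cnt[1]), Inf)  # no empty segment before the wall
})

test_that("confluence energy and acceptance law", {
  expect_equal(delta_E_star(1e5, 1.25e-6, 0, 0), 0)
  expect_equal(delta_E_star(1e5, 1.25e-6, 4, 7), 1.0)
  expect_equal(delta_E_star(1e5, 1.25e-6, 7, 4, rule = "max"), 2 * 1e5 * 1.25e-6 * 7)
  expect_equal(delta_E_star(1e12, 1.25e-6, 1, Inf), 2.5e6)
  set.seed(7)
  expect_true(all(confluence_test(rep(0, 1000))))
  expect_false(any(confluence_test(rep(Inf, 1000))))
  n <- 1e5
  acc <- sum(confluence_test(rep(1, n)))
  p <- exp(-1)
  expect_lt(abs(acc - p * n), 3 * sqrt(p * (1 - p) * n))
})

test_that("tau inheritance has the right moments and a positive floor", {
  set.seed(11)
  expect_equal(inherit_tau(20, A_av = 0, sigma_A = 0), 20)
  draws <- replicate(1e5, inherit_tau(20, A_av = 0.1, sigma_A = 0.05))
  se <- 0.05 * 20 / sqrt(1e5)
  expect_lt(abs(mean(draws) - 22), 3 * se)
  # deep negative region clamps at the floor
  lo <- replicate(200, inherit_tau(20, A_av = -5, sigma_A = 1e-6))
  expect_true(all(lo >= 20 * 1e-3))
})

test_that("variability evolves as a random walk with |1 + b| sigma update", {
  set.seed(13)
  v <- evolve_variability(0.3, 0.05, sigma_B = 0)
  expect_equal(v$A_av, 0.3)
  expect_equal(v$sigma_A, 0.05)
  # ensemble variance of A_av after G generations is (G-1) sigma_B^2
  G <- 10; sB <- 0.01; n <- 1e4
  finals <- replicate(n, {
    a <- 0; s <- 0.01
    for (g in 2:G) {
      vv <- evolve_variability(a, s, sB)
      a <- vv$A_av; s <- vv$sigma_A
    }
    a
  })
  expect_lt(abs(var(finals) - (G - 1) * sB^2) / ((G - 1) * sB^2), 0.05)
  # sigma_A never goes negative even for draws below -1
  set.seed(14)
  sig <- replicate(500, evolve_variability(0, 0.05, sigma_B = 2)$sigma_A)
  expect_true(all(sig >= 0))
})

test_that("death limits remove cells from plate and census", {
  expect_false(apply_death(100, 1e6, growth_params()))  # unbounded defaults
  lim <- growth_params(max_replicative_age = 3)
  expect_false(apply_death(2, 100, lim))
  expect_true(apply_death(3, 100, lim))   # dies at its 4th attempt epoch
  cfg <- growth_only_config(horizon = 400, seed = 21)
  cfg$growth$max_chronological_age <- 100
  sim <- run_simulation(cfg)
  cen <- colony_census(sim)
  expect_true(all(cen$real_age <= 100 + cfg$scheduler$dt_coarse))
  expect_gt(sum(!sim$colony$alive), 0)
  full <- colony_census(sim, alive_only = FALSE)
  expect_gt(nrow(full), nrow(cen))
  # dead cells hold no segments
  seg <- occupied_segments(sim)
  dead <- full$index[!full$index %in% cen$index]
  expect_false(any(seg$cell %in% dead))
})

test_that("occupancy stays consistent through many displacement events", {
  sim <- run_simulation(growth_only_config(horizon = 700, epsilon = 1e5,
                                           seed = 31))
  expect_true(prioncolony:::audit_occupancy(sim$colony))
  cen <- colony_census(sim)
  expect_gt(nrow(cen), 50)
  # every living mother owns exactly two adjacent segments, daughters one
  col <- sim$colony
  for (i in prioncolony:::living(col)) {
    seg <- prioncolony:::cell_segments(col, i)
    if (col$stage[i] == "M") {
      expect_equal(nrow(seg), 2)
      expect_equal(sum(abs(seg[1, ] - seg[2, ])), 1)
    } else {
      expect_equal(nrow(seg), 1)
    }
  }
})

test_that("population growth matches the branching-process oracle", {
  n_col <- 120
  sims <- numeric(n_col)
  for (r in seq_len(n_col)) {
    sim <- run_simulation(growth_only_config(horizon = 160, epsilon = 0,
                                             seed = 1000 + r))
    sims[r] <- nrow(colony_census(sim))
  }
  set.seed(99)
  orc <- replicate(2000, ref_branching(8, 20, tau_M = 20, delta_M = 50,
                                       tau_D = 20, delta_D = 0))
  se <- sqrt(var(sims) / n_col + var(orc) / length(orc))
  expect_lt(abs(mean(sims) - mean(orc)), 3 * se)
})

test_that("non-confluent growth at least matches confluent growth", {
  for (s in c(3, 17)) {
    nc <- run_simulation(growth_only_config(horizon = 500, epsilon = 1e5,
                                            seed = s))
    cf <- run_simulation(growth_only_config(horizon = 500, epsilon = 1e12,
                                            seed = s))
    expect_gte(nrow(colony_census(nc)), nrow(colony_census(cf)))
  }
})

test_that("identical configuration and seed reproduce byte-identical output", {
  cfg <- growth_only_config(horizon = 300, epsilon = 1e5, seed = 8,
                            n_steps = 1200)
  cfg$kinetics <- kinetic_params()   # full default chemistry
  cfg$init_chem["C_M"] <- 1e-7
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_census(run_simulation(cfg), f1)
  write_census(run_simulation(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed gives a different colony
  cfg2 <- cfg; cfg2$scheduler$seed <- 9L
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_census(run_simulation(cfg2), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})
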