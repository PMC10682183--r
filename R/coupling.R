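## The multiscale scheduler.  One coarse interval dt' advances the particle
## model once and every cell's chemistry n_steps times on the fine clock;
## mother/bud pairs exchange material by partition while the septum is open,
## and cells in a growth phase are diluted along a linear volume trajectory.

series_cols <- function() c("time", "cell", "x", "y", "stage", "volume", CHEM_SPECIES)

record_series <- function(col, time, i, samples = NULL) {
  stage_code <- match(col$stage[i], c("D", "M"))
  if (is.null(samples)) {
    row <- c(time, col$idx[i], col$x[i], col$y[i], stage_code,
             col$volume[i], col$chem[i, ])
    col$series[[length(col$series) + 1L]] <- matrix(row, nrow = 1)
  } else {
    ## samples: t_offset, 5 species, volume; t_offset in seconds from t0
    m <- cbind(time - col$config$scheduler$dt_coarse + samples[, 1] / 60,
               col$idx[i], col$x[i], col$y[i], stage_code,
               samples[, 7], samples[, 2:6, drop = FALSE])
    col$series[[length(col$series) + 1L]] <- m
  }
  invisible(col)
}

#' Advance a colony by one coarse interval
#'
#' One pass of the multiscale control loop: (i) every eligible stationary
#' cell runs its stochastic transition attempt (temporal test, then
#' candidate sites tried without replacement against the confluence
#' test); (ii) every living cell's chemistry advances `n_steps` fine
#' steps, with mother/bud pairs exchanging material by partition and
#' growing cells diluted along their linear volume trajectory; (iii) at
#' the end of the interval the septum closes, buds become independent
#' daughters and maturing daughters become mothers; (iv) the clock
#' advances by `dt_coarse`.
#'
#' @param col a `prion_colony`.
#' @return the colony, invisibly (modified in place).
#' @export
step_colony <- function(col) {
  cfg <- col$config
  dt <- cfg$scheduler$dt_coarse
  dt_fine <- dt * 60 / cfg$scheduler$n_steps
  n_fine <- cfg$scheduler$n_steps
  t1 <- col$clock + dt
  Vd <- daughter_volume(cfg$growth)
  Vm <- mother_volume(cfg$growth)

  ## (0) ages advance; deaths applied at the epoch start
  pre_existing <- which(col$alive & col$substate != "nascent")
  col$stage_age[pre_existing] <- col$stage_age[pre_existing] + dt
  for (i in pre_existing) {
    if (apply_death(col$repl_age[i], col$clock - col$birth_time[i],
                    cfg$growth)) {
      kill_cell(col, i, t1 - dt)
    }
  }

  ## (i) transition attempts for stationary cells (snapshot: cells born this
  ## interval are not tested until the next one)
  eligible <- which(col$alive & col$substate == "stationary")
  for (i in eligible) attempt_transition(col, i, dt)

  ## (ii) chemistry on the fine clock
  kin <- unclass(cfg$kinetics)
  linked <- vapply(col$links, function(l) c(l$mother, l$bud), integer(2))
  linked <- if (length(linked)) as.integer(linked) else integer(0)
  for (i in which(col$alive)) {
    if (i %in% linked) next                 # handled pairwise below
    if (col$substate[i] == "enlarging") {
      res <- chem_integrate_cpp(col$chem[i, ], kin, dt_fine, n_fine,
                                Vd, Vm, 10L)
      col$chem[i, ] <- res$state
      col$volume[i] <- Vm
      record_series(col, t1, i, res$samples)
    } else {
      res <- chem_integrate_cpp(col$chem[i, ], kin, dt_fine, n_fine,
                                col$volume[i], col$volume[i], 0L)
      col$chem[i, ] <- res$state
      record_series(col, t1, i)
    }
  }
  for (l in col$links) {
    res <- chem_integrate_pair_cpp(col$chem[l$mother, ], col$chem[l$bud, ],
                                   kin, cfg$partition$k_ab, cfg$partition$k_ba,
                                   dt_fine, n_fine, col$volume[l$mother],
                                   0.05 * Vd, Vd,
                                   beta_fM_off = TRUE, n_record = 10L)
    col$chem[l$mother, ] <- res$state_alpha
    col$chem[l$bud, ] <- res$state_beta
    col$volume[l$bud] <- Vd
    record_series(col, t1, l$mother, res$samples_alpha)
    record_series(col, t1, l$bud, res$samples_beta)
  }

  ## (iii) septum closure and maturation completion
  for (l in col$links) {
    i <- l$mother; j <- l$bud
    col$substate[i] <- "stationary"
    col$repl_age[i] <- col$repl_age[i] + 1L
    col$stage_age[i] <- 0
    col$substate[j] <- "stationary"
    col$stage_age[j] <- 0
    col$septum_time[j] <- t1
  }
  col$links <- list()
  for (i in which(col$alive & col$substate == "enlarging")) {
    col$stage[i] <- "M"
    col$substate[i] <- "stationary"
    col$stage_age[i] <- 0
    col$mature_time[i] <- t1
  }

  ## (iv) advance the coarse clock
  col$clock <- t1
  invisible(col)
}

kill_cell <- function(col, i, time) {
  seg <- cell_segments(col, i)
  for (r in seq_len(nrow(seg))) occ_free(col, seg[r, "x"], seg[r, "y"])
  col$alive[i] <- FALSE
  col$death_time[i] <- time
  log_event(col, time, col$idx[i], "death")
  invisible(col)
}

#' Run a full multiscale simulation
#'
#' Seeds the RNG from the scheduler block, grows a colony from a single
#' founder to the configured horizon and returns an immutable result
#' object bundling the final census, the event log, the per-cell chemical
#' time series and the configuration.  Identical configurations (including
#' seed) reproduce identical results.
#'
#' @param config a [scenario_config()] or preset name (see
#'   [make_scenario()]).
#' @param seed optional RNG seed overriding the scheduler block.
#' @return an object of class `prion_sim` with elements `census`
#'   (tibble, see [colony_census()]), `events`, `series`, `config` and
#'   the final `colony`.
#' @examples
#' \donttest{
#' sim <- run_simulation(make_scenario("fig7_nonconfluent"), seed = 1)
#' sim
#' }
#' @export
run_simulation <- function(config, seed = NULL) {
  if (is.character(config)) config <- make_scenario(config)
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) config$scheduler$seed <- as.integer(seed)
  set.seed(config$scheduler$seed)
  col <- new_colony(config)
  n_steps <- floor(config$scheduler$horizon / config$scheduler$dt_coarse + 1e-9)
  record_series(col, 0, 1L)
  for (s in seq_len(n_steps)) step_colony(col)
  audit_occupancy(col)
  structure(list(census = colony_census(col),
                 events = events_table(col),
                 series = series_table(col),
                 config = config,
                 colony = col),
            class = "prion_sim")
}

#' @export
print.prion_sim <- function(x, ...) {
  cat("<prion_sim>", if (!is.null(x$config$preset)) x$config$preset,
      "- clock", x$colony$clock, "min;",
      sum(x$colony$alive), "living cells,",
      max(x$census$generation), "generations\n")
  invisible(x)
}

events_table <- function(col) {
  if (!length(col$events)) {
    return(tibble::tibble(time = numeric(), cell = integer(),
                          kind = character(), site_x = integer(),
                          site_y = integer(), delta_E = numeric(),
                          sites_tried = integer()))
  }
  dplyr::bind_rows(lapply(col$events, tibble::as_tibble))
}

series_table <- function(col) {
  m <- do.call(rbind, col$series)
  colnames(m) <- series_cols()
  out <- tibble::as_tibble(m)
  out$cell <- as.integer(out$cell)
  out$stage <- c("D", "M")[out$stage]
  out$i_A1_mean <- ifelse(out$C_A1 > 1e-30, out$C_MA1 / out$C_A1, 0)
  out$N_A1 <- particle_number(out$C_A1, out$volume)
  out$N_A2 <- particle_number(out$C_A2, out$volume)
  dplyr::arrange(out, .data$cell, .data$time)
}

#' Colony census
#'
#' One row per cell (living cells by default) with the full per-cell
#' information set: identity, position, stage, ages, lineage, heritable
#' variability parameters, chemical state with derived particle numbers
#' and mean fibril sizes, and the colour-assay RGB channels.
#'
#' @param x a `prion_sim` or `prion_colony`.
#' @param alive_only drop dead cells (default `TRUE`).
#' @return a tibble.
#' @export
colony_census <- function(x, alive_only = TRUE) {
  col <- as_colony(x)
  keep <- if (alive_only) which(col$alive) else seq_along(col$idx)
  chem <- col$chem[keep, , drop = FALSE]
  vol <- col$volume[keep]
  rgb <- colour_of(chem[, "C_M"], col$config$colour)
  tibble::tibble(
    index = col$idx[keep],
    x = col$x[keep], y = col$y[keep], z = 0,
    stage = col$stage[keep],
    replicative_age = col$repl_age[keep],
    real_age = col$clock - col$birth_time[keep],
    stage_age = col$stage_age[keep],
    generation = col$generation[keep],
    lineage = vapply(col$lineage[keep], paste, "", collapse = "/"),
    A_av = col$A_av[keep],
    sigma_A = col$sigma_A[keep],
    C_M = chem[, "C_M"],
    C_A1 = chem[, "C_A1"],
    C_MA1 = chem[, "C_MA1"],
    N_A1 = particle_number(chem[, "C_A1"], vol),
    i_A1_mean = ifelse(chem[, "C_A1"] > 1e-30, chem[, "C_MA1"] / chem[, "C_A1"], 0),
    C_A2 = chem[, "C_A2"],
    C_MA2 = chem[, "C_MA2"],
    N_A2 = particle_number(chem[, "C_A2"], vol),
    i_A2_mean = ifelse(chem[, "C_A2"] > 1e-30, chem[, "C_MA2"] / chem[, "C_A2"], 0),
    colour_R = rgb$R, colour_G = rgb$G, colour_B = rgb$B
  )
}

#' Export simulation tables as CSV
#'
#' `write_census()` writes the per-cell census (the Y-record columns
#' exactly); `write_events()` and `write_series()` write the event log
#' and chemical time series.
#'
#' @param sim a `prion_sim`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_census <- function(sim, path) {
  utils::write.csv(colony_census(sim), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_census
#' @export
write_events <- function(sim, path) {
  utils::write.csv(sim$events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_census
#' @export
write_series <- function(sim, path) {
  utils::write.csv(sim$series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
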