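## Particle-level model: transition timing, bud-site selection, confluence
## testing with whole-cell displacement, heritable variability and death.

#' Temporal transition test
#'
#' Stochastic first-order transition rule: a transition with time constant
#' `tau` and minimum delay `delta` succeeds at stage age `t` when a uniform
#' draw on \[0, 1\] exceeds the survival term `exp(-ln(2) (t - delta) / tau)`.
#' For `t <= delta` the survival term is at least 1, so the test always
#' fails.  Vectorised over `stage_age`.
#'
#' @param stage_age time since the previous transition (minutes).
#' @param tau transition time constant (minutes, > 0).
#' @param delta minimum delay (minutes, >= 0).
#' @return logical vector of successes.
#' @seealso [interval_hazard()] for the per-interval conditional form used
#'   by the scheduler.
#' @export
temporal_test <- function(stage_age, tau, delta) {
  if (tau <= 0) stop("tau must be > 0")
  if (delta < 0) stop("delta must be >= 0")
  stats::runif(length(stage_age)) > exp(-log(2) * (stage_age - delta) / tau)
}

#' Per-interval conditional transition probability
#'
#' The scheduler tests each eligible cell once per coarse interval.  The
#' probability of transitioning during the interval `(t0, t0 + dt]`,
#' conditional on not having transitioned before `t0`, follows from the
#' survival law `S(t) = exp(-ln(2) (t - delta)/tau)` (for `t > delta`):
#' `p = 1 - S(t0 + dt)/S(t0)`.  This makes the per-interval hazard constant
#' (`1 - exp(-ln(2) dt / tau)`) once the delay has passed, so first-success
#' interval counts are geometric, and the discretisation is exact for any
#' coarse step.
#'
#' @param stage_age_start stage age at the start of the interval (minutes).
#' @param dt interval length (minutes).
#' @inheritParams temporal_test
#' @return transition probability in `[0, 1]`.
#' @export
interval_hazard <- function(stage_age_start, dt, tau, delta) {
  if (tau <= 0) stop("tau must be > 0")
  eff <- pmax(0, (stage_age_start + dt) - pmax(delta, stage_age_start))
  1 - exp(-log(2) * eff / tau)
}

#' Candidate bud sites around a mother
#'
#' The six lattice segments adjacent to the mother's two-segment footprint
#' in the plane: one off each end of the domino and two off each long
#' side, in that canonical order.  The caller shuffles them for sampling
#' without replacement.
#'
#' @param x1,y1,x2,y2 the mother's two segment coordinates.
#' @return a 6 x 2 integer matrix of `(x, y)` positions.
#' @export
candidate_bud_sites <- function(x1, y1, x2, y2) {
  ## order the domino so that (ax, ay) is the lesser segment
  if (x2 < x1 || (x2 == x1 && y2 < y1)) {
    tmp <- c(x1, y1); x1 <- x2; y1 <- y2; x2 <- tmp[1]; y2 <- tmp[2]
  }
  if (y1 == y2) {              # horizontal domino
    m <- rbind(c(x1 - 1, y1), c(x2 + 1, y1),
               c(x1, y1 + 1), c(x2, y1 + 1),
               c(x1, y1 - 1), c(x2, y1 - 1))
  } else {                     # vertical domino
    m <- rbind(c(x1, y1 - 1), c(x2, y2 + 1),
               c(x1 + 1, y1), c(x2 + 1, y2),
               c(x1 - 1, y1), c(x2 - 1, y2))
  }
  storage.mode(m) <- "integer"
  colnames(m) <- c("x", "y")
  m
}

#' Candidate expansion sites around a daughter
#'
#' The four segments adjacent to the daughter along the +x, -x, +y and -y
#' axes; occupying the chosen one converts the daughter's footprint into a
#' two-segment mother domino.
#'
#' @param x,y the daughter's segment coordinate.
#' @return a 4 x 2 integer matrix of `(x, y)` positions.
#' @export
candidate_expansion_sites <- function(x, y) {
  m <- rbind(c(x + 1, y), c(x - 1, y), c(x, y + 1), c(x, y - 1))
  storage.mode(m) <- "integer"
  colnames(m) <- c("x", "y")
  m
}

#' Count obstructing segments in the two push directions
#'
#' Counts, along the given axis through `site`, the contiguous occupied
#' segments that would have to shift in the `+axis` and `-axis` direction
#' respectively to free the site.  Each walk starts at the site and moves
#' outward until the first empty segment (the count) or the plate boundary
#' (infinite).  An empty site gives `(0, 0)`.  Segments owned by `ignore`
#' (the growing cell itself, which cannot be displaced by its own growth)
#' terminate a walk with an infinite count.
#'
#' @param col a `prion_colony`.
#' @param site integer `c(x, y)` position.
#' @param axis unit direction `c(dx, dy)` from the growing cell through
#'   the site.
#' @param ignore optional cell index treated as immovable.
#' @return numeric `c(n_perp, n_anti)`; entries may be `Inf`.
#' @export
obstruction_counts <- function(col, site, axis, ignore = NULL) {
  if (is.na(occ_get(col, site[1], site[2]))) return(c(n_perp = 0, n_anti = 0))
  walk <- function(d) {
    n <- 0
    p <- site
    repeat {
      if (!in_plate(col, p[1], p[2])) return(Inf)
      own <- occ_get(col, p[1], p[2])
      if (is.na(own)) return(n)
      if (!is.null(ignore) && own == ignore) return(Inf)
      n <- n + 1
      p <- p + d
    }
  }
  c(n_perp = walk(axis), n_anti = walk(-axis))
}

#' Confluence pseudo-energy of a displacement
#'
#' `delta_E* = 2 * epsilon * R_D * min(N_perp, N_anti)` (dimensionless):
#' the reduced work of pushing the cheaper obstructing chain one segment
#' (a distance `2 R_D`) out of the way.  With `rule = "max"` the dearer
#' direction is priced instead (sensitivity switch).
#'
#' @param epsilon confluence energy per length (m^-1).
#' @param R_D daughter radius in metres.
#' @param n_perp,n_anti obstruction counts (may be `Inf`).
#' @param rule `"min"` or `"max"`.
#' @return non-negative numeric (possibly `Inf`).
#' @export
delta_E_star <- function(epsilon, R_D, n_perp, n_anti, rule = "min") {
  n <- if (rule == "max") max(n_perp, n_anti) else min(n_perp, n_anti)
  if (n == 0) return(0)
  2 * epsilon * R_D * n
}

#' Metropolis-like confluence test
#'
#' Succeeds when a uniform draw on \[0, 1\] falls below `exp(-delta_E*)`.
#'
#' @param dE non-negative pseudo-energy (may be `Inf`); vectorised.
#' @return logical vector.
#' @export
confluence_test <- function(dE) {
  if (any(dE < 0)) stop("delta_E* must be >= 0")
  stats::runif(length(dE)) < exp(-dE)
}

#' Inherit a transition time constant
#'
#' `tau(G) = (1 + g) * tau_base` with `g ~ Normal(A_av, sigma_A^2)`,
#' clamped below at `1e-3 * tau_base` so heritable time constants stay
#' positive.
#'
#' @param tau_base strain-level time constant `tau(0)` (minutes).
#' @param A_av,sigma_A the cell's perturbation distribution parameters.
#' @return a positive time constant (minutes).
#' @export
inherit_tau <- function(tau_base, A_av, sigma_A) {
  if (sigma_A < 0) stop("sigma_A must be >= 0")
  g <- stats::rnorm(1, A_av, sigma_A)
  max((1 + g) * tau_base, 1e-3 * tau_base)
}

#' Evolve the heritable variability parameters across one generation
#'
#' `A_av' = A_av + b1` and `sigma_A' = |1 + b2| * sigma_A` with
#' independent `b1, b2 ~ Normal(0, sigma_B^2)`.  The absolute value keeps
#' the standard deviation non-negative.
#'
#' @param A_av,sigma_A the mother's parameters.
#' @param sigma_B evolution step s.d.
#' @return list with elements `A_av`, `sigma_A`.
#' @export
evolve_variability <- function(A_av, sigma_A, sigma_B) {
  if (sigma_A < 0 || sigma_B < 0) stop("sigma_A and sigma_B must be >= 0")
  b <- stats::rnorm(2, 0, sigma_B)
  list(A_av = A_av + b[1], sigma_A = abs(1 + b[2]) * sigma_A)
}

#' Death rule
#'
#' A cell dies (and its plate segments are freed) at the first division
#' epoch at which its replicative age has reached `max_replicative_age`,
#' or once its chronological age exceeds `max_chronological_age`.  Both
#' limits default to unbounded.
#'
#' @param repl_age replicative age (completed divisions).
#' @param real_age chronological age (minutes).
#' @param limits a [growth_params()].
#' @return `TRUE` if the cell should die.
#' @export
apply_death <- function(repl_age, real_age, limits) {
  repl_age >= limits$max_replicative_age ||
    real_age > limits$max_chronological_age
}

## ---------------------------------------------------------------------------
## Displacement: move whole cells (dominoes stay intact) one segment in
## direction d.  Computes the transitive closure of cells that must move;
## returns FALSE without mutating if the closure leaves the plate or would
## displace the growing cell itself.

push_chain <- function(col, site, d, grower) {
  first <- occ_get(col, site[1], site[2])
  if (is.na(first)) return(TRUE)
  to_move <- c()
  queue <- first
  while (length(queue)) {
    i <- queue[[1]]; queue <- queue[-1]
    if (i %in% to_move) next
    if (i == grower) return(FALSE)
    to_move <- c(to_move, i)
    seg <- cell_segments(col, i)
    tx <- seg[, "x"] + d[1]; ty <- seg[, "y"] + d[2]
    if (!all(in_plate(col, tx, ty))) return(FALSE)
    for (r in seq_along(tx)) {
      own <- occ_get(col, tx[r], ty[r])
      if (!is.na(own) && own != i && !(own %in% to_move)) queue <- c(queue, own)
    }
  }
  ## apply: free all old segments, then occupy all new ones
  for (i in to_move) {
    seg <- cell_segments(col, i)
    for (r in seq_len(nrow(seg))) occ_free(col, seg[r, "x"], seg[r, "y"])
  }
  for (i in to_move) {
    col$x[i] <- col$x[i] + d[1]; col$y[i] <- col$y[i] + d[2]
    if (!is.na(col$x2[i])) {
      col$x2[i] <- col$x2[i] + d[1]; col$y2[i] <- col$y2[i] + d[2]
    }
    seg <- cell_segments(col, i)
    for (r in seq_len(nrow(seg))) occ_set(col, seg[r, "x"], seg[r, "y"], i)
  }
  TRUE
}

## try to free `site` for cell i growing along `axis`; returns delta_E on
## success (site freed and displacement applied), or NULL on failure
try_site <- function(col, i, site, axis) {
  growth <- col$config$growth
  counts <- obstruction_counts(col, site, axis, ignore = i)
  dE <- delta_E_star(growth$epsilon, growth$R_D * 1e-6,
                     counts["n_perp"], counts["n_anti"],
                     rule = growth$obstruction_rule)
  if (is.infinite(dE) || !confluence_test(dE)) return(NULL)
  if (min(counts) > 0) {
    ## push along the cheaper (finite) direction; whole cells move one segment
    dirs <- list(axis, -axis)
    ord <- order(counts)          # min side first; ties keep outward first
    moved <- FALSE
    for (k in ord) {
      if (is.infinite(counts[k])) next
      if (push_chain(col, site, dirs[[k]], grower = i)) { moved <- TRUE; break }
    }
    if (!moved) return(NULL)
  }
  dE
}

## One transition attempt for cell i over the coarse interval that ends at
## col$clock + dt (ages already advanced).  Returns invisibly.
attempt_transition <- function(col, i, dt) {
  cfg <- col$config
  growth <- cfg$growth
  is_mother <- col$stage[i] == "M"
  tau <- if (is_mother) col$tau_MtoD[i] else col$tau_DtoM[i]
  delta <- if (is_mother) growth$delta_MtoD else growth$delta_DtoM
  p <- interval_hazard(col$stage_age[i] - dt, dt, tau, delta)
  if (stats::runif(1) >= p) return(invisible(FALSE))

  sites <- if (is_mother) {
    candidate_bud_sites(col$x[i], col$y[i], col$x2[i], col$y2[i])
  } else {
    candidate_expansion_sites(col$x[i], col$y[i])
  }
  order_try <- sample.int(nrow(sites))
  tried <- 0L
  for (s in order_try) {
    tried <- tried + 1L
    site <- sites[s, ]
    if (!in_plate(col, site[1], site[2])) next   # ineligible, still counted
    ## axis: from the adjacent own segment through the site
    axis <- site_axis(col, i, site)
    dE <- try_site(col, i, site, axis)
    if (is.null(dE)) next
    if (is_mother) {
      start_bud(col, i, site, dE, tried)
    } else {
      start_maturation(col, i, site, dE, tried)
    }
    return(invisible(TRUE))
  }
  log_event(col, col$clock + dt, col$idx[i], "reject",
            sites_tried = tried)
  invisible(FALSE)
}

## unit axis from the growing cell's nearest own segment through the site
site_axis <- function(col, i, site) {
  seg <- cell_segments(col, i)
  dd <- cbind(site[1] - seg[, "x"], site[2] - seg[, "y"])
  adj <- which(abs(dd[, 1]) + abs(dd[, 2]) == 1)[1]
  c(dd[adj, 1], dd[adj, 2])
}

start_bud <- function(col, i, site, dE, tried) {
  cfg <- col$config
  k2 <- col$next_index
  col$next_index <- col$next_index + 1L
  vb <- evolve_variability(col$A_av[i], col$sigma_A[i], cfg$variability$sigma_B)
  j <- add_cell(col, idx = k2, x = site[1], y = site[2],
                stage = "D", substate = "nascent",
                generation = col$generation[i] + 1L,
                lineage = c(col$lineage[[i]], k2),
                A_av = vb$A_av, sigma_A = vb$sigma_A,
                tau_MtoD = inherit_tau(cfg$growth$tau_MtoD, vb$A_av, vb$sigma_A),
                tau_DtoM = inherit_tau(cfg$growth$tau_DtoM, vb$A_av, vb$sigma_A),
                volume = 0.05 * daughter_volume(cfg$growth),
                birth_time = col$clock)
  occ_set(col, site[1], site[2], k2)
  col$substate[i] <- "budding"
  col$links[[length(col$links) + 1L]] <- list(mother = i, bud = j)
  log_event(col, col$clock + cfg$scheduler$dt_coarse, k2, "bud",
            site_x = site[1], site_y = site[2], delta_E = dE,
            sites_tried = tried)
  invisible(col)
}

start_maturation <- function(col, i, site, dE, tried) {
  col$x2[i] <- site[1]; col$y2[i] <- site[2]
  occ_set(col, site[1], site[2], col$idx[i])
  col$substate[i] <- "enlarging"
  log_event(col, col$clock + col$config$scheduler$dt_coarse, col$idx[i],
            "mature", site_x = site[1], site_y = site[2], delta_E = dE,
            sites_tried = tried)
  invisible(col)
}
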