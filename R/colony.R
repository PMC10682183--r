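## Colony state container.
##
## The colony is a mutable environment holding parallel per-cell vectors,
## a lattice occupancy hash and the global clock.  Mutability keeps the
## multiscale stepping loop simple; everything user-facing is exported as
## tibbles (see colony_census(), run_simulation()).

occ_key <- function(x, y) paste(x, y, sep = ",")

occ_get <- function(col, x, y) {
  v <- col$occ[[occ_key(x, y)]]
  if (is.null(v)) NA_integer_ else v
}

occ_set <- function(col, x, y, idx) {
  key <- occ_key(x, y)
  cur <- col$occ[[key]]
  if (!is.null(cur) && cur != idx) {
    stop("occupancy violation: segment (", x, ",", y, ") owned by cell ", cur,
         " while assigning cell ", idx)
  }
  col$occ[[key]] <- as.integer(idx)
  invisible(col)
}

occ_free <- function(col, x, y) {
  rm(list = occ_key(x, y), envir = col$occ)
  invisible(col)
}

in_plate <- function(col, x, y) {
  h <- col$config$growth$plate_half
  ok <- abs(x) <= h & abs(y) <= h
  w <- col$config$growth$wedge
  if (!is.null(w) && any(ok)) {
    seg <- 2 * col$config$growth$R_D
    th <- atan2(y * seg, x * seg)
    ok <- ok & ((x == 0 & y == 0) | (th >= w[1] & th <= w[2]))
  }
  ok
}

#' Create a colony with a single founder mother
#'
#' Places one mature mother cell (a 1 x 2 segment domino) at the centre of
#' the plate, carrying the configuration's initial chemical state.
#'
#' @param config a [scenario_config()].
#' @return a colony environment of class `prion_colony`.
#' @export
new_colony <- function(config) {
  col <- new.env(parent = emptyenv())
  col$config <- config
  col$clock <- 0
  col$next_index <- 2L
  col$occ <- new.env(parent = emptyenv())

  col$idx <- 1L
  col$x <- 0L; col$y <- 0L; col$x2 <- 1L; col$y2 <- 0L
  col$stage <- "M"
  col$substate <- "stationary"
  col$repl_age <- 0L
  col$stage_age <- 0
  col$generation <- 1L
  col$lineage <- list(1L)
  col$A_av <- config$variability$A_av_init
  col$sigma_A <- config$variability$sigma_A_init
  col$tau_MtoD <- config$growth$tau_MtoD
  col$tau_DtoM <- config$growth$tau_DtoM
  col$alive <- TRUE
  col$volume <- mother_volume(config$growth)
  col$birth_time <- 0
  col$septum_time <- 0     # time the cell became an independent cell
  col$mature_time <- 0     # time the cell completed the D -> M transition
  col$death_time <- NA_real_

  col$chem <- matrix(config$init_chem, nrow = 1,
                     dimnames = list(NULL, CHEM_SPECIES))
  occ_set(col, 0L, 0L, 1L)
  occ_set(col, 1L, 0L, 1L)

  col$links <- list()      # active mother/bud division links
  col$series <- list()     # per-interval chemical snapshots (matrices)
  col$events <- list()     # event-log rows

  class(col) <- c("prion_colony", "environment")
  col
}

#' @export
print.prion_colony <- function(x, ...) {
  cat("<prion_colony> ", sum(x$alive), " living / ", length(x$idx),
      " total cells, clock ", x$clock, " min\n", sep = "")
  invisible(x)
}

n_cells <- function(col) length(col$idx)

living <- function(col) which(col$alive)

## both occupied segments of a cell (daughters: one)
cell_segments <- function(col, i) {
  if (is.na(col$x2[i])) {
    cbind(x = col$x[i], y = col$y[i])
  } else {
    cbind(x = c(col$x[i], col$x2[i]), y = c(col$y[i], col$y2[i]))
  }
}

## append one cell record; returns its row position (== index)
add_cell <- function(col, idx, x, y, stage, substate, generation, lineage,
                     A_av, sigma_A, tau_MtoD, tau_DtoM, volume, birth_time,
                     chem = stats::setNames(numeric(5), CHEM_SPECIES)) {
  col$idx <- c(col$idx, as.integer(idx))
  col$x <- c(col$x, as.integer(x)); col$y <- c(col$y, as.integer(y))
  col$x2 <- c(col$x2, NA_integer_); col$y2 <- c(col$y2, NA_integer_)
  col$stage <- c(col$stage, stage)
  col$substate <- c(col$substate, substate)
  col$repl_age <- c(col$repl_age, 0L)
  col$stage_age <- c(col$stage_age, 0)
  col$generation <- c(col$generation, as.integer(generation))
  col$lineage <- c(col$lineage, list(as.integer(lineage)))
  col$A_av <- c(col$A_av, A_av)
  col$sigma_A <- c(col$sigma_A, sigma_A)
  col$tau_MtoD <- c(col$tau_MtoD, tau_MtoD)
  col$tau_DtoM <- c(col$tau_DtoM, tau_DtoM)
  col$alive <- c(col$alive, TRUE)
  col$volume <- c(col$volume, volume)
  col$birth_time <- c(col$birth_time, birth_time)
  col$septum_time <- c(col$septum_time, NA_real_)
  col$mature_time <- c(col$mature_time, NA_real_)
  col$death_time <- c(col$death_time, NA_real_)
  col$chem <- rbind(col$chem, chem)
  length(col$idx)
}

log_event <- function(col, time, cell, kind, site_x = NA_integer_,
                      site_y = NA_integer_, delta_E = NA_real_,
                      sites_tried = NA_integer_) {
  col$events[[length(col$events) + 1L]] <-
    list(time = time, cell = as.integer(cell), kind = kind,
         site_x = site_x, site_y = site_y, delta_E = delta_E,
         sites_tried = sites_tried)
  invisible(col)
}

## exhaustive occupancy consistency check (used by tests and on demand)
audit_occupancy <- function(col) {
  seen <- new.env(parent = emptyenv())
  for (i in living(col)) {
    seg <- cell_segments(col, i)
    expected <- if (col$stage[i] == "M" || col$substate[i] == "enlarging") 2L else 1L
    if (nrow(seg) != expected) {
      stop("cell ", col$idx[i], " owns ", nrow(seg), " segments, expected ", expected)
    }
    if (!all(in_plate(col, seg[, "x"], seg[, "y"]))) {
      stop("cell ", col$idx[i], " lies outside the plate")
    }
    for (r in seq_len(nrow(seg))) {
      key <- occ_key(seg[r, "x"], seg[r, "y"])
      if (!is.null(seen[[key]])) {
        stop("segment ", key, " owned by two cells: ", seen[[key]], ", ", col$idx[i])
      }
      seen[[key]] <- col$idx[i]
      own <- col$occ[[key]]
      if (is.null(own) || own != col$idx[i]) {
        stop("occupancy map out of sync at ", key, " for cell ", col$idx[i])
      }
    }
  }
  n_occ <- length(ls(col$occ))
  n_expect <- length(ls(seen))
  if (n_occ != n_expect) {
    stop("occupancy map has ", n_occ, " entries, expected ", n_expect)
  }
  invisible(TRUE)
}

#' All occupied lattice segments of living cells
#'
#' @param sim a `prion_sim` or `prion_colony`.
#' @return a tibble with columns `x`, `y` (segment coordinates), `cell`.
#' @export
occupied_segments <- function(sim) {
  col <- as_colony(sim)
  rows <- lapply(living(col), function(i) {
    seg <- cell_segments(col, i)
    tibble::tibble(x = seg[, "x"], y = seg[, "y"], cell = col$idx[i])
  })
  dplyr::bind_rows(c(list(tibble::tibble(x = integer(), y = integer(),
                                         cell = integer())), rows))
}

as_colony <- function(x) {
  if (inherits(x, "prion_colony")) return(x)
  if (inherits(x, "prion_sim")) return(x$colony)
  stop("expected a prion_colony or prion_sim object")
}
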