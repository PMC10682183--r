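## Colony interrogation: property queries, histograms, backward lineage
## maps, forward fate maps and curing curves.  All analyses are pure
## functions of the exported tables.

#' Per-cell derived properties
#'
#' The census augmented with the derived interrogation properties:
#' `time_of_birth` (bud appearance), `time_as_daughter` (septum closure
#' to maturation completion), `time_as_mother` (maturation completion to
#' death or censoring at the horizon), `n_children` and the normalised
#' displacement `displacement` = |r - r_centre| / R_D from the unweighted
#' centre of all occupied segments.
#'
#' @param sim a `prion_sim`.
#' @param alive_only drop dead cells (default `TRUE`).
#' @return a tibble: the [colony_census()] columns plus the derived ones.
#' @export
cell_properties <- function(sim, alive_only = TRUE) {
  col <- as_colony(sim)
  cen <- colony_census(col, alive_only = alive_only)
  pos <- match(cen$index, col$idx)
  seg <- occupied_segments(col)
  seg_len <- 2 * col$config$growth$R_D
  cx <- mean(seg$x); cy <- mean(seg$y)
  end_time <- ifelse(is.na(col$death_time[pos]), col$clock, col$death_time[pos])
  mature <- col$mature_time[pos]
  septum <- col$septum_time[pos]
  ## children: cells whose lineage's penultimate element is this cell
  parent <- vapply(col$lineage, function(l) {
    if (length(l) >= 2) l[length(l) - 1L] else NA_integer_
  }, integer(1))
  kids <- table(factor(parent, levels = col$idx))
  dplyr::mutate(cen,
    time_of_birth = col$birth_time[pos],
    time_as_daughter = ifelse(is.na(mature), NA_real_, mature - septum),
    time_as_mother = ifelse(is.na(mature), NA_real_, end_time - mature),
    n_children = as.integer(kids[as.character(.data$index)]),
    displacement = sqrt((.data$x - cx)^2 + (.data$y - cy)^2) * seg_len /
      col$config$growth$R_D
  )
}

#' Query the colony census
#'
#' Filters the per-cell property table with dplyr-style expressions.
#' Referencing a column that does not exist raises an error listing the
#' valid names.
#'
#' @param sim a `prion_sim` (or a census/property tibble).
#' @param ... filter expressions over the census and derived columns.
#' @return the matching rows, a tibble.
#' @examples
#' \donttest{
#' sim <- run_simulation(make_scenario("fig7_nonconfluent"), seed = 1)
#' query_cells(sim, generation == 1)
#' }
#' @export
query_cells <- function(sim, ...) {
  tab <- if (inherits(sim, "prion_sim")) cell_properties(sim) else tibble::as_tibble(sim)
  dots <- rlang::enquos(...)
  for (q in dots) {
    vars <- all.vars(rlang::quo_get_expr(q))
    bad <- setdiff(vars, c(names(tab), ls(baseenv())))
    bad <- bad[!vapply(bad, exists, logical(1))]
    if (length(bad)) {
      stop("unknown column(s) ", paste(bad, collapse = ", "),
           "; valid columns: ", paste(names(tab), collapse = ", "))
    }
  }
  dplyr::filter(tab, !!!dots)
}

#' Histogram of a cell property
#'
#' One-dimensional counts of a census or derived property, optionally
#' split by generation (two-dimensional histogram).
#'
#' @param sim a `prion_sim` or property tibble.
#' @param property column name (string).
#' @param by_generation split counts by generation.
#' @param bins number of bins (ignored for discrete integer properties
#'   with few levels, which are counted directly).
#' @return a tibble with `bin_mid`, optional `generation`, and `count`.
#' @export
histogram_of <- function(sim, property, by_generation = FALSE, bins = 10) {
  tab <- if (inherits(sim, "prion_sim")) cell_properties(sim) else tibble::as_tibble(sim)
  if (!property %in% names(tab)) {
    stop("unknown property '", property, "'; valid columns: ",
         paste(names(tab), collapse = ", "))
  }
  v <- tab[[property]]
  breaks <- pretty(range(v, finite = TRUE), n = bins)
  if (length(unique(breaks)) < 2) breaks <- c(v[1] - 0.5, v[1] + 0.5)
  bin <- cut(v, breaks = breaks, include.lowest = TRUE)
  mids <- (utils::head(breaks, -1) + utils::tail(breaks, -1)) / 2
  tab$bin_mid <- mids[as.integer(bin)]
  grp <- if (by_generation) c("generation", "bin_mid") else "bin_mid"
  dplyr::count(tab, dplyr::across(dplyr::all_of(grp)), name = "count")
}

#' Backward lineage map of a cell
#'
#' Reconstructs the mother chain from the founder to cell `k` and attaches
#' each ancestor's chemical time series (aligned on absolute time) and the
#' event markers along the chain (bud appearance, maturation start and
#' completion).
#'
#' @param sim a `prion_sim`.
#' @param k cell index.
#' @return an object of class `prion_lineage`: list with `chain` (integer
#'   vector of indices, founder first), `series` (tibble) and `events`
#'   (tibble).
#' @export
lineage_of <- function(sim, k) {
  col <- as_colony(sim)
  pos <- match(k, col$idx)
  if (is.na(pos)) stop("no cell with index ", k)
  chain <- col$lineage[[pos]]
  ser <- dplyr::filter(sim$series, .data$cell %in% chain)
  ev <- dplyr::filter(sim$events, .data$cell %in% chain)
  structure(list(chain = chain, target = k, series = ser, events = ev),
            class = "prion_lineage")
}

#' @export
print.prion_lineage <- function(x, ...) {
  cat("<prion_lineage> cell", x$target, ": [",
      paste(x$chain, collapse = ", "), "]\n")
  invisible(x)
}

#' Forward fate map of a cell
#'
#' All descendants of cell `k`, grouped by birth order, with their
#' chemical time series.
#'
#' @param sim a `prion_sim`.
#' @param k root cell index.
#' @return an object of class `prion_fate`: list with `root`, `nodes`
#'   (integer vector of all member indices, root included), `edges`
#'   (tibble `parent`, `child`, `birth_time`) and `series`.
#' @export
fate_of <- function(sim, k) {
  col <- as_colony(sim)
  pos <- match(k, col$idx)
  if (is.na(pos)) stop("no cell with index ", k)
  member <- vapply(col$lineage, function(l) k %in% l, logical(1))
  nodes <- col$idx[member]
  kids <- nodes[nodes != k]
  parent <- vapply(col$lineage[match(kids, col$idx)],
                   function(l) l[length(l) - 1L], integer(1))
  edges <- tibble::tibble(parent = parent, child = kids,
                          birth_time = col$birth_time[match(kids, col$idx)])
  edges <- dplyr::arrange(edges, .data$birth_time, .data$child)
  ser <- dplyr::filter(sim$series, .data$cell %in% nodes)
  structure(list(root = k, nodes = nodes, edges = edges, series = ser,
                 clock = col$clock),
            class = "prion_fate")
}

#' @export
print.prion_fate <- function(x, ...) {
  cat("<prion_fate> root", x$root, ":", length(x$nodes), "cells\n")
  invisible(x)
}

#' Newick representation of a fate tree
#'
#' Serialises a fate map as a newick string with branch lengths equal to
#' the time between a cell's birth and its child's birth (leaves extend
#' to the simulation clock), for use with external tree viewers.
#'
#' @param fate a `prion_fate`.
#' @return a newick string (terminated by `;`).
#' @export
as_newick <- function(fate) {
  stopifnot(inherits(fate, "prion_fate"))
  children <- split(fate$edges$child, fate$edges$parent)
  births <- stats::setNames(c(0, fate$edges$birth_time),
                            c(fate$root, fate$edges$child))
  build <- function(k, t0) {
    kids <- children[[as.character(k)]]
    len <- function(tk) tk - t0
    if (is.null(kids)) {
      return(sprintf("c%d:%g", k, fate$clock - t0))
    }
    ## the cell itself continues alongside its children as a leaf
    parts <- c(vapply(kids, function(j) build(j, births[[as.character(j)]]),
                      ""),
               sprintf("c%d:%g", k, fate$clock - t0))
    sprintf("(%s):%g", paste(parts, collapse = ","), 0)
  }
  paste0(build(fate$root, births[[as.character(fate$root)]]), ";")
}

#' Curing curve
#'
#' Applies the binary prion classifier to every living cell and
#' aggregates by generation: the fraction (or number) of cells classified
#' prion-negative ("cured") per generation.
#'
#' @param sim a `prion_sim` or census tibble.
#' @param params a [colour_params()] carrying the marker and threshold;
#'   defaults to the simulation's own colour block.
#' @param mode `"fraction"` or `"count"`.
#' @return a tibble of class `curing_curve` with columns `generation`,
#'   `n_cells`, `n_cured`, and `fraction_cured`.
#' @export
curing_curve <- function(sim, params = NULL, mode = c("fraction", "count")) {
  mode <- match.arg(mode)
  if (inherits(sim, "prion_sim")) {
    if (is.null(params)) params <- sim$config$colour
    tab <- sim$census
  } else {
    if (is.null(params)) stop("params required when passing a census table")
    tab <- tibble::as_tibble(sim)
  }
  tab$positive <- classify_prion(tab, params)
  out <- dplyr::summarise(dplyr::group_by(tab, .data$generation),
                          n_cells = dplyr::n(),
                          n_cured = sum(!.data$positive), .groups = "drop")
  out$fraction_cured <- out$n_cured / out$n_cells
  out <- dplyr::arrange(out, .data$generation)
  structure(out, class = c("curing_curve", class(out)),
            marker = params$marker, threshold = params$classifier_threshold,
            mode = mode)
}
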