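## Avogadro's number and the um^3 -> litre conversion used for absolute
## particle numbers (N = C * V * 1e-15 * N_AVOGADRO).
N_AVOGADRO <- 6.02214076e23
UM3_TO_L <- 1e-15

CHEM_SPECIES <- c("C_M", "C_A1", "C_MA1", "C_A2", "C_MA2")
PART_CLASSES <- c("M", "A1", "A2")
## which partition class each tracked species belongs to
SPECIES_CLASS <- c(C_M = "M", C_A1 = "A1", C_MA1 = "A1", C_A2 = "A2", C_MA2 = "A2")

COLOUR_MARKERS <- c("C_M", "C_MA1", "N_A1", "C_MA2", "N_A2")

#' Yeast growth and geometry parameters
#'
#' Time constants and minimum delays for the two life-cycle transitions
#' (mother-to-daughter budding, daughter-to-mother maturation), the
#' confluence energy, cell dimensions and optional death ages.  Mature
#' (mother) cells are rectangular solids of aspect ratio 2
#' (`L_M = 2 * W_M`); daughters are spheres of radius `R_D = W_M / 2`.
#' The plate is a square lattice of segments of side `2 * R_D`.
#'
#' @param tau_MtoD,delta_MtoD transition time constant and minimum delay
#'   (minutes) for a mother producing a new bud.
#' @param tau_DtoM,delta_DtoM transition time constant and minimum delay
#'   (minutes) for a daughter maturing into a mother.
#' @param epsilon confluence energy per unit length (m^-1): the reduced
#'   energy required to push one yeast segment a distance `2 * R_D`.
#' @param L_M,W_M,H_M mother dimensions (micrometres).
#' @param R_D daughter radius (micrometres); defaults to `W_M / 2`.
#' @param max_replicative_age,max_chronological_age optional death limits
#'   (count / minutes); `Inf` disables death.
#' @param plate_half half-width of the square plate, in segments.
#' @param wedge optional angular mask `c(theta_min, theta_max)` (radians)
#'   restricting growth to a sector of the plate, or `NULL`.
#' @param obstruction_rule `"min"` (default) prices a displacement by the
#'   cheaper of the two push directions; `"max"` by the dearer one
#'   (sensitivity switch).
#' @return a list of class `growth_params`.
#' @export
growth_params <- function(tau_MtoD = 20, delta_MtoD = 50,
                          tau_DtoM = 20, delta_DtoM = 0,
                          epsilon = 1e5,
                          L_M = 5, W_M = 2.5, H_M = 2.5,
                          R_D = W_M / 2,
                          max_replicative_age = Inf,
                          max_chronological_age = Inf,
                          plate_half = 100,
                          wedge = NULL,
                          obstruction_rule = c("min", "max")) {
  obstruction_rule <- match.arg(obstruction_rule)
  p <- list(tau_MtoD = tau_MtoD, delta_MtoD = delta_MtoD,
            tau_DtoM = tau_DtoM, delta_DtoM = delta_DtoM,
            epsilon = epsilon, L_M = L_M, W_M = W_M, H_M = H_M, R_D = R_D,
            max_replicative_age = max_replicative_age,
            max_chronological_age = max_chronological_age,
            plate_half = plate_half, wedge = wedge,
            obstruction_rule = obstruction_rule)
  class(p) <- "growth_params"
  validate_growth_params(p)
  p
}

validate_growth_params <- function(p) {
  times <- c(p$tau_MtoD, p$delta_MtoD, p$tau_DtoM, p$delta_DtoM)
  if (any(times < 0)) stop("growth times must be >= 0")
  if (p$tau_MtoD <= 0 || p$tau_DtoM <= 0) stop("transition time constants must be > 0")
  if (p$epsilon < 0) stop("epsilon must be >= 0")
  if (abs(p$L_M - 2 * p$W_M) > 1e-12) stop("mothers must have aspect ratio 2 (L_M = 2 * W_M)")
  if (abs(p$R_D - p$W_M / 2) > 1e-12) stop("R_D must equal W_M / 2")
  invisible(p)
}

#' Heritable variability parameters
#'
#' Each new generation perturbs its division time constants by a factor
#' `(1 + g)` with `g ~ Normal(A_av(G), sigma_A(G)^2)`.  `A_av` performs a
#' random walk with step s.d. `sigma_B` across generations and `sigma_A`
#' evolves multiplicatively with the same step s.d.
#'
#' @param A_av_init founder-generation mean of the perturbation (dimensionless).
#' @param sigma_A_init founder-generation s.d. of the perturbation.
#' @param sigma_B per-generation evolution s.d. for both parameters.
#' @return a list of class `variability_params`.
#' @export
variability_params <- function(A_av_init = 0, sigma_A_init = 0.01, sigma_B = 0.01) {
  if (sigma_A_init < 0 || sigma_B < 0) stop("sigma_A_init and sigma_B must be >= 0")
  structure(list(A_av_init = A_av_init, sigma_A_init = sigma_A_init,
                 sigma_B = sigma_B),
            class = "variability_params")
}

#' Amyloid kinetic rate constants
#'
#' Rate constants for monomer turnover, nucleation (nucleus size n = 2
#' throughout), fibril elongation, end-to-end joining / internal breakage
#' and lateral clumping, together with the amino-acid resource feedback
#' parameters.  Two mechanisms are available: `"standard_breakage"`
#' (position-independent breakage, with clumping obtained by setting
#' `f_A2 > 0`) and `"munching"` (position-dependent breakage,
#' `b_A1 != b_G`, single filaments only).  `b_N` is carried in the
#' configuration but aliased to `b_G` inside both derivative functions
#' (nucleus dissociation is assumed equal to endwise monomer loss).
#'
#' @param mechanism `"standard_breakage"` or `"munching"`.
#' @param f_M,b_M monomer production / breakdown rate constants (s^-1).
#' @param f_N nucleation rate constant (M^-1 s^-1, bimolecular; n = 2).
#' @param b_N nucleus dissociation rate constant (s^-1); aliased to `b_G`.
#' @param f_G,b_G elongation (M^-1 s^-1) and endwise monomer loss (s^-1).
#' @param f_A1,b_A1 fibril end-to-end joining (M^-1 s^-1) and internal
#'   breakage (s^-1).
#' @param f_A2,b_A2 lateral clumping (M^-1 s^-1) and clump dissociation
#'   (s^-1).  Clumped fibers never fragment or shed monomer but grow by
#'   monomer addition at both exposed ends.
#' @param C_AA_basal basal amino-acid pool concentration (M).
#' @param psi fractional maximal suppression of the amino-acid pool by
#'   amyloid load, in `[0, 1]`.
#' @param Omega half-saturation amyloid mass concentration (M) of the
#'   resource feedback.
#' @return a list of class `kinetic_params`.
#' @export
kinetic_params <- function(mechanism = c("standard_breakage", "munching"),
                           f_M = 0.01, b_M = 0.01,
                           f_N = 0.001, b_N = 0.005,
                           f_G = 5e5, b_G = 0.005,
                           f_A1 = 0, b_A1 = 0.005,
                           f_A2 = 0, b_A2 = 0,
                           C_AA_basal = 1e-7, psi = 0.95, Omega = 1e-7) {
  mechanism <- match.arg(mechanism)
  rates <- c(f_M, b_M, f_N, b_N, f_G, b_G, f_A1, b_A1, f_A2, b_A2)
  if (any(rates < 0)) stop("all rate constants must be >= 0")
  if (psi < 0 || psi > 1) stop("psi must lie in [0, 1]")
  if (Omega <= 0) stop("Omega must be > 0")
  structure(list(mechanism = mechanism,
                 f_M = f_M, b_M = b_M, f_N = f_N, b_N = b_N,
                 f_G = f_G, b_G = b_G, f_A1 = f_A1, b_A1 = b_A1,
                 f_A2 = f_A2, b_A2 = b_A2,
                 C_AA_basal = C_AA_basal, psi = psi, Omega = Omega),
            class = "kinetic_params")
}

#' Mother/daughter partition rate constants
#'
#' First-order exchange constants for cytosolic species while the septum
#' is open, one pair per species class: `M` (free monomer), `A1` (single
#' fibrils, number and mass) and `A2` (clumped fibers).  `k_ab` is the
#' mother-to-bud direction, `k_ba` the reverse.
#'
#' @param k_ab,k_ba named numeric vectors with entries `M`, `A1`, `A2`
#'   (s^-1).
#' @return a list of class `partition_params`.
#' @export
partition_params <- function(k_ab = c(M = 1, A1 = 1, A2 = 1),
                             k_ba = c(M = 1, A1 = 1, A2 = 1)) {
  k_ab <- k_ab[PART_CLASSES]; k_ba <- k_ba[PART_CLASSES]
  if (anyNA(k_ab) || anyNA(k_ba)) {
    stop("k_ab and k_ba must be named vectors with entries M, A1, A2")
  }
  if (any(c(k_ab, k_ba) < 0)) stop("partition rates must be >= 0")
  structure(list(k_ab = k_ab, k_ba = k_ba), class = "partition_params")
}

#' Colour-assay and binary-classifier parameters
#'
#' The red/white colony screen maps free-monomer concentration to an RGB
#' colour by a gamma transform between `C_M_min` (white) and `C_M_max`
#' (red).  The binary classifier dichotomises cells into prion-positive /
#' prion-negative using one of five markers.
#'
#' @param gamma gamma-transform exponent (> 0); 1 is linear.
#' @param C_M_min,C_M_max monomer concentrations (M) mapped to pure white
#'   and pure red.  The default `C_M_max` is the aggregation-free monomer
#'   steady state `f_M * C_AA_basal / b_M` for the default kinetics, so an
#'   amyloid-free cell is fully red.
#' @param marker one of `"C_M"`, `"C_MA1"`, `"N_A1"`, `"C_MA2"`, `"N_A2"`.
#' @param classifier_threshold threshold in the marker's units.  For the
#'   amyloid markers a cell is prion-positive when the marker is at or
#'   above the threshold; for `C_M`, when the free monomer is *below* it
#'   (low monomer indicates sequestration into prion).
#' @return a list of class `colour_params`.
#' @export
colour_params <- function(gamma = 1, C_M_min = 0, C_M_max = 1e-7,
                          marker = "N_A1", classifier_threshold = 1) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (!(C_M_min < C_M_max)) stop("C_M_min must be < C_M_max")
  if (!marker %in% COLOUR_MARKERS) {
    stop("unknown marker '", marker, "'; valid markers: ",
         paste(COLOUR_MARKERS, collapse = ", "))
  }
  structure(list(gamma = gamma, C_M_min = C_M_min, C_M_max = C_M_max,
                 marker = marker, classifier_threshold = classifier_threshold),
            class = "colour_params")
}

#' Multiscale scheduler parameters
#'
#' @param dt_coarse coarse (particle-level) time step, minutes.  Cell
#'   growth and division complete within one coarse interval.
#' @param n_steps number of fine (chemistry) integration steps per coarse
#'   interval; the fine step is `dt_coarse * 60 / n_steps` seconds.
#' @param horizon total simulated time, minutes.
#' @param seed RNG seed used by [run_simulation()].
#' @return a list of class `scheduler_params`.
#' @export
scheduler_params <- function(dt_coarse = 20, n_steps = 1200,
                             horizon = 700, seed = 1L) {
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (dt_coarse <= 0) stop("dt_coarse must be > 0")
  if (horizon < 0) stop("horizon must be >= 0")
  structure(list(dt_coarse = dt_coarse, n_steps = as.integer(n_steps),
                 horizon = horizon, seed = as.integer(seed)),
            class = "scheduler_params")
}

#' Assemble a full scenario configuration
#'
#' Bundles every parameter block needed to reproduce one simulation run,
#' plus the initial chemical state of the founder cell.
#'
#' @param growth,variability,kinetics,partition,colour,scheduler parameter
#'   blocks; see the respective constructors.
#' @param init_chem named numeric vector of founder concentrations (M)
#'   with entries `C_M`, `C_A1`, `C_MA1`, `C_A2`, `C_MA2`; missing entries
#'   default to 0.
#' @param preset optional preset name this configuration was derived from.
#' @return a list of class `scenario_config`.
#' @seealso [make_scenario()] for the documented presets.
#' @export
scenario_config <- function(growth = growth_params(),
                            variability = variability_params(),
                            kinetics = kinetic_params(),
                            partition = partition_params(),
                            colour = colour_params(),
                            scheduler = scheduler_params(),
                            init_chem = c(C_M = 0, C_A1 = 0, C_MA1 = 0,
                                          C_A2 = 0, C_MA2 = 0),
                            preset = NULL) {
  chem <- stats::setNames(numeric(5), CHEM_SPECIES)
  chem[names(init_chem)] <- init_chem
  if (any(chem < 0)) stop("initial concentrations must be >= 0")
  if (chem["C_A1"] > 0 && chem["C_MA1"] / chem["C_A1"] < 2) {
    stop("initial mean fibril size C_MA1/C_A1 must be >= 2 (nuclei are dimers)")
  }
  cfg <- list(growth = growth, variability = variability,
              kinetics = kinetics, partition = partition,
              colour = colour, scheduler = scheduler,
              init_chem = chem, preset = preset)
  class(cfg) <- "scenario_config"
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>",
      if (!is.null(x$preset)) paste0(" preset: ", x$preset), "\n", sep = "")
  cat("  mechanism:", x$kinetics$mechanism,
      "| epsilon:", format(x$growth$epsilon),
      "| horizon:", x$scheduler$horizon, "min",
      "| dt':", x$scheduler$dt_coarse, "min x", x$scheduler$n_steps, "steps\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Scenario presets.
##
## Each preset reproduces one published parameter set.  Common blocks first.

preset_growth_std <- function(epsilon) {
  growth_params(tau_DtoM = 20, delta_DtoM = 0, tau_MtoD = 20, delta_MtoD = 50,
                epsilon = epsilon)
}

## shared beaker-mode kinetics: f_M = b_M = 0.01 s^-1, f_N = 0.001 M^-1 s^-1,
## (C_AA)_basal = Omega = 1e-7 M, psi = 0.95
preset_kin <- function(...) {
  kinetic_params(f_M = 0.01, b_M = 0.01,
                 C_AA_basal = 1e-7, psi = 0.95, Omega = 1e-7, ...)
}

scenario_presets <- list(
  ## single mother cell of fixed volume; standard breakage mechanism
  fig4A = function() scenario_config(
    growth = preset_growth_std(1e5),
    kinetics = preset_kin(mechanism = "standard_breakage",
                          b_N = 0.005, b_G = 0.005, b_A1 = 0.005,
                          f_G = 5e5, f_A1 = 0, f_A2 = 0, b_A2 = 0),
    init_chem = c(C_M = 1e-7),
    scheduler = scheduler_params(horizon = 500),
    preset = "fig4A"),
  ## endwise 'munching': internal breakage faster than endwise loss
  fig4B = function() scenario_config(
    growth = preset_growth_std(1e5),
    kinetics = preset_kin(mechanism = "munching",
                          b_N = 0, b_G = 0, b_A1 = 0.005,
                          f_G = 5e5, f_A1 = 5e5, f_A2 = 0, b_A2 = 0),
    init_chem = c(C_M = 1e-7),
    scheduler = scheduler_params(horizon = 500),
    preset = "fig4B"),
  ## lateral clumping of fibers (standard mechanism with f_A2 > 0)
  fig4C = function() scenario_config(
    growth = preset_growth_std(1e5),
    kinetics = preset_kin(mechanism = "standard_breakage",
                          b_N = 0.005, b_G = 0.005, b_A1 = 0.005,
                          f_G = 5e5, f_A1 = 5e5, f_A2 = 5e5, b_A2 = 0.005),
    init_chem = c(C_M = 1e-7),
    scheduler = scheduler_params(horizon = 500),
    preset = "fig4C"),
  ## colony growth only (no chemistry), confluent
  fig7_confluent = function() scenario_config(
    growth = preset_growth_std(1e12),
    kinetics = kinetic_params(f_M = 0, b_M = 0, f_N = 0, b_N = 0, f_G = 0,
                              b_G = 0, f_A1 = 0, b_A1 = 0, f_A2 = 0, b_A2 = 0),
    scheduler = scheduler_params(horizon = 700),
    preset = "fig7_confluent"),
  fig7_nonconfluent = function() scenario_config(
    growth = preset_growth_std(1e5),
    kinetics = kinetic_params(f_M = 0, b_M = 0, f_N = 0, b_N = 0, f_G = 0,
                              b_G = 0, f_A1 = 0, b_A1 = 0, f_A2 = 0, b_A2 = 0),
    scheduler = scheduler_params(horizon = 700),
    preset = "fig7_nonconfluent"),
  ## lineage / fate mapping run: standard breakage, free partition
  fig8 = function() scenario_config(
    growth = preset_growth_std(1e5),
    kinetics = preset_kin(mechanism = "standard_breakage",
                          b_N = 0.005, b_G = 0.005, b_A1 = 0.005,
                          f_G = 5e5, f_A1 = 0, f_A2 = 0, b_A2 = 0),
    partition = partition_params(),
    scheduler = scheduler_params(horizon = 700),
    preset = "fig8"),
  ## curing by partition failure: amyloid cannot enter the bud
  fig9A = function() scenario_config(
    growth = preset_growth_std(1e12),
    kinetics = preset_kin(mechanism = "standard_breakage",
                          b_N = 0.005, b_G = 0.005, b_A1 = 0.005,
                          f_G = 5e5, f_A1 = 0, f_A2 = 0, b_A2 = 0),
    partition = partition_params(k_ab = c(M = 1, A1 = 0, A2 = 1)),
    scheduler = scheduler_params(horizon = 900),
    preset = "fig9A"),
  ## partial curing by limited partition
  fig9B = function() scenario_config(
    growth = preset_growth_std(1e12),
    kinetics = preset_kin(mechanism = "standard_breakage",
                          b_N = 0.005, b_G = 0.005, b_A1 = 0.005,
                          f_G = 5e5, f_A1 = 0, f_A2 = 0, b_A2 = 0),
    partition = partition_params(k_ab = c(M = 1, A1 = 0.0065, A2 = 1)),
    scheduler = scheduler_params(horizon = 900),
    preset = "fig9B"),
  ## partial curing by clumping (reduced particle number)
  fig9C = function() scenario_config(
    growth = preset_growth_std(1e12),
    kinetics = preset_kin(mechanism = "standard_breakage",
                          b_N = 0.005, b_G = 0.005, b_A1 = 0.005,
                          f_G = 5e5, f_A1 = 0, f_A2 = 5e4, b_A2 = 0.001),
    partition = partition_params(k_ab = c(M = 1, A1 = 0.0065, A2 = 1)),
    scheduler = scheduler_params(horizon = 900),
    preset = "fig9C"),
  ## GuHCl-type curing: fragmentation switched off, preformed seed diluted
  fig10_guhcl = function() scenario_config(
    growth = preset_growth_std(1e12),
    kinetics = preset_kin(mechanism = "standard_breakage",
                          f_N = 0, b_N = 0, b_G = 0, b_A1 = 0,
                          f_G = 5e5, f_A1 = 0, f_A2 = 0, b_A2 = 0),
    partition = partition_params(),
    init_chem = c(C_A1 = 1e-7, C_MA1 = 5e-7),  # <i_A1> = 5
    scheduler = scheduler_params(horizon = 900),
    preset = "fig10_guhcl")
)

#' Construct a documented scenario preset
#'
#' Returns a fully populated [scenario_config()] for one of the documented
#' in silico experiments: single-cell beaker kinetics under the three
#' mechanism variants (`fig4A` standard breakage, `fig4B` munching,
#' `fig4C` clumping), confluent vs non-confluent colony growth
#' (`fig7_confluent`, `fig7_nonconfluent`), the lineage/fate-mapping run
#' (`fig8`), three curing experiments (`fig9A` partition failure, `fig9B`
#' limited partition, `fig9C` clumping) and the fragmentation-off curing
#' curve run (`fig10_guhcl`).
#'
#' @param name preset identifier.
#' @param seed optional RNG seed override.
#' @return a `scenario_config`.
#' @examples
#' cfg <- make_scenario("fig4A")
#' cfg$kinetics$f_G   # 5e5 M^-1 s^-1
#' @export
make_scenario <- function(name, seed = NULL) {
  if (length(name) != 1 || !name %in% names(scenario_presets)) {
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid presets: ", paste(names(scenario_presets), collapse = ", "))
  }
  cfg <- scenario_presets[[name]]()
  if (!is.null(seed)) cfg$scheduler$seed <- as.integer(seed)
  cfg
}

## ---------------------------------------------------------------------------
## Serialisation.  JSON is canonical; YAML is accepted for convenience.
## Inf (unbounded death ages) is written as the string "Inf".

config_to_list <- function(cfg) {
  enc <- function(x) {
    if (is.list(x)) return(lapply(x, enc))
    if (is.numeric(x) && any(is.infinite(x))) {
      x <- as.list(ifelse(is.infinite(x), "Inf", x))
    }
    x
  }
  blocks <- lapply(unclass(cfg)[c("growth", "variability", "kinetics",
                                  "partition", "colour", "scheduler")],
                   function(b) enc(unclass(b)))
  blocks$partition <- list(k_ab = as.list(cfg$partition$k_ab),
                           k_ba = as.list(cfg$partition$k_ba))
  blocks$init_chem <- as.list(cfg$init_chem)
  blocks$preset <- cfg$preset
  blocks
}

list_to_config <- function(x) {
  dec <- function(v) {
    if (is.list(v)) v <- unlist(v)
    if (is.character(v)) v <- ifelse(v == "Inf", Inf, suppressWarnings(as.numeric(v)))
    v
  }
  base <- if (!is.null(x$preset)) make_scenario(x$preset) else scenario_config()
  num_field <- function(block, field, default) {
    v <- x[[block]][[field]]
    if (is.null(v)) return(default)
    dec(v)
  }
  g <- base$growth
  for (f in setdiff(names(g), c("wedge", "obstruction_rule"))) {
    g[[f]] <- num_field("growth", f, g[[f]])
  }
  if (!is.null(x$growth$obstruction_rule)) g$obstruction_rule <- x$growth$obstruction_rule
  if (!is.null(x$growth$wedge)) g$wedge <- dec(x$growth$wedge)
  validate_growth_params(g)
  v <- base$variability
  for (f in names(v)) v[[f]] <- num_field("variability", f, v[[f]])
  k <- base$kinetics
  if (!is.null(x$kinetics$mechanism)) k$mechanism <- x$kinetics$mechanism
  for (f in setdiff(names(k), "mechanism")) k[[f]] <- num_field("kinetics", f, k[[f]])
  p <- base$partition
  if (!is.null(x$partition$k_ab)) p$k_ab[PART_CLASSES] <- dec(x$partition$k_ab)[PART_CLASSES]
  if (!is.null(x$partition$k_ba)) p$k_ba[PART_CLASSES] <- dec(x$partition$k_ba)[PART_CLASSES]
  cl <- base$colour
  if (!is.null(x$colour$marker)) cl$marker <- x$colour$marker
  for (f in setdiff(names(cl), "marker")) cl[[f]] <- num_field("colour", f, cl[[f]])
  s <- base$scheduler
  for (f in names(s)) s[[f]] <- num_field("scheduler", f, s[[f]])
  s$n_steps <- as.integer(s$n_steps); s$seed <- as.integer(s$seed)
  chem <- base$init_chem
  if (!is.null(x$init_chem)) chem[names(x$init_chem)] <- dec(x$init_chem)[names(x$init_chem)]
  scenario_config(growth = g, variability = v, kinetics = k, partition = p,
                  colour = cl, scheduler = s, init_chem = chem,
                  preset = x$preset)
}

#' Read / write a scenario configuration
#'
#' Scenario configurations round-trip through JSON (canonical) or YAML
#' (convenience); the format is chosen from the file extension.  A file
#' may carry a `"preset"` key, which is expanded first, with any further
#' keys applied as overrides.
#'
#' @param cfg a `scenario_config`.
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_scenario()` returns a `scenario_config`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
write_scenario <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  x <- config_to_list(cfg)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path)
  }
  list_to_config(x)
}

## volumes implied by the geometry (micrometres^3)
mother_volume <- function(growth) growth$L_M * growth$W_M * growth$H_M
daughter_volume <- function(growth) (4 / 3) * pi * growth$R_D^3
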