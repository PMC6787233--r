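# System definitions and simulation parameter containers.

#' Single- or double-walled tube system
#'
#' A system bundles the lattice specifications of the simulated walls. The
#' flash-diluted sample corresponds to the isolated inner tube (single wall);
#' the complete nanotube has both walls with equal axial length.
#'
#' @param n_circ_inner,n_circ_outer Circumferential site counts (30 and 55
#'   for the C8S3 nanotube model).
#' @param n_axial Axial site count (1000 by default).
#' @param lattice_const Lattice constant in nm.
#' @return An object of class `tube_system` with elements `kind`
#'   (`"single"`/`"double"`) and `layers` (named list of [lattice_spec()]).
#' @examples
#' single_wall_system()
#' double_wall_system()
#' @export
single_wall_system <- function(n_circ_inner = 30, n_axial = 1000,
                               lattice_const = 0.74) {
  structure(list(
    kind = "single",
    layers = list(inner = lattice_spec("inner", n_circ_inner, n_axial,
                                       lattice_const))),
    class = "tube_system")
}

#' @rdname single_wall_system
#' @export
double_wall_system <- function(n_circ_inner = 30, n_circ_outer = 55,
                               n_axial = 1000, lattice_const = 0.74) {
  structure(list(
    kind = "double",
    layers = list(
      inner = lattice_spec("inner", n_circ_inner, n_axial, lattice_const),
      outer = lattice_spec("outer", n_circ_outer, n_axial, lattice_const))),
    class = "tube_system")
}

#' @export
print.tube_system <- function(x, ...) {
  cat(sprintf("<tube_system> %s wall\n", x$kind))
  for (l in x$layers) print(l)
  invisible(x)
}

#' Kinetic Monte Carlo simulation parameters
#'
#' Defaults follow the global-fit and measured parameters of the nanotube
#' model: per-step hopping probability `H = 0.04` (per 1 fs step, total over
#' the four neighbours), annihilation radius `R0 = 3` molecules, inter-layer
#' transfer rates `k_io = 0.0013` and `k_oi = 0.0031` fs^-1, one-exciton
#' lifetime 58 ps (isolated inner tube) or 33 ps (complete nanotube).
#' `hop_prob` and `ann_radius` may be length-2 vectors `(inner, outer)`.
#'
#' @param dt Time step in fs.
#' @param hop_prob Total per-step probability to hop to any neighbour.
#' @param lifetime_ps One-exciton lifetime tau in ps (`Inf` disables decay).
#' @param ann_radius Annihilation radius in lattice units (0 disables EEA).
#' @param k_io,k_oi Inner->outer / outer->inner transfer rates in fs^-1.
#' @param density Molecules per exciton (N_m / N_e); identical for both walls.
#' @param t_max_ps Simulation horizon in ps.
#' @param n_real Number of realizations for ensembles.
#' @param seed Master integer seed.
#' @return An object of class `sim_params`.
#' @examples
#' sim_params(lifetime_ps = 33, density = 625, t_max_ps = 30)
#' @export
sim_params <- function(dt = 1, hop_prob = 0.04, lifetime_ps = 33,
                       ann_radius = 3, k_io = 0.0013, k_oi = 0.0031,
                       density = 625, t_max_ps = 50, n_real = 50,
                       seed = 1L) {
  stopifnot(dt > 0, lifetime_ps > 0, all(ann_radius >= 0), density >= 1,
            t_max_ps > 0, n_real >= 1, k_io >= 0, k_oi >= 0)
  hop_prob <- rep_len(hop_prob, 2L)
  ann_radius <- rep_len(ann_radius, 2L)
  budget <- dt / (lifetime_ps * 1000) + max(hop_prob) + max(k_io, k_oi) * dt
  if (any(hop_prob < 0) || budget > 1) {
    stop("per-step probability budget dt/tau + H + k*dt exceeds 1")
  }
  structure(list(dt = dt, hop_prob = hop_prob, lifetime_ps = lifetime_ps,
                 ann_radius = ann_radius, k_io = k_io, k_oi = k_oi,
                 density = density, t_max_ps = t_max_ps,
                 n_real = as.integer(n_real), seed = as.integer(seed)),
            class = "sim_params")
}

#' Table-style parameter sets
#'
#' `inner_tube_params()` returns the parameters used for the isolated inner
#' tube (lifetime 58 ps, no inter-layer transfer); `nanotube_params()` those
#' for the complete double-walled nanotube (lifetime 33 ps, measured
#' transfer rates).
#'
#' @param ... Overrides passed on to [sim_params()].
#' @export
inner_tube_params <- function(...) {
  args <- modifyList(list(lifetime_ps = 58, k_io = 0, k_oi = 0,
                          density = 404), list(...))
  do.call(sim_params, args)
}

#' @rdname inner_tube_params
#' @export
nanotube_params <- function(...) {
  args <- modifyList(list(lifetime_ps = 33, density = 625), list(...))
  do.call(sim_params, args)
}

#' Thermal parameters of the inter-layer equilibrium
#'
#' @param delta_E_cm1 Inner/outer site-energy gap in cm^-1 (300 for C8S3).
#' @param kBT_cm1 Thermal energy in cm^-1 (~200 at room temperature).
#' @param dos_ratio Outer-to-inner molecule count ratio (55/30); the
#'   density of states of each wall is proportional to its molecule count.
#' @return An object of class `thermal_params`.
#' @export
thermal_params <- function(delta_E_cm1 = 300, kBT_cm1 = 200,
                           dos_ratio = 55 / 30) {
  stopifnot(delta_E_cm1 > 0 || delta_E_cm1 == 0, kBT_cm1 > 0, dos_ratio > 0)
  structure(list(delta_E_cm1 = delta_E_cm1, kBT_cm1 = kBT_cm1,
                 dos_ratio = dos_ratio),
            class = "thermal_params")
}

#' Detailed-balance ratio of uphill to downhill transfer rates
#'
#' At thermal equilibrium the net inter-wall fluxes balance, which fixes the
#' uphill (inner -> outer) rate relative to the measured downhill rate via
#' the Boltzmann factor and the density-of-states ratio:
#' `exp(-delta_E / kBT) * dos_ratio`. With the C8S3 values (300 cm^-1 gap,
#' kBT ~ 200 cm^-1, 55/30 molecules) this is ~0.4, consistent with the
#' measured rate quotient 0.0013/0.0031.
#'
#' @param thermal A [thermal_params()] object.
#' @return Dimensionless ratio k_io / k_oi.
#' @examples
#' detailed_balance_ratio(thermal_params())
#' @export
detailed_balance_ratio <- function(thermal = thermal_params()) {
  stopifnot(inherits(thermal, "thermal_params"))
  exp(-thermal$delta_E_cm1 / thermal$kBT_cm1) * thermal$dos_ratio
}
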