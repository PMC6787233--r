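# R-level surface of the kinetic Monte Carlo engine. A simulation state is an
# environment holding an external pointer into the C++ engine; operations on
# it (advance_step, annihilation_sweep) mutate in place, mirroring the
# stochastic process.

layer_index <- c(inner = 1L, outer = 2L)

kmc_layer_list <- function(system, params) {
  k_by_layer <- c(inner = params$k_io, outer = params$k_oi)
  out <- list()
  for (nm in names(system$layers)) {
    spec <- system$layers[[nm]]
    li <- layer_index[[nm]]
    out[[nm]] <- list(n_circ = spec$n_circ, n_axial = spec$n_axial,
                      hop_prob = params$hop_prob[li],
                      ann_radius = params$ann_radius[li],
                      k_transfer = if (system$kind == "double") k_by_layer[[nm]] else 0)
  }
  out
}

#' Number of excitons planted per wall
#'
#' `N_e = round(site_count / density)`, the same density on both walls.
#'
#' @param system A [single_wall_system()] or [double_wall_system()].
#' @param params A [sim_params()] (only `density` is used).
#' @return Named integer vector, one count per wall.
#' @export
exciton_count <- function(system, params) {
  vapply(system$layers, function(spec) {
    as.integer(round(spec$n_circ * spec$n_axial / params$density))
  }, integer(1))
}

#' Plant excitons on the molecular grid
#'
#' Excitons are placed uniformly at random, without double occupancy, at the
#' per-wall counts given by [exciton_count()]; an annihilation sweep is then
#' applied at t = 0 (excitons planted closer than the annihilation radius
#' annihilate immediately, which is why the EEI signal at the highest
#' experimental density peaks at essentially zero waiting time).
#'
#' @param system A tube system.
#' @param params A [sim_params()].
#' @param seed Integer seed for this realization (default `params$seed`).
#' @param positions Optional list (one element per wall) of 2-column integer
#'   matrices of 0-based `(i, j)` positions, overriding random planting.
#' @param t0_sweep Apply the t = 0 annihilation sweep (default `TRUE`).
#' @return A `kmc_state` object.
#' @examples
#' st <- plant_excitons(single_wall_system(100, 100),
#'                      inner_tube_params(density = 100, n_real = 1))
#' nrow(state_snapshot(st))
#' @export
plant_excitons <- function(system, params, seed = params$seed,
                           positions = NULL, t0_sweep = TRUE) {
  stopifnot(inherits(system, "tube_system"), inherits(params, "sim_params"))
  layers <- kmc_layer_list(system, params)
  if (is.null(positions)) {
    ne <- exciton_count(system, params)
    if (sum(ne) < 1L) stop("density too high: no excitons would be planted")
    init <- as.list(ne)
  } else {
    stopifnot(length(positions) == length(layers))
    init <- lapply(positions, function(m) {
      storage.mode(m) <- "integer"
      m
    })
  }
  ptr <- cpp_kmc_create(unname(layers), params$dt,
                        params$lifetime_ps * 1000, as.integer(seed),
                        unname(init))
  if (t0_sweep) cpp_kmc_sweep(ptr)
  st <- new.env(parent = emptyenv())
  st$ptr <- ptr
  st$system <- system
  st$params <- params
  st$seed <- as.integer(seed)
  class(st) <- "kmc_state"
  st
}

#' @export
print.kmc_state <- function(x, ...) {
  snap <- state_snapshot(x)
  cat(sprintf("<kmc_state> t = %g ps, %d excitons (%d alive)\n",
              cpp_kmc_time(x$ptr) / 1000, nrow(snap),
              sum(snap$status == "alive")))
  invisible(x)
}

#' Advance the simulation by whole time steps
#'
#' Each step updates every alive exciton once, in a freshly shuffled order:
#' a first uniform draw decides decay (probability `dt/tau`); surviving
#' excitons then draw once more to either hop to one of the four neighbours
#' (total probability `H`, 1/4 each), attempt inter-layer transfer
#' (probability `k*dt`, performed only if the partner site is unoccupied), or
#' stay. After all excitons have moved, one annihilation sweep runs.
#'
#' @param state A `kmc_state`.
#' @param n Number of steps to advance.
#' @return The state, invisibly (modified in place).
#' @export
advance_step <- function(state, n = 1) {
  stopifnot(inherits(state, "kmc_state"))
  cpp_kmc_step(state$ptr, as.integer(n))
  invisible(state)
}

#' Run the annihilation sweep on the current positions
#'
#' While any same-wall pair of alive excitons is strictly closer than the
#' annihilation radius (minimum-image metric), one pair is picked in random
#' order and one member, chosen uniformly, is deleted; the survivor's
#' annihilation counts are incremented and the partner's origin wall is
#' recorded. Excitons may participate in several sequential events within
#' one sweep. Cross-wall pairs never annihilate.
#'
#' @param state A `kmc_state`.
#' @return The state, invisibly (modified in place).
#' @export
annihilation_sweep <- function(state) {
  stopifnot(inherits(state, "kmc_state"))
  cpp_kmc_sweep(state$ptr)
  invisible(state)
}

status_labels <- c("alive", "decayed", "annihilated", "censored")

snapshot_to_df <- function(snap) {
  layer_names <- c("inner", "outer")
  n <- length(snap$layer)
  data.frame(
    exciton_id = seq_len(n),
    origin_layer = layer_names[snap$origin],
    layer = layer_names[snap$layer],
    i = snap$i, j = snap$j,
    status = status_labels[snap$status + 1L],
    terminal_time_ps = snap$terminal_time_fs / 1000,
    terminal_layer = ifelse(is.na(snap$terminal_layer), NA_character_,
                            layer_names[snap$terminal_layer]),
    n_ann_survived = snap$n_ann_survived,
    n_ann_total = snap$n_ann_total,
    n_ann_same_origin = snap$n_ann_same_origin,
    partner_same_origin = ifelse(snap$n_ann_total == 0, NA,
                                 snap$n_ann_same_origin == snap$n_ann_total),
    disp_i = snap$ux, disp_j = snap$uy,
    stringsAsFactors = FALSE)
}

#' Per-exciton bookkeeping of the current state
#'
#' @param state A `kmc_state`.
#' @return A data frame with one row per planted exciton: origin and current
#'   wall, position, status, terminal time/wall, annihilation counts
#'   (survived, total, with same-origin partner), whether every annihilation
#'   partner shared the exciton's origin wall, and the unwrapped displacement
#'   in lattice units.
#' @export
state_snapshot <- function(state) {
  stopifnot(inherits(state, "kmc_state"))
  snapshot_to_df(cpp_kmc_snapshot(state$ptr))
}

#' Default log-spaced waiting-time grid
#'
#' Zero waiting time followed by geometrically spaced times up to `t_max_ps`,
#' emulating the log-sampled experimental waiting-time axis.
#'
#' @param t_max_ps Horizon in ps.
#' @param n Number of grid points (including 0).
#' @param t_min_ps First positive time.
#' @return Numeric vector of waiting times in ps.
#' @export
sampling_times <- function(t_max_ps = 50, n = 40, t_min_ps = 0.05) {
  c(0, exp(seq(log(t_min_ps), log(t_max_ps), length.out = n - 1L)))
}

times_to_steps <- function(times_ps, dt_fs) {
  sort(unique(as.integer(round(times_ps * 1000 / dt_fs))))
}

#' Run one seeded realization
#'
#' Plants excitons, advances to the horizon, and samples the state (after
#' each step's annihilation sweep, including the t = 0 sweep) at the
#' requested waiting times. Excitons still alive at the horizon are censored
#' with their current wall as terminal wall.
#'
#' @param system A tube system.
#' @param params A [sim_params()].
#' @param sampling_times_ps Waiting times in ps (subset of the step grid
#'   after rounding); default [sampling_times()] up to `params$t_max_ps`.
#' @param seed Integer seed.
#' @param positions Optional explicit planting positions (see
#'   [plant_excitons()]).
#' @return A list of class `kmc_realization`: `times_ps`, `counts` (matrix,
#'   observables x times, see [observable_ids()]), `records` (terminal
#'   per-exciton data frame), `msd_lattice` (mean squared unwrapped
#'   displacement per time, lattice units), `n_planted`, and the raw
#'   per-exciton sampling matrices in `snap`.
#' @export
run_realization <- function(system, params, sampling_times_ps = NULL,
                            seed = params$seed, positions = NULL) {
  if (params$t_max_ps <= 0) stop("t_max_ps must be positive")
  if (is.null(sampling_times_ps)) {
    sampling_times_ps <- sampling_times(params$t_max_ps)
  }
  state <- plant_excitons(system, params, seed = seed, positions = positions)
  steps <- times_to_steps(sampling_times_ps, params$dt)
  horizon <- as.integer(round(params$t_max_ps * 1000 / params$dt))
  if (max(steps) > horizon) stop("sampling times exceed t_max_ps")
  raw <- cpp_kmc_run(state$ptr, steps)
  if (max(steps) < horizon) cpp_kmc_step(state$ptr, horizon - max(steps))
  records <- snapshot_to_df(cpp_kmc_finalize(state$ptr))
  origin <- layer_index[records$origin_layer]
  counts <- count_all(raw, origin)
  structure(list(
    times_ps = raw$times_fs / 1000,
    counts = counts,
    records = records,
    msd_lattice = colMeans(raw$disp2),
    n_planted = exciton_count_actual(records),
    snap = c(raw, list(origin = origin)),
    seed = seed),
    class = "kmc_realization")
}

exciton_count_actual <- function(records) {
  c(inner = sum(records$origin_layer == "inner"),
    outer = sum(records$origin_layer == "outer"))
}

#' Run a seeded ensemble of realizations
#'
#' Spawns one child seed per realization from the master seed and stacks the
#' per-time observable counts. Bit-reproducible for a given
#' (seed, n_real, parameters) triple.
#'
#' @inheritParams run_realization
#' @param collect `"counts"` (default) keeps per-realization observable
#'   counts, records and MSD; `"snapshots"` additionally retains the raw
#'   per-exciton sampling matrices of every realization.
#' @return An object of class `kmc_ensemble`: `times_ps`, `counts` (3-d
#'   array observables x times x realizations), `records` (stacked data
#'   frame with a `realization` column), `msd_lattice` (realizations x
#'   times), `seeds`, `system`, `params`.
#' @export
run_ensemble <- function(system, params, sampling_times_ps = NULL,
                         collect = c("counts", "snapshots"),
                         seed = params$seed) {
  collect <- match.arg(collect)
  if (is.null(sampling_times_ps)) {
    sampling_times_ps <- sampling_times(params$t_max_ps)
  }
  n_real <- params$n_real
  seeds <- spawn_seeds(seed, n_real)
  reals <- vector("list", n_real)
  for (r in seq_len(n_real)) {
    reals[[r]] <- run_realization(system, params, sampling_times_ps,
                                  seed = seeds[r])
  }
  counts <- array(
    unlist(lapply(reals, `[[`, "counts"), use.names = FALSE),
    dim = c(nrow(reals[[1]]$counts), length(reals[[1]]$times_ps), n_real),
    dimnames = list(rownames(reals[[1]]$counts), NULL, NULL))
  records <- do.call(rbind, lapply(seq_len(n_real), function(r) {
    df <- reals[[r]]$records
    df$realization <- r
    df
  }))
  structure(list(
    times_ps = reals[[1]]$times_ps,
    counts = counts,
    records = records,
    msd_lattice = do.call(rbind, lapply(reals, `[[`, "msd_lattice")),
    n_planted = reals[[1]]$n_planted,
    snapshots = if (collect == "snapshots") lapply(reals, `[[`, "snap"),
    seeds = seeds,
    system = system,
    params = params),
    class = "kmc_ensemble")
}

#' @export
print.kmc_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<kmc_ensemble> %s wall, %d realizations, %d sampling",
                     " times, %s excitons/realization\n"),
              x$system$kind, dim(x$counts)[3], length(x$times_ps),
              sum(x$n_planted)))
  invisible(x)
}

# Deterministic child seeds below 2^31 from one master seed.
spawn_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
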