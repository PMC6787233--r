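# Synthetic experiment-shaped datasets with known ground truth: per-fluence
# bundles of absorptive and EEI waiting-time transients with additive
# detection noise, emulating the structure of the measured fluence series so
# that every pipeline stage is testable without experimental data.

#' Ground-truth parameters for a synthetic fluence series
#'
#' Defaults emulate the experimental conditions: the flash-diluted
#' (single-wall) series was measured at 18, 83, 165 and 404 molecules per
#' exciton, the complete-nanotube (double-wall) series at 19, 64 and 625;
#' detection noise is additive Gaussian with standard deviation
#' `noise x series maximum`.
#'
#' @param kind `"single"` (isolated inner tubes) or `"double"` (complete
#'   nanotubes).
#' @param params Generating [sim_params()]; defaults to
#'   [inner_tube_params()] / [nanotube_params()].
#' @param system Tube system; defaults to the standard grids.
#' @param densities Molecules-per-exciton list of the emulated series.
#' @param times_ps Waiting-time grid in ps.
#' @param noise Relative detection-noise level (>= 0).
#' @param seed Master seed.
#' @return Object of class `truth_params`.
#' @export
truth_params <- function(kind = c("single", "double"), params = NULL,
                         system = NULL, densities = NULL,
                         times_ps = sampling_times(50, 40), noise = 0.05,
                         seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(noise >= 0, all(is.null(densities) | densities >= 1))
  if (is.null(params)) {
    params <- if (kind == "single") inner_tube_params() else nanotube_params()
  }
  if (is.null(system)) {
    system <- if (kind == "single") single_wall_system() else
      double_wall_system()
  }
  if (is.null(densities)) {
    densities <- if (kind == "single") c(18, 83, 165, 404) else
      c(19, 64, 625)
  }
  structure(list(kind = kind, params = params, system = system,
                 densities = densities, times_ps = times_ps, noise = noise,
                 seed = as.integer(seed)),
            class = "truth_params")
}

bundle_observables <- function(kind) {
  if (kind == "single") c("abs_inner_diag", "eei_inner_diag")
  else names(obs_table)
}

#' Noise-free forward bundle from truth parameters
#'
#' @param truth A [truth_params()].
#' @param forward_cache Optional environment for memoising forward runs
#'   (shared with the fitting stage).
#' @return An [experiment_bundle()] of clean model transients (`sem` = 0).
#' @export
generate_clean_bundle <- function(truth, forward_cache = NULL) {
  stopifnot(inherits(truth, "truth_params"))
  sim_config <- list(system = truth$system, params = truth$params,
                     n_real = truth$params$n_real, seed = truth$seed)
  entries <- list()
  for (d in truth$densities) {
    ens <- forward_ensemble(truth$params$hop_prob[1],
                            truth$params$ann_radius[1], d, truth$times_ps,
                            sim_config, forward_cache)
    for (obs in bundle_observables(truth$kind)) {
      tr <- transient(ens, obs)
      tr$sem <- rep(0, nrow(tr))
      entries[[length(entries) + 1L]] <-
        list(density = d, observable_id = obs, series = tr)
    }
  }
  experiment_bundle(entries, truth$kind)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Add detection noise to a clean bundle
#'
#' Additive Gaussian noise, independently per point, with standard
#' deviation `noise x max(series)`; the `sem` column of each series is set
#' to that value (the experimental error bars refer to the detection noise
#' level, which is amplitude-independent within one series).
#'
#' @param bundle An [experiment_bundle()].
#' @param noise Relative noise level.
#' @param seed Integer seed for the noise draw.
#' @return The noisy [experiment_bundle()].
#' @export
add_noise <- function(bundle, noise, seed) {
  stopifnot(inherits(bundle, "experiment_bundle"), noise >= 0)
  with_seed(seed, {
    bundle$entries <- lapply(bundle$entries, function(e) {
      sdv <- noise * max(e$series$value)
      e$series$value <- e$series$value + rnorm(nrow(e$series), sd = sdv)
      e$series$sem <- rep(sdv, nrow(e$series))
      e
    })
  })
  bundle
}

#' Generate a synthetic bundle with ground truth sidecar
#'
#' @param truth A [truth_params()].
#' @param noise_seed Seed for the noise draw only (defaults to
#'   `truth$seed + 1`); replicate datasets share the clean forward model
#'   and differ in this seed.
#' @param forward_cache Optional memoisation environment.
#' @return Object of class `synthetic_bundle`: `bundle` (the noisy
#'   [experiment_bundle()]) and `truth`.
#' @export
generate_bundle <- function(truth, noise_seed = NULL, forward_cache = NULL) {
  clean <- generate_clean_bundle(truth, forward_cache)
  if (is.null(noise_seed)) noise_seed <- truth$seed + 1L
  noisy <- if (truth$noise > 0) add_noise(clean, truth$noise, noise_seed)
           else clean
  structure(list(bundle = noisy, truth = truth, noise_seed = noise_seed),
            class = "synthetic_bundle")
}

#' Miniature deterministic test scenarios
#'
#' Small systems with analytically known outcomes, shared across the test
#' suites:
#' \describe{
#'   \item{pure_decay}{No hopping, no annihilation, 1 ps lifetime: the
#'     alive count decays as `exp(-t/tau)`.}
#'   \item{two_exciton_collision}{Two excitons planted 2 sites apart with
#'     annihilation radius 3: the t = 0 sweep deletes one, so the EEI count
#'     is 1 at t = 0+.}
#'   \item{dimer_hsr}{Symmetric dimer with explicit coupling J: eigenvalues
#'     E +- J.}
#'   \item{ring_hsr}{Uniform N-ring with nearest-neighbour coupling J:
#'     eigenvalues `E + 2 J cos(2 pi k / N)`.}
#' }
#'
#' @param name Fixture name.
#' @return A list with the scenario objects and `expected` values.
#' @export
toy_fixture <- function(name = c("pure_decay", "two_exciton_collision",
                                 "dimer_hsr", "ring_hsr")) {
  name <- match.arg(name)
  switch(name,
    pure_decay = list(
      system = single_wall_system(10, 100),
      params = sim_params(hop_prob = 0, lifetime_ps = 1, ann_radius = 0,
                          k_io = 0, k_oi = 0, density = 20, t_max_ps = 5,
                          n_real = 40, seed = 42),
      expected = function(t_ps) exp(-t_ps / 1)),
    two_exciton_collision = list(
      system = single_wall_system(30, 100),
      params = sim_params(hop_prob = 0, lifetime_ps = Inf, ann_radius = 3,
                          k_io = 0, k_oi = 0, density = 1500, t_max_ps = 1,
                          n_real = 1, seed = 7),
      positions = list(inner = rbind(c(0L, 10L), c(0L, 12L))),
      expected = list(eei_count_t0 = 1L, abs_count_t0 = 1L)),
    dimer_hsr = {
      E <- 16700; J <- -100
      mol <- molecule_table(rbind(c(0, 0, 0), c(0, 0, 1)),
                            rbind(c(0, 0, 1), c(0, 0, 1)), E)
      list(model = aggregate_model(mol, coupling = rbind(c(0, J), c(J, 0))),
           expected = list(energies = sort(c(E + J, E - J)), E = E, J = J))
    },
    ring_hsr = {
      E <- 16700; J <- -50; N <- 8
      theta <- 2 * pi * (seq_len(N) - 1) / N
      R <- 1 / (2 * sin(pi / N))  # unit nearest-neighbour spacing
      mol <- molecule_table(cbind(R * cos(theta), R * sin(theta), 0),
                            cbind(-sin(theta), cos(theta), 0), E)
      cpl <- matrix(0, N, N)
      for (n in seq_len(N)) {
        cpl[n, n %% N + 1] <- J
        cpl[n %% N + 1, n] <- J
      }
      list(model = aggregate_model(mol, coupling = cpl,
                                   geometry_kind = "ring"),
           expected = list(
             energies = sort(E + 2 * J * cos(2 * pi * (seq_len(N) - 1) / N)),
             E = E, J = J, N = N))
    })
}
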