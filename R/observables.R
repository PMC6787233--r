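# Observable extraction: convert labelled exciton populations into the
# measurable quantities of EEI2D spectroscopy. Absorptive signals count all
# alive excitons matching an origin/current-wall constraint; EEI signals
# additionally require participation in at least one annihilation event with
# a partner planted on the same wall. The cross peak 2w_outer -> w_inner
# counts excitons (1) planted on the outer wall, (2) that annihilated with a
# same-origin partner, and (3) currently residing on the inner wall. The
# remaining diagonal/cross predicates mirror this construction by symmetry
# (`reconstructed = TRUE` in their metadata).

obs_table <- list(
  abs_inner_diag = list(origin = 1L, current = 1L, min_ann = 0L,
                        same_origin = FALSE, reconstructed = FALSE),
  abs_outer_diag = list(origin = 2L, current = 2L, min_ann = 0L,
                        same_origin = FALSE, reconstructed = TRUE),
  abs_cross_oi   = list(origin = 2L, current = 1L, min_ann = 0L,
                        same_origin = FALSE, reconstructed = FALSE),
  eei_inner_diag = list(origin = 1L, current = 1L, min_ann = 1L,
                        same_origin = TRUE, reconstructed = FALSE),
  eei_outer_diag = list(origin = 2L, current = 2L, min_ann = 1L,
                        same_origin = TRUE, reconstructed = TRUE),
  eei_cross_oi   = list(origin = 2L, current = 1L, min_ann = 1L,
                        same_origin = TRUE, reconstructed = FALSE)
)

#' Observable identifiers
#'
#' The six simulated counterparts of the 2D peak transients plus per-wall
#' and total alive-exciton counts.
#'
#' @return Character vector of row names used in count matrices.
#' @export
observable_ids <- function() {
  c(names(obs_table), "alive_inner", "alive_outer", "alive_total")
}

#' Observable predicate
#'
#' @param id One of the six peak observables, e.g. `"eei_cross_oi"`
#'   (the 2w_outer -> w_inner EEI cross peak).
#' @return A list with the origin-wall and current-wall constraints, the
#'   minimum number of annihilation events, whether a same-origin partner is
#'   required, and whether the predicate is a symmetry reconstruction.
#' @export
obs_predicate <- function(id) {
  if (!id %in% names(obs_table)) stop("unknown observable_id: ", id)
  c(list(observable_id = id), obs_table[[id]])
}

# Count all observables from the raw per-exciton sampling matrices of one
# realization (origin = per-exciton origin wall index).
count_all <- function(raw, origin) {
  alive <- raw$alive == 1L
  nt <- ncol(alive)
  counts <- matrix(0L, nrow = length(observable_ids()), ncol = nt,
                   dimnames = list(observable_ids(), NULL))
  for (id in names(obs_table)) {
    p <- obs_table[[id]]
    m <- alive & (origin == p$origin) & (raw$layer == p$current)
    if (p$same_origin) {
      m <- m & (raw$n_ann_same_origin >= 1L)
    } else if (p$min_ann > 0L) {
      m <- m & (raw$n_ann_total >= p$min_ann)
    }
    counts[id, ] <- colSums(m)
  }
  counts["alive_inner", ] <- colSums(alive & raw$layer == 1L)
  counts["alive_outer", ] <- colSums(alive & raw$layer == 2L)
  counts["alive_total", ] <- colSums(alive)
  counts
}

#' Count excitons matching a predicate at one waiting time
#'
#' @param realization A [run_realization()] result.
#' @param predicate An [obs_predicate()].
#' @param t_ps Waiting time in ps; must be one of the sampled times.
#' @return Integer count of alive excitons satisfying the origin-wall,
#'   current-wall, annihilation-count and partner-origin constraints.
#' @export
count_matching <- function(realization, predicate, t_ps) {
  stopifnot(inherits(realization, "kmc_realization"))
  it <- which(abs(realization$times_ps - t_ps) < 1e-9)
  if (length(it) != 1L) stop("t_ps = ", t_ps, " is not a sampled time")
  unname(realization$counts[predicate$observable_id, it])
}

#' Ensemble-averaged transient of one observable
#'
#' @param ensemble A [run_ensemble()] result.
#' @param observable An observable id (see [observable_ids()]) or an
#'   [obs_predicate()].
#' @return A `transient_series`: data frame with `time_ps`, `value`
#'   (ensemble mean count) and `sem` (standard error over realizations),
#'   with metadata (observable, density, n_real, seed) in attributes.
#' @export
transient <- function(ensemble, observable) {
  stopifnot(inherits(ensemble, "kmc_ensemble"))
  id <- if (is.list(observable)) observable$observable_id else observable
  if (!id %in% rownames(ensemble$counts)) stop("unknown observable_id: ", id)
  n_real <- dim(ensemble$counts)[3]
  if (n_real < 1L) stop("empty ensemble")
  x <- matrix(ensemble$counts[id, , ], nrow = length(ensemble$times_ps))
  transient_series(
    time_ps = ensemble$times_ps,
    value = rowMeans(x),
    sem = if (n_real == 1L) rep(0, nrow(x)) else
      apply(x, 1L, sd) / sqrt(n_real),
    meta = list(observable_id = id, density = ensemble$params$density,
                n_real = n_real, seed = ensemble$params$seed,
                params_hash = params_hash(ensemble$params)))
}

#' Construct a transient series
#'
#' @param time_ps Strictly increasing waiting times in ps.
#' @param value Ensemble-mean counts (optionally scaled).
#' @param sem Non-negative standard errors.
#' @param meta Named list of metadata (observable_id, density, seed, ...).
#' @return A data frame of class `transient_series`.
#' @export
transient_series <- function(time_ps, value, sem = rep(0, length(value)),
                             meta = list()) {
  stopifnot(length(time_ps) == length(value), length(sem) == length(value),
            all(diff(time_ps) > 0), all(sem >= 0))
  structure(data.frame(time_ps = time_ps, value = value, sem = sem),
            meta = meta, class = c("transient_series", "data.frame"))
}

#' Mean-square displacement of an annihilation-free walk
#'
#' Ensemble-averaged squared displacement from the planting site, using
#' unwrapped (cumulative) displacements so that periodic images do not fold
#' the walk back. Requires a run with annihilation disabled (`ann_radius =
#' 0`); decay should also be off (`lifetime_ps = Inf`) so every exciton
#' contributes at all times.
#'
#' @param ensemble A [run_ensemble()] result generated with `ann_radius = 0`.
#' @return Data frame with `tau_ps` and `msd_nm2`.
#' @export
msd_series <- function(ensemble) {
  stopifnot(inherits(ensemble, "kmc_ensemble"))
  if (any(ensemble$params$ann_radius > 0)) {
    stop("msd_series requires an annihilation-free run (ann_radius = 0)")
  }
  a <- ensemble$system$layers[[1]]$lattice_const
  data.frame(tau_ps = ensemble$times_ps,
             msd_nm2 = colMeans(ensemble$msd_lattice) * a^2)
}

#' Diffusion constant from the MSD relation
#'
#' Least-squares fit of `<x^2> = 4 D tau` (slope/4), excluding tau = 0 from
#' the fit window. For the random walk itself the closed form is
#' `D = H a^2 / (4 dt)`: 0.04/fs and a = 0.74 nm give 5.476 nm^2/ps.
#'
#' @param msd Data frame from [msd_series()] (>= 10 points).
#' @param lattice_const Lattice constant in nm, to also report `D / a^2`
#'   in molecular units ("molecules per ps", i.e. squared lattice sites
#'   per ps).
#' @return List with `D_nm2_ps`, `D_mol_ps`, `r_squared` and the `fit`.
#' @export
diffusion_constant <- function(msd, lattice_const = 0.74) {
  stopifnot(nrow(msd) >= 10L)
  w <- msd$tau_ps > 0
  fit <- lm(msd_nm2 ~ tau_ps, data = msd[w, ])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.na(r2) && r2 < 0.99) {
    warning("MSD is not linear in tau (R^2 = ", signif(r2, 3), ")")
  }
  D <- unname(coef(fit)["tau_ps"]) / 4
  list(D_nm2_ps = D, D_mol_ps = D / lattice_const^2, r_squared = r2,
       fit = fit)
}

#' Inter-wall exciton transfer efficiency
#'
#' Fraction of excitons planted on the outer wall whose terminal event
#' (natural decay or annihilation-deletion) occurred while residing on the
#' inner wall; excitons censored at the horizon are counted by their wall at
#' that time. In the low-density limit this converges to the equilibrium
#' occupancy `k_oi / (k_io + k_oi)` (~0.70 for the measured rates).
#'
#' @param x A [run_ensemble()] result from a double-wall run (to a terminal
#'   horizon of at least ~10 lifetimes), or its `records` data frame.
#' @return List with `efficiency`, its binomial `sem`, and `n` (number of
#'   outer-origin excitons).
#' @export
transfer_efficiency <- function(x) {
  records <- if (inherits(x, "kmc_ensemble")) {
    if (x$system$kind != "double") {
      stop("transfer efficiency requires a double-wall system")
    }
    x$records
  } else x
  out <- records[records$origin_layer == "outer", ]
  if (nrow(out) == 0L) stop("no outer-origin excitons in records")
  p <- mean(out$terminal_layer == "inner")
  list(efficiency = p, sem = sqrt(p * (1 - p) / nrow(out)), n = nrow(out))
}

#' Transfer efficiency versus linear exciton density
#'
#' Runs a double-wall ensemble to the terminal horizon at each density and
#' reports the efficiency against excitons per nm of tube length,
#' `(N_e_inner + N_e_outer) / (n_axial * a)`.
#'
#' @param system A [double_wall_system()].
#' @param params Base [sim_params()]; `density` is replaced per grid point.
#' @param densities Molecules-per-exciton values to sweep.
#' @return Data frame with `density`, `linear_density_nm1`, `efficiency`,
#'   `sem`.
#' @export
efficiency_curve <- function(system, params, densities) {
  stopifnot(system$kind == "double")
  rows <- lapply(seq_along(densities), function(k) {
    p <- params
    p$density <- densities[k]
    p$seed <- params$seed + k
    ens <- run_ensemble(system, p,
                        sampling_times_ps = c(0, p$t_max_ps))
    eff <- transfer_efficiency(ens)
    ne <- sum(exciton_count(system, p))
    spec <- system$layers$inner
    data.frame(density = densities[k],
               linear_density_nm1 = ne / (spec$n_axial * spec$lattice_const),
               efficiency = eff$efficiency, sem = eff$sem)
  })
  do.call(rbind, rows)
}

#' Waiting time of the transient maximum
#'
#' Argmax refined by a three-point parabola through the discrete maximum and
#' its neighbours (robust on log-spaced waiting-time grids); returns 0 when
#' the maximum is the first sample.
#'
#' @param series A [transient_series()] with at least 5 points.
#' @return Peak time in ps.
#' @export
peak_time <- function(series) {
  stopifnot(nrow(series) >= 5L)
  y <- series$value
  t <- series$time_ps
  if (all(y == 0)) stop("all-zero series has no peak")
  k <- which.max(y)
  if (k == 1L) return(0)
  if (k == length(y)) return(t[k])
  tt <- t[(k - 1):(k + 1)]
  yy <- y[(k - 1):(k + 1)]
  qf <- lm(yy ~ tt + I(tt^2))
  a2 <- coef(qf)[["I(tt^2)"]]
  if (!is.finite(a2) || a2 >= 0) return(t[k])  # degenerate: no curvature
  vertex <- -coef(qf)[["tt"]] / (2 * a2)
  min(max(vertex, tt[1]), tt[3])
}

#' Fraction of annihilation participants with multiple events
#'
#' Among excitons involved in at least one annihilation event, the fraction
#' that participated in two or more (sequential multi-exciton annihilation).
#' The alternative normalisation by all planted excitons is reported in the
#' metadata since "the excitons" admits either denominator.
#'
#' @param records A records data frame (or [run_ensemble()] result).
#' @return Fraction, with attributes `n_participants`, `n_planted` and
#'   `fraction_of_planted`.
#' @export
multi_annihilation_fraction <- function(records) {
  if (inherits(records, "kmc_ensemble")) records <- records$records
  part <- records$n_ann_total >= 1L
  multi <- records$n_ann_total >= 2L
  f <- if (any(part)) sum(multi) / sum(part) else 0
  structure(f, n_participants = sum(part), n_planted = nrow(records),
            fraction_of_planted = sum(multi) / nrow(records))
}
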