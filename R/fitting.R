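# Global fit of fluence-series transient bundles: exactly two free physics
# parameters (hopping probability H and annihilation radius R0) shared by
# all densities, plus one amplitude scale factor per signal class (one for
# all absorptive series, one for all EEI series), enforcing the constraint
# that a single scaling factor relates simulation counts to measured
# amplitudes across the whole fluence series.

#' Bundle of per-fluence transients
#'
#' @param entries List of entries `list(density =, observable_id =,
#'   series = transient_series)`.
#' @param kind `"single"` or `"double"` wall system that produced the data.
#' @return Object of class `experiment_bundle`.
#' @export
experiment_bundle <- function(entries, kind = c("single", "double")) {
  kind <- match.arg(kind)
  stopifnot(length(entries) >= 1L)
  for (e in entries) {
    stopifnot(is.numeric(e$density), e$observable_id %in% names(obs_table),
              inherits(e$series, "transient_series"))
  }
  dens <- unique(vapply(entries, `[[`, numeric(1), "density"))
  cls <- vapply(entries, function(e) obs_class(e$observable_id), character(1))
  for (d in dens) {
    at_d <- cls[vapply(entries, function(e) e$density == d, logical(1))]
    if (!all(c("abs", "eei") %in% at_d)) {
      stop("each density needs at least one absorptive and one EEI series")
    }
  }
  structure(list(entries = entries, kind = kind, densities = sort(dens)),
            class = "experiment_bundle")
}

obs_class <- function(id) if (startsWith(id, "abs")) "abs" else "eei"

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("<experiment_bundle> %s wall, %d series over densities %s\n",
              x$kind, length(x$entries),
              paste(x$densities, collapse = ", ")))
  invisible(x)
}

# Interpolate a model series onto data times, linear in log-time (the
# waiting-time grids are log-sampled); zero is handled by a small offset of
# half the first positive model time.
interp_log_time <- function(model, times_ps) {
  if (length(model$time_ps) == length(times_ps) &&
      all(abs(model$time_ps - times_ps) < 1e-9)) {
    return(model$value)
  }
  pos <- model$time_ps[model$time_ps > 0]
  off <- if (length(pos)) min(pos) / 2 else 1
  approx(log(model$time_ps + off), model$value, xout = log(times_ps + off),
         rule = 2)$y
}

#' Weighted least-squares amplitude scale between model and data
#'
#' Closed form `s = sum(w m d) / sum(w m^2)` with weights `w = 1/sem^2`
#' (unit weights where the data carry no uncertainties); the model is
#' interpolated to the data times linearly in log-time.
#'
#' @param model,data [transient_series()] objects.
#' @return Scalar scale factor.
#' @export
amplitude_scale <- function(model, data) {
  m <- interp_log_time(model, data$time_ps)
  if (all(m == 0)) stop("all-zero model series cannot be scaled")
  w <- series_weights(data)
  sum(w * m * data$value) / sum(w * m^2)
}

series_weights <- function(data) {
  if (all(data$sem > 0)) 1 / data$sem^2 else rep(1, nrow(data))
}

forward_seed <- function(base, key) {
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147480009
  as.integer((base + h) %% (2^31 - 2) + 1)
}

# Forward-simulate the transients needed for one (H, R0, density[, factor])
# and cache the ensemble; the forward model does not depend on the data, so
# a cache can be shared across fits.
forward_ensemble <- function(hop_prob, ann_radius, density, times_ps,
                             sim_config, forward_cache = NULL) {
  key <- sprintf("H%.8g_R%.8g_d%.8g_n%d_t%.6g", hop_prob, ann_radius,
                 density, sim_config$n_real, max(times_ps))
  if (!is.null(forward_cache) && !is.null(forward_cache[[key]])) {
    return(forward_cache[[key]])
  }
  p <- sim_config$params
  p$hop_prob <- rep_len(hop_prob, 2L)
  p$ann_radius <- rep_len(ann_radius, 2L)
  p$density <- density
  p$n_real <- sim_config$n_real
  p$t_max_ps <- max(times_ps)
  p$seed <- forward_seed(sim_config$seed, key)
  ens <- run_ensemble(sim_config$system, p, sampling_times_ps = times_ps)
  if (!is.null(forward_cache)) forward_cache[[key]] <- ens
  ens
}

#' Goodness of fit of one parameter pair against a bundle
#'
#' Noise-weighted sum of squared errors over all series of the bundle, with
#' the absorptive scale fitted jointly on all absorptive series and the EEI
#' scale on all EEI series (two scalars total). Densities in the bundle are
#' forward-simulated with the shared `(H, R0)`; optional per-density
#' multiplicative density adjustments (within experimental uncertainty) can
#' be supplied and the best combination is used.
#'
#' @param hop_prob,ann_radius The two free physics parameters.
#' @param bundle An [experiment_bundle()].
#' @param sim_config List with `system` (tube system matching
#'   `bundle$kind`), `params` (template [sim_params()]), `n_real`, `seed`.
#' @param density_factors Multiplicative factors tried per density
#'   (default 1: nominal densities).
#' @param forward_cache Optional environment for memoising forward runs.
#' @return List: `objective`, `scale_abs`, `scale_eei`,
#'   `density_adjustments`.
#' @export
fit_objective <- function(hop_prob, ann_radius, bundle, sim_config,
                          density_factors = 1, forward_cache = NULL) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  if (sim_config$system$kind != bundle$kind) {
    stop("sim_config system kind does not match the bundle")
  }
  dens <- bundle$densities
  # model values for every entry under every density factor
  model_vals <- list()
  for (d in dens) {
    idx <- which(vapply(bundle$entries, function(e) e$density == d,
                        logical(1)))
    times <- sort(unique(unlist(
      lapply(bundle$entries[idx], function(e) e$series$time_ps))))
    for (f in density_factors) {
      ens <- forward_ensemble(hop_prob, ann_radius, d * f, times,
                              sim_config, forward_cache)
      for (i in idx) {
        e <- bundle$entries[[i]]
        mod <- transient(ens, e$observable_id)
        model_vals[[paste(i, f)]] <- interp_log_time(mod, e$series$time_ps)
      }
    }
  }
  combos <- expand.grid(rep(list(density_factors), length(dens)))
  best <- NULL
  for (ci in seq_len(nrow(combos))) {
    fac <- as.numeric(combos[ci, ])
    num <- c(abs = 0, eei = 0); den <- c(abs = 0, eei = 0)
    rows <- vector("list", length(bundle$entries))
    for (i in seq_along(bundle$entries)) {
      e <- bundle$entries[[i]]
      f <- fac[match(e$density, dens)]
      m <- model_vals[[paste(i, f)]]
      w <- series_weights(e$series)
      cl <- obs_class(e$observable_id)
      num[cl] <- num[cl] + sum(w * m * e$series$value)
      den[cl] <- den[cl] + sum(w * m^2)
      rows[[i]] <- list(m = m, w = w, cl = cl)
    }
    s <- ifelse(den > 0, num / den, 0)
    obj <- 0
    for (i in seq_along(bundle$entries)) {
      r <- rows[[i]]
      obj <- obj +
        sum(r$w * (bundle$entries[[i]]$series$value - s[r$cl] * r$m)^2)
    }
    if (is.null(best) || obj < best$objective) {
      best <- list(objective = obj, scale_abs = unname(s["abs"]),
                   scale_eei = unname(s["eei"]),
                   density_adjustments = setNames(fac, dens))
    }
  }
  best
}

#' Exhaustive grid fit of hopping probability and annihilation radius
#'
#' Evaluates [fit_objective()] on the full `hop_grid` x `r0_grid` and
#' returns the minimising pair together with the complete objective
#' surface. The grid search is deliberate: the Monte Carlo objective is
#' noisy, so gradient methods are avoided and the result is reproducible
#' for a given seed.
#'
#' @inheritParams fit_objective
#' @param hop_grid Candidate hopping probabilities (per 1 fs step).
#' @param r0_grid Candidate annihilation radii (lattice units).
#' @return Object of class `fit_result`: `hop_prob`, `ann_radius`,
#'   `scale_abs`, `scale_eei`, `objective`, `density_adjustments`,
#'   `surface` (data frame hop_prob, ann_radius, objective), `seed`.
#' @export
grid_fit <- function(bundle, sim_config, hop_grid = c(0.01, 0.02, 0.04, 0.08),
                     r0_grid = 1:6, density_factors = 1,
                     forward_cache = NULL) {
  stopifnot(length(hop_grid) >= 1L, length(r0_grid) >= 1L)
  npts <- vapply(bundle$entries, function(e) nrow(e$series), integer(1))
  if (all(npts < 2L)) stop("degenerate bundle: single-time-point series")
  if (is.null(forward_cache)) forward_cache <- new.env(parent = emptyenv())
  surface <- expand.grid(hop_prob = hop_grid, ann_radius = r0_grid)
  surface$objective <- NA_real_
  best <- NULL
  for (g in seq_len(nrow(surface))) {
    res <- fit_objective(surface$hop_prob[g], surface$ann_radius[g], bundle,
                         sim_config, density_factors, forward_cache)
    surface$objective[g] <- res$objective
    if (is.null(best) || res$objective < best$objective) {
      best <- c(res, list(hop_prob = surface$hop_prob[g],
                          ann_radius = surface$ann_radius[g]))
    }
  }
  structure(list(hop_prob = best$hop_prob, ann_radius = best$ann_radius,
                 scale_abs = best$scale_abs, scale_eei = best$scale_eei,
                 objective = best$objective,
                 density_adjustments = best$density_adjustments,
                 surface = surface, seed = sim_config$seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(paste0("<fit_result> H = %g per step, R0 = %g molecules",
                     " (objective %.4g)\n"),
              x$hop_prob, x$ann_radius, x$objective))
  cat(sprintf("  scales: abs %.4g, eei %.4g\n", x$scale_abs, x$scale_eei))
  invisible(x)
}
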