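test_that("predicates implement the cross-peak prerequisites", {
  p <- obs_predicate("eei_cross_oi")
  expect_equal(p$origin, 2L)     # planted on the outer wall
  expect_equal(p$current, 1L)    # residing on the inner wall
  expect_true(p$same_origin)     # annihilated with a same-origin partner
  expect_error(obs_predicate("nope"), "unknown")
  expect_true(obs_predicate("abs_outer_diag")$reconstructed)
})

test_that("count_matching reproduces the collision fixture", {
  fx <- toy_fixture("two_exciton_collision")
  r <- run_realization(fx$system, fx$params, sampling_times_ps = c(0, 0.5),
                       positions = fx$positions)
  expect_equal(count_matching(r, obs_predicate("eei_inner_diag"), 0),
               fx$expected$eei_count_t0)
  expect_equal(count_matching(r, obs_predicate("abs_inner_diag"), 0),
               fx$expected$abs_count_t0)
  expect_error(count_matching(r, obs_predicate("abs_inner_diag"), 0.123),
               "not a sampled time")
})

test_that("EEI counts are zero without sub-radius encounters", {
  sys <- single_wall_system(30, 100)
  p <- sim_params(hop_prob = 0, lifetime_ps = Inf, ann_radius = 3,
                  k_io = 0, k_oi = 0, density = 10)
  st_pos <- list(inner = rbind(c(0L, 10L), c(0L, 50L), c(15L, 80L)))
  r <- run_realization(sys, p, sampling_times_ps = c(0, 0.2),
                       positions = st_pos)
  expect_equal(unname(r$counts["eei_inner_diag", ]), c(0L, 0L))
  # R0 = 0 never produces EEI counts
  p0 <- sim_params(hop_prob = 0.1, lifetime_ps = Inf, ann_radius = 0,
                   k_io = 0, k_oi = 0, density = 10, t_max_ps = 2)
  r0 <- run_realization(sys, p0, sampling_times_ps = c(0, 1, 2), seed = 2)
  expect_true(all(r0$counts["eei_inner_diag", ] == 0))
})

test_that("absorptive series dominate EEI series pointwise", {
  sys <- double_wall_system(30, 55, 150)
  p <- nanotube_params(density = 40, t_max_ps = 5, n_real = 4, seed = 19)
  ens <- run_ensemble(sys, p, sampling_times_ps = c(0, 0.5, 1, 2, 5))
  for (k in seq_len(dim(ens$counts)[3])) {
    expect_true(all(ens$counts["eei_inner_diag", , k] <=
                      ens$counts["abs_inner_diag", , k]))
    expect_true(all(ens$counts["eei_outer_diag", , k] <=
                      ens$counts["abs_outer_diag", , k]))
    expect_true(all(ens$counts["eei_cross_oi", , k] <=
                      ens$counts["abs_cross_oi", , k]))
    expect_true(all(ens$counts["alive_total", , k] >=
                      ens$counts["abs_inner_diag", , k]))
  }
  tr_abs <- transient(ens, "abs_cross_oi")
  tr_eei <- transient(ens, "eei_cross_oi")
  expect_true(all(tr_eei$value <= tr_abs$value))
  expect_true(all(tr_abs$sem >= 0))
})

test_that("single-realization transients carry zero SEM", {
  sys <- single_wall_system(20, 40)
  p <- sim_params(hop_prob = 0.04, lifetime_ps = 5, ann_radius = 0,
                  k_io = 0, k_oi = 0, density = 20, t_max_ps = 1,
                  n_real = 1, seed = 20)
  tr <- transient(run_ensemble(sys, p, c(0, 0.5, 1)), "abs_inner_diag")
  expect_true(all(tr$sem == 0))
})

test_that("MSD is linear, unwrapped, and yields the closed-form D", {
  sys <- single_wall_system(30, 200)
  p <- sim_params(hop_prob = 0.04, lifetime_ps = Inf, ann_radius = 0,
                  k_io = 0, k_oi = 0, density = 120, t_max_ps = 8,
                  n_real = 80, seed = 21)
  ens <- run_ensemble(sys, p, sampling_times_ps = seq(0, 8, 0.5))
  msd <- msd_series(ens)
  expect_equal(msd$msd_nm2[1], 0)
  dc <- diffusion_constant(msd)
  expect_gt(dc$r_squared, 0.999)
  # closed form D = H a^2 / (4 dt) = 5.476 nm^2/ps; walk extends far
  # beyond the 30-site circumference, so folding would cap the MSD
  expect_equal(dc$D_nm2_ps, 1000 * 0.04 * 0.74^2 / 4, tolerance = 0.06)
  expect_equal(dc$D_mol_ps, dc$D_nm2_ps / 0.74^2)
  # frozen walk: identically zero
  pf <- sim_params(hop_prob = 0, lifetime_ps = Inf, ann_radius = 0,
                   k_io = 0, k_oi = 0, density = 120, t_max_ps = 1)
  mf <- msd_series(run_ensemble(sys, pf, c(0, 0.5, 1)))
  expect_true(all(mf$msd_nm2 == 0))
  # annihilation-enabled runs are rejected
  pa <- sim_params(hop_prob = 0.04, lifetime_ps = Inf, ann_radius = 3,
                   k_io = 0, k_oi = 0, density = 120, t_max_ps = 1)
  expect_error(msd_series(run_ensemble(sys, pa, c(0, 1))),
               "annihilation-free")
})

test_that("diffusion constant recovers a synthetic slope exactly", {
  tau <- seq(0, 10, length.out = 21)
  msd <- data.frame(tau_ps = tau, msd_nm2 = 4 * 2.5 * tau)
  expect_equal(diffusion_constant(msd)$D_nm2_ps, 2.5, tolerance = 1e-12)
})

test_that("doubling the hop probability doubles the diffusion constant", {
  sys <- single_wall_system(30, 200)
  est <- vapply(c(0.02, 0.04), function(H) {
    p <- sim_params(hop_prob = H, lifetime_ps = Inf, ann_radius = 0,
                    k_io = 0, k_oi = 0, density = 200, t_max_ps = 5,
                    n_real = 40, seed = 22)
    diffusion_constant(msd_series(
      run_ensemble(sys, p, seq(0, 5, 0.5))))$D_nm2_ps
  }, numeric(1))
  expect_equal(est[2] / est[1], 2, tolerance = 0.15)
})

test_that("transfer efficiency has the correct limits", {
  sys <- double_wall_system(12, 22, 60)
  # no transfer: no outer exciton ever terminates on the inner wall
  p0 <- sim_params(hop_prob = 0.04, lifetime_ps = 2, ann_radius = 0,
                   k_io = 0, k_oi = 0, density = 30, t_max_ps = 20,
                   n_real = 5, seed = 23)
  expect_equal(transfer_efficiency(
    run_ensemble(sys, p0, c(0, 20)))$efficiency, 0)
  # symmetric fast transfer, no annihilation: one half
  ps <- sim_params(hop_prob = 0.04, lifetime_ps = 5, ann_radius = 0,
                   k_io = 0.02, k_oi = 0.02, density = 30, t_max_ps = 50,
                   n_real = 30, seed = 24)
  eff <- transfer_efficiency(run_ensemble(sys, ps, c(0, 50)))
  expect_equal(eff$efficiency, 0.5, tolerance = 4 * eff$sem + 0.02)
  # single-wall systems are rejected
  p1 <- sim_params(density = 30, t_max_ps = 1)
  expect_error(
    transfer_efficiency(run_ensemble(single_wall_system(12, 60), p1,
                                     c(0, 1))),
    "double-wall")
})

test_that("transfer efficiency is invariant under axial translation", {
  sys <- double_wall_system(12, 22, 60)
  p <- sim_params(hop_prob = 0.04, lifetime_ps = 2, ann_radius = 0,
                  density = 120, t_max_ps = 20, n_real = 10, seed = 25)
  st <- plant_excitons(sys, p, seed = 1)
  base <- state_snapshot(st)
  shift <- lapply(split(base, base$layer), function(df) {
    cbind(as.integer(df$i), as.integer((df$j + 17L) %% 60L))
  })
  # same seed, translated initial condition: identical efficiency
  run_eff <- function(pos) {
    r <- run_realization(sys, p, c(0, 20), seed = 99,
                         positions = list(inner = pos$inner,
                                          outer = pos$outer))
    transfer_efficiency_records <- r$records
    mean(transfer_efficiency_records$terminal_layer[
      transfer_efficiency_records$origin_layer == "outer"] == "inner")
  }
  pos0 <- lapply(split(base, base$layer), function(df) {
    cbind(as.integer(df$i), as.integer(df$j))
  })
  expect_equal(run_eff(pos0), run_eff(shift))
})

test_that("efficiency curve reports linear density and is consistent", {
  sys <- double_wall_system(12, 22, 60)
  p <- sim_params(hop_prob = 0.04, lifetime_ps = 2, ann_radius = 2,
                  density = 50, t_max_ps = 20, n_real = 8, seed = 26)
  cur <- efficiency_curve(sys, p, densities = c(5, 200))
  ne5 <- sum(exciton_count(sys, modifyList(p, list(density = 5))))
  expect_equal(cur$linear_density_nm1[1], ne5 / (60 * 0.74))
  expect_true(all(diff(cur$linear_density_nm1) < 0))
  # high annihilation load reduces the efficiency
  expect_lt(cur$efficiency[1], cur$efficiency[2])
})

test_that("peak_time locates maxima on noisy log grids", {
  t <- sampling_times(30, 40)
  bump <- exp(-(log(t + 0.05) - log(6))^2 / 0.5)
  s <- transient_series(t, bump)
  expect_lt(abs(peak_time(s) - 6), diff(range(t[t > 4 & t < 9])) / 4)
  dec <- transient_series(t, exp(-t))
  expect_equal(peak_time(dec), 0)
  expect_error(peak_time(transient_series(t, rep(0, length(t)))),
               "all-zero")
})

test_that("multi-annihilation fraction uses participants as denominator", {
  sys <- single_wall_system(30, 100)
  p <- sim_params(hop_prob = 0, lifetime_ps = Inf, ann_radius = 3,
                  k_io = 0, k_oi = 0, density = 10)
  # no events
  r0 <- run_realization(sys, p, c(0, 0.1),
                        positions = list(inner = rbind(c(0L, 10L),
                                                       c(0L, 50L))))
  expect_equal(as.numeric(multi_annihilation_fraction(r0$records)), 0)
  # one pair, one event: no exciton reaches two events
  r1 <- run_realization(sys, p, c(0, 0.1),
                        positions = list(inner = rbind(c(0L, 10L),
                                                       c(0L, 12L))))
  f1 <- multi_annihilation_fraction(r1$records)
  expect_equal(as.numeric(f1), 0)
  expect_equal(attr(f1, "n_participants"), 2L)
  # three-exciton cluster: three participants, two events
  r3 <- run_realization(sys, p, c(0, 0.1),
                        positions = list(inner = rbind(c(0L, 10L),
                                                       c(0L, 12L),
                                                       c(2L, 11L))))
  f3 <- multi_annihilation_fraction(r3$records)
  expect_equal(attr(f3, "n_participants"), 3L)
  expect_true(as.numeric(f3) %in% c(0, 1 / 3))
  expect_equal(attr(f3, "fraction_of_planted") * 3,
               as.numeric(f3) * 3)
})
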