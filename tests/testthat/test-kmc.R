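# Stochastic engine behaviour on small systems with analytically known
# outcomes.

test_that("planting places the rounded count on distinct sites", {
  sys <- single_wall_system(30, 1000)
  expect_equal(unname(exciton_count(sys, sim_params(density = 30000))), 1L)
  p <- sim_params(density = 20, ann_radius = 0, lifetime_ps = Inf,
                  k_io = 0, k_oi = 0)
  st <- plant_excitons(sys, p, seed = 3)
  snap <- state_snapshot(st)
  expect_equal(nrow(snap), 1500L)
  expect_equal(anyDuplicated(snap[, c("i", "j")]), 0L)
  occ <- excitube:::cpp_kmc_occupancy(st$ptr, 1L)
  expect_lte(max(occ), 1L)
  # density = 1 fills every site
  sys_small <- single_wall_system(5, 6)
  st2 <- plant_excitons(sys_small, sim_params(density = 1, ann_radius = 0,
                                              lifetime_ps = Inf,
                                              k_io = 0, k_oi = 0), seed = 4)
  expect_equal(nrow(state_snapshot(st2)), 30L)
  expect_error(sim_params(density = 0.5), "density")
})

test_that("frozen dynamics leave positions invariant", {
  sys <- single_wall_system(20, 20)
  p <- sim_params(hop_prob = 0, lifetime_ps = Inf, ann_radius = 0,
                  k_io = 0, k_oi = 0, density = 4)
  st <- plant_excitons(sys, p, seed = 5)
  before <- state_snapshot(st)
  advance_step(st, 200)
  after <- state_snapshot(st)
  expect_identical(before[, c("i", "j")], after[, c("i", "j")])
  expect_true(all(after$status == "alive"))
})

test_that("H = 1 moves the exciton to a neighbour every step", {
  sys <- single_wall_system(50, 50)
  p <- sim_params(hop_prob = 1, lifetime_ps = Inf, ann_radius = 0,
                  k_io = 0, k_oi = 0, density = 2500)
  st <- plant_excitons(sys, p, seed = 6,
                       positions = list(inner = rbind(c(10L, 10L))))
  prev <- state_snapshot(st)
  for (k in 1:25) {
    advance_step(st)
    cur <- state_snapshot(st)
    moved <- abs(cur$disp_i - prev$disp_i) + abs(cur$disp_j - prev$disp_j)
    expect_equal(moved, 1)
    prev <- cur
  }
})

test_that("hop count statistics follow Binomial(n_steps, H)", {
  # E[squared displacement] after n steps equals n * H in lattice units
  sys <- single_wall_system(30, 1000)
  p <- sim_params(hop_prob = 0.04, lifetime_ps = Inf, ann_radius = 0,
                  k_io = 0, k_oi = 0, density = 150, t_max_ps = 1,
                  n_real = 30, seed = 7)
  ens <- run_ensemble(sys, p, sampling_times_ps = c(0, 1))
  msd_end <- mean(ens$msd_lattice[, 2])
  n_walkers <- sum(ens$n_planted) * p$n_real
  se <- sqrt(2 / n_walkers) * 40
  expect_lt(abs(msd_end - 1000 * 0.04), 4 * se)
})

test_that("pure decay produces exponential terminal times", {
  fx <- toy_fixture("pure_decay")
  ens <- run_ensemble(fx$system, fx$params,
                      sampling_times_ps = c(0, 1, 2, 5))
  rec <- ens$records
  expect_true(all(rec$status %in% c("decayed", "censored")))
  dec <- rec$terminal_time_ps[rec$status == "decayed"]
  # KS against the exponential truncated at the 5 ps horizon
  Fq <- function(q) (1 - exp(-q)) / (1 - exp(-5))
  ks <- suppressWarnings(stats::ks.test(dec, Fq))
  expect_gt(ks$p.value, 0.001)
  # alive fraction tracks exp(-t/tau)
  tr <- transient(ens, "abs_inner_diag")
  n0 <- tr$value[1]
  for (k in 2:4) {
    expect_lt(abs(tr$value[k] / n0 - exp(-tr$time_ps[k])),
              4 * sqrt(exp(-tr$time_ps[k]) / (n0 * fx$params$n_real)) + 0.01)
  }
})

test_that("annihilation sweep enforces the strict radius condition", {
  sys <- single_wall_system(30, 100)
  p <- sim_params(hop_prob = 0, lifetime_ps = Inf, ann_radius = 3,
                  k_io = 0, k_oi = 0, density = 10)
  # distance 2 < R0: one of the pair is deleted at t = 0
  st <- plant_excitons(sys, p, seed = 8,
                       positions = list(inner = rbind(c(0L, 10L), c(0L, 12L))))
  snap <- state_snapshot(st)
  expect_equal(sum(snap$status == "alive"), 1L)
  expect_equal(sum(snap$status == "annihilated"), 1L)
  expect_equal(snap$n_ann_survived[snap$status == "alive"], 1L)
  expect_true(all(snap$partner_same_origin))
  # distance exactly 3: no event
  st2 <- plant_excitons(sys, p, seed = 9,
                        positions = list(inner = rbind(c(0L, 10L), c(0L, 13L))))
  expect_equal(sum(state_snapshot(st2)$status == "alive"), 2L)
})

test_that("clustered excitons are resolved within one sweep", {
  sys <- single_wall_system(30, 100)
  p <- sim_params(hop_prob = 0, lifetime_ps = Inf, ann_radius = 3,
                  k_io = 0, k_oi = 0, density = 10)
  for (seed in 1:10) {
    st <- plant_excitons(sys, p, seed = seed,
                         positions = list(inner = rbind(c(0L, 10L),
                                                        c(0L, 12L),
                                                        c(2L, 11L))))
    snap <- state_snapshot(st)
    expect_equal(sum(snap$status == "annihilated"), 2L)
    expect_equal(sum(snap$status == "alive"), 1L)
    # two events, each with two participants
    expect_equal(sum(snap$n_ann_total), 4L)
    expect_gte(snap$n_ann_survived[snap$status == "alive"], 1L)
    # no surviving pair below the radius (trivially: one survivor)
  }
})

test_that("no same-layer alive pair remains within R0 after any sweep", {
  sys <- single_wall_system(30, 60)
  p <- sim_params(hop_prob = 0.2, lifetime_ps = Inf, ann_radius = 3,
                  k_io = 0, k_oi = 0, density = 15)
  st <- plant_excitons(sys, p, seed = 11)
  spec <- sys$layers$inner
  check_pairs <- function(snap) {
    al <- snap[snap$status == "alive", ]
    if (nrow(al) < 2) return(invisible())
    for (a in seq_len(nrow(al) - 1)) {
      for (b in (a + 1):nrow(al)) {
        d <- min_image_distance(site_address("inner", al$i[a], al$j[a]),
                                site_address("inner", al$i[b], al$j[b]),
                                spec)
        expect_gte(d, 3)
      }
    }
  }
  check_pairs(state_snapshot(st))
  for (k in 1:5) {
    advance_step(st, 20)
    check_pairs(state_snapshot(st))
  }
})

test_that("exciton count is conserved against the terminal records", {
  sys <- single_wall_system(30, 200)
  p <- sim_params(hop_prob = 0.04, lifetime_ps = 5, ann_radius = 3,
                  k_io = 0, k_oi = 0, density = 40, t_max_ps = 10,
                  n_real = 1, seed = 12)
  r <- run_realization(sys, p, sampling_times_ps = c(0, 1, 2, 5, 10))
  planted <- nrow(r$records)
  for (k in seq_along(r$times_ps)) {
    gone <- sum(!is.na(r$records$terminal_time_ps) &
                  r$records$status != "censored" &
                  r$records$terminal_time_ps <= r$times_ps[k] + 1e-9)
    expect_equal(unname(r$counts["alive_total", k]), planted - gone)
  }
  # alive count is non-increasing
  expect_true(all(diff(r$counts["alive_total", ]) <= 0))
})

test_that("inter-layer transfer never creates double occupancy", {
  sys <- double_wall_system(12, 22, 40)
  p <- sim_params(hop_prob = 0, lifetime_ps = Inf, ann_radius = 0,
                  k_io = 0.05, k_oi = 0.05, density = 2)
  st <- plant_excitons(sys, p, seed = 13)
  advance_step(st, 300)
  expect_lte(max(excitube:::cpp_kmc_occupancy(st$ptr, 1L)), 1L)
  expect_lte(max(excitube:::cpp_kmc_occupancy(st$ptr, 2L)), 1L)
  # with transfer disabled, per-layer populations are conserved
  p0 <- sim_params(hop_prob = 0.1, lifetime_ps = Inf, ann_radius = 0,
                   k_io = 0, k_oi = 0, density = 10)
  st0 <- plant_excitons(sys, p0, seed = 14)
  n_before <- table(state_snapshot(st0)$layer)
  advance_step(st0, 200)
  snap <- state_snapshot(st0)
  expect_equal(table(snap$layer), n_before)
  expect_true(all(snap$layer == snap$origin_layer))
})

test_that("layer populations equilibrate to the detailed-balance ratio", {
  sys <- double_wall_system()
  p <- sim_params(hop_prob = 0.04, lifetime_ps = Inf, ann_radius = 0,
                  density = 1000, t_max_ps = 3, n_real = 8, seed = 15)
  ens <- run_ensemble(sys, p, sampling_times_ps = c(0, 2, 3))
  frac <- ens$counts["alive_inner", 2:3, ] / ens$counts["alive_total", 2:3, ]
  expect_equal(mean(frac), 0.0031 / (0.0013 + 0.0031),
               tolerance = 3 * sd(frac) / sqrt(length(frac)) + 0.01)
})

test_that("ensembles are reproducible and reduce to single realizations", {
  sys <- single_wall_system(20, 50)
  p <- sim_params(hop_prob = 0.04, lifetime_ps = 10, ann_radius = 3,
                  k_io = 0, k_oi = 0, density = 25, t_max_ps = 2,
                  n_real = 3, seed = 16)
  e1 <- run_ensemble(sys, p, sampling_times_ps = c(0, 1, 2))
  e2 <- run_ensemble(sys, p, sampling_times_ps = c(0, 1, 2))
  expect_identical(e1$counts, e2$counts)
  expect_identical(e1$records, e2$records)
  p1 <- p; p1$n_real <- 1L
  e3 <- run_ensemble(sys, p1, sampling_times_ps = c(0, 1, 2))
  r <- run_realization(sys, p1, sampling_times_ps = c(0, 1, 2),
                       seed = e3$seeds[1])
  expect_equal(e3$counts[, , 1], r$counts)
})

test_that("standard errors shrink with ensemble size", {
  sys <- single_wall_system(30, 100)
  base <- sim_params(hop_prob = 0.04, lifetime_ps = 5, ann_radius = 3,
                     k_io = 0, k_oi = 0, density = 30, t_max_ps = 3,
                     n_real = 12, seed = 17)
  big <- base; big$n_real <- 48L
  s1 <- transient(run_ensemble(sys, base, c(0, 1, 3)), "abs_inner_diag")$sem
  s2 <- transient(run_ensemble(sys, big, c(0, 1, 3)), "abs_inner_diag")$sem
  # fourfold realizations: SEM should shrink roughly twofold
  ratio <- mean(s2[-1] / s1[-1])
  expect_gt(ratio, 0.25)
  expect_lt(ratio, 0.9)
})

test_that("probability budget overruns are rejected", {
  expect_error(sim_params(hop_prob = 0.99, k_oi = 0.02), "budget")
  expect_error(sim_params(hop_prob = -0.1), "budget")
})

test_that("detailed-balance ratio matches the Boltzmann/DOS product", {
  expect_equal(detailed_balance_ratio(thermal_params(300, 200, 55 / 30)),
               exp(-1.5) * 55 / 30)
  expect_equal(round(detailed_balance_ratio(thermal_params()), 1), 0.4)
  expect_equal(detailed_balance_ratio(thermal_params(0, 200, 1)), 1)
})
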