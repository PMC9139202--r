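# Penalized Navier-Stokes solver: nondimensional numbers, projection
# contract, Poiseuille recovery, penalization limit, symmetry, pulsatility.

test_that("reynolds_number implements U D / nu", {
  expect_equal(reynolds_number(1, 1, 1), 1)
  expect_equal(reynolds_number(0.2, 4e-3, 3.25e-6), 246.1538, tolerance = 1e-6)
  expect_equal(reynolds_number(0.4, 4e-3, 3.25e-6),
               2 * reynolds_number(0.2, 4e-3, 3.25e-6))
  expect_error(reynolds_number(-1, 1, 1), class = "aneuflow_domain_error")
  expect_error(reynolds_number(1, 0, 1), class = "aneuflow_domain_error")
})

test_that("zero inlet forcing keeps the field exactly zero", {
  m <- channel_mask(16)
  cfg <- solver_config(reynolds = 10,
                       waveform = inlet_waveform(mean = 0, amplitude = 0))
  st <- init_flow(m, cfg)
  for (k in 1:5) st <- advance_flow(st)
  expect_identical(max(abs(st$u)), 0)
  expect_identical(max(abs(st$v)), 0)
})

test_that("the projection enforces machine-level fluid divergence every step", {
  m <- channel_mask(16)
  cfg <- solver_config(reynolds = 50)
  st <- init_flow(m, cfg)
  for (k in 1:60) {
    st <- advance_flow(st)
    expect_lt(max_fluid_divergence(st), 1e-10)
  }
  # also from a non-trivial developed state
  expect_lt(max(st$residual_history$max_div_fluid), 1e-10)
})

test_that("steady Poiseuille recovery: parabolic profile and mass balance", {
  st <- poiseuille_solution(32)
  expect_true(st$converged)
  cc <- cell_center_velocity(st)
  mid_i <- round(nrow(cc$x) * 0.75)
  prof <- cc$x[mid_i, ]
  # centerline 1.5x the mean inlet speed, within 2 percent
  expect_lt(abs(max(prof) / 1.5 - 1), 0.02)
  # full profile against the analytic parabola vanishing at the penalized
  # wall nodes: L-infinity error under 2 percent of the peak at 32 cells
  m <- st$mask
  h <- st$setup$h
  ylo <- m$meta$wall_lo / m$meta$diameter
  yhi <- m$meta$wall_hi / m$meta$diameter
  yc <- (seq_len(ncol(cc$x)) - 0.5) * h
  inside <- yc > ylo & yc < yhi
  para <- 1.5 * (1 - ((yc - (ylo + yhi) / 2) / ((yhi - ylo) / 2))^2)
  expect_lt(max(abs(prof[inside] - para[inside])) / 1.5, 0.02)
  # global mass balance to 1e-6 relative
  fl <- boundary_fluxes(st)
  expect_lt(abs(fl["inlet"] - fl["outlet"]) / abs(fl["inlet"]), 1e-6)
})

test_that("advancing a converged steady state changes it below tolerance", {
  st <- poiseuille_solution(32)
  st2 <- advance_flow(st)
  delta <- max(abs(st2$u - st$u), abs(st2$v - st$v)) / st2$dt
  expect_lt(delta / 1.5, 10 * st$config$steady_tol)
})

test_that("penalization limit: solid speed decays monotonically with eta", {
  speeds <- penalization_sweep()
  expect_true(all(diff(speeds) < 0))
  # decay consistent with the O(sqrt(eta)) error bound: per decade of eta the
  # speed drops at least sqrt(10)/4, and stays below the sqrt(eta) envelope
  per_decade <- (speeds[-3] / speeds[-1])^(1 / 2)  # adjacent pairs span 2 decades
  expect_true(all(per_decade >= sqrt(10) / 4))
  expect_true(all(speeds <= sqrt(c(1e-4, 1e-6, 1e-8))))
})

test_that("mirrored geometry yields the mirrored flow field", {
  h <- 4e-3 / 16
  top <- make_sidewall_aneurysm(aneurysm_params(sac_side = "top",
                                                vessel_length = 8e-3), h)
  bot <- make_sidewall_aneurysm(aneurysm_params(sac_side = "bottom",
                                                vessel_length = 8e-3), h)
  cfg <- solver_config(reynolds = 50, steady_tol = 1e-5, max_steps = 20000L)
  st_t <- solve_steady(top, cfg)
  st_b <- solve_steady(bot, cfg)
  ny <- ncol(st_t$u)
  expect_lt(max(abs(st_t$u - st_b$u[, ny:1])), 1e-8)
})

test_that("pulsatile runs are periodic and consistent with the steady limit", {
  m <- channel_mask(16)
  base <- solver_config(reynolds = 10, steady_tol = 1e-6)
  st_steady <- solve_steady(m, base)
  cfg <- solver_config(reynolds = 10,
                       waveform = inlet_waveform(1, amplitude = 0.3, period = 1))
  st <- solve_pulsatile(m, cfg, n_periods = 4L, n_phases = 6L)
  expect_length(st$snapshots, 6L)
  # phase-0 states of the last two periods agree (periodic attractor)
  expect_lt(max(abs(st$prev_phase0$u - st$snapshots[[1]]$u)) / 1.5, 2e-3)
  # vanishing amplitude reproduces the steady solution within 1 percent
  cfg_small <- solver_config(reynolds = 10,
                             waveform = inlet_waveform(1, 0.01, 1))
  st_small <- solve_pulsatile(m, cfg_small, n_periods = 3L, n_phases = 4L)
  phase_mean_u <- Reduce(`+`, lapply(st_small$snapshots, `[[`, "u")) / 4
  expect_lt(max(abs(phase_mean_u - st_steady$u)) / 1.5, 0.01)
  # period-averaged inlet flux equals the mean flux (sinusoid integrates out)
  fluxes <- sapply(st$snapshots, function(sn) sum(sn$u[1, ]) * st$setup$h)
  expect_lt(abs(mean(fluxes) / (sum(st_steady$u[1, ]) * st$setup$h) - 1), 0.05)
  # preconditions
  expect_error(solve_pulsatile(m, base), class = "aneuflow_usage_error")
  expect_error(solve_pulsatile(m, cfg, n_periods = 1L),
               class = "aneuflow_usage_error")
  expect_error(solve_steady(m, cfg), class = "aneuflow_usage_error")
})

test_that("a coarse 3-D cylinder run honours divergence, mass and wall leakage", {
  m <- make_straight_vessel(aneurysm_params(vessel_length = 4e-3), 4e-3 / 10,
                            ndim = 3L, domain_height = 6e-3)
  cfg <- solver_config(reynolds = 10, steady_tol = 5e-4, max_steps = 4000L)
  st <- solve_steady(m, cfg)
  expect_lt(max_fluid_divergence(st), 1e-10)
  fl <- boundary_fluxes(st)
  expect_lt(abs(fl["inlet"] - fl["outlet"]) / abs(fl["inlet"]), 1e-6)
  expect_lt(max_solid_speed(st), 1e-3)
  # paraboloid pipe flow: centerline about twice the mean speed (coarse grid)
  cc <- cell_center_velocity(st)
  expect_gt(max(cc$x), 1.6)
  expect_lt(max(cc$x), 2.4)
})
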