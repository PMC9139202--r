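# Shared fixtures. Expensive steady solves are cached per session so several
# test files (and the acceptance suite) can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

channel_mask <- function(cells_across = 32L, length_m = 8e-3,
                         height_m = 8e-3) {
  make_straight_vessel(aneurysm_params(vessel_length = length_m),
                       4e-3 / cells_across, 2L, domain_height = height_m)
}

poiseuille_solution <- function(cells_across = 32L, reynolds = 10) {
  cached(sprintf("poiseuille_%d_Re%g", cells_across, reynolds), {
    m <- channel_mask(cells_across)
    cfg <- solver_config(reynolds = reynolds, steady_tol = 1e-6,
                         max_steps = 40000L)
    solve_steady(m, cfg)
  })
}

aneurysm_solution_coarse <- function() {
  cached("aneurysm_coarse", {
    m <- make_sidewall_aneurysm(aneurysm_params(), 4e-3 / 32)
    cfg <- solver_config(reynolds = 250, steady_tol = 1e-5,
                         max_steps = 15000L)
    list(mask = m, state = solve_steady(m, cfg, on_nonconvergence = "warn"))
  })
}

# refined sidewall-aneurysm run at the study Reynolds number (~256 x 157 grid)
aneurysm_solution_fine <- function() {
  cached("aneurysm_fine", {
    m <- make_sidewall_aneurysm(aneurysm_params(), 4e-3 / 64)
    cfg <- solver_config(reynolds = reynolds_number(0.2, 4e-3, 3.25e-6),
                         steady_tol = 1e-5, max_steps = 12000L)
    list(mask = m, state = solve_steady(m, cfg, on_nonconvergence = "warn"))
  })
}

# max solid-cell speed across a decade sweep of the penalization parameter
penalization_sweep <- function(etas = c(1e-4, 1e-6, 1e-8)) {
  cached("penalization_sweep", {
    m <- channel_mask(32)
    sapply(etas, function(eta) {
      cfg <- solver_config(reynolds = 10, penalization_eta = eta,
                           steady_tol = 1e-6, max_steps = 40000L)
      max_solid_speed(solve_steady(m, cfg))
    })
  })
}

# nested channel triple (16 / 32 / 64 cells across) at a moderate Reynolds
channel_triple <- function() {
  cached("channel_triple", {
    lapply(c(16L, 32L, 64L), function(n) {
      m <- channel_mask(n)
      cfg <- solver_config(reynolds = 20, steady_tol = 1e-6,
                           max_steps = 40000L)
      solve_steady(m, cfg)
    })
  })
}

# steady solve through the chip's cross-section at the high-shear operating
# point; returns the solver's dimensional wall stress (Pa)
chip_crosscheck_tau <- function(tau_target = 1.5) {
  cached(sprintf("chip_crosscheck_%g", tau_target), {
    chip <- chip_spec()
    Q <- flow_for_target_shear(tau_target, chip)
    U <- Q / (chip$height * chip$width)
    nu <- chip$viscosity / chip$density
    Re <- reynolds_number(U, chip$height, nu)
    m <- make_straight_vessel(
      aneurysm_params(vessel_diameter = chip$height,
                      vessel_length = 2 * chip$height),
      chip$height / 32, 2L, domain_height = 2 * chip$height)
    cfg <- solver_config(reynolds = Re, steady_tol = 1e-6, max_steps = 40000L)
    st <- solve_steady(m, cfg)
    w <- compute_wss(st, m, scaling = list(rho = chip$density, nu = nu,
                                           U = U, D = chip$height))
    mid <- w$x > 0.5 * chip$height & w$x < 1.5 * chip$height
    stats::median(w$tau_Pa[mid])
  })
}
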