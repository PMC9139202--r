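#' Reynolds number of the supplying vessel
#'
#' \eqn{Re = U D / \nu}. With the defaults used throughout the package
#' (inlet speed 0.2 m/s, vessel diameter 4 mm, kinematic blood viscosity
#' 3.25e-6 m^2/s) this evaluates to about 246, conventionally rounded to 250
#' for cerebral-vessel flow.
#'
#' @param inlet_speed mean inlet speed, m/s.
#' @param diameter vessel diameter, m.
#' @param kinematic_viscosity kinematic viscosity, m^2/s.
#' @return dimensionless Reynolds number.
#' @export
reynolds_number <- function(inlet_speed, diameter, kinematic_viscosity) {
  if (any(c(inlet_speed, diameter, kinematic_viscosity) <= 0))
    abort_aneuflow("all arguments of reynolds_number must be > 0",
                   "aneuflow_domain_error")
  inlet_speed * diameter / kinematic_viscosity
}

#' Pulsatile inlet waveform
#'
#' Nondimensional inlet forcing \eqn{U(t) = \bar U (1 + \alpha \sin 2\pi t/T)}.
#' A sinusoid is the minimal single-harmonic surrogate of a heartbeat; the
#' relative amplitude must stay below 1 so the inlet never reverses.
#'
#' @param mean nondimensional mean inlet speed (1 by construction).
#' @param amplitude relative pulsatile amplitude \eqn{\alpha \ge 0}
#'   (0 = steady).
#' @param period nondimensional period of one beat (in units of D/U).
#' @return a list of class `inlet_waveform`.
#' @export
inlet_waveform <- function(mean = 1, amplitude = 0, period = 1) {
  if (amplitude < 0 || amplitude >= 1)
    abort_aneuflow("waveform amplitude must lie in [0, 1)",
                   "aneuflow_domain_error")
  if (amplitude > 0 && period <= 0)
    abort_aneuflow("waveform period must be > 0", "aneuflow_domain_error")
  structure(list(mean = mean, amplitude = amplitude, period = period),
            class = "inlet_waveform")
}

waveform_scale <- function(wf, t) {
  if (wf$amplitude == 0) return(wf$mean)
  wf$mean * (1 + wf$amplitude * sin(2 * pi * t / wf$period))
}

#' Solver configuration
#'
#' Collects the nondimensional parameters of the penalized Navier-Stokes
#' solver. The penalization parameter \eqn{\eta} multiplies the Brinkman drag
#' \eqn{-(\chi/\eta) u}; smaller values enforce the solid more strongly (the
#' default 1e-8 makes the screening length far smaller than any cell).
#'
#' @param reynolds Reynolds number U D / nu (dimensionless, > 0).
#' @param penalization_eta Brinkman penalization parameter (0 < eta << 1).
#' @param cfl Courant number in (0, 1], limiting dt against both the advective
#'   and the explicit viscous stability bounds.
#' @param steady_tol steadiness criterion: relative velocity-change norm per
#'   convective time unit, max |du|/dt / U.
#' @param poisson_tol relative residual for the pressure solve; the projection
#'   contract requires fluid-cell divergence below 10x this value.
#' @param max_steps step budget before a run is declared non-converged.
#' @param waveform an [inlet_waveform()].
#' @param inlet_profile `"parabolic"` (2-D) / paraboloid (3-D) matching the
#'   mean speed, or `"plug"`.
#' @param ramp_time smooth inlet start-up time (nondimensional); purely a
#'   transient aid, discarded before any reported statistic.
#' @return a list of class `solver_config`.
#' @export
solver_config <- function(reynolds = 250, penalization_eta = 1e-8, cfl = 0.5,
                          steady_tol = 1e-6, poisson_tol = 1e-10,
                          max_steps = 50000L, waveform = inlet_waveform(),
                          inlet_profile = c("parabolic", "plug"),
                          ramp_time = 0.5) {
  inlet_profile <- match.arg(inlet_profile)
  if (reynolds <= 0) abort_aneuflow("reynolds must be > 0", "aneuflow_domain_error")
  if (penalization_eta <= 0 || penalization_eta >= 1)
    abort_aneuflow("penalization_eta must lie in (0, 1)", "aneuflow_domain_error")
  if (cfl <= 0 || cfl > 1) abort_aneuflow("cfl must lie in (0, 1]",
                                          "aneuflow_domain_error")
  structure(list(reynolds = reynolds, penalization_eta = penalization_eta,
                 cfl = cfl, steady_tol = steady_tol, poisson_tol = poisson_tol,
                 max_steps = as.integer(max_steps), waveform = waveform,
                 inlet_profile = inlet_profile, ramp_time = ramp_time),
            class = "solver_config")
}

# Penalization-weighted Poisson operator. The projection uses face
# transmissibilities beta = 1 on faces between two fluid cells and
# beta = eta/(eta + dt_ref) on faces adjacent to solid cells (the same
# screening factor the implicit penalization applies), so the velocity
# correction through penalized faces is screened identically and the wall
# does not leak an eta-independent dt*grad(p) velocity. Homogeneous Neumann
# on the box boundary; nullspace removed by pinning cell 1. Returns the
# Cholesky factor of the SPD negative weighted Laplacian.
weighted_poisson_factor <- function(face_betas, dims, h) {
  N <- prod(dims)
  id <- array(seq_len(N), dims)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (ax in seq_along(dims)) {
    n <- dims[ax]
    a <- as.vector(slab(ensure3d(id, dims), ax, 1:(n - 1)))
    b <- as.vector(slab(ensure3d(id, dims), ax, 2:n))
    w <- as.vector(face_betas[[ax]]) / h^2
    ii <- c(ii, a, b, a, b)
    jj <- c(jj, a, b, b, a)
    xx <- c(xx, w, w, -w, -w)
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
  A[1, 1] <- A[1, 1] + 1
  Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
}

ensure3d <- function(a, dims) {
  if (length(dims) == 3L) a else array(a, c(dims, 1L))
}

# Reference length (m) used to nondimensionalize a mask: the generator's
# nominal diameter when present, else the wall-to-wall extent of the inlet
# opening.
mask_length_scale <- function(mask) {
  if (!is.null(mask$meta$diameter)) return(mask$meta$diameter)
  cells <- boundary_fluid_cells(mask, mask$inlet)
  ax <- mask$inlet$axis
  cross <- setdiff(seq_along(dim(mask$indicator)), ax)[1]
  (diff(range(cells[, cross])) + 2) * mask$spacing
}

# Inlet profile evaluated on the inlet-face cross-section; returns an array
# shaped like one velocity slab (ny or ny x nz), zero on solid cells, with
# discrete flux equal to mean * geometric opening area (nondimensional).
build_inlet_profile <- function(mask, config, h) {
  chi <- mask$indicator
  d <- dim(chi)
  nd <- length(d)
  if (nd == 2L) {
    col <- chi[1L, ]
    js <- which(col == 0L)
    y <- (seq_len(d[2]) - 0.5) * h
    y_lo <- (min(js) - 1.5) * h   # first solid node below: effective wall
    y_hi <- (max(js) + 0.5) * h
    H <- y_hi - y_lo
    yc <- (y_lo + y_hi) / 2
    prof <- numeric(d[2])
    if (config$inlet_profile == "parabolic") {
      prof[js] <- 1 - ((y[js] - yc) / (H / 2))^2
    } else prof[js] <- 1
    target <- H              # mean speed 1 over the geometric opening
    prof * (target / (sum(prof) * h))
  } else {
    slab <- chi[1L, , ]
    fl <- slab == 0L
    y <- (seq_len(d[2]) - 0.5) * h
    z <- (seq_len(d[3]) - 0.5) * h
    ctr <- mask$meta$center
    if (is.null(ctr)) {
      idx <- which(fl, arr.ind = TRUE)
      ctr <- c(mean(y[idx[, 1]]), mean(z[idx[, 2]]))
    } else ctr <- ctr / mask_length_scale(mask)
    R <- 0.5  # nondimensional vessel radius
    r2 <- outer((y - ctr[1])^2, (z - ctr[2])^2, `+`)
    prof <- matrix(0, d[2], d[3])
    if (config$inlet_profile == "parabolic") {
      prof[fl] <- pmax(1 - r2[fl] / R^2, 0)
    } else prof[fl] <- 1
    target <- pi * R^2
    prof * (target / (sum(prof) * h^2))
  }
}

# Build the cached solver scaffolding for a mask + config pair.
flow_setup <- function(mask, config) {
  chi <- mask$indicator
  d <- dim(chi)
  nd <- length(d)
  Dref <- mask_length_scale(mask)
  h <- mask$spacing / Dref
  solid <- chi == 1L
  setup <- list(dims = d, nd = nd, h = h, Dref = Dref,
                fluid = !solid,
                inlet_profile = build_inlet_profile(mask, config, h))
  # reference dt for the fixed projection weights (stability bound at the
  # nominal inlet speed); the actual dt varies per step, which leaves the
  # projection exact because the weights enter matrix and correction alike
  vmax0 <- max(abs(setup$inlet_profile)) * (1 + config$waveform$amplitude)
  dt_ref <- config$cfl * min(h / max(vmax0, 1e-8),
                             config$reynolds * h^2 / (2 * nd))
  eps0 <- config$penalization_eta / (config$penalization_eta + dt_ref)
  setup$dt_ref <- dt_ref
  if (nd == 2L) {
    nx <- d[1]; ny <- d[2]
    chiu <- matrix(FALSE, nx + 1, ny)
    chiu[2:nx, ] <- solid[1:(nx - 1), ] | solid[2:nx, ]
    chiu[1, ] <- solid[1, ]; chiu[nx + 1, ] <- solid[nx, ]
    chiv <- matrix(FALSE, nx, ny + 1)
    chiv[, 2:ny] <- solid[, 1:(ny - 1)] | solid[, 2:ny]
    chiv[, 1] <- solid[, 1]; chiv[, ny + 1] <- solid[, ny]
    setup$chiu <- chiu; setup$chiv <- chiv
    setup$beta_u <- ifelse(chiu[2:nx, , drop = FALSE], eps0, 1)   # (nx-1) x ny
    setup$beta_v <- ifelse(chiv[, 2:ny, drop = FALSE], eps0, 1)   # nx x (ny-1)
    setup$out_fluid <- chi[nx, ] == 0L
    setup$chol <- weighted_poisson_factor(
      list(setup$beta_u, setup$beta_v), d, h)
  } else {
    nx <- d[1]; ny <- d[2]; nz <- d[3]
    chiu <- array(FALSE, c(nx + 1, ny, nz))
    chiu[2:nx, , ] <- solid[1:(nx - 1), , ] | solid[2:nx, , ]
    chiu[1, , ] <- solid[1, , ]; chiu[nx + 1, , ] <- solid[nx, , ]
    chiv <- array(FALSE, c(nx, ny + 1, nz))
    chiv[, 2:ny, ] <- solid[, 1:(ny - 1), ] | solid[, 2:ny, ]
    chiv[, 1, ] <- solid[, 1, ]; chiv[, ny + 1, ] <- solid[, ny, ]
    chiw <- array(FALSE, c(nx, ny, nz + 1))
    chiw[, , 2:nz] <- solid[, , 1:(nz - 1)] | solid[, , 2:nz]
    chiw[, , 1] <- solid[, , 1]; chiw[, , nz + 1] <- solid[, , nz]
    setup$chiu <- chiu; setup$chiv <- chiv; setup$chiw <- chiw
    setup$beta_u <- ifelse(chiu[2:nx, , , drop = FALSE], eps0, 1)
    setup$beta_v <- ifelse(chiv[, 2:ny, , drop = FALSE], eps0, 1)
    setup$beta_w <- ifelse(chiw[, , 2:nz, drop = FALSE], eps0, 1)
    setup$out_fluid <- chi[nx, , ] == 0L
    setup$chol <- weighted_poisson_factor(
      list(setup$beta_u, setup$beta_v, setup$beta_w), d, h)
  }
  setup
}

#' Initialize a flow state on a mask
#'
#' Zero initial velocity and pressure (the solver is fully deterministic:
#' identical configs give bitwise-identical runs).
#'
#' @param mask a [new_voxel_mask()] with inlet and outlet labels.
#' @param config a [solver_config()].
#' @return an object of class `flow_solution` at time 0.
#' @export
init_flow <- function(mask, config = solver_config()) {
  validate_voxel_mask(mask)
  setup <- flow_setup(mask, config)
  d <- setup$dims
  st <- list(mask = mask, config = config, setup = setup,
             time = 0, step = 0L, dt = NA_real_,
             residual_history = list(step = integer(0), time = numeric(0),
                                     dt = numeric(0), residual = numeric(0),
                                     max_div_fluid = numeric(0)),
             kind = "instantaneous", converged = NA)
  if (setup$nd == 2L) {
    st$u <- matrix(0, d[1] + 1, d[2])
    st$v <- matrix(0, d[1], d[2] + 1)
    st$p <- matrix(0, d[1], d[2])
  } else {
    st$u <- array(0, c(d[1] + 1, d[2], d[3]))
    st$v <- array(0, c(d[1], d[2] + 1, d[3]))
    st$w <- array(0, c(d[1], d[2], d[3] + 1))
    st$p <- array(0, d)
  }
  class(st) <- "flow_solution"
  st
}

# Stability-limited time step.
compute_dt <- function(state) {
  cfg <- state$config
  h <- state$setup$h
  nd <- state$setup$nd
  vmax <- max(abs(state$u), abs(state$v),
              if (nd == 3L) abs(state$w) else 0,
              max(abs(state$setup$inlet_profile)) * (1 + cfg$waveform$amplitude),
              1e-8)
  visc_limit <- cfg$reynolds * h^2 / (2 * nd)
  cfg$cfl * min(h / vmax, visc_limit)
}

#' Advance a flow state by one time step
#'
#' One fractional step: explicit second-order central advective + diffusive
#' update (variable-step Adams-Bashforth 2, Euler on the first step), implicit
#' Brinkman penalization `u <- u / (1 + dt * chi / eta)` on faces adjacent to
#' solid cells, then a pressure projection restoring discrete
#' divergence-freedom in every fluid cell. The inlet carries the prescribed
#' profile at the new time; the outlet a zero-gradient condition corrected to
#' exact global mass balance.
#'
#' @param state a `flow_solution` from [init_flow()] (or a previous step).
#' @param mask,config normally carried inside `state`; supplying different
#'   ones rebuilds the solver scaffolding.
#' @return the advanced `flow_solution`.
#' @export
advance_flow <- function(state, mask = NULL, config = NULL) {
  if (!is.null(mask) || !is.null(config)) {
    state$mask <- mask %||% state$mask
    state$config <- config %||% state$config
    state$setup <- flow_setup(state$mask, state$config)
  }
  if (state$setup$nd == 2L) advance2d(state) else advance3d(state)
}

# Explicit advective + diffusive right-hand side on interior faces
# (conservative second-order central fluxes on the MAC arrangement).
# Ghosts: no-slip (-a) on the solid-backed y sides, v = 0 at the inlet plane,
# zero gradient at the outlet plane.
momentum_rhs_2d <- function(u, v, h, Re) {
  nx <- nrow(u) - 1L; ny <- ncol(u)
  uy <- cbind(-u[, 1], u, -u[, ny])
  vx <- rbind(-v[1, ], v, v[nx, ])
  ucc <- 0.5 * (u[1:nx, ] + u[2:(nx + 1), ])
  Fxx <- ucc * ucc
  ucor <- 0.5 * (uy[, 1:(ny + 1)] + uy[, 2:(ny + 2)])     # (nx+1) x (ny+1)
  vcor <- 0.5 * (vx[1:(nx + 1), ] + vx[2:(nx + 2), ])
  Fxy <- ucor * vcor
  d2yu <- (uy[, 3:(ny + 2)] - 2 * uy[, 2:(ny + 1)] + uy[, 1:ny]) / h^2
  Fu <- (-(Fxx[2:nx, ] - Fxx[1:(nx - 1), ]) / h
         - (Fxy[2:nx, 2:(ny + 1)] - Fxy[2:nx, 1:ny]) / h
         + ((u[3:(nx + 1), ] - 2 * u[2:nx, ] + u[1:(nx - 1), ]) / h^2
            + d2yu[2:nx, ]) / Re)
  vcc <- 0.5 * (v[, 1:ny] + v[, 2:(ny + 1)])
  Fyy <- vcc * vcc
  d2xv <- (vx[3:(nx + 2), ] - 2 * vx[2:(nx + 1), ] + vx[1:nx, ]) / h^2
  Fv <- (-(Fyy[, 2:ny] - Fyy[, 1:(ny - 1)]) / h
         - (Fxy[2:(nx + 1), 2:ny] - Fxy[1:nx, 2:ny]) / h
         + (d2xv[, 2:ny]
            + (v[, 3:(ny + 1)] - 2 * v[, 2:ny] + v[, 1:(ny - 1)]) / h^2) / Re)
  list(Fu = Fu, Fv = Fv)
}

advance2d <- function(st) {
  cfg <- st$config; su <- st$setup
  nx <- su$dims[1]; ny <- su$dims[2]
  h <- su$h; Re <- cfg$reynolds
  u <- st$u; v <- st$v
  dt <- compute_dt(st)
  tnew <- st$time + dt

  rhs_adv <- momentum_rhs_2d(u, v, h, Re)
  Fu <- rhs_adv$Fu; Fv <- rhs_adv$Fv

  if (is.null(st$Fu_prev)) { c1 <- 1; c2 <- 0 } else {
    r <- dt / st$dt_prev
    c1 <- 1 + r / 2; c2 <- r / 2
  }
  u[2:nx, ] <- u[2:nx, ] + dt * (c1 * Fu - c2 * (st$Fu_prev %||% 0))
  v[, 2:ny] <- v[, 2:ny] + dt * (c1 * Fv - c2 * (st$Fv_prev %||% 0))

  # --- boundary conditions ------------------------------------------------
  scale <- waveform_scale(cfg$waveform, tnew)
  if (cfg$ramp_time > 0) scale <- scale * min(1, tnew / cfg$ramp_time)
  u[1, ] <- su$inlet_profile * scale
  u[nx + 1, ] <- u[nx, ]

  # --- implicit penalization ---------------------------------------------
  pen <- 1 / (1 + dt / cfg$penalization_eta)
  u[su$chiu] <- u[su$chiu] * pen
  v[su$chiv] <- v[su$chiv] * pen

  # --- outlet mass fix ----------------------------------------------------
  u[nx + 1, !su$out_fluid] <- 0
  Qin <- sum(u[1, ]) * h
  Qout <- sum(u[nx + 1, ]) * h
  nof <- sum(su$out_fluid)
  if (abs(Qout) > 1e-12 && Qout * Qin > 0) {
    u[nx + 1, su$out_fluid] <- u[nx + 1, su$out_fluid] * (Qin / Qout)
  } else {
    u[nx + 1, su$out_fluid] <- u[nx + 1, su$out_fluid] + (Qin - Qout) / (nof * h)
  }

  # --- projection ---------------------------------------------------------
  div <- (u[2:(nx + 1), ] - u[1:nx, ]) / h + (v[, 2:(ny + 1)] - v[, 1:ny]) / h
  rhs <- -div / dt    # operator is the negative Laplacian (SPD)
  rhs <- rhs - mean(rhs)
  p <- matrix(as.numeric(Matrix::solve(su$chol, as.vector(rhs))), nx, ny)
  u[2:nx, ] <- u[2:nx, ] - dt * su$beta_u * (p[2:nx, ] - p[1:(nx - 1), ]) / h
  v[, 2:ny] <- v[, 2:ny] - dt * su$beta_v * (p[, 2:ny] - p[, 1:(ny - 1)]) / h

  if (anyNA(u) || anyNA(v) || max(abs(u)) > 1e3)
    abort_aneuflow(sprintf(
      "solver instability at step %d (t = %.4g, dt = %.3g): velocity diverged",
      st$step + 1L, tnew, dt), "aneuflow_instability_error")

  div_new <- (u[2:(nx + 1), ] - u[1:nx, ]) / h +
    (v[, 2:(ny + 1)] - v[, 1:ny]) / h
  max_div <- max(abs(div_new[su$fluid]))
  if (max_div > 10 * cfg$poisson_tol * max(1, max(abs(u))) / h)
    abort_aneuflow(sprintf("pressure solve failed: fluid divergence %.3g", max_div),
                   "aneuflow_solver_error")

  res <- max(abs(u - st$u), abs(v - st$v)) / dt
  st$u <- u; st$v <- v; st$p <- p
  st$Fu_prev <- Fu; st$Fv_prev <- Fv; st$dt_prev <- dt
  st$dt <- dt; st$time <- tnew; st$step <- st$step + 1L
  rh <- st$residual_history
  rh$step <- c(rh$step, st$step); rh$time <- c(rh$time, tnew)
  rh$dt <- c(rh$dt, dt); rh$residual <- c(rh$residual, res)
  rh$max_div_fluid <- c(rh$max_div_fluid, max_div)
  st$residual_history <- rh
  st
}

#' March a steady solve to convergence
#'
#' Advances [advance_flow()] until the relative velocity-change norm per
#' convective time unit drops below `steady_tol`, or errors after `max_steps`.
#'
#' @param mask a labeled voxel mask.
#' @param config a [solver_config()]; the waveform amplitude must be 0.
#' @param quiet suppress progress messages.
#' @param on_nonconvergence `"error"` (default) or `"warn"`: what to do if the
#'   step budget is exhausted before the steadiness criterion is met. With
#'   `"warn"` the last state is returned with `converged = FALSE`; useful for
#'   site-topology analyses where a slowly decaying sac recirculation keeps
#'   the residual above a strict tolerance long after the wall-stress pattern
#'   has frozen.
#' @return a converged `flow_solution` with the full residual history.
#' @export
solve_steady <- function(mask, config = solver_config(), quiet = TRUE,
                         on_nonconvergence = c("error", "warn")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  if (config$waveform$amplitude != 0)
    abort_aneuflow("solve_steady requires a steady waveform (amplitude 0)",
                   "aneuflow_usage_error")
  st <- init_flow(mask, config)
  ref <- max(abs(st$setup$inlet_profile))
  repeat {
    st <- advance_flow(st)
    res <- st$residual_history$residual[st$step] / ref
    if (st$time > config$ramp_time && res < config$steady_tol) {
      st$converged <- TRUE
      break
    }
    if (st$step >= config$max_steps) {
      st$converged <- FALSE
      msg <- sprintf(
        "steady solve did not reach tol %.3g in %d steps (last residual %.3g)",
        config$steady_tol, st$step, res)
      if (on_nonconvergence == "error")
        abort_aneuflow(msg, "aneuflow_convergence_error")
      warning(msg)
      break
    }
    if (!quiet && st$step %% 500L == 0L)
      message(sprintf("step %d t=%.3f residual=%.3g", st$step, st$time, res))
  }
  st$kind <- "steady"
  st
}

#' Integrate a pulsatile run and store phase snapshots
#'
#' Integrates `n_periods` beats of the configured waveform; every period
#' before the last is treated as transient. `n_phases` equispaced snapshots of
#' the final period are stored (in `$snapshots`) for time-averaged and peak
#' WSS extraction, together with the phase-0 state of the previous period (for
#' periodicity checks).
#'
#' @param mask a labeled voxel mask.
#' @param config a [solver_config()] whose waveform amplitude is > 0.
#' @param n_periods number of beats to integrate (>= 2; earlier beats are
#'   discarded as transient).
#' @param n_phases number of stored snapshots over the final beat.
#' @param quiet suppress progress messages.
#' @return a `flow_solution` whose `$snapshots` is a list of
#'   `(u, v, [w,] time)` records.
#' @export
solve_pulsatile <- function(mask, config, n_periods = 3L, n_phases = 8L,
                            quiet = TRUE) {
  wf <- config$waveform
  if (wf$amplitude <= 0)
    abort_aneuflow("solve_pulsatile requires waveform amplitude > 0",
                   "aneuflow_usage_error")
  if (n_periods < 2L)
    abort_aneuflow("n_periods must be >= 2 (first beats are transient)",
                   "aneuflow_usage_error")
  st <- init_flow(mask, config)
  t_final_start <- (n_periods - 1) * wf$period
  t_prev_start <- (n_periods - 2) * wf$period
  phase_times <- t_final_start + (seq_len(n_phases) - 1) * wf$period / n_phases
  t_end <- n_periods * wf$period
  snapshots <- vector("list", n_phases)
  next_phase <- 1L
  prev_phase0 <- NULL
  grabbed_prev <- FALSE
  # states at exact phase times come from linear interpolation between the
  # bracketing steps, so snapshot phases do not suffer dt-quantization jitter
  interp_state <- function(prev, cur, t_target) {
    a <- (t_target - prev$time) / (cur$time - prev$time)
    out <- list(u = (1 - a) * prev$u + a * cur$u,
                v = (1 - a) * prev$v + a * cur$v, time = t_target)
    if (!is.null(cur$w)) out$w <- (1 - a) * prev$w + a * cur$w
    out
  }
  prev_state <- list(u = st$u, v = st$v, w = st$w, time = st$time)
  repeat {
    st <- advance_flow(st)
    cur_state <- list(u = st$u, v = st$v, w = st$w, time = st$time)
    if (!grabbed_prev && st$time >= t_prev_start) {
      prev_phase0 <- interp_state(prev_state, cur_state, t_prev_start)
      grabbed_prev <- TRUE
    }
    while (next_phase <= n_phases && st$time >= phase_times[next_phase]) {
      snapshots[[next_phase]] <- interp_state(prev_state, cur_state,
                                              phase_times[next_phase])
      next_phase <- next_phase + 1L
    }
    prev_state <- cur_state
    if (st$time >= t_end) break
    if (st$step >= config$max_steps)
      abort_aneuflow(sprintf("pulsatile run exhausted %d steps before t = %g",
                             config$max_steps, t_end),
                     "aneuflow_convergence_error")
    if (!quiet && st$step %% 500L == 0L)
      message(sprintf("step %d t=%.3f", st$step, st$time))
  }
  st$kind <- "pulsatile"
  st$snapshots <- snapshots
  st$prev_phase0 <- prev_phase0
  st$converged <- TRUE
  st
}

#' Maximum discrete divergence over fluid cells
#' @param state a `flow_solution`.
#' @return scalar max |div u| over cells with indicator 0.
#' @export
max_fluid_divergence <- function(state) {
  su <- state$setup; h <- su$h
  d <- su$dims
  if (su$nd == 2L) {
    div <- (state$u[2:(d[1] + 1), ] - state$u[1:d[1], ]) / h +
      (state$v[, 2:(d[2] + 1)] - state$v[, 1:d[2]]) / h
  } else {
    div <- (state$u[2:(d[1] + 1), , ] - state$u[1:d[1], , ]) / h +
      (state$v[, 2:(d[2] + 1), ] - state$v[, 1:d[2], ]) / h +
      (state$w[, , 2:(d[3] + 1)] - state$w[, , 1:d[3]]) / h
  }
  max(abs(div[su$fluid]))
}

#' Inlet and outlet volumetric fluxes
#' @param state a `flow_solution`.
#' @return named numeric vector `c(inlet =, outlet =)` (nondimensional).
#' @export
boundary_fluxes <- function(state) {
  h <- state$setup$h
  nd <- state$setup$nd
  nx <- state$setup$dims[1]
  a <- if (nd == 2L) h else h^2
  if (nd == 2L)
    c(inlet = sum(state$u[1, ]) * a, outlet = sum(state$u[nx + 1, ]) * a)
  else
    c(inlet = sum(state$u[1, , ]) * a, outlet = sum(state$u[nx + 1, , ]) * a)
}

#' Maximum speed inside the solid (penalized) region
#'
#' Cell-centered speed over solid cells; the volume-penalization error
#' monitor. Decreases monotonically as the penalization parameter eta
#' decreases.
#' @param state a `flow_solution`.
#' @return scalar.
#' @export
max_solid_speed <- function(state) {
  cc <- cell_center_velocity(state)
  sp <- sqrt(Reduce(`+`, lapply(cc, function(a) a^2)))
  max(sp[!state$setup$fluid])
}

#' Cell-centered velocity components
#' @param state a `flow_solution`.
#' @return list of arrays (one per component) on the cell grid.
#' @export
cell_center_velocity <- function(state) {
  d <- state$setup$dims
  if (state$setup$nd == 2L) {
    list(x = 0.5 * (state$u[1:d[1], ] + state$u[2:(d[1] + 1), ]),
         y = 0.5 * (state$v[, 1:d[2]] + state$v[, 2:(d[2] + 1)]))
  } else {
    list(x = 0.5 * (state$u[1:d[1], , ] + state$u[2:(d[1] + 1), , ]),
         y = 0.5 * (state$v[, 1:d[2], ] + state$v[, 2:(d[2] + 1), ]),
         z = 0.5 * (state$w[, , 1:d[3]] + state$w[, , 2:(d[3] + 1)]))
  }
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> %s, %s grid, t = %.4g (%d steps)\n",
              x$kind, paste(x$setup$dims, collapse = " x "), x$time, x$step))
  cat(sprintf("  Re = %g, eta = %g, max speed %.4g, max fluid div %.3g\n",
              x$config$reynolds, x$config$penalization_eta,
              max(abs(x$u)), max_fluid_divergence(x)))
  if (isTRUE(x$converged)) cat("  converged to steadiness tolerance\n")
  if (identical(x$converged, FALSE)) cat("  NOT converged (step budget)\n")
  invisible(x)
}

#' @export
summary.flow_solution <- function(object, ...) {
  fl <- boundary_fluxes(object)
  out <- list(kind = object$kind, dims = object$setup$dims,
              time = object$time, steps = object$step,
              reynolds = object$config$reynolds,
              max_speed = max(abs(object$u), abs(object$v)),
              max_fluid_divergence = max_fluid_divergence(object),
              flux_imbalance = abs(fl[1] - fl[2]) / max(abs(fl[1]), 1e-300),
              max_solid_speed = max_solid_speed(object),
              converged = object$converged)
  class(out) <- "summary.flow_solution"
  out
}

#' @export
print.summary.flow_solution <- function(x, ...) {
  cat(sprintf("%s flow on %s grid, Re = %g, t = %.4g (%d steps)\n", x$kind,
              paste(x$dims, collapse = " x "), x$reynolds, x$time, x$steps))
  cat(sprintf("  max speed          %.4g\n", x$max_speed))
  cat(sprintf("  max fluid div      %.3g\n", x$max_fluid_divergence))
  cat(sprintf("  flux imbalance     %.3g (relative)\n", x$flux_imbalance))
  cat(sprintf("  max solid speed    %.3g\n", x$max_solid_speed))
  invisible(x)
}

#' @export
residuals.flow_solution <- function(object, ...) {
  as.data.frame(object$residual_history)
}

#' @export
plot.flow_solution <- function(x, what = c("speed", "residual"), ...) {
  what <- match.arg(what)
  if (what == "residual") {
    rh <- residuals(x)
    graphics::plot(rh$step, rh$residual, log = "y", type = "l",
                   xlab = "step", ylab = "residual", ...)
    return(invisible(x))
  }
  cc <- cell_center_velocity(x)
  if (x$setup$nd == 3L) cc <- lapply(cc, function(a) a[, , ceiling(dim(a)[3] / 2)])
  sp <- sqrt(cc$x^2 + cc$y^2)
  h <- x$mask$spacing
  xs <- cell_centers_axis(nrow(sp), x$mask$origin[1], h)
  ys <- cell_centers_axis(ncol(sp), x$mask$origin[2], h)
  graphics::image(xs, ys, sp, col = grDevices::hcl.colors(64, "viridis"),
                  asp = 1, xlab = "x [m]", ylab = "y [m]", useRaster = TRUE, ...)
  invisible(x)
}
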