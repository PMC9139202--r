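# 3-D counterpart of advance2d: same fractional step on a MAC arrangement
# u (nx+1, ny, nz), v (nx, ny+1, nz), w (nx, ny, nz+1). Kept separate from the
# 2-D kernel: explicit slicing is easier to audit than a dimension-generic
# formulation, and desk-scale 3-D runs stay coarse.

pad_axis <- function(a, axis, lo, hi) {
  d <- dim(a)
  out <- array(0, d + c(axis == 1, axis == 2, axis == 3) * 2)
  idx <- lapply(dim(out), seq_len)
  idx[[axis]] <- 2:(d[axis] + 1)
  out <- do.call(`[<-`, c(list(out), idx, list(value = a)))
  idx_lo <- idx; idx_lo[[axis]] <- 1L
  idx_hi <- idx; idx_hi[[axis]] <- d[axis] + 2L
  out <- do.call(`[<-`, c(list(out), idx_lo, list(value = lo)))
  do.call(`[<-`, c(list(out), idx_hi, list(value = hi)))
}

slab <- function(a, axis, idx) {
  ii <- lapply(dim(a), seq_len)
  ii[[axis]] <- idx
  do.call(`[`, c(list(a), ii, list(drop = FALSE)))
}

avg_axis <- function(a, axis) {
  n <- dim(a)[axis]
  0.5 * (slab(a, axis, 1:(n - 1)) + slab(a, axis, 2:n))
}

diff_axis <- function(a, axis, h) {
  n <- dim(a)[axis]
  (slab(a, axis, 2:n) - slab(a, axis, 1:(n - 1))) / h
}

second_diff <- function(ap, axis, h) {
  n <- dim(ap)[axis]
  (slab(ap, axis, 3:n) - 2 * slab(ap, axis, 2:(n - 1)) +
     slab(ap, axis, 1:(n - 2))) / h^2
}

advance3d <- function(st) {
  cfg <- st$config; su <- st$setup
  d <- su$dims; nx <- d[1]; ny <- d[2]; nz <- d[3]
  h <- su$h; Re <- cfg$reynolds
  u <- st$u; v <- st$v; w <- st$w
  dt <- compute_dt(st)
  tnew <- st$time + dt

  # ghost-padded copies: no-slip (-a) on solid-backed box sides, v=w=0 at the
  # inlet plane (ghost -a), zero-gradient at the outlet plane (ghost copy)
  vp_x <- pad_axis(v, 1, -slab(v, 1, 1), slab(v, 1, nx))
  wp_x <- pad_axis(w, 1, -slab(w, 1, 1), slab(w, 1, nx))
  vp_z <- pad_axis(v, 3, -slab(v, 3, 1), -slab(v, 3, nz))
  wp_y <- pad_axis(w, 2, -slab(w, 2, 1), -slab(w, 2, ny))

  ## u momentum -------------------------------------------------------------
  ucc <- avg_axis(u, 1)                       # nx, ny, nz
  dFxx <- diff_axis(ucc * ucc, 1, h)          # nx-1, ny, nz
  # xy corners: (nx+1, ny+1, nz)
  u_y <- avg_axis(pad_axis(u, 2, -slab(u, 2, 1), -slab(u, 2, ny)), 2)
  v_x <- avg_axis(vp_x, 1)
  dFxy <- diff_axis(u_y * v_x, 2, h)          # (nx+1, ny, nz)
  # xz corners: (nx+1, ny, nz+1)
  u_z <- avg_axis(pad_axis(u, 3, -slab(u, 3, 1), -slab(u, 3, nz)), 3)
  w_x <- avg_axis(wp_x, 1)
  dFxz <- diff_axis(u_z * w_x, 3, h)          # (nx+1, ny, nz)
  lap_u <- (u[3:(nx + 1), , , drop = FALSE] - 2 * u[2:nx, , , drop = FALSE] +
              u[1:(nx - 1), , , drop = FALSE]) / h^2 +
    second_diff(pad_axis(u, 2, -slab(u, 2, 1), -slab(u, 2, ny)), 2, h)[2:nx, , , drop = FALSE] +
    second_diff(pad_axis(u, 3, -slab(u, 3, 1), -slab(u, 3, nz)), 3, h)[2:nx, , , drop = FALSE]
  Fu <- -dFxx - dFxy[2:nx, , , drop = FALSE] - dFxz[2:nx, , , drop = FALSE] +
    lap_u / Re

  ## v momentum -------------------------------------------------------------
  vcc <- avg_axis(v, 2)
  dFyy <- diff_axis(vcc * vcc, 2, h)          # nx, ny-1, nz
  v_xc <- avg_axis(vp_x, 1)                   # (nx+1, ny+1, nz)
  u_yc <- avg_axis(pad_axis(u, 2, -slab(u, 2, 1), -slab(u, 2, ny)), 2)
  dFyx <- diff_axis(u_yc * v_xc, 1, h)        # (nx, ny+1, nz)
  v_z <- avg_axis(vp_z, 3)                    # (nx, ny+1, nz+1)
  w_y <- avg_axis(wp_y, 2)                    # (nx, ny+1, nz+1)
  dFyz <- diff_axis(v_z * w_y, 3, h)          # (nx, ny+1, nz)
  lap_v <- second_diff(vp_x, 1, h)[, 2:ny, , drop = FALSE] +
    (v[, 3:(ny + 1), , drop = FALSE] - 2 * v[, 2:ny, , drop = FALSE] +
       v[, 1:(ny - 1), , drop = FALSE]) / h^2 +
    second_diff(vp_z, 3, h)[, 2:ny, , drop = FALSE]
  Fv <- -dFyy - dFyx[, 2:ny, , drop = FALSE] - dFyz[, 2:ny, , drop = FALSE] +
    lap_v / Re

  ## w momentum -------------------------------------------------------------
  wcc <- avg_axis(w, 3)
  dFzz <- diff_axis(wcc * wcc, 3, h)          # nx, ny, nz-1
  w_xc <- avg_axis(wp_x, 1)                   # (nx+1, ny, nz+1)
  u_zc <- avg_axis(pad_axis(u, 3, -slab(u, 3, 1), -slab(u, 3, nz)), 3)
  dFzx <- diff_axis(u_zc * w_xc, 1, h)        # (nx, ny, nz+1)
  w_yc <- avg_axis(wp_y, 2)                   # (nx, ny+1, nz+1)
  v_zc <- avg_axis(vp_z, 3)
  dFzy <- diff_axis(v_zc * w_yc, 2, h)        # (nx, ny, nz+1)
  lap_w <- second_diff(wp_x, 1, h)[, , 2:nz, drop = FALSE] +
    second_diff(wp_y, 2, h)[, , 2:nz, drop = FALSE] +
    (w[, , 3:(nz + 1), drop = FALSE] - 2 * w[, , 2:nz, drop = FALSE] +
       w[, , 1:(nz - 1), drop = FALSE]) / h^2
  Fw <- -dFzz - dFzx[, , 2:nz, drop = FALSE] - dFzy[, , 2:nz, drop = FALSE] +
    lap_w / Re

  if (is.null(st$Fu_prev)) { c1 <- 1; c2 <- 0 } else {
    r <- dt / st$dt_prev
    c1 <- 1 + r / 2; c2 <- r / 2
  }
  u[2:nx, , ] <- u[2:nx, , ] + dt * (c1 * Fu - c2 * (st$Fu_prev %||% 0))
  v[, 2:ny, ] <- v[, 2:ny, ] + dt * (c1 * Fv - c2 * (st$Fv_prev %||% 0))
  w[, , 2:nz] <- w[, , 2:nz] + dt * (c1 * Fw - c2 * (st$Fw_prev %||% 0))

  scale <- waveform_scale(cfg$waveform, tnew)
  if (cfg$ramp_time > 0) scale <- scale * min(1, tnew / cfg$ramp_time)
  u[1, , ] <- su$inlet_profile * scale
  u[nx + 1, , ] <- u[nx, , ]

  pen <- 1 / (1 + dt / cfg$penalization_eta)
  u[su$chiu] <- u[su$chiu] * pen
  v[su$chiv] <- v[su$chiv] * pen
  w[su$chiw] <- w[su$chiw] * pen

  out <- u[nx + 1, , ]
  out[!su$out_fluid] <- 0
  Qin <- sum(u[1, , ]) * h^2
  Qout <- sum(out) * h^2
  nof <- sum(su$out_fluid)
  if (abs(Qout) > 1e-12 && Qout * Qin > 0) {
    out[su$out_fluid] <- out[su$out_fluid] * (Qin / Qout)
  } else {
    out[su$out_fluid] <- out[su$out_fluid] + (Qin - Qout) / (nof * h^2)
  }
  u[nx + 1, , ] <- out

  div <- diff_axis(u, 1, h) + diff_axis(v, 2, h) + diff_axis(w, 3, h)
  rhs <- -div / dt    # operator is the negative Laplacian (SPD)
  rhs <- rhs - mean(rhs)
  p <- array(as.numeric(Matrix::solve(su$chol, as.vector(rhs))), d)
  u[2:nx, , ] <- u[2:nx, , ] - dt * su$beta_u * diff_axis(p, 1, h)
  v[, 2:ny, ] <- v[, 2:ny, ] - dt * su$beta_v * diff_axis(p, 2, h)
  w[, , 2:nz] <- w[, , 2:nz] - dt * su$beta_w * diff_axis(p, 3, h)

  if (anyNA(u) || anyNA(v) || anyNA(w) || max(abs(u)) > 1e3)
    abort_aneuflow(sprintf(
      "solver instability at step %d (t = %.4g, dt = %.3g): velocity diverged",
      st$step + 1L, tnew, dt), "aneuflow_instability_error")

  div_new <- diff_axis(u, 1, h) + diff_axis(v, 2, h) + diff_axis(w, 3, h)
  max_div <- max(abs(div_new[su$fluid]))

  res <- max(abs(u - st$u), abs(v - st$v), abs(w - st$w)) / dt
  st$u <- u; st$v <- v; st$w <- w; st$p <- p
  st$Fu_prev <- Fu; st$Fv_prev <- Fv; st$Fw_prev <- Fw; st$dt_prev <- dt
  st$dt <- dt; st$time <- tnew; st$step <- st$step + 1L
  rh <- st$residual_history
  rh$step <- c(rh$step, st$step); rh$time <- c(rh$time, tnew)
  rh$dt <- c(rh$dt, dt); rh$residual <- c(rh$residual, res)
  rh$max_div_fluid <- c(rh$max_div_fluid, max_div)
  st$residual_history <- rh
  st
}
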