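# Wall-face extraction, WSS computation and extreme-site identification.

test_that("wall faces of a channel are the two wall-adjacent rows with axial normals", {
  m <- channel_mask(16, length_m = 4e-3)
  f <- extract_wall_faces(m)
  js <- sort(unique(f$j))
  expect_length(js, 2L)
  mid <- f[f$x > 1e-3 & f$x < 3e-3, ]
  expect_true(all(abs(abs(mid$ny) - 1) < 1e-12))
  expect_true(all(abs(mid$nx) < 1e-12))
  # unit normals throughout
  expect_true(all(abs(sqrt(f$nx^2 + f$ny^2) - 1) < 1e-6))
  # masks without solid are a usage error
  all_fluid <- new_voxel_mask(matrix(0L, 8, 8), 1e-4, inlet = NULL,
                              outlet = NULL, validate = FALSE)
  expect_error(extract_wall_faces(all_fluid), class = "aneuflow_usage_error")
})

test_that("voxel sphere normals align with the exact radial direction", {
  # solid ball in a fluid box; normals should point towards the ball center
  n <- 48L
  h <- 1 / n
  cen <- (seq_len(n) - 0.5) * h
  r2 <- outer(cen - 0.5, cen - 0.5, function(a, b) a^2 + b^2)
  chi <- ifelse(r2 < 0.3^2, 1L, 0L)   # 32 cells across the disk diameter
  m <- new_voxel_mask(chi, h, inlet = NULL, outlet = NULL, validate = FALSE)
  f <- extract_wall_faces(m)
  radial <- cbind(0.5 - f$x, 0.5 - f$y)
  radial <- radial / sqrt(rowSums(radial^2))
  dots <- f$nx * radial[, 1] + f$ny * radial[, 2]
  expect_true(all(dots >= 0.9))
})

test_that("wall-face count of a rectangle matches its perimeter", {
  chi <- matrix(1L, 40, 30)
  chi[6:35, 6:25] <- 0L   # 30 x 20 fluid rectangle
  m <- new_voxel_mask(chi, 1e-4, inlet = NULL, outlet = NULL, validate = FALSE)
  f <- extract_wall_faces(m)
  perimeter_cells <- 2 * (30 + 20) - 4
  expect_lte(abs(nrow(f) - perimeter_cells), 4)
})

test_that("a manufactured linear shear field gives tau = mu G exactly", {
  m <- channel_mask(32, length_m = 8e-3)
  cfg <- solver_config(reynolds = 10)
  st <- init_flow(m, cfg)
  G <- 2
  h <- st$setup$h
  ywall_lo <- m$meta$wall_lo / m$meta$diameter
  yc <- (seq_len(ncol(st$u)) - 0.5) * h
  st$u <- matrix(rep(G * (yc - ywall_lo), each = nrow(st$u)), nrow(st$u))
  w <- compute_wss(st, m)
  lower <- w[w$x > 2e-3 & w$x < 6e-3 & w$ny < -0.9, ]
  expect_equal(unique(round(lower$tau, 12)), G / 10)
  # uniform zero field: tau identically zero
  st$u[] <- 0
  expect_true(all(compute_wss(st, m)$tau == 0))
})

test_that("Poiseuille wall stress matches 6 mu U / H and improves with resolution", {
  errs <- sapply(c(16, 32), function(n) {
    st <- poiseuille_solution(n)
    w <- compute_wss(st, st$mask)
    mid <- w[w$x > 2e-3 & w$x < 6e-3, ]
    abs(stats::median(mid$tau) / (6 / 10) - 1)
  })
  expect_lt(errs[2], 0.03)        # 3 percent at 32 cells across
  expect_lt(errs[2], errs[1])     # refinement reduces the error
})

test_that("WSS scales linearly with velocity in the Stokes regime", {
  st <- poiseuille_solution(16)
  w1 <- compute_wss(st, st$mask)
  st2 <- st
  st2$u <- 3 * st$u; st2$v <- 3 * st$v
  w2 <- compute_wss(st2, st$mask)
  expect_equal(w2$tau, 3 * w1$tau, tolerance = 1e-12)
})

test_that("dimensional scaling attaches tau in pascal", {
  st <- poiseuille_solution(16)
  sc <- list(rho = 1060, nu = 3.25e-6, U = 0.2, D = 4e-3)
  w <- compute_wss(st, st$mask, scaling = sc)
  # dynamic-pressure scaling: rho U^2 = Re * rho nu U / D
  expect_equal(w$tau_Pa, w$tau * 10 * 1060 * 3.25e-6 * 0.2 / 4e-3)
  expect_error(compute_wss(st, st$mask, scaling = list(rho = 1)),
               class = "aneuflow_usage_error")
})

test_that("time averaging returns per-face mean and peak", {
  st <- poiseuille_solution(16)
  w <- compute_wss(st, st$mask)
  avg <- time_average_wss(list(w, w))
  expect_equal(avg$time_averaged$tau, w$tau)
  w3 <- w; w3$tau <- 3 * w$tau
  avg2 <- time_average_wss(list(w, w3))
  expect_equal(avg2$time_averaged$tau, 2 * w$tau)
  expect_equal(avg2$peak$tau, 3 * w$tau)
  expect_error(time_average_wss(list(w)), class = "aneuflow_usage_error")
  bad <- w[-1, ]
  expect_error(time_average_wss(list(w, bad)), class = "aneuflow_usage_error")
})

test_that("pulsatile time-averaged channel WSS is close to the steady value", {
  m <- channel_mask(16)
  cfg <- solver_config(reynolds = 10,
                       waveform = inlet_waveform(1, 0.3, 1))
  st <- solve_pulsatile(m, cfg, n_periods = 3L, n_phases = 6L)
  stats <- pulsatile_wss(st, m)
  st0 <- poiseuille_solution(16)
  w0 <- compute_wss(st0, m)
  mid <- w0$x > 2e-3 & w0$x < 6e-3
  expect_lt(abs(stats::median(stats$time_averaged$tau[mid]) /
                  stats::median(w0$tau[mid]) - 1), 0.05)
  expect_true(all(stats$peak$tau >= stats$time_averaged$tau - 1e-14))
})

test_that("percentile site extraction matches a brute-force hand oracle", {
  # tau values 1..100 on a straight line of wall faces
  chi <- matrix(1L, 102, 5)
  chi[2:101, 3] <- 0L
  m <- new_voxel_mask(chi, 1e-4, inlet = NULL, outlet = NULL, validate = FALSE)
  f <- extract_wall_faces(m)
  f <- f[order(f$i), ]
  w <- f
  w$tau <- as.numeric(seq_len(nrow(f)))
  class(w) <- c("wss_field", "data.frame")
  attr(w, "kind") <- "instantaneous"
  s <- find_extreme_sites(w, 5, 95, min_region_faces = 1L)
  # brute force: quantile thresholds at 5.95 / 95.05 select 1..5 and 96..100
  expect_setequal(s$low_sites[[1]]$faces$tau, 1:5)
  expect_setequal(s$high_sites[[1]]$faces$tau, 96:100)
  # representative values bracket the field median
  expect_lt(s$low_sites[[1]]$tau_median, s$field_median)
  expect_gt(s$high_sites[[1]]$tau_median, s$field_median)
  # constant field: all thresholds tie, no sites
  wc <- w; wc$tau <- rep(1, nrow(w))
  sc <- find_extreme_sites(wc, 5, 95, 1L)
  expect_length(sc$low_sites, 0L)
  expect_length(sc$high_sites, 0L)
  expect_error(find_extreme_sites(w, 95, 5), class = "aneuflow_usage_error")
})

test_that("aneurysm sites sit at the documented locations and mirror correctly", {
  fx <- aneurysm_solution_coarse()
  m <- fx$mask
  w <- compute_wss(fx$state, m)
  s <- find_extreme_sites(w)
  expect_gte(length(s$low_sites), 1L)
  expect_gte(length(s$high_sites), 1L)
  nw <- m$meta$neck_width
  hi <- s$high_sites[[1]]$centroid
  lo <- s$low_sites[[1]]$centroid
  # high shear near the downstream sac-vessel rim
  expect_lt(sqrt(sum((hi - m$meta$rim_downstream)^2)) / nw, 2)
  # low shear on the sac wall, away from the neck
  expect_gt(lo["y"], m$meta$sac_wall_y)
  sac_dist <- sqrt(sum((lo - m$meta$sac_center)^2)) / m$meta$sac_radius
  expect_lt(abs(sac_dist - 1), 0.15)
  neck_mid <- c(mean(c(m$meta$rim_upstream[1], m$meta$rim_downstream[1])),
                m$meta$sac_wall_y)
  expect_gt(sqrt(sum((lo - neck_mid)^2)) / nw, 1)
  # representative site stresses bracket the median
  expect_lt(s$low_sites[[1]]$tau_median, s$field_median)
  expect_gt(s$high_sites[[1]]$tau_median, s$field_median)
})
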