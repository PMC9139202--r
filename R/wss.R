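#' Extract wall faces of the immersed boundary
#'
#' Wall faces are the fluid cells with at least one solid face-neighbor.
#' Outward unit normals (pointing into the solid) come from the discrete
#' gradient of a one-cell box-smoothed indicator, which regularizes the
#' staircase so oblique walls get oblique normals.
#'
#' @param mask a voxel mask with at least one solid cell.
#' @return a data frame with cell indices (`i`, `j`[, `k`]), physical
#'   positions of the cell centers (`x`, `y`[, `z`], meters) and unit normal
#'   components (`nx`, `ny`[, `nz`]).
#' @export
extract_wall_faces <- function(mask) {
  chi <- mask$indicator
  if (!any(chi == 1L))
    abort_aneuflow("mask has no solid cells: no wall to extract",
                   "aneuflow_usage_error")
  d <- dim(chi)
  nd <- length(d)
  solid <- chi == 1L
  near_solid <- array(FALSE, d)
  for (ax in seq_len(nd)) {
    # outside the box is open (inlet/outlet) or already backed by the solid
    # padding, so only actual solid cells define the wall
    near_solid <- near_solid | arr_shift(solid, ax, 1L, FALSE) |
      arr_shift(solid, ax, -1L, FALSE)
  }
  wall <- near_solid & !solid
  idx <- which(wall, arr.ind = TRUE)
  # one-cell box smoothing of the indicator (edge-clamped), then central
  # differences for the outward normal
  sm <- chi * 1.0
  for (ax in seq_len(nd)) {
    sm <- (arr_shift_clamp(sm, (seq_len(nd) == ax) * 1L) + sm +
             arr_shift_clamp(sm, (seq_len(nd) == ax) * -1L)) / 3
  }
  grads <- lapply(seq_len(nd), function(ax) {
    (arr_shift_clamp(sm, (seq_len(nd) == ax) * -1L) -
       arr_shift_clamp(sm, (seq_len(nd) == ax) * 1L)) / 2
  })
  g <- sapply(grads, function(ga) ga[wall])
  g <- matrix(g, ncol = nd)
  nrm <- sqrt(rowSums(g^2))
  nrm[nrm == 0] <- 1
  g <- g / nrm
  h <- mask$spacing
  out <- data.frame(i = idx[, 1], j = idx[, 2])
  pos <- list(x = mask$origin[1] + (idx[, 1] - 0.5) * h,
              y = mask$origin[2] + (idx[, 2] - 0.5) * h)
  if (nd == 3L) {
    out$k <- idx[, 3]
    pos$z <- mask$origin[3] + (idx[, 3] - 0.5) * h
  }
  out <- cbind(out, as.data.frame(pos))
  out$nx <- g[, 1]; out$ny <- g[, 2]
  if (nd == 3L) out$nz <- g[, 3]
  out
}

#' Compute wall shear stress on the immersed boundary
#'
#' For each wall face the tangential velocity is sampled at the first and
#' (when available) second fluid cell along the inward normal and
#' differentiated one-sidedly towards the wall. With strong penalization the
#' no-slip surface of the staircase boundary lies at the first *solid* cell
#' centers, one cell beyond the first fluid center, so the first sample sits
#' at distance `h` from the wall; the two-point stencil `(4 u1 - u2) / (2h)`
#' is exact for linear and parabolic profiles over that geometry, and the
#' method falls back to first order `u1 / h` where no second fluid sample
#' exists. Nondimensional stress is `tau_nd = |du_t/dn| / Re` in
#' dynamic-pressure units; supplying a dimensional `scaling` attaches
#' `tau_Pa = rho U^2 tau_nd`, equivalently `(rho nu U / D) |du_t/dn|`.
#'
#' @param solution a `flow_solution` (instantaneous fields are used; see
#'   [time_average_wss()] for cycle statistics).
#' @param mask the mask the solution was computed on.
#' @param scaling optional `list(rho =, nu =, U =, D =)` in SI units for
#'   dimensional stress output.
#' @return an object of class `wss_field`: the [extract_wall_faces()] data
#'   frame plus `tau` (nondimensional) and optionally `tau_Pa`, with
#'   attributes `kind` and `scaling`.
#' @export
compute_wss <- function(solution, mask, scaling = NULL) {
  if (!identical(dim(mask$indicator), solution$setup$dims))
    abort_aneuflow("solution and mask do not share a grid",
                   "aneuflow_usage_error")
  faces <- extract_wall_faces(mask)
  cc <- cell_center_velocity(solution)
  tau_nd <- wss_from_cc(cc, faces, mask, solution$config$reynolds)
  wss_build(faces, tau_nd, scaling, kind = "instantaneous",
            reynolds = solution$config$reynolds)
}

# shared kernel: tau from cell-centered velocity components at wall faces
wss_from_cc <- function(cc, faces, mask, reynolds) {
  chi <- mask$indicator
  d <- dim(chi)
  nd <- length(d)
  nmat <- as.matrix(faces[, c("nx", "ny", if (nd == 3L) "nz")])
  idx1 <- as.matrix(faces[, c("i", "j", if (nd == 3L) "k")])
  step <- matrix(pmax(pmin(round(nmat), 1), -1), ncol = nd)
  idx2 <- idx1 - step
  ok2 <- rowSums(abs(step)) > 0   # degenerate (flat) normals: first order

  for (ax in seq_len(nd))
    ok2 <- ok2 & idx2[, ax] >= 1 & idx2[, ax] <= d[ax]
  lin1 <- 1 + (idx1 - 1) %*% cumprod(c(1, d[-nd]))
  lin2 <- ifelse(ok2, 1 + (idx2 - 1) %*% cumprod(c(1, d[-nd])), NA)
  ok2 <- ok2 & !is.na(lin2) & chi[ifelse(is.na(lin2), 1, lin2)] == 0L
  vel1 <- sapply(cc, function(a) a[lin1])
  vel1 <- matrix(vel1, ncol = nd)
  tang1 <- vel1 - rowSums(vel1 * nmat) * nmat
  ut1 <- sqrt(rowSums(tang1^2))
  ut2 <- numeric(nrow(faces))
  if (any(ok2)) {
    vel2 <- sapply(cc, function(a) a[lin2[ok2]])
    vel2 <- matrix(vel2, ncol = nd)
    n2 <- nmat[ok2, , drop = FALSE]
    tang2 <- vel2 - rowSums(vel2 * n2) * n2
    # signed projection onto the first tangential direction, so reversing
    # flows do not inflate the derivative
    t1 <- tang1[ok2, , drop = FALSE]
    t1n <- sqrt(rowSums(t1^2)); t1n[t1n == 0] <- 1
    ut2[ok2] <- rowSums(tang2 * t1 / t1n)
  }
  h <- mask$spacing / mask_length_scale_cached(mask)
  a <- h                                   # first sample: one cell off the wall
  b <- h * (1 + sqrt(rowSums(step^2)))     # second sample position
  dudn <- ifelse(ok2,
                 abs(ut1 * b^2 - ut2 * a^2) / (a * b * (b - a)),
                 ut1 / a)
  dudn / reynolds
}

mask_length_scale_cached <- function(mask) {
  if (!is.null(mask$meta$diameter)) mask$meta$diameter else mask_length_scale(mask)
}

wss_build <- function(faces, tau_nd, scaling, kind, reynolds) {
  faces$tau <- as.numeric(tau_nd)
  if (!is.null(scaling)) {
    need <- c("rho", "nu", "U", "D")
    if (!all(need %in% names(scaling)))
      abort_aneuflow("scaling must supply rho, nu, U and D",
                     "aneuflow_usage_error")
    # tau_nd is in dynamic-pressure units (the 1/Re factor is inside it), so
    # the dimensional stress is rho U^2 tau_nd = (rho nu U / D) * Re * tau_nd
    faces$tau_Pa <- faces$tau * reynolds *
      scaling$rho * scaling$nu * scaling$U / scaling$D
  }
  structure(faces, kind = kind, scaling = scaling,
            class = c("wss_field", "data.frame"))
}

#' @export
print.wss_field <- function(x, ...) {
  cat(sprintf("<wss_field> %d wall faces, kind = %s\n", nrow(x),
              attr(x, "kind")))
  cat(sprintf("  tau_nd: median %.4g, range [%.4g, %.4g]\n",
              stats::median(x$tau), min(x$tau), max(x$tau)))
  if (!is.null(x$tau_Pa))
    cat(sprintf("  tau_Pa: median %.4g, range [%.4g, %.4g]\n",
                stats::median(x$tau_Pa), min(x$tau_Pa), max(x$tau_Pa)))
  invisible(x)
}

#' @export
plot.wss_field <- function(x, ...) {
  cols <- grDevices::hcl.colors(64, "viridis")
  ci <- cols[pmax(1, ceiling(64 * x$tau / max(x$tau, 1e-300)))]
  graphics::plot(x$x, x$y, col = ci, pch = 15, cex = 0.5, asp = 1,
                 xlab = "x [m]", ylab = "y [m]", ...)
  invisible(x)
}

#' Cycle statistics of wall shear stress
#'
#' Averages instantaneous WSS fields over stored pulsatile snapshots.
#'
#' @param snapshots a list (length >= 2) of `wss_field` objects on identical
#'   face sets.
#' @return a list with components `time_averaged` (per-face mean tau) and
#'   `peak` (per-face max), both `wss_field` objects.
#' @export
time_average_wss <- function(snapshots) {
  if (length(snapshots) < 2L)
    abort_aneuflow("need at least 2 snapshots to average",
                   "aneuflow_usage_error")
  ref <- snapshots[[1]]
  for (s in snapshots[-1]) {
    if (nrow(s) != nrow(ref) || !all(s$i == ref$i & s$j == ref$j))
      abort_aneuflow("snapshots do not share a wall-face set",
                     "aneuflow_usage_error")
  }
  taus <- sapply(snapshots, function(s) s$tau)
  mean_f <- ref; mean_f$tau <- rowMeans(taus)
  peak_f <- ref; peak_f$tau <- apply(taus, 1, max)
  if (!is.null(ref$tau_Pa)) {
    taup <- sapply(snapshots, function(s) s$tau_Pa)
    mean_f$tau_Pa <- rowMeans(taup)
    peak_f$tau_Pa <- apply(taup, 1, max)
  }
  attr(mean_f, "kind") <- "time_averaged"
  attr(peak_f, "kind") <- "peak"
  list(time_averaged = mean_f, peak = peak_f)
}

#' WSS fields of a pulsatile run's stored phases
#'
#' Convenience wrapper: computes instantaneous WSS for every stored snapshot
#' of [solve_pulsatile()] and returns the cycle statistics.
#'
#' @inheritParams compute_wss
#' @return as [time_average_wss()].
#' @export
pulsatile_wss <- function(solution, mask, scaling = NULL) {
  if (is.null(solution$snapshots))
    abort_aneuflow("solution carries no snapshots (not a pulsatile run?)",
                   "aneuflow_usage_error")
  faces <- extract_wall_faces(mask)
  d <- solution$setup$dims
  fields <- lapply(solution$snapshots, function(sn) {
    cc <- if (solution$setup$nd == 2L) {
      list(x = 0.5 * (sn$u[1:d[1], ] + sn$u[2:(d[1] + 1), ]),
           y = 0.5 * (sn$v[, 1:d[2]] + sn$v[, 2:(d[2] + 1)]))
    } else {
      list(x = 0.5 * (sn$u[1:d[1], , ] + sn$u[2:(d[1] + 1), , ]),
           y = 0.5 * (sn$v[, 1:d[2], ] + sn$v[, 2:(d[2] + 1), ]),
           z = 0.5 * (sn$w[, , 1:d[3]] + sn$w[, , 2:(d[3] + 1)]))
    }
    tau <- wss_from_cc(cc, faces, mask, solution$config$reynolds)
    wss_build(faces, tau, scaling, kind = "instantaneous",
              reynolds = solution$config$reynolds)
  })
  time_average_wss(fields)
}

#' Identify low- and high-shear wall sites
#'
#' Thresholds the WSS distribution at the given percentiles, groups the
#' selected faces into connected regions (face adjacency), keeps regions with
#' at least `min_region_faces` members, and ranks them by the distance of the
#' region median from the field median. In sidewall-aneurysm flows the
#' top-ranked high-shear site lands near the downstream sac-vessel rim and
#' the top low-shear site on the sac wall, the two locations whose stresses
#' define the chip culture conditions.
#'
#' @param wss a `wss_field`.
#' @param low_percentile,high_percentile percentile thresholds in (0, 100),
#'   low < high (defaults 5 and 95).
#' @param min_region_faces minimum faces per reported region (default 3).
#' @return an object of class `shear_sites`: lists `low_sites` and
#'   `high_sites` of site records (`centroid`, `n_faces`, `tau_median`,
#'   `tau_mean`, optionally `tau_median_Pa`, and member `faces`), plus the
#'   thresholds used.
#' @export
find_extreme_sites <- function(wss, low_percentile = 5, high_percentile = 95,
                               min_region_faces = 3L) {
  if (nrow(wss) == 0L)
    abort_aneuflow("empty wall-face set", "aneuflow_usage_error")
  if (!(low_percentile > 0 && low_percentile < high_percentile &&
          high_percentile < 100))
    abort_aneuflow("need 0 < low_percentile < high_percentile < 100",
                   "aneuflow_usage_error")
  t_lo <- stats::quantile(wss$tau, low_percentile / 100, names = FALSE)
  t_hi <- stats::quantile(wss$tau, high_percentile / 100, names = FALSE)
  med <- stats::median(wss$tau)
  mk_sites <- function(sel) {
    if (!any(sel)) return(list())
    d <- max(wss$i, wss$j, if (!is.null(wss$k)) wss$k) + 1L
    nd <- if (is.null(wss$k)) 2L else 3L
    dims <- if (nd == 2L) c(max(wss$i) + 1L, max(wss$j) + 1L)
            else c(max(wss$i) + 1L, max(wss$j) + 1L, max(wss$k) + 1L)
    grid <- array(FALSE, dims)
    lin <- if (nd == 2L) cbind(wss$i[sel], wss$j[sel])
           else cbind(wss$i[sel], wss$j[sel], wss$k[sel])
    grid[lin] <- TRUE
    labs <- label_components(grid, connectivity = "moore")
    face_lab <- labs[lin]
    sites <- lapply(sort(unique(face_lab)), function(L) {
      rows <- which(sel)[face_lab == L]
      f <- wss[rows, , drop = FALSE]
      if (nrow(f) < min_region_faces) return(NULL)
      cen <- c(x = mean(f$x), y = mean(f$y),
               if (!is.null(f$z)) c(z = mean(f$z)))
      site <- list(centroid = cen, n_faces = nrow(f),
                   tau_median = stats::median(f$tau),
                   tau_mean = mean(f$tau), faces = f)
      if (!is.null(f$tau_Pa)) {
        site$tau_median_Pa <- stats::median(f$tau_Pa)
        site$tau_mean_Pa <- mean(f$tau_Pa)
      }
      site
    })
    sites <- Filter(Negate(is.null), sites)
    ord <- order(sapply(sites, function(s) abs(s$tau_median - med)),
                 decreasing = TRUE)
    sites[ord]
  }
  out <- list(low_sites = mk_sites(wss$tau < t_lo),
              high_sites = mk_sites(wss$tau > t_hi),
              threshold_low = t_lo, threshold_high = t_hi,
              field_median = med)
  class(out) <- "shear_sites"
  out
}

#' @export
print.shear_sites <- function(x, ...) {
  cat(sprintf("<shear_sites> %d low / %d high regions (thresholds %.4g / %.4g, median %.4g)\n",
              length(x$low_sites), length(x$high_sites),
              x$threshold_low, x$threshold_high, x$field_median))
  show <- function(ss, lab) {
    for (s in utils::head(ss, 3)) {
      cen <- paste(sprintf("%.3g", s$centroid), collapse = ", ")
      extra <- if (!is.null(s$tau_median_Pa))
        sprintf(", %.3g Pa", s$tau_median_Pa) else ""
      cat(sprintf("  %s: %d faces at (%s) m, tau_med %.4g%s\n",
                  lab, s$n_faces, cen, s$tau_median, extra))
    }
  }
  show(x$low_sites, "low"); show(x$high_sites, "high")
  invisible(x)
}
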