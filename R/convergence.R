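#' Estimate the observed order of grid convergence
#'
#' Richardson estimate from a triple of solutions of the same geometry and
#' configuration at spacings `h`, `h/2`, `h/4`:
#' \eqn{p = \log_2(\|u_h - u_{h/2}\| / \|u_{h/2} - u_{h/4}\|)},
#' with fields compared at a common probe set: the coarse-grid fluid cell
#' centers at least `margin` coarse cells away from any solid cell and from
#' the in/outflow planes, sampled from each solution by bilinear (trilinear)
#' interpolation of the cell-centered velocity. Comparing predictions across
#' resolutions in this way is how the numerical accuracy of the flow and of
#' the derived WSS levels is quantified in practice; the penalized staircase
#' boundary limits the observed order to between 1 (wall-dominated) and 2
#' (interior truncation).
#'
#' @param coarse,medium,fine `flow_solution` objects with spacings in exact
#'   ratio 2.
#' @param margin probe exclusion margin in coarse cells (default 2).
#' @return an object of class `convergence_estimate` with fields `order`,
#'   `err_coarse_medium`, `err_medium_fine`, `n_probes` and `converged`
#'   (`TRUE` when both differences vanish and no order can be formed; `order`
#'   is then `NA`).
#' @export
estimate_convergence_order <- function(coarse, medium, fine, margin = 2L) {
  hs <- c(coarse$mask$spacing, medium$mask$spacing, fine$mask$spacing)
  if (abs(hs[1] / hs[2] - 2) > 1e-9 || abs(hs[2] / hs[3] - 2) > 1e-9)
    abort_aneuflow("grids are not nested with spacing ratio 2",
                   "aneuflow_usage_error")
  chi <- coarse$mask$indicator
  d <- dim(chi)
  nd <- length(d)
  solid <- chi == 1L
  far <- !solid
  for (m in seq_len(margin)) {
    grown <- solid
    for (ax in seq_len(nd)) {
      grown <- grown | arr_shift(solid, ax, 1L, TRUE) |
        arr_shift(solid, ax, -1L, TRUE)
    }
    solid <- grown
  }
  far <- !solid & chi == 0L
  # drop the in/outflow margins
  keep_x <- seq_len(d[1]) > margin & seq_len(d[1]) <= d[1] - margin
  if (nd == 2L) far <- far & outer(keep_x, rep(TRUE, d[2]))
  else far <- far & array(keep_x, d)
  idx <- which(far, arr.ind = TRUE)
  if (nrow(idx) < 4L)
    abort_aneuflow("too few interior probes; refine the geometry or lower margin",
                   "aneuflow_usage_error")
  h <- coarse$mask$spacing
  pts <- (idx - 0.5) * h  # physical positions (origin-relative)
  sample_all <- function(sol) {
    cc <- cell_center_velocity(sol)
    do.call(cbind, lapply(cc, function(a) interp_cc(a, sol$mask$spacing, pts)))
  }
  s1 <- sample_all(coarse); s2 <- sample_all(medium); s3 <- sample_all(fine)
  e12 <- sqrt(mean((s1 - s2)^2))
  e23 <- sqrt(mean((s2 - s3)^2))
  scale <- max(abs(s3), 1e-300)
  converged <- e12 < 1e-10 * scale && e23 < 1e-10 * scale
  order <- if (converged) NA_real_ else log2(e12 / max(e23, 1e-300))
  structure(list(order = order, err_coarse_medium = e12,
                 err_medium_fine = e23, n_probes = nrow(idx),
                 converged = converged),
            class = "convergence_estimate")
}

#' @export
print.convergence_estimate <- function(x, ...) {
  if (x$converged) {
    cat("<convergence_estimate> fields are grid-independent (converged)\n")
  } else {
    cat(sprintf("<convergence_estimate> observed order %.3f (errors %.3g -> %.3g, %d probes)\n",
                x$order, x$err_coarse_medium, x$err_medium_fine, x$n_probes))
  }
  invisible(x)
}

# Bilinear / trilinear interpolation of a cell-centered array at physical
# points (origin-relative); clamps to the boundary cells.
interp_cc <- function(a, spacing, pts) {
  d <- dim(a)
  nd <- length(d)
  fr <- pts / spacing + 0.5   # fractional 1-based cell-center index
  i0 <- pmin(pmax(floor(fr), 1), matrix(rep(d, each = nrow(pts)), ncol = nd))
  i0 <- matrix(as.integer(i0), ncol = nd)
  i1 <- matrix(pmin(i0 + 1L, rep(d, each = nrow(pts))), ncol = nd)
  tfr <- fr - i0
  tfr <- pmin(pmax(tfr, 0), 1)
  if (nd == 2L) {
    lin <- function(ii, jj) a[cbind(ii, jj)]
    (1 - tfr[, 1]) * ((1 - tfr[, 2]) * lin(i0[, 1], i0[, 2]) +
                        tfr[, 2] * lin(i0[, 1], i1[, 2])) +
      tfr[, 1] * ((1 - tfr[, 2]) * lin(i1[, 1], i0[, 2]) +
                    tfr[, 2] * lin(i1[, 1], i1[, 2]))
  } else {
    lin <- function(ii, jj, kk) a[cbind(ii, jj, kk)]
    out <- 0
    for (bx in 0:1) for (by in 0:1) for (bz in 0:1) {
      wx <- if (bx) tfr[, 1] else 1 - tfr[, 1]
      wy <- if (by) tfr[, 2] else 1 - tfr[, 2]
      wz <- if (bz) tfr[, 3] else 1 - tfr[, 3]
      ii <- if (bx) i1[, 1] else i0[, 1]
      jj <- if (by) i1[, 2] else i0[, 2]
      kk <- if (bz) i1[, 3] else i0[, 3]
      out <- out + wx * wy * wz * lin(ii, jj, kk)
    }
    out
  }
}
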