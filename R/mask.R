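#' Voxel occupancy masks on uniform Cartesian grids
#'
#' A `voxel_mask` stores the binary fluid/solid indicator field \eqn{\chi} that
#' the volume-penalization solver consumes: `indicator == 1` marks *solid*
#' (penalized) cells, `indicator == 0` marks fluid. The convention follows the
#' support of the Brinkman drag term \eqn{-(\chi/\eta)\,u}; note that the
#' opposite convention (1 = fluid) is common elsewhere, so the indicator
#' meaning is part of the class contract.
#'
#' Geometry conventions: cells use 0-based physical indexing, the center of
#' cell `i` (1-based R index) lies at `origin + (i - 1/2) * spacing`; spacing
#' is uniform and isotropic, all dimensional quantities are SI (meters).
#' Planar walls produced by the generators are snapped to the *cell-center*
#' lattice: with strong penalization the discrete no-slip surface sits at the
#' first solid cell centers, so placing intended walls on that lattice makes
#' the effective and requested geometry coincide.
#'
#' @param indicator integer array (2-D or 3-D) of 0/1 values, 1 = solid.
#' @param spacing grid cell size in meters (uniform, isotropic).
#' @param origin physical coordinates of the low corner of the box (meters).
#' @param inlet,outlet labels of the domain-boundary side carrying in/outflow,
#'   each a list `list(axis =, side =)` with `side` `"min"` or `"max"`, or
#'   `NULL` for masks not intended for simulation.
#' @param meta optional named list of generator metadata (wall positions, sac
#'   center, neck rim points, nominal diameter) used downstream for scaling
#'   and site localization.
#' @param validate check the class invariants (values, labels, connectivity).
#' @return an object of class `voxel_mask`.
#' @export
new_voxel_mask <- function(indicator, spacing, origin = NULL,
                           inlet = list(axis = 1L, side = "min"),
                           outlet = list(axis = 1L, side = "max"),
                           meta = list(), validate = TRUE) {
  if (is.null(dim(indicator))) stop("indicator must be a 2-D or 3-D array")
  storage.mode(indicator) <- "integer"
  d <- length(dim(indicator))
  if (!d %in% 2:3) stop("indicator must be 2-D or 3-D")
  if (is.null(origin)) origin <- rep(0, d)
  m <- structure(list(indicator = indicator, spacing = spacing,
                      origin = origin, inlet = inlet, outlet = outlet,
                      meta = meta),
                 class = "voxel_mask")
  if (validate) validate_voxel_mask(m)
  m
}

#' Validate the invariants of a voxel mask
#'
#' Checks that the indicator holds only 0/1, that inlet and outlet labels are
#' disjoint boundary sides adjacent to fluid, and that the fluid phase is a
#' single connected component reachable from the inlet (face connectivity).
#'
#' @param mask a [new_voxel_mask()] object.
#' @param check_connectivity flood-fill the fluid phase from the inlet and
#'   require full coverage (skipped when no inlet label is present).
#' @return `mask`, invisibly; errors of class `aneuflow_geometry_error`
#'   otherwise.
#' @export
validate_voxel_mask <- function(mask, check_connectivity = TRUE) {
  chi <- mask$indicator
  if (!all(chi %in% c(0L, 1L)))
    abort_aneuflow("mask indicator must be exactly 0 (fluid) or 1 (solid)",
                   "aneuflow_geometry_error")
  if (!is.null(mask$inlet) && !is.null(mask$outlet)) {
    if (identical(mask$inlet, mask$outlet))
      abort_aneuflow("inlet and outlet labels must be disjoint",
                     "aneuflow_geometry_error")
    for (lab in list(mask$inlet, mask$outlet)) {
      cells <- boundary_fluid_cells(mask, lab)
      if (nrow(cells) == 0L)
        abort_aneuflow(sprintf("no fluid cells on the %s boundary (axis %d)",
                               lab$side, lab$axis),
                       "aneuflow_geometry_error")
    }
    if (check_connectivity) {
      seeds <- boundary_fluid_cells(mask, mask$inlet, linear = TRUE)
      reach <- flood_fill_fluid(chi, seeds)
      n_fluid <- sum(chi == 0L)
      if (sum(reach) != n_fluid)
        abort_aneuflow(sprintf(
          "fluid region is not a single inlet-connected component (%d of %d cells unreachable)",
          n_fluid - sum(reach), n_fluid), "aneuflow_geometry_error")
    }
  }
  invisible(mask)
}

# Fluid cells lying in the one-cell boundary slab of a labeled side.
boundary_fluid_cells <- function(mask, label, linear = FALSE) {
  chi <- mask$indicator
  d <- dim(chi)
  idx <- lapply(d, seq_len)
  idx[[label$axis]] <- if (identical(label$side, "min")) 1L else d[label$axis]
  slab <- do.call(`[`, c(list(chi), idx, list(drop = FALSE)))
  arr_idx <- which(slab == 0L, arr.ind = TRUE)
  full <- matrix(0L, nrow(arr_idx), length(d))
  for (k in seq_along(d)) full[, k] <- arr_idx[, k]
  full[, label$axis] <- if (identical(label$side, "min")) 1L else d[label$axis]
  if (!linear) return(full)
  # convert to linear indices
  mult <- cumprod(c(1L, d[-length(d)]))
  as.integer(1L + (full - 1L) %*% mult)
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$indicator)
  cat(sprintf("<voxel_mask> %s grid, spacing %.4g mm\n",
              paste(d, collapse = " x "), x$spacing * 1e3))
  cat(sprintf("  fluid fraction %.3f (%d fluid / %d cells)\n",
              mean(x$indicator == 0L), sum(x$indicator == 0L),
              length(x$indicator)))
  if (!is.null(x$inlet))
    cat(sprintf("  inlet: axis %d %s, outlet: axis %d %s\n",
                x$inlet$axis, x$inlet$side, x$outlet$axis, x$outlet$side))
  invisible(x)
}

#' @export
plot.voxel_mask <- function(x, ...) {
  chi <- x$indicator
  if (length(dim(chi)) == 3L) chi <- chi[, , ceiling(dim(chi)[3] / 2)]
  xs <- cell_centers_axis(nrow(chi), x$origin[1], x$spacing)
  ys <- cell_centers_axis(ncol(chi), x$origin[2], x$spacing)
  graphics::image(xs, ys, chi, col = c("white", "grey30"), asp = 1,
                  xlab = "x [m]", ylab = "y [m]", useRaster = TRUE, ...)
  invisible(x)
}

#' Fraction of the domain box occupied by fluid
#' @param mask a voxel mask.
#' @return scalar in (0, 1).
#' @export
fluid_fraction <- function(mask) mean(mask$indicator == 0L)

# snap a physical coordinate to the nearest cell-center lattice point
snap_to_centers <- function(y, spacing, origin = 0) {
  k <- round((y - origin) / spacing + 0.5)
  origin + (k - 0.5) * spacing
}

#' Parametric description of a vessel with an optional sidewall aneurysm
#'
#' Synthetic stand-in for a segmented patient geometry: a straight supplying
#' vessel (default diameter 4 mm, the usual proximal cerebral-vessel scale)
#' optionally carrying a circular/spherical sidewall sac connected through a
#' neck opening. The patient sac dimensions behind such models are rarely
#' reported; the defaults (sac radius 2 mm, neck 1.6 mm) are plausible for a
#' small sidewall aneurysm rather than matched to any individual.
#'
#' @param vessel_diameter vessel lumen diameter D in meters.
#' @param vessel_length axial extent of the modeled segment in meters.
#' @param sac_radius radius of the circular (2-D) / spherical (3-D) sac, m.
#' @param neck_width width of the neck opening in the shared wall, m; must not
#'   exceed the sac diameter.
#' @param sac_side which vessel wall carries the sac (`"top"` = +y).
#' @param sac_center_offset axial offset of the sac center from the vessel
#'   midpoint, m.
#' @return a list of class `aneurysm_params`.
#' @export
aneurysm_params <- function(vessel_diameter = 4e-3,
                            vessel_length = 4 * vessel_diameter,
                            sac_radius = 2e-3,
                            neck_width = 1.6e-3,
                            sac_side = c("top", "bottom"),
                            sac_center_offset = 0) {
  sac_side <- match.arg(sac_side)
  if (vessel_diameter <= 0) abort_aneuflow("vessel_diameter must be > 0",
                                           "aneuflow_domain_error")
  if (vessel_length <= 0) abort_aneuflow("vessel_length must be > 0",
                                         "aneuflow_domain_error")
  if (sac_radius <= 0) abort_aneuflow("sac_radius must be > 0",
                                      "aneuflow_domain_error")
  if (neck_width < 0 || neck_width > 2 * sac_radius)
    abort_aneuflow("neck_width must lie in [0, 2 * sac_radius]",
                   "aneuflow_domain_error")
  structure(list(vessel_diameter = vessel_diameter,
                 vessel_length = vessel_length,
                 sac_radius = sac_radius,
                 neck_width = neck_width,
                 sac_side = sac_side,
                 sac_center_offset = sac_center_offset),
            class = "aneurysm_params")
}

check_resolution <- function(diameter, spacing, min_cells = 8L) {
  m <- round(diameter / spacing)
  if (m < min_cells)
    abort_aneuflow(sprintf(
      "spacing %.3g m resolves the %.3g m diameter with only %d cells (>= %d required)",
      spacing, diameter, m, min_cells), "aneuflow_resolution_error")
  as.integer(m)
}

#' Generate a straight-vessel mask
#'
#' 2-D: a plane channel of the given diameter inside a solid-padded box.
#' 3-D: a circular cylinder inside a square-section box. Inlet and outlet are
#' labeled on the two axial domain faces. Planar channel walls are snapped to
#' the cell-center lattice (see [new_voxel_mask()]).
#'
#' @param params an [aneurysm_params()] object (sac fields ignored here).
#' @param spacing grid cell size, m; must resolve the diameter with at least
#'   8 cells.
#' @param ndim 2 or 3.
#' @param domain_height cross-flow extent of the box, m (default twice the
#'   diameter, leaving solid padding that the penalization treats as wall).
#' @return a [new_voxel_mask()] object. The `meta` field records the nominal
#'   diameter and wall positions.
#' @export
make_straight_vessel <- function(params, spacing, ndim = 2L,
                                 domain_height = 2 * params$vessel_diameter) {
  D <- params$vessel_diameter
  m <- check_resolution(D, spacing)
  h <- spacing
  nx <- max(4L, as.integer(round(params$vessel_length / h)))
  ny <- as.integer(round(domain_height / h))
  yc <- ny * h / 2
  wall_lo <- snap_to_centers(yc - D / 2, h)
  wall_hi <- wall_lo + m * h
  if (wall_lo < 1.5 * h || wall_hi > ny * h - 1.5 * h)
    abort_aneuflow("domain box too small: need >= 2 solid cell layers beyond each wall",
                   "aneuflow_geometry_error")
  ycen <- cell_centers_axis(ny, 0, h)
  if (ndim == 2L) {
    fluid_row <- ycen > wall_lo + h / 4 & ycen < wall_hi - h / 4
    chi <- matrix(1L, nx, ny)
    chi[, fluid_row] <- 0L
    meta <- list(kind = "straight_vessel", diameter = m * h,
                 wall_lo = wall_lo, wall_hi = wall_hi, axis = 1L)
    return(new_voxel_mask(chi, h, meta = meta))
  }
  if (ndim != 3L) stop("ndim must be 2 or 3")
  nz <- ny
  zcen <- ycen
  ay <- yc
  az <- nz * h / 2
  r2 <- outer((ycen - ay)^2, (zcen - az)^2, `+`)
  sect <- ifelse(r2 < (D / 2)^2, 0L, 1L)
  chi <- array(rep(as.integer(sect), each = nx), dim = c(nx, ny, nz))
  meta <- list(kind = "straight_vessel", diameter = D, center = c(ay, az),
               axis = 1L)
  new_voxel_mask(chi, h, meta = meta)
}

#' Generate a sidewall-aneurysm mask
#'
#' Fluid region = straight vessel plus a circular (2-D) or spherical (3-D)
#' sac budding from one wall, connected through a neck opening of the
#' requested width. The sac center sits at distance
#' \eqn{b = \sqrt{r^2 - (w_n/2)^2}} beyond the wall so that the chord cut in
#' the wall has exactly the neck width. A zero or sub-resolution neck leaves
#' the sac disconnected, which is rejected as a geometry error.
#'
#' @inheritParams make_straight_vessel
#' @return a [new_voxel_mask()] whose `meta` records the sac center/radius and
#'   the physical positions of the upstream/downstream neck rim.
#' @export
make_sidewall_aneurysm <- function(params, spacing, ndim = 2L) {
  D <- params$vessel_diameter
  r <- params$sac_radius
  wn <- params$neck_width
  m <- check_resolution(D, spacing)
  h <- spacing
  b <- sqrt(max(r^2 - (wn / 2)^2, 0))
  pad <- max(2 * h, D / 4)
  nx <- max(4L, as.integer(round(params$vessel_length / h)))
  wall_lo <- snap_to_centers(pad, h)
  if (wall_lo < 1.5 * h) wall_lo <- wall_lo + h
  wall_hi <- wall_lo + m * h
  ny <- as.integer(ceiling((wall_hi + b + r + pad) / h))
  xcen <- cell_centers_axis(nx, 0, h)
  ycen <- cell_centers_axis(ny, 0, h)
  xc <- nx * h / 2 + params$sac_center_offset
  mirror <- identical(params$sac_side, "bottom")

  if (ndim == 2L) {
    chi <- matrix(1L, nx, ny)
    fluid_row <- ycen > wall_lo + h / 4 & ycen < wall_hi - h / 4
    chi[, fluid_row] <- 0L
    sac_center <- c(xc, wall_hi + b)
    d2 <- outer((xcen - sac_center[1])^2, (ycen - sac_center[2])^2, `+`)
    chi[d2 < r^2] <- 0L
    rim_down <- c(xc + wn / 2, wall_hi)
    rim_up <- c(xc - wn / 2, wall_hi)
    if (mirror) {
      chi <- chi[, rev(seq_len(ny)), drop = FALSE]
      flipy <- function(p) c(p[1], ny * h - p[2])
      sac_center <- flipy(sac_center)
      rim_down <- flipy(rim_down); rim_up <- flipy(rim_up)
      tmp <- wall_lo
      wall_lo <- ny * h - wall_hi
      wall_hi <- ny * h - tmp
    }
    meta <- list(kind = "sidewall_aneurysm", diameter = m * h,
                 wall_lo = wall_lo, wall_hi = wall_hi,
                 sac_center = sac_center, sac_radius = r,
                 neck_width = wn, rim_upstream = rim_up,
                 rim_downstream = rim_down,
                 sac_wall_y = if (mirror) wall_lo else wall_hi,
                 sac_side = params$sac_side, axis = 1L)
    mask <- tryCatch(new_voxel_mask(chi, h, meta = meta),
                     aneuflow_geometry_error = function(e)
                       abort_aneuflow(paste0("sac is not connected to the vessel ",
                                             "(neck too narrow for this spacing): ",
                                             conditionMessage(e)),
                                      "aneuflow_geometry_error"))
    return(mask)
  }
  if (ndim != 3L) stop("ndim must be 2 or 3")
  # 3-D: cylinder along x, spherical sac on +y wall
  nz <- as.integer(round(2 * D / h))
  zcen <- cell_centers_axis(nz, 0, h)
  ay <- wall_lo + m * h / 2  # vessel axis height chosen from snapped walls
  az <- nz * h / 2
  ry2 <- outer((ycen - ay)^2, (zcen - az)^2, `+`)
  sect <- ifelse(ry2 < (D / 2)^2, 0L, 1L)
  chi <- array(rep(as.integer(sect), each = nx), dim = c(nx, ny, nz))
  wall_y <- ay + D / 2
  sac_center <- c(xc, wall_y + b, az)
  for (k in seq_len(nz)) {
    d2 <- outer((xcen - sac_center[1])^2,
                (ycen - sac_center[2])^2, `+`) + (zcen[k] - sac_center[3])^2
    sl <- chi[, , k]
    sl[d2 < r^2] <- 0L
    chi[, , k] <- sl
  }
  meta <- list(kind = "sidewall_aneurysm", diameter = D,
               sac_center = sac_center, sac_radius = r, neck_width = wn,
               rim_upstream = c(xc - wn / 2, wall_y, az),
               rim_downstream = c(xc + wn / 2, wall_y, az),
               sac_wall_y = wall_y, sac_side = "top", axis = 1L)
  tryCatch(new_voxel_mask(chi, h, meta = meta),
           aneuflow_geometry_error = function(e)
             abort_aneuflow(paste0("sac is not connected to the vessel: ",
                                   conditionMessage(e)),
                            "aneuflow_geometry_error"))
}

#' Refine a mask by an integer factor
#'
#' Each cell is replaced by `factor^d` cells of the same value and the spacing
#' divided accordingly; inlet/outlet labels carry over. Raw CT-scale masks
#' (around 2 cells per mm) refined by factors of 15-20 reach the 30-40
#' cells-per-mm range used by highly resolved simulations.
#'
#' @param mask a voxel mask.
#' @param factor integer >= 1.
#' @return the refined mask (fluid fraction is preserved exactly).
#' @export
refine_mask <- function(mask, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    abort_aneuflow("refinement factor must be a positive integer",
                   "aneuflow_domain_error")
  if (factor == 1L) return(mask)
  d <- dim(mask$indicator)
  idx <- lapply(d, function(n) rep(seq_len(n), each = factor))
  chi <- do.call(`[`, c(list(mask$indicator), idx, list(drop = FALSE)))
  new_voxel_mask(chi, mask$spacing / factor, mask$origin,
                 mask$inlet, mask$outlet, mask$meta, validate = FALSE)
}

#' Morphologically smooth a mask
#'
#' Closing followed by opening of the solid phase with a discrete ball
#' structuring element, mirroring the light surface smoothing usually applied
#' to segmented imagery. Removes isolated solid specks and fills pinholes up
#' to the given radius. Connectivity is re-validated afterwards: smoothing
#' that disconnects the fluid path is a geometry error.
#'
#' @param mask a voxel mask.
#' @param radius structuring-element radius in cells (0 = identity).
#' @return the smoothed mask.
#' @export
smooth_mask <- function(mask, radius) {
  if (radius < 0) abort_aneuflow("radius must be >= 0", "aneuflow_domain_error")
  if (radius == 0) return(mask)
  chi <- mask$indicator
  chi <- binary_erode(binary_dilate(chi, radius), radius)  # closing
  chi <- binary_dilate(binary_erode(chi, radius), radius)  # opening
  out <- new_voxel_mask(chi, mask$spacing, mask$origin, mask$inlet,
                        mask$outlet, mask$meta, validate = FALSE)
  validate_voxel_mask(out)
  out
}
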