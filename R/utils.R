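# Internal array helpers shared by the mask, solver and WSS modules.
# All masks/fields are plain base-R arrays; axis 1 is the flow (x) axis.

# Shift `a` along `axis` by `by` cells: result[i] = a[i - by], out-of-range
# entries filled with `fill`.
arr_shift <- function(a, axis, by, fill = 0) {
  d <- dim(a)
  n <- d[axis]
  out <- array(fill, d)
  if (abs(by) >= n) return(out)
  src <- if (by >= 0) seq_len(n - by) else seq.int(1 - by, n)
  dst <- if (by >= 0) seq.int(1 + by, n) else seq_len(n + by)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  idx_src[[axis]] <- src
  idx_dst[[axis]] <- dst
  piece <- do.call(`[`, c(list(a), idx_src, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), idx_dst, list(value = piece)))
}

# Shift by an integer offset vector with edge replication (used by morphology,
# where the domain is treated as continuing its boundary values).
arr_shift_clamp <- function(a, off) {
  d <- dim(a)
  idx <- mapply(function(n, o) pmin(pmax(seq_len(n) - o, 1L), n),
                d, off, SIMPLIFY = FALSE)
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# Integer offsets of a discrete ball of given radius (excluding the origin).
ball_offsets <- function(radius, ndim) {
  if (radius < 1) return(list())
  r <- floor(radius)
  ax <- lapply(seq_len(ndim), function(i) -r:r)
  grid <- as.matrix(expand.grid(ax))
  keep <- rowSums(grid^2) <= radius^2 & rowSums(abs(grid)) > 0
  lapply(which(keep), function(i) grid[i, ])
}

binary_dilate <- function(a, radius) {
  offs <- ball_offsets(radius, length(dim(a)))
  out <- a
  for (o in offs) out <- pmax(out, arr_shift_clamp(a, o))
  out
}

binary_erode <- function(a, radius) {
  offs <- ball_offsets(radius, length(dim(a)))
  out <- a
  for (o in offs) out <- pmin(out, arr_shift_clamp(a, o))
  out
}

# Vectorized flood fill over the fluid phase (indicator == 0) from seed linear
# indices, using face (von Neumann) connectivity. Returns a logical array.
flood_fill_fluid <- function(indicator, seeds) {
  fluid <- indicator == 0L
  reach <- array(FALSE, dim(indicator))
  reach[seeds] <- fluid[seeds]
  if (!any(reach)) return(reach)
  repeat {
    grown <- reach
    for (ax in seq_along(dim(indicator))) {
      grown <- grown | arr_shift(reach, ax, 1L, FALSE) |
        arr_shift(reach, ax, -1L, FALSE)
    }
    grown <- grown & fluid
    if (sum(grown) == sum(reach)) break
    reach <- grown
  }
  reach
}

# Connected components of a logical array; returns an integer label array
# (0 outside the set). `connectivity` "face" (von Neumann) or "moore"
# (includes diagonals) - wall-face bands on a staircase boundary are only
# contiguous under Moore adjacency.
label_components <- function(mask_log, connectivity = c("face", "moore")) {
  connectivity <- match.arg(connectivity)
  nd <- length(dim(mask_log))
  offs <- if (connectivity == "face") {
    lapply(seq_len(nd), function(ax) (seq_len(nd) == ax) * 1L)
  } else {
    g <- as.matrix(expand.grid(rep(list(-1:1), nd)))
    g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
    lapply(seq_len(nrow(g)), function(r) g[r, ])
  }
  grow_once <- function(comp) {
    grown <- comp
    for (o in offs) {
      grown <- grown | shift_multi(comp, o) | shift_multi(comp, -o)
    }
    grown
  }
  labels <- array(0L, dim(mask_log))
  remaining <- mask_log
  next_label <- 0L
  while (any(remaining)) {
    next_label <- next_label + 1L
    seed <- which(remaining)[1L]
    comp <- array(FALSE, dim(mask_log))
    comp[seed] <- TRUE
    repeat {
      grown <- grow_once(comp) & remaining
      if (sum(grown) == sum(comp)) break
      comp <- grown
    }
    labels[comp] <- next_label
    remaining <- remaining & !comp
  }
  labels
}

# shift by an integer offset vector, zero fill
shift_multi <- function(a, off) {
  out <- a
  for (ax in seq_along(off)) {
    if (off[ax] != 0) out <- arr_shift(out, ax, off[ax], FALSE)
  }
  out
}

# index -> physical coordinate of a cell center
cell_centers_axis <- function(n, origin, spacing) origin + (seq_len(n) - 0.5) * spacing

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_aneuflow <- function(msg, class) {
  stop(structure(class = c(class, "aneuflow_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
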