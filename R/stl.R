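#' Read a triangulated surface from an STL file
#'
#' Supports both binary and ASCII STL. The format stores a triangle soup;
#' vertices are de-duplicated exactly so that edge-manifoldness can be
#' checked. Files starting with the literal `solid` keyword are parsed as
#' ASCII unless their byte length matches the binary layout.
#'
#' @param path path to an `.stl` file.
#' @return a list of class `stl_mesh` with `vertices` (n x 3 numeric matrix,
#'   meters) and `faces` (m x 3 integer matrix of 1-based vertex indices).
#' @export
read_stl <- function(path) {
  if (!file.exists(path))
    abort_aneuflow(sprintf("STL file not found: %s", path),
                   "aneuflow_format_error")
  con <- file(path, "rb")
  header <- readBin(con, "raw", 80L)
  ntri_raw <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  close(con)
  fsize <- file.info(path)$size
  is_binary <- length(ntri_raw) == 1L && !is.na(ntri_raw) &&
    fsize == 84 + 50 * as.numeric(ntri_raw)
  tri <- if (is_binary) read_stl_binary(path, ntri_raw) else read_stl_ascii(path)
  if (nrow(tri) == 0L || nrow(tri) %% 3L != 0L)
    abort_aneuflow("STL file contains no complete triangles",
                   "aneuflow_format_error")
  key <- apply(tri, 1L, function(v) paste(v, collapse = "|"))
  uid <- match(key, unique(key))
  vertices <- tri[!duplicated(uid), , drop = FALSE]
  faces <- matrix(uid, ncol = 3L, byrow = TRUE)
  structure(list(vertices = vertices, faces = faces), class = "stl_mesh")
}

read_stl_binary <- function(path, ntri) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 84L)
  rec <- readBin(con, "raw", 50L * ntri)
  # each 50-byte record: 12 floats (normal + 3 vertices) + 2 attribute bytes
  idx <- rep(seq_len(ntri) - 1L, each = 48L) * 50L + rep(seq_len(48L), ntri)
  floats <- readBin(rec[idx], "numeric", size = 4L, n = 12L * ntri,
                    endian = "little")
  m <- matrix(floats, ncol = 12L, byrow = TRUE)
  verts <- matrix(0, 3L * ntri, 3L)
  verts[seq(1L, by = 3L, length.out = ntri), ] <- m[, 4:6]
  verts[seq(2L, by = 3L, length.out = ntri), ] <- m[, 7:9]
  verts[seq(3L, by = 3L, length.out = ntri), ] <- m[, 10:12]
  verts
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4]))
  do.call(rbind, nums)
}

#' Check that a surface mesh is watertight
#'
#' Every edge must be shared by exactly two triangles. Returns the count of
#' open or non-manifold edges (0 for a watertight mesh).
#'
#' @param mesh an `stl_mesh`.
#' @return integer count of defective edges.
#' @export
count_open_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  sum(tab != 2L)
}

#' Voxelize a watertight STL surface onto a Cartesian grid
#'
#' A cell is fluid iff its center lies inside the closed surface, decided by
#' even-odd ray-crossing parity along the +z axis (+y for effectively planar
#' meshes). Ray origins carry a fixed tiny lattice-irrational perturbation so
#' that rays through vertices or edges are resolved deterministically and
#' reproducibly. The grid extends the mesh bounding box by two solid cell
#' layers so the penalization sees walls on every non-labeled face.
#'
#' @param surface an `stl_mesh` from [read_stl()], or a path to an STL file.
#' @param spacing grid cell size, m.
#' @param label_open_boundaries label fluid cells touching the x-min/x-max
#'   domain faces as inlet/outlet (for surfaces cut open along x and closed by
#'   the box; `FALSE` leaves the mask unlabeled, e.g. closed test solids).
#' @return a [new_voxel_mask()] object.
#' @export
voxelize_stl <- function(surface, spacing, label_open_boundaries = FALSE) {
  mesh <- if (is.character(surface)) read_stl(surface) else surface
  if (!inherits(mesh, "stl_mesh")) stop("surface must be an stl_mesh or a path")
  open_edges <- count_open_edges(mesh)
  if (open_edges > 0L)
    abort_aneuflow(sprintf(
      "mesh is not watertight: %d open or non-manifold edges", open_edges),
      "aneuflow_format_error")
  v <- mesh$vertices
  f <- mesh$faces
  h <- spacing
  lo <- apply(v, 2, min) - 2 * h
  hi <- apply(v, 2, max) + 2 * h
  n <- pmax(as.integer(ceiling((hi - lo) / h)), 5L)
  xs <- cell_centers_axis(n[1], lo[1], h)
  ys <- cell_centers_axis(n[2], lo[2], h)
  zs <- cell_centers_axis(n[3], lo[3], h)
  eps <- h * 1e-6 * c(sqrt(2) - 1, sqrt(3) - 1)  # deterministic ray offset
  # Parity accumulation: for each triangle, find (x, y) columns whose ray
  # (along +z) pierces it and record the crossing height.
  cross_col <- integer(0)
  cross_z <- numeric(0)
  for (t in seq_len(nrow(f))) {
    p1 <- v[f[t, 1], ]; p2 <- v[f[t, 2], ]; p3 <- v[f[t, 3], ]
    xmin <- min(p1[1], p2[1], p3[1]); xmax <- max(p1[1], p2[1], p3[1])
    ymin <- min(p1[2], p2[2], p3[2]); ymax <- max(p1[2], p2[2], p3[2])
    ii <- which(xs + eps[1] >= xmin & xs + eps[1] <= xmax)
    jj <- which(ys + eps[2] >= ymin & ys + eps[2] <= ymax)
    if (!length(ii) || !length(jj)) next
    px <- rep(xs[ii] + eps[1], times = length(jj))
    py <- rep(ys[jj] + eps[2], each = length(ii))
    # 2-D barycentric test in the xy projection
    d <- (p2[2] - p3[2]) * (p1[1] - p3[1]) + (p3[1] - p2[1]) * (p1[2] - p3[2])
    if (abs(d) < .Machine$double.eps * max(abs(c(p1, p2, p3)), 1)) next  # ray-parallel
    w1 <- ((p2[2] - p3[2]) * (px - p3[1]) + (p3[1] - p2[1]) * (py - p3[2])) / d
    w2 <- ((p3[2] - p1[2]) * (px - p3[1]) + (p1[1] - p3[1]) * (py - p3[2])) / d
    w3 <- 1 - w1 - w2
    inside <- w1 >= 0 & w2 >= 0 & w3 >= 0
    if (!any(inside)) next
    zc <- w1[inside] * p1[3] + w2[inside] * p2[3] + w3[inside] * p3[3]
    cols <- (rep(ii, times = length(jj)) +
               (rep(jj, each = length(ii)) - 1L) * n[1])[inside]
    cross_col <- c(cross_col, cols)
    cross_z <- c(cross_z, zc)
  }
  chi <- array(1L, dim = n)
  if (length(cross_col)) {
    ord <- order(cross_col, cross_z)
    cross_col <- cross_col[ord]; cross_z <- cross_z[ord]
    splits <- split(cross_z, cross_col)
    for (colname in names(splits)) {
      col <- as.integer(colname)
      zhits <- splits[[colname]]
      # parity of crossings below each cell center
      nbelow <- findInterval(zs, zhits)
      i <- ((col - 1L) %% n[1]) + 1L
      j <- ((col - 1L) %/% n[1]) + 1L
      chi[i, j, nbelow %% 2L == 1L] <- 0L
    }
  }
  inlet <- outlet <- NULL
  if (label_open_boundaries) {
    inlet <- list(axis = 1L, side = "min")
    outlet <- list(axis = 1L, side = "max")
  }
  new_voxel_mask(chi, h, origin = lo, inlet = inlet, outlet = outlet,
                 meta = list(kind = "voxelized_stl"),
                 validate = label_open_boundaries)
}
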