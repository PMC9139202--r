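# Legacy ASCII VTK rectilinear-grid writer/reader. Fields live on the cell
# centers and are written as POINT_DATA over a rectilinear grid whose
# coordinates are those centers, which ParaView renders directly. A matching
# minimal reader supports the package's round-trip tests.

#' Write arrays on a uniform grid to a legacy VTK rectilinear-grid file
#'
#' @param fields named list of numeric arrays, all with identical 2-D or 3-D
#'   dims (2-D arrays are written as one-slab 3-D). Entries named like
#'   `velocity` that are themselves lists of component arrays are written as
#'   VECTORS.
#' @param spacing grid spacing, m.
#' @param origin low-corner coordinates, m.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vtk_grid <- function(fields, spacing, origin, path) {
  stopifnot(length(fields) > 0)
  first <- fields[[1]]
  dm <- if (is.list(first)) dim(first[[1]]) else dim(first)
  if (length(dm) == 2L) dm <- c(dm, 1L)
  if (length(origin) == 2L) origin <- c(origin, 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "aneuflow field export", "ASCII",
               "DATASET RECTILINEAR_GRID",
               sprintf("DIMENSIONS %d %d %d", dm[1], dm[2], dm[3])), con)
  coords <- function(n, o) o + (seq_len(n) - 0.5) * spacing
  for (ax in 1:3) {
    lab <- c("X", "Y", "Z")[ax]
    cs <- if (dm[ax] == 1L) 0 else coords(dm[ax], origin[ax])
    writeLines(sprintf("%s_COORDINATES %d double", lab, dm[ax]), con)
    writeLines(paste(format(cs, digits = 17, scientific = TRUE, trim = TRUE),
                     collapse = " "), con)
  }
  writeLines(sprintf("POINT_DATA %d", prod(dm)), con)
  fmt <- function(x) format(as.vector(x), digits = 17, scientific = TRUE,
                            trim = TRUE)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (is.list(f)) {
      comp <- lapply(f, as.vector)
      while (length(comp) < 3L) comp <- c(comp, list(rep(0, prod(dm))))
      writeLines(sprintf("VECTORS %s double", nm), con)
      writeLines(paste(fmt(comp[[1]]), fmt(comp[[2]]), fmt(comp[[3]])), con)
    } else {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
                 con)
      writeLines(fmt(f), con)
    }
  }
  invisible(path)
}

#' Read back a legacy VTK rectilinear-grid file written by [write_vtk_grid()]
#'
#' @param path file path.
#' @return list with `dims`, `coordinates` (list of 3 vectors) and `fields`
#'   (named list of arrays / lists of component arrays).
#' @export
read_vtk_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  dimln <- grep("^DIMENSIONS", lines, value = TRUE)[1]
  dm <- as.integer(strsplit(dimln, "\\s+")[[1]][2:4])
  coords <- list()
  for (ax in 1:3) {
    lab <- c("X", "Y", "Z")[ax]
    i <- grep(sprintf("^%s_COORDINATES", lab), lines)[1]
    coords[[ax]] <- as.numeric(strsplit(trimws(lines[i + 1]), "\\s+")[[1]])
  }
  npts <- prod(dm)
  fields <- list()
  i <- grep("^POINT_DATA", lines)[1] + 1L
  adim <- if (dm[3] == 1L) dm[1:2] else dm
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^SCALARS", ln)) {
      nm <- strsplit(ln, "\\s+")[[1]][2]
      vals <- as.numeric(scan(text = lines[(i + 2):(i + 1 + npts)],
                              quiet = TRUE))
      fields[[nm]] <- array(vals, adim)
      i <- i + 2L + npts
    } else if (grepl("^VECTORS", ln)) {
      nm <- strsplit(ln, "\\s+")[[1]][2]
      m <- matrix(scan(text = lines[(i + 1):(i + npts)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
      comps <- lapply(seq_len(if (dm[3] == 1L) 2L else 3L),
                      function(c) array(m[, c], adim))
      names(comps) <- c("x", "y", "z")[seq_along(comps)]
      fields[[nm]] <- comps
      i <- i + 1L + npts
    } else i <- i + 1L
  }
  list(dims = dm, coordinates = coords, fields = fields)
}

#' Write a mask as VTK plus a compressed plain-text array with JSON sidecar
#'
#' Three files: `<name>.vtk` (inspectable), `<name>.dat.gz` (the 0/1
#' indicator, one x-row per line) and `<name>.json` (dims, spacing, origin,
#' boundary labels, metadata).
#'
#' @param mask a voxel mask.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return named character vector of the written paths.
#' @export
write_mask <- function(mask, dir, name = "mask") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vtk <- file.path(dir, paste0(name, ".vtk"))
  write_vtk_grid(list(solid_indicator = mask$indicator * 1.0),
                 mask$spacing, mask$origin, vtk)
  datgz <- file.path(dir, paste0(name, ".dat.gz"))
  con <- gzfile(datgz, "w")
  chi <- mask$indicator
  d <- dim(chi)
  flat <- matrix(as.vector(chi), nrow = d[1])
  writeLines(apply(flat, 2, paste, collapse = ""), con)
  close(con)
  side <- file.path(dir, paste0(name, ".json"))
  meta <- mask$meta
  jsonlite::write_json(
    list(dims = dim(chi), spacing = mask$spacing, origin = mask$origin,
         inlet = mask$inlet, outlet = mask$outlet, meta = meta),
    side, auto_unbox = TRUE, digits = NA, null = "null")
  c(vtk = vtk, data = datgz, sidecar = side)
}

#' Read a mask written by [write_mask()]
#' @param dir directory holding the files.
#' @param name file stem.
#' @return a [new_voxel_mask()] object.
#' @export
read_mask <- function(dir, name = "mask") {
  side <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                              simplifyVector = TRUE)
  con <- gzfile(file.path(dir, paste0(name, ".dat.gz")), "r")
  rows <- readLines(con)
  close(con)
  vals <- as.integer(unlist(strsplit(rows, "")))
  chi <- array(vals, dim = side$dims)
  relabel <- function(l) if (is.null(l) || length(l) == 0) NULL else
    list(axis = as.integer(l$axis), side = l$side)
  meta <- side$meta
  if (!is.null(meta)) meta <- lapply(meta, function(x) if (is.list(x)) unlist(x) else x)
  new_voxel_mask(chi, side$spacing, side$origin,
                 relabel(side$inlet), relabel(side$outlet),
                 meta %||% list(), validate = FALSE)
}

#' Write a flow solution's fields to VTK
#' @param state a `flow_solution`.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_flow_vtk <- function(state, path) {
  cc <- cell_center_velocity(state)
  write_vtk_grid(list(velocity = cc, pressure = state$p,
                      solid_indicator = state$mask$indicator * 1.0),
                 state$mask$spacing, state$mask$origin, path)
}

#' Write a WSS field as CSV
#'
#' Columns x, y, (z,) nx, ny, (nz,) tau_nd and, when present, tau_Pa.
#' @param wss a `wss_field`.
#' @param path output csv path.
#' @return `path`, invisibly.
#' @export
write_wss_csv <- function(wss, path) {
  df <- as.data.frame(wss)
  names(df)[names(df) == "tau"] <- "tau_nd"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a WSS field as VTK point data
#'
#' Legacy ASCII POLYDATA: one point per wall face with normals and tau
#' scalars, directly renderable in ParaView.
#' @param wss a `wss_field`.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_wss_vtk <- function(wss, path) {
  n <- nrow(wss)
  z <- if (is.null(wss$z)) rep(0, n) else wss$z
  nz <- if (is.null(wss$nz)) rep(0, n) else wss$nz
  fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "aneuflow wall shear stress",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", n)), con)
  writeLines(paste(fmt(wss$x), fmt(wss$y), fmt(z)), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  writeLines(c("SCALARS tau_nd double 1", "LOOKUP_TABLE default"), con)
  writeLines(fmt(wss$tau), con)
  if (!is.null(wss$tau_Pa)) {
    writeLines(c("SCALARS tau_Pa double 1", "LOOKUP_TABLE default"), con)
    writeLines(fmt(wss$tau_Pa), con)
  }
  writeLines("VECTORS normal double", con)
  writeLines(paste(fmt(wss$nx), fmt(wss$ny), fmt(nz)), con)
  invisible(path)
}

#' Write shear sites as a CSV table
#'
#' One row per site: kind, rank, centroid, face count and representative
#' stresses.
#' @param sites a `shear_sites` object.
#' @param path output csv path.
#' @return `path`, invisibly.
#' @export
write_sites_csv <- function(sites, path) {
  row <- function(s, kind, rank) {
    data.frame(kind = kind, rank = rank,
               x = s$centroid[["x"]], y = s$centroid[["y"]],
               z = if ("z" %in% names(s$centroid)) s$centroid[["z"]] else NA,
               n_faces = s$n_faces, tau_median_nd = s$tau_median,
               tau_mean_nd = s$tau_mean,
               tau_median_Pa = s$tau_median_Pa %||% NA,
               tau_mean_Pa = s$tau_mean_Pa %||% NA)
  }
  rows <- c(mapply(row, sites$low_sites, "low",
                   seq_along(sites$low_sites), SIMPLIFY = FALSE),
            mapply(row, sites$high_sites, "high",
                   seq_along(sites$high_sites), SIMPLIFY = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write shear sites as JSON
#' @param sites a `shear_sites` object.
#' @param path output json path.
#' @return `path`, invisibly.
#' @export
write_sites_json <- function(sites, path) {
  strip <- function(s) s[setdiff(names(s), "faces")]
  jsonlite::write_json(
    list(threshold_low = sites$threshold_low,
         threshold_high = sites$threshold_high,
         field_median = sites$field_median,
         low_sites = lapply(sites$low_sites, strip),
         high_sites = lapply(sites$high_sites, strip)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
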