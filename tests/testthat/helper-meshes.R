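# Mesh fixtures built in code: unit icosphere, axis-aligned cube, and minimal
# ASCII/binary STL writers used to exercise the reader.

icosphere_mesh <- function(subdiv = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  structure(list(vertices = v * radius, faces = f), class = "stl_mesh")
}

cube_mesh <- function(edge = 1, origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * edge
  v <- sweep(v, 2, origin, `+`)
  colnames(v) <- NULL
  # 12 triangles, outward orientation
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z min
    c(5, 6, 7), c(6, 8, 7),   # z max
    c(1, 2, 5), c(2, 6, 5),   # y min
    c(3, 7, 4), c(4, 7, 8),   # y max
    c(1, 5, 3), c(3, 5, 7),   # x min
    c(2, 4, 6), c(4, 8, 6))   # x max
  structure(list(vertices = v, faces = f), class = "stl_mesh")
}

write_stl_ascii <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  v <- mesh$vertices
  for (t in seq_len(nrow(mesh$faces))) {
    p <- v[mesh$faces[t, ], , drop = FALSE]
    nrm <- c(crossprod3(p[2, ] - p[1, ], p[3, ] - p[1, ]))
    nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", nrm[1], nrm[2], nrm[3]), con)
    writeLines("    outer loop", con)
    for (k in 1:3)
      writeLines(sprintf("      vertex %.9g %.9g %.9g", p[k, 1], p[k, 2], p[k, 3]), con)
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid mesh", con)
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  ntri <- nrow(mesh$faces)
  writeBin(as.integer(ntri), con, size = 4L, endian = "little")
  v <- mesh$vertices
  for (t in seq_len(ntri)) {
    p <- v[mesh$faces[t, ], , drop = FALSE]
    nrm <- c(crossprod3(p[2, ] - p[1, ], p[3, ] - p[1, ]))
    nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
    writeBin(as.numeric(c(nrm, t(p))), con, size = 4L, endian = "little")
    writeBin(raw(2L), con)
  }
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# exact enclosed volume of a closed triangulated surface (divergence theorem)
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  abs(sum(sapply(seq_len(nrow(f)), function(t) {
    p <- v[f[t, ], , drop = FALSE]
    det(p) / 6
  })))
}

drop_one_facet <- function(mesh) {
  mesh$faces <- mesh$faces[-1, , drop = FALSE]
  mesh
}
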