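# STL reading, watertightness checking, and voxelization.

test_that("ascii and binary STL round-trip through the reader", {
  sph <- icosphere_mesh(2)
  fa <- withr::local_tempfile(fileext = ".stl")
  fb <- withr::local_tempfile(fileext = ".stl")
  write_stl_ascii(sph, fa)
  write_stl_binary(sph, fb)
  ma <- read_stl(fa); mb <- read_stl(fb)
  expect_equal(nrow(ma$faces), nrow(sph$faces))
  expect_equal(nrow(mb$faces), nrow(sph$faces))
  expect_identical(count_open_edges(ma), 0L)
  expect_identical(count_open_edges(mb), 0L)
  # float32 storage in the binary format limits agreement to ~1e-7
  expect_equal(sort(ma$vertices[, 1]), sort(mb$vertices[, 1]), tolerance = 1e-6)
})

test_that("voxelized sphere volume converges to 4/3 pi r^3", {
  sph <- icosphere_mesh(3)
  m <- voxelize_stl(sph, 1 / 32)
  vol <- sum(m$indicator == 0L) * m$spacing^3
  expect_lt(abs(vol / (4 * pi / 3) - 1), 0.02)
  # voxel volume converges (order >= 1) to the volume the voxelizer actually
  # targets: the polyhedron enclosed by the triangulated surface, which sits
  # ~0.8 percent inside the circumscribed sphere at this subdivision level
  vmesh <- mesh_volume(sph)
  errs <- sapply(c(8, 16, 32), function(n) {
    mm <- voxelize_stl(sph, 1 / n)
    abs(sum(mm$indicator == 0L) * mm$spacing^3 - vmesh)
  })
  orders <- log2(errs[-3] / errs[-1])
  expect_gte(mean(orders), 1)
})

test_that("an axis-aligned cube voxelizes to the exact cell count", {
  m <- voxelize_stl(cube_mesh(1), 1 / 16)
  expect_identical(sum(m$indicator == 0L), 4096L)
})

test_that("open meshes are rejected with the open-edge count", {
  broken <- drop_one_facet(icosphere_mesh(1))
  err <- expect_error(voxelize_stl(broken, 1 / 8),
                      class = "aneuflow_format_error")
  expect_match(conditionMessage(err), "3 open")
})
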