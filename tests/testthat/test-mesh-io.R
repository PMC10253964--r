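# Mesh file round trips and duplicate-vertex handling.

test_that("PLY and OBJ round trips are coordinate-exact", {
  m <- tetra_mesh(scale = 12.3456789123)
  for (fmt in c("ply", "obj")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_mesh(m, path)
    back <- read_mesh(path)
    expect_equal(back$vertices, m$vertices, tolerance = 0)
    expect_equal(back$faces, m$faces)
  }
})

test_that("binary STL round trips within float32 rounding", {
  m <- cube_mesh(edge = 10)
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(m, path, "stl")
  back <- read_mesh(path)
  # all edge lengths 10 mm (axis-aligned cube) within float32 rounding
  ed <- ssmesh:::mesh_edges(back)$edges
  len <- ssmesh:::edge_lengths(back, ed)
  axis_aligned <- len[abs(len - 10) < 1]
  expect_true(all(abs(axis_aligned - 10) < 1e-3))
  expect_equal(nrow(back$vertices), 8L)  # duplicated facet vertices merged
  expect_equal(nrow(back$faces), 12L)
})

test_that("STL duplicate per-facet vertices merge to unique points", {
  # a binary STL stores 3 vertices per facet: a tetrahedron has 12 stored
  # points but only 4 unique coordinate rows (brute-force oracle)
  m <- tetra_mesh()
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(m, path, "stl")
  con <- file(path, "rb")
  invisible(readBin(con, "raw", 80))
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  stored <- matrix(0, 3 * ntri, 3)
  for (i in seq_len(ntri)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
    stored[3 * (i - 1) + 1:3, ] <- matrix(rec[4:12], 3, byrow = TRUE)
  }
  close(con)
  expect_equal(nrow(stored), 12L)
  expect_equal(nrow(unique(round(stored, 6))), 4L)
  expect_equal(nrow(read_mesh(path)$vertices), 4L)
})

test_that("ASCII STL round trips and preserves connectivity", {
  m <- tetra_mesh(scale = 3)
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(m, path, "stl_ascii")
  back <- read_mesh(path)
  expect_equal(nrow(back$vertices), 4L)
  expect_equal(sort(as.vector(round(back$vertices, 9))),
               sort(as.vector(round(m$vertices, 9))))
})

test_that("OBJ writes 1-based indices on disk, reads back 0-shifted", {
  m <- tetra_mesh()
  path <- withr::local_tempfile(fileext = ".obj")
  write_mesh(m, path)
  txt <- readLines(path)
  fl <- grep("^f ", txt, value = TRUE)
  idx <- as.integer(unlist(strsplit(sub("^f ", "", fl), " ")))
  expect_equal(min(idx), 1L)
  expect_equal(max(idx), 4L)
  expect_equal(read_mesh(path)$faces, m$faces)
})

test_that("an icosphere reads back with expected counts and no boundary", {
  s <- icosphere(1)  # 42 vertices
  path <- withr::local_tempfile(fileext = ".ply")
  write_mesh(s, path)
  q <- mesh_quality(read_mesh(path))
  expect_equal(q$n_vertices, 42L)
  expect_equal(q$n_boundary_edges, 0L)
  expect_true(q$is_manifold)
  # Euler formula check V - E + F = 2 for a closed genus-0 surface
  E <- nrow(ssmesh:::mesh_edges(s)$edges)
  expect_equal(q$n_vertices - E + q$n_faces, 2L)
})

test_that("corrupt or empty inputs raise informative errors", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("not", "a", "ply"), path)
  expect_error(read_mesh(path), "line 1")
  path2 <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid x", "facet normal 0 0 1", "vertex 0 0 0",
               "endsolid x"), path2)
  expect_error(read_mesh(path2), "multiple of 3")
  expect_error(read_mesh(file.path(tempdir(), "nope_xyz.ply")), "not found")
})

test_that("PLY deviation-map export carries a per-vertex quality scalar", {
  m <- tetra_mesh()
  path <- withr::local_tempfile(fileext = ".ply")
  dm <- deviation_map(m$vertices, m$vertices + 2)
  export_deviation_map(dm, m, path)
  txt <- readLines(path)
  expect_true(any(grepl("property float quality", txt)))
  expect_true(file.exists(sub("\\.ply$", ".csv", path)))
  got <- read.csv(sub("\\.ply$", ".csv", path))
  expect_equal(got$distance_mm, dm$per_vertex_distance_mm)
})
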