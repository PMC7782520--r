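test_that("MRC round trip preserves data, voxel size and origin", {
  m0 <- random_map(8, seed = 11, voxel = 1.07, origin = c(-8, -8, -8))
  p1 <- withr::local_tempfile(fileext = ".mrc")
  write_map(m0, p1)
  m1 <- read_map(p1)
  # first generation quantizes double -> float32; a second round trip must be
  # bit-exact
  p2 <- withr::local_tempfile(fileext = ".mrc")
  write_map(m1, p2)
  m2 <- read_map(p2)
  expect_identical(m1$data, m2$data)
  expect_lt(max(abs(m1$data - m0$data)), 1e-6)
  expect_lt(max(abs(m1$voxel_size - 1.07)), 1e-4)
  expect_lt(max(abs(m1$origin - c(-8, -8, -8))), 1e-3)
  expect_identical(dim(m1), c(8L, 8L, 8L))
})

test_that("all-zero constructed map has the declared geometry", {
  m <- density_map(array(0, c(8, 8, 8)), voxel_size = 1.5)
  expect_identical(dim(m), c(8L, 8L, 8L))
  expect_equal(m$voxel_size, rep(1.5, 3))
})

test_that("origin falls back to NXSTART * voxel when ORIGIN is zero", {
  m <- density_map(array(seq_len(8^3), c(8, 8, 8)), voxel_size = 2.0)
  p <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, p)
  # patch header: NXSTART..NZSTART (words 5-7) = -4, ORIGIN (words 50-52) = 0
  con <- file(p, "r+b")
  seek(con, 16, rw = "write")
  writeBin(rep(-4L, 3), con, size = 4, endian = "little")
  seek(con, 4 * 49, rw = "write")
  writeBin(rep(0, 3), con, size = 4, endian = "little")
  close(con)
  m2 <- read_map(p)
  expect_equal(m2$origin, c(-8, -8, -8))
  expect_identical(m2$data, m$data)
})

test_that("written headers agree with an independent MRC reader (gemmi)", {
  m <- random_map(6, seed = 3, voxel = 1.25, origin = c(-3, -4.5, 2))
  p <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, p)
  out <- tryCatch(system2("python", c("-c", shQuote(sprintf(
    paste0("import gemmi; m = gemmi.read_ccp4_map('%s'); ",
           "print(round(m.grid.spacing[0], 6), m.header_float(50), ",
           "m.header_float(51), m.header_float(52))"), p
  ))), stdout = TRUE, stderr = TRUE), warning = function(w) NULL)
  expect_false(is.null(out))
  vals <- as.numeric(strsplit(trimws(out[length(out)]), " +")[[1]])
  expect_equal(vals[1], 1.25, tolerance = 1e-5)
  expect_equal(vals[2:4], c(-3, -4.5, 2), tolerance = 1e-5)
})

test_that("grid compatibility errors name the differing attribute", {
  m <- random_map(8, seed = 1)
  expect_invisible(assert_grid_compatible(m, m))
  m_dims <- density_map(array(0, c(8, 8, 7)), 1)
  expect_error(assert_grid_compatible(m, m_dims), "dims")
  m_vox <- density_map(m$data, 1.05)
  expect_error(assert_grid_compatible(m, m_vox), "voxel_size")
  m_orig <- density_map(m$data, 1, origin = c(0.5, 0, 0))
  expect_error(assert_grid_compatible(m, m_orig), "origin")
  expect_error(assert_grid_compatible(m), "at least two")
})

test_that("anisotropic voxel sizes beyond 1% are rejected naming the axis", {
  m <- random_map(8, seed = 2)
  p <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, p)
  con <- file(p, "r+b")
  seek(con, 4 * 10, rw = "write")          # CELLA
  writeBin(c(8, 8, 8 * 1.2), con, size = 4, endian = "little")
  close(con)
  expect_error(read_map(p), "axis z")
})

test_that("MAPC/MAPR/MAPS permutations are normalised on read", {
  m <- random_map(6, seed = 5, voxel = 1)
  p <- withr::local_tempfile(fileext = ".mrc")
  # write a file whose columns run along z: data must be permuted accordingly
  write_map(m, p)
  con <- file(p, "r+b")
  seek(con, 4 * 16, rw = "write")          # MAPC MAPR MAPS
  writeBin(c(3L, 1L, 2L), con, size = 4, endian = "little")
  close(con)
  # file data currently x-fastest but now declared z-fastest: re-reading must
  # invert the permutation
  m2 <- read_map(p)
  expect_equal(m2$data, aperm(m$data, order(c(3, 1, 2))), tolerance = 1e-6)
})

test_that("NaN sentinel substitution on write works", {
  d <- array(1, c(4, 4, 4))
  d[2, 2, 2] <- NaN
  m <- density_map(d, 1)
  p <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, p, nan = -999)
  m2 <- read_map(p)
  expect_equal(m2$data[2, 2, 2], -999)
  expect_equal(m2$data[1, 1, 1], 1)
})
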