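make_locres <- function(vals, provenance, dims = c(4, 4, 4)) {
  lr <- density_map(array(vals, dims), 1)
  lr$provenance <- provenance
  lr$params <- list(window = 11L, threshold = 0.5)
  class(lr) <- c("local_res_map", class(lr))
  lr
}

test_that("FSC-Q is the voxelwise difference of the two branches", {
  h <- make_locres(2.5, "half")
  mm <- make_locres(3.0, "map_model")
  q <- compute_fscq(mm, h)
  expect_true(all(q$data == 0.5))
  expect_true(all(compute_fscq(mm, mm, check_provenance = FALSE)$data == 0))
  # undefined parents stay undefined
  h2 <- h
  h2$data[1, 1, 1] <- NaN
  expect_true(is.nan(compute_fscq(mm, h2)$data[1, 1, 1]))
})

test_that("swapped provenance is refused to protect the sign convention", {
  h <- make_locres(2.5, "half")
  mm <- make_locres(3.0, "map_model")
  expect_error(compute_fscq(h, mm), "provenance")
  expect_silent(compute_fscq(h, mm, check_provenance = FALSE))
})

test_that("FSC-Q is antisymmetric in its arguments", {
  set.seed(31)
  a <- make_locres(runif(64, 2, 6), "half")
  b <- make_locres(runif(64, 2, 6), "half")
  q1 <- compute_fscq(a, b, check_provenance = FALSE)
  q2 <- compute_fscq(b, a, check_provenance = FALSE)
  expect_equal(q1$data, -q2$data)
})

test_that("FSC-Q_R is the fraction of the local resolution", {
  h <- make_locres(2.5, "half")
  mm <- make_locres(3.25, "map_model")
  qr <- compute_fscq_r(mm, h)
  # 0.30 reads as: the disagreement is 30% of the local resolution
  expect_equal(qr$data[1, 1, 1], 0.30)
  set.seed(32)
  hr <- make_locres(runif(64, 2, 6), "half")
  mr <- make_locres(runif(64, 2, 6), "map_model")
  q <- compute_fscq(mr, hr)
  qr2 <- compute_fscq_r(mr, hr)
  expect_equal(qr2$data * hr$data, q$data, tolerance = 1e-12)
  # zero or undefined half-map resolution gives NaN, never Inf
  h0 <- make_locres(c(0, rep(2.5, 63)), "half")
  expect_true(is.nan(compute_fscq_r(mr, h0)$data[1, 1, 1]))
})

test_that("atom projection samples constants and voxel centres exactly", {
  vol <- density_map(array(7.5, c(8, 8, 8)), 1, origin = c(0, 0, 0))
  model <- atomic_model(tibble::tibble(
    name = c("CA", "CB"), res_name = "ALA", chain = "A", res_seq = c(1, 2),
    x = c(3, 4.2), y = c(3, 3.7), z = c(3, 2.9), element = "C"
  ))
  for (mode in c("trilinear", "nearest")) {
    sc <- project_to_atoms(vol, model, mode = mode)
    expect_equal(sc$score, c(7.5, 7.5), info = mode)
  }
  # atom exactly at a voxel centre reads that voxel in both modes
  vol$data[4, 4, 4] <- -2
  m2 <- atomic_model(tibble::tibble(name = "CA", res_name = "ALA", chain = "A",
                                    res_seq = 1, x = 3, y = 3, z = 3,
                                    element = "C"))
  expect_equal(project_to_atoms(vol, m2, "nearest")$score, -2)
  expect_equal(project_to_atoms(vol, m2, "trilinear")$score, -2)
})

test_that("trilinear sampling at a midpoint averages the two voxels", {
  d <- array(1, c(8, 8, 8))
  d[4, 4, 4] <- 2
  d[5, 4, 4] <- 6
  vol <- density_map(d, 1, origin = c(0, 0, 0))
  m <- atomic_model(tibble::tibble(name = "CA", res_name = "ALA", chain = "A",
                                   res_seq = 1, x = 3.5, y = 3, z = 3,
                                   element = "C"))
  expect_equal(project_to_atoms(vol, m, "trilinear")$score, 4)
})

test_that("atoms outside the box score NaN with a warning", {
  vol <- density_map(array(1, c(8, 8, 8)), 1)
  m <- atomic_model(tibble::tibble(name = c("CA", "CB"), res_name = "ALA",
                                   chain = "A", res_seq = 1:2,
                                   x = c(3, 1e6), y = 3, z = 3, element = "C"))
  expect_warning(sc <- project_to_atoms(vol, m), "outside")
  expect_equal(sc$score[1], 1)
  expect_true(is.nan(sc$score[2]))
})

test_that("score summaries enumerate flags, means and undefined atoms", {
  m <- atomic_model(tibble::tibble(
    name = c("CA", "CB", "CG", "CD"), res_name = "LYS", chain = "A",
    res_seq = c(1, 1, 2, 2), x = 0, y = 0, z = 0, element = "C"
  ))
  m$score <- c(0.6, -0.7, 0.1, NaN)
  s <- summarize_fscq(m, cutoff = 0.5)
  expect_equal(s$n_above, 1L)
  expect_equal(s$n_below, 1L)
  expect_equal(s$n_nan, 1L)
  expect_equal(s$mean_abs, mean(abs(c(0.6, -0.7, 0.1))), tolerance = 1e-12)
  expect_equal(s$pct_above, 25)
  expect_equal(sort(s$flagged_residues$res_seq), c(1))
  m$score <- rep(0, 4)
  s0 <- summarize_fscq(m)
  expect_equal(s0$n_above + s0$n_below, 0L)
  expect_equal(s0$mean_abs, 0)
  expect_equal(nrow(s0$flagged_residues), 0L)
})
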