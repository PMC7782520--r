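test_that("fsc_curve matches the brute-force DFT shell oracle", {
  for (seed in c(1, 2, 3)) {
    a <- random_map(8, seed = seed)
    b <- random_map(8, seed = seed + 100)
    cv <- fsc_curve(a, b)
    expect_equal(cv$fsc, brute_fsc(a$data, b$data), tolerance = 1e-10)
  }
})

test_that("FSC is 1 for self-comparison and invariant to scaling", {
  m <- random_map(12, seed = 4)
  expect_true(all(abs(fsc_curve(m, m)$fsc - 1) < 1e-12))
  m2 <- density_map(2 * m$data, m$voxel_size, m$origin)
  expect_true(all(abs(fsc_curve(m, m2)$fsc - 1) < 1e-12))
  expect_error(fsc_curve(m, density_map(array(0, dim(m$data)), 1)), "all-zero")
})

test_that("whole-box FSC is unchanged by shell-constant B-factor scaling", {
  a <- random_map(16, seed = 21)
  b <- random_map(16, seed = 22)
  base <- fsc_curve(a, b)$fsc
  for (B in c(-120, -50, 80)) {
    sharp <- apply_bfactor(a, B, shell_constant = TRUE)
    expect_lt(max(abs(fsc_curve(sharp, b)$fsc - base)), 1e-6)
  }
  # a smooth (non-shell-constant) scaling is only approximately invariant
  smooth <- apply_bfactor(a, -50, shell_constant = FALSE)
  expect_lt(max(abs(fsc_curve(smooth, b)$fsc - base)), 0.05)
})

test_that("threshold crossing interpolates linearly in frequency", {
  cv <- manual_curve(freq = c(0, 0.20, 0.25), fsc = c(1, 0.8, 0.4))
  expect_equal(resolution_at_threshold(cv, 0.5), 1 / 0.2375, tolerance = 1e-12)
  # never crossing -> Nyquist resolution
  flat <- manual_curve(freq = c(0, 0.1, 0.2, 0.3), fsc = rep(1, 4))
  expect_equal(resolution_at_threshold(flat, 0.5), 2.0)
  # below threshold from the first informative shell -> worst representable
  low <- manual_curve(freq = c(0, 0.1, 0.2), fsc = c(1, 0.1, 0.05))
  expect_equal(resolution_at_threshold(low, 0.5), 10)
})

test_that("the window rule applies the five-times-resolution and floor rules", {
  expect_identical(default_window(1.5, 0.6), 13L)
  expect_identical(default_window(1.25, 0.8), 11L)
  expect_identical(default_window(2.8, 1.0), 15L)
  for (res in seq(0.8, 6, by = 0.4)) {
    for (vox in c(0.5, 0.8, 1.0, 1.3)) {
      w <- default_window(res, vox)
      expect_identical(w %% 2L, 1L)
      if (res < 2) expect_gte(w, 11L)
      expect_gte(w + 1L, 5 * res / vox)
    }
  }
  expect_error(default_window(0, 1))
})

test_that("identical maps give Nyquist everywhere evaluated", {
  model <- make_helix_model(6)
  dims <- c(32, 32, 32)
  origin <- c(-16, -16, -12)
  mp <- model_to_map(model, dims, 1, origin)
  msk <- make_soft_mask(mp)
  lr <- local_resolution_map(mp, mp, msk, window = 11, threshold = 0.5,
                             provenance = "half")
  vals <- lr$data[is.finite(lr$data)]
  expect_gt(length(vals), 100)
  expect_true(all(vals == 2.0))
  # voxels outside the support are NaN
  expect_true(is.nan(lr$data[1, 1, 1]))
})

test_that("local resolution values respect the representable bounds", {
  sc <- scenario_inputs("matched_clean", seed = 3)
  noisy1 <- density_map(sc$half1$data + array(rnorm(48^3, sd = 0.3), c(48, 48, 48)),
                        1, sc$half1$origin)
  noisy2 <- density_map(sc$half2$data + array(rnorm(48^3, sd = 0.3), c(48, 48, 48)),
                        1, sc$half2$origin)
  mp <- model_to_map(sc$model, c(48, 48, 48), 1, sc$half1$origin)
  msk <- make_soft_mask(mp)
  lr <- local_resolution_map(noisy1, noisy2, msk, window = 11, threshold = 0.5,
                             step = 2, provenance = "half")
  vals <- lr$data[is.finite(lr$data)]
  expect_true(all(vals >= 2.0 - 1e-12))
  expect_true(all(vals <= 11.0 + 1e-12))
  # stride > 1 still fills every support voxel
  expect_equal(sum(is.finite(lr$data)), nrow(mask_support(msk, 0.5)))
})

test_that("windowed evaluation equals manual extraction plus curve crossing", {
  sc <- scenario_inputs("matched_noisy", seed = 5)
  msk <- make_soft_mask(model_to_map(sc$model, dim(sc$full$data), 1,
                                     sc$full$origin))
  w <- 11L
  lr <- local_resolution_map(sc$half1, sc$half2, msk, window = w,
                             threshold = 0.5, provenance = "half")
  sup <- mask_support(msk, 0.5)
  set.seed(17)
  rows <- sample(nrow(sup), 5)
  half <- (w - 1L) %/% 2L
  for (r in rows) {
    i <- sup$i[r]; j <- sup$j[r]; k <- sup$k[r]
    wa <- fscq:::extract_window(sc$half1$data, i, j, k, half)
    wb <- fscq:::extract_window(sc$half2$data, i, j, k, half)
    cv <- fsc_curve(density_map(wa, 1), density_map(wb, 1))
    expect_identical(lr$data[i, j, k], resolution_at_threshold(cv, 0.5))
  }
})

test_that("local resolution maps are bit-reproducible", {
  model <- make_helix_model(4)
  dims <- c(24, 24, 24)
  origin <- c(-12, -12, -10)
  hm <- make_half_maps(model, dims, 1, origin, noise_sigma = 0.05, seed = 3)
  msk <- make_soft_mask(hm$signal)
  run <- function() local_resolution_map(hm$half1, hm$half2, msk, window = 11,
                                         threshold = 0.5, provenance = "half")
  expect_identical(run()$data, run()$data)
})

test_that("window geometry is validated", {
  m <- random_map(16, seed = 2)
  msk <- density_map(array(1, c(16, 16, 16)), 1)
  expect_error(local_resolution_map(m, m, msk, window = 12, threshold = 0.5,
                                    provenance = "half"), "odd")
  expect_error(local_resolution_map(m, m, msk, window = 17, threshold = 0.5,
                                    provenance = "half"), "larger")
})
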