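test_that("a single atom's density integrates to its zero-frequency factor", {
  m <- single_atom_model(15.5, 15.5, 15.3)
  mp <- model_to_map(m, c(32, 32, 32), 1.0)
  ff <- electron_form_factors("C")[[1]]
  # sum * voxel^3 vs the closed-form Gaussian integral sum(a_i); truncation
  # and residual aliasing keep ~0.1% of the mass out
  expect_equal(sum(mp$data), sum(ff$a), tolerance = 2e-3)
})

test_that("a centred atom gives a radially non-increasing peak", {
  m <- single_atom_model(15, 15, 15)
  mp <- model_to_map(m, c(31, 31, 31), 1.0)
  expect_equal(which(mp$data == max(mp$data), arr.ind = TRUE)[1, ],
               c(dim1 = 16L, dim2 = 16L, dim3 = 16L), ignore_attr = TRUE)
  axis_profile <- mp$data[16:22, 16, 16]
  expect_true(all(diff(axis_profile) <= 0))
  # regions beyond the kernel cutoff hold exactly zero
  expect_true(all(mp$data[28:31, , ] == 0))
})

test_that("density is linear in the model", {
  a <- single_atom_model(10, 14, 16)
  b <- single_atom_model(20, 16, 14, element = "N")
  ab <- atomic_model(dplyr::bind_rows(a, b))
  grid <- list(dims = c(32, 32, 32), voxel = 1.0)
  da <- model_to_map(a, grid$dims, grid$voxel)
  db <- model_to_map(b, grid$dims, grid$voxel)
  dab <- model_to_map(ab, grid$dims, grid$voxel)
  expect_equal(dab$data, da$data + db$data, tolerance = 1e-12)
})

test_that("shifting a model by whole voxels shifts the map identically", {
  m <- single_atom_model(14, 15, 16)
  m2 <- m
  m2$x <- m2$x + 3
  d1 <- model_to_map(m, c(32, 32, 32), 1.0)
  d2 <- model_to_map(m2, c(32, 32, 32), 1.0)
  expect_identical(d2$data[9:28, , ], d1$data[6:25, , ])
})

test_that("unknown elements fall back to carbon with a warning", {
  m <- single_atom_model(15, 15, 15, element = "Xx")
  expect_warning(ff <- electron_form_factors("Xx"), "carbon")
  expect_warning(mp <- model_to_map(m, c(32, 32, 32), 1.0), "carbon")
  ref <- model_to_map(single_atom_model(15, 15, 15), c(32, 32, 32), 1.0)
  expect_identical(mp$data, ref$data)
})

test_that("half maps are deterministic and degenerate at zero noise", {
  model <- make_helix_model(6)
  dims <- c(32, 32, 32)
  origin <- c(-16, -16, -12)
  clean <- make_half_maps(model, dims, 1, origin, noise_sigma = 0, seed = 1)
  expect_identical(clean$half1$data, clean$half2$data)
  expect_identical(clean$full$data, clean$signal$data)
  a <- make_half_maps(model, dims, 1, origin, noise_sigma = 0.1, seed = 42)
  b <- make_half_maps(model, dims, 1, origin, noise_sigma = 0.1, seed = 42)
  expect_identical(a$half1$data, b$half1$data)
  expect_identical(a$half2$data, b$half2$data)
  c2 <- make_half_maps(model, dims, 1, origin, noise_sigma = 0.1, seed = 43)
  expect_false(identical(a$half1$data, c2$half1$data))
})

test_that("half-map shell correlation decays as noise grows", {
  model <- make_helix_model(6)
  dims <- c(32, 32, 32)
  origin <- c(-16, -16, -12)
  shell_val <- function(sigma) {
    hm <- make_half_maps(model, dims, 1, origin, noise_sigma = sigma, seed = 5)
    cv <- fsc_curve(hm$half1, hm$half2)
    mean(cv$fsc[cv$shell %in% 6:10])
  }
  vals <- vapply(c(0.02, 0.1, 0.4), shell_val, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("side-chain perturbation is rigid, local and seeded", {
  model <- make_helix_model(8)
  expect_identical(perturb_side_chain(model, "A", 2, 0, seed = 1), model)
  p <- perturb_side_chain(model, "A", 2, 2.0, seed = 1)
  moved <- model$chain == "A" & model$res_seq == 2 &
    !(model$name %in% c("N", "CA", "C", "O", "OXT"))
  d <- sqrt((p$x - model$x)^2 + (p$y - model$y)^2 + (p$z - model$z)^2)
  expect_equal(d[moved], rep(2.0, sum(moved)))
  expect_true(all(d[!moved] == 0))
  # same seed, same displacement; direction override is honoured
  p2 <- perturb_side_chain(model, "A", 2, 2.0, seed = 1)
  expect_identical(p, p2)
  p3 <- perturb_side_chain(model, "A", 2, 2.0, direction = c(0, 0, 1))
  expect_equal(p3$z[moved] - model$z[moved], rep(2, sum(moved)))
  expect_error(perturb_side_chain(model, "A", 99, 1), "not found")
  gly <- model
  gly$res_name[gly$res_seq == 3] <- "GLY"
  bb <- gly$res_seq != 3 | gly$name %in% c("N", "CA", "C", "O")
  gly <- atomic_model(gly[bb, ])
  expect_error(perturb_side_chain(gly, "A", 3, 1), "side-chain")
})

test_that("model jitter is seeded and scales with sigma", {
  model <- make_helix_model(6)
  j1 <- jitter_model(model, 0.3, seed = 2)
  j2 <- jitter_model(model, 0.3, seed = 2)
  expect_identical(j1, j2)
  expect_identical(jitter_model(model, 0, seed = 2), model)
  d <- sqrt((j1$x - model$x)^2 + (j1$y - model$y)^2 + (j1$z - model$z)^2)
  expect_true(all(d > 0))
  expect_lt(max(d), 0.3 * 6)
})
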