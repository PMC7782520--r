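#' Synthetic helix model
#'
#' Builds an idealized alpha-helical peptide (rise 1.5 A, 100 degrees per
#' residue, CA radius 2.3 A) with a repeating ALA-LYS-SER-GLN sequence, so
#' the scene contains residues with and without long side chains.  The
#' geometry is schematic — bond lengths are plausible (1.2-1.6 A) but not
#' refined stereochemistry — which is all the density simulation needs.
#'
#' @param n_res Number of residues.
#' @param chain Chain identifier.
#' @return An [atomic_model].
#' @export
make_helix_model <- function(n_res = 28, chain = "A") {
  stopifnot(n_res >= 1)
  seq_names <- rep(c("ALA", "LYS", "SER", "GLN"), length.out = n_res)
  rows <- list()
  for (i in seq_len(n_res)) {
    phi <- (i - 1) * 100 * pi / 180
    zc <- (i - 1) * 1.5
    u <- c(cos(phi), sin(phi), 0)   # radial, outward
    v <- c(-sin(phi), cos(phi), 0)  # tangential
    w <- c(0, 0, 1)                 # axial
    ca <- 2.3 * u + zc * w
    pos <- list(
      N = ca - 0.65 * u + 1.0 * v - 0.75 * w,
      CA = ca,
      C = ca - 0.65 * u - 1.0 * v + 0.75 * w,
      O = ca - 1.65 * u - 1.0 * v + 1.45 * w
    )
    elem <- c(N = "N", CA = "C", C = "C", O = "O")
    res <- seq_names[i]
    if (res != "GLY") {
      pos$CB <- ca + 1.35 * u + 0.7 * w
      elem["CB"] <- "C"
    }
    if (res == "LYS") {
      pos$CG <- pos$CB + c(1.3 * u - 0.6 * v)
      pos$CD <- pos$CG + c(1.3 * u + 0.6 * v)
      pos$CE <- pos$CD + c(1.3 * u - 0.6 * v)
      pos$NZ <- pos$CE + c(1.3 * u + 0.6 * v)
      elem[c("CG", "CD", "CE", "NZ")] <- c("C", "C", "C", "N")
    } else if (res == "SER") {
      pos$OG <- pos$CB + c(1.2 * u + 0.6 * w)
      elem["OG"] <- "O"
    } else if (res == "GLN") {
      pos$CG <- pos$CB + c(1.3 * u - 0.6 * v)
      pos$CD <- pos$CG + c(1.3 * u + 0.6 * v)
      pos$OE1 <- pos$CD + c(0.8 * u + 0.95 * w)
      pos$NE2 <- pos$CD + c(0.8 * u - 0.95 * w)
      elem[c("CG", "CD", "OE1", "NE2")] <- c("C", "C", "O", "N")
    }
    m <- do.call(rbind, pos)
    rows[[i]] <- tibble::tibble(
      name = rownames(m), res_name = res, chain = chain, res_seq = i,
      x = unname(m[, 1]), y = unname(m[, 2]), z = unname(m[, 3]),
      occupancy = 1, bfactor = 30, element = unname(elem[rownames(m)]),
      is_hetero = FALSE
    )
  }
  atomic_model(dplyr::bind_rows(rows))
}

# Named scene definitions used by the test-suite and the acceptance script.
# Two constants of the noisy scenes were calibrated once, at scenario
# creation, and frozen: noise_sigma so that the mask-weighted global
# half-map FSC crosses 0.143 near 3 A on this grid (the masked curve is what
# reported resolutions refer to), and fit_jitter (per-axis coordinate error
# of the fitted model, A) so that the masked map-model FSC crossing at 2/3
# coincides with the half-map crossing at 1/2 -- the statistical regime the
# threshold pairing assumes for a refined-but-correct model.  The
# matched-model median tolerance band (Angstrom) was registered at the same
# time.  These constants are part of the scenario definition and are not
# tuning knobs.
scenario_table <- function() {
  list(
    matched_clean = list(
      n_res = 12, dims = c(48L, 48L, 48L), voxel = 1.0,
      noise_sigma = 0, fit_jitter = 0, global_resolution = 3.0,
      perturb = NULL, median_band = c(0, 0)
    ),
    matched_noisy = list(
      n_res = 28, dims = c(64L, 64L, 64L), voxel = 1.0,
      noise_sigma = 0.057, fit_jitter = 0.25, global_resolution = 3.0,
      perturb = NULL, median_band = c(-0.25, 0.25)
    ),
    rotamer_flip = list(
      n_res = 28, dims = c(64L, 64L, 64L), voxel = 1.0,
      noise_sigma = 0.057, fit_jitter = 0.25, global_resolution = 3.0,
      perturb = list(chain = "A", res_seq = 28, displacement = 2.0,
                     direction = "outward"),
      median_band = c(-0.25, 0.25)
    )
  )
}

#' Scenario names
#' @return Character vector of known scenario identifiers.
#' @export
scenario_names <- function() names(scenario_table())

#' In-memory inputs for a named scenario
#'
#' Deterministically generates the standard synthetic scenes: a helix model,
#' its simulated density, two half maps with independent noise, and the full
#' map.  The fitted model returned for scoring carries refinement-scale
#' coordinate error ([jitter_model()]) in the noisy scenes; in
#' `rotamer_flip` it additionally has one LYS side chain rigidly displaced
#' by 2 A — the maps reflect reality and the model is wrong, emulating a
#' misfit rotamer.  Same `(name, seed)` gives bit-identical outputs.
#'
#' @param name One of [scenario_names()].
#' @param seed Integer seed.
#' @return List: `model` (the model to score), `true_model`, `half1`,
#'   `half2`, `full`, `global_resolution`, `noise_sigma`, `median_band`,
#'   `perturb`.
#' @export
scenario_inputs <- function(name, seed = 7) {
  defs <- scenario_table()
  def <- defs[[name]]
  if (is.null(def)) {
    stop(sprintf("unknown scenario '%s' (known: %s)", name,
                 paste(names(defs), collapse = ", ")), call. = FALSE)
  }
  true_model <- make_helix_model(def$n_res)
  centre <- c(0, 0, (def$n_res - 1) * 1.5 / 2)
  origin <- centre - (def$dims - 1) / 2 * def$voxel
  maps <- make_half_maps(true_model, def$dims, def$voxel, origin,
                         noise_sigma = def$noise_sigma, seed = seed)
  model <- jitter_model(true_model, def$fit_jitter, seed = seed + 2000L)
  if (!is.null(def$perturb)) {
    # displace radially away from the helix axis: the misfit side chain ends
    # up clearly outside the density rather than on a neighbouring one
    dir <- NULL
    if (identical(def$perturb$direction, "outward")) {
      phi <- (def$perturb$res_seq - 1) * 100 * pi / 180
      dir <- c(cos(phi), sin(phi), 0)
    }
    model <- perturb_side_chain(model, def$perturb$chain,
                                def$perturb$res_seq, def$perturb$displacement,
                                seed = seed + 1000L, direction = dir)
  }
  list(model = model, true_model = true_model,
       half1 = maps$half1, half2 = maps$half2, full = maps$full,
       signal = maps$signal,
       global_resolution = def$global_resolution,
       noise_sigma = def$noise_sigma, median_band = def$median_band,
       perturb = def$perturb)
}

#' Write a scenario's pipeline inputs to disk
#'
#' Writes `full.mrc`, `half1.mrc`, `half2.mrc`, `model.pdb`, `mask.mrc` and a
#' `manifest.json` with MD5 checksums of every file, so reruns can be
#' verified to be bit-identical.
#'
#' @inheritParams scenario_inputs
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
build_scenario <- function(name, seed = 7, out_dir) {
  sc <- scenario_inputs(name, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_map(sc$full, file.path(out_dir, "full.mrc"))
  write_map(sc$half1, file.path(out_dir, "half1.mrc"))
  write_map(sc$half2, file.path(out_dir, "half2.mrc"))
  write_labeled_model(sc$model, sc$model$occupancy,
                      file.path(out_dir, "model.pdb"))
  model_map <- model_to_map(sc$model, dim(sc$full$data),
                            mean(sc$full$voxel_size), sc$full$origin)
  write_map(make_soft_mask(model_map), file.path(out_dir, "mask.mrc"))
  files <- c("full.mrc", "half1.mrc", "half2.mrc", "model.pdb", "mask.mrc")
  manifest <- list(
    scenario = name, seed = seed,
    global_resolution = sc$global_resolution,
    noise_sigma = sc$noise_sigma,
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files
    ))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run the pipeline on a named scenario
#'
#' Convenience wrapper: generates the scenario in memory and runs
#' [run_pipeline()] with the scenario's declared global resolution and
#' default parameters.
#'
#' @inheritParams scenario_inputs
#' @param ... Passed on to [run_config()] (e.g. `step`, `out_dir`).
#' @return An `fscq_result`.
#' @export
run_scenario <- function(name, seed = 7, ...) {
  sc <- scenario_inputs(name, seed)
  cfg <- run_config(map = sc$full, half1 = sc$half1, half2 = sc$half2,
                    model = sc$model,
                    global_resolution = sc$global_resolution, ...)
  run_pipeline(cfg)
}
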