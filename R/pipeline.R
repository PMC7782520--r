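#' Pipeline configuration
#'
#' Collects every input and parameter of an FSC-Q run.  Map/model arguments
#' may be file paths or in-memory objects ([density_map] / [atomic_model]).
#' The FSC thresholds default to 1/2 for the half-map branch and 2/3 for the
#' map-model branch; the sliding window defaults to [default_window()] of the
#' reported global resolution (required unless `window` is given).
#'
#' @param map,half1,half2 Full map and the two half maps (paths or
#'   [density_map]s).
#' @param model Atomic model (path or [atomic_model]).
#' @param mask Optional soft mask (path or `mask_volume`); built from the
#'   model map with the default recipe when absent.
#' @param global_resolution Reported overall resolution in Angstrom (used
#'   only for the window rule).
#' @param window Window override, odd voxels.
#' @param thr_half,thr_map_model FSC thresholds in (0, 1).
#' @param mask_threshold,mask_dilation,mask_soft_edge Soft-mask recipe.
#' @param step Local FSC evaluation stride.
#' @param interpolation Per-atom sampling, `"trilinear"` or `"nearest"`.
#' @param cutoff Atom flagging threshold, Angstrom.
#' @param use_adp Fold model B-factors into the simulated map.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param keep_intermediates Also write the model map, mask and both local
#'   resolution maps.
#' @return A `run_config` list.
#' @export
run_config <- function(map, half1, half2, model, mask = NULL,
                       global_resolution = NULL, window = NULL,
                       thr_half = 0.5, thr_map_model = 2 / 3,
                       mask_threshold = 0.02, mask_dilation = 3,
                       mask_soft_edge = 3, step = 1L,
                       interpolation = c("trilinear", "nearest"),
                       cutoff = 0.5, use_adp = FALSE, out_dir = NULL,
                       keep_intermediates = FALSE) {
  interpolation <- match.arg(interpolation)
  if (is.null(window) && is.null(global_resolution)) {
    stop("either `global_resolution` or `window` is required", call. = FALSE)
  }
  stopifnot(thr_half > 0, thr_half < 1, thr_map_model > 0, thr_map_model < 1)
  structure(list(
    map = map, half1 = half1, half2 = half2, model = model, mask = mask,
    global_resolution = global_resolution, window = window,
    thr_half = thr_half, thr_map_model = thr_map_model,
    mask_threshold = mask_threshold, mask_dilation = mask_dilation,
    mask_soft_edge = mask_soft_edge, step = as.integer(step),
    interpolation = interpolation, cutoff = cutoff, use_adp = use_adp,
    out_dir = out_dir, keep_intermediates = keep_intermediates
  ), class = "run_config")
}

load_map_input <- function(x) if (is_density_map(x)) x else read_map(x)
load_model_input <- function(x) {
  if (inherits(x, "atomic_model")) x else read_model(x)
}

#' Sanity-check pipeline inputs
#'
#' Returns findings rather than stopping: grid mismatches, atoms outside the
#' box, suspicious voxel sizes, and byte-identical half maps (a duplicated
#' file would make the half-map FSC identically 1).
#'
#' @param config A [run_config()].
#' @return A tibble with columns `level` (`"error"`/`"warning"`) and
#'   `message`; zero rows when the inputs look clean.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  findings <- list()
  add <- function(level, msg) findings[[length(findings) + 1L]] <<-
    tibble::tibble(level = level, message = msg)
  maps <- tryCatch(
    list(map = load_map_input(config$map), half1 = load_map_input(config$half1),
         half2 = load_map_input(config$half2)),
    error = function(e) {
      add("error", conditionMessage(e))
      NULL
    }
  )
  if (!is.null(maps)) {
    cmp <- tryCatch(assert_grid_compatible(maps), error = function(e) e)
    if (inherits(cmp, "error")) add("error", conditionMessage(cmp))
    if (identical(maps$half1$data, maps$half2$data)) {
      add("warning", "half maps are identical; half-map FSC will be 1 everywhere")
    }
    vox <- mean(maps$map$voxel_size)
    if (vox < 0.2 || vox > 5) {
      add("warning", sprintf("suspicious voxel size %.3g A", vox))
    }
    model <- tryCatch(load_model_input(config$model), error = function(e) {
      add("error", conditionMessage(e))
      NULL
    })
    if (!is.null(model)) {
      d <- dim(maps$map$data)
      lo <- maps$map$origin
      hi <- lo + (d - 1) * maps$map$voxel_size
      outside <- model$x < lo[1] | model$x > hi[1] |
        model$y < lo[2] | model$y > hi[2] |
        model$z < lo[3] | model$z > hi[3]
      if (any(outside)) {
        add("warning", sprintf("%d atoms outside the map box", sum(outside)))
      }
    }
  }
  if (length(findings)) dplyr::bind_rows(findings) else {
    tibble::tibble(level = character(), message = character())
  }
}

#' Run the full FSC-Q pipeline
#'
#' Reads the inputs, simulates the model map, builds the soft mask (unless
#' one is supplied), computes the two sliding-window local resolution maps
#' (half1 vs half2 at threshold 1/2; full map vs model map at 2/3), forms
#' FSC-Q and FSC-Q_R, projects FSC-Q onto the atoms and summarises.  When
#' `out_dir` is set, writes `fscq.mrc`, `fscq_r.mrc` (NaN as -999),
#' `model_fscq.pdb` (FSC-Q in the occupancy column), `report.json` and
#' `report.tsv`; with `keep_intermediates` also the model map, mask and
#' local resolution maps (NaN as -1).
#'
#' @param config A [run_config()].
#' @return An `fscq_result`: list with `fscq`, `fscq_r` (volumes),
#'   `v_half`, `v_map_model` (local resolution maps), `atom_scores`
#'   (model tibble with `score` and `score_r`), `summary`
#'   ([summarize_fscq()] output) and `params`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  full <- stage("read_inputs", load_map_input(config$map))
  half1 <- stage("read_inputs", load_map_input(config$half1))
  half2 <- stage("read_inputs", load_map_input(config$half2))
  model <- stage("read_inputs", load_model_input(config$model))
  stage("grid_check", assert_grid_compatible(full, half1, half2))

  vox <- mean(full$voxel_size)
  window <- config$window
  if (is.null(window)) window <- default_window(config$global_resolution, vox)

  model_map <- stage("model_to_map", model_to_map(
    model, dim(full$data), vox, full$origin, use_adp = config$use_adp
  ))
  mask <- if (is.null(config$mask)) {
    stage("make_soft_mask", make_soft_mask(
      model_map, config$mask_threshold, config$mask_dilation,
      config$mask_soft_edge
    ))
  } else {
    m <- stage("read_inputs", load_map_input(config$mask))
    stage("grid_check", assert_grid_compatible(full, m))
    class(m) <- unique(c("mask_volume", class(m)))
    m
  }

  v_half <- stage("local_fsc_half", local_resolution_map(
    half1, half2, mask, window, config$thr_half, step = config$step,
    provenance = "half"
  ))
  v_map_model <- stage("local_fsc_map_model", local_resolution_map(
    full, model_map, mask, window, config$thr_map_model, step = config$step,
    provenance = "map_model"
  ))
  fscq <- stage("fscq", compute_fscq(v_map_model, v_half))
  fscq_r <- stage("fscq", compute_fscq_r(v_map_model, v_half))

  scored <- stage("project_to_atoms",
                  project_to_atoms(fscq, model, mode = config$interpolation))
  scored_r <- stage("project_to_atoms",
                    project_to_atoms(fscq_r, model, mode = config$interpolation))
  scored$score_r <- scored_r$score
  summ <- stage("summarize", summarize_fscq(scored, cutoff = config$cutoff))

  params <- list(
    window = window, thr_half = config$thr_half,
    thr_map_model = config$thr_map_model, step = config$step,
    mask_threshold = config$mask_threshold,
    mask_dilation = config$mask_dilation,
    mask_soft_edge = config$mask_soft_edge,
    interpolation = config$interpolation, cutoff = config$cutoff,
    use_adp = config$use_adp, voxel_size = vox, dims = dim(full$data),
    global_resolution = config$global_resolution
  )
  result <- structure(list(
    fscq = fscq, fscq_r = fscq_r, v_half = v_half, v_map_model = v_map_model,
    mask = mask, model_map = model_map, atom_scores = scored, summary = summ,
    params = params
  ), class = "fscq_result")

  if (!is.null(config$out_dir)) {
    stage("write_outputs", write_result(result, config$out_dir,
                                        keep_intermediates = config$keep_intermediates,
                                        config = config))
  }
  result
}

checksum_if_path <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    unname(tools::md5sum(x))
  } else {
    NA_character_
  }
}

write_result <- function(result, out_dir, keep_intermediates = FALSE,
                         config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_map(result$fscq, file.path(out_dir, "fscq.mrc"), nan = -999)
  write_map(result$fscq_r, file.path(out_dir, "fscq_r.mrc"), nan = -999)
  write_labeled_model(result$atom_scores, result$atom_scores$score,
                      file.path(out_dir, "model_fscq.pdb"))
  if (keep_intermediates) {
    write_map(result$model_map, file.path(out_dir, "model_map.mrc"))
    write_map(result$mask, file.path(out_dir, "mask.mrc"))
    write_map(result$v_half, file.path(out_dir, "locres_half.mrc"), nan = -1)
    write_map(result$v_map_model, file.path(out_dir, "locres_map_model.mrc"),
              nan = -1)
  }
  tab <- result$atom_scores[, c("serial", "name", "chain", "res_name",
                                "res_seq", "score", "score_r")]
  names(tab)[names(tab) == "score"] <- "fscq"
  names(tab)[names(tab) == "score_r"] <- "fscq_r"
  utils::write.table(tab, file.path(out_dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  s <- result$summary
  provenance <- list(
    package = "fscq",
    version = as.character(utils::packageVersion("fscq")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), tz = "UTC"),
    input_md5 = if (!is.null(config)) list(
      map = checksum_if_path(config$map), half1 = checksum_if_path(config$half1),
      half2 = checksum_if_path(config$half2), model = checksum_if_path(config$model)
    )
  )
  report <- list(
    params = result$params,
    provenance = provenance,
    summary = list(
      n_atoms = s$n_atoms, n_scored = s$n_scored, n_nan = s$n_nan,
      n_above = s$n_above, n_below = s$n_below,
      pct_above = s$pct_above, pct_below = s$pct_below,
      mean_abs_fscq = s$mean_abs, mean_fscq = s$mean_signed,
      median_fscq = s$median_signed, cutoff = s$cutoff
    ),
    flagged_residues = s$flagged_residues
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}

#' @export
print.fscq_result <- function(x, ...) {
  cat(sprintf("<fscq_result> %s grid, window %d voxels (thr %.3g / %.3g)\n",
              paste(x$params$dims, collapse = "x"), x$params$window,
              x$params$thr_half, x$params$thr_map_model))
  print(x$summary)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-atom scores of an FSC-Q run
#'
#' @param x An `fscq_result`.
#' @param ... Ignored.
#' @return A tibble with one row per atom: identity columns, `fscq` (A) and
#'   `fscq_r`.
#' @method tidy fscq_result
#' @export
tidy.fscq_result <- function(x, ...) {
  out <- tibble::as_tibble(x$atom_scores[, c("serial", "name", "element",
                                             "chain", "res_name", "res_seq",
                                             "score", "score_r")])
  names(out)[names(out) == "score"] <- "fscq"
  names(out)[names(out) == "score_r"] <- "fscq_r"
  out
}

#' One-row summary of an FSC-Q run
#'
#' @param x An `fscq_result`.
#' @param ... Ignored.
#' @return A one-row tibble: atom counts, flagged counts/percentages, mean
#'   absolute and median FSC-Q, window and thresholds.
#' @method glance fscq_result
#' @export
glance.fscq_result <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_atoms = s$n_atoms, n_scored = s$n_scored, n_nan = s$n_nan,
    n_above = s$n_above, n_below = s$n_below,
    pct_flagged = s$pct_above + s$pct_below,
    mean_abs_fscq = s$mean_abs, mean_fscq = s$mean_signed,
    median_fscq = s$median_signed,
    window = x$params$window, thr_half = x$params$thr_half,
    thr_map_model = x$params$thr_map_model
  )
}

#' Histogram of per-atom FSC-Q scores
#'
#' @param object An `fscq_result`.
#' @param bins Number of histogram bins.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot fscq_result
#' @export
autoplot.fscq_result <- function(object, bins = 40, ...) {
  df <- tidy(object)
  df <- df[is.finite(df$fscq), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fscq)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "grey20") +
    ggplot2::geom_vline(xintercept = c(-object$summary$cutoff, 0,
                                       object$summary$cutoff),
                        linetype = c(2, 1, 2)) +
    ggplot2::labs(x = "FSC-Q (Å)", y = "atoms")
}
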