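check_locres_pair <- function(v_map_model, v_half, check_provenance) {
  stopifnot(inherits(v_map_model, "local_res_map"),
            inherits(v_half, "local_res_map"))
  assert_grid_compatible(v_map_model, v_half)
  if (check_provenance) {
    if (!identical(v_map_model$provenance, "map_model") ||
        !identical(v_half$provenance, "half")) {
      stop(paste0(
        "provenance mismatch: expected (map_model, half), got (",
        v_map_model$provenance %||% "?", ", ", v_half$provenance %||% "?",
        "); a swapped argument order would silently flip the sign of FSC-Q"
      ), call. = FALSE)
    }
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' FSC-Q: local resolution difference between map-model and half maps
#'
#' The per-voxel difference, in Angstrom, between the local resolution of the
#' full map against the model-simulated map and the local resolution between
#' the two half maps.  Values near zero mean the model is supported by the
#' reproducible signal of the data; positive values flag poorly fitted atoms
#' or regions of low resolvability (the model demands resolution the half
#' maps do not support); negative values flag map-model correlation better
#' than the half-map signal, typical of atoms correlating with noise.
#' Undefined wherever either parent volume is undefined.
#'
#' @param v_map_model Local resolution map of (full map, model map), FSC
#'   threshold 2/3.
#' @param v_half Local resolution map of (half1, half2), FSC threshold 1/2.
#' @param check_provenance Refuse swapped arguments (default TRUE).
#' @return A `fscq_map` ([density_map] subclass), Angstrom values.
#' @export
compute_fscq <- function(v_map_model, v_half, check_provenance = TRUE) {
  check_locres_pair(v_map_model, v_half, check_provenance)
  vals <- v_map_model$data - v_half$data
  out <- density_map(vals, v_map_model$voxel_size, v_map_model$origin)
  class(out) <- c("fscq_map", class(out))
  out
}

#' FSC-Q_R: FSC-Q as a fraction of the local resolution
#'
#' FSC-Q divided by the half-map local resolution.  A value of 0.3 reads as
#' "the map-model disagreement represents 30% of the local resolution".
#' Defined where both parents are defined and the half-map local resolution
#' is positive.
#'
#' @inheritParams compute_fscq
#' @return A `fscq_map` ([density_map] subclass), dimensionless values.
#' @export
compute_fscq_r <- function(v_map_model, v_half, check_provenance = TRUE) {
  check_locres_pair(v_map_model, v_half, check_provenance)
  h <- v_half$data
  vals <- ifelse(is.finite(h) & h > 0, (v_map_model$data - h) / h, NaN)
  vals <- array(vals, dim(h))
  out <- density_map(vals, v_map_model$voxel_size, v_map_model$origin)
  class(out) <- c("fscq_map", class(out))
  out
}

#' Sample a per-voxel volume at atom positions
#'
#' Projects a score volume onto the atoms of a model: each atom receives the
#' volume value interpolated at its coordinates (trilinear by default, or the
#' nearest voxel).  Atoms outside the box, or whose interpolation
#' neighbourhood contains undefined voxels, score `NaN` — never an error.
#'
#' @param volume A [density_map] (e.g. FSC-Q or FSC-Q_R).
#' @param model An [atomic_model].
#' @param mode `"trilinear"` or `"nearest"`.
#' @return The model tibble with a `score` column appended.
#' @export
project_to_atoms <- function(volume, model, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(is_density_map(volume), inherits(model, "atomic_model"))
  d <- dim(volume$data)
  vox <- volume$voxel_size
  g1 <- (model$x - volume$origin[1]) / vox[1]  # 0-based fractional indices
  g2 <- (model$y - volume$origin[2]) / vox[2]
  g3 <- (model$z - volume$origin[3]) / vox[3]
  n <- nrow(model)
  score <- rep(NaN, n)

  if (mode == "nearest") {
    i <- round(g1) + 1; j <- round(g2) + 1; k <- round(g3) + 1
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
    score[ok] <- volume$data[cbind(i[ok], j[ok], k[ok])]
  } else {
    i0 <- floor(g1); j0 <- floor(g2); k0 <- floor(g3)
    fx <- g1 - i0; fy <- g2 - j0; fz <- g3 - k0
    ok <- i0 >= 0 & i0 + 1 <= d[1] - 1 & j0 >= 0 & j0 + 1 <= d[2] - 1 &
      k0 >= 0 & k0 + 1 <= d[3] - 1
    if (any(ok)) {
      acc <- numeric(sum(ok))
      io <- i0[ok]; jo <- j0[ok]; ko <- k0[ok]
      fxo <- fx[ok]; fyo <- fy[ok]; fzo <- fz[ok]
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        w <- (if (dx) fxo else 1 - fxo) *
          (if (dy) fyo else 1 - fyo) *
          (if (dz) fzo else 1 - fzo)
        v <- volume$data[cbind(io + dx + 1, jo + dy + 1, ko + dz + 1)]
        acc <- acc + w * v
      }
      score[ok] <- acc
    }
  }
  if (any(!ok)) {
    warning(sprintf("%d atoms fall outside the volume; scored NaN", sum(!ok)))
  }
  out <- model
  out$score <- score
  out
}

#' Summarise per-atom FSC-Q scores
#'
#' Counts and percentages of atoms whose FSC-Q exceeds `cutoff` in either
#' direction (default 0.5 A, the conventional reporting threshold), the mean
#' of absolute scores (the averaging used for per-fragment figures), the
#' signed mean, a per-residue table, and the residues containing flagged
#' atoms.  Undefined scores are counted, never silently dropped to zero.
#'
#' @param scored An [atomic_model] with a `score` column (FSC-Q, Angstrom),
#'   as returned by [project_to_atoms()].
#' @param cutoff Flagging threshold in Angstrom (default 0.5).
#' @return An object of class `fscq_summary`: a list with scalars `n_atoms`,
#'   `n_scored`, `n_nan`, `n_above`, `n_below`, `pct_above`, `pct_below`,
#'   `mean_abs`, `mean_signed`, `median_signed`, `cutoff`, and tibbles
#'   `per_residue` and `flagged_residues`.
#' @export
summarize_fscq <- function(scored, cutoff = 0.5) {
  stopifnot(inherits(scored, "atomic_model"))
  if (is.null(scored$score) || nrow(scored) == 0) {
    stop("no scores to summarise", call. = FALSE)
  }
  s <- scored$score
  ok <- is.finite(s)
  n <- length(s)
  n_above <- sum(s[ok] > cutoff)
  n_below <- sum(s[ok] < -cutoff)
  per_res <- scored |>
    dplyr::group_by(.data$chain, .data$res_seq, .data$res_name) |>
    dplyr::summarise(
      n_atoms = dplyr::n(),
      n_scored = sum(is.finite(.data$score)),
      mean_abs_fscq = mean(abs(.data$score[is.finite(.data$score)])),
      mean_fscq = mean(.data$score[is.finite(.data$score)]),
      n_flagged = sum(is.finite(.data$score) & abs(.data$score) > cutoff),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chain, .data$res_seq)
  structure(list(
    n_atoms = n,
    n_scored = sum(ok),
    n_nan = sum(!ok),
    n_above = n_above,
    n_below = n_below,
    pct_above = 100 * n_above / n,
    pct_below = 100 * n_below / n,
    mean_abs = if (any(ok)) mean(abs(s[ok])) else NaN,
    mean_signed = if (any(ok)) mean(s[ok]) else NaN,
    median_signed = if (any(ok)) stats::median(s[ok]) else NaN,
    cutoff = cutoff,
    per_residue = per_res,
    flagged_residues = dplyr::filter(per_res, .data$n_flagged > 0)
  ), class = "fscq_summary")
}

#' @export
print.fscq_summary <- function(x, ...) {
  cat(sprintf("FSC-Q summary over %d atoms (%d scored, %d undefined)\n",
              x$n_atoms, x$n_scored, x$n_nan))
  cat(sprintf("  mean |FSC-Q| %.3f A, signed mean %.3f A, median %.3f A\n",
              x$mean_abs, x$mean_signed, x$median_signed))
  cat(sprintf("  FSC-Q > %+.2f A: %d atoms (%.1f%%);  FSC-Q < %+.2f A: %d atoms (%.1f%%)\n",
              x$cutoff, x$n_above, x$pct_above, -x$cutoff, x$n_below, x$pct_below))
  if (nrow(x$flagged_residues)) {
    cat(sprintf("  %d residues contain flagged atoms\n", nrow(x$flagged_residues)))
  }
  invisible(x)
}
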