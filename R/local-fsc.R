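# Shell geometry for a cubic (or near-cubic) FFT grid.  Frequencies are
# binned into shells one Fourier voxel wide: shell s collects coefficients
# with round(|k|) == s where k is the integer frequency vector, up to the
# Nyquist index floor(N/2).  Cached per (dims) since the sliding window
# reuses the same geometry at every voxel.
.shell_cache <- new.env(parent = emptyenv())

fsc_shell_geometry <- function(dims) {
  key <- paste(dims, collapse = "x")
  hit <- .shell_cache[[key]]
  if (!is.null(hit)) return(hit)
  nmax <- max(dims)
  axfreq <- function(n) {
    k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
    k / n  # cycles per voxel spacing
  }
  f1 <- axfreq(dims[1]); f2 <- axfreq(dims[2]); f3 <- axfreq(dims[3])
  r <- sqrt(outer(outer(f1^2, f2^2, "+"), f3^2, "+")) * nmax
  shell <- as.integer(round(r))
  ny_shell <- floor(nmax / 2)
  keep <- which(shell <= ny_shell)
  grp <- shell[keep] + 1L
  n_terms <- tabulate(grp, nbins = ny_shell + 1L)
  geom <- list(keep = keep, grp = grp, n_shells = ny_shell + 1L,
               n_terms = n_terms, nmax = nmax,
               shell_index = 0:ny_shell)
  .shell_cache[[key]] <- geom
  geom
}

# Per-shell cross/auto power sums for two equally sized real arrays.
# Returns a 3-column matrix (cross, powA, powB) with one row per shell.
shell_sums <- function(a, b, geom) {
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  fa <- fa[geom$keep]
  fb <- fb[geom$keep]
  cross <- Re(fa) * Re(fb) + Im(fa) * Im(fb)
  pa <- Re(fa)^2 + Im(fa)^2
  pb <- Re(fb)^2 + Im(fb)^2
  rs <- rowsum(cbind(cross, pa, pb), geom$grp, reorder = TRUE)
  out <- matrix(0, nrow = geom$n_shells, ncol = 3L)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

fsc_from_sums <- function(s) {
  den <- sqrt(s[, 2] * s[, 3])
  fsc <- ifelse(den > 0, s[, 1] / den, NA_real_)
  fsc
}

#' Fourier shell correlation between two maps
#'
#' Normalised cross-correlation of the two volumes' Fourier coefficients,
#' accumulated in spherical shells one Fourier voxel wide up to Nyquist.
#' Shell 0 is the DC term; for non-degenerate inputs its correlation is 1 in
#' magnitude.  Shells with zero power in either map are reported as `NA`.
#'
#' @param mapA,mapB Grid-compatible [density_map]s.
#' @return A tibble of class `fsc_curve` with columns `shell`, `shell_freq`
#'   (1/A), `fsc` and `n_terms`; attributes `voxel_size` and `nyquist_res`.
#' @export
fsc_curve <- function(mapA, mapB) {
  assert_grid_compatible(mapA, mapB)
  if (all(mapA$data == 0) || all(mapB$data == 0)) {
    stop("degenerate all-zero map; FSC undefined", call. = FALSE)
  }
  vox <- mean(mapA$voxel_size)
  geom <- fsc_shell_geometry(dim(mapA$data))
  s <- shell_sums(mapA$data, mapB$data, geom)
  curve <- tibble::tibble(
    shell = geom$shell_index,
    shell_freq = geom$shell_index / (geom$nmax * vox),
    fsc = fsc_from_sums(s),
    n_terms = geom$n_terms
  )
  attr(curve, "voxel_size") <- vox
  attr(curve, "nyquist_res") <- 2 * vox
  class(curve) <- c("fsc_curve", class(curve))
  curve
}

# Crossing logic shared by the public and the fast in-loop path.
# freq/fsc exclude the DC shell; returns resolution in Angstrom.
res_from_curve <- function(freq, fsc, threshold, nyquist_res, worst_res) {
  ok <- is.finite(fsc)
  freq <- freq[ok]
  fsc <- fsc[ok]
  if (!length(fsc)) return(worst_res)
  below <- fsc < threshold
  if (!any(below)) return(nyquist_res)
  i <- which(below)[1]
  if (i == 1L) return(worst_res)
  f0 <- freq[i - 1L]; f1 <- freq[i]
  c0 <- fsc[i - 1L]; c1 <- fsc[i]
  fstar <- f0 + (c0 - threshold) / (c0 - c1) * (f1 - f0)
  1 / fstar
}

#' Resolution at an FSC threshold
#'
#' Frequency of the first downward crossing of `threshold`, linearly
#' interpolated between the bracketing shells, returned as a resolution
#' (1/frequency, Angstrom).  A curve that never crosses returns the Nyquist
#' resolution (2 * voxel); a curve already below the threshold at the first
#' non-DC shell returns the worst representable resolution (the box size,
#' i.e. 1 / first shell frequency).  `NA` shells are skipped.
#'
#' @param curve An `fsc_curve` from [fsc_curve()].
#' @param threshold FSC threshold in (0, 1); 1/2 is conventional for
#'   half-map comparisons, 2/3 for comparisons against a full-data-set map.
#' @return Resolution in Angstrom.
#' @export
resolution_at_threshold <- function(curve, threshold) {
  stopifnot(inherits(curve, "fsc_curve"), threshold > 0, threshold < 1)
  nz <- curve$shell > 0
  res_from_curve(curve$shell_freq[nz], curve$fsc[nz], threshold,
                 nyquist_res = attr(curve, "nyquist_res"),
                 worst_res = 1 / curve$shell_freq[nz][1])
}

#' Sliding-window size from the global resolution
#'
#' The local FSC window spans five times the reported overall resolution,
#' rounded to the next odd number of voxels so the window has a centre.  For
#' maps at resolutions better than 2 A the window never drops below 11
#' voxels, which guards against unstable FSC estimates from very small
#' windows.
#'
#' @param global_resolution Reported overall resolution, Angstrom.
#' @param voxel_size Angstrom per voxel.
#' @return Odd integer window size in voxels.
#' @export
default_window <- function(global_resolution, voxel_size) {
  stopifnot(global_resolution > 0, voxel_size > 0)
  w <- round(5 * global_resolution / voxel_size)
  if (w %% 2 == 0) w <- w + 1
  if (global_resolution < 2) w <- max(w, 11)
  as.integer(w)
}

# Extract a window^3 cube centred at (i, j, k), zero-padded at box edges.
extract_window <- function(data, i, j, k, half) {
  d <- dim(data)
  i0 <- i - half; i1 <- i + half
  j0 <- j - half; j1 <- j + half
  k0 <- k - half; k1 <- k + half
  if (i0 >= 1 && j0 >= 1 && k0 >= 1 && i1 <= d[1] && j1 <= d[2] && k1 <= d[3]) {
    return(data[i0:i1, j0:j1, k0:k1])
  }
  w <- 2L * half + 1L
  cube <- array(0, c(w, w, w))
  si <- max(i0, 1):min(i1, d[1])
  sj <- max(j0, 1):min(j1, d[2])
  sk <- max(k0, 1):min(k1, d[3])
  cube[si - i0 + 1L, sj - j0 + 1L, sk - k0 + 1L] <- data[si, sj, sk]
  cube
}

#' Local resolution by sliding-window FSC
#'
#' For every voxel of the mask support (optionally subsampled by `step`), a
#' `window`-cubed subvolume is extracted from each map centred at that voxel
#' (zero-padded at box edges, no apodization), their FSC computed, and the
#' threshold-crossing resolution assigned to the centre voxel.  Voxels
#' skipped by the stride are filled from the nearest evaluated voxel; voxels
#' outside the support are `NaN`.  Windows with no density in either map are
#' assigned the worst representable resolution (`window * voxel`).
#'
#' The mask only gates where the FSC is evaluated; it is not multiplied into
#' the extracted windows (`mask_mode = "multiply"` enables the alternative).
#'
#' @param mapA,mapB Grid-compatible [density_map]s (half1/half2, or
#'   full/model map).
#' @param mask A `mask_volume` from [make_soft_mask()], grid-compatible.
#' @param window Odd window size in voxels (see [default_window()]).
#' @param threshold FSC threshold (1/2 for half maps, 2/3 for map vs model).
#' @param step Evaluation stride in voxels (default 1 = every support voxel).
#' @param provenance `"half"` or `"map_model"`, recorded for downstream
#'   sign-safety checks.
#' @param mask_mode `"gate"` (default) or `"multiply"`.
#' @param support_level Mask level defining the evaluation support.
#' @return A `local_res_map` ([density_map] subclass, Angstrom per voxel
#'   values) with fields `params` and `provenance`.
#' @export
local_resolution_map <- function(mapA, mapB, mask, window, threshold,
                                 step = 1L,
                                 provenance = c("half", "map_model"),
                                 mask_mode = c("gate", "multiply"),
                                 support_level = 0.5) {
  provenance <- match.arg(provenance)
  mask_mode <- match.arg(mask_mode)
  assert_grid_compatible(mapA, mapB, mask)
  d <- dim(mapA$data)
  window <- as.integer(window)
  if (window %% 2 == 0) stop("window must be odd so it has a centre voxel",
                             call. = FALSE)
  if (window > min(d)) stop("window larger than the map box", call. = FALSE)
  if (step < 1) stop("step must be >= 1", call. = FALSE)
  step <- as.integer(step)
  vox <- mean(mapA$voxel_size)
  half <- (window - 1L) %/% 2L

  sup <- mask_support(mask, support_level)
  if (nrow(sup) == 0) stop("empty mask support", call. = FALSE)
  eval_rows <- if (step == 1L) seq_len(nrow(sup)) else {
    which((sup$i - 1L) %% step == 0L & (sup$j - 1L) %% step == 0L &
            (sup$k - 1L) %% step == 0L)
  }
  if (!length(eval_rows)) eval_rows <- 1L

  geom <- fsc_shell_geometry(rep(window, 3))
  nz <- geom$shell_index > 0
  freq <- geom$shell_index[nz] / (geom$nmax * vox)
  nyq <- 2 * vox
  worst <- window * vox

  da <- mapA$data
  db <- mapB$data
  if (mask_mode == "multiply") {
    da <- da * mask$data
    db <- db * mask$data
  }
  out <- array(NaN, d)
  ei <- sup$i[eval_rows]; ej <- sup$j[eval_rows]; ek <- sup$k[eval_rows]
  for (t in seq_along(ei)) {
    wa <- extract_window(da, ei[t], ej[t], ek[t], half)
    wb <- extract_window(db, ei[t], ej[t], ek[t], half)
    if (all(wa == 0) || all(wb == 0)) {
      out[ei[t], ej[t], ek[t]] <- worst
      next
    }
    s <- shell_sums(wa, wb, geom)
    fsc <- fsc_from_sums(s)[nz]
    out[ei[t], ej[t], ek[t]] <- res_from_curve(freq, fsc, threshold, nyq, worst)
  }

  if (step > 1L) {
    todo <- setdiff(seq_len(nrow(sup)), eval_rows)
    if (length(todo)) {
      em <- cbind(ei, ej, ek)
      for (r in todo) {
        p <- c(sup$i[r], sup$j[r], sup$k[r])
        d2 <- (em[, 1] - p[1])^2 + (em[, 2] - p[2])^2 + (em[, 3] - p[3])^2
        q <- em[which.min(d2), ]
        out[p[1], p[2], p[3]] <- out[q[1], q[2], q[3]]
      }
    }
  }

  res <- density_map(out, mapA$voxel_size, mapA$origin)
  res$params <- list(window = window, threshold = threshold, step = step,
                     mask_mode = mask_mode, support_level = support_level)
  res$provenance <- provenance
  class(res) <- c("local_res_map", class(res))
  res
}

#' Apply a B-factor amplitude scaling to a map
#'
#' Multiplies the Fourier amplitudes by `exp(-B * s^2 / 4)` (s = spatial
#' frequency, 1/A): negative B sharpens, positive B blurs.  With
#' `shell_constant = TRUE` the factor is held constant across each FSC shell
#' (evaluated at the shell-centre frequency), which makes whole-box FSC
#' exactly invariant to the scaling; the smooth variant is invariant only up
#' to within-shell variation.
#'
#' @param map A [density_map].
#' @param bfactor B value in A^2.
#' @param shell_constant Hold the factor constant over each Fourier shell.
#' @return A [density_map].
#' @export
apply_bfactor <- function(map, bfactor, shell_constant = FALSE) {
  stopifnot(is_density_map(map))
  d <- dim(map$data)
  vox <- mean(map$voxel_size)
  nmax <- max(d)
  axfreq <- function(n) c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)] / n
  f1 <- axfreq(d[1]); f2 <- axfreq(d[2]); f3 <- axfreq(d[3])
  s2 <- outer(outer(f1^2, f2^2, "+"), f3^2, "+") / vox^2
  if (shell_constant) {
    shell <- round(sqrt(s2) * vox * nmax)
    s2 <- (shell / (nmax * vox))^2
  }
  w <- exp(-bfactor * s2 / 4)
  ft <- stats::fft(map$data) * w
  density_map(Re(stats::fft(ft, inverse = TRUE)) / prod(d),
              map$voxel_size, map$origin)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an FSC curve
#'
#' @param object An `fsc_curve`.
#' @param threshold Optional horizontal reference line (e.g. 0.5 or 2/3).
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot fsc_curve
#' @export
autoplot.fsc_curve <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$shell_freq, y = .data$fsc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "spatial frequency (1/Å)", y = "FSC") +
    ggplot2::ylim(min(0, min(object$fsc, na.rm = TRUE)), 1)
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2)
  }
  p
}

#' @importFrom rlang .data
NULL
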