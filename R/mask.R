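# 1D squared Euclidean distance transform (Felzenszwalb & Huttenlocher lower
# envelope of parabolas).  f: squared distances (Inf where no seed).
dt1d <- function(f) {
  n <- length(f)
  d <- numeric(n)
  v <- integer(n)  # parabola sites
  z <- numeric(n + 1L)  # envelope boundaries
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  for (q in 2:n) {
    if (!is.finite(f[q]) && !is.finite(f[v[k]])) next
    repeat {
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
      if (is.nan(s)) s <- Inf
      if (s <= z[k]) {
        k <- k - 1L
        if (k == 0L) { k <- 1L; v[1L] <- q; z[1L] <- -Inf; z[2L] <- Inf; break }
      } else {
        k <- k + 1L
        v[k] <- q
        z[k] <- s
        z[k + 1L] <- Inf
        break
      }
    }
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# Exact Euclidean distance (in voxels) from every voxel to the nearest TRUE
# voxel of a 3D logical array, by three separable 1D passes.
distance_to_set <- function(core) {
  d <- dim(core)
  f <- array(ifelse(core, 0, Inf), d)
  for (j in seq_len(d[2])) for (k in seq_len(d[3])) f[, j, k] <- dt1d(f[, j, k])
  for (i in seq_len(d[1])) for (k in seq_len(d[3])) f[i, , k] <- dt1d(f[i, , k])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) f[i, j, ] <- dt1d(f[i, j, ])
  sqrt(f)
}

#' Build a soft mask around the macromolecule
#'
#' Standard mask recipe for local FSC evaluation: the model-simulated map is
#' normalised to unit maximum, voxels above `threshold` form the binary core,
#' the core is dilated by `dilation` voxels (Euclidean ball), and a
#' raised-cosine falloff of width `soft_edge` voxels is applied outward.
#' Inside the dilated core the mask is exactly 1; beyond the soft edge it is
#' exactly 0.  Defaults follow the recipe used with model-derived maps:
#' threshold 0.02 (on the unit-max scale) and 3 voxels of dilation.
#'
#' @param model_map A [density_map], normally simulated from the model.
#' @param threshold Core threshold on the map normalised to max 1.
#' @param dilation Dilation radius, voxels.
#' @param soft_edge Raised-cosine falloff width, voxels (0 = binary mask).
#' @return A `mask_volume` (a [density_map] subclass with values in [0, 1]).
#' @export
make_soft_mask <- function(model_map, threshold = 0.02, dilation = 3,
                           soft_edge = 3) {
  stopifnot(is_density_map(model_map), threshold > 0, dilation >= 0,
            soft_edge >= 0)
  mx <- max(model_map$data)
  if (!is.finite(mx) || mx <= 0) stop("model map has no positive density", call. = FALSE)
  core <- model_map$data / mx > threshold
  if (!any(core)) stop("nothing above threshold; empty mask", call. = FALSE)
  dist <- distance_to_set(core) - dilation
  vals <- array(0, dim(core))
  vals[dist <= 0] <- 1
  if (soft_edge > 0) {
    edge <- dist > 0 & dist < soft_edge
    vals[edge] <- 0.5 * (1 + cos(pi * dist[edge] / soft_edge))
  }
  out <- density_map(vals, model_map$voxel_size, model_map$origin)
  class(out) <- c("mask_volume", class(out))
  out
}

#' Voxels at which the mask is at least `level`
#'
#' Selects the evaluation support for windowed local FSC: all voxels where
#' the soft mask is `>= level`.
#'
#' @param mask A `mask_volume` (or any [density_map] with values in [0, 1]).
#' @param level Support level in (0, 1); default 0.5.
#' @return A tibble with integer voxel indices `i`, `j`, `k` (1-based).
#' @export
mask_support <- function(mask, level = 0.5) {
  stopifnot(is_density_map(mask), level > 0, level < 1)
  idx <- which(mask$data >= level, arr.ind = TRUE)
  tibble::tibble(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
                 k = as.integer(idx[, 3]))
}
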