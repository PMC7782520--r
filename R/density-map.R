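#' Density map objects
#'
#' A `density_map` is a light container for a 3D real-valued grid together
#' with its voxel size (Angstrom per voxel along each axis) and the position,
#' in Angstrom, of the centre of the first voxel in the model coordinate
#' frame (the "origin").  It carries experimental maps, half maps, simulated
#' model maps, masks and all derived per-voxel volumes (local resolution,
#' FSC-Q, FSC-Q_R).
#'
#' The coordinate convention is: voxel `(i, j, k)` (1-based) sits at
#' `origin + (i - 1, j - 1, k - 1) * voxel_size` in Angstrom, so a point at
#' the model-frame origin falls on voxel index `1 - origin / voxel_size`.
#'
#' @param data 3D numeric array.
#' @param voxel_size Voxel edge length in Angstrom; scalar or length-3.
#' @param origin Length-3 numeric, Angstrom offset of the first voxel centre.
#' @return An object of class `density_map`.
#' @examples
#' m <- density_map(array(0, c(8, 8, 8)), voxel_size = 1.5)
#' dim(m)
#' @export
density_map <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("`voxel_size` must be positive on all axes", call. = FALSE)
  }
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(origin))) stop("`origin` must be finite", call. = FALSE)
  storage.mode(data) <- "double"
  structure(
    list(data = data, voxel_size = voxel_size, origin = origin),
    class = "density_map"
  )
}

#' @export
dim.density_map <- function(x) dim(x$data)

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<density_map> %d x %d x %d voxels, %.4g A/voxel, origin (%.2f, %.2f, %.2f) A\n",
    d[1], d[2], d[3], mean(x$voxel_size), x$origin[1], x$origin[2], x$origin[3]
  ))
  fin <- x$data[is.finite(x$data)]
  if (length(fin)) {
    cat(sprintf("  range [%.4g, %.4g], mean %.4g", min(fin), max(fin), mean(fin)))
    nbad <- length(x$data) - length(fin)
    if (nbad > 0) cat(sprintf(", %d undefined voxels", nbad))
    cat("\n")
  }
  invisible(x)
}

#' @rdname density_map
#' @param x Object to test.
#' @export
is_density_map <- function(x) inherits(x, "density_map")

#' Check that maps share a grid
#'
#' All volumes entering a local FSC comparison must live on the same grid:
#' identical dimensions, voxel size (within 1e-4 Angstrom) and origin (within
#' 1e-3 Angstrom).  On mismatch the error names the offending attribute and
#' the size of the discrepancy.
#'
#' @param ... Two or more `density_map` objects (or a single list of them).
#' @return Invisibly `TRUE` on success; otherwise an error.
#' @export
assert_grid_compatible <- function(...) {
  maps <- list(...)
  if (length(maps) == 1L && !is_density_map(maps[[1]])) maps <- maps[[1]]
  if (length(maps) < 2L) stop("need at least two maps to compare", call. = FALSE)
  stopifnot(all(vapply(maps, is_density_map, logical(1))))
  ref <- maps[[1]]
  for (i in seq_along(maps)[-1]) {
    m <- maps[[i]]
    if (!identical(dim(ref$data), dim(m$data))) {
      stop(sprintf(
        "grid mismatch: dims differ between map 1 (%s) and map %d (%s)",
        paste(dim(ref$data), collapse = "x"), i, paste(dim(m$data), collapse = "x")
      ), call. = FALSE)
    }
    dv <- abs(ref$voxel_size - m$voxel_size)
    if (any(dv > 1e-4)) {
      stop(sprintf(
        "grid mismatch: voxel_size differs between map 1 and map %d by up to %.3g A",
        i, max(dv)
      ), call. = FALSE)
    }
    dorig <- abs(ref$origin - m$origin)
    if (any(dorig > 1e-3)) {
      stop(sprintf(
        "grid mismatch: origin differs between map 1 and map %d by up to %.3g A",
        i, max(dorig)
      ), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# ---- MRC2014 / CCP4 volume format ------------------------------------------
#
# 1024-byte header of 56 4-byte words plus 800 bytes of text labels; data in
# mode 2 (little-endian IEEE float32) is what we write.  Modes 0 (int8),
# 1 (int16), 2 (float32) and 6 (uint16) are accepted on read.  Word layout
# follows the MRC2014 standard: NX NY NZ MODE NXSTART.. MX.. CELLA CELLB
# MAPC MAPR MAPS DMIN DMAX DMEAN ISPG NSYMBT EXTRA(25) ORIGIN(3) "MAP " MACHST
# RMS NLABL LABEL(10x80).

mrc_read_header <- function(raw) {
  int_at <- function(w) readBin(raw[(4 * (w - 1) + 1):(4 * w)], "integer",
                                size = 4, endian = "little")
  float_at <- function(w) readBin(raw[(4 * (w - 1) + 1):(4 * w)], "double",
                                  size = 4, endian = "little")
  list(
    nx = int_at(1), ny = int_at(2), nz = int_at(3),
    mode = int_at(4),
    nxstart = c(int_at(5), int_at(6), int_at(7)),
    m = c(int_at(8), int_at(9), int_at(10)),
    cella = c(float_at(11), float_at(12), float_at(13)),
    mapcrs = c(int_at(17), int_at(18), int_at(19)),
    nsymbt = int_at(24),
    origin = c(float_at(50), float_at(51), float_at(52)),
    map_tag = rawToChar(raw[(4 * 52 + 1):(4 * 52 + 4)])
  )
}

#' Read an MRC/CCP4 density map
#'
#' Reads an MRC2014/CCP4 volume.  The voxel size comes from `CELLA / MX..MZ`;
#' the grid is normalised to canonical X-fastest axis order from the
#' `MAPC/MAPR/MAPS` header words.  The origin is taken from the `ORIGIN`
#' header field; when `ORIGIN` is exactly zero but `NXSTART..NZSTART` is not,
#' the origin falls back to `NXSTART * voxel_size` (common EMDB deposition
#' practice).  Anisotropic voxel sizes are tolerated to 1% (the mean is used);
#' beyond that the offending axis is reported as an error.
#'
#' @param path Path to an MRC/CCP4 file.
#' @return A [density_map].
#' @seealso [write_map()]
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  raw_hdr <- readBin(con, "raw", n = 1024L)
  if (length(raw_hdr) < 1024L) stop("truncated MRC header", call. = FALSE)
  h <- mrc_read_header(raw_hdr)
  if (any(c(h$nx, h$ny, h$nz) < 1L)) stop("invalid MRC dimensions", call. = FALSE)
  n <- as.numeric(h$nx) * h$ny * h$nz
  if (h$nsymbt > 0) invisible(readBin(con, "raw", n = h$nsymbt))
  vals <- switch(
    as.character(h$mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = FALSE,
                             endian = "little")),
    stop(sprintf("unsupported MRC mode %d (not a real-valued volume)", h$mode),
         call. = FALSE)
  )
  if (length(vals) < n) stop("truncated MRC data block", call. = FALSE)
  arr <- array(vals, dim = c(h$nx, h$ny, h$nz))

  # voxel size per cell axis; tolerate <=1% anisotropy, then use the mean
  m_grid <- ifelse(h$m > 0, h$m, c(h$nx, h$ny, h$nz))
  vox_axes <- ifelse(h$cella > 0, h$cella / m_grid, 1)
  vmean <- mean(vox_axes)
  rel <- abs(vox_axes - vmean) / vmean
  if (any(rel > 0.01)) {
    ax <- c("x", "y", "z")[which.max(rel)]
    stop(sprintf("anisotropic voxel size beyond 1%% on axis %s (%.4f vs mean %.4f A)",
                 ax, vox_axes[which.max(rel)], vmean), call. = FALSE)
  }

  # normalise axis order: file dim d runs along cell axis mapcrs[d]
  mcrs <- h$mapcrs
  if (!setequal(mcrs, 1:3)) mcrs <- 1:3
  nstart <- h$nxstart
  if (!all(mcrs == 1:3)) {
    inv <- order(mcrs)
    arr <- aperm(arr, inv)
    nstart <- nstart[inv]
  }

  origin <- h$origin
  if (all(origin == 0) && any(nstart != 0)) origin <- nstart * vmean
  density_map(arr, voxel_size = vmean, origin = origin)
}

#' Write an MRC/CCP4 density map
#'
#' Writes mode 2 (32-bit float, little-endian) with canonical axis order,
#' `CELLA = dims * voxel_size`, `MAPC/MAPR/MAPS = 1/2/3` and the origin in the
#' `ORIGIN` header field.  Undefined voxels (`NaN`) can be encoded as a
#' sentinel value for viewers that do not handle NaN.
#'
#' @param map A [density_map].
#' @param path Output path.
#' @param nan Value substituted for non-finite voxels, or `NULL` to write NaN
#'   as-is (default).
#' @return Invisibly `path`.
#' @export
write_map <- function(map, path, nan = NULL) {
  stopifnot(is_density_map(map))
  d <- dim(map$data)
  vals <- as.vector(map$data)
  if (!is.null(nan)) vals[!is.finite(vals)] <- as.numeric(nan)
  fin <- vals[is.finite(vals)]
  if (!length(fin)) fin <- 0
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                    # NX NY NZ
  wi(2L)                   # MODE 2 = float32
  wi(c(0L, 0L, 0L))        # NXSTART..
  wi(d)                    # MX MY MZ
  wf(d * map$voxel_size)   # CELLA
  wf(c(90, 90, 90))        # CELLB
  wi(1:3)                  # MAPC MAPR MAPS
  wf(c(min(fin), max(fin), mean(fin)))  # DMIN DMAX DMEAN
  wi(c(1L, 0L))            # ISPG, NSYMBT
  wi(integer(25))          # EXTRA
  wf(map$origin)           # ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(fin))       # RMS
  wi(1L)                   # NLABL
  lab <- sprintf("%-80s", "fscq density map")
  writeBin(charToRaw(paste0(lab, strrep(" ", 80 * 9))), con)
  writeBin(vals, con, size = 4, endian = "little")
  invisible(path)
}
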