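#' Volumetric density map
#'
#' A 3D scalar grid with isotropic voxel size.  The `origin` is the world
#' (Angstrom) position of the *center* of voxel (0,0,0); voxel indices are
#' 0-based in all world<->grid conversions.  Grid mean and standard
#' deviation are computed over the full grid on construction and are the
#' basis of all sigma-scaled contour queries.
#'
#' @param grid 3D numeric array.
#' @param voxel_size Voxel edge length in Angstrom (> 0, isotropic).
#' @param origin Length-3 numeric, world position of the center of voxel
#'   (0,0,0).
#' @return An object of class `density_map`.
#' @export
density_map <- function(grid, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(is.array(grid), length(dim(grid)) == 3)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0) {
    abort("voxel_size must be a single positive number")
  }
  stopifnot(is.numeric(origin), length(origin) == 3)
  m <- mean(grid)
  s <- sqrt(mean((grid - m)^2))  # population sd, as map-contour tools use
  structure(list(grid = grid, voxel_size = voxel_size,
                 origin = as.numeric(origin), mean = m, sd = s),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<density_map> %d x %d x %d voxels @ %.4g A, origin (%.2f, %.2f, %.2f)\n",
              d[1], d[2], d[3], x$voxel_size,
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  mean %.4g, sd %.4g\n", x$mean, x$sd))
  invisible(x)
}

#' @export
dim.density_map <- function(x) dim(x$grid)

map_same_lattice <- function(a, b, tol = 1e-6) {
  all(dim(a$grid) == dim(b$grid)) &&
    abs(a$voxel_size - b$voxel_size) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

#' World coordinates of all voxel centers
#' @param map A [density_map].
#' @return n_voxel x 3 matrix, in array (x fastest) order.
#' @export
voxel_centers <- function(map) {
  d <- dim(map$grid)
  ix <- seq_len(d[1]) - 1L
  iy <- seq_len(d[2]) - 1L
  iz <- seq_len(d[3]) - 1L
  cbind(
    map$origin[1] + map$voxel_size * rep(ix, times = d[2] * d[3]),
    map$origin[2] + map$voxel_size * rep(rep(iy, each = d[1]), times = d[3]),
    map$origin[3] + map$voxel_size * rep(iz, each = d[1] * d[2])
  )
}

#' Trilinear interpolation of raw map values
#'
#' Points outside the support of the voxel-center lattice return `NA`.
#'
#' @param map A [density_map].
#' @param points n x 3 matrix of world coordinates (Angstrom).
#' @return Numeric vector of interpolated raw densities.
#' @export
map_values <- function(map, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  d <- dim(map$grid)
  f <- sweep(points, 2, map$origin) / map$voxel_size  # 0-based frac index
  out <- rep(NA_real_, nrow(points))
  eps <- 1e-9
  ok <- f[, 1] >= -eps & f[, 1] <= d[1] - 1 + eps &
        f[, 2] >= -eps & f[, 2] <= d[2] - 1 + eps &
        f[, 3] >= -eps & f[, 3] <= d[3] - 1 + eps
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(out)
  f <- f[ok, , drop = FALSE]
  f <- pmin(pmax(f, 0), matrix(d - 1, nrow(f), 3, byrow = TRUE))
  i0 <- pmin(floor(f), matrix(d - 2L, nrow(f), 3, byrow = TRUE))
  i0 <- pmax(i0, 0)
  t <- f - i0
  g <- map$grid
  nx <- d[1]; nxy <- d[1] * d[2]
  base <- 1 + i0[, 1] + nx * i0[, 2] + nxy * i0[, 3]
  v <- numeric(nrow(f))
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    w <- (if (cx) t[, 1] else 1 - t[, 1]) *
         (if (cy) t[, 2] else 1 - t[, 2]) *
         (if (cz) t[, 3] else 1 - t[, 3])
    v <- v + w * g[base + cx + nx * cy + nxy * cz]
  }
  out[ok] <- v
  out
}

#' Sigma-scaled map value at world positions
#'
#' Interpolates the raw density trilinearly, then scales as
#' (value - mean) / sd with the full-grid statistics.  Points outside the
#' grid support return `-Inf` (a sentinel that always fails any contour
#' threshold).
#'
#' @param map A [density_map].
#' @param points n x 3 matrix (or length-3 vector) of world coordinates.
#' @return Numeric vector of sigma values.
#' @export
sigma_at <- function(map, points) {
  if (map$sd <= 0) {
    abort("sigma values are undefined for a constant map (sd = 0)")
  }
  v <- map_values(map, points)
  out <- (v - map$mean) / map$sd
  out[is.na(v)] <- -Inf
  out
}

# ---- MRC/CCP4 I/O (mode 2, little-endian float) -------------------------
# Minimal MRC2014 implementation: no R package in the dependency stack
# reads this container, so the 1024-byte header and float32 payload are
# handled directly.

#' Read an MRC/CCP4 density map
#'
#' Supports mode-2 (float32) maps with isotropic voxels.  The ORIGIN header
#' words are interpreted as the world position of the center of voxel
#' (0,0,0); when they are all zero, the NxSTART words times the voxel size
#' are used instead (the CCP4 convention).  Grid statistics are recomputed
#' on read.
#'
#' @param path Path to an MRC file.
#' @return A [density_map].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  con <- file(path, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  nstart <- ints[5:7]
  m <- ints[8:10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")  # angles
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")  # dmin/max/mean
  readBin(con, "integer", n = 2, size = 4, endian = "little")  # ispg, nsymbt
  readBin(con, "integer", n = 25, size = 4, endian = "little") # extra
  orig <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  if (mode != 2) abort(sprintf("unsupported MRC mode %d (only mode 2)", mode))
  if (!all(mapcrs == c(1, 2, 3))) {
    abort("only MAPC/MAPR/MAPS = 1,2,3 (x fastest) axis order is supported")
  }
  vx <- cella / m
  if (max(vx) - min(vx) > 1e-4 * max(vx)) {
    abort(sprintf(
      "anisotropic voxels (%.4g, %.4g, %.4g A) are not supported; this tool assumes isotropic maps",
      vx[1], vx[2], vx[3]))
  }
  voxel <- mean(vx)
  seek(con, 1024)
  n <- nx * ny * nz
  vals <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  if (length(vals) != n) abort("truncated MRC data block")
  if (all(orig == 0) && any(nstart != 0)) {
    orig <- nstart * voxel
  }
  density_map(array(vals, dim = c(nx, ny, nz)), voxel, orig)
}

#' Write a density map to an MRC file
#'
#' Mode-2 (float32) MRC2014 with the map origin stored in the ORIGIN header
#' words.
#'
#' @param map A [density_map].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                       # NX NY NZ
  wi(2)                       # MODE 2
  wi(c(0, 0, 0))              # NXSTART
  wi(d)                       # MX MY MZ
  wf(d * map$voxel_size)      # CELLA
  wf(c(90, 90, 90))           # CELLB
  wi(c(1, 2, 3))              # MAPC MAPR MAPS
  wf(c(min(map$grid), max(map$grid), map$mean))
  wi(c(1, 0))                 # ISPG, NSYMBT
  wi(rep(0, 25))              # EXTRA
  wf(map$origin)              # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(map$sd)                  # RMS
  wi(0)                       # NLABL
  writeBin(raw(800), con)     # labels
  wf(as.numeric(map$grid))
  invisible(path)
}
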