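#' Van der Waals radius table for Gaussian atom spreading
#'
#' Each atom contributes a normalized Gaussian whose standard deviation
#' equals the atom's radius.  The defaults are standard van der Waals
#' radii; the table is configurable because visualization tools differ
#' slightly in the radii they inherit.
#'
#' @param ... Named overrides or additions, e.g. `C = 1.9`.
#' @return Named numeric vector, Angstrom per element.
#' @export
vdw_radii <- function(...) {
  r <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, P = 1.8, S = 1.8)
  over <- c(...)
  if (length(over)) {
    stopifnot(!is.null(names(over)), all(nzchar(names(over))))
    r[names(over)] <- over
  }
  if (any(r <= 0)) abort("all radii must be positive")
  r
}

default_extent <- function(traj, idx, pad) {
  lo <- c(Inf, Inf, Inf); hi <- c(-Inf, -Inf, -Inf)
  for (f in traj$frames) {
    p <- f[idx, , drop = FALSE]
    lo <- pmin(lo, apply(p, 2, min))
    hi <- pmax(hi, apply(p, 2, max))
  }
  rbind(lo - pad, hi + pad)
}

#' Trajectory-averaged Gaussian-spread density map
#'
#' Replaces each selected atom with a normalized 3D Gaussian whose standard
#' deviation equals the atom's radius, sums the Gaussians on a grid for
#' each frame, and averages over frames.  With a generous extent the
#' integral of the map (sum times voxel volume) equals the mean per-frame
#' selected-atom count; Gaussians are truncated at `truncation` standard
#' deviations (4 by default, < 0.01% mass loss).
#'
#' @param traj A [jl_trajectory].
#' @param selection Atom selection: logical mask, integer indices, or a
#'   function of the atom table returning either.
#' @param voxel_size Grid spacing in Angstrom.
#' @param radii Named per-element Gaussian sd table, see [vdw_radii()].
#' @param extent Optional 2 x 3 matrix `rbind(min, max)` of world bounds.
#'   Defaults to the selection's bounding box padded by 4 radii.
#' @param truncation Gaussian truncation radius in standard deviations.
#' @return A [density_map].  Atoms whose centers fall outside the extent
#'   are truncated (not wrapped) and counted in a warning.
#' @export
compute_density_map <- function(traj, selection, voxel_size,
                                radii = vdw_radii(), extent = NULL,
                                truncation = 4) {
  stopifnot(inherits(traj, "jl_trajectory"))
  idx <- resolve_selection(traj$topology, selection)
  if (length(idx) == 0) abort("empty atom selection")
  elem <- traj$topology$atoms$element[idx]
  unknown <- setdiff(unique(elem), names(radii))
  if (length(unknown)) {
    abort(paste0("no radius for element(s): ", paste(unknown, collapse = ", ")))
  }
  sig <- unname(radii[elem])
  if (is.null(extent)) {
    extent <- default_extent(traj, idx, truncation * max(sig))
  }
  extent <- as.matrix(extent)
  stopifnot(nrow(extent) == 2, ncol(extent) == 3)
  nvox <- pmax(2L, as.integer(floor((extent[2, ] - extent[1, ]) / voxel_size)) + 1L)
  origin <- extent[1, ]
  axes <- lapply(1:3, function(a) origin[a] + voxel_size * (seq_len(nvox[a]) - 1L))
  acc <- array(0, dim = nvox)
  n_outside <- 0L
  for (f in traj$frames) {
    p <- f[idx, , drop = FALSE]
    for (a in seq_along(idx)) {
      s <- sig[a]
      ctr <- p[a, ]
      if (any(ctr < extent[1, ] - truncation * s) ||
          any(ctr > extent[2, ] + truncation * s)) {
        n_outside <- n_outside + 1L
        next
      }
      rng <- lapply(1:3, function(d) {
        lo <- ceiling((ctr[d] - truncation * s - origin[d]) / voxel_size)
        hi <- floor((ctr[d] + truncation * s - origin[d]) / voxel_size)
        seq.int(max(0L, lo), min(nvox[d] - 1L, hi)) + 1L
      })
      if (any(lengths(rng) == 0)) { n_outside <- n_outside + 1L; next }
      gx <- dnorm(axes[[1]][rng[[1]]], ctr[1], s)
      gy <- dnorm(axes[[2]][rng[[2]]], ctr[2], s)
      gz <- dnorm(axes[[3]][rng[[3]]], ctr[3], s)
      acc[rng[[1]], rng[[2]], rng[[3]]] <-
        acc[rng[[1]], rng[[2]], rng[[3]]] + gx %o% gy %o% gz
    }
  }
  if (n_outside > 0) {
    warn(sprintf("%d atom instances fell outside the map extent and were truncated",
                 n_outside))
  }
  density_map(acc / length(traj$frames), voxel_size, origin)
}

#' Resample a map onto a finer or coarser lattice
#'
#' Trilinear interpolation onto a new lattice with the same world-space
#' origin.  The new lattice spans the same world bounds (up to one voxel at
#' the far edge).
#'
#' @param map A [density_map].
#' @param target_voxel New voxel size in Angstrom.
#' @return A [density_map] at the new spacing.
#' @export
resample_map <- function(map, target_voxel) {
  stopifnot(inherits(map, "density_map"))
  if (target_voxel <= 0) abort("target_voxel must be positive")
  if (target_voxel > 4 * map$voxel_size) {
    warn("resampling more than 4x coarser than the source loses information")
  }
  if (abs(target_voxel - map$voxel_size) < 1e-12) return(map)
  d <- dim(map$grid)
  span <- (d - 1) * map$voxel_size
  nd <- as.integer(floor(span / target_voxel + 1e-9)) + 1L
  new <- density_map(array(0, dim = nd), target_voxel, map$origin)
  vals <- map_values(map, voxel_centers(new))
  vals[is.na(vals)] <- 0
  density_map(array(vals, dim = nd), target_voxel, map$origin)
}

#' Voxelwise average of density maps
#'
#' All maps must share the lattice (shape, voxel size, origin within 1e-6).
#'
#' @param maps List of [density_map] objects.
#' @return A [density_map] with recomputed statistics.
#' @export
average_maps <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 1)
  ref <- maps[[1]]
  for (m in maps[-1]) {
    if (!map_same_lattice(ref, m)) {
      abort("maps do not share a lattice (voxel size, shape, origin)")
    }
  }
  acc <- Reduce(`+`, lapply(maps, function(m) m$grid))
  density_map(acc / length(maps), ref$voxel_size, ref$origin)
}

#' Point-group symmetrization of a map
#'
#' Averages the map over all rotated copies under the group (trilinear
#' resampling).  Samples falling outside the lattice contribute zero and
#' are counted in a warning; the output is invariant under every group
#' operation up to interpolation error.
#'
#' @param map A [density_map].
#' @param group A `point_group`, e.g. [d6_group()].
#' @return The symmetrized [density_map].
#' @export
symmetrize <- function(map, group) {
  stopifnot(inherits(map, "density_map"), inherits(group, "point_group"))
  pts <- voxel_centers(map)
  acc <- numeric(nrow(pts))
  n_out <- 0L
  for (i in seq_along(group$ops)) {
    v <- map_values(map, apply_symop(pts, group, i))
    miss <- is.na(v)
    n_out <- n_out + sum(miss)
    v[miss] <- 0
    acc <- acc + v
  }
  if (n_out > 0) {
    warn(sprintf("%d rotated samples fell outside the lattice (zero-filled)",
                 n_out))
  }
  density_map(array(acc / length(group$ops), dim = dim(map$grid)),
              map$voxel_size, map$origin)
}
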