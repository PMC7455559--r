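#' Segment acyl-chain rod densities from a lipid density map
#'
#' Voxels with sigma >= `sigma_min` inside the leaflet z-slab are grouped
#' into 26-connected components; components smaller than `min_voxels` are
#' discarded as noise.  Each surviving component ("rod") is assigned to a
#' subunit by the angular sector of its centroid about the symmetry axis
#' (sector s spans [(s-1) * 360/n_subunits, s * 360/n_subunits) degrees
#' measured from +x), and rods within a subunit are numbered by increasing
#' radial distance of the centroid, ties broken by azimuth -- a
#' deterministic, symmetry-consistent numbering.
#'
#' @param map A [density_map] of the lipid acyl-chain density.
#' @param sigma_min Contour threshold in sigma units (default 8).
#' @param z_range Length-2 numeric, the leaflet z-slab in world Angstrom;
#'   `NULL` keeps the whole grid.
#' @param center xy position of the symmetry axis (default origin).
#' @param n_subunits Number of angular sectors (default 12).
#' @param min_voxels Components below this size are dropped (default 20).
#' @param radius_bin Radii are quantized to this bin width (Angstrom)
#'   before ordering, so rods of a common lattice ring count as radial
#'   ties (broken by azimuth) rather than being ordered by sub-voxel
#'   centroid noise.
#' @return An object of class `rod_catalogue`: a tibble with one row per
#'   rod (`rod_id`, `subunit`, `rod`, `n_voxels`, centroid, `radius`,
#'   `azimuth`) carrying the voxel label array, threshold, and lattice in
#'   attributes.
#' @export
build_rod_catalogue <- function(map, sigma_min = 8, z_range = NULL,
                                center = c(0, 0), n_subunits = 12L,
                                min_voxels = 20L, radius_bin = 2) {
  stopifnot(inherits(map, "density_map"))
  if (map$sd <= 0) abort("map is constant; sigma contouring is undefined")
  d <- dim(map$grid)
  sig <- (map$grid - map$mean) / map$sd
  mask <- sig >= sigma_min
  if (!is.null(z_range)) {
    zc <- map$origin[3] + map$voxel_size * (seq_len(d[3]) - 1L)
    zok <- zc >= z_range[1] & zc <= z_range[2]
    mask[, , !zok] <- FALSE
  }
  idx <- which(mask)
  empty <- empty_catalogue(map, sigma_min)
  if (length(idx) == 0) {
    warn("no voxels at or above sigma_min; empty rod catalogue")
    return(empty)
  }
  comp <- connected_components_26(idx, d)
  sizes <- tabulate(comp$membership, comp$n)
  keep_comp <- which(sizes >= min_voxels)
  if (length(keep_comp) == 0) {
    warn("all connected components below min_voxels; empty rod catalogue")
    return(empty)
  }
  vs <- map$voxel_size
  ijk <- arrayInd(idx, d) - 1L
  wx <- map$origin[1] + vs * ijk[, 1]
  wy <- map$origin[2] + vs * ijk[, 2]
  wz <- map$origin[3] + vs * ijk[, 3]
  rows <- purrr::map_dfr(keep_comp, function(cc) {
    sel <- comp$membership == cc
    cx <- mean(wx[sel]); cy <- mean(wy[sel]); cz <- mean(wz[sel])
    az <- (atan2(cy - center[2], cx - center[1]) * 180 / pi) %% 360
    tibble(component = cc, n_voxels = sum(sel),
           x = cx, y = cy, z = cz,
           radius = sqrt((cx - center[1])^2 + (cy - center[2])^2),
           azimuth = az,
           subunit = as.integer(floor(az / (360 / n_subunits))) + 1L)
  })
  rows$radius_rank <- round(rows$radius / radius_bin)
  rows <- dplyr::arrange(rows, .data$subunit, .data$radius_rank,
                         .data$azimuth)
  rows <- dplyr::mutate(dplyr::group_by(rows, .data$subunit),
                        rod = dplyr::row_number())
  rows <- dplyr::ungroup(rows)
  rows$radius_rank <- NULL
  rows$rod_id <- seq_len(nrow(rows))
  per_sub <- table(factor(rows$subunit, levels = seq_len(n_subunits)))
  if (max(per_sub) > 2 * max(1, min(per_sub))) {
    warn(sprintf(
      "rod counts per subunit spread more than 2x (%d-%d); map may not be symmetric",
      min(per_sub), max(per_sub)))
  }
  labels <- array(0L, dim = d)
  memb_to_rod <- integer(comp$n)
  memb_to_rod[rows$component] <- rows$rod_id
  lab <- memb_to_rod[comp$membership]
  labels[idx[lab > 0]] <- lab[lab > 0]
  out <- rows[, c("rod_id", "subunit", "rod", "n_voxels", "x", "y", "z",
                  "radius", "azimuth")]
  structure(out,
            class = c("rod_catalogue", class(out)),
            labels = labels, sigma_min = sigma_min,
            lattice = list(dim = d, voxel_size = vs, origin = map$origin),
            center = center, n_subunits = as.integer(n_subunits))
}

empty_catalogue <- function(map, sigma_min) {
  out <- tibble(rod_id = integer(), subunit = integer(), rod = integer(),
                n_voxels = integer(), x = double(), y = double(),
                z = double(), radius = double(), azimuth = double())
  structure(out, class = c("rod_catalogue", class(out)),
            labels = array(0L, dim = dim(map$grid)), sigma_min = sigma_min,
            lattice = list(dim = dim(map$grid), voxel_size = map$voxel_size,
                           origin = map$origin),
            center = c(0, 0), n_subunits = 12L)
}

# 26-connected components of a voxel index set, via igraph
connected_components_26 <- function(idx, d) {
  rank <- integer(prod(d))
  rank[idx] <- seq_along(idx)
  ijk <- arrayInd(idx, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ]
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    ni <- ijk[, 1] + offs[r, 1]
    nj <- ijk[, 2] + offs[r, 2]
    nk <- ijk[, 3] + offs[r, 3]
    ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
    nidx <- (nk[ok] - 1L) * d[1] * d[2] + (nj[ok] - 1L) * d[1] + ni[ok]
    nb <- rank[nidx]
    hit <- nb > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, nb[hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
  }
  cl <- igraph::components(g)
  list(membership = cl$membership, n = cl$no)
}

#' Rod id of the nearest voxel for each position
#'
#' @param catalogue A [build_rod_catalogue()] result.
#' @param points n x 3 world coordinates.
#' @return Integer vector of rod ids (0 = no rod / outside the grid).
#' @export
rod_label_at <- function(catalogue, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  lat <- attr(catalogue, "lattice")
  labels <- attr(catalogue, "labels")
  d <- lat$dim
  iv <- round(sweep(points, 2, lat$origin) / lat$voxel_size)
  out <- integer(nrow(points))
  ok <- iv[, 1] >= 0 & iv[, 1] < d[1] & iv[, 2] >= 0 & iv[, 2] < d[2] &
    iv[, 3] >= 0 & iv[, 3] < d[3]
  ok[is.na(ok)] <- FALSE
  lin <- 1 + iv[ok, 1] + d[1] * iv[ok, 2] + d[1] * d[2] * iv[ok, 3]
  out[ok] <- labels[lin]
  out
}
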