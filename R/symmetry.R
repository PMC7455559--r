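#' Dihedral point group D6
#'
#' The 12-operation point group of a dodecameric dual-membrane channel: six
#' rotations about the principal 6-fold axis plus six 2-fold rotations
#' about axes perpendicular to it.  With the default axis along z, the
#' 2-fold axes lie in the junction midplane (z = 0), matching the physical
#' symmetry that relates the two hemichannels.
#'
#' @param center Length-3 world position the axes pass through.
#' @param axis Unit 3-vector of the principal axis (default z).
#' @return An object of class `point_group`: a list with `ops` (list of
#'   3x3 rotation matrices), `order`, `axis`, `center`.
#' @export
d6_group <- function(center = c(0, 0, 0), axis = c(0, 0, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  ops <- vector("list", 12)
  for (k in 0:5) ops[[k + 1]] <- rot_axis(c(0, 0, 1), k * pi / 3)
  for (k in 0:5) {
    u <- c(cos(k * pi / 6), sin(k * pi / 6), 0)
    ops[[k + 7]] <- 2 * tcrossprod(u) - diag(3)  # rotation by pi about u
  }
  # conjugate into the requested axis frame
  if (!isTRUE(all.equal(axis, c(0, 0, 1)))) {
    B <- frame_to_axis(axis)
    ops <- lapply(ops, function(R) B %*% R %*% t(B))
  }
  g <- structure(list(ops = ops, order = 12L, axis = axis,
                      center = as.numeric(center)),
                 class = "point_group")
  check_group_closure(g)
  g
}

rot_axis <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

frame_to_axis <- function(axis) {
  # rotation taking z onto `axis`
  z <- c(0, 0, 1)
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  s <- sqrt(sum(v^2))
  c_ <- sum(z * axis)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))
  }
  rot_axis(v / s, atan2(s, c_))
}

check_group_closure <- function(g, tol = 1e-9) {
  for (a in g$ops) for (b in g$ops) {
    p <- a %*% b
    hit <- any(vapply(g$ops, function(o) max(abs(o - p)) < tol, logical(1)))
    if (!hit) abort("point group is not closed under composition")
  }
  invisible(TRUE)
}

#' Apply the point-group operations to coordinates
#'
#' @param xyz n x 3 matrix.
#' @param group A [d6_group()]-style `point_group`.
#' @param op Which operation (1-based index into `group$ops`).
#' @return Transformed n x 3 matrix.
#' @export
apply_symop <- function(xyz, group, op) {
  ctr <- matrix(group$center, nrow(xyz), 3, byrow = TRUE)
  (xyz - ctr) %*% t(group$ops[[op]]) + ctr
}

#' Expand an asymmetric unit by a point group
#'
#' Produces `group$order` geometric copies of the input atoms.  Chain ids
#' are suffixed with the operation index so copies remain distinguishable.
#' No clash checking is performed; the expansion is purely geometric.
#'
#' @param asym A [jl_structure] holding the asymmetric unit.
#' @param group A `point_group`.
#' @return A [jl_structure] with `nrow(asym$atoms) * group$order` atoms.
#' @export
symmetry_expand <- function(asym, group) {
  stopifnot(inherits(asym, "jl_structure"), inherits(group, "point_group"))
  xyz <- coords(asym)
  pieces <- lapply(seq_along(group$ops), function(i) {
    a <- asym$atoms
    new_xyz <- apply_symop(xyz, group, i)
    a$x <- new_xyz[, 1]; a$y <- new_xyz[, 2]; a$z <- new_xyz[, 3]
    a$chain_id <- paste0(a$chain_id, ".", i)
    a
  })
  jl_structure(dplyr::bind_rows(pieces), box = asym$box)
}
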