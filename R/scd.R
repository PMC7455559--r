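#' @title Acyl-chain order parameters
#' @description
#' The deuterium order parameter of an acyl C-H bond is
#' `S_CD = -<(3 cos^2(theta) - 1) / 2>`, where `theta` is the angle the
#' C-H vector makes with the bilayer normal and the average runs over all
#' attached hydrogens and frames.  Values lie in `[-1, 0.5]`: +0.5 for
#' bonds locked perpendicular to the normal, -1 for parallel bonds, 0 for
#' an isotropic orientation distribution; in practice ~0.2 indicates a
#' fluid bilayer and values above ~0.25 a gel-like (ordered) one.
#' @name scd
NULL

scd_check_range <- function(s) {
  bad <- !is.na(s) & (s < -1 - 1e-9 | s > 0.5 + 1e-9)
  if (any(bad)) {
    abort(sprintf("computed S_CD outside [-1, 0.5]: %s",
                  paste(format(head(s[bad], 3)), collapse = ", ")))
  }
  s
}

# sum of -(3cos^2-1)/2 over C-H samples per lipid for one carbon
scd_carbon_sums <- function(xyz, cidx_col, hidx_mat, normal) {
  cpos <- xyz[cidx_col, , drop = FALSE]
  acc <- numeric(nrow(cpos))
  for (j in seq_len(ncol(hidx_mat))) {
    v <- xyz[hidx_mat[, j], , drop = FALSE] - cpos
    cth <- (v %*% normal) / sqrt(rowSums(v^2))
    acc <- acc + as.numeric(-(3 * cth^2 - 1) / 2)
  }
  acc
}

scd_accumulate <- function(traj, lipids, lipid_topo, chains, normal,
                           frames = seq_len(n_frames(traj))) {
  # returns list per chain: sums [lipid, carbon], n_samples [lipid, carbon]
  topo <- traj$topology
  out <- list()
  for (ch in chains) {
    cidx <- chain_carbon_index(topo, lipids, lipid_topo, ch)
    hidx <- chain_hydrogen_index(topo, lipids, lipid_topo, ch)
    sums <- matrix(0, nrow(lipids), ncol(cidx))
    ns <- matrix(0, nrow(lipids), ncol(cidx))
    for (f in frames) {
      xyz <- traj$frames[[f]]
      for (k in seq_len(ncol(cidx))) {
        sums[, k] <- sums[, k] + scd_carbon_sums(xyz, cidx[, k], hidx[[k]], normal)
        ns[, k] <- ns[, k] + ncol(hidx[[k]])
      }
    }
    out[[ch]] <- list(sums = sums, n = ns)
  }
  out
}

#' Per-carbon S_CD profile
#'
#' Averages `-(3 cos^2(theta_CD) - 1)/2` over all attached C-H vectors,
#' all frames, and the selected lipids, for each chain carbon.
#'
#' @param traj A [jl_trajectory]; hydrogens must be present.
#' @param lipid_topo A [lipid_topology].
#' @param chain `"SN1"`, `"SN2"`, or both (default).
#' @param lipids Tibble of lipids (`chain_id`, `residue_id`) to include;
#'   default all lipids of the topology's residue name.
#' @param normal Unit bilayer normal (default z, the junction axis).
#' @return Tibble: `chain`, `carbon`, `scd`, `n_samples`.
#' @export
scd_per_carbon <- function(traj, lipid_topo, chain = c("SN1", "SN2"),
                           lipids = NULL, normal = c(0, 0, 1)) {
  chain <- match.arg(chain, several.ok = TRUE)
  lipids <- lipids %||% lipid_residues(traj$topology, lipid_topo)
  if (nrow(lipids) == 0) abort("no lipids selected")
  normal <- normal / sqrt(sum(normal^2))
  acc <- scd_accumulate(traj, lipids, lipid_topo, chain, normal)
  res <- purrr::map_dfr(chain, function(ch) {
    a <- acc[[ch]]
    tibble(chain = ch, carbon = seq_len(ncol(a$sums)),
           scd = colSums(a$sums) / colSums(a$n),
           n_samples = colSums(a$n))
  })
  scd_check_range(res$scd)
  class(res) <- c("order_profile", class(res))
  res
}

#' Time-averaged S_CD per lipid (combined chains, carbons 4-11)
#'
#' For each lipid, the mean of its per-carbon time-averaged S_CD values
#' over both chains restricted to the stated carbon range -- the scalar
#' used to color lipids by local ordering.
#'
#' @inheritParams scd_per_carbon
#' @param carbons Carbon positions to combine (default 4:11).
#' @return Tibble: `chain_id`, `residue_id`, `scd`.
#' @export
per_lipid_scd <- function(traj, lipid_topo, lipids = NULL, carbons = 4:11,
                          normal = c(0, 0, 1)) {
  lipids <- lipids %||% lipid_residues(traj$topology, lipid_topo)
  normal <- normal / sqrt(sum(normal^2))
  acc <- scd_accumulate(traj, lipids, lipid_topo, c("SN1", "SN2"), normal)
  per_carbon <- cbind(acc$SN1$sums / acc$SN1$n, acc$SN2$sums / acc$SN2$n)
  keep <- c(carbons, length(lipid_topo$sn1_carbons) + carbons)
  vals <- rowMeans(per_carbon[, keep, drop = FALSE])
  scd_check_range(vals)
  tibble(chain_id = lipids$chain_id, residue_id = lipids$residue_id,
         scd = vals)
}

# min distance from each group of points to a reference point set,
# chunked to bound memory
min_dist_by_group <- function(pts, group, ref, chunk = 4000L) {
  n <- nrow(pts)
  ng <- max(group)
  best <- rep(Inf, ng)
  ref2 <- rowSums(ref^2)
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    p <- pts[s:e, , drop = FALSE]
    d2 <- outer(rowSums(p^2), ref2, `+`) - 2 * p %*% t(ref)
    dmin <- sqrt(pmax(apply(d2, 1, min), 0))
    g <- group[s:e]
    agg <- tapply(dmin, g, min)
    ids <- as.integer(names(agg))
    best[ids] <- pmin(best[ids], as.numeric(agg))
  }
  best
}

#' Shell-averaged S_CD profiles around a protein
#'
#' For every frame, each lipid's distance to the protein is the minimum
#' heavy-atom--to--heavy-atom distance; lipid-frame samples are binned
#' into contiguous concentric shells of `shell_width` Angstrom starting at
#' distance 0, and per-shell per-carbon means are computed for SN1 and SN2
#' separately.  Lipids from both membranes are pooled; restrict to one
#' leaflet with `leaflet` to keep EC and IC averages separate.  Empty
#' shells are reported with `n = 0` so profiles align across runs.
#'
#' @inheritParams scd_per_carbon
#' @param protein Selection (mask/indices/function) of protein atoms.
#' @param shell_width Shell width in Angstrom (default 5).
#' @param leaflet Optional `"EC"` or `"IC"` filter.
#' @param leaflets Optional precomputed [assign_leaflets()] table; computed
#'   from frame 1 when needed.
#' @param n_shells Number of shells to report; default spans the data.
#' @return Tibble: `shell`, `r_inner`, `r_outer`, `chain`, `carbon`,
#'   `scd`, `n` (lipid-frame C-H sample count).
#' @export
shell_average_scd <- function(traj, protein, lipid_topo, shell_width = 5,
                              leaflet = NULL, leaflets = NULL,
                              lipids = NULL, n_shells = NULL,
                              normal = c(0, 0, 1)) {
  pidx <- resolve_selection(traj$topology, protein)
  if (length(pidx) == 0) abort("empty protein selection")
  atoms <- traj$topology$atoms
  pidx <- pidx[atoms$element[pidx] != "H"]
  normal <- normal / sqrt(sum(normal^2))
  lipids <- lipids %||% lipid_residues(traj$topology, lipid_topo)
  if (!is.null(leaflet)) {
    lf <- leaflets %||% assign_leaflets(
      set_coords(traj$topology, traj$frames[[1]]), lipid_topo)
    keep <- lf$leaflet == leaflet
    lipids <- dplyr::semi_join(lipids, lf[keep, c("chain_id", "residue_id")],
                               by = c("chain_id", "residue_id"))
  }
  if (nrow(lipids) == 0) abort("no lipids after leaflet filtering")
  # heavy atoms per lipid, grouped
  lipkey <- paste(lipids$chain_id, lipids$residue_id, sep = "\r")
  heavy <- which(atoms$residue_name == lipid_topo$residue_name &
                   atoms$element != "H")
  hv_grp <- match(paste(atoms$chain_id[heavy], atoms$residue_id[heavy],
                        sep = "\r"), lipkey)
  heavy <- heavy[!is.na(hv_grp)]
  hv_grp <- hv_grp[!is.na(hv_grp)]

  cidx <- list(SN1 = chain_carbon_index(traj$topology, lipids, lipid_topo, "SN1"),
               SN2 = chain_carbon_index(traj$topology, lipids, lipid_topo, "SN2"))
  hidx <- list(SN1 = chain_hydrogen_index(traj$topology, lipids, lipid_topo, "SN1"),
               SN2 = chain_hydrogen_index(traj$topology, lipids, lipid_topo, "SN2"))
  nc <- vapply(cidx, ncol, integer(1))
  shell_of <- function(d) as.integer(floor(d / shell_width)) + 1L

  sums <- list(); ns <- list()  # [[chain]] matrices shell x carbon, grown lazily
  for (ch in c("SN1", "SN2")) {
    sums[[ch]] <- matrix(0, 0, nc[[ch]])
    ns[[ch]] <- matrix(0, 0, nc[[ch]])
  }
  grow <- function(m, k) rbind(m, matrix(0, k - nrow(m), ncol(m)))
  ref <- NULL
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$frames[[f]]
    dmin <- min_dist_by_group(xyz[heavy, , drop = FALSE], hv_grp,
                              xyz[pidx, , drop = FALSE])
    sh <- shell_of(dmin)
    kmax <- max(sh)
    for (ch in c("SN1", "SN2")) {
      if (nrow(sums[[ch]]) < kmax) {
        sums[[ch]] <- grow(sums[[ch]], kmax)
        ns[[ch]] <- grow(ns[[ch]], kmax)
      }
      for (k in seq_len(nc[[ch]])) {
        s <- scd_carbon_sums(xyz, cidx[[ch]][, k], hidx[[ch]][[k]], normal)
        add_s <- tapply(s, sh, sum)
        add_n <- tapply(rep(ncol(hidx[[ch]][[k]]), length(s)), sh, sum)
        ids <- as.integer(names(add_s))
        sums[[ch]][ids, k] <- sums[[ch]][ids, k] + as.numeric(add_s)
        ns[[ch]][ids, k] <- ns[[ch]][ids, k] + as.numeric(add_n)
      }
    }
  }
  kmax <- n_shells %||% nrow(sums$SN1)
  for (ch in c("SN1", "SN2")) {
    sums[[ch]] <- grow(sums[[ch]], kmax)
    ns[[ch]] <- grow(ns[[ch]], kmax)
  }
  res <- purrr::map_dfr(c("SN1", "SN2"), function(ch) {
    purrr::map_dfr(seq_len(kmax), function(sh) {
      n <- ns[[ch]][sh, ]
      tibble(shell = sh, r_inner = (sh - 1) * shell_width,
             r_outer = sh * shell_width, chain = ch,
             carbon = seq_len(nc[[ch]]),
             scd = ifelse(n > 0, sums[[ch]][sh, ] / n, NA_real_),
             n = n)
    })
  })
  scd_check_range(res$scd)
  class(res) <- c("shell_profile", class(res))
  res
}

#' Simple per-leaflet area per lipid
#'
#' `(xy box area - protein cross-section in the leaflet z-slab) / n`,
#' where the protein cross-section is the area of a 2D raster of cells
#' within `dilate` Angstrom of any protein heavy atom whose z falls in the
#' slab spanned by the leaflet head-group plane and the membrane midplane.
#'
#' @param x A [jl_structure] frame with a known `box`.
#' @param lipid_topo A [lipid_topology].
#' @param leaflet `"EC"` or `"IC"`.
#' @param membrane Membrane index, 1 or 2.
#' @param protein Optional protein atom selection; `NULL` means no protein
#'   cross-section is subtracted.
#' @param leaflets Optional precomputed [assign_leaflets()] table.
#' @param grid Raster cell edge in Angstrom.
#' @param dilate Dilation radius around protein atoms (Angstrom).
#' @param box_center xy center of the box (default the origin).
#' @return Area per lipid in Angstrom^2 (scalar).
#' @export
area_per_lipid <- function(x, lipid_topo, leaflet = "EC", membrane = 1,
                           protein = NULL, leaflets = NULL, grid = 1,
                           dilate = 2, box_center = c(0, 0)) {
  stopifnot(inherits(x, "jl_structure"))
  if (is.null(x$box)) abort("structure has no box; area per lipid needs one")
  lf <- leaflets %||% assign_leaflets(x, lipid_topo)
  sel <- lf$membrane == membrane & lf$leaflet == leaflet
  n_lip <- sum(sel)
  if (n_lip == 0) abort("no lipids in the requested leaflet")
  box_area <- x$box[1] * x$box[2]
  cross <- 0
  if (!is.null(protein)) {
    pidx <- resolve_selection(x, protein)
    pidx <- pidx[x$atoms$element[pidx] != "H"]
    if (length(pidx)) {
      z_head <- mean(lf$z_phosphorus[sel])
      z_other <- mean(lf$z_phosphorus[lf$membrane == membrane &
                                        lf$leaflet != leaflet])
      z_mid <- (z_head + z_other) / 2
      slab <- sort(c(z_head, z_mid))
      a <- x$atoms[pidx, ]
      a <- a[a$z >= slab[1] - 1 & a$z <= slab[2] + 1, ]
      if (nrow(a)) {
        nx <- ceiling(x$box[1] / grid)
        ny <- ceiling(x$box[2] / grid)
        occ <- matrix(FALSE, nx, ny)
        x0 <- box_center[1] - x$box[1] / 2
        y0 <- box_center[2] - x$box[2] / 2
        cxs <- x0 + (seq_len(nx) - 0.5) * grid
        cys <- y0 + (seq_len(ny) - 0.5) * grid
        for (i in seq_len(nrow(a))) {
          ix <- which(abs(cxs - a$x[i]) <= dilate)
          iy <- which(abs(cys - a$y[i]) <= dilate)
          if (!length(ix) || !length(iy)) next
          dx2 <- (cxs[ix] - a$x[i])^2
          dy2 <- (cys[iy] - a$y[i])^2
          occ[ix, iy] <- occ[ix, iy] | outer(dx2, dy2, `+`) <= dilate^2
        }
        cross <- sum(occ) * grid^2
      }
    }
  }
  (box_area - cross) / n_lip
}
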