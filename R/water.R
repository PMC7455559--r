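#' Hydrogen-bond screening rules
#'
#' Distance-only donor/acceptor criterion: candidate partners are N and O
#' atoms (water oxygens included) strictly closer than `cutoff` Angstrom.
#' Donor-H-acceptor angle screening is deliberately not applied -- modeled
#' waters typically lack hydrogens -- so this is the reproducible core of
#' interactive h-bond tools.
#'
#' @param elements Partner element set.
#' @param cutoff Donor-acceptor distance cutoff in Angstrom (default 4.0,
#'   strict `<`).
#' @param min_partners Minimum partner count for a water to pass
#'   (default 2).
#' @return An object of class `hbond_rules`.
#' @export
hbond_rules <- function(elements = c("N", "O"), cutoff = 4.0,
                        min_partners = 2L) {
  if (cutoff <= 0) abort("cutoff must be positive")
  structure(list(elements = elements, cutoff = cutoff,
                 min_partners = as.integer(min_partners)),
            class = "hbond_rules")
}

water_residue_names <- c("HOH", "WAT", "TIP3", "SOL", "TIP", "SPC")

water_oxygens <- function(x) {
  a <- x$atoms
  which(a$residue_name %in% water_residue_names & a$element == "O")
}

#' Hydrogen-bond partners of a water position
#'
#' @param water Either a length-3 position or the atom index of a water
#'   oxygen in `structure`.
#' @param structure A [jl_structure] with candidate N/O atoms (protein,
#'   lipids, other waters).
#' @param rules An [hbond_rules()] object.
#' @param exclude Atom indices to exclude (the water's own atoms; filled
#'   automatically when `water` is an index).
#' @return Tibble of partners: `atom`, `atom_name`, `element`,
#'   `residue_name`, `residue_id`, `chain_id`, `distance`.
#' @export
find_hbond_partners <- function(water, structure, rules = hbond_rules(),
                                exclude = integer(0)) {
  a <- structure$atoms
  if (length(water) == 1) {
    wi <- as.integer(water)
    pos <- c(a$x[wi], a$y[wi], a$z[wi])
    exclude <- union(exclude,
                     which(a$chain_id == a$chain_id[wi] &
                             a$residue_id == a$residue_id[wi] &
                             a$residue_name == a$residue_name[wi]))
  } else {
    pos <- as.numeric(water)
  }
  cand <- setdiff(which(a$element %in% rules$elements), exclude)
  if (length(cand) == 0) {
    return(tibble(atom = integer(), atom_name = character(),
                  element = character(), residue_name = character(),
                  residue_id = integer(), chain_id = character(),
                  distance = double()))
  }
  d <- sqrt((a$x[cand] - pos[1])^2 + (a$y[cand] - pos[2])^2 +
              (a$z[cand] - pos[3])^2)
  hit <- d < rules$cutoff
  tibble(atom = cand[hit], atom_name = a$atom_name[cand[hit]],
         element = a$element[cand[hit]],
         residue_name = a$residue_name[cand[hit]],
         residue_id = a$residue_id[cand[hit]],
         chain_id = a$chain_id[cand[hit]],
         distance = d[hit])
}

#' Half-map consistency of positions
#'
#' A position passes when its sigma value is at or above `threshold` in
#' BOTH independently reconstructed half-maps.  Positions outside either
#' grid fail with a `-Inf` sentinel.
#'
#' @param positions n x 3 matrix (or length-3 vector) of world positions.
#' @param half1,half2 The two half-[density_map]s.
#' @param threshold Sigma contour (default 2.5).
#' @return Tibble: `sigma_half1`, `sigma_half2`, `pass`.
#' @export
halfmap_consistency <- function(positions, half1, half2, threshold = 2.5) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  s1 <- sigma_at(half1, positions)
  s2 <- sigma_at(half2, positions)
  tibble(sigma_half1 = s1, sigma_half2 = s2,
         pass = s1 >= threshold & s2 >= threshold)
}

#' Experimental/MD density overlap at positions
#'
#' A position passes when the (local-resolution-filtered) experimental map
#' is at or above `threshold_exp` sigma AND the time-averaged MD water map
#' is at or above `threshold_md` sigma there.
#'
#' @param positions n x 3 matrix of world positions.
#' @param exp_map Experimental [density_map].
#' @param md_map MD water-density [density_map], co-aligned in world
#'   space.
#' @param threshold_exp Experimental sigma contour (default 5.3).
#' @param threshold_md MD sigma contour (default 5.0).
#' @return Tibble: `sigma_exp`, `sigma_md`, `pass`.
#' @export
md_overlap <- function(positions, exp_map, md_map, threshold_exp = 5.3,
                       threshold_md = 5.0) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  se <- sigma_at(exp_map, positions)
  sm <- sigma_at(md_map, positions)
  tibble(sigma_exp = se, sigma_md = sm,
         pass = se >= threshold_exp & sm >= threshold_md)
}

#' Three-criterion validation of modeled water positions
#'
#' Per water oxygen: (1) at least `rules$min_partners` hydrogen-bond
#' donor/acceptor partners within the distance cutoff, (2) density at or
#' above `halfmap_threshold` sigma in both half-maps, and (3) overlap of
#' the experimental map (>= `exp_threshold` sigma) with the MD water map
#' (>= `md_threshold` sigma).  Criteria 1-2 are required for the verdict;
#' criterion 3 is an additional supporting measure, reported but not
#' required.
#'
#' @param model A [jl_structure] containing water residues.
#' @param half1,half2 Half-[density_map]s.
#' @param exp_map Optional experimental map for criterion 3.
#' @param md_map Optional MD water map for criterion 3.
#' @param rules An [hbond_rules()].
#' @param halfmap_threshold Criterion-2 contour (default 2.5 sigma).
#' @param exp_threshold,md_threshold Criterion-3 contours (defaults 5.3
#'   and 5.0 sigma).
#' @return A `water_assessment` tibble, one row per water: `water`,
#'   position, `n_hbond_partners`, the sigma columns, `pass_hbond`,
#'   `pass_halfmaps`, `pass_md_overlap`, `accepted`.  Use [glance()] for
#'   the summary fractions.
#' @export
validate_waters <- function(model, half1, half2, exp_map = NULL,
                            md_map = NULL, rules = hbond_rules(),
                            halfmap_threshold = 2.5, exp_threshold = 5.3,
                            md_threshold = 5.0) {
  widx <- water_oxygens(model)
  if (length(widx) == 0) {
    warn("model contains no water residues")
    out <- tibble(water = integer(), x = double(), y = double(),
                  z = double(), n_hbond_partners = integer(),
                  sigma_half1 = double(), sigma_half2 = double(),
                  sigma_exp = double(), sigma_md = double(),
                  pass_hbond = logical(), pass_halfmaps = logical(),
                  pass_md_overlap = logical(), accepted = logical())
    class(out) <- c("water_assessment", class(out))
    return(out)
  }
  a <- model$atoms
  pos <- cbind(a$x[widx], a$y[widx], a$z[widx])
  nhb <- vapply(widx, function(wi) {
    nrow(find_hbond_partners(wi, model, rules))
  }, integer(1))
  hm <- halfmap_consistency(pos, half1, half2, halfmap_threshold)
  if (!is.null(exp_map) && !is.null(md_map)) {
    md <- md_overlap(pos, exp_map, md_map, exp_threshold, md_threshold)
  } else {
    md <- tibble(sigma_exp = rep(NA_real_, length(widx)),
                 sigma_md = NA_real_, pass = NA)
  }
  out <- tibble(
    water = widx, x = pos[, 1], y = pos[, 2], z = pos[, 3],
    n_hbond_partners = nhb,
    sigma_half1 = hm$sigma_half1, sigma_half2 = hm$sigma_half2,
    sigma_exp = md$sigma_exp, sigma_md = md$sigma_md,
    pass_hbond = nhb >= rules$min_partners,
    pass_halfmaps = hm$pass,
    pass_md_overlap = md$pass
  )
  out$accepted <- out$pass_hbond & out$pass_halfmaps
  class(out) <- c("water_assessment", class(out))
  out
}

#' @export
glance.water_assessment <- function(x, ...) {
  n <- nrow(x)
  acc_md <- if (all(is.na(x$pass_md_overlap))) NA_real_ else {
    if (sum(x$accepted) == 0) NA_real_ else
      mean(x$pass_md_overlap[x$accepted])
  }
  tibble(
    n_waters = n,
    frac_hbond = if (n) mean(x$pass_hbond) else NA_real_,
    frac_halfmaps = if (n) mean(x$pass_halfmaps) else NA_real_,
    frac_md_overlap = if (n && !all(is.na(x$pass_md_overlap)))
      mean(x$pass_md_overlap) else NA_real_,
    frac_accepted = if (n) mean(x$accepted) else NA_real_,
    frac_accepted_md = acc_md
  )
}

#' MD water density map from a trajectory
#'
#' Composition of the density pipeline for solvent: Gaussian-spread maps
#' per run, run averaging, then point-group symmetrization.
#'
#' @param trajs A [jl_trajectory] or list of them (independent runs).
#' @param selection Water-oxygen selection (default: water residue oxygen
#'   atoms).
#' @param voxel_size Grid spacing (default 0.649 Angstrom).
#' @param group Optional `point_group` for symmetrization.
#' @param radii Gaussian radius table.
#' @param extent Optional shared extent (required for multiple runs so the
#'   lattices match; defaults to the union bounding box).
#' @return A [density_map].
#' @export
water_density_from_traj <- function(trajs, selection = NULL,
                                    voxel_size = 0.649, group = NULL,
                                    radii = vdw_radii(), extent = NULL) {
  if (inherits(trajs, "jl_trajectory")) trajs <- list(trajs)
  sels <- lapply(trajs, function(tr) {
    if (is.null(selection)) water_oxygens(tr$topology)
    else resolve_selection(tr$topology, selection)
  })
  if (is.null(extent)) {
    boxes <- purrr::map2(trajs, sels, function(tr, s) {
      default_extent(tr, s, 4 * max(radii))
    })
    lo <- Reduce(pmin, lapply(boxes, function(b) b[1, ]))
    hi <- Reduce(pmax, lapply(boxes, function(b) b[2, ]))
    extent <- rbind(lo, hi)
  }
  maps <- purrr::map2(trajs, sels, function(tr, s) {
    compute_density_map(tr, s, voxel_size, radii = radii, extent = extent)
  })
  out <- average_maps(maps)
  if (!is.null(group)) out <- symmetrize(out, group)
  out
}
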