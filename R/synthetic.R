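#' Specification of a synthetic dual-membrane junction system
#'
#' Defines the geometry of the toy system the generator builds: a
#' 12-subunit pseudo-protein spanning two parallel bilayers whose
#' extracellular head-group planes face each other across a ~3.5 nm gap
#' (membrane midplanes at +/- 39.5 A, leaflet offset 17.5 A giving EC
#' planes at +/- 22 A and IC planes at +/- 57 A), two-chain 14-carbon
#' lipids with explicit hydrogens, and waters with planted hydrogen-bond
#' partners.  Everything downstream is deterministic given `seed`.
#'
#' @param n_subunits Number of protein wedges (default 12).
#' @param membrane_midplane |z| of the two membrane midplanes (A).
#' @param leaflet_offset Head-group plane offset from the midplane (A).
#' @param n_lipids_ec,n_lipids_ic Lipids per EC / IC leaflet.
#' @param protein_radius Outer radius of the pseudo-protein (A).
#' @param box Box edge lengths (A).
#' @param n_waters Waters planted with 2 h-bond partners each.
#' @param n_waters_poor Waters planted with only `poor_partners` partners.
#' @param poor_partners Partner count for the poor waters (0 or 1).
#' @param seed RNG seed.
#' @return A `junction_spec` list.
#' @export
junction_spec <- function(n_subunits = 12L, membrane_midplane = 39.5,
                          leaflet_offset = 17.5, n_lipids_ec = 50L,
                          n_lipids_ic = 50L, protein_radius = 20,
                          box = c(130, 130, 150), n_waters = 24L,
                          n_waters_poor = 0L, poor_partners = 1L,
                          seed = 1L) {
  structure(list(n_subunits = as.integer(n_subunits),
                 membrane_midplane = membrane_midplane,
                 leaflet_offset = leaflet_offset,
                 n_lipids_ec = as.integer(n_lipids_ec),
                 n_lipids_ic = as.integer(n_lipids_ic),
                 protein_radius = protein_radius,
                 box = box, n_waters = as.integer(n_waters),
                 n_waters_poor = as.integer(n_waters_poor),
                 poor_partners = as.integer(poor_partners),
                 seed = as.integer(seed)),
            class = "junction_spec")
}

#' Per-leaflet chain-order model for the generator
#'
#' Lipids are posed geometrically: each lipid-frame draws a chain director
#' tilted from the membrane normal by |N(0, tilt_sd)| at a uniform
#' azimuth, chains are all-trans except that each bond independently kinks
#' by 60 degrees with probability `gauche_prob`, and C-H vectors are
#' placed perpendicular to the local chain direction at uniform azimuths.
#' Under this model the ordered (all-trans) leaflet has the closed-form
#' expectation `S_CD = 0.5 - 0.75 E[sin^2 alpha]`, which the generator
#' records as the planted target.
#'
#' @param tilt_sd_deg Gaussian tilt sd in degrees.
#' @param gauche_prob Per-bond kink probability (0 = all-trans).
#' @param head_jitter Per-frame xy jitter of the head group (A).
#' @return An `order_spec` list.
#' @export
order_spec <- function(tilt_sd_deg = 5, gauche_prob = 0, head_jitter = 0.3) {
  structure(list(tilt_sd_deg = tilt_sd_deg, gauche_prob = gauche_prob,
                 head_jitter = head_jitter), class = "order_spec")
}

#' Markov kinetics for rod-hopping lipids
#'
#' A subset of EC-leaflet lipids is placed on the rod lattice and hops
#' between `n_states` candidate pair-configurations under a stationary
#' Markov chain: stay with probability `1 - dt/mean_dwell`, otherwise move
#' uniformly to one of the other candidates, so planted mean dwell time is
#' `mean_dwell_ns`.
#'
#' @param n_lipids Number of kinetically controlled lipids.
#' @param mean_dwell_ns Planted mean dwell time (ns).
#' @param dt_ns Frame spacing (ns).
#' @param n_states Candidate pair-states per lipid (2 or 3).
#' @param site_jitter Per-frame xy jitter of the chains about their rod
#'   sites (Angstrom); keep well below the rods' high-contour core radius
#'   if exact truth recovery is wanted.
#' @return A `kinetic_spec` list.
#' @export
kinetic_spec <- function(n_lipids = 12L, mean_dwell_ns = 2.0, dt_ns = 0.1,
                         n_states = 3L, site_jitter = 0.1) {
  leave <- dt_ns / mean_dwell_ns
  if (leave >= 1) abort("mean_dwell_ns must exceed dt_ns")
  structure(list(n_lipids = as.integer(n_lipids),
                 mean_dwell_ns = mean_dwell_ns, dt_ns = dt_ns,
                 n_states = as.integer(n_states), p_leave = leave,
                 site_jitter = site_jitter),
            class = "kinetic_spec")
}

markov_sample <- function(trans, n_frames) {
  ns <- nrow(trans)
  out <- integer(n_frames)
  st <- sample.int(ns, 1)
  for (f in seq_len(n_frames)) {
    out[f] <- st
    st <- sample.int(ns, 1, prob = trans[st, ])
  }
  out
}

#' Sample planted configurational-state label series
#'
#' Draws per-lipid Markov chains over a candidate pair-state label set
#' under a [kinetic_spec()] -- the same sampling [generate_trajectory()]
#' uses to drive its rod-hopping lipids, exposed so dwell/census
#' statistics can be exercised at scale without posing geometry.
#'
#' @param kinetics A [kinetic_spec()] (its `n_lipids` is ignored here).
#' @param n_lipids Number of lipids to sample.
#' @param n_frames Frames per lipid.
#' @param seed RNG seed.
#' @param labels Candidate pair-state labels (length `kinetics$n_states`).
#' @return Character matrix (lipids x frames) with the planted transition
#'   matrix in attribute `"transition_matrix"`.
#' @export
simulate_state_labels <- function(kinetics, n_lipids, n_frames, seed = 1L,
                                  labels = c("1-3", "1-4", "3-4")) {
  stopifnot(inherits(kinetics, "kinetic_spec"),
            length(labels) == kinetics$n_states)
  set.seed(seed)
  ns <- kinetics$n_states
  trans <- matrix(kinetics$p_leave / (ns - 1), ns, ns)
  diag(trans) <- 1 - kinetics$p_leave
  out <- matrix("", n_lipids, n_frames)
  for (j in seq_len(n_lipids)) {
    out[j, ] <- labels[markov_sample(trans, n_frames)]
  }
  attr(out, "transition_matrix") <- trans
  out
}

# ---- lipid atom template ------------------------------------------------

lipid_template <- function() {
  ks <- 1:14
  name <- c("P",
            paste0("C", ks, "A"),
            as.vector(rbind(paste0("HA", ks), paste0("HB", ks))), "HC14",
            paste0("C", ks, "B"),
            as.vector(rbind(paste0("HD", ks), paste0("HE", ks))), "HF14")
  elem <- c("P", rep("C", 14), rep("H", 29), rep("C", 14), rep("H", 29))
  list(atom_name = name, element = elem, n = length(name),
       i_p = 1L, i_c1 = 1L + ks, i_c2 = 44L + ks)
}

perp_basis <- function(e) {
  a <- if (abs(e[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(a[2] * e[3] - a[3] * e[2],
          a[3] * e[1] - a[1] * e[3],
          a[1] * e[2] - a[2] * e[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e[2] * e1[3] - e[3] * e1[2],
          e[3] * e1[1] - e[1] * e1[3],
          e[1] * e1[2] - e[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# one acyl chain: carbons + hydrogens.  dirs: segment direction leaving
# each carbon; kinks deflect by 60 deg about a perpendicular axis.
chain_coords <- function(base, d0, kink_bonds, kink_az, psi,
                         bond = 1.27, ch = 1.09) {
  nc <- 14L
  dirs <- matrix(0, nc, 3)
  d <- d0
  for (k in seq_len(nc - 1L)) {
    if (k %in% kink_bonds) {
      b <- perp_basis(d)
      az <- kink_az[match(k, kink_bonds)]
      axis <- cos(az) * b$e1 + sin(az) * b$e2
      d <- as.numeric(rot_axis(axis, pi / 3) %*% d)
    }
    dirs[k, ] <- d
  }
  dirs[nc, ] <- dirs[nc - 1L, ]
  cpos <- matrix(0, nc, 3)
  cpos[1, ] <- base
  for (k in 2:nc) cpos[k, ] <- cpos[k - 1L, ] + bond * dirs[k - 1L, ]
  hpos <- matrix(0, 2L * nc + 1L, 3)
  for (k in seq_len(nc)) {
    e <- dirs[k, ]
    b <- perp_basis(e)
    h1 <- cos(psi[k]) * b$e1 + sin(psi[k]) * b$e2
    h2 <- cos(psi[k] + 2 * pi / 3) * b$e1 + sin(psi[k] + 2 * pi / 3) * b$e2
    hpos[2L * k - 1L, ] <- cpos[k, ] + ch * h1
    hpos[2L * k, ] <- cpos[k, ] + ch * h2
  }
  hpos[2L * nc + 1L, ] <- cpos[nc, ] + ch * dirs[nc, ]
  list(c = cpos, h = hpos)
}

# full 87-atom lipid pose; s = +1/-1 core direction along z
pose_lipid <- function(head, s, alpha, phi, kinks1, kaz1, kinks2, kaz2,
                       psi1, psi2) {
  d0 <- c(sin(alpha) * cos(phi), sin(alpha) * sin(phi), s * cos(alpha))
  lat <- c(2.2, 0, 0)
  ch1 <- chain_coords(head + 1.8 * d0 + lat, d0, kinks1, kaz1, psi1)
  ch2 <- chain_coords(head + 1.8 * d0 - lat, d0, kinks2, kaz2, psi2)
  out <- matrix(0, 87, 3)
  out[1, ] <- head
  out[2:15, ] <- ch1$c
  out[16:44, ] <- ch1$h
  out[45:58, ] <- ch2$c
  out[59:87, ] <- ch2$h
  out
}

# kinetic pose: chains vertical at two rod sites, head between them
pose_lipid_sites <- function(site1, site2, z_head, z0, psi1, psi2,
                             jitter = c(0, 0)) {
  up <- c(0, 0, 1)
  b1 <- c(site1[1] + jitter[1], site1[2] + jitter[2], z0)
  b2 <- c(site2[1] + jitter[1], site2[2] + jitter[2], z0)
  ch1 <- chain_coords(b1, up, integer(0), numeric(0), psi1)
  ch2 <- chain_coords(b2, up, integer(0), numeric(0), psi2)
  out <- matrix(0, 87, 3)
  out[1, ] <- c((site1[1] + site2[1]) / 2, (site1[2] + site2[2]) / 2, z_head)
  out[2:15, ] <- ch1$c
  out[16:44, ] <- ch1$h
  out[45:58, ] <- ch2$c
  out[59:87, ] <- ch2$h
  out
}

# ---- rod lattice --------------------------------------------------------

#' Rod-site lattice of the synthetic EC leaflet
#'
#' 19 acyl-chain sites per 30-degree subunit sector (rings at radii
#' 26..56 A), replicated over the 12 sectors, with every pair of sites at
#' least ~6 A apart so planted rod densities stay separable at high
#' contour.  Sites are numbered within each sector by increasing radius,
#' ties by azimuth -- the same convention [build_rod_catalogue()] uses, so
#' planted and recovered numbering coincide.
#'
#' @param spec A [junction_spec()].
#' @return Tibble: `site_id`, `subunit`, `site` (1..19), `x`, `y`, `z0`
#'   (chain start z), `radius`, `azimuth`.
#' @export
rod_sites <- function(spec) {
  radii <- c(26, 32, 38, 44, 50, 56)
  counts <- c(2, 3, 3, 3, 4, 4)
  az0 <- unlist(purrr::map2(radii, counts, function(r, m) {
    (seq_len(m) - 0.5) * 30 / m   # uniform in the sector, symmetric gaps
  }))
  r0 <- rep(radii, counts)
  z_head <- spec$membrane_midplane - spec$leaflet_offset  # EC plane (+22)
  z0 <- z_head + 1.5
  base <- tibble(radius = r0, azimuth0 = az0)
  base <- dplyr::arrange(base, .data$radius, .data$azimuth0)
  base$site <- seq_len(nrow(base))
  out <- purrr::map_dfr(seq_len(spec$n_subunits), function(s) {
    az <- base$azimuth0 + (s - 1) * (360 / spec$n_subunits)
    tibble(subunit = s, site = base$site,
           x = base$radius * cos(az * pi / 180),
           y = base$radius * sin(az * pi / 180),
           z0 = z0, radius = base$radius, azimuth = az %% 360)
  })
  out$site_id <- seq_len(nrow(out))
  out
}

sunflower_annulus <- function(n, r_in, r_out, az_offset = 0) {
  k <- seq_len(n)
  r <- sqrt(r_in^2 + (k - 0.5) / n * (r_out^2 - r_in^2))
  th <- k * 2.399963 + az_offset
  cbind(x = r * cos(th), y = r * sin(th))
}

# ---- system generation --------------------------------------------------

#' Generate the synthetic junction system
#'
#' Builds the pseudo-protein (12 wedges of pseudo-atoms about z spanning
#' both membranes), four leaflets of two-chain 14-carbon lipids with
#' explicit hydrogens at their rest pose, and waters in the gap region
#' with planted hydrogen-bond partner atoms.  Fully deterministic given
#' `spec$seed`; all planted truths are returned alongside the structure.
#'
#' @param spec A [junction_spec()].
#' @return A `junction_system` list: `structure` ([jl_structure]),
#'   `topology` ([lipid_topology]), `spec`, and `truth` (leaflet labels,
#'   planted planes, water table, rod-site lattice).
#' @export
generate_system <- function(spec = junction_spec()) {
  set.seed(spec$seed)
  tpl <- lipid_template()
  mm <- spec$membrane_midplane
  planes <- c(m1_ic = -mm - spec$leaflet_offset,
              m1_ec = -mm + spec$leaflet_offset,
              m2_ec = mm - spec$leaflet_offset,
              m2_ic = mm + spec$leaflet_offset)

  # protein: 12 wedges of CA pseudo-atoms
  prot <- list()
  zs <- seq(-mm - spec$leaflet_offset - 5, mm + spec$leaflet_offset + 5,
            by = 6)
  rads <- c(spec$protein_radius - 6, spec$protein_radius - 2)
  azs <- c(-6, 6)
  for (s in seq_len(spec$n_subunits)) {
    ctr <- (s - 0.5) * 360 / spec$n_subunits
    g <- expand.grid(z = zs, r = rads, a = azs)
    ang <- (ctr + g$a) * pi / 180
    prot[[s]] <- tibble(
      atom_name = "CA", element = "C", residue_name = "GLY",
      residue_id = seq_len(nrow(g)), chain_id = LETTERS[s],
      x = g$r * cos(ang), y = g$r * sin(ang), z = g$z,
      is_hetero = FALSE)
  }

  # lipids: 4 leaflets; chains point toward their membrane midplane
  leaflet_def <- tibble(
    chain_id = c("M", "N", "O", "Q"),
    plane = as.numeric(planes[c("m1_ic", "m1_ec", "m2_ec", "m2_ic")]),
    leaflet = c("IC", "EC", "EC", "IC"),
    membrane = c(1L, 1L, 2L, 2L),
    s = c(1, -1, 1, -1),   # core direction sign along z
    n = c(spec$n_lipids_ic, spec$n_lipids_ec, spec$n_lipids_ec,
          spec$n_lipids_ic))
  lip <- list()
  for (li in seq_len(nrow(leaflet_def))) {
    n <- leaflet_def$n[li]
    if (n == 0) next
    xy <- sunflower_annulus(n, spec$protein_radius + 4,
                            min(spec$box[1:2]) / 2 - 6,
                            az_offset = li)
    rows <- vector("list", n)
    for (k in seq_len(n)) {
      head <- c(xy[k, 1], xy[k, 2],
                leaflet_def$plane[li] + rnorm(1, 0, 0.5))
      xyz <- pose_lipid(head, leaflet_def$s[li], 0, 0,
                        integer(0), numeric(0), integer(0), numeric(0),
                        psi1 = runif(14, 0, 2 * pi),
                        psi2 = runif(14, 0, 2 * pi))
      rows[[k]] <- tibble(
        atom_name = tpl$atom_name, element = tpl$element,
        residue_name = "DMP", residue_id = k,
        chain_id = leaflet_def$chain_id[li],
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], is_hetero = TRUE)
    }
    lip[[li]] <- dplyr::bind_rows(rows)
  }

  # waters in the gap, spaced so they cannot hydrogen-bond each other;
  # partners point up out of the water plane
  n_w <- spec$n_waters + spec$n_waters_poor
  wat <- NULL; prt <- NULL; wtruth <- NULL
  if (n_w > 0) {
    xy <- sunflower_annulus(n_w, spec$protein_radius + 6, 55, az_offset = 2)
    wz <- rnorm(n_w, 0, 0.5)
    n_partners <- c(rep(2L, spec$n_waters),
                    rep(spec$poor_partners, spec$n_waters_poor))
    wat <- tibble(atom_name = "O", element = "O", residue_name = "HOH",
                  residue_id = seq_len(n_w), chain_id = "W",
                  x = xy[, 1], y = xy[, 2], z = wz, is_hetero = TRUE)
    prows <- list()
    for (k in seq_len(n_w)) {
      np <- n_partners[k]
      if (np == 0) next
      dist <- c(2.8, 3.0)[seq_len(np)]
      elem <- c("O", "N")[seq_len(np)]
      th <- runif(np, 0, 2 * pi)
      tiltp <- runif(np, 0, 25) * pi / 180   # within 25 deg of +z
      prows[[length(prows) + 1]] <- tibble(
        atom_name = elem, element = elem, residue_name = "PTN",
        residue_id = k, chain_id = "Z",
        x = xy[k, 1] + dist * sin(tiltp) * cos(th),
        y = xy[k, 2] + dist * sin(tiltp) * sin(th),
        z = wz[k] + dist * cos(tiltp),
        is_hetero = TRUE)
    }
    prt <- dplyr::bind_rows(prows)
    wtruth <- tibble(water = seq_len(n_w), x = xy[, 1], y = xy[, 2],
                     z = wz, n_partners = n_partners)
  }

  atoms <- dplyr::bind_rows(c(prot, lip, list(wat, prt)))
  structure_ <- jl_structure(atoms, box = spec$box)
  leaflet_truth <- purrr::map_dfr(seq_len(nrow(leaflet_def)), function(li) {
    n <- leaflet_def$n[li]
    if (n == 0) return(NULL)
    tibble(chain_id = leaflet_def$chain_id[li], residue_id = seq_len(n),
           membrane = leaflet_def$membrane[li],
           leaflet = leaflet_def$leaflet[li],
           plane = leaflet_def$plane[li], s = leaflet_def$s[li])
  })
  structure(list(structure = structure_, topology = dmpc_topology("DMP"),
                 spec = spec,
                 truth = list(planes = planes, leaflets = leaflet_truth,
                              waters = wtruth, rod_sites = rod_sites(spec))),
            class = "junction_system")
}

#' @export
print.junction_system <- function(x, ...) {
  cat(sprintf("<junction_system> %d atoms, %d lipids, %d waters (seed %d)\n",
              nrow(x$structure$atoms), nrow(x$truth$leaflets),
              if (is.null(x$truth$waters)) 0L else nrow(x$truth$waters),
              x$spec$seed))
  invisible(x)
}

# ---- trajectory generation ----------------------------------------------

#' Generate a posed trajectory with planted order and kinetics
#'
#' Every frame re-poses the lipids from the per-leaflet order model
#' ([order_spec()]): the EC model is applied to EC-leaflet lipids and the
#' IC model to IC-leaflet lipids, so an ordered-EC / disordered-IC
#' contrast is planted by construction.  Under [kinetic_spec()] control,
#' the first `n_lipids` lipids of the upper EC leaflet (chain "O") are
#' instead placed on the rod lattice and hop between candidate
#' pair-configurations by a Markov chain.  Protein and waters are static.
#'
#' The returned trajectory carries a `truth` attribute: per-leaflet
#' planted S_CD targets (`0.5 - 0.75 E[sin^2 alpha]` with the empirical
#' tilt moments), and for kinetic lipids the per-frame true state labels
#' (in the catalogue's within-subunit numbering) and the planted
#' transition matrix.
#'
#' @param system A [generate_system()] result.
#' @param order List with elements `ec` and `ic`, each an [order_spec()].
#' @param kinetics Optional [kinetic_spec()].
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @param dt_ns Frame spacing in ns (default 0.1).
#' @return A [jl_trajectory] with attribute `"truth"`.
#' @export
generate_trajectory <- function(system,
                                order = list(ec = order_spec(5, 0),
                                             ic = order_spec(20, 0.1)),
                                kinetics = NULL, n_frames = 100L,
                                seed = 1L, dt_ns = 0.1) {
  stopifnot(inherits(system, "junction_system"))
  set.seed(seed)
  tpl <- lipid_template()
  atoms <- system$structure$atoms
  base_xyz <- coords(system$structure)
  lt <- system$truth$leaflets
  # atom-block start index of each lipid (template order is contiguous)
  lip_start <- integer(nrow(lt))
  for (i in seq_len(nrow(lt))) {
    lip_start[i] <- which(atoms$chain_id == lt$chain_id[i] &
                            atoms$residue_id == lt$residue_id[i] &
                            atoms$residue_name == "DMP")[1]
  }
  base_head <- cbind(atoms$x[lip_start], atoms$y[lip_start],
                     atoms$z[lip_start])

  # kinetic setup
  kin_idx <- integer(0)
  kin_states <- NULL; kin_pairs <- NULL; kin_labels <- NULL; trans <- NULL
  if (!is.null(kinetics) && kinetics$n_lipids > 0) {
    cand <- which(lt$chain_id == "O")
    if (length(cand) < kinetics$n_lipids) {
      abort("not enough upper-EC lipids for the requested kinetic count")
    }
    kin_idx <- cand[seq_len(kinetics$n_lipids)]
    sites <- system$truth$rod_sites
    ns <- kinetics$n_states
    # per lipid: home subunit and a mutually-close site triple
    # (sites 1, 3, 4 in within-sector numbering: ring-1 and ring-2 sites)
    triple <- c(1L, 3L, 4L)
    pair_sets <- list(c(1, 2), c(1, 3), c(2, 3))[seq_len(ns)]
    kin_pairs <- vector("list", length(kin_idx))
    for (j in seq_along(kin_idx)) {
      sub <- (j - 1L) %% system$spec$n_subunits + 1L
      ss <- sites[sites$subunit == sub & sites$site %in% triple, ]
      ss <- ss[match(triple, ss$site), ]
      kin_pairs[[j]] <- lapply(pair_sets, function(p) ss[p, ])
    }
    trans <- matrix(kinetics$p_leave / (ns - 1), ns, ns)
    diag(trans) <- 1 - kinetics$p_leave
    kin_states <- matrix(0L, length(kin_idx), n_frames)
    for (j in seq_along(kin_idx)) {
      kin_states[j, ] <- markov_sample(trans, n_frames)
    }
    kin_labels <- matrix("", length(kin_idx), n_frames)
    for (j in seq_along(kin_idx)) {
      labs <- vapply(kin_pairs[[j]], function(pp) {
        paste0(pp$site[1], "-", pp$site[2])
      }, character(1))
      kin_labels[j, ] <- labs[kin_states[j, ]]
    }
  }

  spec_of <- function(i) if (lt$leaflet[i] == "EC") order$ec else order$ic
  sin2 <- list(EC = numeric(0), IC = numeric(0))
  frames <- vector("list", n_frames)
  z_head_kin <- system$truth$planes["m2_ec"]
  for (f in seq_len(n_frames)) {
    xyz <- base_xyz
    for (i in seq_len(nrow(lt))) {
      rows <- lip_start[i] + 0:(tpl$n - 1L)
      j <- match(i, kin_idx)
      if (!is.na(j)) {
        pp <- kin_pairs[[j]][[kin_states[j, f]]]
        xyz[rows, ] <- pose_lipid_sites(
          c(pp$x[1], pp$y[1]), c(pp$x[2], pp$y[2]),
          z_head_kin, pp$z0[1],
          psi1 = runif(14, 0, 2 * pi), psi2 = runif(14, 0, 2 * pi),
          jitter = rnorm(2, 0, kinetics$site_jitter))
        next
      }
      os <- spec_of(i)
      alpha <- abs(rnorm(1, 0, os$tilt_sd_deg * pi / 180))
      phi <- runif(1, 0, 2 * pi)
      sin2[[lt$leaflet[i]]] <- c(sin2[[lt$leaflet[i]]], sin(alpha)^2)
      kinks1 <- which(runif(13) < os$gauche_prob)
      kinks2 <- which(runif(13) < os$gauche_prob)
      head <- c(base_head[i, 1] + rnorm(1, 0, os$head_jitter),
                base_head[i, 2] + rnorm(1, 0, os$head_jitter),
                base_head[i, 3])
      xyz[rows, ] <- pose_lipid(head, lt$s[i], alpha, phi,
                                kinks1, runif(length(kinks1), 0, 2 * pi),
                                kinks2, runif(length(kinks2), 0, 2 * pi),
                                psi1 = runif(14, 0, 2 * pi),
                                psi2 = runif(14, 0, 2 * pi))
    }
    frames[[f]] <- xyz
  }
  traj <- jl_trajectory(system$structure, frames, dt_ns)
  truth <- list(
    target_scd = vapply(sin2, function(s2) {
      if (length(s2) == 0) NA_real_ else 0.5 - 0.75 * mean(s2)
    }, double(1)),
    kinetic_lipids = if (length(kin_idx))
      lt[kin_idx, c("chain_id", "residue_id")] else NULL,
    kinetic_states = kin_states,
    kinetic_labels = kin_labels,
    transition_matrix = trans,
    order = order, kinetics = kinetics, seed = seed)
  attr(traj, "truth") <- truth
  traj
}

# ---- map generation -----------------------------------------------------

#' Generate synthetic density maps with planted truth
#'
#' Produces (a) an EC-leaflet acyl-rod density map with one Gaussian rod
#' planted at every lattice site (amplitudes chosen so rod voxels sit far
#' above an 8-sigma contour), and (b) water maps: a noiseless map of the
#' system's water oxygens, two half-maps made by adding independent
#' Gaussian noise fields, and an "MD" water map containing only a chosen
#' fraction of the waters (emulating solvent sites seen by simulation).
#' Decoy positions -- empty locations at least 5 A from every water --
#' are recorded in the truth for specificity tests.
#'
#' @param system A [generate_system()] result.
#' @param voxel Voxel size (A) of all generated maps.
#' @param rod_sigma Gaussian radius of rod pseudo-atoms (A).
#' @param noise Half-map noise sd as a fraction of the noiseless map's
#'   grid sd.
#' @param md_fraction Fraction of waters co-planted in the MD map.
#' @param n_decoys Number of decoy positions to record.
#' @param seed RNG seed for the noise fields and decoys.
#' @return List: `rod_map`, `water_map`, `half1`, `half2`, `md_map`,
#'   `truth` (water positions, `md_planted` flags, `decoys` matrix).
#' @export
generate_maps <- function(system, voxel = 0.55, rod_sigma = 0.65,
                          noise = 0.5, md_fraction = 1.0, n_decoys = 0L,
                          seed = 1L) {
  stopifnot(inherits(system, "junction_system"))
  set.seed(seed)
  sites <- system$truth$rod_sites
  zpts <- (0:13) * 1.27
  rod_atoms <- tibble(
    atom_name = "R", element = "R", residue_name = "ROD",
    residue_id = rep(sites$site_id, each = length(zpts)),
    chain_id = "R",
    x = rep(sites$x, each = length(zpts)),
    y = rep(sites$y, each = length(zpts)),
    z = rep(sites$z0, each = length(zpts)) + rep(zpts, nrow(sites)),
    is_hetero = TRUE)
  rod_traj <- jl_trajectory(jl_structure(rod_atoms),
                            list(unname(as.matrix(rod_atoms[, c("x", "y", "z")]))))
  rmax <- max(sites$radius) + 6
  z0 <- min(sites$z0)
  rod_map <- compute_density_map(
    rod_traj, seq_len(nrow(rod_atoms)), voxel,
    radii = c(R = rod_sigma),
    extent = rbind(c(-rmax, -rmax, z0 - 18),
                   c(rmax, rmax, z0 + max(zpts) + 18)))

  out <- list(rod_map = rod_map)
  wt <- system$truth$waters
  if (!is.null(wt) && nrow(wt) > 0) {
    wpos <- as.matrix(wt[, c("x", "y", "z")])
    watoms <- tibble(atom_name = "O", element = "O", residue_name = "HOH",
                     residue_id = wt$water, chain_id = "W",
                     x = wpos[, 1], y = wpos[, 2], z = wpos[, 3],
                     is_hetero = TRUE)
    wtraj <- jl_trajectory(jl_structure(watoms), list(unname(wpos)))
    pad <- 6
    ext <- rbind(apply(wpos, 2, min) - pad, apply(wpos, 2, max) + pad)
    full <- compute_density_map(wtraj, seq_len(nrow(wpos)), voxel,
                                radii = c(O = 1.0), extent = ext)
    nsd <- noise * full$sd
    d <- dim(full$grid)
    half1 <- density_map(full$grid + array(rnorm(prod(d), 0, nsd), d),
                         voxel, full$origin)
    half2 <- density_map(full$grid + array(rnorm(prod(d), 0, nsd), d),
                         voxel, full$origin)
    n_md <- round(md_fraction * nrow(wt))
    md_planted <- rep(FALSE, nrow(wt))
    md_planted[sample.int(nrow(wt), n_md)] <- TRUE
    if (n_md > 0) {
      mtraj <- jl_trajectory(jl_structure(watoms[md_planted, ]),
                             list(unname(wpos[md_planted, , drop = FALSE])))
      md_map <- compute_density_map(mtraj, seq_len(n_md), voxel,
                                    radii = c(O = 1.0), extent = ext)
    } else {
      md_map <- density_map(array(0, d), voxel, full$origin)
    }
    decoys <- matrix(numeric(0), 0, 3)
    while (nrow(decoys) < n_decoys) {
      r <- runif(1, system$spec$protein_radius + 6, 55)
      th <- runif(1, 0, 2 * pi)
      p <- c(r * cos(th), r * sin(th), runif(1, -3, 3))
      d2 <- (wpos[, 1] - p[1])^2 + (wpos[, 2] - p[2])^2 + (wpos[, 3] - p[3])^2
      if (min(d2) >= 25) decoys <- rbind(decoys, p)
    }
    out <- c(out, list(water_map = full, half1 = half1, half2 = half2,
                       md_map = md_map))
    out$truth <- list(waters = wt, md_planted = md_planted,
                      decoys = decoys, noise_sd = nsd)
  } else {
    out$truth <- list(waters = NULL)
  }
  out
}

#' The ordered-EC reference fixture
#'
#' The standard conditions for the gel-phase order statistic: 200
#' extracellular-leaflet lipids (100 per EC leaflet) posed all-trans with
#' 5-degree Gaussian tilt over 100 frames, plus small disordered IC
#' leaflets for contrast.
#'
#' @param seed RNG seed (default 7).
#' @param n_lipids Total EC lipids (default 200).
#' @param n_frames Frames (default 100).
#' @return List: `system`, `traj`, `ec_lipids` (tibble of the EC lipids),
#'   `truth` (the trajectory truth record).
#' @export
ordered_ec_fixture <- function(seed = 7L, n_lipids = 200L, n_frames = 100L) {
  spec <- junction_spec(n_lipids_ec = as.integer(n_lipids / 2),
                        n_lipids_ic = 8L, n_waters = 0L, seed = seed)
  system <- generate_system(spec)
  traj <- generate_trajectory(system,
                              order = list(ec = order_spec(5, 0),
                                           ic = order_spec(20, 0.1)),
                              n_frames = n_frames, seed = seed)
  lt <- system$truth$leaflets
  list(system = system, traj = traj,
       ec_lipids = lt[lt$leaflet == "EC", c("chain_id", "residue_id")],
       truth = attr(traj, "truth"))
}
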