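# independent flood-fill components oracle (6.. wait: 26-connectivity)
oracle_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        n <- ijk + offs[r, ]
        if (any(n < 1) || any(n > d)) next
        li <- (n[3] - 1) * d[1] * d[2] + (n[2] - 1) * d[1] + n[1]
        if (mask[li] && lab[li] == 0L) {
          lab[li] <- nxt
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

test_that("the synthetic EC map yields the full 228-rod catalogue", {
  fx <- fx_states()
  expect_equal(nrow(fx$catalogue), 228L)
  expect_true(all(table(fx$catalogue$subunit) == 19L))
  expect_true(all(fx$catalogue$rod %in% 1:19))
  expect_true(all(fx$catalogue$n_voxels >= 20))
})

test_that("an empty map gives an empty catalogue with a warning", {
  set.seed(1)
  m <- density_map(array(rnorm(10^3), c(10, 10, 10)), 1)
  expect_warning(cat_ <- build_rod_catalogue(m, sigma_min = 50),
                 "empty")
  expect_equal(nrow(cat_), 0L)
})

test_that("connected components agree with a brute-force flood-fill oracle", {
  set.seed(21)
  # blobby random mask on a small grid
  g <- array(0, c(18, 18, 12))
  for (k in 1:6) {
    c0 <- c(sample(3:16, 2), sample(3:10, 1))
    pts <- voxel_centers(density_map(g, 1))
    g <- g + array(exp(-rowSums(sweep(pts, 2, c0)^2) / 4), dim(g))
  }
  m <- density_map(g, 1)
  sig_thresh <- 1.5
  mask <- (g - m$mean) / m$sd >= sig_thresh
  cat_ <- suppressWarnings(
    build_rod_catalogue(m, sigma_min = sig_thresh, min_voxels = 1L))
  lab_o <- oracle_components(mask)
  lab_p <- attr(cat_, "labels")
  # identical partitions: voxel pairs share a package label iff they share
  # an oracle label
  expect_equal(sum(lab_p > 0), sum(mask))
  key <- paste(lab_o[mask], lab_p[mask])
  expect_equal(length(unique(key)), length(unique(lab_o[mask])))
  expect_equal(length(unique(key)), length(unique(lab_p[mask])))
})

test_that("chain occupancy applies the at-least-five-carbons rule exactly", {
  fx <- fx_states()
  rod <- fx$catalogue[fx$catalogue$subunit == 1 & fx$catalogue$rod == 1, ]
  on_axis <- cbind(rod$x, rod$y, rod$z + seq(-8, 8, length.out = 14))
  occ <- chain_occupancy(on_axis, rod$rod_id, fx$catalogue, fx$map)
  expect_true(occ$occupied)
  expect_gte(occ$carbon_count, 5L)
  # exactly 5 qualifying carbons -> occupied; exactly 4 -> not
  far <- matrix(rep(c(0, 0, 0), 9), ncol = 3, byrow = TRUE)
  five <- rbind(on_axis[5:9, ], far)
  occ5 <- chain_occupancy(five, rod$rod_id, fx$catalogue, fx$map)
  expect_identical(occ5$carbon_count, 5L)
  expect_true(occ5$occupied)
  four <- rbind(on_axis[5:8, ], far, far[1, , drop = FALSE])
  occ4 <- chain_occupancy(four, rod$rod_id, fx$catalogue, fx$map)
  expect_identical(occ4$carbon_count, 4L)
  expect_false(occ4$occupied)
})

test_that("state labels follow the i-j / degenerate / none contract", {
  fx <- fx_states()
  cat_ <- fx$catalogue
  r1 <- cat_[cat_$subunit == 2 & cat_$rod == 1, ]
  r2 <- cat_[cat_$subunit == 2 & cat_$rod == 2, ]
  line <- function(r) cbind(r$x, r$y, r$z + seq(-8, 8, length.out = 14))
  expect_equal(classify_state(line(r1), line(r2), cat_, fx$map), "1-2")
  # SN1/SN2 ordering is kept
  expect_equal(classify_state(line(r2), line(r1), cat_, fx$map), "2-1")
  expect_equal(classify_state(line(r2), line(r1), cat_, fx$map,
                              ordered = FALSE), "1-2")
  r3 <- cat_[cat_$subunit == 3 & cat_$rod == 3, ]
  expect_equal(classify_state(line(r3), line(r3), cat_, fx$map),
               "degenerate")
  bulk <- matrix(rep(c(0, 0, 0), 14), ncol = 3, byrow = TRUE)
  expect_equal(classify_state(line(r1), bulk, cat_, fx$map), "none")
})

test_that("lipids far from the protein are out of range for all frames", {
  fx <- fx_states()
  # lipids in the outermost sunflower ring sit > 15 A from the protein
  ser <- state_timeseries(fx$traj, fx$catalogue, fx$map,
                          fx$system$topology,
                          protein = function(a) !a$is_hetero)
  far <- dplyr::summarise(dplyr::group_by(ser, .data$lipid),
                          any_in = any(.data$in_range))
  expect_true(any(!far$any_in))
  out_rows <- ser[!ser$in_range, ]
  expect_true(all(out_rows$state == "none"))
})

test_that("scripted kinetic lipids hold their planted states", {
  sys <- fx_states()$system
  maps_cat <- fx_states()
  kin <- kinetic_spec(n_lipids = 4L, mean_dwell_ns = 1e6, site_jitter = 0)
  traj <- generate_trajectory(sys, kinetics = kin, n_frames = 20L,
                              seed = 30L)
  tr <- attr(traj, "truth")
  expect_true(all(apply(tr$kinetic_labels, 1,
                        function(r) length(unique(r)) == 1)))
  ser <- state_timeseries(traj, maps_cat$catalogue, maps_cat$map,
                          sys$topology, protein = function(a) !a$is_hetero,
                          lipids = tr$kinetic_lipids)
  got <- matrix(ser$state, nrow = 4, byrow = TRUE)
  expect_identical(got, unname(tr$kinetic_labels))
})

test_that("the classifier agrees with a per-carbon sigma-lookup oracle", {
  fx <- fx_states()
  traj <- fx$traj
  cat_ <- fx$catalogue
  topo <- fx$system$topology
  lips <- fx$truth$kinetic_lipids
  ser <- state_timeseries(traj, cat_, fx$map, topo,
                          protein = function(a) !a$is_hetero,
                          lipids = lips)
  # oracle: naive per-frame, per-lipid, per-carbon classification straight
  # from the grid arrays
  lat <- attr(cat_, "lattice")
  labels <- attr(cat_, "labels")
  smin <- attr(cat_, "sigma_min")
  atoms <- traj$topology$atoms
  oracle_one <- function(xyz, ci) {
    rods <- integer(0)
    for (i in ci) {
      p <- xyz[i, ]
      iv <- round((p - lat$origin) / lat$voxel_size)
      if (any(iv < 0) || any(iv >= lat$dim)) next
      rid <- labels[iv[1] + 1, iv[2] + 1, iv[3] + 1]
      if (rid == 0) next
      if (sigma_at(fx$map, p) < smin) next
      rods <- c(rods, rid)
    }
    if (!length(rods)) return(0L)
    tt <- sort(table(rods), decreasing = TRUE)
    best <- max(tt)
    if (best < 5) return(0L)
    min(as.integer(names(tt)[tt == best]))
  }
  mism <- 0L
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$frames[[f]]
    for (l in seq_len(nrow(lips))) {
      c1 <- which(atoms$chain_id == lips$chain_id[l] &
                    atoms$residue_id == lips$residue_id[l] &
                    atoms$atom_name %in% topo$sn1_carbons)
      c2 <- which(atoms$chain_id == lips$chain_id[l] &
                    atoms$residue_id == lips$residue_id[l] &
                    atoms$atom_name %in% topo$sn2_carbons)
      r1 <- oracle_one(xyz, c1); r2 <- oracle_one(xyz, c2)
      want <- if (r1 == 0 || r2 == 0) "none"
      else if (r1 == r2) "degenerate"
      else paste0(cat_$rod[match(r1, cat_$rod_id)], "-",
                  cat_$rod[match(r2, cat_$rod_id)])
      got <- ser$state[ser$lipid == l & ser$frame == f]
      if (!identical(got, want)) mism <- mism + 1L
    }
  }
  expect_identical(mism, 0L)
})

test_that("classified series recover the planted kinetic truth", {
  fx <- fx_states()
  ser <- state_timeseries(fx$traj, fx$catalogue, fx$map,
                          fx$system$topology,
                          protein = function(a) !a$is_hetero,
                          lipids = fx$truth$kinetic_lipids)
  got <- matrix(ser$state, nrow = nrow(fx$truth$kinetic_labels),
                byrow = TRUE)
  expect_gte(mean(got == fx$truth$kinetic_labels), 0.97)
})

test_that("dwell analysis reproduces hand-computed runs and transitions", {
  ser <- state_series(c("1-2", "1-2", "1-2", "1-5", "1-5"), dt_ns = 0.1)
  da <- dwell_analysis(ser)
  expect_equal(da$dwells$state, c("1-2", "1-5"))
  expect_equal(da$dwells$duration_ns, c(0.3, 0.2))
  expect_equal(da$lipid_summary$n_transitions, 1L)
  expect_equal(da$lipid_summary$classification, "transitioning")

  const <- dwell_analysis(state_series(rep("3-7", 40)))
  expect_equal(nrow(const$dwells), 1L)
  expect_equal(const$lipid_summary$classification, "stable")
})

test_that("dwell records match a run-length-encoding oracle on random series", {
  set.seed(31)
  labs <- sample(c("1-2", "1-5", "none", "degenerate"), 1000,
                 replace = TRUE)
  da <- dwell_analysis(state_series(labs, dt_ns = 0.1))
  r <- rle(labs)
  expect_equal(da$dwells$state, r$values)
  expect_equal(da$dwells$duration_ns, r$lengths * 0.1)
  expect_equal(da$lipid_summary$n_transitions, length(r$values) - 1L)
})

test_that("dwell durations conserve the in-range duration exactly", {
  fx <- fx_states()
  ser <- state_timeseries(fx$traj, fx$catalogue, fx$map,
                          fx$system$topology,
                          protein = function(a) !a$is_hetero)
  da <- dwell_analysis(ser)
  per_lipid <- dplyr::summarise(dplyr::group_by(da$dwells, .data$lipid),
                                total = sum(.data$duration_ns))
  merged <- dplyr::inner_join(per_lipid, da$lipid_summary, by = "lipid")
  expect_equal(merged$total, merged$in_range_ns)
})

test_that("state census fractions sum to one and report single states", {
  one <- state_census(state_series(rep("1-2", 25)))
  expect_equal(one$state, "1-2")
  expect_equal(one$fraction, 1)
  set.seed(32)
  labs <- matrix(sample(c("1-2", "2-3", "none"), 600, replace = TRUE),
                 nrow = 3)
  cen <- state_census(state_series(labs))
  expect_equal(sum(cen$fraction), 1, tolerance = 1e-12)
})

test_that("classification is deterministic for identical inputs", {
  fx <- fx_states()
  lips <- fx$truth$kinetic_lipids[1:2, ]
  run <- function() {
    state_timeseries(fx$traj, fx$catalogue, fx$map, fx$system$topology,
                     protein = function(a) !a$is_hetero, lipids = lips)
  }
  expect_identical(run(), run())
})

test_that("planted Markov kinetics are recovered from label series", {
  kin <- kinetic_spec(n_lipids = 50L, mean_dwell_ns = 2.0)
  labs <- simulate_state_labels(kin, n_lipids = 50L, n_frames = 2000L,
                                seed = 33L)
  da <- dwell_analysis(state_series(labs, dt_ns = 0.1))
  cen <- state_census(state_series(labs, dt_ns = 0.1))
  expect_equal(mean(da$dwells$duration_ns), 2.0, tolerance = 0.2 * 2.0)
  expect_equal(sum(cen$fraction), 1, tolerance = 1e-12)
  # empirical transition probabilities within 3 standard errors
  trans <- attr(labs, "transition_matrix")
  states <- c("1-3", "1-4", "3-4")
  from <- labs[, -ncol(labs)]
  to <- labs[, -1]
  for (i in 1:3) {
    n_i <- sum(from == states[i])
    for (j in 1:3) {
      p_hat <- sum(from == states[i] & to == states[j]) / n_i
      se <- sqrt(trans[i, j] * (1 - trans[i, j]) / n_i)
      expect_lt(abs(p_hat - trans[i, j]), 3 * se + 1e-12)
    }
  }
})
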