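# minimal one-carbon-per-chain topology for constructed C-H geometries
tiny_topology <- function() {
  lipid_topology("LIP", "C1", "C2",
                 list(C1 = c("H11", "H12"), C2 = c("H21", "H22")), "P")
}

# lipids whose C-H vectors are set directly, one frame per row of `dirs`
tiny_ch_traj <- function(dir_fun, n_lipids = 1, n_frames = 1, seed = 1) {
  set.seed(seed)
  atoms <- purrr::map_dfr(seq_len(n_lipids), function(l) {
    tibble::tibble(
      atom_name = c("C1", "H11", "H12", "C2", "H21", "H22"),
      element = c("C", "H", "H", "C", "H", "H"),
      residue_name = "LIP", residue_id = l, chain_id = "L",
      x = 10 * l, y = 0, z = 0, is_hetero = TRUE)
  })
  s <- jl_structure(atoms)
  frames <- lapply(seq_len(n_frames), function(f) {
    xyz <- coords(s)
    for (l in seq_len(n_lipids)) {
      b <- (l - 1) * 6
      cpos1 <- xyz[b + 1, ]; cpos2 <- xyz[b + 4, ]
      xyz[b + 2, ] <- cpos1 + 1.09 * dir_fun()
      xyz[b + 3, ] <- cpos1 + 1.09 * dir_fun()
      xyz[b + 5, ] <- cpos2 + 1.09 * dir_fun()
      xyz[b + 6, ] <- cpos2 + 1.09 * dir_fun()
    }
    xyz
  })
  jl_trajectory(s, frames)
}

test_that("S_CD hits its analytic limits for locked C-H orientations", {
  perp <- tiny_ch_traj(function() c(1, 0, 0))
  pr <- scd_per_carbon(perp, tiny_topology())
  expect_equal(pr$scd, rep(0.5, 2))

  par <- tiny_ch_traj(function() c(0, 0, 1))
  pr2 <- scd_per_carbon(par, tiny_topology())
  expect_equal(pr2$scd, rep(-1, 2))
})

test_that("isotropic C-H orientations give S_CD = 0 within Monte-Carlo error", {
  unit_sphere <- function() {
    v <- rnorm(3)
    v / sqrt(sum(v^2))
  }
  # 60 lipids x 4 C-H x 450 frames > 1e5 samples
  traj <- tiny_ch_traj(unit_sphere, n_lipids = 60, n_frames = 450,
                       seed = 123)
  pr <- scd_per_carbon(traj, tiny_topology())
  pooled <- sum(pr$scd * pr$n_samples) / sum(pr$n_samples)
  expect_gt(sum(pr$n_samples), 1e5)
  expect_equal(pooled, 0, tolerance = 0.005)
})

test_that("missing hydrogens abort naming the carbon", {
  topo <- lipid_topology("LIP", "C1", "C2",
                         list(C1 = "H11", C2 = "HMISSING"), "P")
  traj <- tiny_ch_traj(function() c(1, 0, 0))
  expect_error(scd_per_carbon(traj, topo, chain = "SN2"), "C2")
})

test_that("leaflet assignment recovers the planted four planes", {
  sys <- fx_system()
  lf <- assign_leaflets(sys$structure, sys$topology)
  truth <- sys$truth$leaflets
  merged <- dplyr::inner_join(lf, truth, by = c("chain_id", "residue_id"))
  expect_equal(nrow(merged), nrow(truth))
  expect_true(all(merged$leaflet.x == merged$leaflet.y))
  expect_true(all(merged$membrane.x == merged$membrane.y))
  # planted planes at +/-22 (EC) and +/-57 (IC)
  ec_z <- abs(merged$z_phosphorus[merged$leaflet.x == "EC"])
  ic_z <- abs(merged$z_phosphorus[merged$leaflet.x == "IC"])
  expect_true(all(abs(ec_z - 22) < 2.5))
  expect_true(all(abs(ic_z - 57) < 2.5))
})

test_that("leaflet assignment survives z jitter and rejects single bilayers", {
  sys <- fx_system()
  set.seed(10)
  s <- sys$structure
  pidx <- select_atoms(s, residue_name == "DMP" & atom_name == "P")
  xyz <- coords(s)
  xyz[pidx, 3] <- xyz[pidx, 3] + rnorm(length(pidx), 0, 1.1)  # ~5% of plane
  expect_true(all(
    assign_leaflets(set_coords(s, xyz), sys$topology)$leaflet ==
      sys$truth$leaflets$leaflet))
  # collapse to a single bilayer: keep only membrane 2 chains
  single <- jl_structure(s$atoms[s$atoms$chain_id %in% c("O", "Q"), ])
  expect_error(assign_leaflets(single, sys$topology), "dual bilayer")
})

test_that("shell binning matches manual distance bins for planted lipids", {
  fx <- fx_order_traj()
  sh <- shell_average_scd(fx$traj, function(a) !a$is_hetero,
                          fx$system$topology)
  # manual oracle for the same trajectory: per-lipid min heavy-atom
  # distance, first frame only -> bins must agree with reported shells
  atoms <- fx$traj$topology$atoms
  prot <- which(!atoms$is_hetero & atoms$element != "H")
  xyz <- fx$traj$frames[[1]]
  lips <- lipid_residues(fx$traj$topology, fx$system$topology)
  dmin <- vapply(seq_len(nrow(lips)), function(i) {
    li <- which(atoms$residue_name == "DMP" & atoms$element != "H" &
                  atoms$chain_id == lips$chain_id[i] &
                  atoms$residue_id == lips$residue_id[i])
    min(sqrt(outer(rowSums(xyz[li, , drop = FALSE]^2),
                   rowSums(xyz[prot, ]^2), `+`) -
               2 * xyz[li, , drop = FALSE] %*% t(xyz[prot, ])))
  }, double(1))
  occupied <- sort(unique(floor(dmin / 5) + 1))
  reported <- sort(unique(sh$shell[sh$n > 0]))
  expect_true(all(occupied %in% reported))
  # contiguity and width bookkeeping
  expect_equal(sh$r_outer - sh$r_inner, rep(5, nrow(sh)))
  expect_equal(sort(unique(sh$shell)), seq_len(max(sh$shell)))
})

test_that("a single all-encompassing shell reproduces the global mean", {
  fx <- fx_order_traj()
  lt <- fx$system$truth$leaflets
  ec <- lt[lt$leaflet == "EC", c("chain_id", "residue_id")]
  sh <- shell_average_scd(fx$traj, function(a) !a$is_hetero,
                          fx$system$topology, shell_width = 1000,
                          lipids = ec)
  pr <- scd_per_carbon(fx$traj, fx$system$topology, lipids = ec)
  for (ch in c("SN1", "SN2")) {
    expect_equal(sh$scd[sh$shell == 1 & sh$chain == ch],
                 pr$scd[pr$chain == ch], tolerance = 1e-12)
  }
})

test_that("per-lipid S_CD equals the mean of its per-carbon profile over 4-11", {
  fx <- fx_order_traj()
  lt <- fx$system$truth$leaflets
  one <- lt[lt$leaflet == "EC", c("chain_id", "residue_id")][1, ]
  pl <- per_lipid_scd(fx$traj, fx$system$topology, lipids = one)
  pr <- scd_per_carbon(fx$traj, fx$system$topology, lipids = one)
  expect_equal(pl$scd, mean(pr$scd[pr$carbon %in% 4:11]), tolerance = 1e-12)
})

test_that("disordered-IC lipids score below ordered-EC lipids for every seed", {
  for (seed in 1:5) {
    sys <- generate_system(junction_spec(n_lipids_ec = 6L, n_lipids_ic = 6L,
                                         n_waters = 0L, seed = seed))
    traj <- generate_trajectory(sys, n_frames = 8L, seed = seed)
    lt <- sys$truth$leaflets
    ec <- per_lipid_scd(traj, sys$topology,
                        lipids = lt[lt$leaflet == "EC",
                                    c("chain_id", "residue_id")])
    ic <- per_lipid_scd(traj, sys$topology,
                        lipids = lt[lt$leaflet == "IC",
                                    c("chain_id", "residue_id")])
    expect_lt(mean(ic$scd), mean(ec$scd))
  }
})

test_that("time averages are invariant to frame order", {
  fx <- fx_order_traj()
  lt <- fx$system$truth$leaflets
  ec <- lt[lt$leaflet == "EC", c("chain_id", "residue_id")]
  shuffled <- fx$traj
  set.seed(4)
  shuffled$frames <- shuffled$frames[sample(n_frames(fx$traj))]
  expect_equal(per_lipid_scd(shuffled, fx$system$topology, lipids = ec)$scd,
               per_lipid_scd(fx$traj, fx$system$topology, lipids = ec)$scd)
})

test_that("area per lipid follows its defining arithmetic", {
  # 100 x 100 box, no protein, 50 lipids in the leaflet -> 200 A^2
  mk <- function(n) {
    planes <- c(-30, -10, 10, 30)
    atoms <- purrr::map_dfr(seq_along(planes), function(li) {
      k <- if (planes[li] == 10) n else 10L
      tibble::tibble(atom_name = "P", element = "P", residue_name = "DMP",
                     residue_id = seq_len(k),
                     chain_id = c("M", "N", "O", "Q")[li],
                     x = runif(k, -45, 45), y = runif(k, -45, 45),
                     z = planes[li] + rnorm(k, 0, 0.1), is_hetero = TRUE)
    })
    jl_structure(atoms, box = c(100, 100, 80))
  }
  set.seed(11)
  topo <- dmpc_topology("DMP")
  s50 <- mk(50L)
  expect_equal(area_per_lipid(s50, topo, leaflet = "EC", membrane = 2), 200)
  s100 <- mk(100L)
  expect_equal(area_per_lipid(s100, topo, leaflet = "EC", membrane = 2), 100)
})

test_that("the protein footprint matches a geometric oracle within 5%", {
  # disk of atoms of radius 15.8, dilated by 2 -> ~ pi * 17.8^2 ~ 995 A^2
  set.seed(12)
  grid_pts <- expand.grid(x = seq(-15.5, 15.5, by = 1),
                          y = seq(-15.5, 15.5, by = 1))
  grid_pts <- grid_pts[grid_pts$x^2 + grid_pts$y^2 <= 15.8^2, ]
  prot <- tibble::tibble(atom_name = "CA", element = "C",
                         residue_name = "GLY",
                         residue_id = seq_len(nrow(grid_pts)),
                         chain_id = "A", x = grid_pts$x, y = grid_pts$y,
                         z = 15, is_hetero = FALSE)  # inside the EC slab
  planes <- c(-30, -10, 10, 30)
  lip <- purrr::map_dfr(seq_along(planes), function(li) {
    tibble::tibble(atom_name = "P", element = "P", residue_name = "DMP",
                   residue_id = 1:20, chain_id = c("M", "N", "O", "Q")[li],
                   x = runif(20, -45, 45), y = runif(20, -45, 45),
                   z = planes[li], is_hetero = TRUE)
  })
  s <- jl_structure(dplyr::bind_rows(prot, lip), box = c(100, 100, 80))
  got <- area_per_lipid(s, dmpc_topology("DMP"), leaflet = "EC",
                        membrane = 2, protein = function(a) !a$is_hetero)
  oracle_area <- pi * 17.8^2
  expect_equal(got, (100 * 100 - oracle_area) / 20,
               tolerance = 0.05 * oracle_area / (100 * 100 - oracle_area))
  expect_error(area_per_lipid(s, dmpc_topology("XXX")), "phosphorus")
})
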