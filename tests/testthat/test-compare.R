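aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

make_model <- function(n_res = 24, seed = 1, chains = c("A", "B")) {
  set.seed(seed)
  seq3 <- sample(aa3, n_res, replace = TRUE)
  purrr::map_dfr(chains, function(ch) {
    tibble::tibble(
      atom_name = rep(c("N", "CA", "C", "O"), n_res),
      element = rep(c("N", "C", "C", "O"), n_res),
      residue_name = rep(seq3, each = 4),
      residue_id = rep(seq_len(n_res), each = 4),
      chain_id = ch,
      x = rnorm(4 * n_res, 0, 8), y = rnorm(4 * n_res, 0, 8),
      z = rnorm(4 * n_res, 0, 8),
      is_hetero = FALSE)
  }) |> jl_structure()
}

test_that("identical models pair every subset atom; trimmed residues drop out", {
  a <- make_model()
  p <- pair_atoms(a, a)
  expect_equal(nrow(p), 2 * 24 * 4)
  expect_identical(p$idx_a, p$idx_b)
  pca <- pair_atoms(a, a, subset = "CA")
  expect_equal(nrow(pca), 2 * 24)
  # B missing 10 residues -> exactly those drop out of the pairing
  b <- jl_structure(a$atoms[!(a$atoms$residue_id %in% 8:17 &
                                a$atoms$chain_id == "A"), ])
  pb <- pair_atoms(a, b)
  expect_equal(nrow(pb), 2 * 24 * 4 - 10 * 4)
  expect_false(any(pb$residue_id_a %in% 8:17 & pb$chain_a == "A"))
})

test_that("pairing is invariant to chain storage order", {
  a <- make_model()
  scrambled <- jl_structure(a$atoms[order(a$atoms$chain_id,
                                          decreasing = TRUE), ])
  p1 <- pair_atoms(a, a)
  p2 <- pair_atoms(a, scrambled)
  # same atom pairs, expressed against the scrambled row order
  key1 <- paste(p1$chain_a, p1$residue_id_a, p1$atom_name)
  key2 <- paste(p2$chain_a, p2$residue_id_a, p2$atom_name)
  expect_setequal(key1, key2)
  sc_atoms <- scrambled$atoms
  expect_identical(
    paste(sc_atoms$chain_id[p2$idx_b], sc_atoms$residue_id[p2$idx_b],
          sc_atoms$atom_name[p2$idx_b]),
    paste(p2$chain_a, p2$residue_id_a, p2$atom_name))
})

test_that("models without shared chain ids pair by sequence alignment", {
  a <- make_model(n_res = 20, chains = "A")
  b_atoms <- a$atoms
  b_atoms$chain_id <- "Z"
  # drop a run of residues so the alignment must gap
  b <- jl_structure(b_atoms[!(b_atoms$residue_id %in% 9:11), ])
  expect_message(p <- pair_atoms(a, b), "sequence alignment")
  expect_equal(nrow(p), (20 - 3) * 4)
  expect_false(any(p$residue_id_a %in% 9:11))
  aligned_rmsd <- superpose_rmsd(a, b, pairing = p)$rmsd
  expect_equal(aligned_rmsd, 0, tolerance = 1e-9)
})

test_that("superposition recovers rigid motions and matches a grid oracle", {
  a <- make_model(n_res = 10, chains = "A")
  expect_equal(superpose_rmsd(a, a)$rmsd, 0, tolerance = 1e-10)
  shifted <- set_coords(a, coords(a) + matrix(c(5, 5, 5), nrow(a$atoms), 3,
                                              byrow = TRUE))
  expect_equal(superpose_rmsd(a, shifted)$rmsd, 0, tolerance = 1e-10)

  # 5-atom toy vs a rotation-grid + refinement oracle
  set.seed(3)
  pa <- matrix(rnorm(15, 0, 4), 5, 3)
  pb <- pa %*% t(rot_mat <- {
    th <- 0.6
    matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  }) + matrix(rnorm(15, 0, 0.3), 5, 3)
  A <- jl_structure(tibble::tibble(
    atom_name = "CA", element = "C", residue_name = "GLY",
    residue_id = 1:5, chain_id = "A", x = pa[, 1], y = pa[, 2],
    z = pa[, 3], is_hetero = FALSE))
  B <- set_coords(A, pb)
  got <- superpose_rmsd(A, B, subset = "CA")$rmsd
  rmsd_euler <- function(ang) {
    Rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), sin(t),
                               0, -sin(t), cos(t)), 3, 3)
    Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                               0, 0, 1), 3, 3)
    R <- Rz(ang[1]) %*% Rx(ang[2]) %*% Rz(ang[3])
    qa <- sweep(pa, 2, colMeans(pa))
    qb <- sweep(pb, 2, colMeans(pb)) %*% t(R)
    sqrt(mean(rowSums((qa - qb)^2)))
  }
  grid <- as.matrix(expand.grid(a1 = seq(0, 2 * pi, length.out = 13),
                                a2 = seq(0, pi, length.out = 7),
                                a3 = seq(0, 2 * pi, length.out = 13)))
  vals <- apply(grid, 1, rmsd_euler)
  best <- stats::optim(grid[which.min(vals), ], rmsd_euler,
                       method = "Nelder-Mead",
                       control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(got, best$value, tolerance = 1e-6)
  expect_lte(got, best$value + 1e-9)   # the SVD optimum is never beaten
})

test_that("rmsd is symmetric and superposition never increases rmsd", {
  a <- make_model(seed = 5)
  b <- set_coords(a, coords(a) + matrix(rnorm(length(coords(a)), 0, 0.5),
                                        nrow(a$atoms), 3))
  s_ab <- superpose_rmsd(a, b)
  s_ba <- superpose_rmsd(b, a)
  expect_equal(s_ab$rmsd, s_ba$rmsd, tolerance = 1e-9)
  raw <- sqrt(mean(rowSums((coords(a) - coords(b))^2)))
  expect_lte(s_ab$rmsd, raw + 1e-12)
  expect_equal(det(s_ab$rotation), 1, tolerance = 1e-9)
})

test_that("degenerate superposition inputs are refused", {
  line <- jl_structure(tibble::tibble(
    atom_name = "CA", element = "C", residue_name = "GLY",
    residue_id = 1:5, chain_id = "A", x = 1:5, y = 2 * (1:5),
    z = 3 * (1:5), is_hetero = FALSE))
  expect_error(superpose_rmsd(line, line, subset = "CA"), "collinear")
})

test_that("static trajectories give zero rmsf with zero-width intervals", {
  s <- jl_structure(dplyr::bind_rows(lapply(c("A", "B", "C"), function(ch) {
    random_structure(6, seed = 7, chain = ch)$atoms
  })))
  traj <- jl_trajectory(s, replicate(4, coords(s), simplify = FALSE))
  pr <- rmsf_profile(traj)
  expect_true(all(pr$mean_rmsf == 0))
  expect_true(all(pr$ci_high - pr$ci_low == 0))
})

test_that("equal replicates give a zero-width interval around their value", {
  ci <- t_confidence_interval(rep(1.37, 24))
  expect_equal(ci$mean, 1.37)
  expect_equal(ci$ci_low, ci$ci_high)
  expect_equal(ci$ci_low, 1.37)
})

test_that("the t quantile matches an independent quadrature/bisection oracle", {
  # oracle: integrate the t density (nu = 23) and bisect for the 0.975 point
  t_cdf <- function(x, nu) {
    stats::integrate(function(u) {
      gamma((nu + 1) / 2) / (sqrt(nu * pi) * gamma(nu / 2)) *
        (1 + u^2 / nu)^(-(nu + 1) / 2)
    }, -Inf, x, rel.tol = 1e-12)$value
  }
  lo <- 0; hi <- 10
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (t_cdf(mid, 23) < 0.975) lo <- mid else hi <- mid
  }
  t_oracle <- (lo + hi) / 2
  set.seed(8)
  vals <- rnorm(24, 1, 0.3)
  ci <- t_confidence_interval(vals)
  half_oracle <- t_oracle * sd(vals) / sqrt(24)
  expect_equal(ci$ci_high - ci$mean, half_oracle, tolerance = 1e-6)
  expect_equal(ci$mean - ci$ci_low, half_oracle, tolerance = 1e-6)
})

test_that("confidence intervals achieve nominal coverage", {
  set.seed(9)
  hits <- 0L
  for (i in 1:1000) {
    ci <- t_confidence_interval(rnorm(24, mean = 2, sd = 1))
    if (ci$ci_low <= 2 && 2 <= ci$ci_high) hits <- hits + 1L
  }
  expect_gte(hits, 930L)
  expect_lte(hits, 970L)
})

test_that("symmetry expansion is exact arithmetic with invertible copies", {
  set.seed(10)
  w <- jl_structure(tibble::tibble(
    atom_name = "O", element = "O", residue_name = "HOH",
    residue_id = 1:33, chain_id = "W",
    x = runif(33, 5, 25), y = runif(33, 5, 25), z = runif(33, -12, 12),
    is_hetero = TRUE))
  g6 <- d6_group()
  ex <- symmetry_expand(w, g6)
  expect_equal(nrow(ex$atoms), 396L)      # 33 waters x 12 operations
  one <- jl_structure(w$atoms[1, ])
  expect_equal(nrow(symmetry_expand(one, g6)$atoms), 12L)
  # inverse of each operation maps its copy back onto the unit
  xyz <- coords(w)
  exyz <- coords(ex)
  for (i in 1:12) {
    block <- exyz[(i - 1) * 33 + 1:33, ]
    back <- block %*% g6$ops[[i]]   # transpose of op = inverse
    expect_lt(max(abs(back - xyz)), 1e-9)
  }
})

test_that("rmsf replicates across subunits and runs form t intervals", {
  sys <- generate_system(junction_spec(n_lipids_ec = 2L, n_lipids_ic = 2L,
                                       n_waters = 0L, seed = 12L))
  mk_run <- function(seed) {
    traj <- generate_trajectory(sys, n_frames = 4L, seed = seed)
    set.seed(seed + 100)
    for (f in seq_along(traj$frames)) {
      idx <- which(!traj$topology$atoms$is_hetero)
      traj$frames[[f]][idx, ] <- traj$frames[[f]][idx, ] +
        matrix(rnorm(length(idx) * 3, 0, 0.4), ncol = 3)
    }
    traj
  }
  pr <- rmsf_profile(list(mk_run(1), mk_run(2)))
  expect_equal(pr$n[1], 24)               # 12 subunits x 2 runs
  expect_true(all(pr$ci_low <= pr$mean_rmsf & pr$mean_rmsf <= pr$ci_high))
  expect_true(all(pr$mean_rmsf > 0))
})
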