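# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small junction with waters, for io / leaflet / water tests
fx_system <- function() {
  cached("system", function() {
    generate_system(junction_spec(n_lipids_ec = 10L, n_lipids_ic = 10L,
                                  n_waters = 6L, seed = 3L))
  })
}

# rod map + catalogue + kinetic trajectory, for state tests
fx_states <- function() {
  cached("states", function() {
    sys <- generate_system(junction_spec(n_lipids_ec = 20L,
                                         n_lipids_ic = 5L,
                                         n_waters = 0L, seed = 11L))
    maps <- generate_maps(sys, seed = 11L)
    cat_ <- build_rod_catalogue(maps$rod_map, sigma_min = 8,
                                z_range = c(20, 42))
    traj <- generate_trajectory(
      sys, kinetics = kinetic_spec(n_lipids = 8L, mean_dwell_ns = 2.0),
      n_frames = 30L, seed = 11L)
    list(system = sys, map = maps$rod_map, catalogue = cat_, traj = traj,
         truth = attr(traj, "truth"))
  })
}

# water scene with decoys and partial MD co-planting
fx_waters <- function() {
  cached("waters", function() {
    sys <- generate_system(junction_spec(n_lipids_ec = 4L, n_lipids_ic = 4L,
                                         n_waters = 100L, seed = 5L))
    maps <- generate_maps(sys, md_fraction = 0.76, n_decoys = 100L,
                          seed = 5L)
    list(system = sys, maps = maps)
  })
}

# the ordered-EC reference fixture (shared with the acceptance suite)
fx_ordered_ec <- function() {
  cached("ordered_ec", function() ordered_ec_fixture(seed = 7L))
}

# short disordered trajectory for order-parameter tests
fx_order_traj <- function() {
  cached("order_traj", function() {
    sys <- generate_system(junction_spec(n_lipids_ec = 12L,
                                         n_lipids_ic = 12L,
                                         n_waters = 0L, seed = 2L))
    traj <- generate_trajectory(sys, n_frames = 12L, seed = 2L)
    list(system = sys, traj = traj)
  })
}

# tiny random structure helper
random_structure <- function(n, seed = 1, chain = "A", atom_name = "CA",
                             spread = 8) {
  set.seed(seed)
  jl_structure(tibble::tibble(
    atom_name = atom_name, element = "C", residue_name = "GLY",
    residue_id = seq_len(n), chain_id = chain,
    x = rnorm(n, 0, spread), y = rnorm(n, 0, spread),
    z = rnorm(n, 0, spread), is_hetero = FALSE))
}

single_atom_traj <- function(pos = c(0, 0, 0), element = "C",
                             n_frames = 1) {
  s <- jl_structure(tibble::tibble(
    atom_name = element, element = element, residue_name = "X",
    residue_id = 1L, chain_id = "A", x = pos[1], y = pos[2], z = pos[3],
    is_hetero = FALSE))
  jl_trajectory(s, replicate(n_frames, coords(s), simplify = FALSE))
}
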