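#' Chain occupancy of a rod density
#'
#' A carbon counts toward occupancy when (a) its nearest voxel belongs to
#' the rod's voxel set and (b) the interpolated map value at its position
#' is at or above `sigma_min`; both conditions are required because the
#' interpolated sigma can dip below threshold near component edges.  A rod
#' is occupied when at least `min_carbons` carbons qualify.
#'
#' @param positions Chain-carbon positions, n x 3 matrix.
#' @param rod_id Rod id to test (row of the catalogue).
#' @param catalogue A [build_rod_catalogue()] result.
#' @param map The source [density_map].
#' @param min_carbons Occupancy threshold (default 5 carbons).
#' @return List: `occupied` flag and the qualifying `carbon_count`.
#' @export
chain_occupancy <- function(positions, rod_id, catalogue, map,
                            min_carbons = 5L) {
  lab <- rod_label_at(catalogue, positions)
  sig <- sigma_at(map, positions)
  count <- sum(lab == rod_id & sig >= attr(catalogue, "sigma_min"))
  list(occupied = count >= min_carbons, carbon_count = count)
}

# per-chain rod assignment: counts per rod of qualifying carbons,
# best rod = max count (>= min), ties -> lowest rod_id.  Returns 0 if none.
assign_chain_rod <- function(lab, sig, sigma_min, n_rods, min_carbons) {
  ok <- lab > 0 & sig >= sigma_min
  if (!any(ok)) return(0L)
  counts <- tabulate(lab[ok], n_rods)
  best <- max(counts)
  if (best < min_carbons) return(0L)
  which(counts == best)[1]
}

state_string <- function(rod1, rod2, catalogue, ordered = TRUE) {
  if (rod1 == 0L || rod2 == 0L) return("none")
  if (rod1 == rod2) return("degenerate")
  i <- catalogue$rod[match(rod1, catalogue$rod_id)]
  j <- catalogue$rod[match(rod2, catalogue$rod_id)]
  if (!ordered && i > j) { tmp <- i; i <- j; j <- tmp }
  paste0(i, "-", j)
}

#' Classify the configurational state of one lipid in one frame
#'
#' Each acyl chain is assigned to the rod it occupies (>= `min_carbons`
#' qualifying carbons; if a chain qualifies in several rods the one with
#' the most carbons wins, ties to the lowest rod id).  With SN1 in rod i
#' and SN2 in rod j the state is `"i-j"` (i != j, within-subunit rod
#' numbers, SN1 first); both chains in the same rod is `"degenerate"`;
#' any unassigned chain gives `"none"`.
#'
#' @param sn1_positions,sn2_positions Chain carbon coordinates (n x 3).
#' @param catalogue A [build_rod_catalogue()] result.
#' @param map The source [density_map].
#' @param min_carbons Occupancy threshold (default 5).
#' @param ordered Keep SN1-first ordering in the label (default TRUE); if
#'   FALSE the smaller rod number is printed first.
#' @return The state label string.
#' @export
classify_state <- function(sn1_positions, sn2_positions, catalogue, map,
                           min_carbons = 5L, ordered = TRUE) {
  sigma_min <- attr(catalogue, "sigma_min")
  n_rods <- nrow(catalogue)
  if (n_rods == 0) return("none")
  r1 <- assign_chain_rod(rod_label_at(catalogue, sn1_positions),
                         sigma_at(map, sn1_positions),
                         sigma_min, n_rods, min_carbons)
  r2 <- assign_chain_rod(rod_label_at(catalogue, sn2_positions),
                         sigma_at(map, sn2_positions),
                         sigma_min, n_rods, min_carbons)
  state_string(r1, r2, catalogue, ordered)
}

#' Per-lipid configurational state time series
#'
#' Applies the state classifier to every lipid within `cutoff` Angstrom of
#' the protein (minimum heavy-atom distance, evaluated per frame by
#' default), over each frame.  Out-of-range frames carry the label
#' `"none"` with `in_range = FALSE`.
#'
#' @param traj A [jl_trajectory].
#' @param catalogue A [build_rod_catalogue()] result.
#' @param map The source [density_map].
#' @param lipid_topo A [lipid_topology].
#' @param protein Protein atom selection.
#' @param cutoff Protein proximity cutoff in Angstrom (default 15).
#' @param lipids Optional lipid subset (tibble `chain_id`, `residue_id`).
#' @param min_carbons Occupancy threshold (default 5).
#' @param ordered SN1-first state labels (default TRUE).
#' @param per_frame_membership Re-evaluate the 15 A criterion each frame
#'   (default); if FALSE a lipid is in range for the whole series when it
#'   is in range in any frame.
#' @return A `state_series` tibble: `lipid`, `chain_id`, `residue_id`,
#'   `frame`, `time_ns`, `state`, `in_range`, with `dt_ns` in an
#'   attribute.
#' @export
state_timeseries <- function(traj, catalogue, map, lipid_topo, protein,
                             cutoff = 15, lipids = NULL, min_carbons = 5L,
                             ordered = TRUE, per_frame_membership = TRUE) {
  atoms <- traj$topology$atoms
  pidx <- resolve_selection(traj$topology, protein)
  pidx <- pidx[atoms$element[pidx] != "H"]
  if (length(pidx) == 0) abort("empty protein selection")
  lipids <- lipids %||% lipid_residues(traj$topology, lipid_topo)
  n_lip <- nrow(lipids)
  if (n_lip == 0) abort("no lipids found")
  lipkey <- paste(lipids$chain_id, lipids$residue_id, sep = "\r")
  heavy <- which(atoms$residue_name == lipid_topo$residue_name &
                   atoms$element != "H")
  hv_grp <- match(paste(atoms$chain_id[heavy], atoms$residue_id[heavy],
                        sep = "\r"), lipkey)
  heavy <- heavy[!is.na(hv_grp)]
  hv_grp <- hv_grp[!is.na(hv_grp)]
  cidx1 <- chain_carbon_index(traj$topology, lipids, lipid_topo, "SN1")
  cidx2 <- chain_carbon_index(traj$topology, lipids, lipid_topo, "SN2")
  sigma_min <- attr(catalogue, "sigma_min")
  n_rods <- nrow(catalogue)
  nf <- n_frames(traj)
  states <- matrix("none", n_lip, nf)
  inr <- matrix(FALSE, n_lip, nf)
  for (f in seq_len(nf)) {
    xyz <- traj$frames[[f]]
    dmin <- min_dist_by_group(xyz[heavy, , drop = FALSE], hv_grp,
                              xyz[pidx, , drop = FALSE])
    inr[, f] <- dmin <= cutoff
    if (!any(inr[, f]) || n_rods == 0) next
    p1 <- xyz[t(cidx1), , drop = FALSE]  # lipid-major blocks
    p2 <- xyz[t(cidx2), , drop = FALSE]
    lab1 <- rod_label_at(catalogue, p1); sg1 <- sigma_at(map, p1)
    lab2 <- rod_label_at(catalogue, p2); sg2 <- sigma_at(map, p2)
    nc1 <- ncol(cidx1); nc2 <- ncol(cidx2)
    for (l in which(inr[, f])) {
      s1 <- (l - 1L) * nc1
      s2 <- (l - 1L) * nc2
      r1 <- assign_chain_rod(lab1[s1 + seq_len(nc1)], sg1[s1 + seq_len(nc1)],
                             sigma_min, n_rods, min_carbons)
      r2 <- assign_chain_rod(lab2[s2 + seq_len(nc2)], sg2[s2 + seq_len(nc2)],
                             sigma_min, n_rods, min_carbons)
      states[l, f] <- state_string(r1, r2, catalogue, ordered)
    }
  }
  if (!per_frame_membership) {
    always <- rowSums(inr) > 0
    inr[always, ] <- TRUE
  }
  out <- tibble(
    lipid = rep(seq_len(n_lip), each = nf),
    chain_id = rep(lipids$chain_id, each = nf),
    residue_id = rep(lipids$residue_id, each = nf),
    frame = rep(seq_len(nf), times = n_lip),
    time_ns = rep((seq_len(nf) - 1) * traj$dt_ns, times = n_lip),
    state = as.vector(t(states)),
    in_range = as.vector(t(inr))
  )
  out$state[!out$in_range] <- "none"
  structure(out, class = c("state_series", class(out)), dt_ns = traj$dt_ns)
}

#' Construct a state series from plain label vectors
#'
#' Convenience constructor (used when states come from an external source
#' or a planted truth record rather than [state_timeseries()]).
#'
#' @param labels Character matrix (lipids x frames) or vector (one lipid).
#' @param dt_ns Time per frame in ns.
#' @param in_range Logical matrix/vector matching `labels`; default all
#'   TRUE.
#' @return A `state_series` tibble.
#' @export
state_series <- function(labels, dt_ns = 0.1, in_range = NULL) {
  if (is.vector(labels)) labels <- matrix(labels, nrow = 1)
  if (is.null(in_range)) in_range <- matrix(TRUE, nrow(labels), ncol(labels))
  if (is.vector(in_range)) in_range <- matrix(in_range, nrow = 1)
  nf <- ncol(labels); n_lip <- nrow(labels)
  out <- tibble(
    lipid = rep(seq_len(n_lip), each = nf),
    chain_id = rep("X", n_lip * nf),
    residue_id = rep(seq_len(n_lip), each = nf),
    frame = rep(seq_len(nf), times = n_lip),
    time_ns = rep((seq_len(nf) - 1) * dt_ns, times = n_lip),
    state = as.vector(t(labels)),
    in_range = as.vector(t(in_range))
  )
  out$state[!out$in_range] <- "none"
  structure(out, class = c("state_series", class(out)), dt_ns = dt_ns)
}

is_pair_state <- function(s) grepl("^[0-9]+-[0-9]+$", s)

#' Dwell times, transitions, and stability classification
#'
#' Maximal runs of identical labels over each lipid's in-range frames
#' become dwell records (duration = run length x dt).  A transition is a
#' pair of consecutive in-range frames with different labels.  A lipid is
#' `"stable"` when its sequence of visited pair-states (ignoring
#' interleaved `"none"`/`"degenerate"` frames) never changes, and
#' `"transitioning"` otherwise; lipids that never occupy a pair-state are
#' `"unclassified"`.
#'
#' @param series A `state_series` tibble ([state_timeseries()] or
#'   [state_series()]).
#' @return An object of class `dwell_analysis`: list with `dwells` (tibble
#'   `lipid`, `state`, `start_frame`, `duration_ns`) and `lipid_summary`
#'   (tibble `lipid`, `n_transitions`, `in_range_ns`, `classification`).
#' @export
dwell_analysis <- function(series) {
  stopifnot(is.data.frame(series))
  dt <- attr(series, "dt_ns") %||% 0.1
  split_lip <- split(series[series$in_range, c("lipid", "frame", "state")],
                     series$lipid[series$in_range])
  dwells <- purrr::map_dfr(split_lip, function(df) {
    df <- df[order(df$frame), ]
    r <- rle(df$state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    tibble(lipid = df$lipid[1], state = r$values,
           start_frame = df$frame[starts],
           duration_ns = r$lengths * dt)
  })
  lipid_summary <- purrr::map_dfr(split_lip, function(df) {
    df <- df[order(df$frame), ]
    n_tr <- sum(df$state[-1] != df$state[-nrow(df)])
    pairs <- rle(df$state[is_pair_state(df$state)])$values
    cls <- if (length(pairs) == 0) "unclassified"
           else if (length(unique(pairs)) == 1) "stable"
           else "transitioning"
    tibble(lipid = df$lipid[1], n_transitions = n_tr,
           in_range_ns = nrow(df) * dt, classification = cls)
  })
  structure(list(dwells = dwells, lipid_summary = lipid_summary, dt_ns = dt),
            class = "dwell_analysis")
}

#' @export
print.dwell_analysis <- function(x, ...) {
  cat(sprintf("<dwell_analysis> %d dwell records over %d lipids (%d stable, %d transitioning)\n",
              nrow(x$dwells), nrow(x$lipid_summary),
              sum(x$lipid_summary$classification == "stable"),
              sum(x$lipid_summary$classification == "transitioning")))
  invisible(x)
}

#' @export
tidy.dwell_analysis <- function(x, ...) x$dwells

#' @export
glance.dwell_analysis <- function(x, ...) {
  tibble(n_lipids = nrow(x$lipid_summary),
         n_dwells = nrow(x$dwells),
         n_stable = sum(x$lipid_summary$classification == "stable"),
         n_transitioning = sum(x$lipid_summary$classification == "transitioning"),
         mean_dwell_ns = mean(x$dwells$duration_ns))
}

#' Census of configurational states across lipids
#'
#' Aggregates a state series over all lipids: per state, the fraction of
#' in-range lipid-frames (fractions sum to 1, `"none"` and `"degenerate"`
#' included), the mean dwell duration, and the number of distinct lipids
#' observed in the state.
#'
#' @param series A `state_series` tibble.
#' @return Tibble: `state`, `fraction`, `mean_dwell_ns`, `n_lipids`.
#' @export
state_census <- function(series) {
  inr <- series[series$in_range, ]
  if (nrow(inr) == 0) {
    return(tibble(state = character(), fraction = double(),
                  mean_dwell_ns = double(), n_lipids = integer()))
  }
  da <- dwell_analysis(series)
  frac <- dplyr::count(inr, .data$state)
  frac$fraction <- frac$n / sum(frac$n)
  dw <- dplyr::summarise(dplyr::group_by(da$dwells, .data$state),
                         mean_dwell_ns = mean(.data$duration_ns),
                         n_lipids = dplyr::n_distinct(.data$lipid))
  out <- dplyr::left_join(frac[, c("state", "fraction")], dw, by = "state")
  dplyr::arrange(out, dplyr::desc(.data$fraction))
}
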