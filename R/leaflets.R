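#' Assign lipids to membranes and leaflets in a dual-bilayer junction
#'
#' Head-group phosphorus z coordinates are clustered into four groups
#' (1D k-means); the two lower groups form membrane 1, the two upper form
#' membrane 2.  Within each membrane the leaflet nearer the junction
#' midplane is labeled `EC` (extracellular, facing the inter-membrane gap)
#' and the outward-facing leaflet `IC`.
#'
#' @param x A [jl_structure] (a single frame).
#' @param lipid_topo A [lipid_topology].
#' @param min_gap Minimum separation (Angstrom) required between adjacent
#'   leaflet planes; below this the input is rejected as not a dual
#'   bilayer.
#' @return Tibble with one row per lipid: `chain_id`, `residue_id`,
#'   `membrane` (1 or 2), `leaflet` (`"EC"` or `"IC"`), `z_phosphorus`.
#' @export
assign_leaflets <- function(x, lipid_topo, min_gap = 10) {
  stopifnot(inherits(x, "jl_structure"))
  a <- x$atoms
  sel <- a$residue_name == lipid_topo$residue_name &
    a$atom_name == lipid_topo$headgroup_phosphorus
  if (!any(sel)) abort("no head-group phosphorus atoms found")
  lip <- a[sel, c("chain_id", "residue_id", "z")]
  if (nrow(lip) < 4) abort("fewer than 4 lipids; cannot resolve a dual bilayer")
  km <- kmeans(lip$z, centers = 4, nstart = 10)
  ord <- order(km$centers)
  centers <- sort(as.numeric(km$centers))
  if (min(diff(centers)) < min_gap) {
    abort(sprintf(
      "phosphorus z clusters are separated by < %g A; input does not look like a dual bilayer (4 leaflets)",
      min_gap))
  }
  rank_of <- match(km$cluster, ord)  # 1 = lowest plane .. 4 = highest
  membrane <- ifelse(rank_of <= 2, 1L, 2L)
  # EC = leaflet nearer the junction midplane (between the two membranes)
  leaflet <- ifelse(rank_of %in% c(2, 3), "EC", "IC")
  tibble(chain_id = lip$chain_id, residue_id = lip$residue_id,
         membrane = membrane, leaflet = leaflet, z_phosphorus = lip$z)
}
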