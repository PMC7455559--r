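#' Lipid topology: acyl-chain carbon and hydrogen naming
#'
#' Maps a lipid residue name to its SN1/SN2 acyl-chain carbon atom names
#' (ordered from the glycerol/ester end outward, position 1 = carbonyl
#' carbon) and to the hydrogens attached to each carbon.  Carbon numbering
#' follows the ester-end-first convention; note that force-field atom
#' names are often offset by one from this chemical numbering.
#'
#' @param residue_name Residue name selecting lipids in a structure.
#' @param sn1_carbons,sn2_carbons Character vectors of carbon atom names,
#'   ordered carbon 1..n.
#' @param ch_hydrogens Named list: carbon atom name -> character vector of
#'   attached hydrogen atom names.  Every carbon needs at least one
#'   hydrogen; terminal methyls carry three.
#' @param headgroup_phosphorus Atom name of the head-group phosphorus.
#' @return An object of class `lipid_topology`.
#' @export
lipid_topology <- function(residue_name, sn1_carbons, sn2_carbons,
                           ch_hydrogens, headgroup_phosphorus = "P") {
  stopifnot(is.character(sn1_carbons), is.character(sn2_carbons),
            is.list(ch_hydrogens))
  carbons <- c(sn1_carbons, sn2_carbons)
  missing_h <- setdiff(carbons, names(ch_hydrogens))
  if (length(missing_h)) {
    abort(paste0("no hydrogens declared for carbon(s): ",
                 paste(missing_h, collapse = ", ")))
  }
  if (any(lengths(ch_hydrogens[carbons]) < 1)) {
    abort("every carbon must carry at least one hydrogen")
  }
  structure(list(residue_name = residue_name,
                 sn1_carbons = sn1_carbons,
                 sn2_carbons = sn2_carbons,
                 ch_hydrogens = ch_hydrogens,
                 headgroup_phosphorus = headgroup_phosphorus),
            class = "lipid_topology")
}

#' @export
print.lipid_topology <- function(x, ...) {
  cat(sprintf("<lipid_topology> %s: SN1 %d carbons, SN2 %d carbons, P = %s\n",
              x$residue_name, length(x$sn1_carbons), length(x$sn2_carbons),
              x$headgroup_phosphorus))
  invisible(x)
}

#' Topology of the synthetic two-chain, 14-carbon (DMPC-like) lipid
#'
#' Atom naming used by the synthetic junction generator: SN1 carbons
#' `C1A..C14A` with hydrogens `HA<k>`/`HB<k>` (terminal methyl adds
#' `HC14`), SN2 carbons `C1B..C14B` with `HD<k>`/`HE<k>` (+ `HF14`), and a
#' head-group phosphorus `P`.
#'
#' @param residue_name Residue name (default `"DMP"`).
#' @return A [lipid_topology].
#' @export
dmpc_topology <- function(residue_name = "DMP") {
  ks <- 1:14
  sn1 <- paste0("C", ks, "A")
  sn2 <- paste0("C", ks, "B")
  h <- c(
    setNames(lapply(ks, function(k) {
      hs <- c(paste0("HA", k), paste0("HB", k))
      if (k == 14) hs <- c(hs, "HC14")
      hs
    }), sn1),
    setNames(lapply(ks, function(k) {
      hs <- c(paste0("HD", k), paste0("HE", k))
      if (k == 14) hs <- c(hs, "HF14")
      hs
    }), sn2)
  )
  lipid_topology(residue_name, sn1, sn2, h, "P")
}

#' Enumerate the lipid residues of a structure
#'
#' @param x A [jl_structure].
#' @param lipid_topo A [lipid_topology].
#' @return Tibble with one row per lipid: `chain_id`, `residue_id`.
#' @export
lipid_residues <- function(x, lipid_topo) {
  a <- x$atoms
  dplyr::distinct(
    a[a$residue_name == lipid_topo$residue_name, c("chain_id", "residue_id")])
}

# index matrix [lipid, carbon] into the atom table for one chain's carbons;
# lipids are rows of lipid_residues()
chain_carbon_index <- function(x, lipids, lipid_topo, chain = c("SN1", "SN2")) {
  chain <- match.arg(chain)
  carbons <- if (chain == "SN1") lipid_topo$sn1_carbons else lipid_topo$sn2_carbons
  a <- x$atoms
  key <- paste(a$chain_id, a$residue_id, a$atom_name, sep = "\r")
  idx <- matrix(NA_integer_, nrow(lipids), length(carbons))
  for (j in seq_along(carbons)) {
    idx[, j] <- match(paste(lipids$chain_id, lipids$residue_id, carbons[j],
                            sep = "\r"), key)
  }
  if (anyNA(idx)) abort("some lipids are missing chain carbons named in the topology")
  idx
}

# list over carbons: index matrix [lipid, hydrogen] for that carbon
chain_hydrogen_index <- function(x, lipids, lipid_topo, chain = c("SN1", "SN2")) {
  chain <- match.arg(chain)
  carbons <- if (chain == "SN1") lipid_topo$sn1_carbons else lipid_topo$sn2_carbons
  a <- x$atoms
  key <- paste(a$chain_id, a$residue_id, a$atom_name, sep = "\r")
  lapply(carbons, function(cn) {
    hs <- lipid_topo$ch_hydrogens[[cn]]
    m <- matrix(NA_integer_, nrow(lipids), length(hs))
    for (j in seq_along(hs)) {
      m[, j] <- match(paste(lipids$chain_id, lipids$residue_id, hs[j],
                            sep = "\r"), key)
    }
    if (anyNA(m)) {
      abort(sprintf("missing hydrogen(s) for carbon %s", cn))
    }
    m
  })
}
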