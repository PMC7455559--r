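backbone_names <- c("N", "CA", "C", "O")

subset_names <- function(subset) {
  switch(subset,
         backbone = backbone_names,
         CA = "CA",
         all = NULL)
}

#' Pair equivalent atoms between two models
#'
#' Atoms are matched one-to-one on (chain id, residue id, atom name),
#' restricted to the chosen subset and to residues present in both models
#' (so models trimmed of flexible domains pair over their common core).
#' When the two models share no chain ids, chains are paired in order of
#' appearance and residues matched by identity-maximizing global sequence
#' alignment (logged via a message).
#'
#' @param a,b [jl_structure] models.
#' @param subset `"backbone"` (N, CA, C, O), `"CA"`, or `"all"`.
#' @return An `atom_pairing` tibble: `idx_a`, `idx_b`, `chain_a`,
#'   `chain_b`, `residue_id_a`, `residue_id_b`, `atom_name`; the pairing
#'   policy is stored in an attribute.
#' @export
pair_atoms <- function(a, b, subset = c("backbone", "CA", "all")) {
  subset <- match.arg(subset)
  keep <- subset_names(subset)
  aa <- a$atoms; ab <- b$atoms
  ia <- seq_len(nrow(aa)); ib <- seq_len(nrow(ab))
  if (!is.null(keep)) {
    ia <- ia[aa$atom_name[ia] %in% keep & !aa$is_hetero[ia]]
    ib <- ib[ab$atom_name[ib] %in% keep & !ab$is_hetero[ib]]
  }
  common_chains <- intersect(unique(aa$chain_id[ia]), unique(ab$chain_id[ib]))
  if (length(common_chains) > 0) {
    ka <- paste(aa$chain_id[ia], aa$residue_id[ia], aa$atom_name[ia], sep = "\r")
    kb <- paste(ab$chain_id[ib], ab$residue_id[ib], ab$atom_name[ib], sep = "\r")
    m <- match(ka, kb)
    hit <- !is.na(m)
    out <- tibble(idx_a = ia[hit], idx_b = ib[m[hit]],
                  chain_a = aa$chain_id[ia[hit]],
                  chain_b = ab$chain_id[ib[m[hit]]],
                  residue_id_a = aa$residue_id[ia[hit]],
                  residue_id_b = ab$residue_id[ib[m[hit]]],
                  atom_name = aa$atom_name[ia[hit]])
    policy <- "chain-id + residue-id match"
  } else {
    inform("no shared chain ids; pairing chains in order with sequence alignment")
    out <- pair_by_alignment(a, b, ia, ib)
    policy <- "ordered chains + global sequence alignment"
  }
  out <- out[order(out$idx_a), ]
  if (nrow(out) == 0) abort("atom pairing is empty")
  structure(out, class = c("atom_pairing", class(out)),
            policy = policy, subset = subset)
}

pair_by_alignment <- function(a, b, ia, ib) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("sequence-alignment pairing requires the Biostrings package")
  }
  aa <- a$atoms; ab <- b$atoms
  ch_a <- unique(aa$chain_id[ia]); ch_b <- unique(ab$chain_id[ib])
  n <- min(length(ch_a), length(ch_b))
  purrr::map_dfr(seq_len(n), function(ci) {
    sa <- ia[aa$chain_id[ia] == ch_a[ci]]
    sb <- ib[ab$chain_id[ib] == ch_b[ci]]
    resa <- unique(aa$residue_id[sa]); resb <- unique(ab$residue_id[sb])
    seqa <- vapply(resa, function(r) {
      bio3d::aa321(aa$residue_name[sa[aa$residue_id[sa] == r][1]])
    }, character(1))
    seqb <- vapply(resb, function(r) {
      bio3d::aa321(ab$residue_name[sb[ab$residue_id[sb] == r][1]])
    }, character(1))
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(paste(seqa, collapse = "")),
      Biostrings::AAString(paste(seqb, collapse = "")),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    ra <- 0L; rb <- 0L
    rows <- list()
    for (k in seq_along(pa)) {
      if (pa[k] != "-") ra <- ra + 1L
      if (pb[k] != "-") rb <- rb + 1L
      if (pa[k] != "-" && pb[k] != "-") {
        at_a <- sa[aa$residue_id[sa] == resa[ra]]
        at_b <- sb[ab$residue_id[sb] == resb[rb]]
        mm <- match(aa$atom_name[at_a], ab$atom_name[at_b])
        hit <- !is.na(mm)
        rows[[length(rows) + 1]] <- tibble(
          idx_a = at_a[hit], idx_b = at_b[mm[hit]],
          chain_a = ch_a[ci], chain_b = ch_b[ci],
          residue_id_a = resa[ra], residue_id_b = resb[rb],
          atom_name = aa$atom_name[at_a[hit]])
      }
    }
    dplyr::bind_rows(rows)
  })
}

kabsch <- function(moving, target) {
  # optimal proper rotation R (and translation) minimizing
  # || target - (moving %*% t(R) + t) ||
  cm <- colMeans(moving); ct <- colMeans(target)
  M <- sweep(moving, 2, cm); T <- sweep(target, 2, ct)
  C <- crossprod(M, T)           # 3x3
  sv <- svd(C)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = ct - as.numeric(R %*% cm))
}

#' Least-squares superposition RMSD between two models
#'
#' Rigid-body superposition by the standard SVD (Kabsch) solution with a
#' proper rotation enforced (det = +1), then RMSD over the paired atoms.
#'
#' @param a,b [jl_structure] models (`b` is rotated onto `a`).
#' @param pairing Optional [pair_atoms()] result; computed from `subset`
#'   when missing.
#' @param subset Pairing subset when `pairing` is NULL.
#' @return An object of class `jl_superposition`: list with `rmsd`
#'   (Angstrom), `rotation` (3x3), `translation`, `n_atoms`, `pairing`.
#' @export
superpose_rmsd <- function(a, b, pairing = NULL,
                           subset = c("backbone", "CA", "all")) {
  subset <- match.arg(subset)
  pairing <- pairing %||% pair_atoms(a, b, subset)
  if (nrow(pairing) < 3) abort("need at least 3 atom pairs to superpose")
  pa <- coords(a)[pairing$idx_a, , drop = FALSE]
  pb <- coords(b)[pairing$idx_b, , drop = FALSE]
  svals <- svd(sweep(pa, 2, colMeans(pa)))$d
  if (svals[2] < 1e-8 * max(svals[1], 1)) {
    abort("paired atoms are collinear; superposition is degenerate")
  }
  k <- kabsch(pb, pa)
  fitted <- pb %*% t(k$R) + matrix(k$t, nrow(pb), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((pa - fitted)^2)))
  structure(list(rmsd = rmsd, rotation = k$R, translation = k$t,
                 n_atoms = nrow(pairing), pairing = pairing),
            class = "jl_superposition")
}

#' @export
print.jl_superposition <- function(x, ...) {
  cat(sprintf("<jl_superposition> rmsd = %.4f A over %d atoms\n",
              x$rmsd, x$n_atoms))
  invisible(x)
}

#' @export
glance.jl_superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_atoms = x$n_atoms)
}

#' Two-tailed Student-t confidence interval of replicate values
#'
#' `mean +/- t(1 - (1-conf)/2, n-1) * sd / sqrt(n)`; the interval is
#' symmetric about the mean and has zero width when the replicates agree
#' exactly.
#'
#' @param values Numeric replicate values.
#' @param conf Confidence level (default 0.95).
#' @return Tibble: `mean`, `sd`, `n`, `ci_low`, `ci_high`, `ci_defined`.
#' @export
t_confidence_interval <- function(values, conf = 0.95) {
  n <- length(values)
  mu <- mean(values)
  if (n >= 2) {
    s <- stats::sd(values)
    half <- qt(1 - (1 - conf) / 2, df = n - 1) * s / sqrt(n)
    tibble(mean = mu, sd = s, n = n, ci_low = mu - half,
           ci_high = mu + half, ci_defined = TRUE)
  } else {
    tibble(mean = mu, sd = NA_real_, n = n, ci_low = NA_real_,
           ci_high = NA_real_, ci_defined = FALSE)
  }
}

superpose_frames <- function(frames, idx) {
  # align each frame's subset to the running mean (two passes)
  sub <- lapply(frames, function(f) f[idx, , drop = FALSE])
  ref <- sub[[1]]
  for (pass in 1:2) {
    aligned <- lapply(sub, function(p) {
      k <- kabsch(p, ref)
      p %*% t(k$R) + matrix(k$t, nrow(p), 3, byrow = TRUE)
    })
    ref <- Reduce(`+`, aligned) / length(aligned)
  }
  list(aligned = aligned, mean = ref)
}

#' Per-residue RMSF profile with Student-t confidence intervals
#'
#' Each replicate (for a 12-subunit channel simulated in R runs: each
#' subunit of each run, n = 12 R) is internally superposed to its
#' time-average, and the per-residue fluctuation
#' `rmsf = sqrt(<|x - <x>|^2>)` computed over frames.  Across the n
#' replicate values per residue position the mean, sd, and two-tailed 95%
#' Student-t confidence interval `mean +/- t(0.975, n-1) sd / sqrt(n)` are
#' reported.
#'
#' @param trajs A [jl_trajectory] or list of them (independent runs).
#' @param atom_name Atom used per residue (default `"CA"`).
#' @param chains Chains treated as replicate subunits; default all chains
#'   holding the atom.
#' @param conf Confidence level (default 0.95).
#' @return An `rmsf_profile` tibble: `residue` (position within chain),
#'   `mean_rmsf`, `sd`, `n`, `ci_low`, `ci_high`, `ci_defined`.
#' @export
rmsf_profile <- function(trajs, atom_name = "CA", chains = NULL,
                         conf = 0.95) {
  if (inherits(trajs, "jl_trajectory")) trajs <- list(trajs)
  reps <- list()
  for (tr in trajs) {
    atoms <- tr$topology$atoms
    sel_chains <- chains %||%
      unique(atoms$chain_id[atoms$atom_name == atom_name & !atoms$is_hetero])
    for (ch in sel_chains) {
      idx <- which(atoms$chain_id == ch & atoms$atom_name == atom_name &
                     !atoms$is_hetero)
      if (length(idx) == 0) next
      sp <- superpose_frames(tr$frames, idx)
      dev2 <- Reduce(`+`, lapply(sp$aligned, function(p) {
        rowSums((p - sp$mean)^2)
      })) / length(sp$aligned)
      reps[[length(reps) + 1]] <- sqrt(dev2)
    }
  }
  if (length(reps) == 0) abort("no replicates found")
  m <- lengths(reps)
  if (length(unique(m)) != 1) {
    abort("replicate chains have differing residue counts; cannot align profiles")
  }
  mat <- do.call(cbind, reps)  # residues x replicates
  ci <- purrr::map_dfr(seq_len(nrow(mat)), function(r) {
    t_confidence_interval(mat[r, ], conf)
  })
  out <- tibble(residue = seq_len(nrow(mat)), mean_rmsf = ci$mean,
                sd = ci$sd, n = ci$n, ci_low = ci$ci_low,
                ci_high = ci$ci_high, ci_defined = ci$ci_defined)
  class(out) <- c("rmsf_profile", class(out))
  out
}
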