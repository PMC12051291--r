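# Sequence-guided rigid-body superposition with iterative outlier rejection.

#' Least-squares rigid superposition (Kabsch)
#'
#' Closed-form SVD solution for the proper rotation and translation mapping
#' point set `Q` onto `P` with minimum RMSD (reflections corrected).
#'
#' @param P,Q N x 3 coordinate matrices of paired points (N >= 3).
#' @return list with `rotation` (3 x 3), `translation` (length 3) such that
#'   `Q %*% t(rotation) + translation` best fits `P`, and `rmsd`.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) stop("P and Q must have the same number of points")
  if (nrow(P) < 3) stop("at least 3 point pairs are required")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Qc, Pc)
  sv <- svd(H)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) {
    warning(sprintf("degenerate (near-collinear) point set: singular values %s",
                    paste(signif(sv$d, 3), collapse = ", ")))
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- as.numeric(cp - R %*% cq)
  fitted <- Qc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pc - fitted)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

#' Apply a rigid transform to a Structure or coordinate matrix
#'
#' @param x a `Structure` or an N x 3 matrix.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation vector.
#' @return transformed object of the same kind.
#' @export
apply_transform <- function(x, rotation, translation) {
  if (inherits(x, "Structure")) {
    xyz <- as.matrix(x$atoms[, c("x", "y", "z")])
    xyz <- xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
    x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
    return(x)
  }
  as.matrix(x) %*% t(rotation) +
    matrix(translation, nrow(as.matrix(x)), 3, byrow = TRUE)
}

.scope_atoms <- function(atoms, scope) {
  switch(scope,
    heavy = atoms,
    backbone = atoms[atoms$elety %in% c("N", "CA", "C", "O"), , drop = FALSE],
    calpha = atoms[atoms$elety == "CA", , drop = FALSE],
    stop("unknown atom scope: ", scope)
  )
}

# Restrict a chain's residue-map rows to residues inside domain segments
# (chain-scoped ECOD-style ranges in author numbering).
.in_domain_ranges <- function(chain, resno, restrict_to) {
  keep <- rep(FALSE, length(resno))
  for (d in restrict_to) {
    segs <- if (is.data.frame(d)) d else d$segments
    for (k in seq_len(nrow(segs))) {
      ch_ok <- is.na(segs$chain[k]) | segs$chain[k] == chain
      keep <- keep | (ch_ok & resno >= segs$start[k] & resno <= segs$end[k])
    }
  }
  keep
}

#' Build an atom correspondence between two structures
#'
#' For each residue pair matched by a global sequence alignment, atoms are
#' paired by identical atom name within the chosen scope; atoms present in
#' only one structure are dropped.
#'
#' @param ref,mob `Structure` objects.
#' @param aln `AlignmentResult` aligning the chain sequences (ref as `a`,
#'   mob as `b`).
#' @param ref_chain,mob_chain chain identifiers.
#' @param scope `"heavy"` (default), `"backbone"` or `"calpha"`.
#' @param restrict_to optional list of domain ranges (data.frames with
#'   `chain`, `start`, `end`, or [read_domain_table()] entries); when given,
#'   only reference residues inside the ranges contribute pairs.
#' @return list with `P` (ref coords), `Q` (mob coords), and `meta`
#'   (data.frame: ref chain/resno/insert/elety per pair).
#' @export
build_atom_correspondence <- function(ref, mob, aln, ref_chain, mob_chain,
                                      scope = "heavy", restrict_to = NULL) {
  ref_idx <- chain_sequence(ref, ref_chain)$index
  mob_idx <- chain_sequence(mob, mob_chain)$index
  pairs <- aln$pairs
  if (!is.null(restrict_to)) {
    rch <- ref_idx$chain[pairs[, "pos_a"]]
    rno <- ref_idx$resno[pairs[, "pos_a"]]
    pairs <- pairs[.in_domain_ranges(rch, rno, restrict_to), , drop = FALSE]
  }
  if (nrow(pairs) == 0) stop("no aligned residue pairs within scope")

  ref_at <- .scope_atoms(ref$atoms[!ref$atoms$is_hetero &
                                     ref$atoms$chain == ref_chain, ], scope)
  mob_at <- .scope_atoms(mob$atoms[!mob$atoms$is_hetero &
                                     mob$atoms$chain == mob_chain, ], scope)
  ref_key <- paste(residue_uid(ref_at), ref_at$elety, sep = "|")
  mob_key <- paste(residue_uid(mob_at), mob_at$elety, sep = "|")

  ref_uid_of_pos <- paste(ref_idx$chain, ref_idx$resno, ref_idx$insert,
                          sep = "|")
  mob_uid_of_pos <- paste(mob_idx$chain, mob_idx$resno, mob_idx$insert,
                          sep = "|")

  P <- list(); Q <- list(); meta <- list()
  for (k in seq_len(nrow(pairs))) {
    ru <- ref_uid_of_pos[pairs[k, "pos_a"]]
    mu <- mob_uid_of_pos[pairs[k, "pos_b"]]
    ri <- which(residue_uid(ref_at) == ru)
    if (length(ri) == 0) next
    names_r <- ref_at$elety[ri]
    mi <- which(residue_uid(mob_at) == mu)
    mnames <- mob_at$elety[mi]
    common <- intersect(names_r, mnames)
    if (length(common) == 0) next
    ri <- ri[match(common, names_r)]
    mi <- mi[match(common, mnames)]
    P[[length(P) + 1]] <- as.matrix(ref_at[ri, c("x", "y", "z")])
    Q[[length(Q) + 1]] <- as.matrix(mob_at[mi, c("x", "y", "z")])
    meta[[length(meta) + 1]] <- ref_at[ri, c("chain", "resno", "insert",
                                             "elety")]
  }
  if (length(P) == 0) stop("zero atom pairs in correspondence")
  list(P = do.call(rbind, P), Q = do.call(rbind, Q),
       meta = do.call(rbind, meta))
}

#' Sequence-guided superposition with iterative outlier rejection
#'
#' Chains are paired by shared identifier (or the single chain on each
#' side), their sequences globally aligned, and name-matched atoms pooled
#' into an initial least-squares fit. Up to `max_cycles` refinement cycles
#' follow: per cycle, atom pairs whose deviation under the current transform
#' exceeds `mean + sd_cutoff * SD` of the retained deviations are rejected
#' (as pairs, not whole residues) and the fit repeated; refinement stops
#' early when a cycle rejects nothing or fewer than `min_pairs` would
#' remain. Deviations must also exceed an absolute floor of 1e-6 Angstrom to
#' be rejected, so exact copies never lose pairs to floating-point noise.
#'
#' @param ref reference `Structure`.
#' @param mob mobile `Structure` (superposed onto `ref`).
#' @param max_cycles maximum refinement cycles (default 5).
#' @param sd_cutoff rejection threshold in standard deviations (default 2).
#' @param scope atom scope, see [build_atom_correspondence()].
#' @param restrict_to optional domain ranges limiting the correspondence
#'   (used when domain orientations differ and only the binding domain
#'   should drive the fit).
#' @param identity_floor minimum sequence identity per chain pair.
#' @param min_pairs minimum retained atom pairs (default 10).
#' @param matrix,gap_open,gap_extend alignment parameters.
#' @return object of class `SuperpositionResult`: `rotation`, `translation`,
#'   `cycles` (data.frame `cycle`, `n_pairs`, `rmsd`; cycle 0 is the initial
#'   fit), `final_rmsd`, `pairs_initial`, `n_rejected`, `rejected` (meta rows
#'   of rejected pairs), and `model` (the transformed mobile structure).
#' @export
align_refine <- function(ref, mob, max_cycles = 5, sd_cutoff = 2.0,
                         scope = "heavy", restrict_to = NULL,
                         identity_floor = 0.30, min_pairs = 10,
                         matrix = default_substitution_matrix(),
                         gap_open = 11, gap_extend = 1) {
  ref_chains <- unique(ref$atoms$chain[!ref$atoms$is_hetero])
  mob_chains <- unique(mob$atoms$chain[!mob$atoms$is_hetero])
  shared <- intersect(ref_chains, mob_chains)
  pairs_of_chains <- if (length(shared) > 0) {
    cbind(shared, shared)
  } else if (length(ref_chains) == 1 && length(mob_chains) == 1) {
    cbind(ref_chains, mob_chains)
  } else {
    stop("cannot pair chains: no shared identifiers and both structures are multi-chain")
  }

  P <- NULL; Q <- NULL; meta <- NULL
  for (k in seq_len(nrow(pairs_of_chains))) {
    rc <- pairs_of_chains[k, 1]; mc <- pairs_of_chains[k, 2]
    rs <- chain_sequence(ref, rc); ms <- chain_sequence(mob, mc)
    aln <- global_align(rs$seq, ms$seq, matrix = matrix,
                        gap_open = gap_open, gap_extend = gap_extend)
    if (aln$identity < identity_floor) {
      stop(sprintf("chain %s/%s identity %.2f below floor %.2f",
                   rc, mc, aln$identity, identity_floor))
    }
    corr <- build_atom_correspondence(ref, mob, aln, rc, mc, scope = scope,
                                      restrict_to = restrict_to)
    P <- rbind(P, corr$P); Q <- rbind(Q, corr$Q)
    meta <- rbind(meta, corr$meta)
  }

  keep <- rep(TRUE, nrow(P))
  fit <- kabsch(P, Q)
  dev <- sqrt(rowSums((P - apply_transform(Q, fit$rotation,
                                           fit$translation))^2))
  cycles <- data.frame(cycle = 0L, n_pairs = nrow(P), rmsd = fit$rmsd)

  for (cyc in seq_len(max_cycles)) {
    d_kept <- dev[keep]
    thr <- max(mean(d_kept) + sd_cutoff * stats::sd(d_kept), 1e-6)
    if (is.na(thr)) break
    reject <- keep & dev > thr
    if (!any(reject)) break
    if (sum(keep) - sum(reject) < min_pairs) {
      message(sprintf(
        "cycle %d would leave %d pairs (< %d); keeping previous fit",
        cyc, sum(keep) - sum(reject), min_pairs))
      break
    }
    keep[reject] <- FALSE
    fit <- kabsch(P[keep, , drop = FALSE], Q[keep, , drop = FALSE])
    dev <- sqrt(rowSums((P - apply_transform(Q, fit$rotation,
                                             fit$translation))^2))
    cycles <- rbind(cycles, data.frame(cycle = cyc, n_pairs = sum(keep),
                                       rmsd = fit$rmsd))
  }

  structure(
    list(rotation = fit$rotation, translation = fit$translation,
         cycles = cycles, final_rmsd = fit$rmsd, pairs_initial = nrow(P),
         n_rejected = sum(!keep),
         rejected = meta[!keep, , drop = FALSE],
         model = apply_transform(mob, fit$rotation, fit$translation)),
    class = "SuperpositionResult"
  )
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf(
    "SuperpositionResult: %d/%d atom pairs retained over %d cycle(s), final RMSD %.4f A\n",
    x$pairs_initial - x$n_rejected, x$pairs_initial,
    max(x$cycles$cycle), x$final_rmsd))
  invisible(x)
}
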