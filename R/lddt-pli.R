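# Superposition-free protein-ligand interface conservation score (lDDT-PLI).
#
# Interface atoms are defined on the reference complex only: protein and
# ligand atoms within the interface cutoff of any atom of the binding
# partner. Every unordered pair of interface atoms contributes a distance
# difference |d_pred - d_ref| scored by a piecewise threshold function; each
# atom averages f over its pairs, and the score averages over atoms.

#' Piecewise distance-difference scoring function
#'
#' `f = 1` for differences below 0.5 A, `0.8` on [0.5, 1), `0.6` on [1, 2),
#' `0.4` on [2, 4) and `0` at 4 A or more (lower bounds inclusive).
#'
#' @param delta_d absolute distance difference(s) in Angstrom (>= 0).
#' @return f value(s) in \{1, 0.8, 0.6, 0.4, 0\}.
#' @export
threshold_score <- function(delta_d) {
  if (any(!is.finite(delta_d)) || any(delta_d < 0)) {
    stop("delta_d must be a non-negative absolute distance difference")
  }
  ifelse(delta_d < 0.5, 1,
  ifelse(delta_d < 1.0, 0.8,
  ifelse(delta_d < 2.0, 0.6,
  ifelse(delta_d < 4.0, 0.4, 0))))
}

#' Select interface atoms of a reference complex
#'
#' Protein atoms within `cutoff` of any ligand atom, plus ligand atoms
#' within `cutoff` of any protein atom (boundary inclusive). Defined on the
#' reference only.
#'
#' @param ref reference `Structure`.
#' @param lig a `LigandInstance` belonging to `ref`.
#' @param cutoff interface cutoff in Angstrom (default 5).
#' @return data.frame of interface atoms: `role` ("protein"/"ligand"),
#'   `chain`, `resno`, `insert`, `name`, `x`, `y`, `z`.
#' @export
select_interface_atoms <- function(ref, lig, cutoff = 5.0) {
  prot <- ref$atoms[!ref$atoms$is_hetero, , drop = FALSE]
  if (nrow(prot) == 0) stop("reference has no protein atoms")
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  lxyz <- as.matrix(lig$atoms[, c("x", "y", "z")])
  dp <- .min_dist_within(pxyz, lxyz, cutoff)
  dl <- .min_dist_within(lxyz, pxyz, cutoff)
  sel_p <- is.finite(dp) & dp <= cutoff
  sel_l <- is.finite(dl) & dl <= cutoff
  if (!any(sel_l)) {
    stop(sprintf("empty interface: no ligand atom within %.1f A of the protein",
                 cutoff))
  }
  pr <- prot[sel_p, , drop = FALSE]
  out <- rbind(
    data.frame(role = "protein", chain = pr$chain, resno = pr$resno,
               insert = pr$insert, name = pr$elety,
               x = pr$x, y = pr$y, z = pr$z, stringsAsFactors = FALSE),
    data.frame(role = "ligand", chain = lig$copy_key$chain,
               resno = lig$copy_key$resno, insert = lig$copy_key$insert,
               name = lig$atoms$name[sel_l],
               x = lig$atoms$x[sel_l], y = lig$atoms$y[sel_l],
               z = lig$atoms$z[sel_l], stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}

# Correspondence between reference and model atoms of a complex: protein
# atoms through a per-chain sequence alignment plus atom name, ligand atoms
# by name (after optional positional harmonization of the model copy).
.complex_correspondence <- function(ref, model, comp_id, order = NULL,
                                    model_copy = 1, exclude = .DEFAULT_ION_CODES,
                                    identity_floor = 0.30) {
  ref_chains <- unique(ref$atoms$chain[!ref$atoms$is_hetero])
  mod_chains <- unique(model$atoms$chain[!model$atoms$is_hetero])
  shared <- intersect(ref_chains, mod_chains)
  chain_pairs <- if (length(shared) > 0) cbind(shared, shared)
    else cbind(ref_chains[1], mod_chains[1])

  lookup <- new.env(parent = emptyenv())
  mod_prot <- model$atoms[!model$atoms$is_hetero, , drop = FALSE]
  mod_xyz <- as.matrix(mod_prot[, c("x", "y", "z")])
  mod_key <- paste(residue_uid(mod_prot), mod_prot$elety, sep = "|")

  for (k in seq_len(nrow(chain_pairs))) {
    rs <- chain_sequence(ref, chain_pairs[k, 1])
    ms <- chain_sequence(model, chain_pairs[k, 2])
    rm_ <- map_chain_to_reference(rs, ms$seq, identity_floor = identity_floor)
    for (i in seq_len(nrow(rm_))) {
      if (is.na(rm_$ref_pos[i])) next
      mrow <- ms$index[rm_$ref_pos[i], ]
      ref_uid <- paste(rm_$chain[i], rm_$resno[i], rm_$insert[i], sep = "|")
      assign(ref_uid, paste(mrow$chain, mrow$resno, mrow$insert, sep = "|"),
             envir = lookup)
    }
  }

  mligs <- Filter(function(l) l$comp_id == comp_id,
                  extract_ligands(model, exclude = exclude))
  if (length(mligs) == 0) stop("component ", comp_id, " absent from model")
  ml <- mligs[[min(model_copy, length(mligs))]]
  if (!is.null(order)) ml <- harmonize_atom_names(ml, order)
  lig_xyz <- as.matrix(ml$atoms[, c("x", "y", "z")])

  # returns the model coordinates of one reference interface atom, or NULL
  function(role, chain, resno, insert, name) {
    if (role == "ligand") {
      j <- match(name, ml$atoms$name)
      if (is.na(j)) return(NULL)
      return(lig_xyz[j, ])
    }
    ref_uid <- paste(chain, resno, insert, sep = "|")
    mod_uid <- tryCatch(get(ref_uid, envir = lookup), error = function(e) NULL)
    if (is.null(mod_uid)) return(NULL)
    j <- match(paste(mod_uid, name, sep = "|"), mod_key)
    if (is.na(j)) return(NULL)
    mod_xyz[j, ]
  }
}

#' lDDT-PLI interface conservation score
#'
#' For each unordered pair of reference interface atoms, the absolute
#' difference between the reference and model inter-atom distances is scored
#' by [threshold_score()]; per-atom means over all pairs involving the atom
#' are averaged over the N interface atoms. Distances are internal, so the
#' score is invariant to any rigid motion of the model and no superposition
#' is required.
#'
#' @param ref reference `Structure` containing the ligand.
#' @param model model `Structure` of the same complex.
#' @param comp_id ligand component code.
#' @param cutoff interface cutoff in Angstrom (default 5).
#' @param order optional `ComponentAtomOrder` to harmonize model ligand
#'   atom names.
#' @param ref_copy,model_copy which ligand copy to use on each side (index).
#' @param include_intra include protein-protein (and ligand-ligand) interface
#'   pairs (default TRUE); `FALSE` scores protein-ligand contacts only.
#' @param strict if TRUE (default), a reference interface atom without a
#'   model correspondent is an error; if FALSE such atoms are dropped with a
#'   message.
#' @param identity_floor minimum chain alignment identity.
#' @param exclude hetero codes excluded from ligand extraction.
#' @return object of class `InterfaceScore`: `score`, `n_atoms`, `per_atom`
#'   (data.frame `role`, `chain`, `resno`, `insert`, `name`, `m`, `f_mean`),
#'   `ledger` (per-pair `i`, `j`, `d_ref`, `d_pred`, `delta`, `f`) and
#'   `params`.
#' @export
lddt_pli <- function(ref, model, comp_id, cutoff = 5.0, order = NULL,
                     ref_copy = 1, model_copy = 1, include_intra = TRUE,
                     strict = TRUE, identity_floor = 0.30,
                     exclude = .DEFAULT_ION_CODES) {
  rligs <- Filter(function(l) l$comp_id == comp_id,
                  extract_ligands(ref, exclude = exclude))
  if (length(rligs) == 0) stop("component ", comp_id, " absent from reference")
  rl <- rligs[[min(ref_copy, length(rligs))]]

  iface <- select_interface_atoms(ref, rl, cutoff = cutoff)
  model_coord_of <- .complex_correspondence(
    ref, model, comp_id, order = order, model_copy = model_copy,
    exclude = exclude, identity_floor = identity_floor
  )

  n0 <- nrow(iface)
  mc <- matrix(NA_real_, n0, 3)
  for (i in seq_len(n0)) {
    v <- model_coord_of(iface$role[i], iface$chain[i], iface$resno[i],
                        iface$insert[i], iface$name[i])
    if (!is.null(v)) mc[i, ] <- v
  }
  missing <- !is.finite(mc[, 1])
  if (any(missing)) {
    desc <- paste(iface$role[missing], iface$name[missing], collapse = ", ")
    if (strict) {
      stop(sprintf("%d interface atom(s) lack a model correspondent: %s",
                   sum(missing), desc))
    }
    message(sprintf("dropped %d interface atom(s) without model correspondent",
                    sum(missing)))
    iface <- iface[!missing, , drop = FALSE]
    mc <- mc[!missing, , drop = FALSE]
  }
  n <- nrow(iface)
  if (n < 2) stop("fewer than 2 interface atoms with correspondence")

  rc <- as.matrix(iface[, c("x", "y", "z")])
  pair_idx <- t(combn(n, 2))
  if (!include_intra) {
    inter <- iface$role[pair_idx[, 1]] != iface$role[pair_idx[, 2]]
    pair_idx <- pair_idx[inter, , drop = FALSE]
    if (nrow(pair_idx) == 0) stop("no protein-ligand interface pairs")
  }
  d_ref <- sqrt(rowSums((rc[pair_idx[, 1], , drop = FALSE] -
                           rc[pair_idx[, 2], , drop = FALSE])^2))
  d_pred <- sqrt(rowSums((mc[pair_idx[, 1], , drop = FALSE] -
                            mc[pair_idx[, 2], , drop = FALSE])^2))
  delta <- abs(d_pred - d_ref)
  f <- threshold_score(delta)

  f_sum <- numeric(n); m_i <- integer(n)
  for (k in seq_len(nrow(pair_idx))) {
    i <- pair_idx[k, 1]; j <- pair_idx[k, 2]
    f_sum[i] <- f_sum[i] + f[k]; f_sum[j] <- f_sum[j] + f[k]
    m_i[i] <- m_i[i] + 1L; m_i[j] <- m_i[j] + 1L
  }
  scored <- m_i > 0
  per_atom <- data.frame(
    iface[, c("role", "chain", "resno", "insert", "name")],
    m = m_i, f_mean = ifelse(scored, f_sum / pmax(m_i, 1), NA_real_),
    stringsAsFactors = FALSE
  )
  score <- mean(per_atom$f_mean[scored])

  structure(
    list(score = score, n_atoms = sum(scored), per_atom = per_atom,
         ledger = data.frame(i = pair_idx[, 1], j = pair_idx[, 2],
                             d_ref = d_ref, d_pred = d_pred,
                             delta = delta, f = f),
         params = list(comp_id = comp_id, cutoff = cutoff,
                       include_intra = include_intra, strict = strict)),
    class = "InterfaceScore"
  )
}

#' @export
print.InterfaceScore <- function(x, ...) {
  cat(sprintf("InterfaceScore (lDDT-PLI): %.4f over %d interface atoms (%d pairs)\n",
              x$score, x$n_atoms, nrow(x$ledger)))
  invisible(x)
}
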