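# No-fit ligand RMSD after protein superposition, with positional atom-name
# harmonization against a canonical component atom order.

#' Rename ligand atoms positionally against a canonical atom order
#'
#' Predicted models often carry arbitrary ligand atom names while preserving
#' the canonical atom order of the component definition; harmonization
#' renames the i-th ligand atom to the i-th canonical name. Renaming is
#' all-or-nothing: any count or element mismatch aborts it.
#'
#' @param lig a `LigandInstance`.
#' @param order a `ComponentAtomOrder` from [read_component_atom_order()].
#' @return the ligand with harmonized atom names.
#' @export
harmonize_atom_names <- function(lig, order) {
  n <- nrow(lig$atoms)
  if (n != length(order$atom_names)) {
    stop(sprintf(
      "atom count mismatch: ligand has %d heavy atoms, component order has %d",
      n, length(order$atom_names)))
  }
  if (!is.null(order$elements)) {
    lig_el <- toupper(lig$atoms$elesy)
    bad <- which(lig_el != toupper(order$elements))
    if (length(bad) > 0) {
      stop(sprintf(
        "element mismatch at position %d: ligand %s vs component %s (%s)",
        bad[1], lig_el[bad[1]], toupper(order$elements[bad[1]]),
        order$atom_names[bad[1]]))
    }
  }
  lig$atoms$name <- order$atom_names
  lig
}

#' RMSD between two ligand poses without fitting
#'
#' Atoms are paired strictly by name; the result is the root of the mean
#' squared coordinate distance over the pairs, with no superposition applied
#' (the protein superposition is assumed done beforehand).
#'
#' @param a,b `LigandInstance` objects with identical atom-name sets.
#' @return RMSD in Angstrom.
#' @export
rmsd_no_fit <- function(a, b) {
  na <- a$atoms$name; nb <- b$atoms$name
  if (!setequal(na, nb) || length(na) != length(nb)) {
    only_a <- setdiff(na, nb); only_b <- setdiff(nb, na)
    stop(sprintf(
      "atom name sets differ; only in first: {%s}; only in second: {%s}",
      paste(only_a, collapse = ","), paste(only_b, collapse = ",")))
  }
  m <- match(na, nb)
  A <- as.matrix(a$atoms[, c("x", "y", "z")])
  B <- as.matrix(b$atoms[m, c("x", "y", "z")])
  sqrt(mean(rowSums((A - B)^2)))
}

#' Per-copy ligand RMSD report
#'
#' For every (model copy, reference copy) pair of the component, computes
#' the no-fit RMSD. The model must already be superposed onto the reference
#' (e.g. the `model` element of [align_refine()]); this function never
#' refits. When name sets differ and a component atom order is supplied, the
#' model copy is renamed positionally first.
#'
#' @param model superposed model `Structure`.
#' @param reference reference `Structure`.
#' @param comp_id ligand component code.
#' @param order optional `ComponentAtomOrder` for harmonization.
#' @param exclude hetero codes excluded from ligand extraction.
#' @return data.frame with one row per copy pair: `comp_id`,
#'   `model_copy`, `reference_copy`, `n_atoms`, `rmsd`, `harmonization`
#'   (`"name-matched"` or `"order-renamed"`), `best` (TRUE for the
#'   minimum-RMSD reference copy of each model copy).
#' @export
ligand_rmsd_report <- function(model, reference, comp_id, order = NULL,
                               exclude = .DEFAULT_ION_CODES) {
  pick <- function(s, label) {
    ligs <- Filter(function(l) l$comp_id == comp_id,
                   extract_ligands(s, exclude = exclude))
    if (length(ligs) == 0) {
      stop(sprintf("component %s absent from %s structure", comp_id, label))
    }
    ligs
  }
  mligs <- pick(model, "model")
  rligs <- pick(reference, "reference")
  copy_label <- function(l) {
    paste0(l$copy_key$chain, l$copy_key$resno, l$copy_key$insert)
  }
  rows <- list()
  for (ml in mligs) {
    for (rl in rligs) {
      harm <- "name-matched"
      ml_use <- ml
      if (!setequal(ml$atoms$name, rl$atoms$name)) {
        if (is.null(order)) {
          stop(sprintf(
            "atom names of model copy %s do not match reference copy %s and no component atom order was given",
            copy_label(ml), copy_label(rl)))
        }
        ml_use <- harmonize_atom_names(ml, order)
        harm <- "order-renamed"
      }
      rows[[length(rows) + 1]] <- data.frame(
        comp_id = comp_id, model_copy = copy_label(ml),
        reference_copy = copy_label(rl), n_atoms = nrow(ml_use$atoms),
        rmsd = rmsd_no_fit(ml_use, rl), harmonization = harm,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$best <- FALSE
  for (mc in unique(out$model_copy)) {
    idx <- which(out$model_copy == mc)
    out$best[idx[which.min(out$rmsd[idx])]] <- TRUE
  }
  rownames(out) <- NULL
  out
}
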