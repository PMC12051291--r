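# End-to-end orchestration: annotate (binding-site-proximal PTMs) and
# compare (superposition + ligand RMSD + lDDT-PLI), with every fixed
# parameter of the analysis surfaced in one config object.

#' Pipeline run configuration
#'
#' Defaults are the analysis' fixed parameters: 10 A PTM proximity cutoff,
#' 5 A interface cutoff, up to 5 refinement cycles with 2-SD outlier
#' rejection, all-heavy-atom scope, 0.30 identity floor, strict interface
#' correspondence.
#'
#' @param proximity_cutoff PTM-to-ligand proximity cutoff, Angstrom.
#' @param interface_cutoff interface atom selection cutoff, Angstrom.
#' @param max_cycles maximum superposition refinement cycles.
#' @param sd_cutoff outlier rejection threshold, standard deviations.
#' @param scope atom scope for superposition.
#' @param identity_floor minimum chain alignment identity.
#' @param strict strict (error) vs lenient (drop) interface correspondence.
#' @param exclude_ions hetero codes excluded from ligand extraction.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(proximity_cutoff = 10.0, interface_cutoff = 5.0,
                       max_cycles = 5L, sd_cutoff = 2.0, scope = "heavy",
                       identity_floor = 0.30, strict = TRUE,
                       exclude_ions = .DEFAULT_ION_CODES) {
  stopifnot(proximity_cutoff > 0, interface_cutoff > 0, max_cycles >= 1,
            sd_cutoff > 0)
  structure(list(proximity_cutoff = proximity_cutoff,
                 interface_cutoff = interface_cutoff,
                 max_cycles = as.integer(max_cycles), sd_cutoff = sd_cutoff,
                 scope = scope, identity_floor = identity_floor,
                 strict = strict, exclude_ions = exclude_ions),
            class = "RunConfig")
}

#' Write / read a run configuration as JSON
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the `RunConfig`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "RunConfig"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

.read_fasta_one <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) stop("no sequences in ", path)
  list(accession = sub("\\s.*$", "", names(seqs)[1]),
       seq = as.character(seqs[[1]]))
}

#' Annotate binding-site-proximal PTM sites
#'
#' Reads a reference complex, maps each protein chain onto the reference
#' sequence, validates the PTM table against it, and reports every validated
#' site within the proximity cutoff of each ligand copy, with optional
#' domain assignment.
#'
#' @param reference path to the reference structure (PDB/mmCIF).
#' @param ptm_table path to the PTM site TSV.
#' @param ref_fasta path to the reference sequence FASTA (first record
#'   used).
#' @param domains optional path to a domain-range TSV.
#' @param out optional output TSV path (written even when no site is
#'   proximal, header only).
#' @param config a [run_config()].
#' @return data.frame of proximal sites (one row per site x ligand copy),
#'   invisibly when `out` is given.
#' @export
run_annotate <- function(reference, ptm_table, ref_fasta, domains = NULL,
                         out = NULL, config = run_config()) {
  s <- read_structure(reference)
  fa <- .read_fasta_one(ref_fasta)
  sites <- read_ptm_table(ptm_table)
  sites <- validate_sites(sites, fa$seq)
  ligs <- extract_ligands(s, exclude = config$exclude_ions)
  dom_list <- if (!is.null(domains)) read_domain_table(domains) else NULL

  chains <- unique(s$atoms$chain[!s$atoms$is_hetero])
  results <- list()
  for (ch in chains) {
    rmap <- map_chain_to_reference(chain_sequence(s, ch), fa$seq,
                                   identity_floor = config$identity_floor)
    for (lig in ligs) {
      hits <- find_proximal_ptms(s, lig, sites, rmap,
                                 cutoff = config$proximity_cutoff)
      if (nrow(hits) > 0) results[[length(results) + 1]] <- hits
    }
  }
  out_df <- if (length(results) > 0) do.call(rbind, results) else
    .empty_proximal_df()
  if (!is.null(dom_list) && nrow(out_df) > 0) {
    assign_ <- map_sites_to_domains(out_df, dom_list)
    first_dom <- assign_[!duplicated(assign_[, c("accession", "position")]), ]
    out_df$domain_id <- first_dom$domain_id[
      match(paste(out_df$accession, out_df$position),
            paste(first_dom$accession, first_dom$position))]
  } else {
    out_df$domain_id <- rep(NA_character_, nrow(out_df))
  }
  if (!is.null(out)) {
    write.table(out_df, out, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out_df))
  }
  out_df
}

#' Compare a model complex against a reference
#'
#' Superposes the model onto the reference (sequence-guided, iterative
#' outlier rejection), then reports per-copy no-fit ligand RMSD and the
#' lDDT-PLI interface score.
#'
#' @param reference,model structure file paths (PDB/mmCIF).
#' @param comp_id ligand component code.
#' @param component optional SDF/CCD component file for atom-name
#'   harmonization.
#' @param restrict optional ECOD-style range string (e.g. `"A:1-120"`)
#'   restricting the superposition to the binding domain.
#' @param out_prefix optional path prefix; writes
#'   `<prefix>_ligand_rmsd.tsv`, `<prefix>_lddt_pli.json`,
#'   `<prefix>_superposed.pdb` and `<prefix>_superposition.json`.
#' @param config a [run_config()].
#' @return list with `superposition` (`SuperpositionResult`), `ligand_rmsd`
#'   (report data.frame) and `lddt_pli` (`InterfaceScore`).
#' @export
run_compare <- function(reference, model, comp_id, component = NULL,
                        restrict = NULL, out_prefix = NULL,
                        config = run_config()) {
  ref <- read_structure(reference)
  mob <- read_structure(model)
  order <- if (!is.null(component)) read_component_atom_order(component)
    else NULL
  restrict_to <- if (!is.null(restrict)) list(parse_domain_ranges(restrict))
    else NULL

  sup <- align_refine(ref, mob, max_cycles = config$max_cycles,
                      sd_cutoff = config$sd_cutoff, scope = config$scope,
                      restrict_to = restrict_to,
                      identity_floor = config$identity_floor)
  rmsd_rep <- ligand_rmsd_report(sup$model, ref, comp_id, order = order,
                                 exclude = config$exclude_ions)
  score <- lddt_pli(ref, sup$model, comp_id,
                    cutoff = config$interface_cutoff, order = order,
                    strict = config$strict,
                    identity_floor = config$identity_floor,
                    exclude = config$exclude_ions)

  if (!is.null(out_prefix)) {
    write.table(rmsd_rep, paste0(out_prefix, "_ligand_rmsd.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(score = score$score, n_atoms = score$n_atoms,
           per_atom = score$per_atom, ledger = score$ledger,
           params = score$params),
      paste0(out_prefix, "_lddt_pli.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE, dataframe = "rows")
    jsonlite::write_json(
      list(cycles = sup$cycles, final_rmsd = sup$final_rmsd,
           pairs_initial = sup$pairs_initial, n_rejected = sup$n_rejected),
      paste0(out_prefix, "_superposition.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE, dataframe = "rows")
    write_structure_pdb(sup$model, paste0(out_prefix, "_superposed.pdb"))
  }
  list(superposition = sup, ligand_rmsd = rmsd_rep, lddt_pli = score)
}
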