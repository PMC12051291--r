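#' @importFrom stats sd setNames
#' @importFrom utils read.delim write.table combn
NULL

# Residue-name codes always treated as water.
.WATER_CODES <- c("HOH", "WAT", "DOD", "H2O")

# Monoatomic ions commonly deposited as hetero components; excluded from
# ligand extraction by default (drug/cofactor analyses ignore bare ions).
.DEFAULT_ION_CODES <- c(
  "NA", "K", "MG", "CA", "ZN", "CL", "MN", "FE", "FE2", "CO", "CU", "NI",
  "CD", "HG", "BR", "IOD", "F", "CS", "LI", "RB", "SR", "BA", "AL", "PB"
)

# Parent-component table for common modified residues; anything not listed
# here or in the standard 20 becomes 'X' (which never matches in identity
# checks downstream).
.NONSTANDARD_PARENT <- c(
  MSE = "M", SEP = "S", TPO = "T", PTR = "Y", CSO = "C", CME = "C",
  CSD = "C", OCS = "C", KCX = "K", LLP = "K", MLY = "K", ALY = "K",
  M3L = "K", HYP = "P", PCA = "E", SAC = "S", AIB = "A", FME = "M",
  NEP = "H", HIC = "H", CGU = "E", DAL = "A", SAR = "G"
)

.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

.aa_three_to_one <- function(resid) {
  out <- .AA3TO1[resid]
  miss <- is.na(out)
  out[miss] <- .NONSTANDARD_PARENT[resid[miss]]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Construct a Structure object from an atom table
#'
#' The atom table is the package's uniform representation of a parsed model:
#' one row per heavy atom, with author chain/residue numbering and insertion
#' codes preserved.
#'
#' @param atoms data.frame with columns `type` ("ATOM"/"HETATM"), `elety`
#'   (atom name), `resid` (3-letter component code), `chain`, `resno`
#'   (integer), `insert` (insertion code, `""` if none), `x`, `y`, `z`,
#'   `o` (occupancy), `elesy` (element symbol).
#' @param id structure identifier.
#' @param source_format `"PDB"` or `"mmCIF"`.
#' @return an object of class `Structure`.
#' @export
new_structure <- function(atoms, id = "structure", source_format = "PDB") {
  required <- c("type", "elety", "resid", "chain", "resno", "insert",
                "x", "y", "z", "o", "elesy")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("structure contains no atoms")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("non-finite atom coordinates")
  if (any(!nzchar(atoms$elety))) stop("empty atom name")
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$is_hetero <- atoms$type == "HETATM"
  rownames(atoms) <- NULL
  structure(
    list(id = id, atoms = atoms, source_format = source_format),
    class = "Structure"
  )
}

#' @export
print.Structure <- function(x, ...) {
  prot <- x$atoms[!x$atoms$is_hetero, ]
  het <- x$atoms[x$atoms$is_hetero, ]
  cat(sprintf(
    "Structure '%s' (%s): %d chains, %d residues, %d protein atoms, %d hetero atoms\n",
    x$id, x$source_format, length(unique(x$atoms$chain)),
    length(unique(residue_uid(prot))), nrow(prot), nrow(het)
  ))
  invisible(x)
}

# Unique residue key "chain|resno|insert" for an atom table.
residue_uid <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
}

# Resolve alternate locations: keep, per (residue, atom name), the conformer
# with the highest occupancy; ties broken by altloc letter order.
.resolve_altloc <- function(atoms) {
  alt <- atoms$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(atoms)
  key <- paste(residue_uid(atoms), atoms$resid, atoms$elety, sep = "|")
  occ <- atoms$o
  occ[is.na(occ)] <- 1
  ord <- order(key, -occ, alt)
  atoms <- atoms[ord, ]
  atoms[!duplicated(key[ord]), ]
}

.atoms_from_bio3d <- function(pdb) {
  at <- pdb$atom
  at$insert <- ifelse(is.na(at$insert), "", at$insert)
  at$elesy <- ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                     .guess_element(at$elety), toupper(at$elesy))
  at <- .resolve_altloc(at)
  # heavy atoms only
  at <- at[!(at$elesy %in% c("H", "D")), ]
  at[, c("type", "elety", "resid", "chain", "resno", "insert",
         "x", "y", "z", "o", "elesy")]
}

.guess_element <- function(elety) {
  # first alphabetic character of the atom name; adequate for fixtures and
  # standard residues when the element column is absent
  toupper(substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", elety)), 1, 1))
}

#' Read a macromolecular structure from PDB or mmCIF
#'
#' Loads heavy atoms only (hydrogens and deuteriums dropped), resolves
#' alternate locations to the highest-occupancy conformer (ties broken by
#' altloc letter), and preserves author numbering with insertion codes.
#'
#' @param path path to a PDB or mmCIF file.
#' @param fmt `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return a [new_structure()] `Structure`.
#' @export
read_structure <- function(path, fmt = c("auto", "pdb", "cif")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "auto") {
    fmt <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (fmt == "cif") {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE))
    },
    error = function(e) {
      stop(sprintf("failed to parse %s as %s: %s", path, fmt,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  atoms <- .atoms_from_bio3d(parsed)
  if (nrow(atoms) == 0) stop("empty structure: ", path)
  new_structure(atoms,
                id = sub("\\.[^.]*$", "", basename(path)),
                source_format = if (fmt == "cif") "mmCIF" else "PDB")
}

#' Write a Structure as a PDB file
#'
#' @param s a `Structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  at <- s$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = at$type, resno = at$resno, resid = at$resid,
    chain = at$chain, insert = at$insert, elety = at$elety,
    o = at$o, b = rep(0, nrow(at)), elesy = at$elesy
  )
  invisible(path)
}

#' Extract ligand instances from a structure
#'
#' Hetero components are returned as one instance per copy (a copy is a
#' distinct chain/residue-number placement of the component). Waters are
#' always excluded; monoatomic ions are excluded by a configurable list.
#'
#' @param s a `Structure`.
#' @param exclude component codes to exclude in addition to water; defaults
#'   to a built-in monoatomic-ion list. Use `character(0)` to keep ions.
#' @return list of `LigandInstance` objects (possibly empty), each with
#'   `comp_id`, `copy_key` (chain, resno, insert) and an `atoms` data.frame.
#' @export
extract_ligands <- function(s, exclude = .DEFAULT_ION_CODES) {
  het <- s$atoms[s$atoms$is_hetero, , drop = FALSE]
  het <- het[!(het$resid %in% c(.WATER_CODES, exclude)), , drop = FALSE]
  if (nrow(het) == 0) return(list())
  keys <- paste(het$resid, residue_uid(het), sep = "|")
  lapply(split(seq_len(nrow(het)), factor(keys, levels = unique(keys))),
         function(idx) {
    a <- het[idx, , drop = FALSE]
    if (anyDuplicated(a$elety)) {
      stop("duplicate atom names within ligand copy ", keys[idx[1]])
    }
    structure(
      list(
        comp_id = a$resid[1],
        copy_key = list(chain = a$chain[1], resno = a$resno[1],
                        insert = a$insert[1]),
        atoms = data.frame(name = a$elety, elesy = a$elesy,
                           x = a$x, y = a$y, z = a$z,
                           stringsAsFactors = FALSE)
      ),
      class = "LigandInstance"
    )
  }) |> unname()
}

#' @export
print.LigandInstance <- function(x, ...) {
  cat(sprintf("LigandInstance %s [%s %s%s]: %d heavy atoms\n",
              x$comp_id, x$copy_key$chain, x$copy_key$resno,
              x$copy_key$insert, nrow(x$atoms)))
  invisible(x)
}

#' One-letter sequence of a protein chain
#'
#' Returns the observed sequence (one letter per standard residue, in
#' residue order) together with an index mapping 1-based sequence position
#' to the structure residue key. Nonstandard residues map through a built-in
#' parent-component table (e.g. MSE to M, SEP to S), otherwise to `X`.
#'
#' @param s a `Structure`.
#' @param chain_id chain identifier.
#' @return list with `seq` (character scalar) and `index` (data.frame with
#'   columns `pos`, `chain`, `resno`, `insert`, `letter`).
#' @export
chain_sequence <- function(s, chain_id) {
  prot <- s$atoms[!s$atoms$is_hetero, , drop = FALSE]
  available <- unique(prot$chain)
  if (!(chain_id %in% available)) {
    stop(sprintf("chain '%s' not found; available protein chains: %s",
                 chain_id, paste(available, collapse = ", ")))
  }
  ch <- prot[prot$chain == chain_id, , drop = FALSE]
  uid <- residue_uid(ch)
  first <- !duplicated(uid)
  res <- ch[first, c("chain", "resno", "insert", "resid")]
  letters1 <- .aa_three_to_one(res$resid)
  index <- data.frame(
    pos = seq_len(nrow(res)), chain = res$chain, resno = res$resno,
    insert = res$insert, letter = letters1, stringsAsFactors = FALSE
  )
  list(seq = paste(letters1, collapse = ""), index = index)
}

#' Read a canonical component atom order from an SDF or CCD component file
#'
#' Heavy-atom names in file order. CCD-style component mmCIF files carry
#' explicit atom names (`_chem_comp_atom.atom_id`); SDF atom blocks carry
#' only elements, so names are generated by the PDB convention of
#' per-element numbering in file order (C1, C2, N1, O1, ...).
#'
#' @param path SDF (`.sdf`/`.mol`) or CCD component mmCIF (`.cif`) file.
#' @param comp_id optional component code; defaults to the id declared in
#'   the file.
#' @return list with `comp_id` and `atom_names` (class `ComponentAtomOrder`).
#' @export
read_component_atom_order <- function(path, comp_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    out <- .read_ccd_component(path)
  } else {
    out <- .read_sdf_component(path)
  }
  if (!is.null(comp_id)) out$comp_id <- comp_id
  if (length(out$atom_names) == 0) stop("component has no heavy atoms: ", path)
  if (anyDuplicated(out$atom_names)) {
    stop("duplicate atom names in component file: ", path)
  }
  class(out) <- "ComponentAtomOrder"
  out
}

.read_sdf_component <- function(path) {
  sdf <- ChemmineR::read.SDFset(path)
  if (length(sdf) != 1) stop("expected exactly one component per SDF file")
  ab <- ChemmineR::atomblock(sdf[[1]])
  elements <- toupper(sub("_.*$", "", rownames(ab)))
  heavy <- elements != "H"
  elements <- elements[heavy]
  counts <- integer(0)
  names_out <- character(length(elements))
  for (i in seq_along(elements)) {
    el <- elements[i]
    counts[el] <- if (is.na(counts[el])) 1L else counts[el] + 1L
    names_out[i] <- paste0(el, counts[el])
  }
  comp <- trimws(ChemmineR::header(sdf[[1]])[1])
  list(comp_id = if (nzchar(comp)) comp else "LIG",
       atom_names = names_out, elements = elements)
}

# Minimal CCD component reader: the _chem_comp_atom loop only.
.read_ccd_component <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_starts <- grep("^\\s*loop_\\s*$", lines)
  for (ls in loop_starts) {
    i <- ls + 1
    fields <- character(0)
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      fields <- c(fields, trimws(lines[i]))
      i <- i + 1
    }
    if (!any(grepl("^_chem_comp_atom\\.", fields))) next
    keys <- sub("^_chem_comp_atom\\.", "", fields)
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || grepl("^(loop_|_|#|data_)", ln)) break
      rows[[length(rows) + 1]] <- scan(text = ln, what = character(),
                                       quiet = TRUE)
      i <- i + 1
    }
    tab <- do.call(rbind, rows)
    colnames(tab) <- keys
    if (!all(c("atom_id", "type_symbol") %in% keys)) {
      stop("CCD component file lacks atom_id/type_symbol: ", path)
    }
    el <- toupper(tab[, "type_symbol"])
    heavy <- el != "H"
    comp <- if ("comp_id" %in% keys) unname(tab[1, "comp_id"]) else "LIG"
    return(list(comp_id = comp,
                atom_names = gsub('"', "", tab[heavy, "atom_id"]),
                elements = el[heavy]))
  }
  stop("no _chem_comp_atom loop found in ", path)
}
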