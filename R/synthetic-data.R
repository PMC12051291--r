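# Self-contained synthetic fixtures: toy protein-ligand complexes with
# planted PTM sites at exact nearest-atom distances, plus model variants
# derived from the reference by known perturbations. Every planted quantity
# is recorded in a JSON manifest so pipeline outputs can be checked against
# ground truth.

.SYN_ACCESSION <- "SYNP1"
.SYN_COMP <- "LIG"

#' Specification of a synthetic protein-ligand fixture
#'
#' @param n_residues number of protein residues (>= 5; default 60).
#' @param ligand_atoms number of ligand heavy atoms (>= 2; default 8).
#' @param seed RNG seed; a fixed seed gives byte-identical fixture files.
#' @param planted_sites data.frame with columns `position`, `residue`,
#'   `ptm_type`, `distance` (intended nearest-atom distance to the ligand in
#'   Angstrom). Default: one phosphosite at 8 A and one at 12 A, bracketing
#'   the 10 A proximity cutoff, at positions scaled to the chain length.
#' @param bad_sites data.frame (may be empty) with `position`, `residue`,
#'   `ptm_type` rows to plant as invalid table entries (wrong residue letter
#'   or out-of-range position); these must be excluded by validation.
#' @param n_pocket number of binding-pocket residues (default 4) relocated
#'   to 3.0-4.5 A of the ligand so the complex has a non-empty 5 A
#'   interface; they carry no PTM annotation.
#' @return list of class `FixtureSpec`.
#' @export
fixture_spec <- function(n_residues = 60, ligand_atoms = 8, seed = 1,
                         planted_sites = NULL,
                         bad_sites = NULL, n_pocket = 4) {
  if (n_residues < 5) stop("n_residues must be >= 5")
  if (is.null(planted_sites)) {
    pos <- pmax(c(1, 2), round(c(0.2, 0.45) * n_residues))
    planted_sites <- data.frame(
      position = pos, residue = c("S", "T"), ptm_type = "Phosphorylation",
      distance = c(8.0, 12.0), stringsAsFactors = FALSE
    )
  }
  if (ligand_atoms < 2) stop("ligand_atoms must be >= 2")
  if (n_pocket < 0 || n_pocket > 4) stop("n_pocket must be in 0..4")
  if (nrow(planted_sites) + n_pocket > n_residues) {
    stop("more planted/pocket residues than residues")
  }
  if (nrow(planted_sites) > 0) {
    if (any(planted_sites$position < 1 |
              planted_sites$position > n_residues)) {
      stop("planted site position outside the chain")
    }
    if (any(planted_sites$distance <= 0)) stop("planted distance must be > 0")
    if (anyDuplicated(planted_sites$position)) {
      stop("planted site positions must be unique")
    }
  }
  structure(list(n_residues = n_residues, ligand_atoms = ligand_atoms,
                 seed = seed, planted_sites = planted_sites,
                 bad_sites = bad_sites, n_pocket = n_pocket),
            class = "FixtureSpec")
}

# Side-chain/backbone placeholder offsets from the residue anchor point, in
# local coordinates (first axis points away from the ligand for planted
# residues, so the anchor atom is always the residue's nearest atom).
.RESIDUE_OFFSETS <- list(
  CB = c(0.0, 0.0, 0.0),
  CA = c(1.5, 0.0, 0.0),
  N  = c(2.4, 0.9, 0.0),
  C  = c(2.4, -0.9, 0.4),
  O  = c(3.5, -1.1, 0.6)
)

.one_to_three <- function(letter) {
  names(.AA3TO1)[match(letter, .AA3TO1)]
}

# Deterministic residue alphabet draw (common residues, no duplicate-prone
# exotic codes).
.random_sequence <- function(n, rng) {
  pool <- c("A", "G", "S", "T", "K", "L", "E", "V", "R", "Y")
  pool[1 + floor(rng(n) * length(pool)) %% length(pool)]
}

#' Build a synthetic protein-ligand complex with planted PTM geometry
#'
#' The protein is an idealized helical backbone (2.3 A radius, 1.5 A rise,
#' 100 degrees per residue, with placeholder N/CA/C/O/CB atoms) centred at
#' the origin; the ligand is a short heteroatom chain placed 40 A away along
#' +x, so unplanted residues are far outside any realistic cutoff. Each
#' planted site's residue is relocated so its CB sits at exactly the
#' requested nearest-atom distance from the nearest ligand atom, with all
#' other residue atoms strictly farther — the intended minimum distance is
#' realized to machine precision and recorded in the manifest.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @param formats structure formats to write, subset of `c("pdb", "cif")`.
#' @return list with `structure` (the in-memory reference), `manifest`, and
#'   `paths` (reference files, PTM TSV, domain TSV, sequence FASTA,
#'   component SDF and CCD files, manifest JSON).
#' @export
make_toy_complex <- function(spec, dir = tempfile("fixture"),
                             formats = c("pdb")) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  rng <- function(n) stats::runif(n)

  n <- spec$n_residues
  letters_seq <- .random_sequence(n, rng)
  letters_seq[letters_seq == "G"] <- "A"   # keep CB placeholders everywhere
  ps <- spec$planted_sites
  if (nrow(ps) > 0) letters_seq[ps$position] <- ps$residue

  # residues relocated next to the ligand: planted PTM sites at their
  # requested distances, plus unannotated pocket residues that give the
  # complex a non-empty interface at 5 A
  reloc <- data.frame(position = integer(0), distance = numeric(0),
                      phi_deg = numeric(0))
  if (nrow(ps) > 0) {
    reloc <- data.frame(position = ps$position, distance = ps$distance,
                        phi_deg = (seq_len(nrow(ps)) - 1) * 25 - 45)
  }
  if (spec$n_pocket > 0) {
    free <- setdiff(rev(seq_len(n)), ps$position)
    pocket <- data.frame(
      position = free[seq_len(spec$n_pocket)],
      distance = c(3.0, 3.4, 3.8, 4.2)[seq_len(spec$n_pocket)],
      phi_deg = c(-80, -65, 65, 80)[seq_len(spec$n_pocket)]
    )
    reloc <- rbind(reloc, pocket)
  } else {
    pocket <- NULL
  }

  # helical anchor trace
  theta <- (seq_len(n) - 1) * 100 * pi / 180
  anchors <- cbind(2.3 * cos(theta), 2.3 * sin(theta),
                   (seq_len(n) - 1) * 1.5)

  # ligand: chain of heavy atoms along +x, nearest atom first
  lig_first <- c(40, 0, (n - 1) * 1.5 / 2)
  lig_el <- rep(c("C", "N", "O"), length.out = spec$ligand_atoms)
  lig_xyz <- t(vapply(seq_len(spec$ligand_atoms) - 1L,
                      function(k) lig_first + c(1.4 * k, 0, 0), numeric(3)))
  counts <- integer(0)
  lig_names <- character(spec$ligand_atoms)
  for (i in seq_along(lig_el)) {
    el <- lig_el[i]
    counts[el] <- if (is.na(counts[el])) 1L else counts[el] + 1L
    lig_names[i] <- paste0(el, counts[el])
  }

  # residue atoms; planted residues rebuilt next to the ligand so that the
  # CB anchor realizes the requested minimum distance exactly
  atom_rows <- list()
  for (i in seq_len(n)) {
    plant <- match(i, reloc$position)
    if (!is.na(plant)) {
      phi <- reloc$phi_deg[plant] * pi / 180
      u <- c(-cos(phi), sin(phi), 0)   # u_x < 0: points away from the chain
      anchor <- lig_first + reloc$distance[plant] * u
      frame_x <- u
    } else {
      anchor <- anchors[i, ]
      frame_x <- c(-1, 0, 0)
    }
    # orthonormal local frame (second/third axes fixed)
    fy <- c(frame_x[2], -frame_x[1], 0)
    if (sum(fy^2) < 1e-12) fy <- c(0, 1, 0)
    fy <- fy / sqrt(sum(fy^2))
    fz <- c(frame_x[2] * 0 - 0, 0 - frame_x[1] * 0, frame_x[1] * fy[2] -
              frame_x[2] * fy[1])
    fz <- fz / sqrt(sum(fz^2))
    for (nm in names(.RESIDUE_OFFSETS)) {
      off <- .RESIDUE_OFFSETS[[nm]]
      xyz <- anchor + off[1] * frame_x + off[2] * fy + off[3] * fz
      atom_rows[[length(atom_rows) + 1]] <- data.frame(
        type = "ATOM", elety = nm,
        resid = .one_to_three(letters_seq[i]), chain = "A", resno = i,
        insert = "", x = xyz[1], y = xyz[2], z = xyz[3], o = 1,
        elesy = substr(nm, 1, 1), stringsAsFactors = FALSE
      )
    }
  }
  lig_rows <- data.frame(
    type = "HETATM", elety = lig_names, resid = .SYN_COMP, chain = "A",
    resno = n + 101L, insert = "", x = lig_xyz[, 1], y = lig_xyz[, 2],
    z = lig_xyz[, 3], o = 1, elesy = lig_el, stringsAsFactors = FALSE
  )
  ref <- new_structure(rbind(do.call(rbind, atom_rows), lig_rows),
                       id = "synthetic_reference")

  # --- files ---
  paths <- list()
  if ("pdb" %in% formats) {
    paths$reference_pdb <- file.path(dir, "reference.pdb")
    write_structure_pdb(ref, paths$reference_pdb)
  }
  if ("cif" %in% formats) {
    paths$reference_cif <- file.path(dir, "reference.cif")
    .write_minimal_cif(ref, paths$reference_cif)
  }

  seq_str <- paste(letters_seq, collapse = "")
  paths$sequence_fasta <- file.path(dir, "reference.fasta")
  writeLines(c(paste0(">", .SYN_ACCESSION), seq_str), paths$sequence_fasta)

  ptm <- data.frame(accession = character(0), position = integer(0),
                    residue = character(0), ptm_type = character(0))
  if (nrow(ps) > 0) {
    ptm <- data.frame(accession = .SYN_ACCESSION, position = ps$position,
                      residue = ps$residue, ptm_type = ps$ptm_type,
                      stringsAsFactors = FALSE)
  }
  if (!is.null(spec$bad_sites) && nrow(spec$bad_sites) > 0) {
    ptm <- rbind(ptm, data.frame(accession = .SYN_ACCESSION,
                                 position = spec$bad_sites$position,
                                 residue = spec$bad_sites$residue,
                                 ptm_type = spec$bad_sites$ptm_type,
                                 stringsAsFactors = FALSE))
  }
  paths$ptm_tsv <- file.path(dir, "ptm_sites.tsv")
  write.table(ptm, paths$ptm_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)

  half <- floor(n / 2)
  domains <- data.frame(
    domain_id = c("D1", "D2"), accession = .SYN_ACCESSION,
    range = c(sprintf("A:1-%d", half), sprintf("A:%d-%d", half + 1, n)),
    stringsAsFactors = FALSE
  )
  paths$domain_tsv <- file.path(dir, "domains.tsv")
  write.table(domains, paths$domain_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)

  paths$component_sdf <- file.path(dir, "component.sdf")
  .write_component_sdf(lig_names, lig_el, lig_xyz, paths$component_sdf)
  paths$component_cif <- file.path(dir, "component.cif")
  .write_component_cif(lig_names, lig_el, paths$component_cif)

  manifest <- list(
    accession = .SYN_ACCESSION, comp_id = .SYN_COMP, seed = spec$seed,
    n_residues = n, ligand_atoms = spec$ligand_atoms,
    sequence = seq_str,
    planted_sites = if (nrow(ps) > 0) {
      data.frame(ps, stringsAsFactors = FALSE)
    } else NULL,
    n_bad_sites = if (is.null(spec$bad_sites)) 0L else nrow(spec$bad_sites),
    n_valid_sites = nrow(ps),
    pocket_residues = pocket,
    domains = domains,
    ligand_copy = list(chain = "A", resno = n + 101L)
  )
  paths$manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  list(structure = ref, manifest = manifest, paths = paths, dir = dir)
}

# random proper rotation from the current RNG stream
.random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

.rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) * cos(a) + sin(a) * ux + (1 - cos(a)) * (u %o% u)
}

#' Derive a model structure from a reference by a known perturbation
#'
#' Supported perturbations and their analytic expectations (written to the
#' manifest):
#' \describe{
#'   \item{`none`}{identical copy; ligand RMSD 0, lDDT-PLI 1.}
#'   \item{`rigid`}{whole-complex rotation+translation (random under `seed`
#'     unless `R`/`t` supplied); post-superposition ligand RMSD 0.}
#'   \item{`ligand_shift`}{ligand translated by `d` Angstrom (direction
#'     random under `seed` unless `direction` supplied); protein unchanged,
#'     so expected ligand RMSD is exactly `d`.}
#'   \item{`jitter`}{i.i.d. N(0, sigma^2) noise on each ligand atom
#'     coordinate, protein unchanged; expected squared ligand RMSD 3*sigma^2.}
#'   \item{`hinge`}{residues from `pivot_residue` on rotated by `angle`
#'     degrees about an axis through the pivot anchor; domain-restricted vs
#'     whole-structure superposition contrast.}
#'   \item{`residue_kick`}{one residue's atoms translated by `d` Angstrom;
#'     its atom pairs should be rejected during refinement.}
#' }
#'
#' @param reference reference `Structure` (from [make_toy_complex()]).
#' @param perturbation list with `type` and type-specific fields (see above).
#' @param seed RNG seed for random perturbation draws.
#' @param dir output directory; model PDB and manifest are written there.
#' @return list with `structure` (the model), `manifest`, `paths`.
#' @export
make_model_variant <- function(reference, perturbation = list(type = "none"),
                               seed = 1, dir = tempfile("model")) {
  stopifnot(inherits(reference, "Structure"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  mod <- reference
  mod$id <- "synthetic_model"
  at <- mod$atoms
  is_lig <- at$is_hetero & at$resid == .SYN_COMP
  expect <- list()
  type <- perturbation$type

  if (type == "none") {
    expect$ligand_rmsd <- 0
    expect$lddt_pli <- 1
  } else if (type == "rigid") {
    R <- if (!is.null(perturbation[["R"]])) perturbation[["R"]] else
      .random_rotation()
    t_vec <- if (!is.null(perturbation[["t"]])) perturbation[["t"]] else
      stats::runif(3, -20, 20)
    mod <- apply_transform(mod, R, t_vec)
    expect$ligand_rmsd <- 0
    expect$lddt_pli <- 1
  } else if (type == "ligand_shift") {
    d <- perturbation$d
    u <- if (!is.null(perturbation$direction)) {
      perturbation$direction / sqrt(sum(perturbation$direction^2))
    } else {
      v <- stats::rnorm(3); v / sqrt(sum(v^2))
    }
    at$x[is_lig] <- at$x[is_lig] + d * u[1]
    at$y[is_lig] <- at$y[is_lig] + d * u[2]
    at$z[is_lig] <- at$z[is_lig] + d * u[3]
    mod$atoms <- at
    expect$ligand_rmsd <- d
  } else if (type == "jitter") {
    sigma <- perturbation$sigma
    nl <- sum(is_lig)
    noise <- matrix(stats::rnorm(3 * nl, sd = sigma), nl, 3)
    at$x[is_lig] <- at$x[is_lig] + noise[, 1]
    at$y[is_lig] <- at$y[is_lig] + noise[, 2]
    at$z[is_lig] <- at$z[is_lig] + noise[, 3]
    mod$atoms <- at
    expect$mean_squared_rmsd <- 3 * sigma^2
    expect$realized_squared_rmsd <- mean(rowSums(noise^2))
  } else if (type == "hinge") {
    angle <- perturbation$angle
    pivot <- perturbation$pivot_residue
    moved <- !at$is_hetero & at$resno >= pivot
    pivot_anchor <- as.numeric(
      at[!at$is_hetero & at$resno == pivot, c("x", "y", "z")][1, ])
    R <- .rotation_about(c(1, 0, 0), angle)
    xyz <- as.matrix(at[moved, c("x", "y", "z")])
    xyz <- sweep(xyz, 2, pivot_anchor)
    xyz <- xyz %*% t(R)
    xyz <- sweep(xyz, 2, pivot_anchor, `+`)
    at$x[moved] <- xyz[, 1]; at$y[moved] <- xyz[, 2]; at$z[moved] <- xyz[, 3]
    mod$atoms <- at
    expect$hinge <- list(angle = angle, pivot_residue = pivot)
    expect$restricted_rmsd <- 0
  } else if (type == "residue_kick") {
    idx <- perturbation$index
    d <- perturbation$d
    moved <- !at$is_hetero & at$resno == idx
    if (!any(moved)) stop("residue_kick index not in structure")
    at$y[moved] <- at$y[moved] + d
    mod$atoms <- at
    expect$kicked_residue <- idx
    expect$kick_distance <- d
    expect$final_rmsd_max <- 0.1
  } else {
    stop("unknown perturbation type: ", type)
  }

  paths <- list(model_pdb = file.path(dir, "model.pdb"),
                manifest = file.path(dir, "model_manifest.json"))
  write_structure_pdb(mod, paths$model_pdb)
  manifest <- list(perturbation = perturbation[names(perturbation) != "R"],
                   seed = seed, expectations = expect)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(structure = mod, manifest = manifest, paths = paths, dir = dir)
}

# Minimal mmCIF writer (atom_site loop only) for synthetic fixtures.
.write_minimal_cif <- function(s, path) {
  at <- s$atoms
  lines <- c(
    paste0("data_", gsub("[^A-Za-z0-9_]", "_", s$id)),
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    sprintf("%s %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
            at$type, seq_len(nrow(at)), at$elesy, at$elety, at$resid,
            at$chain, at$resno,
            ifelse(nzchar(at$insert), at$insert, "?"),
            at$x, at$y, at$z, at$o, 0, at$resno, at$resid, at$chain,
            at$elety)
  )
  writeLines(lines, path)
  invisible(path)
}

# Toy SDF (V2000) for the synthetic component: linear chain bonds.
.write_component_sdf <- function(names_, elements, xyz, path) {
  n <- length(elements)
  nb <- max(n - 1, 0)
  lines <- c(
    .SYN_COMP, "  synthetic component", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            xyz[, 1], xyz[, 2], xyz[, 3], elements),
    if (nb > 0) sprintf("%3d%3d  1  0", seq_len(nb), seq_len(nb) + 1),
    "M  END", "$$$$"
  )
  writeLines(lines, path)
  invisible(path)
}

# CCD-style component file carrying the canonical atom names.
.write_component_cif <- function(names_, elements, path) {
  lines <- c(
    paste0("data_", .SYN_COMP),
    "loop_",
    "_chem_comp_atom.comp_id", "_chem_comp_atom.atom_id",
    "_chem_comp_atom.type_symbol",
    sprintf("%s %s %s", .SYN_COMP, names_, elements)
  )
  writeLines(lines, path)
  invisible(path)
}
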