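# PTM site ingestion, validation against reference sequences, proximity
# search around bound ligands, and domain-range assignment.

#' Read a PTM site table (dbPTM-like TSV)
#'
#' Expects tab-separated columns `accession`, `position`, `residue`,
#' `ptm_type` (header optional; `col_map` selects/renames columns for other
#' dialects). Duplicate (accession, position, ptm_type) rows are collapsed
#' so counts are non-duplicated per accession. Rows with non-integer
#' positions are rejected with a warning and returned in
#' `attr(, "rejected")`.
#'
#' @param path TSV file path.
#' @param header whether the file has a header row.
#' @param col_map named integer vector giving the column index of each of
#'   accession, position, residue, ptm_type.
#' @return data.frame of PTM sites with `status = NA` (set by
#'   [validate_sites()]).
#' @export
read_ptm_table <- function(path, header = TRUE,
                           col_map = c(accession = 1, position = 2,
                                       residue = 3, ptm_type = 4)) {
  if (!file.exists(path)) stop("PTM table not found: ", path)
  raw <- read.delim(path, header = header, sep = "\t",
                    colClasses = "character", stringsAsFactors = FALSE)
  sites <- data.frame(
    accession = raw[[col_map[["accession"]]]],
    position_raw = raw[[col_map[["position"]]]],
    residue = toupper(raw[[col_map[["residue"]]]]),
    ptm_type = raw[[col_map[["ptm_type"]]]],
    stringsAsFactors = FALSE
  )
  pos <- suppressWarnings(as.integer(sites$position_raw))
  bad <- is.na(pos) | pos < 1 | pos != suppressWarnings(as.numeric(sites$position_raw))
  if (any(bad)) {
    warning(sprintf("rejected %d PTM row(s) with non-integer position: %s",
                    sum(bad),
                    paste(utils::head(sites$position_raw[bad], 5),
                          collapse = ", ")))
  }
  rejected <- sites[bad, , drop = FALSE]
  sites <- sites[!bad, , drop = FALSE]
  sites$position <- pos[!bad]
  dup <- duplicated(sites[, c("accession", "position", "ptm_type")])
  sites <- sites[!dup, c("accession", "position", "residue", "ptm_type")]
  sites$status <- rep(NA_character_, nrow(sites))
  rownames(sites) <- NULL
  attr(sites, "rejected") <- rejected
  sites
}

#' Validate PTM sites against a reference sequence
#'
#' A site is `valid` iff the reference sequence carries the stated residue
#' type at the stated position. Mismatches are flagged `residue_mismatch`
#' and positions beyond the sequence `unmapped`; both are excluded from the
#' downstream proximity search but retained (never silently dropped).
#'
#' @param sites PTM site data.frame (one accession).
#' @param ref_seq reference sequence for that accession.
#' @return `sites` with `status` filled in; exclusion counts are reported
#'   via [message()] and in `attr(, "n_excluded")`.
#' @export
validate_sites <- function(sites, ref_seq) {
  if (length(unique(sites$accession)) > 1) {
    stop("validate_sites expects sites of a single accession")
  }
  letters_ref <- strsplit(toupper(ref_seq), "")[[1]]
  n <- length(letters_ref)
  status <- character(nrow(sites))
  inside <- sites$position >= 1 & sites$position <= n
  status[!inside] <- "unmapped"
  ok <- inside
  match_ok <- ok & letters_ref[pmin(sites$position, n)] == sites$residue
  status[ok & match_ok] <- "valid"
  status[ok & !match_ok] <- "residue_mismatch"
  sites$status <- status
  n_excl <- sum(status != "valid")
  if (n_excl > 0) {
    message(sprintf(
      "excluded %d PTM site(s): %d residue mismatch, %d beyond sequence",
      n_excl, sum(status == "residue_mismatch"), sum(status == "unmapped")
    ))
  }
  attr(sites, "n_excluded") <- n_excl
  sites
}

.empty_proximal_df <- function() {
  data.frame(
    accession = character(), position = integer(), residue = character(),
    ptm_type = character(), comp_id = character(), lig_chain = character(),
    lig_resno = integer(), chain = character(), resno = integer(),
    insert = character(), min_distance = numeric(),
    stringsAsFactors = FALSE
  )
}

# Grid (cell-list) nearest-neighbour distances: for each query point, the
# minimum distance to any target point, exact whenever that minimum is
# <= cutoff (cells are cutoff-sized, so only the 27 neighbouring cells can
# hold a target within cutoff). Returns Inf where no target lies within
# cutoff. Contract (and test oracle) is the all-pairs scan.
.min_dist_within <- function(query, target, cutoff) {
  stopifnot(ncol(query) == 3, ncol(target) == 3, cutoff > 0)
  origin <- apply(target, 2, min) - cutoff
  cell_of <- function(m) {
    ic <- floor(sweep(m, 2, origin) / cutoff)
    paste(ic[, 1], ic[, 2], ic[, 3], sep = ",")
  }
  ict <- floor(sweep(target, 2, origin) / cutoff)
  tkey <- paste(ict[, 1], ict[, 2], ict[, 3], sep = ",")
  buckets <- split(seq_len(nrow(target)), tkey)
  icq <- floor(sweep(query, 2, origin) / cutoff)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- rep(Inf, nrow(query))
  for (q in seq_len(nrow(query))) {
    neigh <- sweep(offs, 2, icq[q, ], `+`)
    keys <- paste(neigh[, 1], neigh[, 2], neigh[, 3], sep = ",")
    idx <- unlist(buckets[keys], use.names = FALSE)
    if (length(idx) == 0) next
    d2 <- colSums((t(target[idx, , drop = FALSE]) - query[q, ])^2)
    out[q] <- sqrt(min(d2))
  }
  out[out > cutoff] <- Inf
  out
}

#' Find PTM sites proximal to a ligand instance
#'
#' A validated site is proximal iff the minimum distance over all (site
#' residue heavy atom, ligand heavy atom) pairs is at most `cutoff`
#' (boundary inclusive). The site's reference position is mapped onto the
#' structure through a [map_chain_to_reference()] residue map; sites whose
#' mapped residue has no coordinates are skipped with a message.
#'
#' @param s reference `Structure`.
#' @param lig a `LigandInstance` from [extract_ligands()].
#' @param sites validated PTM sites (rows with `status != "valid"` are
#'   ignored).
#' @param rmap `ResidueMap` linking the structure chain to the sites'
#'   accession.
#' @param cutoff proximity cutoff in Angstrom (default 10).
#' @return data.frame with one row per proximal site: site fields plus
#'   `comp_id`, `lig_chain`, `lig_resno`, `chain`, `resno`, `insert`,
#'   `min_distance`.
#' @export
find_proximal_ptms <- function(s, lig, sites, rmap, cutoff = 10.0) {
  if (nrow(lig$atoms) == 0) stop("ligand instance has no atoms")
  if ("status" %in% names(sites)) {
    sites <- sites[!is.na(sites$status) & sites$status == "valid", ,
                   drop = FALSE]
  }
  empty <- .empty_proximal_df()
  if (nrow(sites) == 0) return(empty)
  hit <- match(sites$position, rmap$ref_pos)
  unmapped <- is.na(hit)
  if (any(unmapped)) {
    message(sprintf("%d site(s) have no mapped structure residue; skipped",
                    sum(unmapped)))
  }
  sites <- sites[!unmapped, , drop = FALSE]
  hit <- hit[!unmapped]
  if (nrow(sites) == 0) return(empty)

  prot <- s$atoms[!s$atoms$is_hetero, , drop = FALSE]
  uid <- residue_uid(prot)
  want_uid <- paste(rmap$chain[hit], rmap$resno[hit], rmap$insert[hit],
                    sep = "|")
  have_coords <- want_uid %in% uid
  if (any(!have_coords)) {
    message(sprintf("%d site(s) map to residues without coordinates; skipped",
                    sum(!have_coords)))
    sites <- sites[have_coords, , drop = FALSE]
    hit <- hit[have_coords]
    want_uid <- want_uid[have_coords]
  }
  if (nrow(sites) == 0) return(empty)

  keep_atoms <- uid %in% want_uid
  qa <- prot[keep_atoms, , drop = FALSE]
  qxyz <- as.matrix(qa[, c("x", "y", "z")])
  lxyz <- as.matrix(lig$atoms[, c("x", "y", "z")])
  dmin_atom <- .min_dist_within(qxyz, lxyz, cutoff)
  dmin_res <- tapply(dmin_atom, residue_uid(qa), min)
  md <- as.numeric(dmin_res[want_uid])
  proximal <- is.finite(md) & md <= cutoff
  out <- data.frame(
    accession = sites$accession, position = sites$position,
    residue = sites$residue, ptm_type = sites$ptm_type,
    comp_id = lig$comp_id, lig_chain = lig$copy_key$chain,
    lig_resno = lig$copy_key$resno,
    chain = rmap$chain[hit], resno = rmap$resno[hit],
    insert = rmap$insert[hit], min_distance = md,
    stringsAsFactors = FALSE
  )[proximal, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse an ECOD-style domain range string
#'
#' Range strings such as `"A:12-150,A:200-240"` become one segment per
#' comma-separated piece. A piece without an explicit chain inherits none.
#'
#' @param range_string range specification.
#' @return data.frame with `chain`, `start`, `end`.
#' @export
parse_domain_ranges <- function(range_string) {
  pieces <- trimws(strsplit(range_string, ",")[[1]])
  pieces <- pieces[nzchar(pieces)]
  if (length(pieces) == 0) stop("empty domain range string")
  segs <- lapply(pieces, function(p) {
    m <- regmatches(p, regexec("^(?:([A-Za-z0-9]+):)?(-?\\d+)-(-?\\d+)$", p))[[1]]
    if (length(m) == 0) stop("cannot parse domain range piece: ", p)
    data.frame(chain = ifelse(nzchar(m[2]), m[2], NA_character_),
               start = as.integer(m[3]), end = as.integer(m[4]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  if (any(out$start > out$end)) stop("domain segment with start > end")
  out
}

#' Read a domain-range table
#'
#' TSV with columns `domain_id`, `accession`, `range` (an ECOD-style range
#' string interpreted in reference-sequence coordinates).
#'
#' @param path TSV file path.
#' @return list of domains, each `domain_id`, `accession`, `segments`.
#' @export
read_domain_table <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(raw)), function(i) {
    list(domain_id = raw$domain_id[i], accession = raw$accession[i],
         segments = parse_domain_ranges(raw$range[i]))
  })
}

#' Assign PTM sites to domain ranges
#'
#' A site is assigned to every domain whose segments contain its reference
#' position; sites contained by more than one domain are assigned to all,
#' with the ambiguity reported via [message()].
#'
#' @param sites PTM site data.frame (needs `accession`, `position`).
#' @param domains list of domains from [read_domain_table()].
#' @return data.frame with one row per (site, domain) assignment plus one
#'   `domain_id = NA` row per unassigned site.
#' @export
map_sites_to_domains <- function(sites, domains) {
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    acc <- sites$accession[i]
    pos <- sites$position[i]
    hits <- vapply(domains, function(d) {
      d$accession == acc && any(pos >= d$segments$start & pos <= d$segments$end)
    }, logical(1))
    ids <- vapply(domains[hits], `[[`, character(1), "domain_id")
    if (length(ids) > 1) {
      message(sprintf("site %s:%d inside %d overlapping domains (%s)",
                      acc, pos, length(ids), paste(ids, collapse = ", ")))
    }
    if (length(ids) == 0) ids <- NA_character_
    data.frame(accession = acc, position = pos, domain_id = ids,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
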