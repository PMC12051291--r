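# Global pairwise alignment used for (a) chain -> reference-sequence
# renumbering and (b) residue correspondence before superposition.

.blosum62_cache <- new.env(parent = emptyenv())

#' Default substitution matrix (BLOSUM62, unknowns scored 0)
#'
#' BLOSUM62 with all entries involving `X` set to zero, so positions of
#' unknown type neither reward nor penalize the alignment.
#'
#' @return numeric substitution matrix.
#' @export
default_substitution_matrix <- function() {
  if (is.null(.blosum62_cache$m)) {
    m <- get(utils::data("BLOSUM62", package = "Biostrings",
                         envir = environment()))
    m["X", ] <- 0
    m[, "X"] <- 0
    .blosum62_cache$m <- m
  }
  .blosum62_cache$m
}

#' Read an NCBI-format substitution matrix file
#'
#' Parses the plain-text layout used by BLAST matrix files: `#` comment
#' lines, a header row of column letters, then one row per letter.
#'
#' @param path matrix file path.
#' @return numeric matrix with letter dimnames.
#' @export
load_substitution_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- scan(text = lines[1], what = character(), quiet = TRUE)
  rows <- lapply(lines[-1], function(ln) {
    scan(text = ln, what = character(), quiet = TRUE)
  })
  m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(header))))
  rownames(m) <- vapply(rows, `[`, character(1), 1)
  colnames(m) <- header
  if (!isTRUE(all.equal(m[colnames(m), colnames(m)],
                        t(m[colnames(m), colnames(m)])))) {
    warning("substitution matrix is not symmetric")
  }
  m
}

.clean_seq <- function(x, matrix_letters) {
  x <- toupper(x)
  letters_in <- strsplit(x, "")[[1]]
  unknown <- !(letters_in %in% matrix_letters)
  if (any(unknown)) {
    message(sprintf("%d unknown letter(s) treated as X: %s",
                    sum(unknown), paste(unique(letters_in[unknown]),
                                        collapse = ", ")))
    letters_in[unknown] <- "X"
  }
  paste(letters_in, collapse = "")
}

#' Global pairwise sequence alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment under a substitution matrix and affine gap
#' penalties (a gap of length L costs `gap_open + L * gap_extend`,
#' terminal gaps included). Letters absent from the matrix are treated as
#' `X` with zero substitution score. Defaults are the standard BLOSUM62
#' pairing (11/1).
#'
#' @param a,b amino-acid sequences (character scalars).
#' @param matrix substitution matrix; default [default_substitution_matrix()].
#' @param gap_open,gap_extend affine gap penalties (positive numbers).
#' @return list of class `AlignmentResult`: `aligned_a`, `aligned_b` (gapped
#'   strings), `score`, `pairs` (n x 2 matrix of 1-based matched positions),
#'   `identity` (fraction of matched positions with equal non-X letters).
#' @export
global_align <- function(a, b, matrix = default_substitution_matrix(),
                         gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  letters_m <- rownames(matrix)
  a <- .clean_seq(a, letters_m)
  b <- .clean_seq(b, letters_m)
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  ga <- as.character(Biostrings::alignedPattern(pa))
  gb <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  pos_a <- cumsum(ca != "-")
  pos_b <- cumsum(cb != "-")
  matched <- ca != "-" & cb != "-"
  pairs <- cbind(pos_a = pos_a[matched], pos_b = pos_b[matched])
  ident <- if (nrow(pairs) == 0) 0 else {
    mean(ca[matched] == cb[matched] & ca[matched] != "X")
  }
  structure(
    list(aligned_a = ga, aligned_b = gb, score = Biostrings::score(pa),
         pairs = pairs, identity = ident),
    class = "AlignmentResult"
  )
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat(sprintf("AlignmentResult: score %.1f, %d matched positions, identity %.3f\n",
              x$score, nrow(x$pairs), x$identity))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Map chain residues to reference-sequence numbering
#'
#' Aligns the observed chain sequence against a reference (UniProt-style)
#' sequence and records, for every chain residue, the matched reference
#' position and whether the letters agree. Chains aligning below the
#' identity floor are rejected as probable chimeras or wrong references.
#'
#' @param chain_seq output of [chain_sequence()].
#' @param ref_seq reference sequence (character scalar).
#' @param identity_floor minimum alignment identity (default 0.30).
#' @param ... passed to [global_align()].
#' @return data.frame of class `ResidueMap`: one row per chain residue, with
#'   `chain`, `resno`, `insert`, `chain_pos`, `ref_pos` (NA if unmapped),
#'   `chain_letter`, `ref_letter`, `identical`, `status` in
#'   \{mapped, unmapped\}. Alignment identity stored in `attr(, "identity")`.
#' @export
map_chain_to_reference <- function(chain_seq, ref_seq, identity_floor = 0.30,
                                   ...) {
  aln <- global_align(chain_seq$seq, ref_seq, ...)
  if (aln$identity < identity_floor) {
    stop(sprintf(
      "alignment identity %.2f below floor %.2f: chain is a probable chimera or mismatched reference",
      aln$identity, identity_floor
    ))
  }
  idx <- chain_seq$index
  ref_letters <- strsplit(toupper(ref_seq), "")[[1]]
  map <- data.frame(
    chain = idx$chain, resno = idx$resno, insert = idx$insert,
    chain_pos = idx$pos, ref_pos = NA_integer_,
    chain_letter = idx$letter, ref_letter = NA_character_,
    stringsAsFactors = FALSE
  )
  map$ref_pos[aln$pairs[, "pos_a"]] <- aln$pairs[, "pos_b"]
  mapped <- !is.na(map$ref_pos)
  map$ref_letter[mapped] <- ref_letters[map$ref_pos[mapped]]
  map$identical <- mapped & map$chain_letter == map$ref_letter &
    map$chain_letter != "X"
  map$status <- ifelse(mapped, "mapped", "unmapped")
  attr(map, "identity") <- aln$identity
  class(map) <- c("ResidueMap", "data.frame")
  map
}
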