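# Independent oracles and small fixture builders shared across tests.

# --- brute-force global alignment score ------------------------------------
# Maximum over all monotone matchings (= sets of aligned columns) of the
# substitution scores minus affine gap costs, with unmatched stretches
# between consecutive columns arranged as single contiguous gap runs (the
# cheapest arrangement under affine penalties). Enumerates every matching;
# no dynamic programming, so it is independent of the aligner under test.
bf_align_score <- function(a, b, mat, gap_open, gap_extend) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- mat[A, B, drop = FALSE]
  gapcost <- function(len) if (len > 0) gap_open + gap_extend * len else 0
  env <- new.env()
  env$best <- -Inf
  rec <- function(i, j, acc) {
    total <- acc - gapcost(n - i) - gapcost(m - j)
    if (total > env$best) env$best <- total
    if (i < n && j < m) {
      for (ii in (i + 1):n) {
        for (jj in (j + 1):m) {
          rec(ii, jj, acc - gapcost(ii - i - 1) - gapcost(jj - j - 1) +
                S[ii, jj])
        }
      }
    }
  }
  rec(0L, 0L, 0)
  env$best
}

# toy substitution matrix over a letter set
toy_matrix <- function(letters_set = c("A", "G", "S", "T", "X"),
                       match = 1, mismatch = 0) {
  k <- length(letters_set)
  m <- matrix(mismatch, k, k, dimnames = list(letters_set, letters_set))
  diag(m) <- match
  m["X", ] <- 0
  m[, "X"] <- 0
  m
}

# --- quaternion (Horn) rigid-fit RMSD --------------------------------------
# Closed-form maximum eigenvalue of the 4x4 key matrix; independent of the
# SVD route used by kabsch().
quat_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  S <- crossprod(Qc, Pc)
  K <- matrix(c(
    S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2],
    S[3, 1] - S[1, 3], S[1, 2] - S[2, 1],
    S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3],
    S[1, 2] + S[2, 1], S[3, 1] + S[1, 3],
    S[3, 1] - S[1, 3], S[1, 2] + S[2, 1],
    -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2],
    S[1, 2] - S[2, 1], S[3, 1] + S[1, 3],
    S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE)$values)
  sqrt(max((sum(Pc^2) + sum(Qc^2) - 2 * lambda) / nrow(P), 0))
}

# --- all-pairs minimum distances -------------------------------------------
# O(N*M) scan; per query point, min distance to any target, Inf if > cutoff.
allpairs_min_within <- function(query, target, cutoff) {
  out <- vapply(seq_len(nrow(query)), function(i) {
    sqrt(min(colSums((t(target) - query[i, ])^2)))
  }, numeric(1))
  out[out > cutoff] <- Inf
  out
}

# --- structure builders ------------------------------------------------------
# A residue's worth of atom rows at given coordinates.
atom_row <- function(elety, resid, resno, x, y, z, chain = "A",
                     type = "ATOM", elesy = substr(elety, 1, 1),
                     insert = "", o = 1) {
  data.frame(type = type, elety = elety, resid = resid, chain = chain,
             resno = resno, insert = insert, x = x, y = y, z = z, o = o,
             elesy = elesy, stringsAsFactors = FALSE)
}

# Minimal complex for interface tests: protein CB-only residues plus one
# ligand, all at caller-chosen coordinates.
mini_complex <- function(prot_xyz, lig_xyz, lig_names = NULL,
                         lig_el = NULL, prot_letters = NULL) {
  np <- nrow(prot_xyz)
  if (is.null(prot_letters)) prot_letters <- rep("ALA", np)
  rows <- do.call(rbind, lapply(seq_len(np), function(i) {
    atom_row("CB", prot_letters[i], i, prot_xyz[i, 1], prot_xyz[i, 2],
             prot_xyz[i, 3])
  }))
  nl <- nrow(lig_xyz)
  if (is.null(lig_names)) lig_names <- paste0("C", seq_len(nl))
  if (is.null(lig_el)) lig_el <- rep("C", nl)
  lig_rows <- atom_row(lig_names, "LIG", 900L, lig_xyz[, 1], lig_xyz[, 2],
                       lig_xyz[, 3], type = "HETATM", elesy = lig_el)
  new_structure(rbind(rows, lig_rows), id = "mini")
}

# a bare LigandInstance from coordinates
mini_ligand <- function(xyz, names_ = NULL, el = NULL, comp_id = "LIG") {
  n <- nrow(xyz)
  if (is.null(names_)) names_ <- paste0("C", seq_len(n))
  if (is.null(el)) el <- rep("C", n)
  structure(
    list(comp_id = comp_id,
         copy_key = list(chain = "A", resno = 900L, insert = ""),
         atoms = data.frame(name = names_, elesy = el, x = xyz[, 1],
                            y = xyz[, 2], z = xyz[, 3],
                            stringsAsFactors = FALSE)),
    class = "LigandInstance"
  )
}

random_rotation_matrix <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  R <- qr.Q(qr(M))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
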