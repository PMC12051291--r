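# Kabsch fit, atom correspondence and iterative refinement.

test_that("kabsch recovers exact rigid transforms", {
  set.seed(1)
  P <- matrix(rnorm(30), ncol = 3)
  fit0 <- kabsch(P, P)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit0$translation, rep(0, 3), tolerance = 1e-9)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)

  R0 <- random_rotation_matrix()
  t0 <- c(3, -2, 7)
  Q <- P %*% t(R0) + matrix(t0, nrow(P), 3, byrow = TRUE)
  fit <- kabsch(P, Q)
  expect_equal(fit$rotation %*% R0, diag(3), tolerance = 1e-6)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  # applying the fit maps Q back onto P
  expect_equal(apply_transform(Q, fit$rotation, fit$translation), P,
               tolerance = 1e-9)
})

test_that("kabsch RMSD matches the quaternion solver on random clouds", {
  set.seed(2)
  for (k in 1:25) {
    n <- sample(4:20, 1)
    P <- matrix(rnorm(3 * n), ncol = 3)
    Q <- matrix(rnorm(3 * n), ncol = 3)
    expect_equal(kabsch(P, Q)$rmsd, quat_rmsd(P, Q), tolerance = 1e-9)
  }
})

test_that("degenerate inputs are refused or flagged", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_warning(kabsch(line, line), "degenerate")
})

test_that("atom correspondence pairs by name within scope", {
  fx <- make_toy_complex(fixture_spec(n_residues = 12, seed = 3),
                         dir = tempfile())
  ref <- fx$structure
  aln <- global_align(chain_sequence(ref, "A")$seq,
                      chain_sequence(ref, "A")$seq)
  corr <- build_atom_correspondence(ref, ref, aln, "A", "A", scope = "heavy")
  expect_equal(nrow(corr$P), sum(!ref$atoms$is_hetero))

  # CA-only scope pairs one atom per aligned residue
  corr_ca <- build_atom_correspondence(ref, ref, aln, "A", "A",
                                       scope = "calpha")
  expect_equal(nrow(corr_ca$P), 12)

  # dropping one side-chain atom from the mobile reduces pairs accordingly
  mob <- ref
  drop_row <- which(!mob$atoms$is_hetero & mob$atoms$resno == 5 &
                      mob$atoms$elety == "CB")
  mob$atoms <- mob$atoms[-drop_row, ]
  corr2 <- build_atom_correspondence(ref, mob, aln, "A", "A", scope = "heavy")
  expect_equal(nrow(corr2$P), nrow(corr$P) - 1)
})

test_that("refinement is a no-op on rigid copies", {
  fx <- make_toy_complex(fixture_spec(n_residues = 25, seed = 4),
                         dir = tempfile())
  mv <- make_model_variant(fx$structure, list(type = "rigid"), seed = 9)
  sup <- align_refine(fx$structure, mv$structure)
  expect_lt(sup$final_rmsd, 1e-6)
  expect_equal(sup$n_rejected, 0)
  expect_equal(sup$cycles$n_pairs, sup$pairs_initial) # non-increasing, here constant
  # orthonormal proper rotation
  expect_equal(t(sup$rotation) %*% sup$rotation, diag(3), tolerance = 1e-9)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-6)
  # superposing a structure onto itself leaves coordinates unchanged
  self_sup <- align_refine(fx$structure, fx$structure)
  expect_lt(max(abs(as.matrix(self_sup$model$atoms[, c("x", "y", "z")]) -
                      as.matrix(fx$structure$atoms[, c("x", "y", "z")]))),
            1e-9)
})

test_that("a displaced residue is rejected within the cycle budget", {
  fx <- make_toy_complex(fixture_spec(n_residues = 30, seed = 5),
                         dir = tempfile())
  mv <- make_model_variant(fx$structure,
                           list(type = "residue_kick", index = 7, d = 20),
                           seed = 1)
  sup <- align_refine(fx$structure, mv$structure)
  expect_lte(max(sup$cycles$cycle), 5)
  expect_equal(unique(sup$rejected$resno), 7)
  expect_equal(sup$n_rejected, 5)   # all five atoms of the residue
  expect_lt(sup$final_rmsd, 0.1)
  # retained pair counts never increase across cycles
  expect_true(all(diff(sup$cycles$n_pairs) <= 0))
})

test_that("domain-restricted superposition isolates a hinge motion", {
  fx <- make_toy_complex(fixture_spec(n_residues = 40, seed = 6),
                         dir = tempfile())
  mv <- make_model_variant(fx$structure,
                           list(type = "hinge", angle = 35,
                                pivot_residue = 21), seed = 1)
  whole <- align_refine(fx$structure, mv$structure)
  restricted <- align_refine(fx$structure, mv$structure,
                             restrict_to = list(parse_domain_ranges("A:1-20")))
  expect_gt(whole$final_rmsd, 1)
  expect_lt(restricted$final_rmsd, 1e-3)
})

test_that("the fit is equivariant under pre-transforms of the mobile", {
  fx <- make_toy_complex(fixture_spec(n_residues = 20, seed = 8),
                         dir = tempfile())
  mv <- make_model_variant(fx$structure, list(type = "jitter", sigma = 0.4),
                           seed = 3)
  base <- align_refine(fx$structure, mv$structure)
  set.seed(10)
  for (k in 1:3) {
    moved <- apply_transform(mv$structure, random_rotation_matrix(),
                             runif(3, -30, 30))
    sup <- align_refine(fx$structure, moved)
    expect_equal(sup$final_rmsd, base$final_rmsd, tolerance = 1e-6)
  }
})

test_that("final RMSD is least-squares optimal on the retained set", {
  fx <- make_toy_complex(fixture_spec(n_residues = 20, seed = 9),
                         dir = tempfile())
  mv <- make_model_variant(fx$structure,
                           list(type = "residue_kick", index = 3, d = 12),
                           seed = 1)
  sup <- align_refine(fx$structure, mv$structure)
  # rebuild the retained pair set and compare against the initial fit
  aln <- global_align(chain_sequence(fx$structure, "A")$seq,
                      chain_sequence(mv$structure, "A")$seq)
  corr <- build_atom_correspondence(fx$structure, mv$structure, aln, "A", "A")
  init <- kabsch(corr$P, corr$Q)
  rejected_uid <- paste(sup$rejected$resno, sup$rejected$elety)
  kept <- !(paste(corr$meta$resno, corr$meta$elety) %in% rejected_uid)
  dev_init <- sqrt(rowSums((corr$P - apply_transform(
    corr$Q, init$rotation, init$translation))^2))
  rmsd_init_on_kept <- sqrt(mean(dev_init[kept]^2))
  expect_lte(sup$final_rmsd, rmsd_init_on_kept + 1e-12)
})
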