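# Interface selection and the lDDT-PLI score.

test_that("the piecewise scoring function reproduces its defining cases", {
  expect_identical(threshold_score(0.3), 1)
  expect_identical(threshold_score(0.7), 0.8)
  expect_identical(threshold_score(1.5), 0.6)
  expect_identical(threshold_score(3.0), 0.4)
  expect_identical(threshold_score(5.0), 0)
  # lower bounds are inclusive
  expect_identical(threshold_score(c(0.5, 1.0, 2.0, 4.0)),
                   c(0.8, 0.6, 0.4, 0))
  expect_error(threshold_score(-0.1), "non-negative")
})

test_that("interface atoms are those within the inclusive cutoff", {
  lig_xyz <- rbind(c(0, 0, 0), c(1.4, 0, 0))
  prot_xyz <- rbind(
    c(-3, 0, 0), c(0, 3.5, 0), c(1.4, -4, 0), c(4.4, 3, 0),  # 3-4.3 A
    c(0, 0, 10), c(20, 0, 0)                                  # >= 8 A
  )
  s <- mini_complex(prot_xyz, lig_xyz)
  lig <- extract_ligands(s)[[1]]
  iface <- select_interface_atoms(s, lig, cutoff = 5)
  expect_equal(nrow(iface), 6)
  expect_equal(sum(iface$role == "protein"), 4)
  expect_equal(sum(iface$role == "ligand"), 2)

  # exactly 5.0 A is included
  s2 <- mini_complex(rbind(c(-5, 0, 0), c(30, 0, 0)),
                     matrix(c(0, 0, 0), 1))
  iface2 <- select_interface_atoms(s2, extract_ligands(s2)[[1]], cutoff = 5)
  expect_equal(sum(iface2$role == "protein"), 1)

  # unbound ligand is an error
  s3 <- mini_complex(matrix(c(-20, 0, 0), 1), matrix(c(0, 0, 0), 1))
  expect_error(select_interface_atoms(s3, extract_ligands(s3)[[1]]),
               "empty interface")
})

test_that("an identical model scores exactly 1", {
  fx <- make_toy_complex(fixture_spec(n_residues = 20, seed = 2),
                         dir = tempfile())
  score <- lddt_pli(fx$structure, fx$structure, "LIG")
  expect_identical(score$score, 1)
  expect_true(all(score$ledger$delta == 0))
  expect_equal(score$score, mean(score$per_atom$f_mean), tolerance = 1e-12)
})

test_that("a three-atom toy system matches the hand computation", {
  ref <- mini_complex(rbind(c(3, 0, 0), c(0, 4, 0)),
                      matrix(c(0, 0, 0), 1))
  model <- mini_complex(rbind(c(3.7, 0, 0), c(0, 5.5, 0)),
                        matrix(c(0, 0, 0), 1))
  # d_ref = {3, 4, 5}; d_pred = {3.7, 5.5, 6.6287}; deltas 0.7, 1.5, 1.6287
  # f = {0.8, 0.6, 0.6}; per-atom means {0.7, 0.6, 0.7}; score = 2/3
  score <- lddt_pli(ref, model, "LIG")
  expect_equal(score$n_atoms, 3)
  expect_equal(sort(score$ledger$f), c(0.6, 0.6, 0.8))
  expect_equal(score$score, 2 / 3, tolerance = 1e-12)
})

test_that("a far-displaced ligand scores zero on every contact pair", {
  fx <- make_toy_complex(fixture_spec(n_residues = 20, seed = 3),
                         dir = tempfile())
  mv <- make_model_variant(fx$structure,
                           list(type = "ligand_shift", d = 10,
                                direction = c(0, 0, 1)), seed = 1)
  score <- lddt_pli(fx$structure, mv$structure, "LIG")
  roles <- score$per_atom$role
  cross <- score$ledger[roles[score$ledger$i] != roles[score$ledger$j], ]
  expect_true(all(cross$delta >= 4))
  expect_true(all(cross$f == 0))
  # ligand-contacts-only mode scores exactly these pairs
  score_pl <- lddt_pli(fx$structure, mv$structure, "LIG",
                       include_intra = FALSE)
  expect_identical(score_pl$score, 0)
})

test_that("the score is invariant to rigid motion of the model", {
  fx <- make_toy_complex(fixture_spec(n_residues = 20, seed = 4),
                         dir = tempfile())
  mv <- make_model_variant(fx$structure, list(type = "jitter", sigma = 0.5),
                           seed = 2)
  base <- lddt_pli(fx$structure, mv$structure, "LIG")
  set.seed(5)
  for (k in 1:3) {
    moved <- apply_transform(mv$structure, random_rotation_matrix(),
                             runif(3, -50, 50))
    expect_equal(lddt_pli(fx$structure, moved, "LIG")$score, base$score,
                 tolerance = 1e-12)
  }
  # per-atom means are averages of the five f levels and stay in [0, 1]
  expect_true(all(base$ledger$f %in% c(1, 0.8, 0.6, 0.4, 0)))
  expect_true(all(base$per_atom$f_mean >= 0 & base$per_atom$f_mean <= 1))
})

test_that("increasing coordinate noise degrades the median score", {
  fx <- make_toy_complex(fixture_spec(n_residues = 20, seed = 6),
                         dir = tempfile())
  med <- vapply(c(0.05, 0.3, 1.5), function(sigma) {
    stats::median(vapply(1:20, function(k) {
      mv <- make_model_variant(fx$structure,
                               list(type = "jitter", sigma = sigma),
                               seed = 1000 + k)
      lddt_pli(fx$structure, mv$structure, "LIG")$score
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) <= 0))
  expect_lt(med[3], med[1])
})

test_that("missing correspondents error in strict mode and drop in lenient", {
  ref <- mini_complex(rbind(c(3, 0, 0), c(0, 4, 0)),
                      matrix(c(0, 0, 0), 1))
  # model lacks the second residue entirely
  model <- mini_complex(matrix(c(3, 0, 0), 1), matrix(c(0, 0, 0), 1))
  expect_error(lddt_pli(ref, model, "LIG", strict = TRUE), "correspondent")
  expect_message(score <- lddt_pli(ref, model, "LIG", strict = FALSE),
                 "dropped")
  expect_equal(score$n_atoms, 2)
})
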