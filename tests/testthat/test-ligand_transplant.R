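# Ligand transplantation: chain selection, eligibility, placement, gates.

test_that("best-matching donor chain selection and the ligand-count tie-break", {
  set.seed(101)
  pair <- make_donor_pair(n = 24, seed = 17,
                          ligands = list(list(anchor = 8, offset = c(4, 0, 0)),
                                         list(anchor = 16, offset = c(0, 4, 0))),
                          duplicate_chain = TRUE)
  # chains A and B have identical sequences; A carries 2 ligands, B carries 1
  expect_setequal(unique(pair$donor$residues$chain), c("A", "B"))
  expect_equal(select_best_chain(pair$ai, pair$donor), "A")

  single <- make_donor_pair(n = 15, seed = 19)
  expect_equal(select_best_chain(single$ai, single$donor), "A")
})

test_that("a chain of the right protein beats a chain of a different protein", {
  set.seed(111)
  ai <- make_helix(20)
  # chain A: unrelated sequence (poly-GLY); chain B: matching poly-ALA
  a <- make_helix(20, model_type = "homology")
  a$atoms$resname <- "GLY"
  b_atoms <- make_helix(20, model_type = "homology")$atoms
  b_atoms$chain <- "B"
  b_atoms[, c("x", "y", "z")] <- b_atoms[, c("x", "y", "z")] + 50
  donor <- structure_model(rbind(a$atoms, b_atoms), "homology",
                           accession = "SYNTH")
  expect_equal(select_best_chain(ai, donor), "B")
})

test_that("eligibility excludes non-small-molecules and uncontacted ligands", {
  set.seed(121)
  pair <- make_donor_pair(n = 20, seed = 23)
  donor <- pair$donor
  ca <- ca_coords(donor)
  mk <- function(het, center, resno) {
    list(het_id = het, chain = "A", resno = resno, icode = "",
         atoms = structrefine:::pseudo_ligand_atoms(center, 4, het, "A", resno),
         category = structrefine:::categorize_het(het))
  }
  donor$ligands <- c(donor$ligands,
                     list(mk("DA", ca[5, ] + c(4, 0, 0), 910),
                          mk("ALA", ca[8, ] + c(4, 0, 0), 911),
                          mk("FLT", ca[12, ] + c(30, 0, 0), 912)))
  el <- eligible_ligands(donor, "A")
  expect_equal(vapply(el$eligible, `[[`, character(1), "het_id"), "LIG")
  expect_equal(el$excluded$reason[el$excluded$het_id == "DA"],
               "excluded_category")
  expect_equal(el$excluded$reason[el$excluded$het_id == "ALA"],
               "excluded_category")
  expect_equal(el$excluded$reason[el$excluded$het_id == "FLT"],
               "no_donor_contact")
})

test_that("self-transplant reproduces donor ligand coordinates exactly", {
  set.seed(131)
  pair <- make_donor_pair(n = 25, seed = 29,
                          ligands = list(list(anchor = 8, offset = c(4, 0, 0)),
                                         list(anchor = 13, offset = c(0, 4.2, 0)),
                                         list(anchor = 19, offset = c(-4, 1, 0))))
  res <- transplant_all(pair$ai, pair$donor)
  expect_equal(res$report$outcome, rep("transplanted", 3))
  expect_true(all(res$report$best_rmsd < 1e-8))
  for (k in 1:3) {
    placed <- as.matrix(res$model$ligands[[k]]$atoms[, c("x", "y", "z")])
    expect_equal(placed, pair$ground_truth[[k]], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("a rigidly transformed donor lands ligands on the ground truth", {
  set.seed(141)
  rot <- structrefine:::random_rotation()
  pair <- make_donor_pair(n = 28, seed = 31, rotation = rot,
                          translation = c(12, -7, 4))
  res <- transplant_all(pair$ai, pair$donor)
  expect_equal(res$report$outcome, "transplanted")
  placed <- as.matrix(res$model$ligands[[1]]$atoms[, c("x", "y", "z")])
  expect_lt(max(abs(placed - pair$ground_truth[[1]])), 1e-6)
})

test_that("transplantation is equivariant under rigid motion of the acceptor", {
  set.seed(151)
  pair <- make_donor_pair(n = 22, seed = 37)
  rot <- structrefine:::random_rotation()
  tra <- c(-4, 9, 2)
  moved_ai <- structrefine:::rigid_transform_model(pair$ai, rot, tra)
  res0 <- transplant_all(pair$ai, pair$donor)
  res1 <- transplant_all(moved_ai, pair$donor)
  expect_equal(res1$report$outcome, "transplanted")
  lig0 <- as.matrix(res0$model$ligands[[1]]$atoms[, c("x", "y", "z")])
  lig1 <- as.matrix(res1$model$ligands[[1]]$atoms[, c("x", "y", "z")])
  expect_lt(max(abs(structrefine:::apply_rigid(lig0, rot, tra) - lig1)), 1e-6)
})

test_that("acceptor protein coordinates are never modified", {
  set.seed(161)
  pair <- make_donor_pair(n = 20, seed = 41)
  before <- pair$ai$atoms
  res <- transplant_all(pair$ai, pair$donor)
  expect_identical(res$model$atoms, before)
})

test_that("the RMSD gate accepts deformations below 7 A and rejects above", {
  set.seed(171)
  # small protein so a 15 A site around the central ligand spans every
  # residue and the site fit sees the whole rigid-orthogonal deformation
  pair <- make_donor_pair(n = 14, seed = 43)
  policy <- transplant_policy(radii = 15, strategies = "sequence")
  for (case in list(list(mag = 6.5, outcome = "transplanted"),
                    list(mag = 7.5, outcome = "rmsd_gate_failed"))) {
    donor <- orthogonal_deform(pair$donor, case$mag)
    lig <- donor$ligands[[1]]
    res <- transplant_ligand(pair$ai, donor, "A", lig, policy)
    expect_equal(res$outcome, case$outcome,
                 info = sprintf("magnitude %.1f", case$mag))
    expect_equal(res$best_rmsd, case$mag, tolerance = 0.05)
  }
})

test_that("lowering the gate never enlarges the transplanted set", {
  set.seed(181)
  pair <- make_donor_pair(n = 20, seed = 47)
  donor <- orthogonal_deform(pair$donor, 3)
  prev <- NULL
  for (gate in c(10, 5, 2, 0.5)) {
    policy <- transplant_policy(rmsd_max = gate, strategies = "sequence")
    res <- transplant_all(pair$ai, donor, policy)
    n <- sum(res$report$outcome == "transplanted")
    if (!is.null(prev)) expect_lte(n, prev)
    prev <- n
  }
})

test_that("clash screening deletes overlapping ligands and keeps clean ones", {
  m <- make_helix(20)
  ca <- ca_coords(m)
  prot <- as.matrix(m$atoms[, c("x", "y", "z")])
  one_atom_lig <- function(het, dist, resno) {
    dir <- c(1, 0, 0)
    gap <- function(s) oracle_min_dist(matrix(ca[10, ] + dir * s, 1, 3),
                                       prot) - dist
    s <- uniroot(gap, c(0, 60), tol = 1e-10)$root
    p <- ca[10, ] + dir * s
    list(het_id = het, chain = "A", resno = resno, icode = "",
         atoms = data.frame(serial = 1L, name = "C1", resname = het,
                            chain = "A", resno = resno, icode = "",
                            x = p[1], y = p[2], z = p[3], occ = 1, b = 0,
                            element = "C", stringsAsFactors = FALSE),
         category = "small_molecule")
  }
  m$ligands <- list(one_atom_lig("CLS", 1.2, 920),
                    one_atom_lig("OKY", 3.0, 921))
  out <- clash_screen(m)
  expect_equal(vapply(out$ligands, `[[`, character(1), "het_id"), "OKY")
  expect_equal(attr(out, "clashed"), "CLS")

  clean <- clash_screen(make_helix(10))
  expect_equal(length(clean$ligands), 0L)
})

test_that("minimizer hook runs between placement and screening, errors surface", {
  set.seed(191)
  pair <- make_donor_pair(n = 18, seed = 53)
  # identity hook: copies the complex through an external command
  res <- transplant_all(pair$ai, pair$donor, minimizer_hook = "cp {in} {out}")
  expect_equal(res$report$outcome, "transplanted")
  expect_equal(length(res$model$ligands), 1L)
  expect_error(
    transplant_all(pair$ai, pair$donor, minimizer_hook = "false {in} {out}"),
    "minimizer hook failed")
})

test_that("donor without ligands yields an empty report and unchanged model", {
  ai <- make_helix(15)
  donor <- make_helix(15, model_type = "homology")
  res <- transplant_all(ai, donor)
  expect_equal(nrow(res$report), 0L)
  expect_identical(res$model$atoms, ai$atoms)
  expect_error(transplant_all(structure_model(ai$atoms, "alphafold2",
                                              accession = "OTHER"),
                              donor), "accession")
})
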