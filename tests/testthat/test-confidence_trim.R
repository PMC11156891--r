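# Windowed pLDDT trimming and geometric pruning of detached segments.

test_that("window averaging truncates at chain termini", {
  expect_equal(window_average_plddt(rep(80, 10), 3), rep(80, 10))
  prof <- c(60, 60, 60, 80, 80, 80, 80)
  expect_equal(window_average_plddt(prof, 3)[4], 500 / 7)
  prof2 <- c(50, 90, 90, 90, 90, 90, 90, 90)
  expect_equal(window_average_plddt(prof2, 3)[1], (50 + 90 * 3) / 4)
  expect_error(window_average_plddt(numeric(0), 3), "empty")
})

test_that("the removal threshold is strict", {
  expect_true(flag_low_confidence(69.99, 70))
  expect_false(flag_low_confidence(70.00, 70))
  expect_equal(sum(flag_low_confidence(rep(100, 20), 70)), 0)
})

test_that("segment partition yields maximal retained runs", {
  m <- make_helix(20)
  mask <- rep(FALSE, 20); mask[5:8] <- TRUE
  segs <- segment_partition(m, mask)
  expect_equal(length(segs), 2L)
  expect_equal(c(segs[[1]]$start_index, segs[[1]]$end_index), c(1, 4))
  expect_equal(c(segs[[2]]$start_index, segs[[2]]$end_index), c(9, 20))

  expect_equal(length(segment_partition(m, rep(FALSE, 20))), 1L)
  expect_equal(length(segment_partition(m, rep(TRUE, 20))), 0L)
})

test_that("detached segments are pruned against the core with one bridging hop", {
  # far fragment, no bridge: removed
  f <- make_trim_fixture(30, c(rep(90, 18), rep(50, 4), rep(90, 8)),
                         detach = list(list(range = 23:30, distance = 12)))
  tr <- trim_model(f)
  expect_equal(tr$report$removed_by_geometry, 23:30)

  # hand-placed single-atom segments with exact gaps: core (6 residues,
  # x = 0..5), bridge 8 A from the core, outer fragment 4 A from the bridge
  # and 14 A from the core -> the one-hop rule keeps the outer fragment
  xs <- c(0:5, 13:15, 19:20)
  atoms <- data.frame(serial = seq_along(xs), name = "CA", resname = "ALA",
                      chain = "A", resno = seq_along(xs), icode = "",
                      x = xs, y = 0, z = 0, occ = 1, b = 90, element = "C",
                      stringsAsFactors = FALSE)
  m3 <- structure_model(atoms, "alphafold2")
  segs3 <- list(list(chain = "A", start_index = 1, end_index = 6),
                list(chain = "A", start_index = 7, end_index = 9),
                list(chain = "A", start_index = 10, end_index = 11))
  pr3 <- geometric_prune(m3, segs3)
  expect_equal(length(pr3$kept), 3L)

  # without the bridge, the outer fragment is >10 A from the core: removed
  m4 <- structure_model(atoms[c(1:6, 10:11), ], "alphafold2")
  segs4 <- list(list(chain = "A", start_index = 1, end_index = 6),
                list(chain = "A", start_index = 7, end_index = 8))
  pr4 <- geometric_prune(m4, segs4)
  expect_equal(length(pr4$removed), 1L)
  expect_equal(pr4$removed[[1]]$start_index, 7)

  # but the hop is not iterated: a chain core -8- s1 -4- s2 -4- s3 keeps s2
  # (s1 bridges) and removes s3 (s2 is not itself within 10 A of the core)
  xs5 <- c(0:5, 13:14, 18:19, 23:24)
  atoms5 <- data.frame(serial = seq_along(xs5), name = "CA", resname = "ALA",
                       chain = "A", resno = seq_along(xs5), icode = "",
                       x = xs5, y = 0, z = 0, occ = 1, b = 90, element = "C",
                       stringsAsFactors = FALSE)
  m5 <- structure_model(atoms5, "alphafold2")
  segs5 <- list(list(chain = "A", start_index = 1, end_index = 6),
                list(chain = "A", start_index = 7, end_index = 8),
                list(chain = "A", start_index = 9, end_index = 10),
                list(chain = "A", start_index = 11, end_index = 12))
  pr5 <- geometric_prune(m5, segs5)
  removed_starts <- vapply(pr5$removed, function(s) as.numeric(s$start_index),
                           numeric(1))
  expect_equal(removed_starts, 11)

  # single segment is its own core
  one <- geometric_prune(make_helix(10), list(list(chain = "A",
                                                   start_index = 1,
                                                   end_index = 10)))
  expect_equal(length(one$kept), 1L)
  expect_equal(length(one$removed), 0L)
})

test_that("two-lobe-low-linker fixture loses exactly the hand-derived linker set", {
  f <- make_trim_fixture(28, "two-lobe-low-linker")
  # profile: 10x90, 8x50, 10x90; +/-3 window means averages dip below 70
  # exactly for residues 11..18
  tr <- trim_model(f)
  expect_equal(tr$report$removed_by_plddt, 11:18)
  # whether the second lobe also falls to geometric pruning is decided by
  # its distance to the first (core) lobe; check against the brute-force
  # distance oracle
  xyz <- segment_xyz_list(f, list(list(start_index = 1, end_index = 10),
                                  list(start_index = 19, end_index = 28)))
  lobe_gap <- oracle_min_dist(xyz[[1]], xyz[[2]])
  expected_kept <- if (lobe_gap <= 10) c(1:10, 19:28) else 1:10
  expect_equal(sort(tr$model$residues$resno), expected_kept)
})

test_that("trimming is pure deletion and survivors pass the window criterion", {
  f <- make_trim_fixture(40, c(rep(90, 16), rep(40, 6), rep(85, 18)))
  tr <- trim_model(f)
  kept_resno <- tr$model$residues$resno
  orig_atoms <- f$atoms[f$atoms$resno %in% kept_resno, c("x", "y", "z")]
  expect_equal(as.matrix(tr$model$atoms[, c("x", "y", "z")]),
               as.matrix(orig_atoms), ignore_attr = TRUE)
  avg <- window_average_plddt(f$residues$plddt, 3)
  expect_true(all(avg[kept_resno] >= 70))

  # confident model passes through untouched
  hi <- make_helix(25, bfactor = 90)
  tr2 <- trim_model(hi)
  expect_equal(nrow(tr2$model$residues), 25L)
  expect_equal(length(tr2$report$removed_by_plddt), 0L)
})

test_that("raising the threshold never enlarges the retained set", {
  set.seed(404)
  for (i in 1:20) {
    prof <- runif(30, 40, 100)
    f <- make_trim_fixture(30, prof)
    kept_prev <- NULL
    for (thr in c(50, 70, 90)) {
      tr <- trim_model(f, trim_policy(plddt_threshold = thr, min_residues = 1))
      kept <- if (is.null(tr$model)) integer(0) else tr$model$residues$resno
      if (!is.null(kept_prev)) expect_true(all(kept %in% kept_prev))
      kept_prev <- kept
    }
  }
})

test_that("models falling below the survival threshold are dropped", {
  # an 11-residue confident block flanked by low confidence erodes by one
  # residue per edge under the +/-3 window, leaving 9 survivors: dropped
  f9 <- make_trim_fixture(42, c(rep(20, 15), rep(95, 11), rep(20, 16)))
  tr9 <- trim_model(f9)
  expect_equal(sum(!seq_len(42) %in% tr9$report$removed_by_plddt), 9L)
  expect_true(tr9$report$model_dropped)
  expect_null(tr9$model)

  # a 12-residue block leaves exactly 10 survivors: kept
  f10 <- make_trim_fixture(44, c(rep(20, 15), rep(95, 12), rep(20, 17)))
  tr10 <- trim_model(f10)
  expect_false(tr10$report$model_dropped)
  expect_equal(nrow(tr10$model$residues), 10L)
})

test_that("trimming requires per-residue confidence", {
  hm <- make_helix(12, model_type = "homology")
  expect_error(trim_model(hm), "pLDDT")
})

test_that("ligand retention keeps only ligands within the contact distance", {
  m <- make_helix(20)
  ca <- ca_coords(m)
  base <- make_helix(20)
  # exact contact distances, one atom each
  one_atom <- function(center, resno) {
    data.frame(serial = 1L, name = "C1", resname = "LIG", chain = "A",
               resno = resno, icode = "", x = center[1], y = center[2],
               z = center[3], occ = 1, b = 0, element = "C",
               stringsAsFactors = FALSE)
  }
  prot <- as.matrix(base$atoms[, c("x", "y", "z")])
  dir <- c(1, 0, 0)
  # place single-atom ligands at exact minimum distances 4.9 and 6.0
  place_at <- function(dist) {
    gap <- function(s) {
      p <- matrix(ca[10, ] + dir * s, 1, 3)
      oracle_min_dist(p, prot) - dist
    }
    s <- uniroot(gap, c(0, 60), tol = 1e-10)$root
    ca[10, ] + dir * s
  }
  base$ligands <- list(
    list(het_id = "NEA", chain = "A", resno = 901, icode = "",
         atoms = one_atom(place_at(4.9), 901), category = "small_molecule"),
    list(het_id = "FAR", chain = "A", resno = 902, icode = "",
         atoms = one_atom(place_at(6.0), 902), category = "small_molecule"))
  out <- ligand_retention_filter(base)
  expect_equal(vapply(out$ligands, `[[`, character(1), "het_id"), "NEA")
  expect_equal(attr(out, "ligands_dropped"), "FAR")

  # no ligands: unchanged
  plain <- ligand_retention_filter(m)
  expect_equal(length(plain$ligands), 0L)
})

test_that("geometric pruning agrees with the brute-force oracle on random fixtures", {
  set.seed(2024)
  n_agree <- 0L
  n_trials <- 300L
  for (trial in seq_len(n_trials)) {
    rs <- random_segment_model()
    pr <- geometric_prune(rs$model, rs$segments)
    kept_pkg <- vapply(pr$kept, function(s) s$start_index, integer(1))
    keep_oracle <- oracle_prune_keep(segment_xyz_list(rs$model, rs$segments),
                                     rs$sizes, rs$starts)
    kept_orc <- rs$starts[keep_oracle]
    expect_equal(sort(kept_pkg), sort(kept_orc),
                 info = sprintf("trial %d", trial))
    n_agree <- n_agree + identical(sort(kept_pkg), sort(kept_orc))
  }
  expect_equal(n_agree, n_trials)
})

test_that("trimming is deterministic", {
  f <- make_trim_fixture(35, c(rep(88, 12), rep(45, 7), rep(92, 16)),
                         detach = list(list(range = 28:35, distance = 11)))
  a <- trim_model(f)
  b <- trim_model(f)
  expect_identical(a, b)
})
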