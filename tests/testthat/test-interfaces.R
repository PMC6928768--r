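test_that("contact cutoff is a sharp boundary on heavy-atom distance", {
  near <- list(one_atom_subunit("A", 0, 0, 0), one_atom_subunit("B", 4.4, 0, 0))
  far <- list(one_atom_subunit("A", 0, 0, 0), one_atom_subunit("B", 4.6, 0, 0))
  p_near <- find_interfaces(near, contact_criterion(4.5))
  expect_length(p_near, 1)
  expect_equal(p_near[[1]]$residues_i$resno, 1)
  expect_equal(p_near[[1]]$residues_j$resno, 1)
  expect_length(find_interfaces(far, contact_criterion(4.5)), 0)
  # hydrogens are ignored by default
  h <- list(one_atom_subunit("A", 0, 0, 0, element = "H"),
            one_atom_subunit("B", 1, 0, 0))
  expect_length(find_interfaces(h, contact_criterion(4.5)), 0)
  expect_error(find_interfaces(list()), "empty")
})

test_that("cell-list contact search is identical to the all-pairs search", {
  set.seed(31)
  for (rep in 1:100) {
    ni <- sample(3:40, 1); nj <- sample(3:40, 1)
    xi <- matrix(stats::runif(ni * 3, 0, 15), ni)
    xj <- matrix(stats::runif(nj * 3, 0, 15), nj)
    cutoff <- stats::runif(1, 1, 6)
    a <- contact_pairs(xi, xj, cutoff, method = "grid")
    b <- contact_pairs(xi, xj, cutoff, method = "brute")
    expect_identical(a[order(a[, 1], a[, 2]), , drop = FALSE],
                     b[order(b[, 1], b[, 2]), , drop = FALSE])
  }
})

test_that("interface listing is symmetric and order independent", {
  set.seed(5)
  xa <- matrix(stats::runif(30, 0, 8), 10)
  xb <- matrix(stats::runif(30, 0, 8), 10)
  sa <- bead_subunit("A", xa); sb <- bead_subunit("B", xb)
  p1 <- find_interfaces(list(sa, sb))[[1]]
  p2 <- find_interfaces(list(sb, sa))[[1]]
  # residue r of A lists r' of B iff r' of B lists r of A
  for (k in seq_len(nrow(p1$residues_i))) {
    r <- p1$residues_i$resno[k]
    for (rp in p1$residues_i$partners[[k]]) {
      j <- which(p1$residues_j$resno == as.integer(rp))
      expect_true(as.character(r) %in% p1$residues_j$partners[[j]])
    }
  }
  expect_setequal(p1$residues_i$resno, p2$residues_j$resno)
  expect_setequal(p1$residues_j$resno, p2$residues_i$resno)
})

test_that("toy capsid interfaces are exactly the planted residues", {
  fam <- toy_family_cached()
  asm <- assemble_capsid(fam$members[[1]]$au, generate_group())
  pairs <- find_interfaces(asm, focus = c("A1", "B1", "C1"))
  for (cl in c("A", "B", "C")) {
    expect_identical(interface_residue_union(pairs, cl),
                     as.integer(fam$truth$interface))
  }
  # union semantics: duplicates collapse, empty input yields empty set
  expect_identical(interface_residue_union(c(pairs, pairs), "A"),
                   as.integer(fam$truth$interface))
  expect_length(interface_residue_union(list(), "A"), 0)
})

test_that("interfaces classify by the symmetry fold of the relating operator", {
  g <- generate_group()
  r2z <- rotation_about(c(0, 0, 1), pi)
  # chain A bead near the z 2-fold axis (far enough from it that A cannot
  # touch its own image); chain B bead next to A's 2-fold image, so the B
  # copy generated by the z 2-fold lands beside A1 across that axis — the
  # cross-class dimer geometry of a 2-fold interface
  a_bead <- c(2.8 * cos(0.3), 2.8 * sin(0.3), 46)
  b_bead <- as.numeric(r2z %*% a_bead) + c(0.2, 0.15, 0.1)
  au <- new_asym_unit(list(bead_subunit("A", matrix(a_bead, 1)),
                           bead_subunit("B", matrix(b_bead, 1))), "fold")
  asm <- assemble_capsid(au, g)
  pairs <- find_interfaces(asm, focus = c("A1"))
  cross <- Filter(function(p)
    substr(p$subunit_i, 1, 1) != substr(p$subunit_j, 1, 1), pairs)
  expect_true(length(cross) >= 1)
  expect_true(all(vapply(cross, `[[`, "", "fold_class") == "2-fold"))
  # same-class 2-fold dimer: one A bead close enough to its own 2-fold image
  a2 <- c(1.9 * cos(0.3), 1.9 * sin(0.3), 46)
  asm2 <- assemble_capsid(new_asym_unit(list(bead_subunit("A", matrix(a2, 1))),
                                        "fold2"), g)
  p2 <- find_interfaces(asm2, focus = "A1")
  expect_true(length(p2) >= 1)
  expect_true(all(vapply(p2, `[[`, "", "fold_class") == "2-fold"))
  # self-interface is rejected
  expect_error(classify_interface_fold(list(subunit_i = "A1", subunit_j = "A1"),
                                       asm), "self")
})

test_that("quasi-equivalent (intra-unit) contacts are tagged quasi", {
  # chains A and B side by side inside one asymmetric-unit copy, far from
  # any symmetry axis: related by the identity, so no fold applies
  g <- generate_group()
  u <- c(sin(36 * pi / 180) * cos(8 * pi / 180),
         sin(36 * pi / 180) * sin(8 * pi / 180), cos(36 * pi / 180))
  au <- new_asym_unit(list(bead_subunit("A", matrix(50 * u, 1)),
                           bead_subunit("B", matrix(50 * u + c(3, 0, 0), 1))),
                      "quasi")
  asm <- assemble_capsid(au, g)
  pairs <- find_interfaces(asm, focus = c("A1"))
  ab <- Filter(function(p) setequal(c(p$subunit_i, p$subunit_j), c("A1", "B1")),
               pairs)
  expect_length(ab, 1)
  expect_identical(ab[[1]]$fold_class, "quasi")
})
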