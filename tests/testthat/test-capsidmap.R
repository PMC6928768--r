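test_that("angular projection follows the spherical convention", {
  expect_equal(project_point(c(0, 0, 10)), data.frame(phi = 0, psi = 0))
  expect_equal(project_point(c(7, 7, 0)), data.frame(phi = 45, psi = 90))
  expect_equal(project_point(c(-1, 0, 0))$phi, -180)  # phi lives in [-180, 180)
  expect_error(project_point(c(0, 0, 0)), "center")
  # radial invariance
  expect_equal(project_point(c(2, 3, 6)), project_point(10 * c(2, 3, 6)))
  # joint rotation about z shifts phi by exactly the rotation angle
  set.seed(21)
  for (rep in 1:20) {
    v <- stats::rnorm(3); v[3] <- abs(v[3]) + 0.5
    ang <- stats::runif(1, -180, 180)
    rz <- rotation_about(c(0, 0, 1), ang * pi / 180)
    p0 <- project_point(v)
    p1 <- project_point(as.numeric(rz %*% v))
    expect_equal(p1$psi, p0$psi, tolerance = 1e-9)
    dphi <- (p1$phi - p0$phi - ang) %% 360
    expect_lt(min(dphi, 360 - dphi), 1e-9)
  }
})

test_that("capsid map has one point per interface residue and respects symmetry", {
  fam <- toy_family_cached()
  au <- fam$members[[1]]$au
  iface <- stats::setNames(rep(list(fam$truth$interface), 3), c("A", "B", "C"))
  map <- build_capsidmap(au, iface)
  expect_equal(nrow(map$points), 3 * length(fam$truth$interface))
  # full-capsid point cloud: projecting every symmetry copy of the unit gives
  # a point set invariant under any group operator (the operator permutes the
  # copies)
  g <- generate_group()
  all_angles <- function(start_op) {
    pts <- lapply(seq_along(g$operators), function(k) {
      op <- g$operators[[k]] %*% start_op
      au_k <- new_asym_unit(list(bead_subunit(
        "A", as.matrix(au$subunits[[1]]$atoms[fam$truth$interface, c("x", "y", "z")]) %*% t(op))),
        "rot")
      build_capsidmap(au_k, list(A = seq_along(fam$truth$interface)))$points[, c("phi", "psi")]
    })
    m <- round(as.matrix(do.call(rbind, pts)), 5)
    m[order(m[, 1], m[, 2]), ]
  }
  expect_equal(all_angles(diag(3)), all_angles(g$operators[[13]]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("strict conservation finds exactly the invariant gap-free columns", {
  a1 <- new_alignment_set(c(x = "ACD", y = "ACD", z = "ACD"))
  expect_identical(conserved_columns(a1)$columns, 1:3)
  a2 <- new_alignment_set(c(x = "ACD", y = "AED", z = "ACD"))
  cc <- conserved_columns(a2)
  expect_identical(cc$columns, c(1L, 3L))
  expect_identical(cc$residue_numbers$x, c(1L, 3L))
  # gapped columns are never conserved, and gaps shift author numbering
  a3 <- new_alignment_set(c(x = "A-CD", y = "AACD", z = "AACD"))
  cc3 <- conserved_columns(a3, offsets = c(x = 5L, y = 1L, z = 1L))
  expect_identical(cc3$columns, c(1L, 3L, 4L))
  expect_identical(cc3$residue_numbers$x, c(5L, 6L, 7L))
  expect_identical(cc3$residue_numbers$y, c(1L, 3L, 4L))
  # toy family: planted conserved columns recovered exactly
  fam <- toy_family_cached()
  aln <- new_alignment_set(vapply(fam$members, `[[`, "", "sequence"))
  expect_identical(conserved_columns(aln)$columns,
                   as.integer(fam$truth$seq_conserved))
})

test_that("map alignment applies the angular overlap threshold sharply", {
  ref <- map_from_points("r", data.frame(chain = "A", resno = 1:2,
                                         phi = c(10, 50), psi = c(40, 60)))
  mk <- function(dphi, dpsi = 0) {
    map_from_points("m", data.frame(chain = "A", resno = 1:2,
                                    phi = c(10 + dphi, 50), psi = c(40 + dpsi, 60)))
  }
  corr <- list(r = 1:2, m = 1:2)
  hit <- function(m) align_maps(list(r = ref, m = m), corr)$resno
  expect_identical(hit(mk(0)), 1:2)           # identical maps fully conserved
  expect_true(1 %in% hit(mk(2.9)))            # inside the 3-degree overlap
  expect_false(1 %in% hit(mk(3.1)))           # outside it
  expect_false(1 %in% hit(mk(0, 3.1)))        # threshold applies to both angles
  # wrap-around: -179 and +179 degrees are 2 degrees apart
  r2 <- map_from_points("r", data.frame(chain = "A", resno = 1, phi = -179, psi = 90))
  m2 <- map_from_points("m", data.frame(chain = "A", resno = 1, phi = 179, psi = 90))
  expect_identical(align_maps(list(r = r2, m = m2), list(r = 1, m = 1))$resno, 1)
  # monotone in the threshold
  set.seed(3)
  noisy <- map_from_points("m", data.frame(chain = "A", resno = 1:2,
                                           phi = c(10, 50) + stats::runif(2, -4, 4),
                                           psi = c(40, 60) + stats::runif(2, -4, 4)))
  c3 <- align_maps(list(r = ref, m = noisy), corr, angle_threshold = 3)$resno
  c4 <- align_maps(list(r = ref, m = noisy), corr, angle_threshold = 4)$resno
  expect_true(all(c3 %in% c4))
  # chains are compared class-wise
  other_chain <- map_from_points("m", data.frame(chain = "B", resno = 1:2,
                                                 phi = c(10, 50), psi = c(40, 60)))
  expect_length(align_maps(list(r = ref, m = other_chain), corr)$resno, 0)
  # guards
  expect_error(align_maps(list(r = ref), corr), "two")
  bad <- map_from_points("m", data.frame(chain = "A", resno = 1, phi = 0, psi = 0),
                         orientation_tag = "other")
  expect_error(align_maps(list(r = ref, m = bad), corr), "orientation")
})

test_that("a global rotation applied to every map leaves the conserved set unchanged", {
  fam <- toy_family_cached()
  res0 <- run_prediction(fam$members)
  maps <- attr(res0, "maps")
  shift <- function(m, d) { m$points$phi <- ((m$points$phi + d + 180) %% 360) - 180; m }
  aln <- new_alignment_set(vapply(fam$members, `[[`, "", "sequence"))
  corr <- msa_residue_map(aln)
  s0 <- align_maps(maps, corr)
  s1 <- align_maps(lapply(maps, shift, d = 117), corr)
  expect_identical(s1$resno, s0$resno)
  expect_identical(s1$chain, s0$chain)
})

test_that("hot spots are the three-way intersection, independent of member order", {
  iface <- list(v1 = c(5L, 9L, 14L, 21L), v2 = c(5L, 9L, 14L, 21L))
  hs <- predict_hotspots(iface, seq_conserved = c(3L, 9L, 14L),
                         space_conserved = c(9L, 14L, 21L), reference = "v1")
  expect_identical(hs$hot_spots$resno, c(9L, 14L))
  # every hot spot belongs to each of the three sets
  expect_true(all(hs$hot_spots$resno %in% hs$interface_sets$v1))
  expect_true(all(hs$hot_spots$resno %in% hs$sequence_conserved))
  expect_true(all(hs$hot_spots$resno %in% hs$space_conserved))
  # no sequence conservation, no hot spots
  empty <- predict_hotspots(iface, integer(0), c(9L, 14L), reference = "v1")
  expect_identical(nrow(empty$hot_spots), 0L)
  # member order does not matter when the reference is fixed
  hs_rev <- predict_hotspots(rev(iface), c(3L, 9L, 14L), c(9L, 14L, 21L),
                             reference = "v1")
  expect_identical(hs_rev$hot_spots, hs$hot_spots)
})
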