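# Pore geometry, contacts, distances and superposition.

test_that("structure round-trips through PDB with altloc/hydrogen handling", {
  toy <- gen_toy_pentamer(ring_z = c(0, 6, 12), ring_radius = 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(toy$structure, f)
  s <- read_structure(f)
  expect_s3_class(s, "Structure3D")
  expect_equal(nrow(s$atoms), 15L)  # 3 rings x 5 chains
  expect_equal(sort(unique(s$atoms$chain)), LETTERS[1:5])
  expect_equal(s$atoms$element, rep("C", 15))
  coords_in <- as.matrix(toy$structure$atoms[c("x", "y", "z")])
  ord <- order(s$atoms$chain, s$atoms$resno)
  ord_in <- order(toy$structure$atoms$chain, toy$structure$atoms$resno)
  expect_equal(as.matrix(s$atoms[ord, c("x", "y", "z")]),
               coords_in[ord_in, ], ignore_attr = TRUE, tolerance = 1e-3)
  # unknown chain in the role map is an error
  expect_error(read_structure(f, chain_roles = c(Z = "alpha1")), "absent")
})

test_that("altloc resolution keeps the highest-occupancy copy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            "ATOM", 1, " CA", "A", "ALA", "A", 1, 1.0, 0.0, 0.0, 0.60, 0.0, "C"),
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            "ATOM", 2, " CA", "B", "ALA", "A", 1, 9.0, 0.0, 0.0, 0.40, 0.0, "C"),
    "END"), f)
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$x, 1.0)
})

test_that("pore axis recovers the symmetry axis, also under rotation", {
  toy <- gen_toy_pentamer(ring_z = seq(0, 30, by = 6), ring_radius = 5)
  ax <- pore_axis(toy$structure)
  expect_gt(abs(sum(ax$direction * c(0, 0, 1))), cos(pi / 180))  # within 1 degree
  R <- rotation_matrix(c(1, 2, 0.5), 0.8)
  toy_r <- gen_toy_pentamer(ring_z = seq(0, 30, by = 6), ring_radius = 5,
                            rotation = R, translation = c(3, -7, 11))
  ax_r <- pore_axis(toy_r$structure)
  expect_gt(abs(sum(ax_r$direction * toy_r$axis$direction)), cos(pi / 180))
  # a single chain cannot define a pore
  one_chain <- toy$structure
  one_chain$atoms <- one_chain$atoms[one_chain$atoms$chain == "A", ]
  expect_error(pore_axis(one_chain), ">= 3 chains")
})

test_that("pore radii match the analytic C5 profile within 0.05 A", {
  toy <- gen_toy_pentamer(ring_z = seq(0, 24, by = 6),
                          ring_radius = c(5, 5, 3.5, 5, 5))
  prof <- pore_profile(toy$structure, toy$axis, s_values = toy$analytic$z)
  expect_lt(max(abs(prof$steps$radius - toy$analytic$radius)), 0.05)
  # the global minimum sits at the narrow ring
  expect_equal(which.min(prof$steps$radius), 3L)
  expect_lt(abs(min(prof$steps$radius) - (3.5 - 1.70)), 0.05)
})

test_that("pore radii are invariant under rigid motion", {
  z <- seq(0, 24, by = 6); r <- c(5, 4, 3.6, 4.5, 5)
  plain <- gen_toy_pentamer(ring_z = z, ring_radius = r)
  moved <- gen_toy_pentamer(ring_z = z, ring_radius = r,
                            rotation = rotation_matrix(c(0.3, 1, 2), 1.1),
                            translation = c(-20, 5, 8))
  p1 <- pore_profile(plain$structure, plain$axis, s_values = z)
  p2 <- pore_profile(moved$structure, moved$axis, s_values = z)
  expect_lt(max(abs(p2$steps$radius - p1$steps$radius)), 0.05)
})

test_that("blocked and undefined steps are flagged", {
  # mutated middle ring narrowed below the carbon vdW radius: blocked
  toy <- gen_toy_pentamer(ring_z = c(0, 6, 12), ring_radius = c(5, 3.2, 5),
                          mutation_mask = 2L, radius_decrement = 1.4)
  expect_equal(toy$analytic$radius[2], 3.2 - 1.4 - 1.70)  # 0.10 A analytic
  prof <- pore_profile(toy$structure, toy$axis, s_values = c(0, 6, 12))
  expect_equal(prof$steps$radius[2], 0.10, tolerance = 0.05)
  blocked <- gen_toy_pentamer(ring_z = c(0, 6, 12), ring_radius = c(5, 3.2, 5),
                              mutation_mask = 2L, radius_decrement = 1.6)
  prof_b <- pore_profile(blocked$structure, blocked$axis, s_values = c(0, 6, 12))
  expect_true(prof_b$steps$blocked[2])
  expect_equal(prof_b$steps$radius[2], 0)
  # a step far outside the atom slab is undefined
  prof_u <- pore_profile(toy$structure, toy$axis, s_values = c(0, 6, 12, 100))
  expect_true(prof_u$steps$undefined[4])
})

test_that("permeation classification follows the chloride radii", {
  expect_equal(classify_permeation(1.60), "blocked")
  expect_equal(classify_permeation(1.81), "dehydrated-Cl-only")
  expect_equal(classify_permeation(3.55), "hydrated-Cl-passable")
  expect_error(classify_permeation(-0.1), "non-negative")
  # monotone step function of radius
  rr <- seq(0, 5, by = 0.01)
  cls <- classify_permeation(rr)
  lev <- c("blocked", "dehydrated-Cl-only", "hydrated-Cl-passable")
  expect_true(all(diff(match(cls, lev)) >= 0))
  expect_equal(ion_constants(), c(cl_pauling = 1.81, cl_hydrated = 3.2))
})

test_that("profile comparison localizes and orders mutant narrowing", {
  z <- seq(0, 24, by = 6)
  wt <- gen_toy_pentamer(ring_z = z, ring_radius = 5)
  one <- gen_toy_pentamer(ring_z = z, ring_radius = 5, mutation_mask = 3L,
                          radius_decrement = 0.6)
  both <- gen_toy_pentamer(ring_z = z, ring_radius = 5, mutation_mask = 3L,
                           radius_decrement = 1.2)
  pw <- pore_profile(wt$structure, wt$axis, s_values = z)
  p1 <- pore_profile(one$structure, one$axis, s_values = z)
  p2 <- pore_profile(both$structure, both$axis, s_values = z)
  # identical profile: all deltas zero
  d0 <- compare_profiles(pw, pw)
  expect_equal(d0$delta, rep(0, 5))
  expect_false(any(d0$flagged))
  d <- compare_profiles(pw, list(one = p1, both = p2))
  d_one <- d[d$mutant == "one", ]
  expect_equal(which(d_one$flagged), 3L)  # only the mutated ring's step
  expect_equal(d_one$delta[3], -0.6, tolerance = 0.05)
  # monotone narrowing with the number of mutated subunit copies
  d_both <- d[d$mutant == "both", ]
  expect_lt(d_both$delta[3], d_one$delta[3])
  # mismatched steps are an error
  p_short <- pore_profile(wt$structure, wt$axis, s_values = z[1:3])
  expect_error(compare_profiles(pw, p_short), "mismatch")
})

test_that("contact detection follows the distance rules and is symmetric", {
  at <- data.frame(chain = c("A", "B", "B", "C"), resno = c(1L, 1L, 2L, 1L),
                   resname = "RNG", atom = c("C1", "C1", "N1", "O1"),
                   element = c("C", "C", "N", "O"),
                   x = c(0, 3.5, 0, 2.9), y = c(0, 0, 10, 10), z = 0, occ = 1,
                   stringsAsFactors = FALSE)
  s <- structure(list(structure_id = "toy", atoms = at, het = at[0, ],
                      chain_roles = NULL), class = "Structure3D")
  cs <- contacts(s)
  vdw <- cs[cs$type == "vdw", ]
  # carbons 3.5 A apart touch (1.7 + 1.7 + 0.5 = 3.9)
  expect_true(any(vdw$chain_a == "A" & vdw$chain_b == "B" & vdw$resno_b == 1))
  # N-O at 2.9 A is both a vdw contact and a hydrogen bond
  hb <- cs[cs$type == "hbond", ]
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.9)
  expect_true(hb$inter_subunit)
  # carbons 4.2 A apart do not touch
  at2 <- at; at2$x[2] <- 4.2
  s2 <- structure(list(structure_id = "toy", atoms = at2, het = at2[0, ],
                       chain_roles = NULL), class = "Structure3D")
  cs2 <- contacts(s2)
  expect_false(any(cs2$chain_a == "A" & cs2$chain_b == "B" & cs2$resno_b == 1))
  # symmetry: the contact set is invariant under relabelling the pair order
  key1 <- sort(paste(cs$chain_a, cs$resno_a, cs$chain_b, cs$resno_b, cs$type))
  at_rev <- at[rev(seq_len(nrow(at))), ]
  s_rev <- structure(list(structure_id = "toy", atoms = at_rev, het = at[0, ],
                          chain_roles = NULL), class = "Structure3D")
  cs_rev <- contacts(s_rev)
  key2 <- sort(apply(cs_rev[c("chain_a", "resno_a", "chain_b", "resno_b", "type")],
                     1, function(r) {
    ab <- paste(r[1], r[2]); cd <- paste(r[3], r[4])
    if (ab <= cd) paste(ab, cd, r[5]) else paste(cd, ab, r[5])
  }))
  expect_equal(key2, key1)
})

test_that("residue distances honor both conventions", {
  at <- data.frame(chain = c("A", "A", "B", "B"), resno = c(1L, 1L, 2L, 2L),
                   resname = "GLY", atom = c("CA", "CB", "CA", "CB"),
                   element = "C",
                   x = c(0, 1, 7, 6), y = 0, z = 0, occ = 1,
                   stringsAsFactors = FALSE)
  s <- structure(list(structure_id = "toy", atoms = at, het = at[0, ],
                      chain_roles = NULL), class = "Structure3D")
  expect_equal(residue_distance(s, list(chain = "A", resno = 1L),
                                list(chain = "B", resno = 2L), "ca"), 7)
  expect_equal(residue_distance(s, list(chain = "A", resno = 1L),
                                list(chain = "B", resno = 2L), "min-heavy"), 5)
  expect_equal(residue_distance(s, list(chain = "A", resno = 1L),
                                list(chain = "A", resno = 1L), "min-heavy"), 0)
  expect_error(residue_distance(s, list(chain = "A", resno = 1L),
                                list(chain = "Z", resno = 9L), "ca"), "missing")
})

test_that("Kabsch superposition matches the quaternion oracle to 1e-9", {
  set.seed(31)
  for (rep in 1:10) {
    A <- matrix(rnorm(30), 10, 3)
    B <- matrix(rnorm(30), 10, 3)
    k <- kabsch_rmsd(A, B)
    expect_equal(k$rmsd, quaternion_rmsd(A, B), tolerance = 1e-9)
    expect_equal(kabsch_rmsd(B, A)$rmsd, k$rmsd, tolerance = 1e-9)
    expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  }
})

test_that("Kabsch RMSD is zero exactly for rigidly congruent sets", {
  set.seed(5)
  A <- matrix(rnorm(24), 8, 3)
  expect_equal(kabsch_rmsd(A, A)$rmsd, 0, tolerance = 1e-12)
  B <- A %*% t(rotation_matrix(c(1, 1, 1), 2.1)) +
    matrix(rep(c(4, -2, 9), each = 8), 8, 3)
  k <- kabsch_rmsd(A, B)
  expect_equal(k$rmsd, 0, tolerance = 1e-9)
  expect_equal(B %*% k$rotation + matrix(k$translation, 8, 3, byrow = TRUE),
               A, tolerance = 1e-9)
  # a mirrored set is not properly congruent: rmsd stays positive
  M <- A %*% diag(c(-1, 1, 1))
  expect_gt(kabsch_rmsd(A, M)$rmsd, 1e-3)
  expect_error(kabsch_rmsd(A[1:2, ], A[1:2, ]), "3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_rmsd(line, line), "collinear")
})
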