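test_that("a minimal PDB fixture parses with correct coordinates", {
  xyz <- rbind(c(1, 2, 3), c(4, 6, 3))
  path <- write_pdb_fixture(tempfile(fileext = ".pdb"), xyz)
  m <- read_structure(path)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m), 2)
  expect_equal(m$x, c(1, 4))
  expect_equal(m$resno, c(1, 2))
})

test_that("the same content as PDB and mmCIF gives identical models", {
  set.seed(20)
  xyz <- round(helix_coords(12), 3)
  p1 <- write_pdb_fixture(tempfile(fileext = ".pdb"), xyz, chain = "A",
                          resno = 5:16)
  p2 <- write_cif_fixture(tempfile(fileext = ".cif"), xyz, chain = "A",
                          resno = 5:16)
  m1 <- read_structure(p1)
  m2 <- suppressWarnings(read_structure(p2))
  expect_equal(m1$chain, m2$chain)
  expect_equal(m1$resno, m2$resno)
  expect_equal(m1$x, m2$x)
  expect_equal(m1$y, m2$y)
  expect_equal(m1$z, m2$z)
})

test_that("files without protein C-alphas or with odd extensions error", {
  xyz <- rbind(c(0, 0, 0))
  het <- write_pdb_fixture(tempfile(fileext = ".pdb"), xyz, hetatm = TRUE)
  expect_error(read_structure(het), "C-alpha")
  expect_error(read_structure(write_pdb_fixture(tempfile(fileext = ".xyz"),
                                                xyz)), "format")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  # residue 1 has conformers A (occ 0.4, x=0) and B (occ 0.6, x=10)
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 20.00           C",
    "ATOM      2  CA BALA A   1      10.000   0.000   0.000  0.60 20.00           C",
    "END")
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  m <- read_structure(path)
  expect_equal(nrow(m), 1)
  expect_equal(m$x, 10)
})

test_that("superposing a range onto itself is the identity", {
  xyz <- helix_coords(20)
  path <- write_pdb_fixture(tempfile(fileext = ".pdb"), xyz)
  m <- read_structure(path)
  s <- superpose(m, residue_range("A", 1, 20), residue_range("A", 1, 20))
  expect_equal(s$rmsd_A, 0, tolerance = 1e-10)
  expect_equal(s$rotation, diag(3), tolerance = 1e-10)
  expect_equal(s$n_atoms, 20)
})

test_that("a 90-degree rotation about z is recovered exactly", {
  xyz <- helix_coords(15)
  R90 <- rotation_about(c(0, 0, 1), 90)
  rot <- xyz %*% t(R90) + matrix(c(5, -3, 2), 15, 3, byrow = TRUE)
  path <- tempfile(fileext = ".pdb")
  write_pdb_fixture(path, rbind(xyz, rot), chain = c(rep("A", 15), rep("B", 15)),
                    resno = rep(1:15, 2))
  m <- read_structure(path)
  s <- superpose(m, residue_range("B", 1, 15), residue_range("A", 1, 15))
  expect_equal(s$rmsd_A, 0, tolerance = 1e-6)
  expect_equal(rotation_angle(s$rotation), 90, tolerance = 1e-6)
  expect_equal(det(s$rotation), 1, tolerance = 1e-8)
})

test_that("rotation angles follow the trace formula", {
  expect_equal(rotation_angle(diag(3)), 0)
  expect_equal(rotation_angle(rotation_about(c(1, 1, 0), 180)), 180,
               tolerance = 1e-6)
  # trace 2.5 <=> acos(0.75)
  R <- rotation_about(c(0, 0, 1), acos(0.75) * 180 / pi)
  expect_equal(rotation_angle(R), 41.40962, tolerance = 1e-4)
  expect_error(rotation_angle(matrix(1, 3, 3)), "rotation")
  # angle is invariant under transposition (inverse rotation)
  Rr <- rotation_about(c(1, 2, 3), 73)
  expect_equal(rotation_angle(Rr), rotation_angle(t(Rr)))
})

test_that("superposition is optimal and rigid-motion invariant", {
  set.seed(21)
  P <- matrix(rnorm(30), 10, 3)
  Q <- matrix(rnorm(30), 10, 3)
  base <- retarrays:::.kabsch(P, Q)
  # no random rotation beats the SVD optimum (best of 1000 draws)
  rmsd_for <- function(R) {
    Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  best_random <- min(replicate(1000, {
    ax <- rnorm(3); rmsd_for(rotation_about(ax, runif(1, 0, 360)))
  }))
  expect_lte(base$rmsd, best_random + 1e-12)

  # a joint rigid motion of both point sets leaves the rmsd unchanged
  Rg <- rotation_about(c(2, -1, 1), 37)
  shift <- matrix(c(3, 4, 5), 10, 3, byrow = TRUE)
  moved <- retarrays:::.kabsch(P %*% t(Rg) + shift, Q %*% t(Rg) + shift)
  expect_equal(moved$rmsd, base$rmsd, tolerance = 1e-9)

  # the same answer emerges through the model-level interface
  path <- tempfile(fileext = ".pdb")
  xyzr <- round(rbind(P, Q), 3)
  write_pdb_fixture(path, xyzr, chain = c(rep("A", 10), rep("B", 10)),
                    resno = rep(1:10, 2))
  m <- read_structure(path)
  s <- superpose(m, residue_range("A", 1, 10), residue_range("B", 1, 10))
  expect_equal(s$rmsd_A, retarrays:::.kabsch(xyzr[1:10, ], xyzr[11:20, ])$rmsd,
               tolerance = 1e-9)
})

test_that("unmatched residue selections raise a pairing error", {
  xyz <- helix_coords(10)
  path <- write_pdb_fixture(tempfile(fileext = ".pdb"), xyz)
  m <- read_structure(path)
  expect_error(superpose(m, residue_range("A", 1, 2),
                         residue_range("A", 8, 9)),
               "unmatched")
})

test_that("a constructed hinge is measured exactly", {
  # chain A: reference domain (1-30) + moving domain (31-60)
  set.seed(22)
  ref <- helix_coords(30)
  mov <- helix_coords(30) + matrix(c(40, 0, 0), 30, 3, byrow = TRUE)
  A <- rbind(ref, mov)
  # chain B: same molecule, moving domain rotated 10 deg about a hinge
  # point, then the whole chain displaced by a global rigid motion
  hinge_pt <- c(40, 0, 0)
  Rh <- rotation_about(c(0, 1, 0), 10)
  movB <- sweep(sweep(mov, 2, hinge_pt) %*% t(Rh), 2, hinge_pt, "+")
  Rg <- rotation_about(c(1, 1, 1), 25)
  B <- rbind(ref, movB) %*% t(Rg) + matrix(c(100, 50, -20), 60, 3,
                                           byrow = TRUE)
  path <- tempfile(fileext = ".pdb")
  write_pdb_fixture(path, rbind(A, B),
                    chain = c(rep("A", 60), rep("B", 60)),
                    resno = rep(1:60, 2))
  m <- read_structure(path)
  h <- hinge(m, reference_domain = c(1, 30), moving_domain = c(31, 60),
             chain_a = "A", chain_b = "B")
  # tolerances reflect the 3-decimal PDB coordinate field
  expect_equal(h$hinge_angle_deg, 10, tolerance = 1e-4)
  expect_lt(h$reference_rmsd_A, 2e-3)
  # the analytic maximum displacement over the rotated domain
  disp <- unname(sqrt(rowSums((movB - mov)^2)))
  expect_equal(h$max_displacement_A, max(disp), tolerance = 1e-3)
  expect_equal(h$at_residue, 30 + which.max(disp))

  # duplicated chain: zero hinge, zero displacement
  path0 <- tempfile(fileext = ".pdb")
  write_pdb_fixture(path0, rbind(A, A),
                    chain = c(rep("A", 60), rep("B", 60)),
                    resno = rep(1:60, 2))
  h0 <- hinge(read_structure(path0), c(1, 30), c(31, 60), "A", "B")
  expect_equal(h0$hinge_angle_deg, 0, tolerance = 1e-6)
  expect_equal(h0$max_displacement_A, 0, tolerance = 1e-8)
})

test_that("C-alpha distances are Euclidean and symmetric", {
  xyz <- rbind(c(0, 0, 0), c(3, 4, 0))
  path <- write_pdb_fixture(tempfile(fileext = ".pdb"), xyz)
  m <- read_structure(path)
  expect_equal(ca_distance(m, "A", 1, "A", 2), 5)
  expect_equal(ca_distance(m, "A", 2, "A", 1), 5)
  expect_equal(ca_distance(m, "A", 1, "A", 1), 0)
  expect_error(ca_distance(m, "A", 1, "B", 99), "B/99")
})

test_that("measurement reports run per row and tolerate failures", {
  xyz <- rbind(c(0, 0, 0), c(3, 4, 0))
  path <- write_pdb_fixture(tempfile(fileext = ".pdb"), xyz)
  m <- read_structure(path)
  expect_equal(nrow(measure_report(m, list())), 0)
  spec <- list(
    list(name = "d12", type = "distance", chain_a = "A", res_a = 1,
         chain_b = "A", res_b = 2),
    list(name = "bad", type = "distance", chain_a = "Z", res_a = 1,
         chain_b = "A", res_b = 2))
  rep_ <- measure_report(m, spec)
  expect_equal(rep_$value[1], 5)
  expect_equal(rep_$status[1], "ok")
  expect_true(is.na(rep_$value[2]))
  expect_match(rep_$status[2], "Z/1")
  # JSON round trip of the spec file
  sp <- tempfile(fileext = ".json")
  jsonlite::write_json(spec, sp, auto_unbox = TRUE)
  expect_equal(measure_report(m, sp)$value[1], 5)
})
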