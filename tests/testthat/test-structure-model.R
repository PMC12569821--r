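test_that("PDB parsing assigns entity classes from residue names", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00 50.00           C",
    "ATOM      2  C1'  DA B   1       5.000   0.000   0.000  1.00 60.00           C",
    "HETATM    3 MG    MG C   1       9.000   0.000   0.000  1.00 70.00          MG",
    "END"), f)
  m <- parse_structure(f)
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(unname(m$chains[c("A", "B", "C")]), c("protein", "dna", "ion"))
  expect_equal(m$atoms$confidence, c(50, 60, 70))
})

test_that("unknown residues are classed as ligand with a warning", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  C1  XYZ Z   1       0.000   0.000   0.000  1.00 10.00           C",
    "END"), f)
  expect_warning(m <- parse_structure(f), "unknown residue")
  expect_equal(unname(m$chains["Z"]), "ligand")
})

test_that("malformed coordinate lines error with the line number", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00 50.00           C",
    "ATOM      2  CA  GLY A   2       xx.000   0.000  0.000  1.00 50.00           C",
    "END"), f)
  expect_error(parse_structure(f), "line 2")
})

test_that("mmCIF atom_site parsing picks up B_iso as confidence", {
  f <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_fixture",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . SER A 1 206 ? 11.104 6.134 -6.504 1.00 83.40 206 SER A N 1",
    "ATOM 2 O OG . SER A 1 206 ? 12.000 7.000 -5.000 1.00 83.40 206 SER A OG 1",
    "ATOM 3 C CA . SER A 1 206 ? 10.000 6.000 -6.000 1.00 83.40 206 SER A CA 1"),
    f)
  m <- parse_structure(f)
  expect_equal(nrow(m$atoms), 3L)
  expect_true(all(m$atoms$confidence == 83.4))
  expect_equal(mean_plddt(m), 83.4)
})

test_that("write_structure round-trips synthetic models field-by-field", {
  for (m in list(gen_toy_complex(6, 100, seed = 3),
                 gen_bdna("TTGATCAA",
                          place_ions = list(list(strand = "top", index = 2,
                                                 offset = 3))))) {
    f <- tempfile(fileext = ".pdb")
    write_structure(m, f)
    m2 <- parse_structure(f)
    for (col in c("serial", "name", "element", "resname", "chain", "resno")) {
      expect_equal(m2$atoms[[col]], m$atoms[[col]], info = col)
    }
    for (col in c("x", "y", "z", "occupancy", "confidence")) {
      expect_equal(m2$atoms[[col]], m$atoms[[col]], tolerance = 1e-3,
                   info = col)
    }
    expect_equal(m2$chains[names(m$chains)], m$chains)
  }
})

test_that("write_structure rejects bad inputs", {
  m <- gen_toy_complex(0, 50, seed = 1)
  m$atoms$name[1] <- "ABCDE"
  expect_error(write_structure(m, tempfile(fileext = ".pdb")), "4 characters")
  m2 <- gen_toy_complex(0, 50, seed = 1)
  m2$atoms$x[1] <- 123456
  expect_error(write_structure(m2, tempfile(fileext = ".pdb")), "overflow")
  expect_error(structure_model(m2$atoms[0, ]), "empty")
})

test_that("mean pLDDT averages per residue, then over residues", {
  at <- make_atoms(
    atom("N", "N", "GLY", "A", 1, c(0, 0, 0), conf = 80),
    atom("CA", "C", "GLY", "A", 1, c(1, 0, 0), conf = 100),
    atom("N", "N", "ALA", "A", 2, c(2, 0, 0), conf = 70))
  m <- structure_model(at, chains = c(A = "protein"))
  expect_equal(plddt_by_residue(m)$plddt, c(90, 70))
  expect_equal(mean_plddt(m), 80)
  # atom-weighted mean would give (80+100+70)/3 = 83.33; must differ
  expect_false(isTRUE(all.equal(mean_plddt(m), mean(at$confidence))))
})

test_that("mean pLDDT is invariant to atom order and chain relabeling", {
  m <- gen_toy_complex(4, 30, seed = 5)
  m$atoms$confidence <- seq(10, 90, length.out = nrow(m$atoms))
  ref <- mean_plddt(m)
  perm <- m
  set.seed(1)
  perm$atoms <- perm$atoms[sample(nrow(perm$atoms)), ]
  expect_equal(mean_plddt(perm), ref)
  relab <- m
  relab$atoms$chain <- chartr("PD", "XY", relab$atoms$chain)
  names(relab$chains) <- chartr("PD", "XY", names(relab$chains))
  expect_equal(mean_plddt(relab), ref)
})

test_that("single-atom model with zero confidence gives zero", {
  m <- gen_sphere_fixture("C", matrix(0, 1, 3), confidence = 0)
  expect_equal(mean_plddt(m), 0)
})

test_that("superposition recovers exact rigid motions", {
  set.seed(7)
  ref <- matrix(rnorm(30), 10, 3)
  s <- superpose(ref, ref)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(s$rotation, diag(3), tolerance = 1e-8)

  shifted <- sweep(ref, 2, c(5, -2, 1), "-")  # mobile = reference - t
  s2 <- superpose(shifted, ref)
  expect_equal(s2$rmsd, 0, tolerance = 1e-10)
  expect_equal(s2$translation, c(5, -2, 1), tolerance = 1e-8)
})

test_that("noisy rotated clouds are recovered and agree with bio3d", {
  skip_if_not_installed("bio3d")
  set.seed(11)
  ref <- matrix(rnorm(30, sd = 4), 10, 3)
  R <- rotation_matrix(c(1, 2, 0.5), 0.8)
  noise <- matrix(rnorm(30, sd = 0.1), 10, 3)
  mob <- ref %*% R + noise  # rows transformed by t(R') with R' = t(R)
  s <- superpose(mob, ref)
  expect_equal(s$rmsd, 0.1 * sqrt(3), tolerance = 0.5)
  # recovered rotation within 1 degree: angle of R_est %*% R (should be I)
  resid_cos <- (sum(diag(s$rotation %*% t(R))) - 1) / 2
  expect_true(acos(min(1, resid_cos)) < 1 * pi / 180)
  expect_equal(det(s$rotation), 1, tolerance = 1e-8)

  fitted <- bio3d::fit.xyz(fixed = as.vector(t(ref)),
                           mobile = as.vector(t(mob)),
                           fixed.inds = 1:30, mobile.inds = 1:30)
  oracle_rmsd <- sqrt(mean(rowSums((matrix(fitted, 10, 3, byrow = TRUE) -
                                      ref)^2)))
  expect_equal(s$rmsd, oracle_rmsd, tolerance = 1e-6)
})

test_that("superposition is invariant under proper rigid motion of mobile", {
  set.seed(13)
  ref <- matrix(rnorm(24, sd = 3), 8, 3)
  mob <- ref + matrix(rnorm(24, sd = 0.2), 8, 3)
  base <- superpose(mob, ref)$rmsd
  R <- rotation_matrix(c(0, 1, 1), 1.2)
  moved <- sweep(mob %*% t(R), 2, c(10, -4, 2), "+")
  expect_equal(superpose(moved, ref)$rmsd, base, tolerance = 1e-8)
})

test_that("degenerate superposition inputs error", {
  expect_error(superpose(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "degenerate")
})
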