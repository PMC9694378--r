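test_that("read_receptor parses coordinates, filters waters and altLocs", {
  lines <- c(
    pdb_line(1, "N", "ALA", "A", 1, 1.234, 2.345, 3.456, element = "N"),
    pdb_line(2, "CA", "ALA", "A", 1, 4.0, 5.0, 6.0),
    pdb_line(3, "CB", "ALA", "A", 1, 7.5, 8.5, 9.5))
  r <- read_receptor(write_test_pdb(lines))
  expect_equal(nrow(r$atoms), 3)
  expect_equal(r$atoms$x, c(1.234, 4.0, 7.5))
  expect_equal(r$atoms$element, c("N", "C", "C"))

  # waters dropped
  lines2 <- c(lines[1:2],
              pdb_line(3, "O", "HOH", "A", 2, 0, 0, 0, element = "O",
                       het = TRUE))
  expect_equal(nrow(read_receptor(write_test_pdb(lines2))$atoms), 2)

  # altLoc: keep the occ-0.6 A conformer
  lines3 <- c(
    pdb_line(1, "CA", "ALA", "A", 1, 1.0, 0, 0, occ = 0.6, altloc = "A"),
    pdb_line(2, "CA", "ALA", "A", 1, 9.0, 0, 0, occ = 0.4, altloc = "B"))
  r3 <- read_receptor(write_test_pdb(lines3))
  expect_equal(nrow(r3$atoms), 1)
  expect_equal(r3$atoms$x, 1.0)

  expect_error(read_receptor(tempfile()), "cannot read")
  expect_error(read_receptor(write_test_pdb("REMARK nothing")),
               "no ATOM")
})

test_that("read_ligand_poses handles SDF records, scores and errors", {
  poses <- read_ligand_poses(scored_sdf(), score_field = "score")
  expect_length(poses, 2)
  expect_equal(vapply(poses, `[[`, 0, "native_score"), c(1.5, 2.5))
  expect_equal(vapply(poses, `[[`, "", "compound_id"),
               c("cmpdA", "cmpdB"))
  expect_equal(poses[[1]]$pose_id, "cmpdA_1")

  empty <- tempfile(fileext = ".sdf"); writeLines("", empty)
  expect_error(read_ligand_poses(empty), "empty")

  # missing score field: fail by default, NA on request
  expect_error(read_ligand_poses(scored_sdf(), score_field = "nope"),
               "lacks score field")
  p <- read_ligand_poses(scored_sdf(), score_field = "nope",
                         on_missing_score = "na")
  expect_true(all(is.na(vapply(p, `[[`, 0, "native_score"))))
})

test_that("read_ligand_poses parses MOL2 (ethanol: 3 heavy atoms, 2 bonds)", {
  p <- read_ligand_poses(ethanol_mol2())
  expect_length(p, 1)
  expect_equal(nrow(p[[1]]$atoms), 3)
  expect_equal(nrow(p[[1]]$bonds), 2)
  expect_equal(p[[1]]$atoms$element, c("C", "C", "O"))
})

test_that("assign_vdw_radii uses the Bondi table with warn-and-default", {
  a <- atoms_at(c(0, 0, 0), element = "C", vdw = NA_real_)
  expect_equal(assign_vdw_radii(a)$vdw, 1.70)
  a$element <- "N"
  expect_equal(assign_vdw_radii(a)$vdw, 1.55)
  a$element <- "X"
  expect_warning(out <- assign_vdw_radii(a), "unknown element")
  expect_equal(out$vdw, 1.80)
})

test_that("extract_binding_site keeps whole residues within cutoff", {
  rec <- read_receptor(mini_receptor_pdb())
  lig <- structure(list(
    atoms = atoms_at(c(0, 3, 0), is_ligand = TRUE),
    bonds = data.frame(i = integer(), j = integer(), order = integer()),
    compound_id = "L", pose_id = "L_1", native_score = NA_real_),
    class = "ligand_pose")

  # residue minimum distances from (0, 3, 0): res1 ~sqrt(0.8^2)=0.8 at O,
  # compute directly against the brute-force oracle
  d_res <- vapply(1:3, function(r) {
    at <- rec$atoms[rec$atoms$resid == r, ]
    min(sqrt((at$x - 0)^2 + (at$y - 3)^2 + at$z^2))
  }, 0)
  for (cutoff in c(2, 5, 12)) {
    expect_kept <- sum(d_res <= cutoff)
    if (expect_kept == 0) {
      expect_error(extract_binding_site(rec, lig, cutoff),
                   "empty binding site")
    } else {
      site <- extract_binding_site(rec, lig, cutoff)
      expect_equal(length(unique(site$atoms$resid)), expect_kept)
      # whole residues: atom count is a multiple of 4 in this fixture
      expect_equal(nrow(site$atoms) %% 4, 0)
    }
  }

  # monotone in cutoff
  s1 <- extract_binding_site(rec, lig, 4)
  s2 <- extract_binding_site(rec, lig, 8)
  expect_true(all(s1$atoms$serial %in% s2$atoms$serial))

  far <- lig; far$atoms$x <- far$atoms$x + 100
  expect_error(extract_binding_site(rec, far, 5), "empty binding site")
})

test_that("assemble_complex is additive, pure and never moves atoms", {
  rec <- read_receptor(mini_receptor_pdb())
  lig <- structure(list(
    atoms = atoms_at(rbind(c(0, 3, 0), c(1, 3, 0)), is_ligand = TRUE),
    bonds = data.frame(i = 1L, j = 2L, order = 1L),
    compound_id = "L", pose_id = "L_1", native_score = NA_real_),
    class = "ligand_pose")
  rec_before <- rec$atoms
  cpx <- assemble_complex(rec, lig)
  expect_equal(nrow(complex_atoms(cpx)), nrow(rec$atoms) + 2)
  expect_equal(rec$atoms, rec_before)  # inputs not mutated
  # coordinates unchanged
  expect_equal(complex_atoms(cpx)[, c("x", "y", "z")],
               rbind(rec$atoms, lig$atoms)[, c("x", "y", "z")],
               ignore_attr = TRUE)
  # serials unique after re-indexing
  expect_false(anyDuplicated(complex_atoms(cpx)$serial) > 0)
  cpx2 <- assemble_complex(rec, lig)
  expect_identical(cpx, cpx2)
})

test_that("PDB round-trip preserves atom count and coordinates", {
  rec <- read_receptor(mini_receptor_pdb())
  out <- tempfile(fileext = ".pdb")
  write_pdb(rec, out)
  back <- read_receptor(out)
  expect_equal(nrow(back$atoms), nrow(rec$atoms))
  expect_equal(back$atoms[, c("x", "y", "z")],
               rec$atoms[, c("x", "y", "z")], tolerance = 1e-3)
})
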