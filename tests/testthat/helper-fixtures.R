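# Fixtures are built in code at test time; no binary files.

# quick bare atom table for SASA-level tests (carbon-like by default)
atoms_at <- function(xyz, element = "C", vdw = 1.7, is_ligand = FALSE) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  data.frame(serial = seq_len(n), name = paste0(element, seq_len(n)),
             element = element,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             resname = if (is_ligand) "LIG" else "RES",
             resid = seq_len(n), chain = if (is_ligand) "L" else "A",
             occupancy = 1, is_ligand = is_ligand, charge = 0L,
             vdw = vdw, stringsAsFactors = FALSE)
}

pdb_line <- function(serial, name, resname, chain, resid, x, y, z,
                     occ = 1, altloc = " ", element = NULL, het = FALSE) {
  element <- element %||% substr(name, 1, 1)
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, name, altloc, resname,
          chain, resid, x, y, z, occ, 0, element)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

write_test_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# a 3-residue GLY-like mini peptide strand along x
mini_receptor_pdb <- function(path = tempfile(fileext = ".pdb")) {
  lines <- character()
  s <- 0
  for (r in 1:3) {
    x0 <- (r - 1) * 4
    lines <- c(lines,
      pdb_line(s + 1, "N",  "GLY", "A", r, x0 + 0.0, 0, 0, element = "N"),
      pdb_line(s + 2, "CA", "GLY", "A", r, x0 + 1.5, 0, 0, element = "C"),
      pdb_line(s + 3, "C",  "GLY", "A", r, x0 + 2.5, 1, 0, element = "C"),
      pdb_line(s + 4, "O",  "GLY", "A", r, x0 + 2.5, 2.2, 0, element = "O"))
    s <- s + 4
  }
  write_test_pdb(lines, path)
}

# --- SDF builders ----------------------------------------------------

sdf_record <- function(title, atoms, bonds, tags = list(), chg = NULL) {
  # atoms: data.frame x, y, z, el; bonds: data.frame i, j, order
  out <- c(title, "  test", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   nrow(atoms), nrow(bonds)))
  out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        atoms$x, atoms$y, atoms$z, atoms$el))
  if (nrow(bonds))
    out <- c(out, sprintf("%3d%3d%3d  0", bonds$i, bonds$j, bonds$order))
  if (!is.null(chg))
    out <- c(out, paste0("M  CHG", sprintf("%3d", length(chg) / 2),
                         paste(sprintf("%4d", chg), collapse = "")))
  out <- c(out, "M  END")
  for (nm in names(tags))
    out <- c(out, sprintf(">  <%s>", nm), as.character(tags[[nm]]), "")
  c(out, "$$$$")
}

benzene_sdf <- function(path = tempfile(fileext = ".sdf")) {
  ang <- (0:5) * pi / 3
  atoms <- data.frame(x = 1.39 * cos(ang), y = 1.39 * sin(ang), z = 0,
                      el = "C")
  bonds <- data.frame(i = 1:6, j = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1))
  writeLines(sdf_record("benzene", atoms, bonds), path)
  path
}

acetate_sdf <- function(path = tempfile(fileext = ".sdf")) {
  atoms <- data.frame(x = c(0, 1.5, 2.2, 2.1), y = c(0, 0, 1.1, -1.1),
                      z = 0, el = c("C", "C", "O", "O"))
  bonds <- data.frame(i = c(1, 2, 2), j = c(2, 3, 4), order = c(1, 2, 1))
  writeLines(sdf_record("acetate", atoms, bonds, chg = c(4, -1)), path)
  path
}

scored_sdf <- function(path = tempfile(fileext = ".sdf")) {
  a <- data.frame(x = c(0, 1.5), y = 0, z = 0, el = "C")
  b <- data.frame(i = 1, j = 2, order = 1)
  writeLines(c(sdf_record("cmpdA", a, b, tags = list(score = 1.5)),
               sdf_record("cmpdB", a, b, tags = list(score = 2.5))),
             path)
  path
}

ethanol_mol2 <- function(path = tempfile(fileext = ".mol2")) {
  writeLines(c(
    "@<TRIPOS>MOLECULE", "ethanol", " 3 2 0 0 0", "SMALL", "NO_CHARGES",
    "@<TRIPOS>ATOM",
    "  1 C1  0.000 0.000 0.000 C.3",
    "  2 C2  1.520 0.000 0.000 C.3",
    "  3 O1  2.150 1.250 0.000 O.3",
    "@<TRIPOS>BOND",
    "  1 1 2 1",
    "  2 2 3 1"), path)
  path
}

# independent oracles -------------------------------------------------

auc_pairwise <- function(labels, scores) {
  act <- scores[labels == 1]; ina <- scores[labels == 0]
  tot <- 0
  for (a in act) tot <- tot + sum(a > ina) + 0.5 * sum(a == ina)
  tot / (length(act) * length(ina))
}

bedroc_oracle <- function(labels, scores, alpha = 20, ids = NULL) {
  N <- length(labels); n <- sum(labels == 1)
  ids <- ids %||% as.character(seq_len(N))
  ord <- order(-scores, ids)
  ri <- which(labels[ord] == 1)
  Ra <- n / N
  rand_sum <- (n / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1)
  rie <- sum(exp(-alpha * ri / N)) / rand_sum
  rie * Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
}

confusion_oracle <- function(TP, TN, FP, FN) {
  n <- TP + TN + FP + FN
  d <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- d(TP, TP + FN); spec <- d(TN, TN + FP)
  prec <- d(TP, TP + FP); acc <- d(TP + TN, n)
  mccden <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  po <- acc
  pe <- d((TP + FP) * (TP + FN) + (FN + TN) * (FP + TN), n * n)
  list(sensitivity = sens, specificity = spec, precision = prec,
       concordance = acc,
       youden_j = if (anyNA(c(sens, spec))) NA_real_ else sens + spec - 1,
       mcc = if (mccden > 0) (TP * TN - FP * FN) / sqrt(mccden)
             else NA_real_,
       f1 = if (anyNA(c(prec, sens)) || prec + sens == 0) NA_real_
            else 2 * prec * sens / (prec + sens),
       kappa = if (anyNA(c(po, pe)) || pe == 1) NA_real_
               else (po - pe) / (1 - pe))
}

lig_bound_delta <- function(tri) {
  n <- length(tri$ligand_unbound$per_atom_area)
  tri$ligand_unbound$total -
    sum(utils::tail(tri$bound$per_atom_area, n))
}
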