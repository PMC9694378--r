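# Internal canonical atom-table columns. All structure containers carry a
# data.frame with exactly these columns.
.atom_cols <- c("serial", "name", "element", "x", "y", "z",
                "resname", "resid", "chain", "occupancy",
                "is_ligand", "charge", "vdw")

.empty_atoms <- function() {
  data.frame(serial = integer(), name = character(), element = character(),
             x = numeric(), y = numeric(), z = numeric(),
             resname = character(), resid = integer(), chain = character(),
             occupancy = numeric(), is_ligand = logical(),
             charge = integer(), vdw = numeric(),
             stringsAsFactors = FALSE)
}

.check_atoms <- function(atoms, what = "structure") {
  stopifnot(is.data.frame(atoms))
  missing <- setdiff(.atom_cols, names(atoms))
  if (length(missing))
    stop(what, ": atom table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(atoms) && any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop(what, ": non-finite atom coordinates")
  invisible(atoms)
}

#' Bondi van der Waals radii
#'
#' The default element-to-radius table (Angstrom) used for SASA
#' calculations. Elements absent from the table receive the documented
#' default of 1.80 Angstrom (with a warning) when radii are assigned.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
bondi_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
    P = 1.80, S = 1.80, CL = 1.75, BR = 1.85, I = 1.98,
    SE = 1.90, B = 1.92, SI = 2.10)
}

#' Assign van der Waals radii to a structure
#'
#' @param structure A `receptor_structure`, `ligand_pose`, or bare atom
#'   data.frame.
#' @param radius_table Named numeric vector, element symbol to radius in
#'   Angstrom. Defaults to [bondi_radii()].
#' @param default Radius used for elements missing from the table (1.80 A);
#'   a warning lists the affected elements.
#' @return The input with the `vdw` column of every atom set (> 0).
#' @export
assign_vdw_radii <- function(structure, radius_table = bondi_radii(),
                             default = 1.80) {
  atoms <- .get_atoms(structure)
  el <- toupper(atoms$element)
  r <- unname(radius_table[el])
  unknown <- unique(el[is.na(r)])
  if (length(unknown)) {
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            ": using default vdW radius ", default, " A")
    r[is.na(r)] <- default
  }
  atoms$vdw <- r
  .set_atoms(structure, atoms)
}

.get_atoms <- function(x) {
  if (is.data.frame(x)) x else x$atoms
}

.set_atoms <- function(x, atoms) {
  if (is.data.frame(x)) return(atoms)
  x$atoms <- atoms
  x
}

#' Read a receptor structure from a PDB file
#'
#' Parses ATOM/HETATM records. Waters and (by default) common monoatomic
#' ions are dropped; for alternate locations only the highest-occupancy
#' (first on tie) conformation of each atom is retained. Hydrogens are
#' kept if present, never added.
#'
#' @param path PDB file.
#' @param drop_resnames Residue names removed before assembly; defaults to
#'   waters and common ions.
#' @param source_id Identifier stored with the structure; defaults to the
#'   file base name.
#' @return A `receptor_structure`: list with `atoms` (data.frame) and
#'   `source_id`.
#' @export
read_receptor <- function(path,
                          drop_resnames = c("HOH", "WAT", "DOD",
                                            "NA", "CL", "K", "MG", "CA",
                                            "ZN", "SO4", "PO4"),
                          source_id = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (!length(lines)) stop("no ATOM/HETATM records in ", path)

  fx <- function(a, b) trimws(substr(lines, a, b))
  atoms <- data.frame(
    serial    = as.integer(fx(7, 11)),
    name      = fx(13, 16),
    altloc    = fx(17, 17),
    resname   = fx(18, 20),
    chain     = fx(22, 22),
    resid     = as.integer(fx(23, 26)),
    x         = as.numeric(fx(31, 38)),
    y         = as.numeric(fx(39, 46)),
    z         = as.numeric(fx(47, 54)),
    occupancy = suppressWarnings(as.numeric(fx(55, 60))),
    element   = fx(77, 78),
    stringsAsFactors = FALSE
  )
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  # element column may be absent in minimal files: fall back to atom name
  noel <- atoms$element == ""
  atoms$element[noel] <- gsub("[^A-Za-z].*$", "", atoms$name[noel])
  atoms$element[noel] <- ifelse(nchar(atoms$element[noel]) > 1 &
                                  !toupper(atoms$element[noel]) %in%
                                    c("CL", "BR", "SE", "FE", "ZN", "MG", "NA"),
                                substr(atoms$element[noel], 1, 1),
                                atoms$element[noel])
  atoms$element <- toupper(atoms$element)

  atoms <- atoms[!(atoms$resname %in% drop_resnames), , drop = FALSE]

  # alternate locations: keep the highest-occupancy record per atom site
  if (nrow(atoms) && any(atoms$altloc != "")) {
    key <- paste(atoms$chain, atoms$resid, atoms$resname, atoms$name)
    ord <- order(key, -atoms$occupancy, atoms$altloc)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resid,
                                     atoms$resname, atoms$name)), ,
                   drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }
  if (!nrow(atoms)) stop("zero atoms retained from ", path)

  atoms$altloc <- NULL
  atoms$is_ligand <- FALSE
  atoms$charge <- 0L
  atoms$vdw <- NA_real_
  atoms <- atoms[, .atom_cols]
  .check_atoms(atoms, "read_receptor")
  structure(list(atoms = atoms,
                 source_id = source_id %||%
                   tools::file_path_sans_ext(basename(path))),
            class = "receptor_structure")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read docked ligand poses from an SDF or MOL2 file
#'
#' One `ligand_pose` per record. The docking score is taken from the named
#' SDF data tag; `compound_id` comes from the record title and `pose_id`
#' appends a running per-compound index.
#'
#' @param path SDF (V2000) or MOL2 file; format chosen by extension unless
#'   `format` is given.
#' @param score_field Name of the SDF property holding the docking score,
#'   or `NULL` for no score (MOL2 has no data fields).
#' @param format `"sdf"` or `"mol2"`.
#' @param on_missing_score `"fail"` (default) or `"na"` when a record lacks
#'   `score_field`.
#' @return List of `ligand_pose` objects, each a list with `atoms`, `bonds`
#'   (data.frame i, j, order), `compound_id`, `pose_id`, `native_score`.
#' @export
read_ligand_poses <- function(path, score_field = NULL, format = NULL,
                              on_missing_score = c("fail", "na")) {
  on_missing_score <- match.arg(on_missing_score)
  if (!file.exists(path)) stop("cannot read pose file: ", path)
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               sdf = "sdf", sd = "sdf", mol2 = "mol2",
                               stop("cannot infer pose file format for ", path))
  lines <- readLines(path, warn = FALSE)
  if (!length(trimws(lines)) || all(trimws(lines) == ""))
    stop("empty pose file: ", path)
  recs <- switch(format,
                 sdf = .parse_sdf(lines, score_field, on_missing_score),
                 mol2 = .parse_mol2(lines))
  if (!length(recs)) stop("no parseable records in ", path)
  # pose_id = title + running index per compound
  ids <- vapply(recs, function(p) p$compound_id, "")
  idx <- stats::ave(seq_along(ids), ids, FUN = seq_along)
  for (i in seq_along(recs))
    recs[[i]]$pose_id <- paste0(ids[i], "_", idx[i])
  recs
}

.new_pose <- function(atoms, bonds, compound_id, native_score = NA_real_) {
  atoms$is_ligand <- TRUE
  atoms <- atoms[, .atom_cols]
  .check_atoms(atoms, "ligand_pose")
  if (nrow(bonds) &&
      (any(bonds$i < 1) || any(bonds$j > nrow(atoms))))
    stop("ligand bond indices out of range")
  if (!nzchar(compound_id)) stop("empty compound_id in pose record")
  structure(list(atoms = atoms, bonds = bonds, compound_id = compound_id,
                 pose_id = compound_id, native_score = native_score),
            class = "ligand_pose")
}

.parse_sdf <- function(lines, score_field, on_missing_score) {
  # split on $$$$ delimiters
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) ends <- length(lines)
  starts <- c(1, utils::head(ends, -1) + 1)
  poses <- list()
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    block <- block[block != "$$$$"]
    if (!length(trimws(block)) || all(trimws(block) == "")) next
    title <- trimws(block[1])
    counts <- block[4]
    na <- as.integer(substr(counts, 1, 3))
    nb <- as.integer(substr(counts, 4, 6))
    if (is.na(na)) stop("malformed SDF counts line in record ", k)
    at <- block[5:(4 + na)]
    atoms <- data.frame(
      serial = seq_len(na),
      name = paste0(toupper(trimws(substr(at, 32, 34))), seq_len(na)),
      element = toupper(trimws(substr(at, 32, 34))),
      x = as.numeric(substr(at, 1, 10)),
      y = as.numeric(substr(at, 11, 20)),
      z = as.numeric(substr(at, 21, 30)),
      resname = "LIG", resid = 1L, chain = "L",
      occupancy = 1, is_ligand = TRUE, charge = 0L, vdw = NA_real_,
      stringsAsFactors = FALSE
    )
    bonds <- if (nb > 0) {
      bl <- block[(5 + na):(4 + na + nb)]
      data.frame(i = as.integer(substr(bl, 1, 3)),
                 j = as.integer(substr(bl, 4, 6)),
                 order = as.integer(substr(bl, 7, 9)))
    } else data.frame(i = integer(), j = integer(), order = integer())
    # M CHG overrides
    chg <- grep("^M  CHG", block, value = TRUE)
    for (cl in chg) {
      f <- scan(text = substr(cl, 7, nchar(cl)), quiet = TRUE)
      n <- f[1]
      for (q in seq_len(n))
        atoms$charge[f[2 * q]] <- as.integer(f[2 * q + 1])
    }
    score <- NA_real_
    if (!is.null(score_field)) {
      tag <- grep(paste0("^>.*<", score_field, ">"), block)
      if (length(tag)) {
        score <- suppressWarnings(as.numeric(trimws(block[tag[1] + 1])))
      } else if (on_missing_score == "fail") {
        stop("record ", k, " (", title, ") lacks score field '",
             score_field, "'")
      }
    }
    poses[[length(poses) + 1]] <- .new_pose(atoms, bonds, title, score)
  }
  poses
}

.parse_mol2 <- function(lines) {
  mol_at <- grep("^@<TRIPOS>MOLECULE", lines)
  if (!length(mol_at)) stop("no @<TRIPOS>MOLECULE record found")
  bounds <- c(mol_at, length(lines) + 1)
  poses <- list()
  for (k in seq_along(mol_at)) {
    block <- lines[bounds[k]:(bounds[k + 1] - 1)]
    title <- trimws(block[2])
    counts <- scan(text = block[3], quiet = TRUE)
    na <- counts[1]; nb <- if (length(counts) > 1) counts[2] else 0
    ai <- grep("^@<TRIPOS>ATOM", block)[1]
    at <- block[(ai + 1):(ai + na)]
    parse_row <- function(s) strsplit(trimws(s), "[[:space:]]+")[[1]]
    rows <- lapply(at, parse_row)
    sybyl <- vapply(rows, `[`, "", 6)
    atoms <- data.frame(
      serial = seq_len(na),
      name = vapply(rows, `[`, "", 2),
      element = toupper(sub("\\..*$", "", sybyl)),
      x = as.numeric(vapply(rows, `[`, "", 3)),
      y = as.numeric(vapply(rows, `[`, "", 4)),
      z = as.numeric(vapply(rows, `[`, "", 5)),
      resname = "LIG", resid = 1L, chain = "L",
      occupancy = 1, is_ligand = TRUE, charge = 0L, vdw = NA_real_,
      stringsAsFactors = FALSE
    )
    bonds <- data.frame(i = integer(), j = integer(), order = integer(),
                        aromatic = logical())
    if (nb > 0) {
      bi <- grep("^@<TRIPOS>BOND", block)[1]
      bl <- lapply(block[(bi + 1):(bi + nb)], parse_row)
      typ <- vapply(bl, `[`, "", 4)
      bonds <- data.frame(
        i = as.integer(vapply(bl, `[`, "", 2)),
        j = as.integer(vapply(bl, `[`, "", 3)),
        order = ifelse(typ == "ar", 4L,
                       suppressWarnings(as.integer(
                         ifelse(typ == "am", "1", typ))))
      )
      bonds$order[is.na(bonds$order)] <- 1L
    }
    # sybyl ".ar" atom subtype marks aromaticity even without bond block
    pose <- .new_pose(atoms, bonds, title)
    pose$sybyl_aromatic <- grepl("\\.ar$", sybyl)
    poses[[length(poses) + 1]] <- pose
  }
  poses
}

#' Extract the receptor binding site around a ligand pose
#'
#' Keeps every residue having at least one heavy atom within `cutoff` of
#' any ligand heavy atom. Whole residues are retained, never fragments.
#'
#' @param receptor A `receptor_structure`.
#' @param ligand A `ligand_pose`.
#' @param cutoff Heavy-atom contact distance in Angstrom (default 5.0).
#' @return A `receptor_structure` restricted to the binding site.
#' @export
extract_binding_site <- function(receptor, ligand, cutoff = 5.0) {
  stopifnot(cutoff > 0)
  ra <- receptor$atoms
  la <- ligand$atoms
  rh <- ra[ra$element != "H", , drop = FALSE]
  lh <- la[la$element != "H", , drop = FALSE]
  if (!nrow(rh) || !nrow(lh)) stop("no heavy atoms for binding-site search")
  rm <- as.matrix(rh[, c("x", "y", "z")])
  lm <- as.matrix(lh[, c("x", "y", "z")])
  d2 <- outer(rowSums(rm^2), rowSums(lm^2), "+") - 2 * rm %*% t(lm)
  near <- apply(d2 <= cutoff^2 + 1e-12, 1, any)
  keys <- paste(rh$chain, rh$resid, rh$resname)
  hit_keys <- unique(keys[near])
  if (!length(hit_keys))
    stop("empty binding site: no receptor residue within ", cutoff,
         " A of the ligand")
  all_keys <- paste(ra$chain, ra$resid, ra$resname)
  out <- ra[all_keys %in% hit_keys, , drop = FALSE]
  structure(list(atoms = out, source_id = receptor$source_id),
            class = "receptor_structure")
}

#' Assemble a pose complex
#'
#' Joins a (binding-site) receptor and one ligand pose with no change to
#' any coordinate: relaxation on binding is deliberately not modelled.
#' Overlapping serial numbers are re-indexed.
#'
#' @param receptor_subset `receptor_structure` (typically a binding site).
#' @param ligand `ligand_pose`.
#' @param cutoff_used Optional record of the binding-site cutoff.
#' @return A `pose_complex`: list with `receptor`, `ligand`, `cutoff_used`.
#' @export
assemble_complex <- function(receptor_subset, ligand, cutoff_used = NA_real_) {
  if (!nrow(receptor_subset$atoms)) stop("empty receptor subset")
  if (!nrow(ligand$atoms)) stop("empty ligand")
  rec <- receptor_subset
  lig <- ligand
  rec$atoms$serial <- seq_len(nrow(rec$atoms))
  lig$atoms$serial <- nrow(rec$atoms) + seq_len(nrow(lig$atoms))
  structure(list(receptor = rec, ligand = lig, cutoff_used = cutoff_used),
            class = "pose_complex")
}

#' All atoms of a pose complex as one table
#' @param complex A `pose_complex`.
#' @return data.frame of receptor atoms followed by ligand atoms.
#' @export
complex_atoms <- function(complex) {
  rbind(complex$receptor$atoms, complex$ligand$atoms)
}

#' Write atoms to a minimal PDB file (debug round-trip helper)
#' @param structure Structure or atom data.frame.
#' @param path Output file.
#' @export
write_pdb <- function(structure, path) {
  a <- .get_atoms(structure)
  rec <- ifelse(a$is_ligand, "HETATM", "ATOM  ")
  lines <- sprintf("%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, a$serial, substr(a$name, 1, 4), "",
                   substr(a$resname, 1, 3), substr(a$chain, 1, 1),
                   a$resid, "", a$x, a$y, a$z, a$occupancy, 0,
                   substr(a$element, 1, 2))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
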