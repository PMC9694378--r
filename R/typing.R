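# Pharmacophoric atom typing: every atom gets exactly one of seven
# categories so that per-category SASA sums partition the total exactly.
#
# The typing dictionary is this package's own, documented table (the
# descriptor algebra only requires a fixed, total, single-category
# partition). Ligands are typed from the molecular graph by a fixed
# priority cascade; receptors by a residue/atom-name lookup.

#' The seven pharmacophoric categories
#'
#' H (Hydrophobic), Ar (Aromatic), D (Donor), Ac (Acceptor), P (Positive),
#' N (Negative), O (Other).
#'
#' @return Character vector of length 7 in canonical order.
#' @export
pharm_categories <- function() c("H", "Ar", "D", "Ac", "P", "N", "O")

# ---------------------------------------------------------------- ligand

#' Type ligand atoms from the molecular graph
#'
#' Priority cascade, first match wins:
#' Negative (formal charge < 0, or terminal O on a carboxylate /
#' phosphate / sulfonate group) > Positive (formal charge > 0, or N of a
#' guanidinium/amidine group, or a non-amide sp3 amine N) > Donor (N/O/S
#' with at least one explicit or implicit H) > Acceptor (remaining N/O) >
#' Aromatic (atom in an aromatic ring) > Hydrophobic (C or S bonded only
#' to C/H/S) > Other. Hydrogens inherit the category of their bonded
#' heavy atom.
#'
#' @param ligand A `ligand_pose` with bonds populated.
#' @return Character vector of categories, one per atom.
#' @export
type_ligand_atoms <- function(ligand) {
  a <- ligand$atoms
  b <- ligand$bonds
  n <- nrow(a)
  if (!n) stop("cannot type an empty ligand")
  el <- toupper(a$element)
  chg <- a$charge

  # adjacency with bond orders (aromatic flagged as order 4)
  nbrs <- vector("list", n)
  orders <- vector("list", n)
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      i <- b$i[k]; j <- b$j[k]; o <- b$order[k]
      nbrs[[i]] <- c(nbrs[[i]], j); orders[[i]] <- c(orders[[i]], o)
      nbrs[[j]] <- c(nbrs[[j]], i); orders[[j]] <- c(orders[[j]], o)
    }
  }
  heavy_nbrs <- lapply(nbrs, function(v) v[el[v] != "H"])
  n_h_expl <- vapply(nbrs, function(v) sum(el[v] == "H"), 0L)

  # implicit hydrogens from standard valences (aromatic bond counts 1.5)
  std_val <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, CL = 1, BR = 1,
               I = 1, H = 1)
  bond_sum <- vapply(seq_len(n), function(i) {
    o <- orders[[i]]
    if (!length(o)) return(0)
    sum(ifelse(o == 4, 1.5, o))
  }, 0)
  val <- unname(std_val[el]); val[is.na(val)] <- 0
  n_h_impl <- pmax(0, round(val + chg - bond_sum))
  has_h <- n_h_expl > 0 | n_h_impl > 0

  aromatic <- .aromatic_atoms(el, nbrs, orders, n)
  if (!is.null(ligand$sybyl_aromatic))
    aromatic <- aromatic | ligand$sybyl_aromatic

  terminal_o <- el == "O" & lengths(heavy_nbrs) == 1

  cat <- rep("O", n)
  for (i in seq_len(n)) {
    e <- el[i]
    if (e == "H") next  # inherited below
    hn <- heavy_nbrs[[i]]
    # Negative
    neg <- chg[i] < 0
    if (!neg && terminal_o[i]) {
      p <- hn[1]
      term_o_on_p <- sum(terminal_o[heavy_nbrs[[p]]])
      neg <- (el[p] == "C" && term_o_on_p >= 2) ||
             (el[p] %in% c("P", "S") && term_o_on_p >= 2)
    }
    if (neg) { cat[i] <- "N"; next }
    # Positive
    if (chg[i] > 0) { cat[i] <- "P"; next }
    if (e == "N" && !aromatic[i]) {
      c_nbrs <- hn[el[hn] == "C"]
      guanid <- any(vapply(c_nbrs, function(p)
        sum(el[heavy_nbrs[[p]]] == "N") >= 2, TRUE))
      amide <- any(vapply(c_nbrs, function(p) {
        oo <- orders[[p]]; vv <- nbrs[[p]]
        any(el[vv] == "O" & oo == 2)
      }, TRUE))
      sp3 <- all(orders[[i]] %in% c(1L))
      amine <- sp3 && !amide && all(el[hn] %in% c("C"))
      if (guanid || amine) { cat[i] <- "P"; next }
    }
    # Donor
    if (e %in% c("N", "O", "S") && has_h[i]) { cat[i] <- "D"; next }
    # Acceptor
    if (e %in% c("N", "O")) { cat[i] <- "Ac"; next }
    # Aromatic
    if (aromatic[i]) { cat[i] <- "Ar"; next }
    # Hydrophobic
    if (e %in% c("C", "S") &&
        (!length(hn) || all(el[hn] %in% c("C", "S")))) {
      cat[i] <- "H"; next
    }
    cat[i] <- "O"
  }
  # hydrogens inherit the parent heavy atom's category
  for (i in which(el == "H")) {
    p <- heavy_nbrs[[i]]
    cat[i] <- if (length(p)) cat[p[1]] else "O"
  }
  cat
}

# ring perception: cycles of length 5-6 where every ring atom is sp2-like
# (has a double/aromatic bond, or is N/O/S contributing a lone pair)
.aromatic_atoms <- function(el, nbrs, orders, n) {
  arom <- rep(FALSE, n)
  if (!n) return(arom)
  has_multi <- vapply(seq_len(n), function(i)
    any(orders[[i]] %in% c(2L, 4L)), TRUE)
  # explicit aromatic bond flag
  for (i in seq_len(n))
    if (any(orders[[i]] == 4L)) arom[i] <- TRUE
  # Kekule rings: DFS for cycles up to length 6 over heavy atoms
  rings <- .find_rings(nbrs, el, max_size = 6)
  for (ring in rings) {
    ok <- all(vapply(ring, function(i)
      has_multi[i] || el[i] %in% c("N", "O", "S"), TRUE))
    n_multi <- sum(has_multi[ring])
    if (ok && n_multi >= length(ring) - 2) arom[ring] <- TRUE
  }
  arom
}

.find_rings <- function(nbrs, el, max_size = 6) {
  n <- length(nbrs)
  heavy <- which(el != "H")
  rings <- list()
  seen <- character()
  for (start in heavy) {
    stack <- list(c(start))
    while (length(stack)) {
      path <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      last <- path[length(path)]
      for (nx in nbrs[[last]]) {
        if (el[nx] == "H") next
        if (nx == start && length(path) >= 3) {
          key <- paste(sort(path), collapse = "-")
          if (!key %in% seen) {
            seen <- c(seen, key)
            rings[[length(rings) + 1]] <- path
          }
        } else if (!(nx %in% path) && length(path) < max_size &&
                   nx > start) {
          stack[[length(stack) + 1]] <- c(path, nx)
        }
      }
    }
  }
  rings[lengths(rings) %in% c(5, 6)]
}

# -------------------------------------------------------------- receptor

#' Default receptor typing table
#'
#' Residue/atom-name lookup used by [type_receptor_atoms()]. Shipped as
#' `inst/extdata/receptor_typing.csv` for reference; entries here are
#' authoritative.
#'
#' @return data.frame with columns residue, atom_name, category.
#' @export
receptor_typing_table <- function() {
  path <- system.file("extdata", "receptor_typing.csv",
                      package = "ppirescore")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Type receptor atoms by residue/atom-name lookup
#'
#' Charged side-chain termini are Positive/Negative, H-bearing N/O (and
#' thiol S) are Donors, carbonyl and carboxamide O plus remaining N/O are
#' Acceptors, side-chain ring carbons of Phe/Tyr/Trp/His are Aromatic,
#' other C and S are Hydrophobic, anything else is Other. His ND1/NE2 are
#' Positive by default (protonatable at physiological pH; set
#' `his_positive = FALSE` for a neutral Donor/Acceptor pair). Atoms of
#' non-standard residues fall back to element rules with a warning.
#' Hydrogens inherit the category of the nearest heavy atom in the same
#' residue.
#'
#' @param receptor A `receptor_structure`.
#' @param his_positive Treat histidine ring nitrogens as Positive
#'   (default TRUE).
#' @param table Optional custom lookup (columns residue, atom_name,
#'   category) overriding the shipped one.
#' @return Character vector of categories, one per atom.
#' @export
type_receptor_atoms <- function(receptor, his_positive = TRUE,
                                table = NULL) {
  a <- receptor$atoms
  n <- nrow(a)
  if (!n) stop("cannot type an empty receptor")
  tab <- table %||% receptor_typing_table()
  if (!his_positive) {
    drop <- tab$residue == "HIS" & tab$atom_name %in% c("ND1", "NE2")
    tab$category[drop & tab$atom_name == "ND1"] <- "D"
    tab$category[drop & tab$atom_name == "NE2"] <- "Ac"
  }
  key <- paste(toupper(a$resname), toupper(a$name))
  tkey <- paste(toupper(tab$residue), toupper(tab$atom_name))
  hit <- match(key, tkey)
  # generic backbone / OXT entries apply across residues
  gkey <- paste("*", toupper(a$name))
  gtab <- tkey[tab$residue == "*"]
  ghit <- match(gkey, tkey)
  cat <- ifelse(!is.na(hit), tab$category[hit],
                ifelse(!is.na(ghit), tab$category[ghit], NA))

  std_res <- unique(tab$residue[tab$residue != "*"])
  el <- toupper(a$element)
  unk <- is.na(cat) & el != "H"
  if (any(unk & !(toupper(a$resname) %in% std_res)))
    warning("non-standard residue(s) typed by element fallback: ",
            paste(unique(a$resname[unk & !(toupper(a$resname) %in% std_res)]),
                  collapse = ", "))
  # element fallback for unmatched heavy atoms
  cat[unk & el %in% c("N", "O")] <- "Ac"
  cat[unk & el %in% c("C", "S")] <- "H"
  cat[is.na(cat) & el != "H"] <- "O"

  # hydrogens inherit nearest heavy atom in the same residue
  hs <- which(el == "H")
  if (length(hs)) {
    xyz <- as.matrix(a[, c("x", "y", "z")])
    rid <- paste(a$chain, a$resid)
    for (i in hs) {
      cand <- which(rid == rid[i] & el != "H")
      if (!length(cand)) cand <- which(el != "H")
      if (!length(cand)) { cat[i] <- "O"; next }
      d2 <- colSums((t(xyz[cand, , drop = FALSE]) - xyz[i, ])^2)
      cat[i] <- cat[cand[which.min(d2)]]
    }
  }
  cat
}

# ------------------------------------------------------------- sums

#' Per-category SASA sums for one molecule in one state
#'
#' @param sasa A `sasa_result`.
#' @param categories Character vector from [type_ligand_atoms()] or
#'   [type_receptor_atoms()], aligned with the atoms behind `sasa`.
#' @param role `"receptor"` or `"ligand"`.
#' @param state `"bound"` or `"unbound"`.
#' @return A `category_sums`: list with `total`, `per_category` (named
#'   numeric over the 7 categories, summing to `total`), `role`, `state`.
#' @export
category_sums <- function(sasa, categories,
                          role = c("receptor", "ligand"),
                          state = c("bound", "unbound")) {
  role <- match.arg(role); state <- match.arg(state)
  area <- sasa$per_atom_area
  if (length(area) != length(categories))
    stop("category_sums: ", length(area), " areas vs ",
         length(categories), " categories")
  bad <- setdiff(unique(categories), pharm_categories())
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  per <- vapply(pharm_categories(),
                function(k) sum(area[categories == k]), 0)
  structure(list(total = sasa$total, per_category = per,
                 role = role, state = state),
            class = "category_sums")
}
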