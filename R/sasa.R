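# Shrake-Rupley solvent-accessible surface area with a deterministic
# golden-section spiral point set. Deterministic by construction: the same
# atoms, probe and n_points always give bit-identical areas.

#' Deterministic unit sphere point set (golden-section spiral)
#'
#' @param n Number of points (>= 16).
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 16)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' For each atom a sphere of radius `vdw + probe` is sampled at `n_points`
#' spiral points; a point is exposed when it lies outside every neighbor's
#' expanded sphere. The per-atom area is
#' `exposed/n_points * 4 * pi * (vdw + probe)^2`.
#'
#' @param atoms Atom data.frame (needs columns x, y, z, vdw) or a structure
#'   carrying one.
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points Sphere sample points per atom (default 960).
#' @return A `sasa_result`: list with `per_atom_area` (Angstrom^2, aligned
#'   with the atom table), `total`, `probe_radius`, `n_points`.
#' @export
per_atom_sasa <- function(atoms, probe = 1.4, n_points = 960) {
  a <- .get_atoms(atoms)
  .check_atoms(a, "per_atom_sasa")
  if (any(is.na(a$vdw)) || any(a$vdw <= 0))
    stop("per_atom_sasa: all atoms need a positive vdW radius ",
         "(run assign_vdw_radii first)")
  n <- nrow(a)
  pts <- sphere_points(n_points)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  R <- a$vdw + probe
  area <- numeric(n)

  # neighbor candidates: centers closer than the sum of expanded radii
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  for (i in seq_len(n)) {
    cutoff2 <- (R[i] + R)^2
    nb <- which(d2[i, ] < cutoff2 & seq_len(n) != i)
    if (!length(nb)) {
      area[i] <- 4 * pi * R[i]^2
      next
    }
    P <- pts * R[i]
    P <- sweep(P, 2, xyz[i, ], "+")
    NC <- xyz[nb, , drop = FALSE]
    pd2 <- outer(rowSums(P^2), rowSums(NC^2), "+") - 2 * P %*% t(NC)
    covered <- pd2 < matrix(R[nb]^2, n_points, length(nb), byrow = TRUE)
    exposed <- sum(rowSums(covered) == 0)
    area[i] <- exposed / n_points * 4 * pi * R[i]^2
  }
  structure(list(per_atom_area = area, total = sum(area),
                 probe_radius = probe, n_points = n_points),
            class = "sasa_result")
}

#' Bound/unbound SASA of a pose complex
#'
#' Computes the three states the descriptor layer needs: the bound complex
#' (receptor + ligand together), the unbound receptor, and the unbound
#' ligand, all at identical coordinates (no relaxation on binding).
#'
#' @param complex A `pose_complex`.
#' @inheritParams per_atom_sasa
#' @return A `sasa_triple`: list with `bound`, `receptor_unbound`,
#'   `ligand_unbound` (`sasa_result` objects). The bound per-atom areas are
#'   ordered receptor atoms first, then ligand atoms.
#' @export
tristate_sasa <- function(complex, probe = 1.4, n_points = 960) {
  stopifnot(inherits(complex, "pose_complex"))
  all_atoms <- complex_atoms(complex)
  nr <- nrow(complex$receptor$atoms)
  bound <- per_atom_sasa(all_atoms, probe, n_points)
  rec_un <- per_atom_sasa(complex$receptor$atoms, probe, n_points)
  lig_un <- per_atom_sasa(complex$ligand$atoms, probe, n_points)
  stopifnot(length(bound$per_atom_area) ==
              length(rec_un$per_atom_area) + length(lig_un$per_atom_area))
  structure(list(bound = bound, receptor_unbound = rec_un,
                 ligand_unbound = lig_un, n_receptor_atoms = nr),
            class = "sasa_triple")
}

#' Dump per-atom SASA of a triple as a data.frame
#' @param triple A `sasa_triple`.
#' @return data.frame with atom index, state, role and area.
#' @export
sasa_dump <- function(triple) {
  nr <- triple$n_receptor_atoms
  nb <- length(triple$bound$per_atom_area)
  data.frame(
    atom = c(seq_len(nb), seq_len(nr), seq_len(nb - nr)),
    role = c(rep(c("receptor", "ligand"), c(nr, nb - nr)),
             rep("receptor", nr), rep("ligand", nb - nr)),
    state = rep(c("bound", "unbound"), c(nb, nb)),
    area = c(triple$bound$per_atom_area,
             triple$receptor_unbound$per_atom_area,
             triple$ligand_unbound$per_atom_area)
  )
}
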