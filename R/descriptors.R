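# The 80 SASA descriptors of a docked pose. For each pharmacophoric
# category X (T = total, then H, Ar, D, Ac, P, N, O) and each role
# M in {R = receptor, L = ligand}:
#   unbound   X_MU,   bound X_MB,
#   delta     dX_M  = X_MU - X_MB          (surface buried on binding)
#   relative  rel.X_M = X_MB / X_MU        (low = deep burial)
# and the receptor-ligand combinations
#   dX_RL   = (X_RU + X_LU) - (X_RB + X_LB)
#   rel.X_RL = (X_RB + X_LB) / (X_RU + X_LU)

.desc_categories <- function() c("T", pharm_categories())

#' Names of the 80 SASA descriptors in canonical order
#'
#' Receptor block (32), ligand block (32), receptor-ligand block (16);
#' within each block categories T, H, Ar, D, Ac, P, N, O, and within each
#' category unbound, bound, delta, relative (delta and relative only for
#' the receptor-ligand block).
#'
#' @return Character vector of length 80.
#' @export
descriptor_names <- function() {
  cats <- .desc_categories()
  rec <- unlist(lapply(cats, function(x)
    c(paste0(x, "_RU"), paste0(x, "_RB"),
      paste0("delta ", x, "_R"), paste0("rel. ", x, "_R"))))
  lig <- unlist(lapply(cats, function(x)
    c(paste0(x, "_LU"), paste0(x, "_LB"),
      paste0("delta ", x, "_L"), paste0("rel. ", x, "_L"))))
  rl <- unlist(lapply(cats, function(x)
    c(paste0("delta ", x, "_RL"), paste0("rel. ", x, "_RL"))))
  c(rec, lig, rl)
}

.sums_vector <- function(cs) {
  # total first, then the 7 categories, in canonical order
  c(T = unname(cs$total), cs$per_category)
}

#' Derive the 80-descriptor vector of one pose
#'
#' @param receptor_bound,receptor_unbound,ligand_bound,ligand_unbound
#'   `category_sums` for the respective role and state.
#' @param clamp_tol Deltas more negative than `-clamp_tol` (relative to the
#'   unbound value) trigger a warning before being clamped at 0; smaller
#'   negatives are silent discretization noise.
#' @return Named numeric vector of length 80 (order of
#'   [descriptor_names()]), with attribute `n_rel_imputed` counting
#'   relative descriptors set to 1 because their unbound denominator was 0
#'   (no surface of that category exists, so none is buried).
#' @export
derive_descriptor_vector <- function(receptor_bound, receptor_unbound,
                                     ligand_bound, ligand_unbound,
                                     clamp_tol = 1e-6) {
  stopifnot(receptor_bound$state == "bound",
            receptor_unbound$state == "unbound",
            ligand_bound$state == "bound",
            ligand_unbound$state == "unbound",
            receptor_bound$role == "receptor",
            ligand_bound$role == "ligand")
  rb <- .sums_vector(receptor_bound); ru <- .sums_vector(receptor_unbound)
  lb <- .sums_vector(ligand_bound);   lu <- .sums_vector(ligand_unbound)
  if (any(c(rb, ru, lb, lu) < 0)) stop("negative SASA sums")

  imputed <- 0L
  block <- function(u, b) {
    d <- u - b
    bad <- d < -clamp_tol * pmax(u, 1)
    if (any(bad))
      warning("delta SASA negative beyond tolerance; clamped at 0")
    d <- pmax(d, 0)
    r <- ifelse(u > 0, pmin(b / u, 1), 1)
    imputed <<- imputed + sum(u <= 0)
    list(d = d, r = r)
  }
  rbl <- block(ru, rb)
  lbl <- block(lu, lb)
  cbl <- block(ru + lu, rb + lb)

  ncat <- length(.desc_categories())
  rec <- as.vector(rbind(ru, rb, rbl$d, rbl$r))
  lig <- as.vector(rbind(lu, lb, lbl$d, lbl$r))
  rl <- as.vector(rbind(cbl$d, cbl$r))
  out <- c(rec, lig, rl)
  names(out) <- descriptor_names()
  attr(out, "n_rel_imputed") <- imputed
  out
}

#' SASA descriptors of a single pose complex
#'
#' Runs the tri-state SASA calculation and pharmacophoric typing, then
#' the descriptor algebra.
#'
#' @param complex A `pose_complex` with vdW radii assigned (radii are
#'   assigned from [bondi_radii()] when missing).
#' @param probe,n_points Passed to [tristate_sasa()].
#' @param receptor_categories,ligand_categories Optional pre-computed
#'   category vectors (used by fixtures to bypass pattern typing).
#' @param his_positive Passed to [type_receptor_atoms()].
#' @return The result of [derive_descriptor_vector()].
#' @export
pose_descriptors <- function(complex, probe = 1.4, n_points = 960,
                             receptor_categories = NULL,
                             ligand_categories = NULL,
                             his_positive = TRUE) {
  stopifnot(inherits(complex, "pose_complex"))
  if (any(is.na(complex$receptor$atoms$vdw)))
    complex$receptor <- assign_vdw_radii(complex$receptor)
  if (any(is.na(complex$ligand$atoms$vdw)))
    complex$ligand <- assign_vdw_radii(complex$ligand)
  tri <- tristate_sasa(complex, probe, n_points)
  nr <- tri$n_receptor_atoms
  rcat <- receptor_categories %||%
    type_receptor_atoms(complex$receptor, his_positive)
  lcat <- ligand_categories %||% type_ligand_atoms(complex$ligand)

  nb <- length(tri$bound$per_atom_area)
  rec_bound <- structure(list(
    per_atom_area = tri$bound$per_atom_area[seq_len(nr)],
    total = sum(tri$bound$per_atom_area[seq_len(nr)])),
    class = "sasa_result")
  lig_bound <- structure(list(
    per_atom_area = tri$bound$per_atom_area[(nr + 1):nb],
    total = sum(tri$bound$per_atom_area[(nr + 1):nb])),
    class = "sasa_result")

  derive_descriptor_vector(
    category_sums(rec_bound, rcat, "receptor", "bound"),
    category_sums(tri$receptor_unbound, rcat, "receptor", "unbound"),
    category_sums(lig_bound, lcat, "ligand", "bound"),
    category_sums(tri$ligand_unbound, lcat, "ligand", "unbound"))
}

#' Descriptor table over a list of pose complexes
#'
#' @param poses List of `pose_complex` objects.
#' @param labels Optional data.frame (compound_id, label) joined by
#'   compound_id; compounds without a label get NA.
#' @param ... Passed to [pose_descriptors()].
#' @return data.frame with columns compound_id, pose_id, the 80
#'   descriptors, n_rel_imputed, and (when labels are given) label.
#' @export
descriptor_table <- function(poses, labels = NULL, ...) {
  nm <- descriptor_names()
  if (!length(poses)) {
    out <- as.data.frame(matrix(numeric(), 0, length(nm),
                                dimnames = list(NULL, nm)),
                         check.names = FALSE)
    return(cbind(data.frame(compound_id = character(),
                            pose_id = character()), out,
                 data.frame(n_rel_imputed = integer())))
  }
  key <- vapply(poses, function(p)
    paste(p$ligand$compound_id, p$ligand$pose_id), "")
  if (anyDuplicated(key))
    stop("duplicate (compound_id, pose_id) among poses")
  rows <- lapply(poses, function(p) pose_descriptors(p, ...))
  mat <- do.call(rbind, rows)
  out <- data.frame(
    compound_id = vapply(poses, function(p) p$ligand$compound_id, ""),
    pose_id = vapply(poses, function(p) p$ligand$pose_id, ""),
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(mat, check.names = FALSE))
  out$n_rel_imputed <- vapply(rows, function(r)
    attr(r, "n_rel_imputed"), 0L)
  if (!is.null(labels)) {
    m <- match(out$compound_id, labels$compound_id)
    out$label <- labels$label[m]
  }
  rownames(out) <- NULL
  out
}
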