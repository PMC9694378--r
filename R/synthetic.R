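# Synthetic fixtures: parametric pocket-ligand complexes with a burial
# dial, two-class descriptor tables with a stated standardized class
# separation and imbalance, and correlated multi-function score tables.
# Every generator is a pure function of its spec and seed.

#' Synthetic pocket-ligand complex with controllable burial
#'
#' The receptor is a dense spherical cage of carbon-like atoms; the
#' ligand a small rigid carbon cluster moved along the +z axis from
#' out-of-contact (`burial_depth = 0`) to the cage center
#' (`burial_depth = 1`, fully enclosed). Burial of the ligand surface
#' increases strictly with depth by construction.
#'
#' @param burial_depth d in \[0, 1\].
#' @param n_receptor_atoms Cage atom count before the mouth is cut
#'   (default 300; the default cage wall is probe-tight at 960 sphere
#'   points).
#' @param pocket_radius Cage radius in Angstrom (default 5; snug, so the
#'   wall overlaps the ligand's probe-expanded surface at full burial).
#' @param ligand_n_atoms Ligand cluster size (default 8).
#' @param mouth_deg Half-angle of the cage mouth in degrees (default 20):
#'   wide enough that a partially inserted ligand keeps exposed surface,
#'   narrow enough that the rim occludes everything at full burial.
#' @param seed Seed for the small positional jitter of cage atoms.
#' @return A `pose_complex` with vdW radii assigned.
#' @export
make_pocket_complex <- function(burial_depth, n_receptor_atoms = 300,
                                pocket_radius = 5, ligand_n_atoms = 8,
                                mouth_deg = 20, seed = 1L) {
  stopifnot(burial_depth >= 0, burial_depth <= 1,
            pocket_radius > 0, ligand_n_atoms >= 1)
  lig_core <- 1.5  # radius of the ligand cluster shell
  if (burial_depth == 1 && lig_core + 1.7 >= pocket_radius - 1.7)
    stop("ligand does not fit inside the pocket at full burial")

  cage <- sphere_points(n_receptor_atoms) * pocket_radius
  jit <- .with_seed(seed,
    matrix(stats::runif(3 * n_receptor_atoms, -0.05, 0.05),
           ncol = 3))
  cage <- cage + jit
  cage <- cage[cage[, 3] <= cos(mouth_deg * pi / 180) * pocket_radius, ,
               drop = FALSE]
  n_receptor_atoms <- nrow(cage)
  rec_atoms <- data.frame(
    serial = seq_len(n_receptor_atoms),
    name = "CB", element = "C",
    x = cage[, 1], y = cage[, 2], z = cage[, 3],
    resname = "ALA", resid = seq_len(n_receptor_atoms), chain = "A",
    occupancy = 1, is_ligand = FALSE, charge = 0L, vdw = NA_real_,
    stringsAsFactors = FALSE)
  receptor <- structure(list(atoms = rec_atoms, source_id = "pocket"),
                        class = "receptor_structure")

  lp <- if (ligand_n_atoms == 1) matrix(0, 1, 3)
        else {
          shell <- sphere_points(max(16, ligand_n_atoms - 1))
          pick <- unique(round(seq(1, nrow(shell),
                                   length.out = ligand_n_atoms - 1)))
          rbind(c(0, 0, 0), shell[pick, , drop = FALSE] * lig_core)
        }
  # clearance: beyond contact range (sum of expanded radii) at d = 0
  z0 <- pocket_radius + lig_core + 2 * (1.7 + 1.4) + 0.5
  zpos <- z0 * (1 - burial_depth)
  lp[, 3] <- lp[, 3] + zpos
  lig_atoms <- data.frame(
    serial = seq_len(nrow(lp)),
    name = paste0("C", seq_len(nrow(lp))), element = "C",
    x = lp[, 1], y = lp[, 2], z = lp[, 3],
    resname = "LIG", resid = 1L, chain = "L",
    occupancy = 1, is_ligand = TRUE, charge = 0L, vdw = NA_real_,
    stringsAsFactors = FALSE)
  nb <- nrow(lp) - 1
  bonds <- if (nb > 0) data.frame(i = 1L, j = 1L + seq_len(nb),
                                  order = 1L)
           else data.frame(i = integer(), j = integer(),
                           order = integer())
  ligand <- structure(list(atoms = lig_atoms, bonds = bonds,
                           compound_id = sprintf("pocket_d%.2f",
                                                 burial_depth),
                           pose_id = sprintf("pocket_d%.2f_1",
                                             burial_depth),
                           native_score = NA_real_),
                      class = "ligand_pose")
  cpx <- assemble_complex(receptor, ligand, cutoff_used = NA_real_)
  cpx$receptor <- assign_vdw_radii(cpx$receptor)
  cpx$ligand <- assign_vdw_radii(cpx$ligand)
  cpx
}

#' Synthetic two-class 80-descriptor table
#'
#' Informative columns are class-conditional Gaussians separated by
#' `effect_size` standard deviations; the rest are class-independent.
#' Latent scores are mapped monotonically onto physically plausible
#' ranges (non-negative areas; relative descriptors in \[0, 1\]), which
#' preserves per-column Bayes AUC `pnorm(effect_size / sqrt(2))`.
#' The default 1:9 imbalance mirrors the milder ratios of curated PPI
#' screening decks; pass `n_active`/`n_inactive` for extreme (~1:45)
#' presets.
#'
#' @param n_active,n_inactive Class sizes (default 200 and 1800).
#' @param n_informative Number of informative descriptors (default 10,
#'   <= 80).
#' @param effect_size Standardized mean difference on informative columns
#'   (default 3).
#' @param noise_sd Within-class standard deviation (default 1).
#' @param seed Seed.
#' @return data.frame with compound_id, the 80 descriptor columns and a
#'   0/1 `label`; attribute `informative` names the informative columns.
#' @export
make_descriptor_table <- function(n_active = 200, n_inactive = 1800,
                                  n_informative = 10, effect_size = 3,
                                  noise_sd = 1, seed = 1L) {
  stopifnot(n_active > 0, n_inactive > 0,
            n_informative >= 0, n_informative <= 80)
  nm <- descriptor_names()
  n <- n_active + n_inactive
  .with_seed(seed, {
    info <- sort(sample(80, n_informative))
    label <- c(rep(1, n_active), rep(0, n_inactive))
    Z <- matrix(stats::rnorm(n * 80, sd = noise_sd), n, 80)
    Z[, info] <- Z[, info] + effect_size * noise_sd * label
    # monotone map to plausible scales: 'rel.' columns to [0,1],
    # everything else to non-negative areas
    X <- Z
    is_rel <- grepl("^rel\\.", nm)
    X[, is_rel] <- stats::plogis(Z[, is_rel])
    X[, !is_rel] <- exp(Z[, !is_rel] * 0.35 + log(200))
    colnames(X) <- nm
    out <- data.frame(compound_id = sprintf("cmpd%05d", seq_len(n)),
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(X, check.names = FALSE))
    out$label <- label
    attr(out, "informative") <- nm[info]
    out
  })
}

#' Synthetic multi-function score table
#'
#' K score columns sharing a latent activity signal plus independent
#' noise; odd columns are emitted higher-better, even columns are
#' sign-flipped and declared lower-better to exercise orientation
#' handling.
#'
#' @param n_compounds Total compounds (default 200).
#' @param K Number of scoring functions (default 6).
#' @param signal Latent activity shift in noise SDs (0 = pure noise).
#' @param active_fraction Fraction of actives (default 0.1).
#' @param seed Seed.
#' @return List with `scores` (data.frame compound_id + K columns),
#'   `orientations` (character vector) and `labels` (0/1).
#' @export
make_score_table <- function(n_compounds = 200, K = 6, signal = 1,
                             active_fraction = 0.1, seed = 1L) {
  stopifnot(K >= 1, n_compounds >= 4)
  .with_seed(seed, {
    n1 <- max(1, round(active_fraction * n_compounds))
    labels <- sample(c(rep(1, n1), rep(0, n_compounds - n1)))
    latent <- signal * labels + stats::rnorm(n_compounds)
    orient <- rep(c("higher_better", "lower_better"), length.out = K)
    scores <- data.frame(compound_id = sprintf("cmpd%04d",
                                               seq_len(n_compounds)),
                         stringsAsFactors = FALSE)
    for (k in seq_len(K)) {
      s <- latent + stats::rnorm(n_compounds)
      if (orient[k] == "lower_better") s <- -s
      scores[[paste0("score", k)]] <- s
    }
    list(scores = scores, orientations = orient, labels = labels)
  })
}
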