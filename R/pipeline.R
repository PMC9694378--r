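# End-to-end orchestration: descriptor derivation -> best-pose selection
# -> consensus rescoring -> screening metrics -> ML train/CV/test, under
# one config with recorded seeds. Stage outputs are plain CSV/JSON so any
# stage can be replaced by external files (e.g., real rescoring tables).

#' Default pipeline configuration
#'
#' Fully synthetic ("fixtures") run; override fields to point at real
#' receptor/pose/score/label files (`mode = "files"`).
#'
#' @param outdir Output directory.
#' @param seed Global seed; every stage seed is derived from it.
#' @return Named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(outdir = tempfile("ppirescore_run_"),
                            seed = 1L) {
  list(
    mode = "fixtures",
    outdir = outdir,
    seed = as.integer(seed),
    sasa = list(probe = 1.4, n_points = 960),
    site_cutoff = 5.0,
    # files mode inputs
    receptor = NULL, poses = NULL, score_field = NULL,
    scores = NULL, score_orientations = NULL, labels = NULL,
    # fixtures mode shapes
    fixtures = list(n_compounds = 300, K = 6, signal = 1.5,
                    active_fraction = 0.1,
                    table = list(n_active = 60, n_inactive = 540,
                                 n_informative = 10, effect_size = 3)),
    metrics = list(fractions = c(0.01, 0.05), alpha = 20),
    split = list(train_fraction = 0.7),
    families = c("tree", "logistic_regression"),
    cv_folds = 0
  )
}

.write_csv <- function(df, path) {
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  path
}

#' Run the full pipeline
#'
#' Stages in order: descriptor table, best-pose selection, consensus
#' rescoring, virtual-screening metrics, ML train/test (and optional
#' cross-validation). Outputs are CSV/JSON files under `config$outdir`
#' plus a run manifest (`manifest.json`) carrying the config, seeds and
#' input checksums; a rerun with the same config is byte-identical for
#' all deterministic stages. Without labels the screening and ML stages
#' are skipped with a warning and descriptors are still emitted.
#'
#' @param config List from [pipeline_config()] (or a path to a JSON file
#'   with the same fields).
#' @return Invisibly, the manifest list (stage outputs, file paths).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- utils::modifyList(pipeline_config(), config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg, outputs = list())
  seed <- cfg$seed

  # ---- stage 1: descriptor table -------------------------------------
  if (cfg$mode == "fixtures") {
    tb <- cfg$fixtures$table
    desc <- make_descriptor_table(tb$n_active, tb$n_inactive,
                                  tb$n_informative, tb$effect_size,
                                  seed = seed)
    labels <- data.frame(compound_id = desc$compound_id,
                         label = desc$label)
    st <- make_score_table(cfg$fixtures$n_compounds, cfg$fixtures$K,
                           cfg$fixtures$signal,
                           cfg$fixtures$active_fraction, seed = seed + 1)
    scores <- st$scores
    score_orient <- st$orientations
    score_labels <- st$labels
  } else {
    receptor <- assign_vdw_radii(read_receptor(cfg$receptor))
    poses <- read_ligand_poses(cfg$poses, cfg$score_field)
    poses <- lapply(poses, function(p) {
      p <- assign_vdw_radii(p)
      site <- extract_binding_site(receptor, p, cfg$site_cutoff)
      assemble_complex(site, p, cfg$site_cutoff)
    })
    labels <- if (!is.null(cfg$labels))
      utils::read.csv(cfg$labels, stringsAsFactors = FALSE) else NULL
    desc <- descriptor_table(poses, labels,
                             probe = cfg$sasa$probe,
                             n_points = cfg$sasa$n_points)
    scores <- if (!is.null(cfg$scores))
      utils::read.csv(cfg$scores, stringsAsFactors = FALSE) else NULL
    score_orient <- cfg$score_orientations
    score_labels <- if (!is.null(labels) && !is.null(scores))
      labels$label[match(scores$compound_id, labels$compound_id)] else NULL
  }
  manifest$outputs$descriptors <- .write_csv(desc,
    file.path(cfg$outdir, "descriptors.csv"))

  # ---- stage 2+3: best pose / consensus ------------------------------
  if (!is.null(scores)) {
    num_cols <- setdiff(names(scores), c("compound_id", "pose_id"))
    if ("pose_id" %in% names(scores))
      scores <- best_pose_per_compound(scores, num_cols[1])
    cons <- consensus_rank(scores[num_cols],
                           score_orient %||% "higher_better",
                           compound_id = scores$compound_id)
    manifest$outputs$consensus <- .write_csv(cons,
      file.path(cfg$outdir, "consensus.csv"))

    # ---- stage 4: screening metrics ----------------------------------
    if (!is.null(score_labels)) {
      rep1 <- screen_report(score_labels, scores[num_cols],
                            score_orient == "higher_better",
                            cfg$metrics$fractions, cfg$metrics$alpha,
                            ids = scores$compound_id)
      repc <- screen_report(score_labels,
                            data.frame(consensus = -cons$consensus_rank),
                            TRUE, cfg$metrics$fractions,
                            cfg$metrics$alpha, ids = scores$compound_id)
      manifest$outputs$screen_metrics <- .write_csv(rbind(rep1, repc),
        file.path(cfg$outdir, "screen_metrics.csv"))
    } else {
      warning("no labels: screening-metric stage skipped")
    }
  }

  # ---- stage 5: ML ----------------------------------------------------
  if (!is.null(desc$label) && !all(is.na(desc$label))) {
    nm <- intersect(descriptor_names(), names(desc))
    X <- desc[nm]
    y <- desc$label
    sp <- stratified_split(y, cfg$split$train_fraction, seed = seed + 2)
    rows <- lapply(cfg$families, function(fam) {
      ms <- model_spec(fam, seed = seed + 3)
      m <- fit_model(ms, X[sp$train, ], y[sp$train])
      em <- predict_and_enrich(m, X[sp$test, ], y[sp$test],
                               cfg$metrics$fractions, cfg$metrics$alpha)
      cm <- confusion_metrics(confusion_table(
        y[sp$test], predict_prob(m, X[sp$test, ])))
      cv <- if (cfg$cv_folds >= 2)
        cross_validate(ms, X[sp$train, ], y[sp$train], cfg$cv_folds,
                       seed = seed + 4)
      c(list(family = fam, test_auc = em$auc, bedroc = em$bedroc),
        as.list(em$ef), cm,
        if (!is.null(cv)) list(cv_auc_mean = unname(cv$mean["auc"]),
                               cv_auc_sd = unname(cv$sd["auc"])))
    })
    ml <- as.data.frame(do.call(rbind, lapply(rows, function(r)
      unlist(r))), check.names = FALSE)
    ml <- cbind(family = vapply(rows, function(r) r$family, ""),
                as.data.frame(lapply(ml[-1], as.numeric),
                              check.names = FALSE))
    manifest$outputs$ml_report <- .write_csv(ml,
      file.path(cfg$outdir, "ml_report.csv"))
  } else if (is.null(desc$label)) {
    warning("no labels: ML stage skipped")
  }

  # ---- manifest -------------------------------------------------------
  manifest$checksums <- as.list(tools::md5sum(unlist(manifest$outputs)))
  manifest$r_version <- R.version.string
  jsonlite::write_json(manifest,
                       file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
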