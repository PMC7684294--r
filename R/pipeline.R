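#' Read a cohort written by [write_cohort()]
#'
#' Loads the per-subject NIfTI volumes, the subject metadata CSV and, when
#' present, the signature and atlas volumes. Real (non-simulated) data laid
#' out the same way load identically; grids must already be aligned (no
#' resampling is performed).
#'
#' @param dir directory containing `metadata.csv` and the volumes.
#' @return A `pain_cohort` (without a generating config; `config` holds only
#'   the grid).
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stop("no metadata.csv in '", dir, "'")
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  need <- c("subject", "study", "modality", "file")
  if (!all(need %in% names(meta)))
    stop("metadata.csv must have columns: ", paste(need, collapse = ", "))
  if (is.null(meta$condition)) meta$condition <- "pain"
  if (is.null(meta$rating)) meta$rating <- NA_real_
  if (is.null(meta$study_name)) meta$study_name <- paste0("study", meta$study)
  if (is.null(meta$contrast)) meta$contrast <- NA_character_
  vols <- lapply(file.path(dir, meta$file), read_volume)
  grid <- dim(vols[[1]])
  studies <- lapply(split(seq_len(nrow(meta)), meta$study), function(idx) {
    m1 <- meta[idx[1], ]
    structure(list(study = m1$study, name = m1$study_name,
                   modality = m1$modality, condition = m1$condition,
                   contrast = m1$contrast, n_subjects = length(idx),
                   d_true = NA_real_, offset = NA_real_,
                   subject = meta$subject[idx],
                   maps = lapply(vols[idx], vol_data),
                   amplitude = rep(NA_real_, length(idx)),
                   rating = meta$rating[idx]),
              class = "study_dataset")
  })
  studies <- studies[order(vapply(studies, function(s) s$study, 0))]
  sig_path <- file.path(dir, "signature.nii.gz")
  atl_path <- file.path(dir, "atlas_labels.nii.gz")
  atlas <- NULL
  if (file.exists(atl_path)) {
    lab <- vol_data(read_volume(atl_path))
    ks <- sort(unique(lab[lab > 0]))
    nm <- if (length(ks) == 7L)
      c("visual", "somatomotor", "dorsal_attention", "ventral_attention",
        "limbic", "frontoparietal", "default")
    else paste0("parcel", ks)
    parcels <- lapply(ks, function(k) lab == k)
    names(parcels) <- nm
    atlas <- structure(list(parcels = parcels, names = nm,
                            labels = array(as.integer(lab), dim = dim(lab)),
                            dim = dim(lab)),
                       class = "network_atlas")
  }
  structure(list(studies = unname(studies),
                 signature = if (file.exists(sig_path)) read_volume(sig_path),
                 atlas = atlas, config = list(grid = grid),
                 sigma_score = NA_real_, sigma_total = NA_real_),
            class = "pain_cohort")
}

#' Pipeline configuration
#'
#' Assembles every knob of the two-stage classification pipeline into one
#' validated object: simulation parameters (or a cohort directory to load),
#' the signature scaling, the stage list, the FDR level, the CV fold count,
#' the somatovisceral training studies, the null proportion for the binomial
#' generalization tests, and a master seed. Every random stage derives its
#' seed from `seed`, so a run is a deterministic function of its config.
#'
#' @param seed master RNG seed.
#' @param simulate list of arguments to [simulation_config()]; by default
#'   the seven pain studies of [default_study_table()] plus two no-pain
#'   control studies (cognitive control, negative emotion; `d_true = 0`, no
#'   network loadings) used by the pain/no-pain stage.
#' @param cohort_dir optionally, a directory to [read_cohort()] instead of
#'   simulating.
#' @param scaling signature score scaling, `"cosine"` or `"dot"`.
#' @param stages subset of `c("score", "stage1", "stage2", "glm", "behav")`.
#' @param train_studies study ids used to train the somatovisceral
#'   classifier (default 2 and 7: one rectal, one thermal study).
#' @param q FDR level for the GLM stage.
#' @param folds CV fold count for the classifier stage.
#' @param p0 null proportion for the binomial generalization test.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, simulate = list(), cohort_dir = NULL,
                            scaling = c("cosine", "dot"),
                            stages = c("score", "stage1", "stage2", "glm", "behav"),
                            train_studies = c(2L, 7L), q = 0.05, folds = 10L,
                            p0 = 0.6249) {
  scaling <- match.arg(scaling)
  bad <- setdiff(stages, c("score", "stage1", "stage2", "glm", "behav"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (folds < 2) stop("folds must be >= 2")
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  if (is.null(cohort_dir)) {
    if (is.null(simulate$studies)) {
      pain <- default_study_table()
      pain$condition <- "pain"
      ctrl <- data.frame(
        study = 8:9, name = c("cognitive_control", "negative_emotion"),
        modality = c("somatic", "visceral"), n_subjects = c(15L, 15L),
        d_true = 0, offset = 0, contrast = "task-rest", condition = "control",
        stringsAsFactors = FALSE)
      simulate$studies <- rbind(pain, ctrl)
    }
    if (is.null(simulate$seed)) simulate$seed <- seed
    sim_cfg <- do.call(simulation_config, simulate)
  } else sim_cfg <- NULL
  structure(list(seed = as.integer(seed), simulate = sim_cfg,
                 cohort_dir = cohort_dir, scaling = scaling, stages = stages,
                 train_studies = train_studies, q = q,
                 folds = as.integer(folds), p0 = p0),
            class = "pipeline_config")
}

#' Run the two-stage classification pipeline
#'
#' Orchestrates the full analysis on a (simulated or loaded) multi-study
#' cohort: signature-expression scoring; stage 1, single-interval pain/
#' no-pain classification of every map from its signature score; stage 2,
#' the cross-validated network-based somatovisceral classifier, applied
#' prospectively to every map stage 1 classified as pain; plus the optional
#' voxel-wise GLM/conjunction stage and the robust brain--behavior stage.
#' When `out_dir` is given, all tabular outputs (CSV/JSON), the thresholded
#' maps (NIfTI) and the configuration (YAML) are written there; a run is
#' reproducible from its stored config alone.
#'
#' @param config a [pipeline_config()] (or a path to a YAML file of
#'   arguments for it).
#' @param out_dir optional output directory.
#' @return A `pipeline_result` list with elements per executed stage.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) {
    args <- yaml::read_yaml(config)
    if (!is.null(args$simulate$studies))
      args$simulate$studies <- do.call(
        rbind, lapply(args$simulate$studies, as.data.frame))
    config <- do.call(pipeline_config, args)
  }
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (is.null(config$cohort_dir)) simulate_cohort(config$simulate)
            else read_cohort(config$cohort_dir)
  res <- list(config = config)

  scores <- cohort_signature_responses(cohort, scaling = config$scaling)
  if ("score" %in% config$stages) {
    res$scores <- scores
    res$study_stats <- cohort_signature_stats(scores[scores$condition == "pain", ])
  }

  if ("stage1" %in% config$stages) {
    pain_true <- as.integer(scores$condition == "pain")
    rep1 <- single_interval_classify(scores$score, pain_true)
    res$stage1 <- list(report = rep1,
                       classified_pain = scores$subject[rep1$predicted == 1])
  }

  if ("stage2" %in% config$stages) {
    feats <- cohort_network_features(cohort)
    tr <- feats$meta$study %in% config$train_studies &
      feats$meta$condition == "pain"
    if (!any(tr)) stop("no training subjects for stage 2")
    cv <- crossval_classifier(feats$features[tr, , drop = FALSE],
                              feats$labels[tr], k = config$folds,
                              seed = config$seed)
    pain_idx <- if (!is.null(res$stage1))
      feats$meta$subject %in% res$stage1$classified_pain
    else feats$meta$condition == "pain"
    pred <- apply_classifier(cv$model, feats$features[pain_idx, , drop = FALSE])
    pred_tab <- data.frame(feats$meta[pain_idx, c("subject", "study", "modality")],
                           prob_somatic = pred$prob, class = pred$class,
                           stringsAsFactors = FALSE)
    held_out <- pred_tab[!pred_tab$study %in% config$train_studies, , drop = FALSE]
    test_tab <- do.call(rbind, lapply(
      split(held_out, held_out$study),
      function(d) {
        ks <- sum(d$class == "somatic")
        data.frame(study = d$study[1], n = nrow(d),
                   p_somatic = ks / nrow(d),
                   se = prop_se(ks / nrow(d), nrow(d)),
                   p_binomial = binomial_test_two_sided(ks, nrow(d), config$p0),
                   stringsAsFactors = FALSE)
      }))
    if (is.null(test_tab))
      test_tab <- data.frame(study = integer(), n = integer(),
                             p_somatic = numeric(), se = numeric(),
                             p_binomial = numeric())
    rownames(test_tab) <- NULL
    res$stage2 <- list(crossval = cv, predictions = pred_tab,
                       per_study = test_tab)
  }

  if ("glm" %in% config$stages) {
    meta <- cohort_metadata(cohort)
    keep <- meta$condition == "pain"
    maps <- cohort_maps(cohort)[keep]
    des <- group_design(meta$study[keep], meta$modality[keep])
    sm <- fit_group_glm(maps, des)
    thr <- lapply(stats::setNames(nm = names(des$contrasts)),
                  function(cn) threshold_map(sm, cn, q = config$q))
    conj <- conjunction(thr$somatic, thr$visceral)
    res$glm <- list(
      stat_maps = sm, thresholded = thr, conjunction = conj,
      somatic_gt_visceral = masked_difference(thr$somatic_vs_visceral,
                                              thr$combined, "activation"),
      visceral_gt_somatic = masked_difference(thr$visceral_vs_somatic,
                                              thr$combined, "activation"),
      somatic_lt_visceral = masked_difference(thr$somatic_vs_visceral,
                                              thr$combined, "deactivation"),
      visceral_lt_somatic = masked_difference(thr$visceral_vs_somatic,
                                              thr$combined, "deactivation"))
  }

  if ("behav" %in% config$stages) {
    visc <- scores[scores$condition == "pain" & scores$modality == "visceral", ]
    st <- factor(visc$study)
    covs <- if (nlevels(st) > 1)
      stats::model.matrix(~ st)[, -1, drop = FALSE]
    res$behav <- robust_regress(visc$rating, visc$score, covariates = covs)
  }

  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_outputs(res, cohort, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> stages:", paste(x$config$stages, collapse = ", "), "\n")
  if (!is.null(x$stage1)) {
    cat(sprintf("  stage 1 (pain/no-pain): accuracy %.0f%%, AUROC %.2f, %d maps -> pain\n",
                100 * x$stage1$report$accuracy, x$stage1$report$auroc,
                length(x$stage1$classified_pain)))
  }
  if (!is.null(x$stage2))
    cat(sprintf("  stage 2 (somatovisceral): CV AUROC %.2f on %d training maps\n",
                x$stage2$crossval$report$auroc, length(x$stage2$crossval$labels)))
  if (!is.null(x$behav))
    cat(sprintf("  brain-behavior: beta = %.2f +/- %.2f, r_weighted = %.2f\n",
                coef(x$behav)["x"], x$behav$se["x"], x$behav$r_weighted))
  invisible(x)
}

# Serialize every pipeline artifact as text (CSV/JSON/YAML) plus NIfTI maps.
write_pipeline_outputs <- function(res, cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, f) jsonlite::write_json(x, file.path(out_dir, f),
                                            auto_unbox = TRUE, digits = NA,
                                            pretty = TRUE)
  if (!is.null(res$scores))
    utils::write.csv(res$scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
  if (!is.null(res$study_stats))
    utils::write.csv(res$study_stats, file.path(out_dir, "study_stats.csv"),
                     row.names = FALSE)
  if (!is.null(res$stage1))
    wj(res$stage1$report[c("cutoff", "n", "sensitivity", "specificity",
                           "accuracy", "accuracy_se", "balanced_accuracy",
                           "auroc", "auroc_binormal", "d_a")],
       "stage1_report.json")
  if (!is.null(res$stage2)) {
    m <- res$stage2$crossval$model
    wj(list(coefficients = as.list(m$coefficients), threshold = m$threshold,
            cv_threshold = m$cv_threshold, folds = res$stage2$crossval$k,
            seed = res$stage2$crossval$seed), "classifier_model.json")
    utils::write.csv(res$stage2$predictions,
                     file.path(out_dir, "stage2_predictions.csv"),
                     row.names = FALSE)
    utils::write.csv(res$stage2$per_study,
                     file.path(out_dir, "stage2_per_study.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$glm)) {
    for (nm in names(res$glm$thresholded))
      write_thresholded(res$glm$thresholded[[nm]],
                        file.path(out_dir, paste0("thr_", nm, ".nii.gz")))
    write_thresholded(res$glm$conjunction,
                      file.path(out_dir, "conjunction.nii.gz"))
  }
  if (!is.null(res$behav))
    wj(list(beta = unname(coef(res$behav)["x"]), se = unname(res$behav$se["x"]),
            p = unname(res$behav$p["x"]), r_weighted = res$behav$r_weighted),
       "brain_behavior.json")
  cfg <- res$config
  yaml::write_yaml(list(seed = cfg$seed, scaling = cfg$scaling,
                        stages = cfg$stages, train_studies = cfg$train_studies,
                        q = cfg$q, folds = cfg$folds, p0 = cfg$p0),
                   file.path(out_dir, "pipeline_config.yaml"))
  invisible(out_dir)
}
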