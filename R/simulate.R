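#' Default multi-study design table
#'
#' Seven studies mirroring a typical multi-site somatovisceral cohort: four
#' visceral (gastric, two rectal, esophageal) and three somatic (vulvar, two
#' thermal) studies with sample sizes 15/15/29/15/30/28/33 and per-study
#' planted signature effect sizes spanning the 1.2--3.7 range reported for
#' such designs. `offset` is a study-level baseline shift (arbitrary contrast
#' units) emulating inter-study scanner/sequence differences.
#'
#' @return A data.frame with columns `study`, `name`, `modality`,
#'   `n_subjects`, `d_true`, `offset`, `contrast`.
#' @export
default_study_table <- function() {
  data.frame(
    study = 1:7,
    name = c("gastric", "rectal1", "rectal2", "vulvar", "esophageal",
             "thermal1", "thermal2"),
    modality = c("visceral", "visceral", "visceral", "somatic", "visceral",
                 "somatic", "somatic"),
    n_subjects = c(15L, 15L, 29L, 15L, 30L, 28L, 33L),
    d_true = c(1.20, 1.21, 1.50, 2.22, 3.74, 2.88, 2.11),
    offset = c(-0.3, -0.2, -0.1, 0, 0.1, 0.2, 0.3),
    contrast = c("certain_pain-safe_nopain", "certain_pain-safe_nopain",
                 "certain_pain-safe_nopain", "certain_pain-safe_nopain",
                 "stimulation-rest", "high_heat-rest", "high_heat-low_heat"),
    stringsAsFactors = FALSE
  )
}

#' Default modality-specific network loadings
#'
#' Mean parcel activations (contrast units) added to every subject map of a
#' modality, indexed in atlas order (visual, somatomotor, dorsal attention,
#' ventral attention, limbic, frontoparietal, default). The sign structure
#' encodes the somatovisceral double dissociation: somatic stimulation loads
#' positively on the somatomotor and attention networks, visceral
#' stimulation loads positively on the frontoparietal network, and both
#' deactivate the default network (somatic more strongly).
#'
#' @param gamma overall contrast magnitude scaling. The default 0.4 is
#'   calibrated (on the default 12x12x12 grid) so that the best-separating
#'   network's Fisher-z feature separates the modalities by about 2 pooled
#'   SDs.
#' @return Named list with numeric 7-vectors `somatic` and `visceral`.
#' @export
default_network_loadings <- function(gamma = 0.4) {
  base <- c(visual = 0, somatomotor = 1, dorsal_attention = 0.5,
            ventral_attention = 1, limbic = 0, frontoparietal = -0.25,
            default = -1)
  visc <- c(visual = 0, somatomotor = -0.5, dorsal_attention = -0.5,
            ventral_attention = 0.5, limbic = 0, frontoparietal = 0.75,
            default = -0.25)
  list(somatic = gamma * base, visceral = gamma * visc)
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic cohort generator. Defaults define
#' a realistic multi-study somatovisceral cohort: a 12x12x12 voxel grid, a
#' 7-parcel atlas, a planted unit-norm signature, spatially smoothed Gaussian
#' noise (FWHM 2 voxels), study-level offsets, modality-dependent network
#' loadings, and ratings on a 0--100 VAS scale linearly coupled to the
#' planted signature amplitude.
#'
#' @param studies design table as from [default_study_table()].
#' @param grid integer length-3 grid shape.
#' @param n_networks number of atlas parcels.
#' @param network_loadings list with `somatic` and `visceral` numeric
#'   vectors of per-parcel mean activations; see
#'   [default_network_loadings()].
#' @param signature_loadings per-parcel loadings of the true signature
#'   pattern (it also has a smooth random-field component).
#' @param noise_sd per-voxel SD of the smoothed noise field.
#' @param fwhm smoothing FWHM in voxels, applied to noise and signature
#'   field.
#' @param atlas_margin width (voxels) of the grid border left outside the
#'   parcellation. The parcels tile only the interior region, emulating
#'   cortical networks that cover a proper subset of the analysis mask;
#'   without this border the seven parcel indicators would sum to one at
#'   every voxel and the network similarity features would be collinear.
#' @param amplitude_sd between-subject SD of the signature amplitude,
#'   expressed relative to the SD of the noise projection onto the signature
#'   (1 = amplitude variability comparable to scan noise on the score scale).
#' @param rating_per_sd VAS points per SD of signature amplitude (ratings
#'   are `b * amplitude + noise` with `b` set from this).
#' @param rating_sd SD of the rating noise (VAS points).
#' @param seed RNG seed; the whole cohort is a deterministic function of the
#'   config.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(studies = default_study_table(),
                              grid = c(12L, 12L, 12L),
                              n_networks = 7L,
                              network_loadings = default_network_loadings(),
                              signature_loadings = c(0, 0.5, 0.25, 0.5, 0, 0.25, -0.5),
                              noise_sd = 1,
                              fwhm = 2,
                              atlas_margin = 1L,
                              amplitude_sd = 1,
                              rating_per_sd = 7,
                              rating_sd = 10,
                              seed = 1L) {
  stopifnot(is.data.frame(studies),
            all(c("study", "modality", "n_subjects", "d_true") %in% names(studies)))
  if (any(studies$n_subjects < 2)) stop("each study needs n_subjects >= 2")
  if (any(!is.finite(studies$d_true))) stop("d_true must be finite")
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (!all(studies$modality %in% c("somatic", "visceral")))
    stop("modality must be 'somatic' or 'visceral'")
  if (is.null(studies$offset)) studies$offset <- 0
  if (is.null(studies$name)) studies$name <- paste0("study", studies$study)
  if (is.null(studies$condition)) studies$condition <- "pain"
  if (!all(studies$condition %in% c("pain", "control")))
    stop("condition must be 'pain' or 'control'")
  if (length(signature_loadings) != n_networks)
    stop("signature_loadings must have one entry per network")
  for (m in c("somatic", "visceral"))
    if (length(network_loadings[[m]]) != n_networks)
      stop("network_loadings$", m, " must have one entry per network")
  if (any(2 * atlas_margin >= grid)) stop("atlas_margin leaves no interior voxels")
  structure(list(studies = studies, grid = as.integer(grid),
                 n_networks = as.integer(n_networks),
                 network_loadings = network_loadings,
                 signature_loadings = signature_loadings,
                 noise_sd = noise_sd, fwhm = fwhm,
                 atlas_margin = as.integer(atlas_margin),
                 amplitude_sd = amplitude_sd,
                 rating_per_sd = rating_per_sd, rating_sd = rating_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# SD of the dot product between the (unit-norm) signature and one realization
# of the smoothed, variance-preserving noise field. Exact under the circular
# convolution used by smooth_field: Var = noise_sd^2 * ||G w||^2 / ||g||^2.
noise_score_sd <- function(weights, fwhm, noise_sd) {
  if (all(fwhm == 0)) return(noise_sd * sqrt(sum(weights^2)))
  gw <- smooth_field(weights, fwhm, normalize = "sum")
  noise_sd * sqrt(sum(gw^2)) / kernel_l2_norm(fwhm)
}

#' Simulate a multi-study cohort of contrast maps
#'
#' Generates, per subject, a contrast map
#' `x_i = offset_study + a_i * W + sum_k g_k(modality) * parcel_k + noise_i`
#' where `W` is the planted unit-norm signature, `a_i` is the subject's
#' signature amplitude, `g` the modality-specific network loadings and the
#' noise a smoothed Gaussian field. Amplitudes are calibrated so that the
#' population effect size of the dot-product signature score equals the
#' study's `d_true`: `a_i ~ N(d_true * s_tot, tau)` with `tau` the
#' between-subject amplitude SD and `s_tot = sqrt(s_noise^2 + tau^2)` the
#' total score SD, `s_noise` being the (analytically computed) SD of the
#' noise projection onto `W`. Ratings are `b * a_i + N(0, rating_sd)` on a
#' VAS-like scale, with the baseline condition's rating defined as 0.
#'
#' @param config a [simulation_config()].
#' @return A `pain_cohort`: list with `studies` (each holding `maps`, a list
#'   of 3-D arrays, plus labels, amplitudes and ratings), `signature`,
#'   `atlas`, `config` and the score-noise SD `sigma_score`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  grid <- config$grid
  base <- config$seed
  interior <- array(FALSE, dim = grid)
  mg <- config$atlas_margin
  interior[(1 + mg):(grid[1] - mg), (1 + mg):(grid[2] - mg),
           (1 + mg):(grid[3] - mg)] <- TRUE
  atlas <- make_atlas(grid, config$n_networks, seed = base, mask = interior)
  signature <- make_signature(grid, atlas, config$signature_loadings,
                              fwhm = config$fwhm, seed = base + 1L,
                              name = "planted-signature")
  w <- signature$values
  sigma_score <- noise_score_sd(w, config$fwhm, config$noise_sd)
  tau <- config$amplitude_sd * sigma_score
  sigma_tot <- sqrt(sigma_score^2 + tau^2)
  b <- if (tau > 0) config$rating_per_sd / tau else 0

  studies <- vector("list", nrow(config$studies))
  for (i in seq_len(nrow(config$studies))) {
    row <- config$studies[i, ]
    # control studies (non-pain manipulations) get no modality network
    # loadings; their signature effect is whatever d_true says (normally 0)
    is_pain <- row$condition == "pain"
    g <- if (is_pain) config$network_loadings[[row$modality]]
         else numeric(config$n_networks)
    gmap <- array(0, dim = grid)
    for (k in seq_len(config$n_networks))
      gmap <- gmap + g[k] * atlas$parcels[[k]]
    fixed <- row$offset + gmap
    n <- row$n_subjects
    res <- with_seed(base + 100L + i, {
      a <- stats::rnorm(n, mean = row$d_true * sigma_tot, sd = tau)
      maps <- vector("list", n)
      for (s in seq_len(n)) {
        eps <- array(stats::rnorm(prod(grid), sd = config$noise_sd), dim = grid)
        if (config$fwhm > 0) eps <- smooth_field(eps, config$fwhm, normalize = "l2")
        maps[[s]] <- fixed + a[s] * w + eps
      }
      rating <- b * a + stats::rnorm(n, sd = config$rating_sd)
      list(a = a, maps = maps, rating = rating)
    })
    studies[[i]] <- structure(
      list(study = row$study, name = row$name, modality = row$modality,
           condition = row$condition,
           contrast = if (!is.null(row$contrast)) row$contrast else NA_character_,
           n_subjects = n, d_true = row$d_true, offset = row$offset,
           subject = sprintf("s%02d_%02d", row$study, seq_len(n)),
           maps = res$maps, amplitude = res$a, rating = res$rating),
      class = "study_dataset")
  }
  structure(list(studies = studies, signature = signature, atlas = atlas,
                 config = config, sigma_score = sigma_score,
                 sigma_total = sigma_tot),
            class = "pain_cohort")
}

#' @export
print.pain_cohort <- function(x, ...) {
  cat(sprintf("<pain_cohort> %d studies, %d subjects, grid %s\n",
              length(x$studies), sum(vapply(x$studies, function(s) s$n_subjects, 0L)),
              paste(x$config$grid, collapse = "x")))
  for (s in x$studies)
    cat(sprintf("  study %d %-11s %-8s n=%2d d_true=%.2f\n",
                s$study, s$name, s$modality, s$n_subjects, s$d_true))
  invisible(x)
}

#' Subject-level metadata of a cohort
#'
#' @param cohort a `pain_cohort`.
#' @return A data.frame with one row per subject: `subject`, `study`,
#'   `study_name`, `modality`, `contrast`, `rating`.
#' @export
cohort_metadata <- function(cohort) {
  stopifnot(inherits(cohort, "pain_cohort"))
  do.call(rbind, lapply(cohort$studies, function(s)
    data.frame(subject = s$subject, study = s$study, study_name = s$name,
               modality = s$modality, condition = s$condition,
               contrast = s$contrast, rating = s$rating,
               stringsAsFactors = FALSE)))
}

# Flat list of all subject maps, in metadata row order.
cohort_maps <- function(cohort) {
  do.call(c, lapply(cohort$studies, function(s) s$maps))
}

#' Write a cohort to disk
#'
#' One NIfTI volume per subject, subject metadata as CSV, and the generating
#' configuration as YAML.
#'
#' @param cohort a `pain_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pain_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- cohort_metadata(cohort)
  meta$file <- paste0(meta$subject, ".nii.gz")
  maps <- cohort_maps(cohort)
  for (i in seq_len(nrow(meta)))
    write_volume(maps[[i]], file.path(dir, meta$file[i]))
  write_volume(cohort$signature, file.path(dir, "signature.nii.gz"))
  write_volume(array(as.double(cohort$atlas$labels), dim = cohort$atlas$dim),
               file.path(dir, "atlas_labels.nii.gz"))
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  cfg <- cohort$config
  cfg_list <- list(studies = lapply(seq_len(nrow(cfg$studies)), function(i)
                     as.list(cfg$studies[i, ])),
                   grid = cfg$grid, n_networks = cfg$n_networks,
                   network_loadings = lapply(cfg$network_loadings, as.numeric),
                   signature_loadings = as.numeric(cfg$signature_loadings),
                   noise_sd = cfg$noise_sd, fwhm = cfg$fwhm,
                   atlas_margin = cfg$atlas_margin,
                   amplitude_sd = cfg$amplitude_sd,
                   rating_per_sd = cfg$rating_per_sd, rating_sd = cfg$rating_sd,
                   seed = cfg$seed)
  yaml::write_yaml(cfg_list, file.path(dir, "config.yaml"))
  invisible(dir)
}
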