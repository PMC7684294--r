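#' Group-level design matrix for a multi-study cohort
#'
#' Builds the second-level design used to compare stimulation modalities
#' across studies: an intercept, a modality regressor (somatic = 1, visceral
#' = 0), and study nuisance dummies constructed within modality (one
#' reference study per modality is dropped, so the dummies are not collinear
#' with the modality effect). Standard contrast vectors are attached:
#' `combined` (average of the somatic and visceral study-mean baselines),
#' `somatic` and `visceral` (per-modality averages of study means versus
#' baseline), and `somatic_vs_visceral` / `visceral_vs_somatic`.
#'
#' @param study vector of study ids, one per subject.
#' @param modality `"somatic"`/`"visceral"`, one per subject.
#' @return A `group_design`: list with the design matrix `X` (full column
#'   rank, one row per subject) and the named list `contrasts` of contrast
#'   vectors.
#' @export
group_design <- function(study, modality) {
  stopifnot(length(study) == length(modality),
            all(modality %in% c("somatic", "visceral")))
  study <- as.character(study)
  som <- as.numeric(modality == "somatic")
  X <- cbind(intercept = 1, modality = som)
  # study dummies within modality, dropping the first study of each modality
  dummy_info <- list()
  for (mod in c("visceral", "somatic")) {
    st <- unique(study[modality == mod])
    for (s in st[-1]) {
      col <- as.numeric(study == s)
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- paste0("study", s)
      dummy_info[[paste0("study", s)]] <- mod
    }
  }
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design; check columns: ",
         paste(colnames(X), collapse = ", "))
  }
  n_st <- function(mod) length(unique(study[modality == mod]))
  # average of per-study means: beta0 (+ modality) + mean of that modality's
  # dummy coefficients (the reference study contributes 0)
  cvec <- function(base, mod) {
    v <- stats::setNames(numeric(ncol(X)), colnames(X))
    v[names(base)] <- base
    dn <- names(dummy_info)[unlist(dummy_info) == mod]
    v[dn] <- 1 / n_st(mod)
    v
  }
  visc <- cvec(c(intercept = 1), "visceral")
  soma <- cvec(c(intercept = 1, modality = 1), "somatic")
  contrasts <- list(combined = (soma + visc) / 2, somatic = soma,
                    visceral = visc, somatic_vs_visceral = soma - visc,
                    visceral_vs_somatic = visc - soma)
  structure(list(X = X, contrasts = contrasts, study = study,
                 modality = modality),
            class = "group_design")
}

#' Voxel-wise group GLM
#'
#' Ordinary least squares fitted independently at every voxel of the joint
#' valid mask, with contrast t-statistics and two-tailed p-values at
#' `df = n - rank(X)`.
#'
#' @param maps list of subject contrast maps (one per design row).
#' @param design a [group_design()] (or any list with full-rank `X` and
#'   named `contrasts` vectors).
#' @param contrasts character vector of contrast names to evaluate (default
#'   all in the design).
#' @param mask optional analysis mask; intersected with the voxels finite in
#'   every map.
#' @return A `stat_maps`: per contrast, vectors of `beta`, `t`, `p` over the
#'   mask; plus `mask`, `dim`, `df`, `n`.
#' @export
fit_group_glm <- function(maps, design, contrasts = NULL, mask = NULL) {
  X <- design$X
  if (length(maps) != nrow(X))
    stop("number of maps (", length(maps), ") != design rows (", nrow(X), ")")
  r <- qr(X)$rank
  if (r < ncol(X)) stop("rank-deficient design")
  if (is.null(contrasts)) contrasts <- names(design$contrasts)
  missing_c <- setdiff(contrasts, names(design$contrasts))
  if (length(missing_c)) stop("unknown contrast(s): ", paste(missing_c, collapse = ", "))
  grid <- dim(vol_data(maps[[1]]))
  m <- if (is.null(mask)) full_mask(grid) else mask_data(mask)
  m <- joint_valid_mask(maps, m)
  Y <- vapply(maps, function(v) vol_data(v)[m], numeric(sum(m)))  # V x n
  Y <- t(Y)                                                       # n x V
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, Y)                                 # p x V
  res <- Y - X %*% B
  df <- nrow(X) - r
  s2 <- colSums(res^2) / df
  out <- list()
  for (cn in contrasts) {
    cv <- design$contrasts[[cn]]
    beta <- drop(crossprod(cv, B))
    se <- sqrt(drop(crossprod(cv, XtXinv %*% cv)) * s2)
    t <- beta / se
    out[[cn]] <- list(beta = beta, t = t, p = 2 * stats::pt(-abs(t), df))
  }
  structure(list(contrasts = out, mask = m, dim = grid, df = df, n = nrow(X)),
            class = "stat_maps")
}

#' @export
print.stat_maps <- function(x, ...) {
  cat(sprintf("<stat_maps> n = %d, df = %d, %d voxels, contrasts: %s\n",
              x$n, x$df, sum(x$mask), paste(names(x$contrasts), collapse = ", ")))
  invisible(x)
}

#' Extract a statistic volume from fitted stat maps
#'
#' @param statmaps a `stat_maps`.
#' @param contrast contrast name.
#' @param what `"t"`, `"beta"` or `"p"`.
#' @return A 3-D array (`NA` outside the mask).
#' @export
stat_volume <- function(statmaps, contrast, what = c("t", "beta", "p")) {
  what <- match.arg(what)
  stopifnot(inherits(statmaps, "stat_maps"))
  if (!contrast %in% names(statmaps$contrasts))
    stop("unknown contrast '", contrast, "'")
  out <- array(NA_real_, dim = statmaps$dim)
  out[statmaps$mask] <- statmaps$contrasts[[contrast]][[what]]
  out
}

#' FDR-threshold a contrast map
#'
#' Benjamini--Hochberg step-up applied to the voxel-wise p-values of one
#' contrast within the analysis mask; surviving voxels are signed by their
#' beta (+1 activation, -1 deactivation).
#'
#' @param statmaps a `stat_maps`.
#' @param contrast contrast name.
#' @param q FDR level (default 0.05).
#' @return A `thresholded_map`: list with `signed` (integer 3-D array in
#'   {-1, 0, +1}), `q`, `p_threshold` (attained p cutoff, `NA` if nothing
#'   survives), `n_significant`, `mask`, `dim`.
#' @export
threshold_map <- function(statmaps, contrast, q = 0.05) {
  stopifnot(inherits(statmaps, "stat_maps"))
  if (!contrast %in% names(statmaps$contrasts))
    stop("unknown contrast '", contrast, "'")
  sm <- statmaps$contrasts[[contrast]]
  bh <- fdr_bh(sm$p, q)
  signed <- array(0L, dim = statmaps$dim)
  idx <- which(statmaps$mask)
  signed[idx[bh$significant]] <- ifelse(sm$beta[bh$significant] > 0, 1L, -1L)
  structure(list(signed = signed, q = q, p_threshold = bh$threshold,
                 n_significant = sum(bh$significant), mask = statmaps$mask,
                 dim = statmaps$dim, contrast = contrast),
            class = "thresholded_map")
}

#' @export
print.thresholded_map <- function(x, ...) {
  cat(sprintf(
    "<thresholded_map> %s: %d significant voxels (q = %g, p <= %s); +%d / -%d\n",
    if (!is.null(x$contrast)) x$contrast else "map", x$n_significant, x$q,
    format(x$p_threshold, digits = 3), sum(x$signed == 1), sum(x$signed == -1)))
  invisible(x)
}

new_thresholded <- function(signed, template, contrast) {
  structure(list(signed = signed, q = template$q, p_threshold = NA_real_,
                 n_significant = sum(signed != 0), mask = template$mask,
                 dim = template$dim, contrast = contrast),
            class = "thresholded_map")
}

#' Minimum-statistic conjunction of thresholded maps
#'
#' A voxel is jointly significant only if it is significant with the same
#' sign in both maps: +1 where both are +1, -1 where both are -1, 0
#' elsewhere. Over already-FDR-thresholded maps this is the
#' minimum-statistic conjunction (intersection with sign agreement).
#'
#' @param a,b `thresholded_map`s on the same grid.
#' @return A `thresholded_map`.
#' @export
conjunction <- function(a, b) {
  stopifnot(inherits(a, "thresholded_map"), inherits(b, "thresholded_map"))
  if (!identical(a$dim, b$dim)) stop("grid mismatch between thresholded maps")
  signed <- array(0L, dim = a$dim)
  signed[a$signed == 1L & b$signed == 1L] <- 1L
  signed[a$signed == -1L & b$signed == -1L] <- -1L
  new_thresholded(signed, a, paste0("conjunction(", a$contrast, ", ", b$contrast, ")"))
}

#' Inclusively masked difference map
#'
#' Retains the significant voxels of a thresholded difference contrast (e.g.
#' somatic - visceral) only where an inclusive activation mask has the
#' stated direction: with `direction = "activation"` only where the
#' inclusive map is +1 (stimulation > baseline), with `"deactivation"` only
#' where it is -1. On the retained voxels the difference map keeps only the
#' matching sign (+1 differences for activation, -1 for deactivation), so
#' the result reads "activation occurs and is stronger for X" (or the
#' deactivation analogue).
#'
#' @param difference a `thresholded_map` of the difference contrast.
#' @param inclusive a `thresholded_map` providing the activation/
#'   deactivation mask (e.g. the `combined` baseline contrast).
#' @param direction `"activation"` or `"deactivation"`.
#' @return A `thresholded_map`.
#' @export
masked_difference <- function(difference, inclusive,
                              direction = c("activation", "deactivation")) {
  direction <- match.arg(direction)
  stopifnot(inherits(difference, "thresholded_map"))
  if (is.null(inclusive)) stop("missing inclusive mask")
  stopifnot(inherits(inclusive, "thresholded_map"))
  if (!identical(difference$dim, inclusive$dim))
    stop("grid mismatch between difference and inclusive maps")
  want <- if (direction == "activation") 1L else -1L
  signed <- array(0L, dim = difference$dim)
  keep <- difference$signed == want & inclusive$signed == want
  signed[keep] <- want
  new_thresholded(signed, difference,
                  paste0(difference$contrast, " [", direction, "-masked]"))
}

#' Write a thresholded map as NIfTI
#'
#' @param map a `thresholded_map` (or `stat_maps` via [stat_volume()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_thresholded <- function(map, path) {
  stopifnot(inherits(map, "thresholded_map"))
  write_volume(array(as.double(map$signed), dim = map$dim), path)
}
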