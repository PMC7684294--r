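#' Signature response of a contrast map
#'
#' The expression of a multivariate signature in a subject's contrast map:
#' the dot product of the vectorized map with the vectorized weight pattern,
#' optionally scaled by the l2 norms of both (cosine similarity). Cosine
#' scaling reduces differences in overall map scaling across studies and is
#' the default. Computation is restricted to the voxels that are finite in
#' both images and inside `mask`.
#'
#' @param map a [brain_volume] or 3-D array (subject contrast map).
#' @param pattern the signature weight map (same grid).
#' @param mask optional analysis mask; default is the full grid.
#' @param scaling `"cosine"` (default) or `"dot"`.
#' @return A single numeric score. Cosine scores lie in `[-1, 1]`.
#' @export
signature_response <- function(map, pattern, mask = NULL,
                               scaling = c("cosine", "dot")) {
  scaling <- match.arg(scaling)
  x <- vol_data(map); w <- vol_data(pattern)
  check_same_grid(x, w, "map and pattern")
  m <- if (is.null(mask)) full_mask(dim(x)) else mask_data(mask)
  m <- joint_valid_mask(list(x, w), m)
  xv <- x[m]; wv <- w[m]
  d <- sum(xv * wv)
  if (scaling == "dot") return(d)
  nx <- sqrt(sum(xv^2)); nw <- sqrt(sum(wv^2))
  if (nx == 0 || nw == 0)
    stop("degenerate input: zero-norm ", if (nx == 0) "map" else "pattern",
         " under cosine scaling")
  d / (nx * nw)
}

#' Signature responses for a whole cohort
#'
#' @param cohort a `pain_cohort` (or any list of maps via `maps =`).
#' @param pattern signature weight map; defaults to the cohort's planted
#'   signature.
#' @param mask optional analysis mask.
#' @param scaling `"cosine"` or `"dot"`.
#' @return [cohort_metadata()] with a `score` column appended.
#' @export
cohort_signature_responses <- function(cohort, pattern = NULL, mask = NULL,
                                       scaling = c("cosine", "dot")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(cohort, "pain_cohort"))
  if (is.null(pattern)) pattern <- cohort$signature
  meta <- cohort_metadata(cohort)
  maps <- cohort_maps(cohort)
  meta$score <- vapply(maps, signature_response, 0, pattern = pattern,
                       mask = mask, scaling = scaling)
  meta
}

#' Hedges--Olkin confidence interval for an effect size
#'
#' Normal-theory interval `d +/- z * sqrt(var)` with the two-independent-
#' group variance `var(d) = (n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2))`. For
#' within-subject contrast-versus-baseline designs both group sizes are set
#' to the study N. The multiplier is fixed at 1.96 for the default 95%
#' coverage.
#'
#' @param d effect size estimate (standardized mean difference).
#' @param n1,n2 group sizes (>= 2).
#' @param coverage interval coverage (default 0.95).
#' @return Numeric length-2 `c(lower, upper)`.
#' @export
hedges_olkin_ci <- function(d, n1, n2 = n1, coverage = 0.95) {
  stopifnot(n1 >= 2, n2 >= 2, coverage > 0, coverage < 1)
  z <- if (coverage == 0.95) 1.96 else stats::qnorm((1 + coverage) / 2)
  v <- (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))
  d + c(-1, 1) * z * sqrt(v)
}

#' One-study signature-response statistics
#'
#' Summary statistics of a vector of per-subject signature scores from a
#' contrast-versus-baseline design, where the baseline condition's score is 0
#' by construction (the contrast image already encodes the difference): mean,
#' SE, two-tailed one-sample t test against 0, effect size `d_a = mean / SD`
#' with its Hedges--Olkin 95% CI, and forced-choice accuracy (the proportion
#' of subjects whose score exceeds 0; ties count as incorrect).
#'
#' @param scores numeric vector of per-subject scores (n >= 2).
#' @return An `effect_size_result`: list with `n`, `mean`, `se`, `t`, `df`,
#'   `p`, `d_a`, `ci_low`, `ci_high`, `accuracy`.
#' @export
study_signature_stats <- function(scores) {
  scores <- as.numeric(scores)
  n <- length(scores)
  if (n < 2) stop("need at least 2 scores")
  if (any(!is.finite(scores))) stop("scores must be finite")
  s <- stats::sd(scores)
  if (s == 0) stop("degenerate variance: all scores identical")
  m <- mean(scores)
  se <- s / sqrt(n)
  t <- m / se
  df <- n - 1
  p <- 2 * stats::pt(-abs(t), df)
  d_a <- m / s
  ci <- hedges_olkin_ci(d_a, n, n)
  structure(list(n = n, mean = m, se = se, t = t, df = df, p = p, d_a = d_a,
                 ci_low = ci[1], ci_high = ci[2], accuracy = mean(scores > 0)),
            class = "effect_size_result")
}

#' @export
print.effect_size_result <- function(x, ...) {
  cat(sprintf("signature response %.4g +/- %.4g [t(%d) = %.2f, p = %.3g]\n",
              x$mean, x$se, x$df, x$t, x$p))
  cat(sprintf("  d_a = %.2f [%.3f, %.3f], forced-choice accuracy = %.1f%%\n",
              x$d_a, x$ci_low, x$ci_high, 100 * x$accuracy))
  invisible(x)
}

#' Per-study effect-size table for a cohort
#'
#' Applies [study_signature_stats()] to each study's scores.
#'
#' @param scores data.frame as from [cohort_signature_responses()].
#' @return One row per study: n, mean, se, t, df, p, d_a, CI, accuracy.
#' @export
cohort_signature_stats <- function(scores) {
  stopifnot(all(c("study", "score") %in% names(scores)))
  out <- lapply(split(scores, scores$study), function(d) {
    st <- study_signature_stats(d$score)
    data.frame(study = d$study[1], study_name = d$study_name[1],
               modality = d$modality[1], n = st$n, mean = st$mean, se = st$se,
               t = st$t, df = st$df, p = st$p, d_a = st$d_a,
               ci_low = st$ci_low, ci_high = st$ci_high,
               accuracy = st$accuracy, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$study), , drop = FALSE]
}

#' Spatial similarity between two maps
#'
#' Whole-brain Pearson correlation between the voxel vectors of a map and a
#' reference over the joint valid mask. When the reference is a binary parcel
#' mask the same quantity is a point-biserial correlation; `kind =
#' "point_biserial"` additionally validates that the reference is 0/1.
#'
#' @param map,reference volumes on the same grid.
#' @param mask optional analysis mask.
#' @param kind `"pearson"` (default) or `"point_biserial"`.
#' @return Pearson r in `[-1, 1]`.
#' @export
spatial_similarity <- function(map, reference, mask = NULL,
                               kind = c("pearson", "point_biserial")) {
  kind <- match.arg(kind)
  x <- vol_data(map)
  r <- if (kind == "point_biserial") {
    md <- mask_data(reference)
    array(as.double(md), dim = dim(md))
  } else vol_data(reference)
  check_same_grid(x, r, "map and reference")
  m <- if (is.null(mask)) full_mask(dim(x)) else mask_data(mask)
  m <- joint_valid_mask(list(x, r), m)
  if (sum(m) < 3) stop("joint valid mask has fewer than 3 voxels")
  xv <- x[m]; rv <- r[m]
  if (stats::sd(rv) == 0 || stats::sd(xv) == 0)
    stop("undefined correlation: constant input on the mask")
  stats::cor(xv, rv)
}

#' Group test of spatial similarities
#'
#' One-sample two-tailed t test of per-subject spatial correlations against
#' zero, performed on Fisher r-to-z transformed values (`atanh(r)`); the mean
#' is reported on the r scale.
#'
#' @param r numeric vector of per-subject correlations, all strictly inside
#'   `(-1, 1)`.
#' @return List with `mean_r`, `se_r`, `t`, `df`, `p`, `d_a` (on the z
#'   scale), `n`.
#' @export
group_similarity_test <- function(r) {
  r <- as.numeric(r)
  if (length(r) < 2) stop("need at least 2 correlations")
  if (any(abs(r) >= 1)) stop("infinite z: |r| = 1 cannot be Fisher-transformed")
  z <- atanh(r)
  if (stats::sd(z) == 0) stop("degenerate variance: all correlations identical")
  tt <- stats::t.test(z)
  list(mean_r = mean(r), se_r = stats::sd(r) / sqrt(length(r)),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d_a = mean(z) / stats::sd(z), n = length(r))
}

#' Repeated-measures comparison of signature similarities
#'
#' One-way repeated-measures ANOVA over a complete subjects x signatures
#' matrix of Fisher-z similarities (df1 = k - 1, df2 = (k - 1)(n - 1)),
#' followed by paired t tests of each signature against the first
#' (reference) column with Bonferroni correction.
#'
#' @param zmat numeric matrix, subjects in rows, signatures in columns
#'   (Fisher-z scale); column names label the signatures.
#' @return List with `F`, `df1`, `df2`, `p` and a data.frame `pairwise`
#'   (signature, t, df, p_uncorrected, p_bonferroni).
#' @export
compare_signatures_rm_anova <- function(zmat) {
  zmat <- as.matrix(zmat)
  if (any(!is.finite(zmat))) stop("incomplete design: missing or non-finite cells")
  n <- nrow(zmat); k <- ncol(zmat)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 signatures")
  if (is.null(colnames(zmat))) colnames(zmat) <- paste0("sig", seq_len(k))
  # explicit degenerate-variance check: zero within-subject residual SS
  grand <- mean(zmat)
  ss_tot <- sum((zmat - grand)^2)
  ss_err <- ss_tot - n * sum((colMeans(zmat) - grand)^2) -
    k * sum((rowMeans(zmat) - grand)^2)
  if (ss_err <= 1e-10 * max(ss_tot, .Machine$double.xmin))
    stop("degenerate ANOVA: zero within-subject error variance")
  long <- data.frame(
    z = as.vector(zmat),
    subject = factor(rep(seq_len(n), times = k)),
    signature = factor(rep(colnames(zmat), each = n), levels = colnames(zmat))
  )
  fit <- stats::aov(z ~ signature + Error(subject), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  Fval <- tab["signature", "F value"]
  df1 <- tab["signature", "Df"]
  df2 <- tab["Residuals", "Df"]
  pval <- tab["signature", "Pr(>F)"]
  if (!is.finite(Fval)) stop("degenerate ANOVA: zero within-subject variance")
  pw <- do.call(rbind, lapply(seq_len(k)[-1], function(j) {
    tt <- stats::t.test(zmat[, 1], zmat[, j], paired = TRUE)
    data.frame(signature = colnames(zmat)[j], t = unname(tt$statistic),
               df = unname(tt$parameter), p_uncorrected = tt$p.value,
               p_bonferroni = min(1, tt$p.value * (k - 1)),
               stringsAsFactors = FALSE)
  }))
  rownames(pw) <- NULL
  list(F = unname(Fval), df1 = unname(df1), df2 = unname(df2), p = unname(pval),
       pairwise = pw)
}

#' Benjamini--Hochberg FDR thresholding
#'
#' Step-up procedure controlling the false discovery rate at level `q`:
#' a p-value is declared significant iff its BH-adjusted value is at most
#' `q`. Also returns the attained p-value threshold (the largest raw p among
#' the significant set, `NA` if none).
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with logical `significant` and scalar `threshold`.
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  p <- as.numeric(pvalues)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  sig <- stats::p.adjust(p, method = "BH") <= q
  list(significant = sig,
       threshold = if (any(sig)) max(p[sig]) else NA_real_)
}
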