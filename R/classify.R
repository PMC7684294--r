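# Coerce class labels to 0/1 with 1 = positive class.
coerce_labels <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  lv <- unique(as.character(labels))
  if (length(lv) > 2) stop("labels must have at most 2 classes, got ", length(lv))
  if (is.null(positive)) {
    hit <- intersect(c("somatic", "pain"), lv)
    if (length(hit) == 0)
      stop("cannot infer the positive class from labels {",
           paste(lv, collapse = ", "), "}; supply `positive`")
    positive <- hit[1]
  }
  as.integer(as.character(labels) == positive)
}

#' Standard error of a proportion
#'
#' `sqrt(p (1 - p) / n)`, the binomial SE used for all classification-rate
#' uncertainties.
#'
#' @param p proportion in `[0, 1]`.
#' @param n sample size.
#' @return Numeric SE.
#' @export
prop_se <- function(p, n) {
  stopifnot(all(p >= 0 & p <= 1), all(n >= 1))
  sqrt(p * (1 - p) / n)
}

#' Empirical AUROC
#'
#' Area under the empirical ROC curve, computed as the Mann--Whitney
#' statistic `U / (n1 n0)` via midranks, so tied scores count 1/2.
#'
#' @param scores numeric scores (higher = more positive-class-like).
#' @param labels binary labels (1/`"pain"`/`"somatic"` = positive).
#' @param positive positive class label when `labels` is character/factor.
#' @return AUC in `[0, 1]`.
#' @export
empirical_auroc <- function(scores, labels, positive = NULL) {
  y <- coerce_labels(labels, positive)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n1 <- as.numeric(sum(y == 1)); n0 <- as.numeric(sum(y == 0))
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binormal ROC model
#'
#' ROC curve implied by Gaussian models of each class's scores, without an
#' equal-variance constraint: `AUC = Phi((mu1 - mu0) / sqrt(s1^2 + s0^2))`.
#' The standardized separation `d_a` uses the pooled SD, so under equal
#' variances `AUC = Phi(d_a / sqrt(2))`.
#'
#' @inheritParams empirical_auroc
#' @param n_points number of cutoffs at which to evaluate the fitted curve.
#' @return A `binormal_roc`: list with `auc`, `d_a`, class means/SDs and a
#'   `curve` data.frame (`cutoff`, `fpr`, `tpr`).
#' @export
binormal_roc <- function(scores, labels, positive = NULL, n_points = 101L) {
  y <- coerce_labels(labels, positive)
  s1 <- scores[y == 1]; s0 <- scores[y == 0]
  if (length(s1) < 2 || length(s0) < 2) stop("need >= 2 scores per class")
  m1 <- mean(s1); m0 <- mean(s0)
  v1 <- stats::var(s1); v0 <- stats::var(s0)
  if (v1 == 0 || v0 == 0) stop("degenerate: zero within-class variance")
  pooled <- sqrt(((length(s1) - 1) * v1 + (length(s0) - 1) * v0) /
                 (length(s1) + length(s0) - 2))
  auc <- stats::pnorm((m1 - m0) / sqrt(v1 + v0))
  cuts <- seq(min(scores) - 3 * sqrt(max(v1, v0)),
              max(scores) + 3 * sqrt(max(v1, v0)), length.out = n_points)
  curve <- data.frame(cutoff = cuts,
                      fpr = 1 - stats::pnorm(cuts, m0, sqrt(v0)),
                      tpr = 1 - stats::pnorm(cuts, m1, sqrt(v1)))
  structure(list(auc = auc, d_a = (m1 - m0) / pooled, mu1 = m1, mu0 = m0,
                 sd1 = sqrt(v1), sd0 = sqrt(v0), curve = curve),
            class = "binormal_roc")
}

#' @export
print.binormal_roc <- function(x, ...) {
  cat(sprintf("<binormal_roc> AUC = %.3f, d_a = %.2f (mu1 = %.3g, mu0 = %.3g)\n",
              x$auc, x$d_a, x$mu1, x$mu0))
  invisible(x)
}

#' @export
plot.binormal_roc <- function(x, ...) {
  plot(x$curve$fpr, x$curve$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate", ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Single-interval classification report
#'
#' Labels each observation positive iff its score exceeds a single cutoff,
#' with the cutoff selected to maximize overall accuracy on the supplied
#' data (ties broken toward the lowest such cutoff; candidate cutoffs are
#' midpoints between adjacent distinct scores, plus one below the minimum
#' and one above the maximum). Reports sensitivity, specificity, overall and
#' balanced accuracy with binomial SEs, empirical and binormal AUROC, and
#' the standardized separation `d_a`.
#'
#' @inheritParams empirical_auroc
#' @param cutoff optional fixed cutoff; if `NULL` (default) the
#'   accuracy-maximizing cutoff is selected.
#' @return A `classification_report`.
#' @export
single_interval_classify <- function(scores, labels, positive = NULL,
                                     cutoff = NULL) {
  y <- coerce_labels(labels, positive)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  if (is.null(cutoff)) {
    u <- sort(unique(scores))
    cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
              u[length(u)] + 1)
    acc <- vapply(cand, function(cc) mean((scores > cc) == (y == 1)), 0)
    cutoff <- cand[which.max(acc)]   # which.max returns the first (lowest) max
  }
  pred <- as.integer(scores > cutoff)
  sens <- mean(pred[y == 1] == 1)
  spec <- mean(pred[y == 0] == 0)
  accuracy <- mean(pred == y)
  n <- length(y)
  balanced <- (sens + spec) / 2
  bin <- tryCatch(binormal_roc(scores, y), error = function(e) NULL)
  structure(list(
    cutoff = cutoff, n = n, n_positive = n1, n_negative = n0,
    sensitivity = sens, sensitivity_se = prop_se(sens, n1),
    specificity = spec, specificity_se = prop_se(spec, n0),
    accuracy = accuracy, accuracy_se = prop_se(accuracy, n),
    balanced_accuracy = balanced,
    balanced_accuracy_se = sqrt(prop_se(sens, n1)^2 + prop_se(spec, n0)^2) / 2,
    auroc = empirical_auroc(scores, y),
    auroc_binormal = if (is.null(bin)) NA_real_ else bin$auc,
    d_a = if (is.null(bin)) NA_real_ else bin$d_a,
    predicted = pred
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> n = %d (%d+/%d-), cutoff = %.4g\n",
              x$n, x$n_positive, x$n_negative, x$cutoff))
  cat(sprintf("  AUROC = %.2f (binormal %.2f), d_a = %.2f\n",
              x$auroc, x$auroc_binormal, x$d_a))
  cat(sprintf("  sensitivity = %.0f%%, specificity = %.0f%%\n",
              100 * x$sensitivity, 100 * x$specificity))
  cat(sprintf("  accuracy = %.0f +/- %.1f%%, balanced = %.0f +/- %.1f%%\n",
              100 * x$accuracy, 100 * x$accuracy_se,
              100 * x$balanced_accuracy, 100 * x$balanced_accuracy_se))
  invisible(x)
}

#' Network-similarity features of a map
#'
#' Fisher-z transformed point-biserial correlations between a contrast map
#' and each atlas parcel, in fixed atlas order, computed over the analysis
#' mask. These are the inputs to the somatovisceral classifier.
#'
#' @param map a [brain_volume] or 3-D array.
#' @param atlas a `network_atlas`.
#' @param mask optional analysis mask.
#' @return Named numeric vector, one `atanh(r_pb)` per parcel.
#' @export
network_features <- function(map, atlas, mask = NULL) {
  stopifnot(inherits(atlas, "network_atlas"))
  x <- vol_data(map)
  m <- if (is.null(mask)) full_mask(dim(x)) else mask_data(mask)
  m <- joint_valid_mask(list(x), m)
  n_mask <- sum(m)
  z <- vapply(seq_along(atlas$parcels), function(k) {
    n_in <- sum(atlas$parcels[[k]] & m)
    if (n_in == 0) stop("parcel '", atlas$names[k], "' empty within the mask")
    if (n_in == n_mask)
      stop("parcel '", atlas$names[k], "' covers the whole mask: indicator undefined")
    ind <- array(0, dim = dim(x)); ind[atlas$parcels[[k]]] <- 1
    r <- stats::cor(x[m], ind[m])
    if (abs(r) >= 1) stop("infinite z: |r| = 1 for parcel '", atlas$names[k], "'")
    atanh(r)
  }, 0)
  names(z) <- atlas$names
  z
}

#' Network features for a whole cohort
#'
#' @param cohort a `pain_cohort`.
#' @param studies optional vector of study ids to include (default all).
#' @param mask optional analysis mask.
#' @return List with `features` (subjects x parcels matrix), `labels`
#'   (modality character vector) and `meta` (metadata rows).
#' @export
cohort_network_features <- function(cohort, studies = NULL, mask = NULL) {
  stopifnot(inherits(cohort, "pain_cohort"))
  meta <- cohort_metadata(cohort)
  maps <- cohort_maps(cohort)
  keep <- if (is.null(studies)) rep(TRUE, nrow(meta)) else meta$study %in% studies
  feats <- t(vapply(maps[keep], network_features, numeric(length(cohort$atlas)),
                    atlas = cohort$atlas, mask = mask))
  rownames(feats) <- meta$subject[keep]
  list(features = feats, labels = meta$modality[keep], meta = meta[keep, , drop = FALSE])
}

#' Fit the network-based logistic classifier
#'
#' Unregularized maximum-likelihood logistic regression of class (somatic
#' coded 1) on the network feature vector, fitted by IRLS (deviance
#' tolerance 1e-8, at most 100 iterations), with Wald standard errors and
#' two-tailed p-values. Complete or quasi-complete separation is detected
#' (diverging coefficients with fitted probabilities at 0/1) and flagged via
#' a warning and the `separation` field; coefficients are still returned.
#'
#' @param features numeric matrix (subjects x networks) with column names.
#' @param labels binary class labels (1/`"somatic"` = positive).
#' @param positive positive class label when `labels` is character/factor.
#' @param threshold decision threshold on the predicted probability
#'   (default 0.5).
#' @return A `network_logit`: coefficients, SEs, z and p-values, deviance,
#'   convergence/separation flags, feature names and decision threshold.
#' @export
fit_logistic <- function(features, labels, positive = NULL, threshold = 0.5) {
  features <- as.matrix(features)
  y <- coerce_labels(labels, positive)
  if (nrow(features) != length(y)) stop("features and labels differ in length")
  if (sum(y == 1) == 0 || sum(y == 0) == 0) stop("both classes must be present")
  if (nrow(features) <= ncol(features) + 1)
    stop("need n > number of features + 1")
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  dat <- data.frame(.y = y, features, check.names = FALSE)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  separation <- sep_warn && any(abs(stats::coef(fit)) > 15)
  if (separation)
    warning("possible complete/quasi-complete separation: coefficients unstable")
  sm <- summary(fit)$coefficients
  structure(list(coefficients = stats::coef(fit), se = sm[, "Std. Error"],
                 z = sm[, "z value"], p = sm[, "Pr(>|z|)"],
                 deviance = fit$deviance, converged = fit$converged,
                 separation = separation,
                 feature_names = colnames(features), threshold = threshold,
                 n = nrow(features)),
            class = "network_logit")
}

#' @export
print.network_logit <- function(x, ...) {
  cat(sprintf("<network_logit> n = %d, deviance = %.2f, threshold = %.2f%s\n",
              x$n, x$deviance, x$threshold,
              if (x$separation) " [separation flagged]" else ""))
  tab <- data.frame(beta = x$coefficients, se = x$se, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.network_logit <- function(object, ...) object$coefficients

#' @rdname fit_logistic
#' @param object a `network_logit`.
#' @param newdata feature matrix with the same column names as used in
#'   training.
#' @param type `"response"` (probability of the positive class) or `"link"`.
#' @param ... unused.
#' @export
predict.network_logit <- function(object, newdata, type = c("response", "link"),
                                  ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)) ||
      !identical(colnames(newdata), object$feature_names))
    stop("feature contract violated: columns must be {",
         paste(object$feature_names, collapse = ", "), "} in that order")
  eta <- drop(cbind(1, newdata) %*% object$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}

# Deterministic class-stratified fold assignment. k >= n degenerates to
# leave-one-out (one subject per fold, independent of the seed).
stratified_folds <- function(y, k, seed) {
  if (k >= length(y)) return(seq_along(y))
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  })
  folds
}

#' Cross-validated network classifier
#'
#' Stratified k-fold cross-validation of [fit_logistic()]: each subject's
#' class probability is predicted by the model not trained on their fold;
#' the final model's coefficients are the unweighted mean of the fold
#' models' coefficients. The report is computed from the cross-validated
#' probabilities at the accuracy-maximizing probability threshold; the
#' model's prospective decision threshold stays at `threshold` (0.5 by
#' default).
#'
#' @inheritParams fit_logistic
#' @param k number of folds (>= 2, default 10).
#' @param seed RNG seed for the fold randomization (mandatory).
#' @param folds optional explicit integer fold assignment in `1..k`
#'   (overrides the seeded stratified assignment).
#' @return A `crossval_result`: `probabilities` (per subject, CV),
#'   `labels`, `report` ([single_interval_classify] of the CV
#'   probabilities), `model` (fold-averaged `network_logit`, including
#'   `cv_threshold`), `folds`, `seed`.
#' @export
crossval_classifier <- function(features, labels, k = 10L, seed = 1L,
                                positive = NULL, threshold = 0.5,
                                folds = NULL) {
  if (k < 2) stop("k must be >= 2")
  features <- as.matrix(features)
  y <- coerce_labels(labels, positive)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  if (is.null(folds)) folds <- stratified_folds(y, k, seed)
  stopifnot(length(folds) == length(y), all(folds %in% seq_len(k)))
  prob <- rep(NA_real_, length(y))
  coefs <- NULL
  n_separated <- 0L
  for (f in sort(unique(folds))) {
    tr <- folds != f
    # separation inside a training fold is expected with well-separated
    # classes; count it rather than warn once per fold
    m <- withCallingHandlers(
      fit_logistic(features[tr, , drop = FALSE], y[tr], threshold = threshold),
      warning = function(w) {
        if (grepl("separation", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    if (m$separation) n_separated <- n_separated + 1L
    coefs <- rbind(coefs, m$coefficients)
    if (any(!tr))
      prob[!tr] <- predict(m, features[!tr, , drop = FALSE])
  }
  avg <- colMeans(coefs)
  model <- structure(list(coefficients = avg, se = NULL, z = NULL, p = NULL,
                          deviance = NA_real_, converged = TRUE,
                          separation = FALSE,
                          feature_names = colnames(features),
                          threshold = threshold, n = nrow(features)),
                     class = "network_logit")
  report <- single_interval_classify(prob, y)
  model$cv_threshold <- report$cutoff
  names(prob) <- rownames(features)
  structure(list(probabilities = prob, labels = y, report = report,
                 model = model, fold_coefficients = coefs, folds = folds,
                 n_separated_folds = n_separated, seed = seed, k = k),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("<crossval_result> %d-fold CV, n = %d, seed = %s\n",
              x$k, length(x$labels), format(x$seed)))
  print(x$report)
  invisible(x)
}

#' Stability of the cross-validated classifier
#'
#' Repeats the whole k-fold procedure `n_iter` times with independent fold
#' randomizations and summarizes (a) the SD of the cross-validated
#' classification error (at the model's decision threshold) and (b) the mean
#' pairwise Pearson correlation of the fold-averaged coefficient vectors
#' across iterations.
#'
#' @inheritParams crossval_classifier
#' @param n_iter number of independent fold randomizations (>= 2).
#' @return List with `sd_error`, `mean_coef_correlation`, per-iteration
#'   `errors` and the `coefficients` matrix (iterations x parameters).
#' @export
stability_assessment <- function(features, labels, n_iter = 1000L, k = 10L,
                                 seed = 1L, positive = NULL) {
  if (n_iter < 2) stop("n_iter must be >= 2 to estimate an SD")
  y <- coerce_labels(labels, positive)
  errors <- numeric(n_iter)
  coefs <- NULL
  for (i in seq_len(n_iter)) {
    cv <- crossval_classifier(features, y, k = k, seed = seed + i - 1L)
    errors[i] <- mean((cv$probabilities > cv$model$threshold) != (y == 1))
    coefs <- rbind(coefs, cv$model$coefficients)
  }
  cc <- stats::cor(t(coefs))
  list(sd_error = stats::sd(errors),
       mean_coef_correlation = mean(cc[upper.tri(cc)]),
       errors = errors, coefficients = coefs)
}

#' Apply a trained classifier to new data
#'
#' Predicts each subject's class (somatic iff predicted probability exceeds
#' the model's decision threshold) and summarizes the proportion classified
#' somatic with its binomial SE.
#'
#' @param model a `network_logit` (typically the fold-averaged model from
#'   [crossval_classifier()]).
#' @param features feature matrix with the training column order.
#' @return List with `class` (character), `prob`, `p_somatic`, `se`, `n`.
#' @export
apply_classifier <- function(model, features) {
  stopifnot(inherits(model, "network_logit"))
  prob <- predict(model, features)
  cls <- ifelse(prob > model$threshold, "somatic", "visceral")
  p <- mean(cls == "somatic")
  list(class = cls, prob = prob, p_somatic = p, se = prop_se(p, length(cls)),
       n = length(cls))
}

#' Exact two-sided binomial test (doubled smaller tail)
#'
#' `p = min(1, 2 min(P(X <= k), P(X >= k)))` under `Binomial(n, p0)`. This
#' doubled-smaller-tail convention is used to compare classification rates
#' in held-out studies against a fixed null proportion.
#'
#' @param k number of successes (0..n).
#' @param n number of trials.
#' @param p0 null success probability in (0, 1).
#' @return Two-sided p-value.
#' @export
binomial_test_two_sided <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  lo <- stats::pbinom(k, n, p0)
  hi <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  min(1, 2 * min(lo, hi))
}
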