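test_that("empirical AUROC equals all-pairs counting, with ties at half", {
  expect_equal(empirical_auroc(c(1, 2, 10, 11), c(0, 0, 1, 1)), 1)
  expect_error(empirical_auroc(1:4, c(1, 1, 1, 1)), "both classes")

  set.seed(71)
  big <- empirical_auroc(rnorm(4000), rep(0:1, 2000))
  expect_lt(abs(big - 0.5), 0.05)

  for (seed in 1:20) {
    set.seed(seed)
    s <- sample(1:8, 40, replace = TRUE)  # heavy ties
    y <- rbinom(40, 1, 0.4)
    if (sum(y) %in% c(0, 40)) next
    expect_equal(empirical_auroc(s, y), auroc_brute(s, y))
  }
})

test_that("binormal ROC matches its closed form and the empirical curve", {
  set.seed(72)
  s0 <- rnorm(50); s1 <- rnorm(50)  # zero separation
  b <- binormal_roc(c(s0, s1), rep(0:1, each = 50))
  expect_equal(b$auc, pnorm((mean(s1) - mean(s0)) / sqrt(var(s1) + var(s0))))

  # equal-variance identity AUC = Phi(d_a / sqrt(2)): a d_a of 2.13
  # corresponds to AUC ~ 0.934
  expect_equal(pnorm(2.13 / sqrt(2)), 0.934, tolerance = 5e-4)
  set.seed(73)
  x0 <- rnorm(2000); x1 <- rnorm(2000, 2.13)
  bb <- binormal_roc(c(x0, x1), rep(0:1, each = 2000))
  expect_equal(bb$auc, pnorm(bb$d_a / sqrt(2)), tolerance = 0.01)

  # large-sample agreement between empirical and binormal AUC
  set.seed(74)
  y <- rep(0:1, each = 50000)
  s <- c(rnorm(50000), rnorm(50000, 1))
  expect_lt(abs(empirical_auroc(s, y) - binormal_roc(s, y)$auc), 0.01)

  expect_error(binormal_roc(c(1, 1, 2, 3), c(1, 1, 0, 0)), "degenerate")
})

test_that("single-interval cutoff maximizes accuracy with lowest-cutoff ties", {
  rep1 <- single_interval_classify(c(1, 2, 3), c(0, 1, 1))
  expect_gt(rep1$cutoff, 1); expect_lt(rep1$cutoff, 2)
  expect_equal(rep1$accuracy, 1)
  expect_equal(rep1$sensitivity, 1)
  expect_equal(rep1$specificity, 1)

  expect_equal(prop_se(0.86, 270), 0.0211, tolerance = 1e-3)

  # exhaustive-scan oracle: no other midpoint does better, and ties go to
  # the lowest cutoff
  for (seed in 1:10) {
    set.seed(seed)
    s <- rnorm(200); y <- rbinom(200, 1, 0.5)
    rep <- single_interval_classify(s, y)
    u <- sort(unique(s))
    cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
    accs <- vapply(cand, function(cc) mean((s > cc) == (y == 1)), 0)
    expect_equal(rep$accuracy, max(accs))
    expect_equal(rep$cutoff, cand[which.max(accs)])
  }

  expect_error(single_interval_classify(1:3, c(1, 1, 1)), "both classes")
  # fixed-cutoff evaluation path
  repf <- single_interval_classify(c(1, 2, 3, 4), c(0, 0, 1, 1), cutoff = 3.5)
  expect_equal(repf$sensitivity, 0.5)
  expect_equal(repf$specificity, 1)
})

test_that("network features pick out loaded parcels and reject degeneracies", {
  grid <- c(8, 8, 8)
  atlas <- make_atlas(grid, 7, seed = 2)

  hits <- vapply(1:100, function(sd) {
    set.seed(sd)
    x <- 1.5 * atlas$parcels[[1]] + array(rnorm(prod(grid)), dim = grid)
    which.max(network_features(x, atlas))
  }, 0L)
  expect_gt(mean(hits == 1L), 0.95)

  set.seed(81)
  noise <- array(rnorm(22^3), dim = c(22, 22, 22))
  atlas_big <- make_atlas(c(22, 22, 22), 7, seed = 3)
  expect_true(all(abs(network_features(noise, atlas_big)) < 0.05))

  # parcel identical to the whole mask -> indicator undefined
  atlas2 <- make_atlas(grid, 2, seed = 4)
  expect_error(network_features(rand_volume(grid), atlas2,
                                mask = atlas2$parcels[[1]]),
               "covers the whole mask|empty within")
  # indicator map itself would give |r| = 1: degenerate is caught
  ind <- array(0, dim = grid); ind[atlas$parcels[[1]]] <- 1
  expect_error(network_features(ind, atlas), "infinite z|undefined")
})

test_that("logistic fitting recovers parameters and is deterministic", {
  set.seed(91)
  n <- 5000
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  beta <- c(-0.5, 1, -1.5, 0)
  pr <- plogis(beta[1] + X %*% beta[-1])
  y <- rbinom(n, 1, pr)
  fit <- fit_logistic(X, y)
  expect_true(all(abs(fit$coefficients - beta) < 3 * fit$se))
  fit2 <- fit_logistic(X, y)
  expect_identical(fit$coefficients, fit2$coefficients)
  expect_false(fit$separation)

  # glm oracle: identical coefficients
  oracle <- glm(y ~ X, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(oracle)), tolerance = 1e-8)

  # type-I error of coefficient Wald tests under the null
  set.seed(92)
  fp <- replicate(100, {
    Xn <- matrix(rnorm(500 * 2), 500, 2)
    yn <- rbinom(500, 1, 0.5)
    fit_logistic(Xn, yn)$p[-1] < 0.05
  })
  expect_lt(mean(fp), 0.10)

  # complete separation is flagged, coefficients still returned
  Xs <- matrix(c(seq(-3, -1, length.out = 20), seq(1, 3, length.out = 20)),
               ncol = 1, dimnames = list(NULL, "a"))
  ys <- rep(0:1, each = 20)
  expect_warning(fs <- fit_logistic(Xs, ys), "separation")
  expect_true(fs$separation)
  expect_true(all(is.finite(fs$coefficients)))
})

test_that("predict enforces the feature contract", {
  set.seed(93)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  y <- rbinom(50, 1, 0.5)
  m <- fit_logistic(X, y)
  expect_error(predict(m, X[, c(2, 1, 3, 4)]), "feature contract")
  p <- predict(m, X)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(qlogis(p), predict(m, X, type = "link"))
})

test_that("cross-validation is seeded, leak-free and honest under shuffling", {
  co <- simulate_cohort(training_pair_config(grid = c(8, 8, 8), seed = 10))
  f <- cohort_network_features(co)

  cv1 <- crossval_classifier(f$features, f$labels, k = 10, seed = 5)
  cv2 <- crossval_classifier(f$features, f$labels, k = 10, seed = 5)
  expect_identical(cv1$probabilities, cv2$probabilities)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$report$auroc, cv2$report$auroc)
  expect_false(identical(cv1$folds,
                         crossval_classifier(f$features, f$labels,
                                             k = 10, seed = 6)$folds))
  # stratification balances fold sizes
  expect_true(all(table(cv1$folds) >= 4))

  # leak test: flipping one held-out subject's label cannot change that
  # subject's own prediction when the folds are held fixed
  y0 <- as.integer(f$labels == "somatic")
  i <- 7L
  y1 <- y0; y1[i] <- 1L - y1[i]
  cva <- crossval_classifier(f$features, y0, k = 10, seed = 5,
                             folds = cv1$folds)
  cvb <- crossval_classifier(f$features, y1, k = 10, seed = 5,
                             folds = cv1$folds)
  expect_equal(cva$probabilities[i], cvb$probabilities[i])

  # label shuffling destroys performance
  set.seed(94)
  aucs <- replicate(3, {
    ys <- sample(f$labels)
    crossval_classifier(f$features, ys, k = 10, seed = 1)$report$auroc
  })
  expect_true(all(aucs > 0.25 & aucs < 0.75))

  expect_error(crossval_classifier(f$features, f$labels, k = 1), "k must be")
})

test_that("stability assessment summarizes repeated fold randomizations", {
  co <- simulate_cohort(training_pair_config(grid = c(8, 8, 8), seed = 11))
  f <- cohort_network_features(co)
  st <- stability_assessment(f$features, f$labels, n_iter = 10, k = 10, seed = 2)
  expect_length(st$errors, 10)
  expect_gt(st$mean_coef_correlation, 0.9)   # separable data: stable estimates
  expect_error(stability_assessment(f$features, f$labels, n_iter = 1), "n_iter")

  # leave-one-out folds admit a single partition: zero error variance
  y <- as.integer(f$labels == "somatic")
  n <- length(y)
  lo <- stability_assessment(f$features, y, n_iter = 3, k = n, seed = 3)
  expect_equal(lo$sd_error, 0)
})

test_that("apply_classifier reports proportions with binomial SEs", {
  m <- structure(list(coefficients = c(`(Intercept)` = 0, a = 5),
                      feature_names = "a", threshold = 0.5, n = 30,
                      separation = FALSE, converged = TRUE),
                 class = "network_logit")
  X <- matrix(c(rep(1, 29), -1), ncol = 1, dimnames = list(NULL, "a"))
  out <- apply_classifier(m, X)
  expect_equal(out$p_somatic, 29 / 30)
  expect_equal(out$se, 0.0328, tolerance = 1e-3)
  expect_equal(prop_se(10 / 15, 15), 0.1217, tolerance = 1e-3)
  X0 <- matrix(rep(-1, 12), ncol = 1, dimnames = list(NULL, "a"))
  expect_equal(apply_classifier(m, X0)$se, 0)
})

test_that("two-sided binomial test doubles the smaller tail and caps at 1", {
  expect_equal(round(binomial_test_two_sided(13, 15, 0.6249), 3), 0.083)
  expect_equal(binomial_test_two_sided(15, 15, 0.5), 2 * 0.5^15)
  expect_equal(binomial_test_two_sided(5, 10, 0.5), 1)  # mode of the null
})
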