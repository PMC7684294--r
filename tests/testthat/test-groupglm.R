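make_glm_fixture <- function(n_vox = 60, seed = 1) {
  # flat list of "maps" as 1 x 1 x n_vox grids for fast voxel-wise checks
  set.seed(seed)
  study <- rep(c("1", "2", "6", "7"), times = c(6, 5, 7, 6))
  modality <- ifelse(study %in% c("1", "2"), "visceral", "somatic")
  des <- group_design(study, modality)
  maps <- lapply(seq_along(study), function(i)
    array(rnorm(n_vox, mean = ifelse(modality[i] == "somatic", 0.5, 0)),
          dim = c(1, 1, n_vox)))
  list(des = des, maps = maps, study = study, modality = modality)
}

test_that("group design is full rank with interpretable contrasts", {
  fx <- make_glm_fixture()
  X <- fx$des$X
  expect_equal(qr(X)$rank, ncol(X))
  expect_equal(nrow(X), length(fx$study))
  # contrast vectors exist and are consistent
  cs <- fx$des$contrasts
  expect_setequal(names(cs), c("combined", "somatic", "visceral",
                               "somatic_vs_visceral", "visceral_vs_somatic"))
  expect_equal(cs$somatic_vs_visceral, cs$somatic - cs$visceral)
  expect_equal(cs$combined, (cs$somatic + cs$visceral) / 2)

  # a manually collinear design is rejected
  bad <- fx$des
  bad$X <- cbind(bad$X, dup = bad$X[, "modality"])
  bad$contrasts <- lapply(bad$contrasts, function(v) c(v, dup = 0))
  expect_error(fit_group_glm(fx$maps, bad), "rank-deficient")
})

test_that("voxel-wise GLM equals per-voxel lm and one-sample t oracles", {
  fx <- make_glm_fixture(n_vox = 60, seed = 2)
  sm <- fit_group_glm(fx$maps, fx$des)
  expect_equal(sm$df, nrow(fx$des$X) - ncol(fx$des$X))

  # oracle: per-voxel lm with identical contrast algebra on 50 random voxels
  Y <- sapply(fx$maps, function(m) as.vector(m))  # vox x n
  set.seed(3)
  for (v in sample(nrow(Y), 50)) {
    fit <- lm(Y[v, ] ~ 0 + fx$des$X)
    cv <- fx$des$contrasts$somatic_vs_visceral
    beta_or <- sum(cv * coef(fit))
    Sigma <- vcov(fit)
    se_or <- sqrt(drop(t(cv) %*% Sigma %*% cv))
    expect_equal(sm$contrasts$somatic_vs_visceral$beta[v], beta_or,
                 tolerance = 1e-8)
    expect_equal(sm$contrasts$somatic_vs_visceral$t[v], beta_or / se_or,
                 tolerance = 1e-8)
  }

  # intercept-only design reduces to the voxel-wise one-sample t test
  n <- 12
  maps1 <- lapply(1:n, function(i) array(rnorm(40, 0.3), dim = c(1, 1, 40)))
  des1 <- list(X = cbind(intercept = rep(1, n)),
               contrasts = list(mean = c(intercept = 1)))
  sm1 <- fit_group_glm(maps1, des1)
  Y1 <- sapply(maps1, as.vector)
  for (v in c(1, 7, 40)) {
    tt <- t.test(Y1[v, ])
    expect_equal(sm1$contrasts$mean$t[v], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(sm1$contrasts$mean$p[v], tt$p.value, tolerance = 1e-10)
  }

  # adding a constant to every map shifts only baseline contrasts
  maps_shift <- lapply(fx$maps, function(m) m + 2)
  sm_s <- fit_group_glm(maps_shift, fx$des)
  expect_equal(sm_s$contrasts$somatic_vs_visceral$beta,
               sm$contrasts$somatic_vs_visceral$beta, tolerance = 1e-10)
  expect_equal(sm_s$contrasts$combined$beta,
               sm$contrasts$combined$beta + 2, tolerance = 1e-10)
})

test_that("planted modality differences localize to the loaded parcel", {
  grid <- c(12, 12, 12)   # default study grid: planted separation as calibrated
  hits <- vapply(1:20, function(sd) {
    cfg <- training_pair_config(grid = grid, seed = 300 + sd)
    co <- simulate_cohort(cfg)
    meta <- cohort_metadata(co)
    des <- group_design(meta$study, meta$modality)
    sm <- fit_group_glm(cohort_maps(co), des)
    tmap <- abs(sm$contrasts$somatic_vs_visceral$t)
    # somatomotor has the largest planted contrast, but dorsal attention and
    # default are also strongly loaded: accept the peak in any parcel whose
    # planted |somatic - visceral| is at least half the maximum
    g <- default_network_loadings()
    dif <- abs(g$somatic - g$visceral)
    strong <- which(dif >= max(dif) / 2)
    lab <- co$atlas$labels[sm$mask][which.max(tmap)]
    lab %in% strong
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("FDR thresholding matches brute force and controls the null", {
  fx <- make_glm_fixture(n_vox = 200, seed = 4)
  sm <- fit_group_glm(fx$maps, fx$des)
  thr <- threshold_map(sm, "combined", q = 0.05)
  brute <- bh_brute(sm$contrasts$combined$p, 0.05)
  expect_equal(as.vector(thr$signed[sm$mask] != 0), brute)
  expect_true(all(thr$signed[sm$mask][brute] ==
                  sign(sm$contrasts$combined$beta[brute])))
  expect_equal(thr$n_significant, sum(brute))

  # a single huge effect survives
  maps_fx <- fx$maps
  for (i in seq_along(maps_fx))
    maps_fx[[i]][1, 1, 5] <- ifelse(fx$modality[i] == "somatic", 50, -50) +
      rnorm(1, sd = 0.1)
  sm2 <- fit_group_glm(maps_fx, fx$des)
  thr2 <- threshold_map(sm2, "somatic_vs_visceral", q = 0.05)
  expect_equal(thr2$signed[1, 1, 5], 1L)

  # weak control under the global null: P(any detection) <= q (+ MC slack)
  set.seed(5)
  n <- 20
  any_det <- replicate(200, {
    maps0 <- lapply(1:n, function(i) array(rnorm(1000), dim = c(1, 1, 1000)))
    des0 <- list(X = cbind(intercept = rep(1, n)),
                 contrasts = list(mean = c(intercept = 1)))
    threshold_map(fit_group_glm(maps0, des0), "mean", 0.05)$n_significant > 0
  })
  expect_lte(mean(any_det), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("uncorrected voxel-wise type-I rate matches alpha under the null", {
  set.seed(6)
  n <- 15
  maps0 <- lapply(1:n, function(i) array(rnorm(5000), dim = c(1, 1, 5000)))
  des0 <- list(X = cbind(intercept = rep(1, n)),
               contrasts = list(mean = c(intercept = 1)))
  sm <- fit_group_glm(maps0, des0)
  rate <- mean(sm$contrasts$mean$p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 5000))
})

test_that("conjunction is sign-respecting intersection", {
  fx <- make_glm_fixture(n_vox = 100, seed = 7)
  sm <- fit_group_glm(fx$maps, fx$des)
  a <- threshold_map(sm, "somatic", 0.3)
  b <- threshold_map(sm, "visceral", 0.3)
  cj <- conjunction(a, b)
  expect_identical(conjunction(a, a)$signed, a$signed)  # idempotence
  # brute-force rule and set inclusion
  for (i in seq_along(cj$signed)) {
    sa <- a$signed[i]; sb <- b$signed[i]
    expect_equal(cj$signed[i],
                 if (sa == 1L && sb == 1L) 1L
                 else if (sa == -1L && sb == -1L) -1L else 0L)
  }
  expect_true(all(cj$signed == 0 | cj$signed == a$signed))
  expect_true(all(cj$signed == 0 | cj$signed == b$signed))

  # disjoint maps conjoin to nothing
  za <- a; zb <- b
  za$signed <- array(0L, dim = a$dim); za$signed[1, 1, 1] <- 1L
  zb$signed <- array(0L, dim = b$dim); zb$signed[1, 1, 2] <- 1L
  expect_equal(sum(conjunction(za, zb)$signed != 0), 0)
})

test_that("masked differences honor direction and the inclusive mask", {
  fx <- make_glm_fixture(n_vox = 100, seed = 8)
  sm <- fit_group_glm(fx$maps, fx$des)
  diffm <- threshold_map(sm, "somatic_vs_visceral", 0.3)
  incl <- threshold_map(sm, "combined", 0.3)

  act <- masked_difference(diffm, incl, "activation")
  expect_true(all(act$signed %in% c(0L, 1L)))
  expect_true(all(incl$signed[act$signed == 1L] == 1L))
  expect_true(all(diffm$signed[act$signed == 1L] == 1L))

  deact <- masked_difference(diffm, incl, "deactivation")
  expect_true(all(deact$signed %in% c(0L, -1L)))

  empty <- incl
  empty$signed <- array(0L, dim = incl$dim)
  expect_equal(sum(masked_difference(diffm, empty, "activation")$signed != 0), 0)
  expect_error(masked_difference(diffm, NULL), "missing inclusive mask")

  # difference significant only outside the inclusive mask vanishes
  lone <- diffm
  lone$signed <- array(0L, dim = diffm$dim)
  lone$signed[1, 1, 3] <- 1L
  incl0 <- incl
  incl0$signed <- array(0L, dim = incl$dim)
  incl0$signed[1, 1, 4] <- 1L
  expect_equal(sum(masked_difference(lone, incl0, "activation")$signed != 0), 0)
})
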