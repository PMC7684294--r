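# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed so failures are reproducible.

rand_volume <- function(grid = c(6, 6, 6), seed = 1, na_frac = 0) {
  withr_seed(seed)
  v <- array(rnorm(prod(grid)), dim = grid)
  if (na_frac > 0) v[sample.int(length(v), round(na_frac * length(v)))] <- NA_real_
  v
}

# minimal local stand-in so helpers do not depend on withr
withr_seed <- function(seed) set.seed(seed)

rand_mask <- function(grid = c(6, 6, 6), p = 0.5, seed = 2) {
  repeat {
    m <- array(runif(prod(grid)) < p, dim = grid)
    if (any(m)) return(m)
  }
}

# single-study config with no offsets or network loadings: isolates the
# planted signature effect
clean_study_config <- function(n = 30, d = 1.5, grid = c(10, 10, 10), seed = 1,
                               ...) {
  st <- data.frame(study = 1, name = "s1", modality = "somatic",
                   n_subjects = as.integer(n), d_true = d, offset = 0)
  simulation_config(studies = st, grid = grid,
                    network_loadings = list(somatic = numeric(7),
                                            visceral = numeric(7)),
                    seed = seed, ...)
}

# two-study training design (one rectal-like visceral n=15, one thermal-like
# somatic n=33) with the default planted network loadings
training_pair_config <- function(grid = c(10, 10, 10), seed = 1, ...) {
  simulation_config(studies = default_study_table()[c(2, 7), ], grid = grid,
                    seed = seed, ...)
}

# brute-force BH step-up: largest k with p_(k) <= k q / n
bh_brute <- function(p, q) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- suppressWarnings(max(which(ps <= seq_len(n) * q / n)))
  sig <- logical(n)
  if (is.finite(k)) sig[o[seq_len(k)]] <- TRUE
  sig
}

# brute-force AUROC by pair counting with ties = 1/2
auroc_brute <- function(scores, y) {
  s1 <- scores[y == 1]; s0 <- scores[y == 0]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}
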