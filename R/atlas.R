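#' Build a synthetic parcellation atlas
#'
#' Partitions the grid (or a supplied analysis mask) into `n_networks`
#' mutually exclusive, non-empty parcels, as Voronoi cells of randomly placed
#' seed voxels. With the default `n_networks = 7` the parcels stand in for
#' the seven canonical resting-state cortical networks and are named
#' accordingly; the names are labels only.
#'
#' @param grid integer length-3 grid shape.
#' @param n_networks number of parcels (>= 2, default 7).
#' @param seed RNG seed; the atlas is fully determined by `(grid, n_networks,
#'   seed)`.
#' @param mask optional analysis mask; parcels tile the mask, voxels outside
#'   it belong to no parcel.
#' @return An object of class `network_atlas`: list with `parcels` (list of
#'   logical arrays), `names`, `labels` (integer array, 0 = outside mask) and
#'   `dim`.
#' @export
make_atlas <- function(grid, n_networks = 7L, seed = 1L, mask = NULL) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3L, n_networks >= 2L)
  m <- if (is.null(mask)) full_mask(grid) else mask_data(mask)
  if (!identical(dim(m), grid)) stop("mask grid does not match requested grid")
  vox <- which(m)
  if (length(vox) < n_networks)
    stop("grid too small: ", length(vox), " voxels in mask for ", n_networks, " parcels")
  coords <- arrayInd(vox, grid)
  centers <- with_seed(seed, vox[sample.int(length(vox), n_networks)])
  cc <- arrayInd(centers, grid)
  # nearest center, squared Euclidean distance in voxel units; ties -> lowest
  # center index (deterministic)
  d2 <- matrix(0, nrow = length(vox), ncol = n_networks)
  for (k in seq_len(n_networks))
    d2[, k] <- (coords[, 1] - cc[k, 1])^2 + (coords[, 2] - cc[k, 2])^2 +
      (coords[, 3] - cc[k, 3])^2
  assign_k <- max.col(-d2, ties.method = "first")
  labels <- array(0L, dim = grid)
  labels[vox] <- assign_k
  nm <- if (n_networks == 7L)
    c("visual", "somatomotor", "dorsal_attention", "ventral_attention",
      "limbic", "frontoparietal", "default")
  else paste0("parcel", seq_len(n_networks))
  parcels <- lapply(seq_len(n_networks), function(k) labels == k)
  names(parcels) <- nm
  structure(list(parcels = parcels, names = nm, labels = labels, dim = grid),
            class = "network_atlas")
}

#' @export
print.network_atlas <- function(x, ...) {
  sizes <- vapply(x$parcels, sum, 0L)
  cat(sprintf("<network_atlas> %d parcels on %s grid\n", length(x$parcels),
              paste(x$dim, collapse = "x")))
  for (k in seq_along(sizes))
    cat(sprintf("  %-18s %d voxels\n", x$names[k], sizes[k]))
  invisible(x)
}

#' @export
length.network_atlas <- function(x) length(x$parcels)

#' Build a synthetic signature weight map
#'
#' A signature pattern is the sum of parcel-wise loadings and a smoothed
#' Gaussian random field, normalized to unit l2 norm over the grid. It stands
#' in for published multivariate weight maps (NPS-like patterns) in
#' simulations; real weight maps can be used anywhere a signature is expected
#' by loading them with [read_volume()].
#'
#' @param grid integer length-3 grid shape.
#' @param atlas a [make_atlas()] result on the same grid.
#' @param loadings numeric, one weight per parcel.
#' @param fwhm smoothing FWHM (voxels) of the random-field component.
#' @param seed RNG seed.
#' @param noise_scale SD of the random-field component relative to unit
#'   parcel loading (default 1).
#' @param name label for the resulting volume.
#' @return A `signature_pattern`: a [brain_volume] with unit l2 norm, class
#'   `c("signature_pattern", "brain_volume")`.
#' @export
make_signature <- function(grid, atlas, loadings, fwhm = 2, seed = 1L,
                           noise_scale = 1, name = "synthetic-signature") {
  grid <- as.integer(grid)
  stopifnot(inherits(atlas, "network_atlas"), identical(atlas$dim, grid))
  if (length(loadings) != length(atlas))
    stop("loadings length ", length(loadings), " != number of parcels ", length(atlas))
  w <- array(0, dim = grid)
  for (k in seq_along(loadings)) w <- w + loadings[k] * atlas$parcels[[k]]
  field <- with_seed(seed, array(stats::rnorm(prod(grid)), dim = grid))
  if (fwhm > 0) field <- smooth_field(field, fwhm, normalize = "l2")
  w <- w + noise_scale * field
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) stop("degenerate pattern: all-zero signature")
  out <- brain_volume(w / nrm, name = name)
  class(out) <- c("signature_pattern", class(out))
  out
}
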