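#' Construct a brain volume
#'
#' A `brain_volume` is a 3-D numeric grid with minimal spatial metadata: the
#' voxel size in mm along each axis and a free-text label. It is the common
#' carrier for subject contrast maps, signature weight maps and statistic
#' maps. Values may be `NA`/`NaN` outside the acquisition coverage; all
#' cross-volume computations in this package operate on the joint set of
#' finite voxels (see [joint_valid_mask()]).
#'
#' @param values numeric 3-D array.
#' @param voxel_size numeric length-3, mm per axis (default 1 mm isotropic).
#' @param name label carried through to outputs.
#' @return An object of class `brain_volume`.
#' @export
brain_volume <- function(values, voxel_size = c(1, 1, 1), name = "") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("expected 3-D array of values, got ", paste(dim(values), collapse = "x"))
  storage.mode(values) <- "double"
  structure(
    list(values = values, voxel_size = as.numeric(voxel_size), name = as.character(name)),
    class = "brain_volume"
  )
}

#' @export
print.brain_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<brain_volume> %s  grid %dx%dx%d  voxel %s mm  finite %d/%d\n",
              if (nzchar(x$name)) x$name else "(unnamed)", d[1], d[2], d[3],
              paste(signif(x$voxel_size, 3), collapse = "x"),
              sum(is.finite(x$values)), length(x$values)))
  invisible(x)
}

#' @export
dim.brain_volume <- function(x) dim(x$values)

#' @export
as.array.brain_volume <- function(x, ...) x$values

# Accept a brain_volume, a 3-D array, or a logical array; return the bare array.
vol_data <- function(x) {
  if (inherits(x, "brain_volume")) return(x$values)
  if (is.logical(x)) {
    y <- array(as.double(x), dim = dim(x))
    return(y)
  }
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop("expected a brain_volume or a 3-D array")
}

check_same_grid <- function(a, b, what = "volumes") {
  da <- dim(vol_data(a)); db <- dim(vol_data(b))
  if (!identical(da, db))
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  invisible(TRUE)
}

# Coerce to a logical mask array, validating the {0,1} contract.
mask_data <- function(mask) {
  m <- vol_data(mask)
  if (is.logical(m)) m <- m > 0
  else {
    if (any(!(m %in% c(0, 1)) & is.finite(m)))
      stop("mask values must be 0/1")
    m <- is.finite(m) & m > 0
  }
  if (!any(m)) stop("empty mask: no voxels set")
  m
}

#' Read a 3-D NIfTI volume
#'
#' Thin wrapper around [RNifti::readNifti()] that enforces the 3-D contract
#' used throughout the package and preserves the voxel size.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param name optional label; defaults to the file name.
#' @return A [brain_volume].
#' @export
read_volume <- function(path, name = NULL) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read NIfTI file '", path, "': ",
                                           conditionMessage(e)))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.numeric(img), dim = d[1:3])
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop("expected 3-D volume, got ", length(d), "-D image in '", path, "'")
  vs <- RNifti::pixdim(img)[1:3]
  brain_volume(array(as.numeric(img), dim = d), voxel_size = vs,
               name = if (is.null(name)) basename(path) else name)
}

#' Write a volume to NIfTI-1
#'
#' @param volume a [brain_volume] or 3-D array.
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  arr <- vol_data(volume)
  vs <- if (inherits(volume, "brain_volume")) volume$voxel_size else c(1, 1, 1)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vs
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Vectorize a volume over a mask
#'
#' Extracts the masked voxel values as an ordered vector together with the
#' index map back to the grid. Ordering is the ascending linear index with the
#' first axis fastest (R's native array order), so dot products between
#' vectors produced with the same mask are reproducible bit-for-bit.
#'
#' @param volume a [brain_volume] or 3-D array.
#' @param mask a binary mask on the same grid.
#' @param drop_nonfinite if `TRUE`, non-finite voxels inside the mask are
#'   dropped from the vector (their indices are dropped too).
#' @return An object of class `voxel_vector`: list with `values`, `idx`
#'   (linear grid indices) and `dim` (grid shape).
#' @export
vectorize <- function(volume, mask, drop_nonfinite = FALSE) {
  arr <- vol_data(volume)
  m <- mask_data(mask)
  check_same_grid(arr, m, "volume and mask")
  idx <- which(m)
  vals <- arr[idx]
  if (drop_nonfinite) {
    keep <- is.finite(vals)
    idx <- idx[keep]
    vals <- vals[keep]
  }
  if (length(idx) == 0L) stop("empty mask: no voxels retained")
  structure(list(values = vals, idx = idx, dim = dim(arr)), class = "voxel_vector")
}

#' Restore a voxel vector to its 3-D grid
#'
#' Inverse of [vectorize()]: voxels outside the mask are set to `fill`.
#'
#' @param vv a `voxel_vector`.
#' @param fill value for voxels outside the mask (default `NA`).
#' @return A 3-D array.
#' @export
devectorize <- function(vv, fill = NA_real_) {
  stopifnot(inherits(vv, "voxel_vector"))
  out <- array(fill, dim = vv$dim)
  out[vv$idx] <- vv$values
  out
}

#' Joint valid mask across volumes
#'
#' Voxel-wise AND of finiteness across a list of volumes, intersected with a
#' base mask. Maps pooled from different studies rarely share coverage; all
#' joint computations (similarity scoring, group GLM) are restricted to this
#' mask.
#'
#' @param volumes list of [brain_volume]s / 3-D arrays on a shared grid.
#' @param base_mask binary mask on the same grid.
#' @return A logical 3-D array (the mask).
#' @export
joint_valid_mask <- function(volumes, base_mask) {
  if (inherits(volumes, "brain_volume") || (is.array(volumes) && !is.list(volumes)))
    volumes <- list(volumes)
  m <- mask_data(base_mask)
  for (v in volumes) {
    arr <- vol_data(v)
    check_same_grid(arr, m, "volume and base mask")
    m <- m & is.finite(arr)
  }
  if (!any(m)) stop("empty mask: no voxel is finite in every volume")
  m
}

#' Full-grid mask
#'
#' Convenience: an all-`TRUE` mask for a given grid shape.
#' @param grid integer length-3 grid shape.
#' @return A logical 3-D array.
#' @export
full_mask <- function(grid) array(TRUE, dim = as.integer(grid))
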