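#' Scalar volumes on axis-aligned voxel grids
#'
#' A `volume` stores a 3D scalar array with its voxel spacing and the world
#' position of voxel (1,1,1)'s centre; the voxel-to-world map is the affine
#' `world = origin + (ijk - 1) * spacing` (0-based indices in the affine
#' returned by [volume_affine()]).
#'
#' @param data 3D numeric array.
#' @param spacing voxel spacing per axis (mm), all positive.
#' @param origin world coordinates of the first voxel centre (mm).
#' @return A `volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3L, all(spacing > 0), length(origin) == 3L)
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)), class = "volume")
}

#' @rdname volume
#' @param x object to test.
#' @export
is_volume <- function(x) inherits(x, "volume")

#' @rdname volume
#' @param vol a `volume` or `binary_mask`.
#' @return `volume_affine`: the 4x4 voxel(0-based)-to-world matrix.
#' @export
volume_affine <- function(vol) {
  m <- diag(4)
  m[1:3, 1:3] <- diag(vol$spacing, 3, 3)
  m[1:3, 4] <- vol$origin
  m
}

#' Binary masks aligned to a volume grid
#'
#' @param mask 3D logical array.
#' @param spacing,origin grid geometry as in [volume()].
#' @return A `binary_mask`.
#' @export
binary_mask <- function(mask, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, all(spacing > 0))
  structure(list(mask = mask, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)), class = "binary_mask")
}

#' @rdname binary_mask
#' @param x object to test.
#' @export
is_binary_mask <- function(x) inherits(x, "binary_mask")

#' @export
print.volume <- function(x, ...) {
  cat("<volume> ", paste(dim(x$data), collapse = " x "), "voxels, spacing",
      paste(format(x$spacing), collapse = " x "), "mm\n")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask>", paste(dim(x$mask), collapse = " x "),
      " (", sum(x$mask), "foreground voxels )\n")
  invisible(x)
}
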