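#' 3D volume and lesion-mask containers
#'
#' A `svd_volume` is a numeric 3D array carrying its isotropic (or per-axis)
#' voxel spacing in mm and a 4x4 voxel-to-world affine (0-based voxel indices,
#' RAS+ world axes). A `svd_mask` is a binary `svd_volume` tagged with the
#' lesion class it represents (`"infarct"`, `"wmh"` or `"lacune"`).
#'
#' By default the world origin sits at the grid centre, so rotations expressed
#' about the origin act about the centre of the head.
#'
#' @param data numeric 3D array of voxel values (for masks: 0/1).
#' @param voxel_size voxel edge length(s) in mm; scalar or length 3.
#' @param affine optional 4x4 voxel-to-world matrix; computed from
#'   `voxel_size` (grid-centred) when `NULL`.
#' @return `volume_image()` returns a `svd_volume`; `lesion_mask()` a
#'   `svd_mask`.
#' @examples
#' v <- volume_image(array(rnorm(8^3), c(8, 8, 8)))
#' m <- lesion_mask(array(0L, c(8, 8, 8)), like = v, class = "wmh")
#' @export
volume_image <- function(data, voxel_size = 1, affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel_size must be > 0", call. = FALSE)
  if (is.null(affine)) affine <- centred_affine(dim(data), voxel_size)
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(data,
            voxel_size = voxel_size,
            affine = affine,
            class = c("svd_volume", "array"))
}

#' @param like a `svd_volume` supplying grid geometry for the mask.
#' @param class lesion class tag: `"infarct"`, `"wmh"` or `"lacune"`.
#' @rdname volume_image
#' @export
lesion_mask <- function(data, like = NULL, class = c("infarct", "wmh", "lacune"),
                        voxel_size = 1, affine = NULL) {
  class <- match.arg(class)
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1)))
    stop("mask values must be binary (0/1); found ",
         paste(utils::head(setdiff(vals, c(0, 1)), 3), collapse = ", "),
         call. = FALSE)
  if (!is.null(like)) {
    voxel_size <- attr(like, "voxel_size")
    affine <- attr(like, "affine")
  }
  v <- volume_image(array(as.integer(data), dim(data)), voxel_size, affine)
  attr(v, "lesion_class") <- class
  class(v) <- c("svd_mask", class(v))
  v
}

# voxel-to-world affine placing the grid centre at the world origin
centred_affine <- function(dim, voxel_size) {
  a <- diag(c(voxel_size, 1))
  a[1:3, 4] <- -(dim - 1) / 2 * voxel_size
  a
}

#' @export
print.svd_volume <- function(x, ...) {
  kind <- if (inherits(x, "svd_mask"))
    sprintf("lesion mask [%s, %d voxels on]", lesion_class(x), sum(x > 0))
  else "volume image"
  cat(sprintf("<svd_volume> %s  %s  voxel %s mm\n", kind,
              paste(dim(x), collapse = "x"),
              paste(signif(attr(x, "voxel_size"), 3), collapse = "x")))
  invisible(x)
}

#' Grid geometry accessors
#'
#' @param x a `svd_volume` or `svd_mask`.
#' @return `voxel_size()` the per-axis spacing in mm; `voxel_volume_mm3()` the
#'   volume of one voxel; `vox2world()`/`world2vox()` the 4x4 transforms
#'   between 0-based voxel indices and world mm; `lesion_class()` the class
#'   tag of a mask.
#' @export
voxel_size <- function(x) attr(x, "voxel_size")

#' @rdname voxel_size
#' @export
voxel_volume_mm3 <- function(x) prod(attr(x, "voxel_size"))

#' @rdname voxel_size
#' @export
vox2world <- function(x) attr(x, "affine")

#' @rdname voxel_size
#' @export
world2vox <- function(x) solve(attr(x, "affine"))

#' @rdname voxel_size
#' @export
lesion_class <- function(x) attr(x, "lesion_class")

#' Do two volumes share a grid?
#'
#' Same dimensions and voxel-to-world affine (to `tol`).
#' @param a,b volumes.
#' @param tol absolute tolerance on affine entries.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a), dim(b)) &&
    max(abs(vox2world(a) - vox2world(b))) < tol
}

stop_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("grid mismatch: %s must share dimensions and affine", what),
         call. = FALSE)
  invisible(TRUE)
}

# new volume with same geometry, different data
volume_like <- function(x, data) {
  volume_image(data, voxel_size = attr(x, "voxel_size"),
               affine = attr(x, "affine"))
}

mask_like <- function(x, data, class) {
  lesion_mask(data, voxel_size = attr(x, "voxel_size"),
              affine = attr(x, "affine"), class = class)
}

# world coordinates (n x 3) of 0-based voxel index matrix (n x 3)
apply_affine <- function(A, pts) {
  pts <- rbind(t(pts), 1)
  t(A %*% pts)[, 1:3, drop = FALSE]
}

# 0-based voxel index matrix of every voxel in a grid (column-major order)
grid_voxels <- function(dim) {
  cbind(rep(seq_len(dim[1]) - 1L, times = dim[2] * dim[3]),
        rep(rep(seq_len(dim[2]) - 1L, each = dim[1]), times = dim[3]),
        rep(seq_len(dim[3]) - 1L, each = dim[1] * dim[2]))
}
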