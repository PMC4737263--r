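#' Build a world-to-world affine transform
#'
#' Composes rotation, shear, anisotropic scaling and translation about a
#' centre point: `p -> centre + t + R S H (p - centre)` with `R = Rz Ry Rx`.
#' The result is a 4x4 homogeneous matrix of class `svd_affine`, tagged with
#' its degrees of freedom (`6` rigid, `12` full affine).
#'
#' @param rotation rotations about x, y, z in degrees.
#' @param translation translation in mm.
#' @param scale per-axis scale factors.
#' @param shear shear coefficients (xy, xz, yz).
#' @param center centre of rotation/scaling in world mm.
#' @return a `svd_affine` 4x4 matrix.
#' @examples
#' A <- affine_transform(rotation = c(0, 0, 5), translation = c(4, -3, 2))
#' solve(A) %*% A  # identity
#' @export
affine_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                             scale = c(1, 1, 1), shear = c(0, 0, 0),
                             center = c(0, 0, 0)) {
  r <- rotation * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  H <- rbind(c(1, shear[1], shear[2]), c(0, 1, shear[3]), c(0, 0, 1))
  L <- Rz %*% Ry %*% Rx %*% H %*% diag(rep_len(scale, 3))
  A <- diag(4)
  A[1:3, 1:3] <- L
  A[1:3, 4] <- center + translation - L %*% center
  dof <- if (all(scale == 1) && all(shear == 0)) 6L else 12L
  new_affine(A, dof)
}

new_affine <- function(A, dof = 12L) {
  stopifnot(all(dim(A) == c(4L, 4L)))
  if (max(abs(A[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("affine last row must be (0,0,0,1)", call. = FALSE)
  structure(A, dof = as.integer(dof), class = c("svd_affine", "matrix", "array"))
}

#' @export
print.svd_affine <- function(x, ...) {
  cat(sprintf("<svd_affine> dof=%d\n", attr(x, "dof")))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Compose and invert affine transforms
#'
#' `compose_affine(A, B)` returns the transform applying `B` first then `A`;
#' `invert_affine(A)` the matrix inverse, preserving the dof tag.
#' @param A,B `svd_affine` matrices (or plain 4x4 matrices).
#' @export
compose_affine <- function(A, B) {
  dof <- max(attr(A, "dof") %||% 12L, attr(B, "dof") %||% 12L)
  new_affine(unclass(A) %*% unclass(B), dof)
}

#' @rdname compose_affine
#' @export
invert_affine <- function(A) new_affine(solve(unclass(A)), attr(A, "dof") %||% 12L)

#' Read/write a transform as a plain-text 4x4 matrix
#'
#' One row per line, whitespace separated, world-to-world in RAS+ mm.
#' @param A transform; `path` file path.
#' @param path file path.
#' @export
write_transform <- function(A, path) {
  utils::write.table(format(unclass(A), digits = 17), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  new_affine(m)
}

# voxel-to-voxel matrix: target grid voxel -> source grid voxel, through a
# world-to-world map g (target world -> source world)
vox_map <- function(source, target, g = diag(4)) {
  world2vox(source) %*% unclass(g) %*% vox2world(target)
}
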