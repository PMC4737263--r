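#' Read and write volumes and masks as NIfTI-1
#'
#' Intensity volumes are stored as 32-bit float, masks as unsigned 8-bit.
#' On read, images whose stored orientation is not RAS+ are reoriented (with a
#' message); anisotropic images are resampled to 1 mm isotropic with the
#' resampling parameters logged. Masks must contain only 0/1 after read.
#'
#' @param vol a `svd_volume`; `mask` a `svd_mask`.
#' @param path file path, conventionally ending in `.nii.gz`.
#' @return the read `svd_volume` / `svd_mask`; writers return `path`
#'   invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(structure(array(as.numeric(vol), dim(vol)),
                                   pixdim = voxel_size(vol)),
                         datatype = "float")
  img <- set_xform(img, vox2world(vol))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(structure(array(as.integer(mask), dim(mask)),
                                   pixdim = voxel_size(mask)),
                         datatype = "uint8")
  img <- set_xform(img, vox2world(mask))
  RNifti::writeNifti(img, path)
  invisible(path)
}

set_xform <- function(img, affine) {
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  img
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (!identical(RNifti::orientation(img), "RAS")) {
    message("reorienting ", basename(path), " from ",
            RNifti::orientation(img), " to RAS")
    RNifti::orientation(img) <- "RAS"
  }
  aff <- unclass(RNifti::xform(img))
  attr(aff, "code") <- NULL
  attr(aff, "imagedim") <- NULL
  vs <- sqrt(colSums(aff[1:3, 1:3]^2))   # spacing from the affine
  vol <- volume_image(array(as.numeric(img), dim(img)[1:3]),
                      voxel_size = vs, affine = aff)
  if (max(vs) - min(vs) > 1e-6) {
    message(sprintf(
      "resampling %s from %s mm to 1 mm isotropic (trilinear)",
      basename(path), paste(signif(vs, 4), collapse = "x")))
    vol <- resample_to_iso(vol, 1)
  }
  vol
}

#' @rdname write_volume
#' @export
read_mask <- function(path, class = c("infarct", "wmh", "lacune")) {
  class <- match.arg(class)
  img <- RNifti::readNifti(path)
  if (!identical(RNifti::orientation(img), "RAS"))
    RNifti::orientation(img) <- "RAS"
  aff <- unclass(RNifti::xform(img))
  attr(aff, "code") <- NULL
  attr(aff, "imagedim") <- NULL
  vals <- unique(as.vector(img))
  if (!all(vals %in% c(0, 1)))
    stop("mask file ", basename(path), " is not binary: values ",
         paste(utils::head(setdiff(vals, c(0, 1)), 3), collapse = ", "),
         call. = FALSE)
  lesion_mask(array(as.integer(img), dim(img)[1:3]),
              voxel_size = sqrt(colSums(aff[1:3, 1:3]^2)), affine = aff,
              class = class)
}

#' Resample a volume to an isotropic grid
#'
#' Trilinear pull-back onto a new RAS+ grid with edge length `iso_mm`
#' covering the same world-space extent.
#' @param vol a `svd_volume`.
#' @param iso_mm target isotropic voxel size in mm.
#' @export
resample_to_iso <- function(vol, iso_mm = 1) {
  extent <- dim(vol) * voxel_size(vol)
  tdim <- pmax(2L, as.integer(round(extent / iso_mm)))
  # keep the same world centre as the source grid
  src_centre <- apply_affine(vox2world(vol), matrix((dim(vol) - 1) / 2, 1))
  taff <- diag(c(rep(iso_mm, 3), 1))
  taff[1:3, 4] <- as.numeric(src_centre) - (tdim - 1) / 2 * iso_mm
  target <- volume_image(array(0, tdim), voxel_size = rep(iso_mm, 3),
                         affine = taff)
  M <- vox_map(vol, target)
  out <- c_affine_resample(as.numeric(vol), dim(vol), tdim, M, 0)
  volume_like(target, out)
}
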