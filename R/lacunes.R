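#' Detect lacunes by FLAIR thresholding and morphometry
#'
#' Lacunes are round or ovoid fluid-filled cavities with CSF-like signal,
#' at least 3 mm in diameter. The detector thresholds the FLAIR-like volume
#' below a CSF/parenchyma cutoff inside the brain mask, labels 26-connected
#' components, discards components overlapping the ventricles or touching
#' the brain-mask boundary, and keeps components whose equivalent spherical
#' diameter lies in `[min_diam_mm, max_diam_mm]` with sphericity at or above
#' `min_sphericity`.
#'
#' The default threshold is the midpoint of the CSF and grey-matter
#' intensity means when `tissue_means` is supplied; otherwise Otsu's method
#' (via EBImage) on the brain voxels. Sphericity is
#' `pi^(1/3) (6V)^(2/3) / A` with `A` the voxel-face surface-area estimate;
#' for a voxelized sphere this estimate is about 0.66 rather than 1 because
#' face counting overestimates the area of a smooth surface, hence the
#' permissive default cutoff.
#'
#' @param seq_flair FLAIR-like `svd_volume`.
#' @param brain_mask binary parenchymal mask (`svd_mask` or array).
#' @param ventricle_mask binary mask of the ventricles; overlapping
#'   components are discarded.
#' @param min_diam_mm,max_diam_mm equivalent-diameter bounds (mm).
#' @param min_sphericity minimum sphericity score in `[0, 1]`.
#' @param threshold intensity cutoff; overrides `tissue_means`.
#' @param tissue_means optional named vector with `csf` and `grey` means of
#'   the FLAIR sequence, used to place the default cutoff at their midpoint.
#' @return list with `mask` (union `svd_mask`, class `"lacune"`) and
#'   `components`, a tibble sorted by volume descending: `component_id`,
#'   `n_voxels`, `volume_ml`, `equivalent_diameter_mm`, `sphericity`,
#'   `centroid_i/j/k` (1-based voxel indices).
#' @export
detect_lacunes <- function(seq_flair, brain_mask, ventricle_mask = NULL,
                           min_diam_mm = 3, max_diam_mm = 15,
                           min_sphericity = 0.3, threshold = NULL,
                           tissue_means = NULL) {
  brain <- as.vector(brain_mask) > 0
  if (!any(brain))
    stop("input error: brain mask is empty", call. = FALSE)
  flair <- as.vector(seq_flair)
  if (is.null(threshold)) {
    if (!is.null(tissue_means)) {
      threshold <- (tissue_means[["csf"]] + tissue_means[["grey"]]) / 2
    } else {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("supply `threshold` or `tissue_means`, or install EBImage for ",
             "Otsu thresholding", call. = FALSE)
      v <- flair[brain]
      rng <- range(v)
      threshold <- EBImage::otsu(array((v - rng[1]) / diff(rng),
                                       c(length(v), 1)),
                                 range = c(0, 1)) * diff(rng) + rng[1]
    }
  }
  dm <- dim(seq_flair)
  vs <- voxel_size(seq_flair)
  voxvol <- prod(vs)
  cand <- array(as.integer(flair < threshold & brain), dm)
  lab <- label_components(cand, connectivity = 26)
  ncomp <- max(lab)
  empty_mask <- function() lesion_mask(array(0L, dm), voxel_size = vs,
                                       affine = vox2world(seq_flair),
                                       class = "lacune")
  empty_tbl <- tibble(component_id = integer(), n_voxels = integer(),
                      volume_ml = numeric(), equivalent_diameter_mm = numeric(),
                      sphericity = numeric(), centroid_i = numeric(),
                      centroid_j = numeric(), centroid_k = numeric())
  if (ncomp == 0)
    return(list(mask = empty_mask(), components = empty_tbl))

  brain_arr <- array(brain, dm)
  vent <- if (is.null(ventricle_mask)) NULL else as.vector(ventricle_mask) > 0
  rows <- vector("list", ncomp)
  keep_ids <- integer(0)
  for (k in seq_len(ncomp)) {
    idx <- which(lab == k)
    if (!is.null(vent) && any(vent[idx])) next
    comp <- array(lab == k, dm)
    if (touches_mask_boundary(comp, brain_arr)) next
    v <- length(idx)
    vol_mm3 <- v * voxvol
    d_eq <- (6 * vol_mm3 / pi)^(1 / 3)
    A <- surface_area_voxels(comp, vs)
    psi <- pi^(1 / 3) * (6 * vol_mm3)^(2 / 3) / A
    if (d_eq < min_diam_mm || d_eq > max_diam_mm || psi < min_sphericity)
      next
    ctr <- colMeans(arrayInd(idx, dm))
    keep_ids <- c(keep_ids, k)
    rows[[k]] <- tibble(component_id = k, n_voxels = v,
                        volume_ml = vol_mm3 / 1000,
                        equivalent_diameter_mm = d_eq, sphericity = psi,
                        centroid_i = ctr[1], centroid_j = ctr[2],
                        centroid_k = ctr[3])
  }
  comps <- dplyr::bind_rows(rows)
  if (nrow(comps) == 0)
    return(list(mask = empty_mask(), components = empty_tbl))
  comps <- dplyr::arrange(comps, dplyr::desc(.data$volume_ml))
  comps$component_id <- seq_len(nrow(comps))
  mask <- array(as.integer(lab %in% keep_ids), dm)
  list(mask = lesion_mask(mask, voxel_size = vs,
                          affine = vox2world(seq_flair), class = "lacune"),
       components = comps)
}

# does any 6-neighbour of a component voxel fall outside the mask (or grid)?
touches_mask_boundary <- function(comp, mask) {
  dm <- dim(comp)
  idx <- which(comp)
  co <- arrayInd(idx, dm)
  for (ax in 1:3) {
    for (dir in c(-1L, 1L)) {
      nb <- co
      nb[, ax] <- nb[, ax] + dir
      outside <- nb[, ax] < 1 | nb[, ax] > dm[ax]
      if (any(outside)) return(TRUE)
      lin <- nb[, 1] + (nb[, 2] - 1L) * dm[1] + (nb[, 3] - 1L) * dm[1] * dm[2]
      if (any(!mask[lin])) return(TRUE)
    }
  }
  FALSE
}

# voxel-face surface area of a binary component (mm^2)
surface_area_voxels <- function(comp, vs) {
  dm <- dim(comp)
  face_area <- c(vs[2] * vs[3], vs[1] * vs[3], vs[1] * vs[2])
  idx <- which(comp)
  co <- arrayInd(idx, dm)
  area <- 0
  for (ax in 1:3) {
    for (dir in c(-1L, 1L)) {
      nb <- co
      nb[, ax] <- nb[, ax] + dir
      outside <- nb[, ax] < 1 | nb[, ax] > dm[ax]
      lin <- pmin(pmax(nb[, 1], 1L), dm[1]) +
        (pmin(pmax(nb[, 2], 1L), dm[2]) - 1L) * dm[1] +
        (pmin(pmax(nb[, 3], 1L), dm[3]) - 1L) * dm[1] * dm[2]
      exposed <- outside | !comp[lin]
      area <- area + sum(exposed) * face_area[ax]
    }
  }
  area
}
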