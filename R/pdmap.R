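#' Voxel-wise lesion probability-density map
#'
#' Sums binary lesion masks over subjects and divides by the denominator
#' `N`: the proportion of the population with a lesion of the given class
#' involving each voxel. With `denominator_mode = "all"` every supplied
#' subject counts toward `N`; with `"affected_only"` only subjects whose
#' mask is non-empty count (the rule used for lacunes, which only a subset
#' of patients have).
#'
#' @param masks list of `svd_mask` on one common grid (one per subject).
#' @param denominator_mode `"all"` or `"affected_only"`.
#' @return a `svd_pdmap`: a `svd_volume` of values in `[0, 1]` with
#'   attributes `denominator` (N), `lesion_class`, and `n_masks` (number of
#'   masks supplied).
#' @examples
#' g <- array(0L, c(8, 8, 8))
#' m1 <- g; m1[4, 4, 4] <- 1L
#' masks <- list(lesion_mask(m1, class = "wmh"), lesion_mask(g, class = "wmh"))
#' pd <- pd_map(masks)
#' pd[4, 4, 4]  # 0.5
#' @export
pd_map <- function(masks, denominator_mode = c("all", "affected_only")) {
  denominator_mode <- match.arg(denominator_mode)
  if (length(masks) < 1) stop("input error: need >= 1 mask", call. = FALSE)
  ref <- masks[[1]]
  acc <- array(0, dim(ref))
  nonempty <- 0L
  for (m in masks) {
    stop_grid_mismatch(ref, m, "lesion masks")
    mm <- as.integer(m)
    if (any(mm > 0)) nonempty <- nonempty + 1L
    acc <- acc + array(mm, dim(ref))
  }
  N <- if (denominator_mode == "all") length(masks) else nonempty
  if (N == 0L)
    stop("input error: denominator_mode 'affected_only' with no non-empty masks",
         call. = FALSE)
  out <- volume_like(ref, acc / N)
  attr(out, "denominator") <- N
  attr(out, "lesion_class") <- lesion_class(ref)
  attr(out, "n_masks") <- length(masks)
  class(out) <- c("svd_pdmap", class(out))
  out
}

#' @export
print.svd_pdmap <- function(x, ...) {
  cat(sprintf("<svd_pdmap> %s  class %s  N=%d  max PD %.3f\n",
              paste(dim(x), collapse = "x"),
              attr(x, "lesion_class") %||% "?", attr(x, "denominator"),
              max(x)))
  invisible(x)
}

#' Write / read a PD map as NIfTI with a JSON sidecar
#'
#' The 32-bit float NIfTI carries the voxel values; the sidecar records the
#' denominator, lesion class and number of masks.
#' @param pd a `svd_pdmap`; `path` the `.nii.gz` path (sidecar replaces the
#'   extension with `.json`).
#' @param path file path.
#' @export
write_pd_map <- function(pd, path) {
  write_volume(pd, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(denominator = attr(pd, "denominator"),
                            lesion_class = attr(pd, "lesion_class"),
                            n_masks = attr(pd, "n_masks")),
                       side, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pd_map
#' @export
read_pd_map <- function(path) {
  vol <- read_volume(path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- jsonlite::read_json(side)
  attr(vol, "denominator") <- as.integer(meta$denominator)
  attr(vol, "lesion_class") <- meta$lesion_class
  attr(vol, "n_masks") <- as.integer(meta$n_masks)
  class(vol) <- c("svd_pdmap", class(vol))
  vol
}

#' Cubic regions-of-interest on atlas structures
#'
#' Places one small cube (side `side_mm`, default 2 mm, i.e. 2x2x2 voxels at
#' 1 mm isotropic) at the voxel centroid of each atlas region. Regions named
#' `*_left` / `*_right` carry a laterality tag; others are `bilateral`.
#' ROIs are clamped to lie entirely within the grid.
#'
#' @param atlas integer label `svd_volume` with a named `labels` attribute.
#' @param side_mm cube side in mm.
#' @return a tibble: `region` (base name), `laterality`, `label`,
#'   `center_i/j/k` (1-based voxel index of the cube's low corner),
#'   `side_vox`.
#' @export
region_rois <- function(atlas, side_mm = 2) {
  labels <- attr(atlas, "labels")
  if (is.null(labels)) stop("atlas has no `labels` attribute", call. = FALSE)
  vs <- voxel_size(atlas)
  side_vox <- pmax(1L, as.integer(round(side_mm / vs)))
  dm <- dim(atlas)
  av <- as.vector(unclass(atlas))
  purrr::map_dfr(names(labels), function(nm) {
    idx <- which(av == labels[[nm]])
    if (length(idx) == 0) return(NULL)
    co <- arrayInd(idx, dm)
    ctr <- colMeans(co)
    # snap to the in-region voxel nearest the centroid, so ring-shaped
    # regions (periventricular shell) get an ROI inside the structure
    nearest <- which.min(rowSums(sweep(co, 2, ctr)^2))
    ctr <- co[nearest, ]
    lo <- pmin(pmax(as.integer(ctr - floor(side_vox / 2)), 1L),
               dm - side_vox + 1L)
    lat <- if (grepl("_left$", nm)) "left"
           else if (grepl("_right$", nm)) "right" else "bilateral"
    tibble(region = sub("_(left|right)$", "", nm), laterality = lat,
           label = labels[[nm]],
           center_i = lo[1], center_j = lo[2], center_k = lo[3],
           side_vox_i = side_vox[1], side_vox_j = side_vox[2],
           side_vox_k = side_vox[3])
  })
}

#' Sample a PD map in a region-of-interest
#'
#' @param pd a `svd_pdmap` (or `svd_volume`).
#' @param roi one row of a [region_rois()] tibble (or a list with the same
#'   fields).
#' @param summary `"mean"` (default) or `"max"` over the ROI voxels.
#' @return scalar in `[0, 1]`.
#' @export
sample_roi <- function(pd, roi, summary = c("mean", "max")) {
  summary <- match.arg(summary)
  dm <- dim(pd)
  i <- roi$center_i + seq_len(roi$side_vox_i) - 1L
  j <- roi$center_j + seq_len(roi$side_vox_j) - 1L
  k <- roi$center_k + seq_len(roi$side_vox_k) - 1L
  if (min(i, j, k) < 1 || max(i) > dm[1] || max(j) > dm[2] || max(k) > dm[3])
    stop("geometry error: ROI extends outside the grid", call. = FALSE)
  vals <- unclass(pd)[i, j, k]
  if (summary == "mean") mean(vals) else max(vals)
}

#' Regional PD table
#'
#' One row per (region, laterality), one column of PD per lesion class:
#' the machinery behind a per-region lesion-probability table. Values are
#' kept at full precision; use `round_pd()` for a 3-decimal report.
#'
#' @param pdmaps named list of `svd_pdmap` (names = lesion classes), all on
#'   one grid.
#' @param rois tibble from [region_rois()].
#' @param summary ROI summary statistic, `"mean"` or `"max"`.
#' @param classes classes required in the output (default: names of
#'   `pdmaps`).
#' @return a `svd_region_table` tibble: `region`, `laterality`, then one
#'   numeric column per lesion class.
#' @export
region_table <- function(pdmaps, rois, summary = "mean",
                         classes = names(pdmaps)) {
  if (is.null(names(pdmaps)) || any(names(pdmaps) == ""))
    stop("`pdmaps` must be a named list (names = lesion classes)",
         call. = FALSE)
  missing <- setdiff(classes, names(pdmaps))
  if (length(missing) > 0)
    stop("input error: missing PD map for class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (nm in names(pdmaps)) stop_grid_mismatch(pdmaps[[1]], pdmaps[[nm]],
                                               "PD maps")
  out <- rois[, c("region", "laterality")]
  for (cls in classes) {
    out[[cls]] <- vapply(seq_len(nrow(rois)), function(r)
      sample_roi(pdmaps[[cls]], rois[r, ], summary = summary), numeric(1))
  }
  denoms <- vapply(pdmaps[classes], function(p)
    as.integer(attr(p, "denominator") %||% NA_integer_), integer(1))
  structure(out, denominators = denoms,
            class = c("svd_region_table", class(out)))
}

#' Round a region table for report
#'
#' Half-up rounding to `digits` decimals, mirroring the usual 3-decimal
#' presentation of regional PD values; the unrounded table remains the
#' analysis object.
#' @param tab a `svd_region_table`.
#' @param digits decimal places.
#' @export
round_pd <- function(tab, digits = 3) {
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x)
    floor(x * 10^digits + 0.5) / 10^digits)
  tab
}

#' Subtract two PD maps
#'
#' Voxel-wise `a - b` (in `[-1, 1]`), plus an overlap summary: the fraction
#' of voxels positive in both maps among voxels positive in either. Used to
#' check how much two lesion classes share territory.
#'
#' @param a,b `svd_pdmap`s on one grid.
#' @return list with `difference` (a `svd_volume`), `overlap_fraction`
#'   (NaN when both maps are empty), `n_both`, `n_either`.
#' @export
subtract_maps <- function(a, b) {
  stop_grid_mismatch(a, b, "PD maps")
  av <- as.numeric(a); bv <- as.numeric(b)
  both <- sum(av > 0 & bv > 0)
  either <- sum(av > 0 | bv > 0)
  list(difference = volume_like(a, array(av - bv, dim(a))),
       overlap_fraction = if (either > 0) both / either else NaN,
       n_both = both, n_either = either)
}
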