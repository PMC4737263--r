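#' Specification of the synthetic brain template
#'
#' Describes the phantom grid and tissue contrast used by [make_template()].
#' The phantom emulates a 1 mm isotropic T1-like template plus a co-registered
#' FLAIR-like volume: nested ellipsoids for intracranial space, cortical grey
#' ribbon and white matter, paired lateral ventricles, deep grey nuclei and a
#' brainstem, with a corticospinal-tract tube descending from the corona
#' radiata through the internal capsule region to the brainstem.
#'
#' @param grid_shape voxels per axis (each >= 32).
#' @param voxel_size_mm isotropic voxel edge in mm (> 0).
#' @param tissue_means named list with elements `flair` and `t1`, each a named
#'   vector of intensity means for `csf`, `grey`, `white`. Means must be
#'   distinct within each sequence so that tissue contrast exists.
#' @param noise_sd SD of additive Gaussian noise (>= 0).
#' @param seed RNG seed for the template noise.
#' @return a `template_spec` list.
#' @export
template_spec <- function(grid_shape = c(64, 64, 64),
                          voxel_size_mm = 1,
                          tissue_means = list(
                            flair = c(csf = 40, grey = 120, white = 100),
                            t1 = c(csf = 50, grey = 110, white = 150)),
                          noise_sd = 5,
                          seed = 1) {
  spec <- list(grid_shape = as.integer(rep_len(grid_shape, 3)),
               voxel_size_mm = voxel_size_mm,
               tissue_means = tissue_means, noise_sd = noise_sd,
               seed = as.integer(seed))
  validate_template_spec(spec)
  structure(spec, class = "template_spec")
}

validate_template_spec <- function(spec) {
  cfg_err <- function(field, msg)
    stop(sprintf("invalid template_spec: field `%s` %s", field, msg),
         call. = FALSE)
  if (any(spec$grid_shape < 32)) cfg_err("grid_shape", "must be >= 32 per axis")
  if (!is.numeric(spec$voxel_size_mm) || spec$voxel_size_mm <= 0)
    cfg_err("voxel_size_mm", "must be > 0")
  for (sq in c("flair", "t1")) {
    tm <- spec$tissue_means[[sq]]
    if (is.null(tm) || !all(c("csf", "grey", "white") %in% names(tm)))
      cfg_err("tissue_means", sprintf("must name csf/grey/white for `%s`", sq))
    if (anyDuplicated(tm[c("csf", "grey", "white")]))
      cfg_err("tissue_means", sprintf("must be distinct within `%s`", sq))
  }
  if (!is.numeric(spec$noise_sd) || spec$noise_sd < 0)
    cfg_err("noise_sd", "must be >= 0")
  invisible(spec)
}

#' Specification of synthetic lesion placement
#'
#' Controls where and how the three lesion classes are planted by
#' [make_subject()]. Recent small subcortical infarcts (exactly one per
#' subject) are centred on the corticospinal-tract curve; WMH are multifocal
#' with a periventricular weighting; lacunes are present in a configurable
#' fraction of subjects with CSF-like signal on both sequences.
#'
#' @param infarct_center_jitter_mm SD of the Gaussian jitter applied to the
#'   sampled tract-curve point used as infarct centre.
#' @param infarct_axial_diameter_range_mm range the in-plane infarct diameter
#'   is drawn from; must stay below `infarct_max_axial_diameter_mm`.
#' @param infarct_max_axial_diameter_mm hard cap on in-plane diameter
#'   (default 20 mm, the "small subcortical" criterion).
#' @param wmh_count_mean Poisson mean of the number of WMH foci (>= 1 focus
#'   is always planted).
#' @param wmh_periventricular_weight probability that a focus is seeded in
#'   the periventricular shell rather than general white matter.
#' @param wmh_blob_radius_range_mm per-axis ellipsoid radius range of a
#'   WMH focus.
#' @param lacune_prevalence fraction of subjects carrying at least one lacune
#'   (default 0.465, emulating 87/187).
#' @param lacune_diameter_range_mm diameter range lacunes are drawn from;
#'   lower bound >= 3 mm.
#' @param lesion_means named list (`flair`, `t1`) of intensity means for
#'   `infarct`, `wmh`, `lacune`.
#' @param misalign_rotation_deg,misalign_translation_mm max magnitude of the
#'   random subject misalignment.
#' @param misalign_scale_range scale factor range of the misalignment.
#' @return a `lesion_spec` list.
#' @export
lesion_spec <- function(infarct_center_jitter_mm = 1.5,
                        infarct_axial_diameter_range_mm = c(6, 16),
                        infarct_max_axial_diameter_mm = 20,
                        wmh_count_mean = 8,
                        wmh_periventricular_weight = 0.7,
                        wmh_blob_radius_range_mm = c(2, 5),
                        lacune_prevalence = 0.465,
                        lacune_diameter_range_mm = c(3, 15),
                        lesion_means = list(
                          flair = c(infarct = 190, wmh = 180, lacune = 40),
                          t1 = c(infarct = 100, wmh = 95, lacune = 50)),
                        misalign_rotation_deg = 5,
                        misalign_translation_mm = 5,
                        misalign_scale_range = c(0.97, 1.03)) {
  spec <- as.list(environment())
  cfg_err <- function(field, msg)
    stop(sprintf("invalid lesion_spec: field `%s` %s", field, msg),
         call. = FALSE)
  if (spec$lacune_prevalence < 0 || spec$lacune_prevalence > 1)
    cfg_err("lacune_prevalence", "must lie in [0, 1]")
  if (spec$lacune_diameter_range_mm[1] < 3)
    cfg_err("lacune_diameter_range_mm", "lower bound must be >= 3 mm")
  if (spec$infarct_max_axial_diameter_mm > 20)
    cfg_err("infarct_max_axial_diameter_mm", "must be <= 20 mm")
  if (max(spec$infarct_axial_diameter_range_mm) >
      spec$infarct_max_axial_diameter_mm)
    cfg_err("infarct_axial_diameter_range_mm", "must stay below the cap")
  if (spec$wmh_periventricular_weight < 0 || spec$wmh_periventricular_weight > 1)
    cfg_err("wmh_periventricular_weight", "must lie in [0, 1]")
  structure(spec, class = "lesion_spec")
}

# ---- geometry of the phantom (coordinates in mm for a 64 mm box, scaled) ----

phantom_shapes <- function(scale) {
  s <- function(p) p * scale
  list(
    intracranial = list(center = s(c(0, 0, 0)),  radii = s(c(26, 29, 25))),
    brain        = list(center = s(c(0, 0, 0)),  radii = s(c(24, 27, 23))),
    white        = list(center = s(c(0, 0, 1)),  radii = s(c(19, 22, 18))),
    ventricle_r  = list(center = s(c(6, 2, 2)),  radii = s(c(3.5, 10, 4))),
    ventricle_l  = list(center = s(c(-6, 2, 2)), radii = s(c(3.5, 10, 4))),
    caudate_r    = list(center = s(c(9, 8, 6)),  radii = s(c(3, 5, 3.5))),
    caudate_l    = list(center = s(c(-9, 8, 6)), radii = s(c(3, 5, 3.5))),
    lentiform_r  = list(center = s(c(14, 0, 2)), radii = s(c(4.5, 7, 4.5))),
    lentiform_l  = list(center = s(c(-14, 0, 2)), radii = s(c(4.5, 7, 4.5))),
    thalamus_r   = list(center = s(c(8, -6, 2)), radii = s(c(4.5, 5.5, 4))),
    thalamus_l   = list(center = s(c(-8, -6, 2)), radii = s(c(4.5, 5.5, 4))),
    extcap_r     = list(center = s(c(20, 0, 2)), radii = s(c(2, 7, 4.5))),
    extcap_l     = list(center = s(c(-20, 0, 2)), radii = s(c(2, 7, 4.5))),
    brainstem    = list(center = s(c(0, -8, -16)), radii = s(c(5, 6, 8)))
  )
}

# control points of the corticospinal-tract curve (right hemisphere; the
# left is its x mirror); cubic Bezier sampled at n points
tract_curve_points <- function(side, scale, n = 257) {
  ctrl <- rbind(c(11, -2, 14), c(11, -3, 2), c(6, -7, -8), c(2, -8, -16))
  ctrl <- sweep(ctrl, 2, scale, `*`)
  if (side == "left") ctrl[, 1] <- -ctrl[, 1]
  t <- seq(0, 1, length.out = n)
  b <- cbind((1 - t)^3, 3 * t * (1 - t)^2, 3 * t^2 * (1 - t), t^3)
  b %*% ctrl
}

TRACT_RADIUS_MM <- 2.5
PERIVENT_SHELL_MM <- 4

in_ellipsoid <- function(W, shape) {
  ((W[, 1] - shape$center[1]) / shape$radii[1])^2 +
    ((W[, 2] - shape$center[2]) / shape$radii[2])^2 +
    ((W[, 3] - shape$center[3]) / shape$radii[3])^2 <= 1
}

# voxels whose centre lies within `radius` of any row of `pts` (chunked over
# candidate voxels inside the bounding box)
near_points <- function(W, pts, radius) {
  lo <- apply(pts, 2, min) - radius
  hi <- apply(pts, 2, max) + radius
  cand <- which(W[, 1] >= lo[1] & W[, 1] <= hi[1] &
                W[, 2] >= lo[2] & W[, 2] <= hi[2] &
                W[, 3] >= lo[3] & W[, 3] <= hi[3])
  out <- logical(nrow(W))
  r2 <- radius^2
  for (start in seq(1, length(cand), by = 4096)) {
    idx <- cand[start:min(start + 4095, length(cand))]
    d2 <- outer(W[idx, 1], pts[, 1], `-`)^2 +
      outer(W[idx, 2], pts[, 2], `-`)^2 +
      outer(W[idx, 3], pts[, 3], `-`)^2
    out[idx] <- matrixStats_rowMins(d2) <= r2
  }
  out
}

# row minima without extra dependencies
matrixStats_rowMins <- function(m) do.call(pmin, as.data.frame(m))

ATLAS_LABELS <- c(ventricle_left = 1L, ventricle_right = 2L,
                  periventricular_left = 3L, periventricular_right = 4L,
                  tract_left = 5L, tract_right = 6L,
                  caudate_left = 7L, caudate_right = 8L,
                  lentiform_left = 9L, lentiform_right = 10L,
                  thalamus_left = 11L, thalamus_right = 12L,
                  external_capsule_left = 13L, external_capsule_right = 14L,
                  brainstem = 15L)

#' Generate the synthetic template and subcortical atlas
#'
#' Builds the population-template stand-in on which lesion masks are compared:
#' T1-like and FLAIR-like intensity volumes, a tissue label volume, a brain
#' mask, and an integer atlas with named subcortical regions (ventricles,
#' periventricular shell, corticospinal tract, caudate / lentiform / thalamus
#' left and right, external capsules, brainstem; label 0 = background).
#' Deterministic given `spec$seed`.
#'
#' @param spec a [template_spec()].
#' @return a `svd_template` list with elements `t1`, `flair` (`svd_volume`),
#'   `atlas` (integer `svd_volume`, `attr(, "labels")` named), `tissue`
#'   (0 background, 1 CSF, 2 grey, 3 white), `brain_mask`, `tract_points`,
#'   `world` (voxel-centre world coordinates) and `spec`.
#' @examples
#' tpl <- make_template(template_spec(grid_shape = c(48, 48, 48)))
#' table(as.vector(tpl$atlas[tpl$atlas > 0]))
#' @export
make_template <- function(spec = template_spec()) {
  validate_template_spec(spec)
  dm <- spec$grid_shape
  vs <- rep(spec$voxel_size_mm, 3)
  aff <- centred_affine(dm, vs)
  W <- apply_affine(aff, grid_voxels(dm))
  scale <- dm * vs / 64
  sh <- phantom_shapes(scale)

  icv <- in_ellipsoid(W, sh$intracranial)
  brain <- in_ellipsoid(W, sh$brain)
  white <- in_ellipsoid(W, sh$white) & brain
  vent_l <- in_ellipsoid(W, sh$ventricle_l) & brain
  vent_r <- in_ellipsoid(W, sh$ventricle_r) & brain
  vent <- vent_l | vent_r
  nuclei <- list(caudate_left = in_ellipsoid(W, sh$caudate_l),
                 caudate_right = in_ellipsoid(W, sh$caudate_r),
                 lentiform_left = in_ellipsoid(W, sh$lentiform_l),
                 lentiform_right = in_ellipsoid(W, sh$lentiform_r),
                 thalamus_left = in_ellipsoid(W, sh$thalamus_l),
                 thalamus_right = in_ellipsoid(W, sh$thalamus_r))
  nuclei <- lapply(nuclei, function(m) m & brain & !vent)
  extcap_l <- in_ellipsoid(W, sh$extcap_l) & brain & !vent
  extcap_r <- in_ellipsoid(W, sh$extcap_r) & brain & !vent
  stem <- in_ellipsoid(W, sh$brainstem) & icv

  # tissue: 0 background, 1 csf, 2 grey, 3 white
  tissue <- integer(nrow(W))
  tissue[icv] <- 1L
  tissue[brain] <- 2L
  tissue[white] <- 3L
  for (m in nuclei) tissue[m] <- 2L
  tissue[stem] <- 3L
  tissue[vent] <- 1L

  # periventricular shell: enlarged ventricle ellipsoids within white matter
  enlarge <- function(shp) list(center = shp$center,
                                radii = shp$radii + PERIVENT_SHELL_MM)
  pv_l <- in_ellipsoid(W, enlarge(sh$ventricle_l)) & tissue == 3L
  pv_r <- in_ellipsoid(W, enlarge(sh$ventricle_r)) & tissue == 3L

  tract_pts <- list(left = tract_curve_points("left", scale),
                    right = tract_curve_points("right", scale))
  tract_l <- near_points(W, tract_pts$left, TRACT_RADIUS_MM) & icv
  tract_r <- near_points(W, tract_pts$right, TRACT_RADIUS_MM) & icv

  # precedence: later assignments win; the tract tube is assigned last so
  # that its atlas voxel count is exactly the rasterized tube within the
  # intracranial space
  atlas <- integer(nrow(W))
  atlas[pv_l] <- ATLAS_LABELS[["periventricular_left"]]
  atlas[pv_r] <- ATLAS_LABELS[["periventricular_right"]]
  atlas[extcap_l] <- ATLAS_LABELS[["external_capsule_left"]]
  atlas[extcap_r] <- ATLAS_LABELS[["external_capsule_right"]]
  for (nm in names(nuclei)) atlas[nuclei[[nm]]] <- ATLAS_LABELS[[nm]]
  atlas[stem] <- ATLAS_LABELS[["brainstem"]]
  atlas[vent_l] <- ATLAS_LABELS[["ventricle_left"]]
  atlas[vent_r] <- ATLAS_LABELS[["ventricle_right"]]
  atlas[tract_l] <- ATLAS_LABELS[["tract_left"]]
  atlas[tract_r] <- ATLAS_LABELS[["tract_right"]]

  intensity <- function(seq_name) {
    tm <- spec$tissue_means[[seq_name]]
    v <- numeric(nrow(W))
    v[tissue == 1L] <- tm[["csf"]]
    v[tissue == 2L] <- tm[["grey"]]
    v[tissue == 3L] <- tm[["white"]]
    v
  }
  set.seed(spec$seed)
  n <- nrow(W)
  t1 <- intensity("t1")
  flair <- intensity("flair")
  if (spec$noise_sd > 0) {
    t1 <- t1 + rnorm(n, 0, spec$noise_sd)
    flair <- flair + rnorm(n, 0, spec$noise_sd)
  }

  as_vol <- function(v) volume_image(array(v, dm), vs, aff)
  atlas_vol <- as_vol(atlas)
  attr(atlas_vol, "labels") <- ATLAS_LABELS
  structure(list(
    t1 = as_vol(t1), flair = as_vol(flair),
    atlas = atlas_vol,
    tissue = as_vol(tissue),
    brain_mask = lesion_mask(array(as.integer(brain | stem), dm),
                             voxel_size = vs, affine = aff, class = "wmh"),
    tract_points = tract_pts,
    tract_radius_mm = TRACT_RADIUS_MM,
    world = W,
    spec = spec), class = "svd_template")
}

#' @export
print.svd_template <- function(x, ...) {
  cat(sprintf("<svd_template> %s grid, %d atlas regions\n",
              paste(dim(x$t1), collapse = "x"),
              length(attr(x$atlas, "labels"))))
  invisible(x)
}

# deterministic per-subject seed table from the master seed: a draw from the
# master stream decorrelates the per-subject generators (linearly spaced
# seeds produce correlated Mersenne-Twister output), while the prefix
# property keeps subject i's seed independent of the cohort size and of the
# order of generation
subject_seeds <- function(master_seed, n) {
  set.seed(as.integer(master_seed))
  sample.int(2147483646L, n)
}

subject_seed <- function(master_seed, index) {
  subject_seeds(master_seed, index)[index]
}
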