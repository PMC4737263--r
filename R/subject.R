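#' Generate one synthetic subject
#'
#' Plants the three lesion classes into the template with class-appropriate
#' intensity signatures — the acute infarct and WMH hyperintense on the
#' FLAIR-like sequence, lacunes at CSF-like intensity on both sequences —
#' then misaligns the subject by a small random affine (recorded as
#' `true_affine`, mapping subject world coordinates to template world
#' coordinates) and measures the four volumetric features from the generated
#' volumes. Exactly one recent small subcortical infarct is planted per
#' subject, centred on the corticospinal-tract curve; lacunes are present
#' with probability `lspec$lacune_prevalence`.
#'
#' @param template a `svd_template` from [make_template()].
#' @param lspec a [lesion_spec()].
#' @param subject_id character id.
#' @param seed integer RNG seed; the same seed reproduces the subject
#'   exactly.
#' @return a `svd_subject` list: `subject_id`, `flair`, `t1`
#'   (`svd_volume`), `brain_mask`, `truth` (list of `svd_mask` per class, in
#'   subject space), `true_affine` (`svd_affine`), `volumetrics` (named
#'   vector, ml: intracranial, brain, ventricular, wmh).
#' @export
make_subject <- function(template, lspec = lesion_spec(),
                         subject_id = "sub-001", seed = 1) {
  stopifnot(inherits(template, "svd_template"))
  set.seed(seed)
  dm <- dim(template$t1)
  vs <- voxel_size(template$t1)
  aff <- vox2world(template$t1)
  W <- template$world
  tissue <- as.vector(unclass(template$tissue))
  atlas <- as.vector(unclass(template$atlas))
  labels <- attr(template$atlas, "labels")
  parenchyma <- tissue >= 2L
  vent <- atlas %in% labels[c("ventricle_left", "ventricle_right")]

  # ---- infarct: one component on the tract curve, in-plane diameter capped
  infarct <- plant_infarct(template, lspec, W, parenchyma, dm)

  # ---- WMH: multifocal, periventricular-weighted
  wmh <- plant_wmh(template, lspec, W, parenchyma, vent, atlas, labels, tissue)
  wmh <- wmh & !infarct

  # ---- lacunes
  lacune <- rep(FALSE, length(tissue))
  if (lspec$lacune_prevalence > 0 && runif(1) < lspec$lacune_prevalence)
    lacune <- plant_lacunes(lspec, W, tissue, vent, atlas, labels, infarct)

  # ---- template-space intensities (noise is added in subject space)
  tm <- template$spec$tissue_means
  lm <- lspec$lesion_means
  intens <- function(sq) {
    v <- numeric(length(tissue))
    v[tissue == 1L] <- tm[[sq]][["csf"]]
    v[tissue == 2L] <- tm[[sq]][["grey"]]
    v[tissue == 3L] <- tm[[sq]][["white"]]
    v[wmh] <- lm[[sq]][["wmh"]]
    v[infarct] <- lm[[sq]][["infarct"]]
    v[lacune] <- lm[[sq]][["lacune"]]
    v
  }
  flair_t <- intens("flair")
  t1_t <- intens("t1")

  # ---- random misalignment (subject world -> template world)
  A <- affine_transform(
    rotation = runif(3, -lspec$misalign_rotation_deg,
                     lspec$misalign_rotation_deg),
    translation = runif(3, -lspec$misalign_translation_mm,
                        lspec$misalign_translation_mm),
    scale = runif(3, lspec$misalign_scale_range[1],
                  lspec$misalign_scale_range[2]))

  # subject grid voxel -> template grid voxel
  M <- solve(aff) %*% unclass(A) %*% aff
  warp_num <- function(v, fill = 0)
    c_affine_resample(as.numeric(v), dm, dm, M, fill)
  warp_bin <- function(v) array(as.integer(warp_num(v) >= 0.5), dm)

  noise_sd <- template$spec$noise_sd
  flair_s <- warp_num(array(flair_t, dm))
  t1_s <- warp_num(array(t1_t, dm))
  if (noise_sd > 0) {
    flair_s <- flair_s + rnorm(length(flair_s), 0, noise_sd)
    t1_s <- t1_s + rnorm(length(t1_s), 0, noise_sd)
  }

  truth <- list(
    infarct = largest_component(warp_bin(array(as.integer(infarct), dm))),
    wmh = warp_bin(array(as.integer(wmh), dm)),
    lacune = warp_bin(array(as.integer(lacune), dm)))
  icv_s <- warp_bin(array(as.integer(tissue > 0L), dm))
  brain_s <- warp_bin(array(as.integer(parenchyma), dm))
  vent_s <- warp_bin(array(as.integer(vent), dm))

  vol_ml <- function(m) sum(m) * prod(vs) / 1000
  volumetrics <- c(intracranial = vol_ml(icv_s), brain = vol_ml(brain_s),
                   ventricular = vol_ml(vent_s),
                   wmh = vol_ml(truth$wmh))

  as_vol <- function(v) volume_image(array(v, dm), vs, aff)
  structure(list(
    subject_id = subject_id,
    flair = as_vol(flair_s),
    t1 = as_vol(t1_s),
    brain_mask = lesion_mask(brain_s, voxel_size = vs, affine = aff,
                             class = "wmh"),
    ventricle_mask = lesion_mask(vent_s, voxel_size = vs, affine = aff,
                                 class = "lacune"),
    truth = list(
      infarct = lesion_mask(truth$infarct, voxel_size = vs, affine = aff,
                            class = "infarct"),
      wmh = lesion_mask(truth$wmh, voxel_size = vs, affine = aff,
                        class = "wmh"),
      lacune = lesion_mask(truth$lacune, voxel_size = vs, affine = aff,
                           class = "lacune")),
    true_affine = A,
    volumetrics = volumetrics,
    seed = as.integer(seed)), class = "svd_subject")
}

plant_infarct <- function(template, lspec, W, parenchyma, dm) {
  side <- sample(c("left", "right"), 1)
  pts <- template$tract_points[[side]]
  for (try in 1:20) {
    ctr <- pts[sample(nrow(pts), 1), ] +
      rnorm(3, 0, lspec$infarct_center_jitter_mm)
    d_ax <- runif(1, lspec$infarct_axial_diameter_range_mm[1],
                  lspec$infarct_axial_diameter_range_mm[2])
    rz <- d_ax / 2 * runif(1, 0.7, 1)
    m <- in_ellipsoid(W, list(center = ctr, radii = c(d_ax / 2, d_ax / 2, rz)))
    m <- m & parenchyma
    if (sum(m) >= 4) {
      m <- largest_component(array(as.integer(m), dm)) > 0
      return(as.vector(m))
    }
  }
  stop("generation error: could not place infarct after 20 attempts",
       call. = FALSE)
}

plant_wmh <- function(template, lspec, W, parenchyma, vent, atlas, labels,
                      tissue) {
  n_foci <- max(1L, stats::rpois(1, lspec$wmh_count_mean))
  pv_pool <- which(atlas %in% labels[c("periventricular_left",
                                       "periventricular_right")])
  wm_pool <- which(tissue == 3L)
  wmh <- rep(FALSE, length(tissue))
  for (f in seq_len(n_foci)) {
    pool <- if (runif(1) < lspec$wmh_periventricular_weight) pv_pool else wm_pool
    ctr <- W[pool[sample(length(pool), 1)], ] + rnorm(3, 0, 1)
    radii <- runif(3, lspec$wmh_blob_radius_range_mm[1],
                   lspec$wmh_blob_radius_range_mm[2])
    wmh <- wmh | (in_ellipsoid(W, list(center = ctr, radii = radii)) &
                    parenchyma & !vent)
  }
  wmh
}

plant_lacunes <- function(lspec, W, tissue, vent, atlas, labels, infarct) {
  n_lac <- 1L + rbinom(1, 1, 0.25)
  pool <- which(atlas %in% labels[c("caudate_left", "caudate_right",
                                    "lentiform_left", "lentiform_right",
                                    "thalamus_left", "thalamus_right",
                                    "external_capsule_left",
                                    "external_capsule_right")] |
                  tissue == 3L)
  lac <- rep(FALSE, length(tissue))
  for (l in seq_len(n_lac)) {
    placed <- FALSE
    for (try in 1:20) {
      ctr <- W[pool[sample(length(pool), 1)], ]
      d <- runif(1, lspec$lacune_diameter_range_mm[1],
                 lspec$lacune_diameter_range_mm[2])
      sph <- in_ellipsoid(W, list(center = ctr, radii = rep(d / 2, 3)))
      if (!any(sph)) next
      inside <- mean(tissue[sph] >= 2L)
      if (inside >= 0.8 && !any(sph & vent) && !any(sph & infarct)) {
        lac <- lac | (sph & tissue >= 2L)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("generation error: could not place lacune after 20 attempts",
           call. = FALSE)
  }
  lac
}

#' @export
print.svd_subject <- function(x, ...) {
  cat(sprintf("<svd_subject> %s  infarct %d vx, wmh %d vx, lacune %d vx\n",
              x$subject_id, sum(x$truth$infarct), sum(x$truth$wmh),
              sum(x$truth$lacune)))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' `n` subjects with independent per-subject seeds derived deterministically
#' from the master seed (hashing the pair, so a subject's data do not depend
#' on the order of generation or cohort size).
#'
#' @inheritParams make_subject
#' @param n number of subjects (>= 2).
#' @param seed master seed.
#' @return a `svd_cohort`: list of `svd_subject` with attributes `seed`, `n`.
#' @examples
#' \donttest{
#' tpl <- make_template(template_spec(grid_shape = c(48, 48, 48)))
#' coh <- make_cohort(3, tpl, lesion_spec(), seed = 7)
#' cohort_volumetrics(coh)
#' }
#' @export
make_cohort <- function(n, template, lspec = lesion_spec(), seed = 1) {
  if (!is.numeric(n) || n < 2)
    stop("configuration error: cohort size `n` must be >= 2", call. = FALSE)
  n <- as.integer(n)
  seeds <- subject_seeds(seed, n)
  subjects <- lapply(seq_len(n), function(i)
    make_subject(template, lspec, subject_id = sprintf("sub-%03d", i),
                 seed = seeds[i]))
  structure(subjects, class = "svd_cohort", seed = as.integer(seed), n = n)
}

#' @export
print.svd_cohort <- function(x, ...) {
  cat(sprintf("<svd_cohort> %d subjects (seed %d), %d with lacunes\n",
              length(x), attr(x, "seed"),
              sum(vapply(x, function(s) sum(s$truth$lacune) > 0, logical(1)))))
  invisible(x)
}

#' Volumetric features of a cohort
#'
#' One row per subject with the four features used for representative-subject
#' selection: intracranial, brain, ventricular and WMH volumes (ml).
#' @param cohort a `svd_cohort` (or list of `svd_subject`).
#' @return a tibble: subject_id, intracranial_ml, brain_ml, ventricular_ml,
#'   wmh_ml.
#' @export
cohort_volumetrics <- function(cohort) {
  purrr::map_dfr(cohort, function(s)
    tibble(subject_id = s$subject_id,
           intracranial_ml = s$volumetrics[["intracranial"]],
           brain_ml = s$volumetrics[["brain"]],
           ventricular_ml = s$volumetrics[["ventricular"]],
           wmh_ml = s$volumetrics[["wmh"]]))
}

#' Write a cohort to disk
#'
#' Volumes and masks as NIfTI-1 (images 32-bit float, masks 8-bit unsigned),
#' the true affine of each subject as a 4x4 text matrix, and a manifest CSV
#' with file paths, volumetrics and affine parameters.
#'
#' @param cohort a `svd_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest tibble, invisibly; written to `dir/manifest.csv`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map_dfr(cohort, function(s) {
    base <- file.path(dir, s$subject_id)
    write_volume(s$flair, paste0(base, "_flair.nii.gz"))
    write_volume(s$t1, paste0(base, "_t1.nii.gz"))
    write_mask(s$brain_mask, paste0(base, "_brain.nii.gz"))
    for (cls in names(s$truth))
      write_mask(s$truth[[cls]], paste0(base, "_", cls, ".nii.gz"))
    write_transform(s$true_affine, paste0(base, "_true_affine.txt"))
    A <- unclass(s$true_affine)
    aff_cols <- setNames(as.list(as.vector(t(A[1:3, ]))),
                         paste0("affine_", rep(1:3, each = 4), rep(1:4, 3)))
    dplyr::bind_cols(
      tibble(subject_id = s$subject_id,
             flair = paste0(base, "_flair.nii.gz"),
             t1 = paste0(base, "_t1.nii.gz"),
             brain_mask = paste0(base, "_brain.nii.gz"),
             infarct = paste0(base, "_infarct.nii.gz"),
             wmh = paste0(base, "_wmh.nii.gz"),
             lacune = paste0(base, "_lacune.nii.gz"),
             intracranial_ml = s$volumetrics[["intracranial"]],
             brain_ml = s$volumetrics[["brain"]],
             ventricular_ml = s$volumetrics[["ventricular"]],
             wmh_ml = s$volumetrics[["wmh"]]),
      tibble::as_tibble(aff_cols))
  })
  utils::write.csv(rows, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(rows)
}
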