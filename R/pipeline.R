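#' Pipeline run configuration
#'
#' Every stage parameter with its default, in one serializable object.
#' A configuration round-trips unchanged through [write_config()] /
#' [read_config()].
#'
#' @param n_subjects cohort size.
#' @param grid_shape,voxel_size_mm,noise_sd,template_seed synthetic template
#'   geometry and noise (see [template_spec()]).
#' @param seed master seed for cohort generation.
#' @param lesions named list of [lesion_spec()] arguments.
#' @param segmentation list: `K` (quantization clusters), `percentile`
#'   (centroid-red centile for WMH extraction).
#' @param lacune_detection list: `min_diam_mm`, `max_diam_mm`,
#'   `min_sphericity`.
#' @param registration list: `enabled`, `dof` (subject to representative),
#'   `template_dof` (representative to template), `use_true_affines`
#'   (bypass estimation with the generator's ground-truth transforms).
#' @param use_truth_masks skip segmentation and map the ground-truth masks
#'   (for bypass-equivalence checks).
#' @param pdmap list: `roi_side_mm`, `roi_summary`.
#' @param comparisons list of treatment pairs for the Friedman comparisons.
#' @param average_laterality average left/right PDs per region before
#'   testing.
#' @param output_dir optional directory for all file outputs.
#' @return a `svd_run_config` list.
#' @export
run_config <- function(n_subjects = 12,
                       grid_shape = c(48, 48, 48),
                       voxel_size_mm = 1,
                       noise_sd = 5,
                       template_seed = 1,
                       seed = 1,
                       lesions = list(),
                       segmentation = list(K = 5, percentile = 100),
                       lacune_detection = list(min_diam_mm = 3,
                                               max_diam_mm = 15,
                                               min_sphericity = 0.3),
                       registration = list(enabled = TRUE, dof = 12,
                                           template_dof = 6,
                                           use_true_affines = FALSE),
                       use_truth_masks = FALSE,
                       pdmap = list(roi_side_mm = 2, roi_summary = "mean"),
                       comparisons = list(c("infarct", "wmh"),
                                          c("infarct", "lacune")),
                       average_laterality = TRUE,
                       output_dir = NULL) {
  cfg <- as.list(environment())
  defaults <- list(segmentation = list(K = 5, percentile = 100),
                   lacune_detection = list(min_diam_mm = 3, max_diam_mm = 15,
                                           min_sphericity = 0.3),
                   registration = list(enabled = TRUE, dof = 12,
                                       template_dof = 6,
                                       use_true_affines = FALSE),
                   pdmap = list(roi_side_mm = 2, roi_summary = "mean"))
  for (blk in names(defaults))
    cfg[[blk]] <- utils::modifyList(defaults[[blk]], as.list(cfg[[blk]]))
  structure(cfg, class = "svd_run_config")
}

#' @rdname run_config
#' @param config a `svd_run_config`; `path` a YAML file path.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$comparisons <- lapply(cfg$comparisons, as.character)
  do.call(run_config, cfg)
}

#' Segment one subject
#'
#' The per-subject segmentation stage: RGB fusion of the FLAIR-like and
#' T1-like sequences, minimum-variance quantization, WMH extraction with the
#' acute-infarct mask excluded, and lacune detection with ventricle
#' exclusion.
#'
#' @param subject a `svd_subject`.
#' @param tissue_means the template's tissue means (for the lacune
#'   threshold); `NULL` falls back to Otsu.
#' @param K,percentile quantization parameters.
#' @param lacune_args list of [detect_lacunes()] arguments.
#' @return list: `wmh` (mask), `lacune` (mask), `lacune_components`
#'   (tibble), `model` (`svd_quantization`).
#' @export
segment_subject <- function(subject, tissue_means = NULL, K = 5,
                            percentile = 100, lacune_args = list()) {
  colours <- fuse_channels(subject$flair, subject$t1, subject$brain_mask)
  q <- minimum_variance_quantize(colours, K = K)
  wmh <- extract_lesion_class(q$labels, q$model, colours,
                              percentile = percentile,
                              infarct_mask = subject$truth$infarct)
  lac <- do.call(detect_lacunes,
                 c(list(seq_flair = subject$flair,
                        brain_mask = subject$brain_mask,
                        ventricle_mask = subject$ventricle_mask,
                        tissue_means = tissue_means),
                   lacune_args))
  list(wmh = wmh, lacune = lac$mask, lacune_components = lac$components,
       model = q$model)
}

with_stage <- function(stage, subject_id, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage `%s`%s: %s", stage,
                 if (is.null(subject_id)) "" else paste0(" subject ", subject_id),
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full lesion-mapping pipeline
#'
#' Synthetic-cohort generation, per-subject segmentation, Mahalanobis
#' representative-subject selection, affine spatial normalization (subject
#' to representative, representative to template, composed), PD mapping per
#' lesion class (lacunes over affected subjects only), regional ROI
#' quantification, and Friedman comparisons of the regional distributions.
#' Subjects whose registration fails the quality check (final cost not below
#' the identity-transform cost) are excluded from the PD denominators and
#' listed in the manifest. The manifest carries input hashes, parameters and
#' versions; identical config and seed give identical manifests.
#'
#' @param config a [run_config()].
#' @return a `svd_run_report`: `template`, `cohort`, `segmentations`,
#'   `representative` (index), `transforms`, `exclusions`, `pdmaps`,
#'   `region_table`, `comparisons`, `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "svd_run_config"))
  out_dir <- config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  report <- tryCatch(
    run_pipeline_impl(config),
    error = function(e) {
      if (!is.null(out_dir))
        jsonlite::write_json(list(status = "failed",
                                  message = conditionMessage(e)),
                             file.path(out_dir, "manifest.json"),
                             auto_unbox = TRUE)
      stop(e)
    })
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

run_pipeline_impl <- function(config) {
  tpl_spec <- template_spec(grid_shape = config$grid_shape,
                            voxel_size_mm = config$voxel_size_mm,
                            noise_sd = config$noise_sd,
                            seed = config$template_seed)
  template <- with_stage("template", NULL, make_template(tpl_spec))
  lspec <- do.call(lesion_spec, config$lesions)
  cohort <- with_stage("cohort", NULL,
                       make_cohort(config$n_subjects, template, lspec,
                                   seed = config$seed))

  # ---- segmentation (or truth-mask ingestion)
  flair_means <- tpl_spec$tissue_means$flair
  segs <- lapply(cohort, function(s) {
    if (config$use_truth_masks)
      return(list(wmh = s$truth$wmh, lacune = s$truth$lacune,
                  lacune_components = NULL, model = NULL))
    with_stage("segmentation", s$subject_id,
               segment_subject(s, tissue_means = flair_means,
                               K = config$segmentation$K,
                               percentile = config$segmentation$percentile,
                               lacune_args = config$lacune_detection))
  })

  # ---- representative subject (Mahalanobis to the cohort median)
  feats <- cohort_volumetrics(cohort)
  rep_idx <- with_stage("template-selection", NULL,
                        as.integer(select_representative(feats)))

  # ---- spatial normalization: subject -> representative -> template
  transforms <- vector("list", length(cohort))
  quality <- logical(length(cohort))
  if (config$registration$use_true_affines || !config$registration$enabled) {
    for (i in seq_along(cohort)) {
      transforms[[i]] <- cohort[[i]]$true_affine
      quality[i] <- TRUE
    }
  } else {
    rep_s <- cohort[[rep_idx]]
    A_rep <- with_stage("registration", rep_s$subject_id,
                        register_affine(rep_s$t1, template$t1,
                                        dof = config$registration$template_dof))
    for (i in seq_along(cohort)) {
      s <- cohort[[i]]
      A_i <- if (i == rep_idx) {
        new_affine(diag(4), dof = config$registration$dof)
      } else {
        with_stage("registration", s$subject_id,
                   register_affine(s$flair, rep_s$flair,
                                   dof = config$registration$dof))
      }
      transforms[[i]] <- compose_affine(A_rep, A_i)
      quality[i] <- attr(A_i, "converged") %||% TRUE
    }
  }
  included <- which(quality)
  exclusions <- tibble(
    subject_id = vapply(cohort[!quality], `[[`, character(1), "subject_id"),
    reason = rep("registration quality: cost not below identity",
                 sum(!quality)))

  # ---- map masks to template space and build PD maps
  to_template <- function(mask, i)
    resample_mask(mask, transforms[[i]], template$t1)
  masks_std <- list(
    infarct = lapply(included, function(i)
      to_template(cohort[[i]]$truth$infarct, i)),
    wmh = lapply(included, function(i) to_template(segs[[i]]$wmh, i)),
    lacune = lapply(included, function(i) to_template(segs[[i]]$lacune, i)))
  pdmaps <- list(
    infarct = with_stage("pd-mapping", NULL,
                         pd_map(masks_std$infarct, "all")),
    wmh = with_stage("pd-mapping", NULL, pd_map(masks_std$wmh, "all")),
    lacune = with_stage("pd-mapping", NULL, tryCatch(
      pd_map(masks_std$lacune, "affected_only"),
      error = function(e) pd_map(masks_std$lacune, "all"))))

  # ---- regional quantification and comparisons
  rois <- region_rois(template$atlas, side_mm = config$pdmap$roi_side_mm)
  rtab <- with_stage("region-table", NULL,
                     region_table(pdmaps, rois,
                                  summary = config$pdmap$roi_summary))
  comparisons <- lapply(config$comparisons, function(tr)
    with_stage("statistics", NULL,
               compare_lesion_distributions(
                 rtab, treatments = tr,
                 average_laterality = config$average_laterality)))
  names(comparisons) <- vapply(config$comparisons, paste, character(1),
                               collapse = "_vs_")

  manifest <- build_manifest(config, cohort, segs, pdmaps, rtab, rep_idx,
                             exclusions)
  structure(list(template = template, cohort = cohort,
                 segmentations = segs, representative = rep_idx,
                 transforms = transforms, exclusions = exclusions,
                 pdmaps = pdmaps, region_table = rtab,
                 comparisons = comparisons, manifest = manifest),
            class = "svd_run_report")
}

build_manifest <- function(config, cohort, segs, pdmaps, rtab, rep_idx,
                           exclusions) {
  list(
    package_version = as.character(utils::packageVersion("svdmap")),
    seed = config$seed,
    parameters = unclass(config),
    representative = cohort[[rep_idx]]$subject_id,
    excluded = exclusions$subject_id,
    input_hashes = setNames(
      lapply(cohort, function(s)
        list(flair = rlang::hash(as.numeric(s$flair)),
             t1 = rlang::hash(as.numeric(s$t1)))),
      vapply(cohort, `[[`, character(1), "subject_id")),
    pd_map_hashes = lapply(pdmaps, function(p) rlang::hash(as.numeric(p))),
    region_table_hash = rlang::hash(as.data.frame(rtab)))
}

write_report <- function(report, out_dir) {
  for (cls in names(report$pdmaps))
    write_pd_map(report$pdmaps[[cls]],
                 file.path(out_dir, paste0("pd_", cls, ".nii.gz")))
  utils::write.csv(round_pd(report$region_table),
                   file.path(out_dir, "region_table.csv"), row.names = FALSE)
  jsonlite::write_json(lapply(report$comparisons, function(f)
    as.list(tidy(f))), file.path(out_dir, "comparisons.json"),
    auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(report$transforms))
    write_transform(report$transforms[[i]],
                    file.path(out_dir, sprintf("%s_to_template.txt",
                                               report$cohort[[i]]$subject_id)))
  invisible(out_dir)
}

#' @export
print.svd_run_report <- function(x, ...) {
  cat(sprintf("<svd_run_report> %d subjects (%d included), representative %s\n",
              length(x$cohort), length(x$cohort) - nrow(x$exclusions),
              x$cohort[[x$representative]]$subject_id))
  for (nm in names(x$comparisons)) {
    f <- x$comparisons[[nm]]
    cat(sprintf("  %s: chi2 = %.3f, p = %.4g (%s)\n", nm, f$statistic,
                f$p_value, f$method))
  }
  invisible(x)
}

#' @export
glance.svd_run_report <- function(x, ...) {
  purrr::map_dfr(names(x$comparisons), function(nm) {
    t <- tidy(x$comparisons[[nm]])
    t$comparison <- nm
    t[, c("comparison", setdiff(names(t), "comparison"))]
  })
}
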