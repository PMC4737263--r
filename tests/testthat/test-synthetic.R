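test_that("template generation is deterministic and validates its spec", {
  sp <- template_spec(grid_shape = c(48, 48, 48), seed = 5)
  t1 <- make_template(sp)
  t2 <- make_template(sp)
  expect_identical(as.numeric(t1$t1), as.numeric(t2$t1))
  expect_identical(as.numeric(t1$flair), as.numeric(t2$flair))
  expect_identical(as.integer(t1$atlas), as.integer(t2$atlas))

  expect_error(template_spec(grid_shape = c(16, 64, 64)), "grid_shape")
  expect_error(template_spec(voxel_size_mm = 0), "voxel_size_mm")
  expect_error(template_spec(noise_sd = -1), "noise_sd")
  expect_error(template_spec(tissue_means = list(
    flair = c(csf = 1, grey = 1, white = 2),
    t1 = c(csf = 1, grey = 2, white = 3))), "tissue_means")
})

test_that("noiseless template takes exactly the tissue-mean intensities", {
  tpl <- fix_template48_clean()
  tm <- tpl$spec$tissue_means
  expect_setequal(unique(as.numeric(tpl$flair)), c(0, tm$flair))
  expect_setequal(unique(as.numeric(tpl$t1)), c(0, tm$t1))
})

test_that("atlas has the required named regions and background 0", {
  tpl <- fix_template48()
  labels <- attr(tpl$atlas, "labels")
  expect_gte(length(labels), 8)
  expect_true(any(grepl("^tract", names(labels))))
  expect_true(any(grepl("^periventricular", names(labels))))
  for (nucleus in c("caudate", "lentiform", "thalamus")) {
    expect_true(paste0(nucleus, "_left") %in% names(labels))
    expect_true(paste0(nucleus, "_right") %in% names(labels))
  }
  av <- as.integer(tpl$atlas)
  expect_true(all(av %in% c(0L, unname(labels))))
  expect_gt(sum(av == 0L), 0)
  # every named region is non-empty
  for (lb in labels) expect_gt(sum(av == lb), 0)
})

test_that("atlas tract voxels match a brute-force re-rasterization", {
  tpl <- fix_template48()
  labels <- attr(tpl$atlas, "labels")
  icv <- as.integer(tpl$tissue) > 0L
  # the two tubes overlap near the brainstem, so compare their union
  tube <- as.vector(
    brute_tube(dim(tpl$t1), vox2world(tpl$t1), tpl$tract_points$left,
               tpl$tract_radius_mm) |
      brute_tube(dim(tpl$t1), vox2world(tpl$t1), tpl$tract_points$right,
                 tpl$tract_radius_mm))
  expected <- which(tube & icv)
  got <- which(as.integer(tpl$atlas) %in%
                 labels[c("tract_left", "tract_right")])
  expect_identical(got, expected)
})

test_that("subjects are reproducible and lesions respect their contracts", {
  tpl <- fix_template48()
  lsp <- lesion_spec(lacune_diameter_range_mm = c(3, 6))
  s1 <- make_subject(tpl, lsp, seed = 11)
  s2 <- make_subject(tpl, lsp, seed = 11)
  expect_identical(as.numeric(s1$flair), as.numeric(s2$flair))
  expect_identical(as.integer(s1$truth$wmh), as.integer(s2$truth$wmh))
  expect_identical(unclass(s1$true_affine), unclass(s2$true_affine))

  # exactly one infarct component, in-plane diameter below the cap
  lab <- svdmap:::label_components(array(as.integer(s1$truth$infarct),
                                         dim(s1$truth$infarct)))
  expect_identical(max(lab), 1L)
  expect_lte(max_axial_diameter(unclass(s1$truth$infarct),
                                voxel_size(s1$truth$infarct)),
             lsp$infarct_max_axial_diameter_mm)

  # volumetrics: WMH entry equals mask voxel count x voxel volume, exactly
  expect_identical(s1$volumetrics[["wmh"]],
                   sum(s1$truth$wmh) * prod(voxel_size(s1$flair)) / 1000)
  expect_true(all(s1$volumetrics > 0))
  expect_gte(s1$volumetrics[["intracranial"]], s1$volumetrics[["brain"]])
  expect_gte(s1$volumetrics[["brain"]], s1$volumetrics[["ventricular"]])
})

test_that("lacune prevalence 0 gives empty masks; planted diameter is recovered", {
  tpl <- fix_template48()
  s <- make_subject(tpl, lesion_spec(lacune_prevalence = 0), seed = 3)
  expect_identical(sum(s$truth$lacune), 0L)

  # force lacunes of 4 mm diameter and recompute from the truth mask
  lsp <- lesion_spec(lacune_prevalence = 1,
                     lacune_diameter_range_mm = c(4, 4))
  s4 <- make_subject(tpl, lsp, seed = 7)
  lab <- svdmap:::label_components(array(as.integer(s4$truth$lacune),
                                         dim(s4$truth$lacune)))
  expect_gte(max(lab), 1L)
  voxvol <- prod(voxel_size(s4$flair))
  for (k in seq_len(max(lab))) {
    v <- sum(lab == k) * voxvol
    d_eq <- (6 * v / pi)^(1 / 3)
    expect_lt(abs(d_eq - 4), 1)
  }
})

test_that("cohorts derive stable per-subject seeds and check n", {
  tpl <- fix_template48()
  lsp <- lesion_spec(lacune_diameter_range_mm = c(3, 6))
  expect_error(make_cohort(1, tpl, lsp), "n.*>= 2")

  coh2 <- make_cohort(2, tpl, lsp, seed = 9)
  expect_length(coh2, 2)

  # subject i is independent of cohort size (hash-derived seeds)
  coh4 <- make_cohort(4, tpl, lsp, seed = 9)
  expect_identical(as.numeric(coh2[[2]]$flair), as.numeric(coh4[[2]]$flair))

  # different master seeds give different truth masks
  cohB <- make_cohort(2, tpl, lsp, seed = 10)
  expect_false(identical(as.integer(coh2[[1]]$truth$wmh),
                         as.integer(cohB[[1]]$truth$wmh)))
})

test_that("empirical lacune prevalence tracks the specified rate", {
  # small grid keeps 120 subjects affordable; diameters capped so lacunes
  # fit the scaled-down deep structures
  tpl <- make_template(template_spec(grid_shape = c(32, 32, 32), seed = 2))
  lsp <- lesion_spec(lacune_prevalence = 0.465,
                     lacune_diameter_range_mm = c(3, 5))
  n <- 120
  coh <- make_cohort(n, tpl, lsp, seed = 21)
  hits <- sum(vapply(coh, function(s) sum(s$truth$lacune) > 0, logical(1)))
  # 99% binomial interval for p = 0.465, n = 120
  bounds <- qbinom(c(0.005, 0.995), n, 0.465)
  expect_gte(hits, bounds[1])
  expect_lte(hits, bounds[2])
})

test_that("written cohorts round-trip through the manifest", {
  tpl <- fix_template48()
  lsp <- lesion_spec(lacune_diameter_range_mm = c(3, 6))
  coh <- make_cohort(2, tpl, lsp, seed = 4)
  dir <- withr::local_tempdir()
  man <- write_cohort(coh, dir)
  expect_identical(nrow(man), 2L)
  expect_true(all(file.exists(man$flair)))
  flair_back <- read_volume(man$flair[1])
  expect_lt(max(abs(as.numeric(flair_back) - as.numeric(coh[[1]]$flair))),
            1e-4)
  wmh_back <- read_mask(man$wmh[2], "wmh")
  expect_identical(as.integer(wmh_back), as.integer(coh[[2]]$truth$wmh))
  A <- read_transform(file.path(dir, "sub-001_true_affine.txt"))
  expect_lt(max(abs(A - coh[[1]]$true_affine)), 1e-12)
})
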