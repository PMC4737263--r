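mask_with <- function(voxels, dm = c(16, 16, 16), class = "wmh") {
  arr <- array(0L, dm)
  for (v in voxels) arr[v[1], v[2], v[3]] <- 1L
  lesion_mask(arr, class = class)
}

test_that("PD values are lesioned-subject proportions", {
  v <- c(8, 8, 8)
  # one of 188 subjects lesioned: PD = 1/188, printed as 0.005 at 3 decimals
  masks <- c(list(mask_with(list(v))),
             replicate(187, mask_with(list()), simplify = FALSE))
  pd <- pd_map(masks, "all")
  expect_identical(attr(pd, "denominator"), 188L)
  expect_equal(pd[8, 8, 8], 1 / 188)
  expect_identical(floor(pd[8, 8, 8] * 1000 + 0.5) / 1000, 0.005)

  # all subjects lesioned: PD = 1; half: PD = 0.5
  all_m <- replicate(188, mask_with(list(v)), simplify = FALSE)
  expect_identical(max(pd_map(all_m, "all")), 1)
  half <- c(replicate(94, mask_with(list(v)), simplify = FALSE),
            replicate(94, mask_with(list()), simplify = FALSE))
  expect_identical(pd_map(half, "all")[8, 8, 8], 0.5)
})

test_that("denominator modes count the right subjects", {
  v <- c(4, 4, 4)
  masks <- c(replicate(3, mask_with(list(v), class = "lacune"),
                       simplify = FALSE),
             replicate(5, mask_with(list(), class = "lacune"),
                       simplify = FALSE))
  pd_all <- pd_map(masks, "all")
  pd_aff <- pd_map(masks, "affected_only")
  expect_identical(attr(pd_all, "denominator"), 8L)
  expect_identical(attr(pd_aff, "denominator"), 3L)
  expect_equal(pd_aff[4, 4, 4], 1)
  expect_error(pd_map(replicate(4, mask_with(list()), simplify = FALSE),
                      "affected_only"), "non-empty")
  bad <- lesion_mask(array(0L, c(8, 8, 8)), class = "wmh")
  expect_error(pd_map(list(masks[[1]], bad), "all"), "grid mismatch")
})

test_that("PD maps conserve mass and respect ordering properties", {
  set.seed(31)
  masks <- replicate(9, {
    arr <- array(rbinom(16^3, 1, 0.05), c(16, 16, 16))
    lesion_mask(arr, class = "wmh")
  }, simplify = FALSE)
  pd <- pd_map(masks, "all")
  total <- sum(vapply(masks, function(m) sum(m), integer(1)))
  expect_equal(sum(as.numeric(pd)) * attr(pd, "denominator"), total,
               tolerance = 1e-9)
  # every voxel value is a multiple of 1/N
  expect_lt(max(abs(as.numeric(pd) * attr(pd, "denominator") -
                      round(as.numeric(pd) * attr(pd, "denominator")))),
            1e-9)
  # adding an empty mask under "all" never increases any voxel
  pd2 <- pd_map(c(masks, list(mask_with(list()))), "all")
  expect_true(all(as.numeric(pd2) <= as.numeric(pd) + 1e-12))
  # and leaves the map unchanged under "affected_only"
  pd3 <- pd_map(c(masks, list(mask_with(list()))), "affected_only")
  expect_identical(as.numeric(pd3), as.numeric(pd_map(masks,
                                                      "affected_only")))
  # subject order is irrelevant
  pd4 <- pd_map(rev(masks), "all")
  expect_identical(as.numeric(pd4), as.numeric(pd))
})

test_that("mirror-symmetric cohorts give mirror-symmetric PD maps", {
  set.seed(7)
  masks <- replicate(6, {
    arr <- array(rbinom(16^3, 1, 0.04), c(16, 16, 16))
    sym <- arr | arr[16:1, , ]
    lesion_mask(array(as.integer(sym), dim(arr)), class = "wmh")
  }, simplify = FALSE)
  pd <- pd_map(masks, "all")
  flipped <- unclass(pd)[16:1, , ]
  expect_lt(max(abs(unclass(pd) - flipped)), 2 / attr(pd, "denominator"))
})

test_that("ROI sampling summarizes PD over the cube", {
  pd <- pd_map(list(mask_with(list(c(8, 8, 8)))), "all")
  roi <- list(center_i = 1L, center_j = 1L, center_k = 1L,
              side_vox_i = 2L, side_vox_j = 2L, side_vox_k = 2L)
  expect_identical(sample_roi(pd, roi), 0)

  # hand-built 8-voxel ROI with four 0.2 values: mean 0.1, max 0.2
  vol <- array(0, c(16, 16, 16))
  vol[5:6, 5:6, 5] <- 0.2
  pd2 <- volume_image(vol)
  attr(pd2, "denominator") <- 5L
  class(pd2) <- c("svd_pdmap", class(pd2))
  roi2 <- list(center_i = 5L, center_j = 5L, center_k = 5L,
               side_vox_i = 2L, side_vox_j = 2L, side_vox_k = 2L)
  expect_equal(sample_roi(pd2, roi2, "mean"), 0.1)
  expect_equal(sample_roi(pd2, roi2, "max"), 0.2)

  # uniform map: both summaries return the constant
  u <- volume_image(array(0.37, c(16, 16, 16)))
  class(u) <- c("svd_pdmap", class(u))
  expect_equal(sample_roi(u, roi2, "mean"), 0.37)
  expect_equal(sample_roi(u, roi2, "max"), 0.37)

  out <- list(center_i = 16L, center_j = 16L, center_k = 16L,
              side_vox_i = 2L, side_vox_j = 2L, side_vox_k = 2L)
  expect_error(sample_roi(pd, out), "geometry error")
})

test_that("region tables quantify lesion classes against the atlas", {
  tpl <- fix_template48()
  rois <- region_rois(tpl$atlas, side_mm = 2)
  expect_true(all(c("region", "laterality") %in% names(rois)))
  expect_true(all(rois$side_vox_i == 2L))

  # lesions planted only inside the tract: tract PD exceeds all others
  labels <- attr(tpl$atlas, "labels")
  tract <- as.integer(tpl$atlas) %in%
    labels[c("tract_left", "tract_right")]
  masks <- replicate(4, lesion_mask(array(as.integer(tract), dim(tpl$atlas)),
                                    like = tpl$t1, class = "infarct"),
                     simplify = FALSE)
  empty <- lesion_mask(array(0L, dim(tpl$atlas)), like = tpl$t1,
                       class = "wmh")
  pdmaps <- list(infarct = pd_map(masks, "all"),
                 wmh = pd_map(list(empty), "all"))
  tab <- region_table(pdmaps, rois)
  tract_rows <- tab$region == "tract"
  expect_gt(min(tab$infarct[tract_rows]), max(tab$infarct[!tract_rows]))
  # single-class columns populate; the all-empty class is all zero
  expect_true(all(tab$wmh == 0))
  expect_error(region_table(pdmaps, rois, classes = c("infarct", "lacune")),
               "lacune")

  rounded <- round_pd(tab)
  expect_true(all(abs(rounded$infarct * 1000 -
                        round(rounded$infarct * 1000)) < 1e-9))
})

test_that("subtraction maps report signed differences and overlap", {
  a <- pd_map(list(mask_with(list(c(4, 4, 4), c(5, 5, 5)))), "all")
  same <- subtract_maps(a, a)
  expect_identical(max(abs(as.numeric(same$difference))), 0)
  expect_identical(same$overlap_fraction, 1)

  b <- pd_map(list(mask_with(list(c(10, 10, 10)))), "all")
  dis <- subtract_maps(a, b)
  expect_identical(dis$overlap_fraction, 0)

  # a's support inside b's with equal values on the overlap
  bb <- pd_map(list(mask_with(list(c(4, 4, 4), c(5, 5, 5), c(6, 6, 6)))),
               "all")
  sub <- subtract_maps(a, bb)
  expect_identical(min(as.numeric(sub$difference)), -1)
  expect_identical(max(as.numeric(sub$difference)), 0)
  expect_equal(sub$overlap_fraction, 2 / 3)
})

test_that("PD maps round-trip with their JSON sidecar", {
  pd <- pd_map(list(mask_with(list(c(3, 3, 3))),
                    mask_with(list(c(3, 3, 3), c(4, 4, 4)))), "all")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_pd_map(pd, f)
  back <- read_pd_map(f)
  expect_identical(attr(back, "denominator"), 2L)
  expect_lt(max(abs(as.numeric(back) - as.numeric(pd))), 1e-7)
})
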