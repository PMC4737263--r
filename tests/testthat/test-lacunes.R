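# phantom with a uniform white-matter brain sphere, CSF-intensity cavities,
# and an ellipsoidal "ventricle"
lacune_phantom <- function(cavities, vent_center = c(0, 10, 8),
                           vent_radii = c(3, 6, 3), brain_r = 24,
                           white = 100, csf = 40) {
  dm <- c(64L, 64L, 64L)
  base <- volume_image(array(0, dm))
  W <- svdmap:::apply_affine(vox2world(base), svdmap:::grid_voxels(dm))
  brain <- rowSums(W^2) <= brain_r^2
  flair <- numeric(nrow(W))
  flair[brain] <- white
  vent <- svdmap:::in_ellipsoid(W, list(center = vent_center,
                                        radii = vent_radii)) & brain
  flair[vent] <- csf
  for (cv in cavities) {
    sph <- rowSums(sweep(W, 2, cv$center)^2) <= (cv$d / 2)^2
    flair[sph & brain] <- csf
  }
  list(flair = volume_like(base, array(flair, dm)),
       brain = lesion_mask(array(as.integer(brain), dm), like = base,
                           class = "wmh"),
       vent = lesion_mask(array(as.integer(vent), dm), like = base,
                          class = "lacune"))
}

std_cavities <- list(list(center = c(-14, 0, 0), d = 2),
                     list(center = c(14, 0, 0), d = 4),
                     list(center = c(0, -14, 0), d = 8),
                     list(center = c(0, 0, -12), d = 20),
                     list(center = c(0, 10, 12), d = 6))  # merges w/ ventricle

test_that("size and ventricle filters keep exactly the true lacunes", {
  ph <- lacune_phantom(std_cavities)
  res <- detect_lacunes(ph$flair, ph$brain, ph$vent,
                        tissue_means = c(csf = 40, grey = 120))
  expect_identical(nrow(res$components), 2L)
  # sorted by volume descending: the 8 mm cavity first
  expect_equal(res$components$equivalent_diameter_mm, c(8, 4),
               tolerance = 0.15)
  expect_identical(sum(res$mask), sum(res$components$n_voxels))
})

test_that("a 2 mm cavity alone yields no detection", {
  ph <- lacune_phantom(list(list(center = c(14, 0, 0), d = 2)))
  res <- detect_lacunes(ph$flair, ph$brain, ph$vent,
                        tissue_means = c(csf = 40, grey = 120))
  expect_identical(nrow(res$components), 0L)
  expect_identical(sum(res$mask), 0L)
})

test_that("a cavity merged with the ventricle is excluded", {
  ph <- lacune_phantom(list(list(center = c(0, 10, 12), d = 6)))
  res <- detect_lacunes(ph$flair, ph$brain, ph$vent,
                        tissue_means = c(csf = 40, grey = 120))
  expect_identical(nrow(res$components), 0L)
})

test_that("components touching the brain-mask boundary are excluded", {
  ph <- lacune_phantom(list(list(center = c(0, 23, 0), d = 6)))
  res <- detect_lacunes(ph$flair, ph$brain, ph$vent,
                        tissue_means = c(csf = 40, grey = 120))
  expect_identical(nrow(res$components), 0L)
})

test_that("raising min_diam_mm never increases the detection count", {
  ph <- lacune_phantom(std_cavities)
  counts <- vapply(seq(1, 12, by = 1), function(d)
    nrow(detect_lacunes(ph$flair, ph$brain, ph$vent, min_diam_mm = d,
                        tissue_means = c(csf = 40, grey = 120))$components),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("equivalent diameter is exact in the voxel count", {
  ph <- lacune_phantom(list(list(center = c(14, 0, 0), d = 5)))
  res <- detect_lacunes(ph$flair, ph$brain, ph$vent,
                        tissue_means = c(csf = 40, grey = 120))
  voxvol <- prod(voxel_size(ph$flair))
  expect_identical(res$components$equivalent_diameter_mm,
                   (6 * res$components$n_voxels * voxvol / pi)^(1 / 3))
  expect_true(all(res$components$sphericity > 0 &
                    res$components$sphericity <= 1))
})

test_that("an empty brain mask is an input error; Otsu fallback works", {
  ph <- lacune_phantom(std_cavities)
  empty <- lesion_mask(array(0L, dim(ph$flair)), like = ph$flair,
                       class = "wmh")
  expect_error(detect_lacunes(ph$flair, empty), "input error")
  res <- detect_lacunes(ph$flair, ph$brain, ph$vent)  # Otsu threshold
  expect_identical(nrow(res$components), 2L)
})
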