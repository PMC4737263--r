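test_that("Mahalanobis distance matches hand-evaluated cases", {
  expect_identical(mahalanobis_distance(c(1, 2, 3, 4), c(1, 2, 3, 4),
                                        diag(4)), 0)
  expect_equal(mahalanobis_distance(c(3, 4, 0, 0), c(0, 0, 0, 0), diag(4)),
               5)
  expect_equal(mahalanobis_distance(c(2, 0, 0, 0), c(0, 0, 0, 0),
                                    diag(c(4, 1, 1, 1))), 1)
  expect_error(mahalanobis_distance(c(1, 0), c(0, 0),
                                    matrix(c(1, 1, 1, 1), 2)), "singular")
  # agreement with stats::mahalanobis on random SPD cases
  set.seed(8)
  for (i in 1:20) {
    A <- matrix(rnorm(16), 4)
    S <- crossprod(A) + diag(4) * 0.1
    x <- rnorm(4); ctr <- rnorm(4)
    expect_equal(mahalanobis_distance(x, ctr, S),
                 sqrt(stats::mahalanobis(x, ctr, S)), tolerance = 1e-10)
  }
})

test_that("Mahalanobis distance is invariant under common feature rescaling", {
  set.seed(13)
  X <- matrix(rexp(40, 0.1), 10, 4)
  ctr <- apply(X, 2, median)
  S <- cov(X)
  a <- 3.7; b <- c(100, -5, 2, 0)
  X2 <- sweep(X * a, 2, b, `+`)
  S2 <- cov(X2)
  for (i in 1:10) {
    d1 <- mahalanobis_distance(X[i, ], ctr, S, ridge = 0)
    d2 <- mahalanobis_distance(X2[i, ], apply(X2, 2, median), S2, ridge = 0)
    expect_equal(d1, d2, tolerance = 1e-6)
  }
})

test_that("representative selection matches brute force on small cohorts", {
  expect_error(select_representative(matrix(1, 2, 4)), ">= 3")
  set.seed(77)
  for (trial in 1:100) {
    n <- sample(3:8, 1)
    X <- cbind(rnorm(n, 1400, 120), rnorm(n, 1150, 100),
               rnorm(n, 30, 10), rexp(n, 1 / 15))
    expect_identical(as.integer(select_representative(X)),
                     as.integer(brute_representative(X)))
  }
})

test_that("representative selection handles medians, ties and duplication", {
  # a subject exactly at the component-wise median wins
  X <- rbind(c(10, 10, 10, 10), c(30, 30, 30, 30), c(20, 20, 20, 20),
             c(5, 28, 22, 14))
  med <- apply(X, 2, median)
  X2 <- rbind(X, med)
  expect_identical(as.integer(select_representative(X2)), nrow(X2))

  # duplicating every subject selects the same feature vector
  set.seed(5)
  Y <- matrix(rexp(28, 0.05), 7, 4)
  i1 <- select_representative(Y)
  i2 <- select_representative(rbind(Y, Y))
  expect_equal(Y[i1, ], rbind(Y, Y)[i2, ])
})

test_that("self-registration returns the identity transform", {
  tpl <- fix_template48()
  A <- register_affine(tpl$flair, tpl$flair, dof = 6)
  expect_lt(max(abs(unclass(A)[1:3, 4])), 0.01)       # mm
  rot <- unclass(A)[1:3, 1:3]
  expect_lt(max(abs(rot - diag(3))), 2e-4)            # ~0.01 degrees
})

test_that("a known translation is recovered to sub-voxel accuracy", {
  tpl <- fix_template48()
  A_true <- affine_transform(translation = c(4, -3, 2))
  moving <- resample_volume(tpl$flair, invert_affine(A_true), tpl$flair)
  A <- register_affine(moving, tpl$flair, dof = 6)
  expect_lt(max(abs(unclass(A)[1:3, 4] - c(4, -3, 2))), 0.5)
})

test_that("synthetic misalignments are recovered below one voxel", {
  tpl <- fix_template48()
  lsp <- lesion_spec(lacune_diameter_range_mm = c(3, 6))
  errs <- vapply(c(1, 2, 3), function(sd) {
    s <- make_subject(tpl, lsp, seed = sd)
    A <- register_affine(s$flair, tpl$flair, dof = 12)
    W <- tpl$world[as.vector(unclass(tpl$brain_mask)) > 0, ]
    dif <- (cbind(W, 1) %*% t(unclass(A) - unclass(s$true_affine)))[, 1:3]
    median(sqrt(rowSums(dif^2)))
  }, numeric(1))
  expect_lt(median(errs), 1)
})

test_that("mask resampling preserves binarity, identity and integer shifts", {
  tpl <- fix_template48()
  set.seed(2)
  arr <- array(0L, dim(tpl$t1))
  arr[20:26, 18:24, 21:25] <- rbinom(7 * 7 * 5, 1, 0.5)
  m <- lesion_mask(arr, like = tpl$t1, class = "wmh")

  ident <- resample_mask(m, affine_transform(), tpl$t1)
  expect_identical(as.integer(ident), as.integer(m))

  shift <- affine_transform(translation = c(1, 0, 0))
  sh <- resample_mask(m, shift, tpl$t1)
  expect_identical(sum(sh), sum(m))
  back <- resample_mask(sh, invert_affine(shift), tpl$t1)
  expect_identical(as.integer(back), as.integer(m))

  empty <- lesion_mask(array(0L, dim(tpl$t1)), like = tpl$t1, class = "wmh")
  out <- resample_mask(empty, affine_transform(rotation = c(3, 2, 1)),
                       tpl$t1)
  expect_identical(sum(out), 0L)

  degenerate <- svdmap:::new_affine(diag(c(0, 1, 1, 1)))
  expect_error(resample_mask(m, degenerate, tpl$t1), "degenerate")
})
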