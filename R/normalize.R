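#' Mahalanobis distance between feature vectors
#'
#' Covariance-scaled distance `sqrt((x - center)' S^-1 (x - center))`, used
#' to pick the subject whose intracranial, brain, ventricular and WMH
#' volumes sit closest to the cohort median.
#'
#' @param x,center numeric feature vectors of equal length.
#' @param covariance symmetric positive-definite covariance matrix (after
#'   adding `ridge` to the diagonal).
#' @param ridge non-negative value added to the diagonal before inversion.
#' @return non-negative scalar; 0 iff `x == center`.
#' @examples
#' mahalanobis_distance(c(3, 4, 0, 0), c(0, 0, 0, 0), diag(4))  # 5
#' @export
mahalanobis_distance <- function(x, center, covariance, ridge = 0) {
  d <- as.numeric(x) - as.numeric(center)
  S <- unname(as.matrix(covariance)) + diag(ridge, length(d))
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch))
    stop("numerical error: covariance is singular (after regularization)",
         call. = FALSE)
  sqrt(sum(backsolve(ch, d, transpose = TRUE)^2))
}

#' Select the population-representative subject
#'
#' The representative ("average") subject is the one whose four volumetric
#' features are jointly closest to the component-wise cohort median in
#' Mahalanobis distance, with the cohort sample covariance (ridge-stabilized
#' by `1e-8 * trace / p` on the diagonal). Ties break to the lowest index.
#'
#' @param features a data frame (or matrix) of one row per subject; all
#'   numeric columns are used as features (a `subject_id` column, if present,
#'   is ignored).
#' @return the selected subject's row index, with the per-subject distances
#'   attached as attribute `"distances"`.
#' @export
select_representative <- function(features) {
  if (is.data.frame(features)) {
    num <- vapply(features, is.numeric, logical(1))
    X <- as.matrix(features[, num, drop = FALSE])
  } else X <- as.matrix(features)
  if (nrow(X) < 3)
    stop("input error: representative selection needs >= 3 subjects",
         call. = FALSE)
  ctr <- apply(X, 2, median)
  S <- cov(X)
  ridge <- 1e-8 * sum(diag(S)) / ncol(X)
  d <- vapply(seq_len(nrow(X)), function(i)
    mahalanobis_distance(X[i, ], ctr, S, ridge = ridge), numeric(1))
  structure(which.min(d), distances = d)
}

# block-mean downsampling by integer factor f (crops to a multiple of f)
downsample_volume <- function(vol, f) {
  if (f == 1) return(vol)
  dm <- dim(vol)
  nd <- dm %/% f
  a <- unclass(vol)[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f)]
  dim(a) <- c(f, nd[1], f, nd[2], f, nd[3])
  a <- apply(a, c(2, 4, 6), mean)
  S <- diag(c(f, f, f, 1))
  S[1:3, 4] <- (f - 1) / 2
  volume_image(a, voxel_size = voxel_size(vol) * f,
               affine = vox2world(vol) %*% S)
}

# intensity centre of mass in world mm
com_world <- function(vol) {
  v <- pmax(as.numeric(vol), 0)
  ijk <- grid_voxels(dim(vol))
  w <- sum(v)
  as.numeric(apply_affine(vox2world(vol),
                          matrix(colSums(ijk * v) / w, 1)))
}

reg_params_to_affine <- function(theta, dof) {
  if (dof == 6)
    affine_transform(rotation = theta[1:3], translation = theta[4:6])
  else
    affine_transform(rotation = theta[1:3], translation = theta[4:6],
                     scale = exp(theta[7:9]), shear = theta[10:12])
}

#' Intensity-based affine registration
#'
#' Estimates the world-to-world transform mapping `moving` into `fixed` by
#' minimizing the mean squared intensity difference over a coarse-to-fine
#' pyramid (block-mean downsampling by 4, 2, 1). Optimization is a
#' deterministic quasi-Newton search (BFGS) per level, started from the
#' identity, over rotations and translations (`dof = 6`) plus log-scales and
#' shears (`dof = 12`); no stochastic voxel sampling is used, so repeated
#' runs are identical.
#'
#' @param moving,fixed `svd_volume`s with overlapping fields of view.
#' @param dof 6 (rigid) or 12 (full affine).
#' @param levels pyramid downsampling factors, coarse to fine.
#' @param max_iter BFGS iteration cap per level (recycled).
#' @return a `svd_affine` mapping moving world to fixed world, with
#'   attributes `cost` (final MSE), `initial_cost` (identity MSE at the
#'   finest level) and `converged`. When the full schedule fails to reduce
#'   the cost below the identity cost a registration-quality warning is
#'   raised and the transform is still returned.
#' @export
register_affine <- function(moving, fixed, dof = 12, levels = c(4, 2, 1),
                            max_iter = c(80, 60, 40),
                            search_rot_deg = seq(-6, 6, by = 3)) {
  stopifnot(dof %in% c(6, 12))
  npar <- if (dof == 6) 6L else 12L
  parscale_all <- c(rep(1, 3), rep(1, 3), rep(0.02, 9))
  max_iter <- rep_len(max_iter, length(levels))
  init_cost_fine <- NA_real_
  final_cost <- NA_real_
  theta <- NULL
  for (li in seq_along(levels)) {
    f <- levels[li]
    mv <- downsample_volume(moving, f)
    fx <- downsample_volume(fixed, f)
    v2w_f <- vox2world(fx)
    w2v_m <- world2vox(mv)
    # rigid-only at the coarsest level, then the requested dof
    np <- if (li == 1) 6L else npar
    cost <- function(th) {
      # reject parameter values far outside the plausible capture range so
      # the line search cannot wander into degenerate transforms
      if (!all(is.finite(th)) || any(abs(th[1:3]) > 45) ||
          any(abs(th[4:6]) > 60) ||
          (length(th) > 6 && (any(abs(th[7:9]) > 0.7) ||
                              any(abs(th[10:12]) > 1))))
        return(1e12)
      A <- unclass(reg_params_to_affine(th, if (length(th) == 6) 6 else 12))
      Ainv <- tryCatch(solve(A), error = function(e) NULL)
      if (is.null(Ainv)) return(1e12)
      M <- w2v_m %*% Ainv %*% v2w_f
      val <- c_affine_mse(as.numeric(fx), dim(fx), as.numeric(mv), dim(mv),
                          M, 1L, 0)
      if (!is.finite(val)) 1e12 else val
    }
    if (li == 1) {
      # deterministic search stage: centre-of-mass translation plus an
      # exhaustive grid over initial rotations, to step over the rotational
      # local minima of a near-symmetric head
      t0 <- com_world(fx) - com_world(mv)
      grid <- as.matrix(expand.grid(rx = search_rot_deg, ry = search_rot_deg,
                                    rz = search_rot_deg))
      cands <- rbind(cbind(grid, matrix(rep(t0, nrow(grid)), ncol = 3,
                                        byrow = TRUE)),
                     matrix(0, 1, 6))
      cc <- apply(cands, 1, cost)
      # refine the three best starts briefly; keep the best refined result
      top <- order(cc)[1:3]
      refined <- lapply(top, function(i)
        stats::optim(cands[i, ], cost, method = "BFGS",
                     control = list(maxit = 15,
                                    parscale = parscale_all[1:6],
                                    reltol = 1e-10)))
      theta <- refined[[which.min(vapply(refined, `[[`, numeric(1),
                                         "value"))]]$par
    } else if (np > length(theta)) {
      theta <- c(theta, rep(0, np - length(theta)))
    }
    if (f == min(levels)) init_cost_fine <- cost(rep(0, np))
    opt <- stats::optim(theta, cost, method = "BFGS",
                        control = list(maxit = max_iter[li],
                                       parscale = parscale_all[seq_len(np)],
                                       reltol = 1e-10))
    theta <- opt$par
    final_cost <- opt$value
  }
  A <- reg_params_to_affine(theta, if (length(theta) == 6) 6 else 12)
  converged <- is.finite(final_cost) && final_cost <= init_cost_fine + 1e-12
  if (!converged)
    warning(sprintf(paste0("registration-quality warning: cost did not ",
                           "decrease (identity %.4g, final %.4g); ",
                           "returning the transform anyway"),
                    init_cost_fine, final_cost), call. = FALSE)
  attr(A, "cost") <- final_cost
  attr(A, "initial_cost") <- init_cost_fine
  attr(A, "converged") <- converged
  attr(A, "dof") <- as.integer(dof)
  A
}

#' Resample a binary mask through an affine transform
#'
#' Pull-back resampling onto the target grid with trilinear interpolation of
#' the 0/1 values, thresholded at 0.5 so the result stays binary. An empty
#' mask stays empty.
#'
#' @param mask a `svd_mask` (in moving space).
#' @param transform `svd_affine` mapping moving world to target (fixed)
#'   world.
#' @param target a `svd_volume`/`svd_mask` defining the output grid.
#' @return a `svd_mask` on the target grid with the same lesion class.
#' @export
resample_mask <- function(mask, transform, target) {
  A <- unclass(transform)
  if (abs(det(A)) < 1e-12)
    stop("numerical error: transform is degenerate (det ~ 0)", call. = FALSE)
  M <- world2vox(mask) %*% solve(A) %*% vox2world(target)
  vals <- c_affine_resample(as.numeric(mask), dim(mask), dim(target), M, 0)
  lesion_mask(array(as.integer(vals >= 0.5), dim(target)),
              voxel_size = voxel_size(target), affine = vox2world(target),
              class = lesion_class(mask) %||% "wmh")
}

#' @rdname resample_mask
#' @param vol a `svd_volume` to resample with trilinear interpolation
#'   (no thresholding).
#' @export
resample_volume <- function(vol, transform, target) {
  A <- unclass(transform)
  if (abs(det(A)) < 1e-12)
    stop("numerical error: transform is degenerate (det ~ 0)", call. = FALSE)
  M <- world2vox(vol) %*% solve(A) %*% vox2world(target)
  vals <- c_affine_resample(as.numeric(vol), dim(vol), dim(target), M, 0)
  volume_image(array(vals, dim(target)), voxel_size = voxel_size(target),
               affine = vox2world(target))
}
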