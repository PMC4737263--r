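#' Fuse two MRI sequences into RGB colour space
#'
#' Multispectral fusion for minimum-variance quantization: the first sequence
#' (FLAIR-like, on which WMH are hyperintense) is percentile-clipped and
#' rescaled to the red channel, the second (T1-like) to the green channel,
#' and blue is zero. Channels are rounded to whole 0-255 levels inside the
#' brain mask; voxels outside the mask are 0.
#'
#' @param seq_a,seq_b co-registered `svd_volume`s on one grid (FLAIR-like
#'   first).
#' @param brain_mask binary mask restricting the analysis.
#' @param clip lower/upper percentile clip applied before rescaling.
#' @return a `svd_colour` list: `red`, `green`, `blue` (integer arrays),
#'   `brain_mask`, `dim`.
#' @export
fuse_channels <- function(seq_a, seq_b, brain_mask, clip = c(0.01, 0.99)) {
  stop_grid_mismatch(seq_a, seq_b, "sequences")
  stop_grid_mismatch(seq_a, brain_mask, "sequence and brain mask")
  inside <- as.vector(brain_mask) > 0
  rescale <- function(x, which) {
    v <- as.vector(x)[inside]
    q <- stats::quantile(v, clip, names = FALSE, type = 7)
    if (q[2] - q[1] <= 0)
      stop(sprintf("rescale error: sequence `%s` is constant inside the brain mask",
                   which), call. = FALSE)
    out <- integer(length(as.vector(x)))
    out[inside] <- as.integer(round(pmin(pmax((v - q[1]) / (q[2] - q[1]), 0), 1) * 255))
    array(out, dim(x))
  }
  structure(list(red = rescale(seq_a, "seq_a"),
                 green = rescale(seq_b, "seq_b"),
                 blue = array(0L, dim(seq_a)),
                 brain_mask = array(as.integer(inside), dim(seq_a)),
                 voxel_size = voxel_size(seq_a),
                 affine = vox2world(seq_a)),
            class = "svd_colour")
}

#' @export
print.svd_colour <- function(x, ...) {
  n <- sum(x$brain_mask)
  cols <- unique(cbind(x$red[x$brain_mask > 0], x$green[x$brain_mask > 0]))
  cat(sprintf("<svd_colour> %s, %d brain voxels, %d distinct colours\n",
              paste(dim(x$red), collapse = "x"), n, nrow(cols)))
  invisible(x)
}

# weighted within-cluster sum of squares of colour rows X (m x 3), weights w
cluster_ss <- function(X, w) {
  W <- sum(w)
  if (W == 0) return(0)
  mu <- colSums(X * w) / W
  sum(w * rowSums(sweep(X, 2, mu)^2))
}

# best single-threshold split of a cluster: exhaustive threshold scan along
# each weighted-covariance eigenvector and each colour axis, keeping the
# direction/threshold pair with the lowest two-part sum of squares.
# Returns NULL if the cluster cannot be split.
best_split <- function(X, w) {
  m <- nrow(X)
  if (m < 2) return(NULL)
  W <- sum(w)
  mu <- colSums(X * w) / W
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc * sqrt(w))
  ev <- eigen(S, symmetric = TRUE)
  dirs <- cbind(ev$vectors, diag(3))
  best <- NULL
  cands <- list()
  for (d in seq_len(ncol(dirs))) {
    v <- dirs[, d]
    nz <- which(abs(v) > 1e-12)[1]
    if (is.na(nz)) next
    if (v[nz] < 0) v <- -v                    # deterministic sign
    proj <- as.numeric(X %*% v)
    ord <- order(proj, seq_len(m))
    Xo <- X[ord, , drop = FALSE]
    wo <- w[ord]
    cw <- cumsum(wo)
    cwx <- apply(Xo * wo, 2, cumsum)
    cwx2 <- cumsum(wo * rowSums(Xo^2))
    tw <- cw[m]; twx <- cwx[m, ]; twx2 <- cwx2[m]
    i <- seq_len(m - 1)
    ss_l <- cwx2[i] - rowSums(cwx[i, , drop = FALSE]^2) / cw[i]
    wr <- tw - cw[i]
    sxr <- sweep(-cwx[i, , drop = FALSE], 2, twx, `+`)
    ss_r <- (twx2 - cwx2[i]) - rowSums(sxr^2) / wr
    tot <- ss_l + ss_r
    cut <- which.min(tot)
    parent_ss <- twx2 - sum(twx^2) / tw
    cand <- list(gain = parent_ss - tot[cut],
                 left = ord[seq_len(cut)], right = ord[(cut + 1):m])
    cands[[d]] <- cand
    if (is.null(best) || cand$gain > best$gain + 1e-12) best <- cand
  }
  if (!is.null(best)) attr(best, "candidates") <- cands
  best
}

# deterministic best-improvement single-point moves (Hartigan-Wong style):
# move one unique colour to another cluster when that strictly lowers the
# objective; repeat with the best available move until none improves
swap_refine <- function(X, w, assign, K, max_moves = 200) {
  m <- nrow(X)
  for (move in seq_len(max_moves)) {
    Wk <- vapply(seq_len(K), function(k) sum(w[assign == k]), numeric(1))
    centroids <- matrix(0, K, 3)
    for (k in seq_len(K))
      if (Wk[k] > 0)
        centroids[k, ] <- colSums(X[assign == k, , drop = FALSE] *
                                    w[assign == k]) / Wk[k]
    d2 <- outer(rowSums(X^2), rep(1, K)) - 2 * X %*% t(centroids) +
      outer(rep(1, m), rowSums(centroids^2))
    a <- assign
    Wa <- Wk[a]
    # objective change of moving point i to cluster k: insertion cost minus
    # removal gain; moves that would empty a cluster are disallowed
    movable <- Wa - w > 1e-12
    rem <- w * Wa / pmax(Wa - w, 1e-300) * d2[cbind(seq_len(m), a)]
    delta <- matrix(Inf, m, K)
    for (k in seq_len(K)) {
      gain <- w * Wk[k] / (Wk[k] + w) * d2[, k] - rem
      gain[a == k | !movable] <- Inf
      delta[, k] <- gain
    }
    best <- which.min(delta)
    if (!is.finite(delta[best]) || delta[best] >= -1e-12) break
    i <- (best - 1) %% m + 1
    k <- (best - 1) %/% m + 1
    assign[i] <- k
  }
  assign
}

# Lloyd refinement on weighted unique colours from an initial assignment
lloyd_refine <- function(X, w, assign, K, tol = 1e-9, max_iter = 100) {
  obj_prev <- Inf
  for (iter in seq_len(max_iter)) {
    centroids <- matrix(0, K, 3)
    for (k in seq_len(K)) {
      idx <- assign == k
      if (!any(idx)) next
      centroids[k, ] <- colSums(X[idx, , drop = FALSE] * w[idx]) / sum(w[idx])
    }
    d2 <- outer(rowSums(X^2), rep(1, K)) - 2 * X %*% t(centroids) +
      outer(rep(1, nrow(X)), rowSums(centroids^2))
    assign_new <- max.col(-d2, ties.method = "first")
    # re-seed any emptied cluster at the worst-fitted colour
    for (k in seq_len(K)) {
      if (!any(assign_new == k)) {
        worst <- which.max(d2[cbind(seq_len(nrow(X)), assign_new)] * w)
        assign_new[worst] <- k
        centroids[k, ] <- X[worst, ]
      }
    }
    obj <- sum(w * d2[cbind(seq_len(nrow(X)), assign_new)])
    assign <- assign_new
    if (obj_prev - obj < tol) break
    obj_prev <- obj
  }
  # final exact centroids and objective for the final assignment
  for (k in seq_len(K)) {
    idx <- assign == k
    if (any(idx))
      centroids[k, ] <- colSums(X[idx, , drop = FALSE] * w[idx]) / sum(w[idx])
  }
  obj <- sum(w * rowSums((X - centroids[assign, , drop = FALSE])^2))
  list(assign = assign, centroids = centroids, objective = obj)
}

#' Minimum-variance colour quantization
#'
#' Partitions the brain-voxel colours into `K` clusters minimizing the total
#' within-cluster squared distance, by a deterministic divisive scheme: unique
#' colours are weighted by voxel count; starting from one cluster, the
#' algorithm repeatedly performs the single best threshold split along a
#' cluster's weighted principal colour axis (choosing the cluster whose split
#' decreases the objective most) and refines with Lloyd
#' assignment/centroid-update iterations until the objective change falls
#' below `tol`. No random initialization is used, so results are exactly
#' reproducible.
#'
#' @param colours a `svd_colour` from [fuse_channels()].
#' @param K number of clusters (>= 1); reduced with a warning when fewer
#'   distinct colours exist.
#' @param tol convergence tolerance on the objective.
#' @return list with `model` (a `svd_quantization`: `K`, `centroids`,
#'   `objective`) and `labels` (integer array, 1..K inside the brain mask,
#'   0 outside).
#' @export
minimum_variance_quantize <- function(colours, K = 5, tol = 1e-9) {
  stopifnot(inherits(colours, "svd_colour"), K >= 1)
  inside <- which(colours$brain_mask > 0)
  pix <- cbind(colours$red[inside], colours$green[inside],
               colours$blue[inside])
  key <- pix[, 1] * 65536 + pix[, 2] * 256 + pix[, 3]
  tab <- sort(unique(key))
  X <- cbind(tab %/% 65536, (tab %/% 256) %% 256, tab %% 256)
  storage.mode(X) <- "double"
  w <- as.numeric(tabulate(match(key, tab), nbins = length(tab)))
  m <- nrow(X)
  if (m < K) {
    warning(sprintf("only %d distinct colours; reducing K from %d to %d",
                    m, K, m), call. = FALSE)
    K <- m
  }
  assign <- rep(1L, m)
  k_now <- 1L
  # tentative candidates get a Lloyd polish, plus the single-point swap
  # search when the colour table is small enough for it to be cheap; on
  # large tables the swap phase is reserved for accepted configurations
  refine <- function(trial, k) {
    r <- lloyd_refine(X, w, trial, k, tol, max_iter = 15)
    if (m > 512) return(r)
    a <- swap_refine(X, w, r$assign, k)
    lloyd_refine(X, w, a, k, tol, max_iter = 15)
  }
  polish <- function(assign, k) {
    r <- lloyd_refine(X, w, assign, k, tol)
    a <- swap_refine(X, w, r$assign, k)
    lloyd_refine(X, w, a, k, tol)
  }
  while (k_now < K) {
    # tentatively split each cluster along each candidate direction, refine,
    # and keep the configuration with the lowest objective
    cands <- list()
    for (k in seq_len(k_now)) {
      idx <- which(assign == k)
      sp <- best_split(X[idx, , drop = FALSE], w[idx])
      if (is.null(sp)) next
      for (cand in attr(sp, "candidates")) {
        if (cand$gain <= 0) next
        trial <- assign
        trial[idx[cand$right]] <- k_now + 1L
        cands[[length(cands) + 1L]] <- refine(trial, k_now + 1L)
      }
    }
    if (length(cands) == 0) break
    objs <- vapply(cands, `[[`, numeric(1), "objective")
    assign <- polish(cands[[which.min(objs)]]$assign, k_now + 1L)$assign
    k_now <- k_now + 1L
  }
  res <- polish(assign, k_now)
  # merge-and-resplit rounds: escape partition-level local minima that
  # single-point moves cannot fix
  if (k_now >= 2) {
    for (round in 1:5) {
      improved <- FALSE
      for (a in seq_len(k_now - 1)) {
        for (b in (a + 1):k_now) {
          trial <- res$assign
          trial[trial == b] <- a
          trial[trial == k_now] <- b    # keep labels 1..k_now-1 contiguous
          cand_objs <- rep(Inf, k_now - 1)
          cand_assigns <- vector("list", k_now - 1)
          for (s in seq_len(k_now - 1)) {
            idx <- which(trial == s)
            sp <- best_split(X[idx, , drop = FALSE], w[idx])
            if (is.null(sp) || sp$gain <= 0) next
            t2 <- trial
            t2[idx[sp$right]] <- k_now
            r2 <- refine(t2, k_now)
            cand_objs[s] <- r2$objective
            cand_assigns[[s]] <- r2$assign
          }
          s <- which.min(cand_objs)
          if (cand_objs[s] < res$objective - 1e-9) {
            res <- polish(cand_assigns[[s]], k_now)
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
  }
  labels <- integer(length(colours$red))
  labels[inside] <- res$assign[match(key, tab)]
  model <- structure(list(K = k_now, centroids = res$centroids,
                          objective = res$objective),
                     class = "svd_quantization")
  list(model = model, labels = array(labels, dim(colours$red)))
}

#' @export
print.svd_quantization <- function(x, ...) {
  cat(sprintf("<svd_quantization> K=%d, objective=%.4g\n", x$K, x$objective))
  print(round(x$centroids, 1))
  invisible(x)
}

#' Extract the WMH class from a quantization
#'
#' Selects the cluster(s) whose centroid red value (the FLAIR-hyperintense
#' channel) is at or above a percentile of the centroid reds (default 100:
#' only the most hyperintense cluster). Voxels belonging to the supplied
#' acute-infarct mask are excluded so that the symptomatic lesion is not
#' counted as WMH.
#'
#' @param labels integer label array from [minimum_variance_quantize()].
#' @param model the corresponding `svd_quantization`.
#' @param colours the `svd_colour` the labels were computed on (grid
#'   geometry).
#' @param percentile centile of centroid red values a cluster must reach.
#' @param infarct_mask optional `svd_mask` of the acute infarct to exclude.
#' @param rule cluster-selection rule; only `"max_red"` is implemented.
#' @return a `svd_mask` of class tag `"wmh"`; empty (with a warning) when no
#'   cluster passes the rule.
#' @export
extract_lesion_class <- function(labels, model, colours, rule = "max_red",
                                 percentile = 100, infarct_mask = NULL) {
  rule <- match.arg(rule, "max_red")
  reds <- model$centroids[, 1]
  thr <- stats::quantile(reds, percentile / 100, names = FALSE, type = 7)
  sel <- which(reds >= thr - 1e-12)
  out <- array(as.integer(labels %in% sel), dim(labels))
  if (!any(out == 1L))
    warning("no cluster passes the max_red rule; returning an empty WMH mask",
            call. = FALSE)
  if (!is.null(infarct_mask)) out[as.vector(infarct_mask) > 0] <- 0L
  lesion_mask(out, voxel_size = colours$voxel_size, affine = colours$affine,
              class = "wmh")
}
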