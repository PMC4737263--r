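# Independent brute-force oracles. These deliberately use different code
# paths (plain loops, recursion, base stats functions) from the package
# implementations they check.

# exhaustive minimum total within-cluster SS over all partitions of the
# weighted colour rows X into at most K clusters (canonical-assignment DFS
# with incremental sums)
brute_min_variance <- function(X, w, K) {
  n <- nrow(X)
  Wk <- numeric(K); Sk <- matrix(0, K, 3); Qk <- numeric(K)
  best <- Inf
  rec <- function(i, kmax) {
    if (i > n) {
      used <- which(Wk > 0)
      obj <- sum(Qk[used] - rowSums(Sk[used, , drop = FALSE]^2) / Wk[used])
      if (obj < best) best <<- obj
      return(invisible())
    }
    for (k in seq_len(min(kmax + 1L, K))) {
      Wk[k] <<- Wk[k] + w[i]
      Sk[k, ] <<- Sk[k, ] + w[i] * X[i, ]
      Qk[k] <<- Qk[k] + w[i] * sum(X[i, ]^2)
      rec(i + 1L, max(kmax, k))
      Wk[k] <<- Wk[k] - w[i]
      Sk[k, ] <<- Sk[k, ] - w[i] * X[i, ]
      Qk[k] <<- Qk[k] - w[i] * sum(X[i, ]^2)
    }
  }
  rec(1L, 0L)
  best
}

# brute-force tube rasterization: walk a voxel neighbourhood around every
# curve sample point and mark voxels whose centre lies within `radius`
brute_tube <- function(dm, aff, pts, radius) {
  out <- array(FALSE, dm)
  w2v <- solve(aff)
  vs <- sqrt(colSums(aff[1:3, 1:3]^2))
  for (p in seq_len(nrow(pts))) {
    v <- (w2v %*% c(pts[p, ], 1))[1:3]
    lo <- pmax(floor(v - radius / vs) , 0)
    hi <- pmin(ceiling(v + radius / vs), dm - 1)
    for (i in lo[1]:hi[1])
      for (j in lo[2]:hi[2])
        for (k in lo[3]:hi[3]) {
          wc <- aff %*% c(i, j, k, 1)
          if (sum((wc[1:3] - pts[p, ])^2) <= radius^2)
            out[i + 1, j + 1, k + 1] <- TRUE
        }
  }
  out
}

# representative-subject selection by explicit per-candidate evaluation with
# stats::mahalanobis
brute_representative <- function(X) {
  ctr <- apply(X, 2, median)
  S <- cov(X)
  S <- S + diag(1e-8 * sum(diag(S)) / ncol(X), ncol(X))
  d2 <- numeric(nrow(X))
  for (i in seq_len(nrow(X)))
    d2[i] <- stats::mahalanobis(X[i, ], ctr, S)
  which.min(d2)
}

# exact Friedman permutation p by exhaustively permuting every block and
# recomputing the statistic with stats::friedman.test
brute_friedman_exact_p <- function(X) {
  n <- nrow(X); k <- ncol(X)
  perms <- svdmap:::permutations_of(k)
  obs <- unname(stats::friedman.test(X)$statistic)
  idx <- do.call(expand.grid, rep(list(seq_len(nrow(perms))), n))
  stats_all <- apply(idx, 1, function(sel) {
    Y <- X
    for (b in seq_len(n)) Y[b, ] <- X[b, perms[sel[b], ]]
    unname(stats::friedman.test(Y)$statistic)
  })
  mean(stats_all >= obs - 1e-9)
}

# max pairwise in-plane (axial) diameter of a binary mask, mm
max_axial_diameter <- function(mask, vs) {
  dm <- dim(mask)
  best <- 0
  for (k in seq_len(dm[3])) {
    sl <- which(mask[, , k] > 0, arr.ind = TRUE)
    if (nrow(sl) < 2) next
    xy <- sweep(sl, 2, c(0, 0)) * rep(vs[1:2], each = nrow(sl))
    d <- as.matrix(stats::dist(xy))
    best <- max(best, max(d) + 0)
  }
  best
}
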