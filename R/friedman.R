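#' Midranks of a numeric vector
#'
#' Ranks with ties replaced by the average of the tied positions, the rank
#' transform used inside the Friedman statistic.
#' @param values non-empty numeric vector.
#' @return numeric vector of midranks.
#' @examples
#' midrank(c(5, 5, 9))  # 1.5 1.5 3
#' @export
midrank <- function(values) {
  if (length(values) == 0) stop("`values` must be non-empty", call. = FALSE)
  rank(values, ties.method = "average")
}

#' Friedman's two-way ANOVA by ranks
#'
#' Tests whether `k` related treatments differ across `n` blocks, on the
#' within-block midranks. The statistic uses the standard tie-correction:
#' `chi2 = (k-1) * sum_j (R_j - n(k+1)/2)^2 / (sum_ij r_ij^2 - n k (k+1)^2 / 4)`
#' with `R_j` the rank sum of treatment `j`; without ties it reduces to
#' `12/(n k (k+1)) sum_j R_j^2 - 3 n (k+1)`. The p-value is exact (full
#' enumeration of all `(k!)^n` within-block orderings) whenever that count
#' does not exceed `exact_limit`, otherwise from the chi-squared
#' distribution with `k - 1` degrees of freedom.
#'
#' @param table numeric matrix or data frame, `n` blocks (rows) x `k`
#'   treatments (columns) of raw values (e.g. regional PDs).
#' @param exact_limit enumeration cap for the exact permutation p-value.
#' @return a `svd_friedman` object: `statistic`, `df`, `p_value`, `method`
#'   (`"exact permutation"` or `"chi-squared approximation"`),
#'   `p_asymptotic`, `rank_sums`, `n`, `k`, `tie_corrected`.
#' @examples
#' m <- rbind(c(1, 2, 3), c(2, 4, 6), c(0.1, 0.2, 0.3))
#' friedman_test(m)  # chi2 = 6, the perfect-ordering value for n = k = 3
#' @export
friedman_test <- function(table, exact_limit = 2e6) {
  X <- as.matrix(table)
  storage.mode(X) <- "double"
  n <- nrow(X); k <- ncol(X)
  if (n < 2 || k < 2)
    stop("input error: need n >= 2 blocks and k >= 2 treatments",
         call. = FALSE)
  r <- t(apply(X, 1, midrank))
  Rj <- colSums(r)
  denom <- sum(r^2) - n * k * (k + 1)^2 / 4
  ties <- any(apply(r, 1, anyDuplicated) > 0)
  if (denom <= 0) {
    warning("degenerate data: every treatment tied in every block; ",
            "statistic is 0", call. = FALSE)
    stat <- 0
  } else {
    stat <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / denom
  }
  df <- as.integer(k - 1)
  p_asym <- pchisq(stat, df, lower.tail = FALSE)
  n_orderings <- factorial(k)^n
  if (n_orderings <= exact_limit && denom > 0) {
    p <- friedman_exact_p(r, stat)
    method <- "exact permutation"
  } else {
    p <- p_asym
    method <- "chi-squared approximation"
  }
  structure(list(statistic = stat, df = df, p_value = p,
                 p_asymptotic = p_asym, method = method,
                 rank_sums = Rj, n = n, k = k, tie_corrected = ties),
            class = "svd_friedman")
}

# exact permutation distribution: all (k!)^n assignments of each block's
# midranks to treatments, accumulated as a growing matrix of rank-sum
# vectors. The tie-correction denominator is permutation-invariant, so only
# the rank sums vary.
friedman_exact_p <- function(r, observed) {
  n <- nrow(r); k <- ncol(r)
  perms <- permutations_of(k)
  denom <- sum(r^2) - n * k * (k + 1)^2 / 4
  sums <- matrix(0, 1, k)
  for (i in seq_len(n)) {
    block <- matrix(r[i, ][perms], nrow = nrow(perms))
    idx_s <- rep(seq_len(nrow(sums)), each = nrow(block))
    idx_b <- rep(seq_len(nrow(block)), times = nrow(sums))
    sums <- sums[idx_s, , drop = FALSE] + block[idx_b, , drop = FALSE]
  }
  stats <- (k - 1) * rowSums((sums - n * (k + 1) / 2)^2) / denom
  mean(stats >= observed - 1e-9)
}

# all permutations of 1..k as a (k! x k) matrix, lexicographic
permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 1L
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' @export
print.svd_friedman <- function(x, ...) {
  cat(sprintf("Friedman rank test: chi2 = %.4f, df = %d, p = %.4g (%s)\n",
              x$statistic, x$df, x$p_value, x$method))
  cat("rank sums:", paste(signif(x$rank_sums, 4), collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.svd_friedman <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
         method = x$method, n_blocks = x$n, n_treatments = x$k,
         tie_corrected = x$tie_corrected)
}

#' @export
glance.svd_friedman <- function(x, ...) tidy(x)

#' Compare regional lesion distributions
#'
#' The headline comparison of the pipeline: for two (or more) lesion
#' classes, are the regional PD profiles drawn from the same distribution?
#' Blocks are regions; by default the left and right PD of each region are
#' averaged into one block (set `average_laterality = FALSE` to keep the two
#' sides as separate blocks).
#'
#' @param tab a `svd_region_table` from [region_table()].
#' @param treatments lesion-class columns to compare.
#' @param average_laterality average left/right per region before testing.
#' @param ... passed to [friedman_test()].
#' @return a `svd_friedman` with a `comparison` field naming the treatments.
#' @export
compare_lesion_distributions <- function(tab,
                                         treatments = c("infarct", "wmh"),
                                         average_laterality = TRUE, ...) {
  missing <- setdiff(treatments, names(tab))
  if (length(missing) > 0)
    stop("input error: region table lacks class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (average_laterality) {
    blocks <- dplyr::summarise(dplyr::group_by(tab, .data$region),
                               dplyr::across(dplyr::all_of(treatments), mean),
                               .groups = "drop")
    X <- as.matrix(blocks[, treatments])
    rownames(X) <- blocks$region
  } else {
    X <- as.matrix(tab[, treatments])
    rownames(X) <- paste(tab$region, tab$laterality, sep = "_")
  }
  out <- friedman_test(X, ...)
  out$comparison <- treatments
  out
}
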