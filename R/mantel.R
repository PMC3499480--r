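# Mantel matrix-permutation test of association between two distance
# matrices (here: patristic vs chemical-profile distances).

check_distance_pair <- function(A, B, min_n = 4) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (is.null(rownames(A)) || is.null(rownames(B))) {
    stop_chemophylo("distance matrices must carry labels")
  }
  if (!identical(rownames(A), rownames(B))) {
    stop_chemophylo("label mismatch between the two matrices")
  }
  if (nrow(A) < min_n) stop_chemophylo("need at least ", min_n, " taxa")
  for (m in list(A, B)) {
    if (max(abs(m - t(m))) > 1e-8 || any(abs(diag(m)) > 1e-8)) {
      stop_chemophylo("matrices must be symmetric with zero diagonal")
    }
  }
  list(A = A, B = B)
}

mantel_result <- function(r, p, n_permutations, n, seed, null_r,
                          exhaustive = FALSE) {
  structure(list(r = r, p = p, n_permutations = n_permutations, n = n,
                 seed = seed, null_r = null_r, exhaustive = exhaustive),
            class = "mantel_result")
}

#' Mantel test between two distance matrices
#'
#' The observed statistic is the Pearson correlation of the strictly upper
#' triangles. The null distribution is generated by applying a random
#' taxon-label permutation simultaneously to the rows and columns of `B`
#' and recomputing the correlation, 999 times by default. The one-tailed
#' p-value for positive association uses the add-one convention
#' `p = (count of null r >= observed r + 1) / (n_permutations + 1)`, so p
#' is never 0; `correct = FALSE` gives the plain fraction.
#'
#' @param A,B Labeled symmetric zero-diagonal matrices over the same taxa
#'   in the same order (e.g. [patristic_matrix()] vs
#'   [binary_squared_euclidean_matrix()]).
#' @param n_permutations Number of permutations (999 by default).
#' @param seed Integer seed.
#' @param alternative `"greater"` (one-tailed, positive association;
#'   default) or `"two.sided"`.
#' @param correct Add-one p-value correction (default `TRUE`).
#' @return An object of class `"mantel_result"` with fields `r`, `p`,
#'   `n_permutations`, `n`, `seed`, and the null correlations `null_r`.
#' @export
mantel_test <- function(A, B, n_permutations = 999, seed = NULL,
                        alternative = c("greater", "two.sided"),
                        correct = TRUE) {
  alternative <- match.arg(alternative)
  m <- check_distance_pair(A, B)
  n <- nrow(m$A)
  ut <- upper.tri(m$A)
  a <- m$A[ut]
  b <- m$B[ut]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_chemophylo("zero variance in a distance matrix; correlation undefined")
  }
  r_obs <- stats::cor(a, b)
  null_r <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      idx <- sample.int(n)
      stats::cor(a, m$B[idx, idx][ut])
    }, numeric(1))
  })
  extreme <- if (alternative == "greater") {
    sum(null_r >= r_obs)
  } else {
    sum(abs(null_r) >= abs(r_obs))
  }
  p <- if (correct) (extreme + 1) / (n_permutations + 1) else
    extreme / n_permutations
  mantel_result(r_obs, p, n_permutations, n, seed %||% NA_integer_, null_r)
}

# All permutations of 1..n as a matrix (n! rows). Internal oracle support.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (v in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      rest <- sub[i, ] + (sub[i, ] >= v)
      out[row, ] <- c(v, rest)
      row <- row + 1L
    }
  }
  out
}

#' Exact Mantel test by exhaustive permutation enumeration
#'
#' Enumerates all `n!` simultaneous row/column permutations of `B` (hence
#' limited to `n <= 7`) and reports the exact one-tailed probability of a
#' null correlation at least as large as the observed one. The identity
#' permutation is part of the enumeration, so `p >= 1/n!`. Serves as the
#' oracle for the sampled [mantel_test()].
#'
#' @inheritParams mantel_test
#' @return A `"mantel_result"` with `exhaustive = TRUE` and
#'   `n_permutations = n!`.
#' @export
exhaustive_mantel <- function(A, B) {
  m <- check_distance_pair(A, B, min_n = 3)
  n <- nrow(m$A)
  if (n > 7) stop_chemophylo("exhaustive enumeration limited to n <= 7")
  ut <- upper.tri(m$A)
  a <- m$A[ut]
  if (stats::sd(a) == 0 || stats::sd(m$B[ut]) == 0) {
    stop_chemophylo("zero variance in a distance matrix; correlation undefined")
  }
  r_obs <- stats::cor(a, m$B[ut])
  perms <- all_permutations(n)
  null_r <- vapply(seq_len(nrow(perms)), function(i) {
    idx <- perms[i, ]
    stats::cor(a, m$B[idx, idx][ut])
  }, numeric(1))
  p <- sum(null_r >= r_obs - 1e-12) / nrow(perms)
  mantel_result(r_obs, p, nrow(perms), n, NA_integer_, null_r,
                exhaustive = TRUE)
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.3f, p = %.4g (%s%d permutations, n = %d)\n",
              x$r, x$p, if (x$exhaustive) "exhaustive " else "",
              x$n_permutations, x$n))
  invisible(x)
}
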