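#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation of the strictly-lower-triangle entries of two
#' aligned distance matrices, with significance assessed by permuting the
#' site labels of the second matrix (the same permutation applied to rows
#' and columns, so the off-diagonal multiset is preserved). The p-value is
#' the one-sided upper tail with the add-one estimator,
#' (1 + #\{r_perm >= r_obs\}) / (1 + n_perm), so it is never zero.
#'
#' @param d1,d2 `dist_matrix` objects over the same sites.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return A `mantel_result` with `r`, `p`, `n_perm`, `seed`.
#' @examples
#' pts <- tibble::tibble(site_id = paste0("s", 1:10),
#'                       x = rnorm(10), y = rnorm(10))
#' d <- euclidean_matrix(pts)
#' mantel_test(d, d, n_perm = 99, seed = 1)
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1) {
  sites <- dist_sites(d1)
  if (!setequal(sites, dist_sites(d2))) {
    abort("The two distance matrices cover different site sets.",
          class = "betadrivers_alignment_error")
  }
  if (length(sites) < 4) {
    abort("Mantel test needs at least 4 sites.",
          class = "betadrivers_data_error")
  }
  n_perm <- stopifnot_scalar_int(n_perm, "n_perm")
  m2 <- unclass(d2)[sites, sites]
  v1 <- lower_vec(unclass(d1))
  v2 <- lower_vec(m2)
  if (sd(v1) == 0 || sd(v2) == 0) {
    abort("Zero variance in a distance triangle: correlation undefined.",
          class = "betadrivers_degenerate_error")
  }
  r_obs <- cor(v1, v2)
  n <- length(sites)
  lower <- lower.tri(m2)
  local_seed(seed)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    cor(v1, m2[p, p][lower])
  }, numeric(1))
  p_val <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  structure(list(r = r_obs, p = p_val, n_perm = n_perm,
                 seed = as.integer(seed), n = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations, n = %d)\n",
              x$r, x$p, x$n_perm, x$n))
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble(estimate = x$r, p.value = x$p, n.perm = x$n_perm, n = x$n)
}

#' @rdname tidy
#' @export
glance.mantel_result <- function(x, ...) tidy(x)

#' Pairwise Mantel correlations among named distance matrices
#'
#' Convenience batch mode: runs `mantel_test()` for every unordered pair
#' of a named list of distance matrices (predictor inter-correlation
#' tables).
#'
#' @param dists Named list of `dist_matrix` objects on one site set.
#' @param n_perm,seed Passed to `mantel_test()`.
#' @return A tibble with one row per pair: `matrix_a`, `matrix_b`,
#'   `estimate`, `p.value`.
#' @export
mantel_pairs <- function(dists, n_perm = 999, seed = 1) {
  stopifnot(length(dists) >= 2, !is.null(names(dists)))
  pairs <- utils::combn(names(dists), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]
    b <- pairs[2, i]
    res <- mantel_test(dists[[a]], dists[[b]], n_perm = n_perm,
                       seed = derive_seed(seed, i))
    tibble(matrix_a = a, matrix_b = b, estimate = res$r, p.value = res$p)
  })
}
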