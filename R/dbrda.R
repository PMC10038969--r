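#' Gower double-centering of a distance matrix
#'
#' Computes G = C A C with A = -1/2 D*D (element-wise square) and
#' C = I - (1/n) 11', the inner-product matrix underlying principal
#' coordinates analysis and distance-based RDA. Rows and columns of G sum
#' to zero.
#'
#' @param d A `dist_matrix`.
#' @return A symmetric, doubly centered numeric matrix.
#' @export
gower_center <- function(d) {
  m <- unclass(d)
  a <- -0.5 * m * m
  rm_ <- rowMeans(a)
  g <- a - outer(rm_, rep(1, ncol(a))) -
    outer(rep(1, nrow(a)), colMeans(a)) + mean(a)
  g <- (g + t(g)) / 2
  attr(g, "metric") <- NULL
  g
}

#' Principal-coordinate expansion of a distance matrix
#'
#' Eigen-decomposes the Gower-centered matrix and returns axes scaled by
#' the square root of their eigenvalues. Axes are retained while their
#' eigenvalue exceeds `rel_tol` times the largest one; negative-eigenvalue
#' dimensions are dropped. Use `max_axes` to cap the expansion when a
#' dissimilarity matrix enters a constrained model as a predictor and
#' residual degrees of freedom are scarce.
#'
#' @param d A `dist_matrix`.
#' @param rel_tol Relative eigenvalue cutoff (default 1e-8).
#' @param max_axes Keep at most this many leading axes (default all).
#' @return Predictor tibble `site_id`, `PCo1`, `PCo2`, ... with the
#'   eigenvalues in attribute `"eigenvalues"` (all retained axes).
#' @export
pcoa_axes <- function(d, rel_tol = 1e-8, max_axes = Inf) {
  g <- gower_center(d)
  eg <- eigen(g, symmetric = TRUE)
  keep <- eg$values > rel_tol * max(eg$values)
  if (!any(keep)) {
    abort("Distance matrix has no positive principal-coordinate axes.",
          class = "betadrivers_degenerate_error")
  }
  k <- min(sum(keep), max_axes)
  ax <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(k)]), k)
  colnames(ax) <- paste0("PCo", seq_len(k))
  out <- dplyr::bind_cols(tibble(site_id = dist_sites(d)), as_tibble(ax))
  attr(out, "eigenvalues") <- eg$values[seq_len(k)]
  out
}

# numeric rank by singular-value threshold, after centering
centered_rank <- function(xc, tol = 1e-10) {
  if (!ncol(xc)) return(0L)
  sv <- svd(xc, nu = 0, nv = 0)$d
  if (!length(sv) || max(sv) == 0) return(0L)
  sum(sv > tol * max(sv))
}

#' Ezekiel-adjusted R-squared
#'
#' 1 - (1 - r2) (n - 1) / (n - m - 1), the sample-size and
#' predictor-count correction that makes explained-variance fractions
#' comparable across predictor sets. May be negative. With m = 0 the
#' value is returned unchanged.
#'
#' @param r2 Unadjusted proportion of variance explained.
#' @param n Number of sites.
#' @param m Rank of the centered constraint matrix.
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, m) {
  if (n < m + 2) {
    abort(sprintf("Need n >= m + 2 (n = %d, m = %d).", n, m),
          class = "betadrivers_df_error")
  }
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

#' Distance-based redundancy analysis fit
#'
#' Regresses a Gower-centered dissimilarity matrix on a predictor block:
#' predictors are column-centered, the hat matrix H is built through a
#' rank-revealing pseudo-inverse, and R-squared is the trace ratio
#' tr(H G H) / tr(G) with negative-eigenvalue contributions retained in
#' the total (McArdle-Anderson convention). The Ezekiel adjustment uses
#' the numeric rank m of the centered predictors, so collinear variables
#' (such as land-cover proportions summing to one) do not inflate the
#' model degrees of freedom.
#'
#' @param d A `dist_matrix` response.
#' @param x Predictor tibble aligned to `d`'s sites.
#' @return A `dbrda_fit` object with elements `r2`, `adj_r2`, `n`, `m`,
#'   `trace_total`, `trace_fitted`.
#' @export
dbrda_fit <- function(d, x) {
  xm <- block_matrix(x, "x")
  sites <- dist_sites(d)
  if (!setequal(rownames(xm), sites)) {
    abort("Predictor sites do not match the distance matrix.",
          class = "betadrivers_alignment_error")
  }
  xm <- xm[sites, , drop = FALSE]
  n <- length(sites)
  g <- gower_center(d)
  xc <- scale(xm, center = TRUE, scale = FALSE)
  m <- centered_rank(xc)
  if (n - m - 1 <= 0) {
    abort(sprintf(
      "Insufficient residual degrees of freedom (n = %d, rank m = %d); cap predictor axes (e.g. `max_axes`).",
      n, m), class = "betadrivers_df_error")
  }
  trace_total <- sum(diag(g))
  if (m == 0) {
    fit <- list(r2 = 0, adj_r2 = 0, n = n, m = 0L,
                trace_total = trace_total, trace_fitted = 0)
    return(structure(fit, class = "dbrda_fit"))
  }
  sv <- svd(xc)
  u <- sv$u[, sv$d > 1e-10 * max(sv$d), drop = FALSE]
  # H = U U' idempotent, so tr(H G H) = tr(G H) = sum((G U) * U)
  trace_fitted <- sum((g %*% u) * u)
  r2 <- trace_fitted / trace_total
  structure(list(r2 = r2, adj_r2 = adjusted_r2(r2, n, m), n = n,
                 m = as.integer(m), trace_total = trace_total,
                 trace_fitted = trace_fitted),
            class = "dbrda_fit")
}

#' @export
print.dbrda_fit <- function(x, ...) {
  cat(sprintf(
    "dbRDA fit: n = %d sites, m = %d constraints\n  R2 = %.4f, adjusted R2 = %.4f\n",
    x$n, x$m, x$r2, x$adj_r2))
  invisible(x)
}

#' @export
glance.dbrda_fit <- function(x, ...) {
  tibble(r.squared = x$r2, adj.r.squared = x$adj_r2, n = x$n, m = x$m,
         trace.total = x$trace_total, trace.fitted = x$trace_fitted)
}
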