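#' Distance matrix objects
#'
#' Symmetric, zero-diagonal site-by-site dissimilarity matrices with a
#' metric tag. Stored as a base matrix with site ids as dimnames so linear
#' algebra stays direct; `as_tibble()` gives the long pairwise form.
#'
#' @param values Symmetric numeric matrix with site-id dimnames.
#' @param metric Metric tag, `"sorensen"` or `"euclidean"`.
#' @return A `dist_matrix`.
#' @export
new_dist_matrix <- function(values, metric) {
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    abort("`values` must be a square matrix.",
          class = "betadrivers_data_error")
  }
  if (is.null(rownames(values))) {
    abort("Distance matrices need site-id dimnames.",
          class = "betadrivers_data_error")
  }
  if (any(!is.finite(values))) {
    abort("Distance matrices must be finite.",
          class = "betadrivers_data_error")
  }
  if (max(abs(values - t(values))) > 1e-12) {
    abort("Distance matrix is not symmetric within 1e-12.",
          class = "betadrivers_data_error")
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  colnames(values) <- rownames(values)
  structure(values, metric = metric,
            class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix: %d sites, metric = %s>\n", nrow(x),
              attr(x, "metric")))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' @export
as_tibble.dist_matrix <- function(x, ...) {
  n <- nrow(x)
  idx <- which(lower.tri(x), arr.ind = TRUE)
  tibble(site_a = rownames(x)[idx[, 2]],
         site_b = rownames(x)[idx[, 1]],
         distance = x[idx],
         metric = attr(x, "metric"))
}

dist_sites <- function(d) rownames(d)

# strictly-lower-triangle vector, column-major
lower_vec <- function(d) d[lower.tri(d)]

#' Sorensen dissimilarity matrix from presence-absence data
#'
#' For two sites sharing `a` taxa with `b` and `c` taxa unique to each,
#' the Sorensen distance is (b + c) / (2a + b + c) — identical to
#' Bray-Curtis computed on 0/1 data. A pair of entirely empty sites gets
#' distance 0 by convention, with a warning.
#'
#' @param community Community tibble (at least two sites).
#' @return A `dist_matrix` tagged `"sorensen"`.
#' @examples
#' cm <- as_community(matrix(c(1, 1, 1, 1, 1, 0, 0, 1), 2, 4,
#'   dimnames = list(c("s1", "s2"), c("A", "B", "C", "D"))))
#' sorensen_matrix(cm)  # a = 2, b = c = 1 -> 2/6
#' @export
sorensen_matrix <- function(community) {
  validate_community(community)
  m <- cm_matrix(community)
  if (nrow(m) < 2) {
    abort("Need at least two sites for a dissimilarity matrix.",
          class = "betadrivers_data_error")
  }
  shared <- m %*% t(m)                       # a
  rich <- rowSums(m)
  tot <- outer(rich, rich, "+")              # 2a + b + c
  d <- 1 - 2 * shared / tot
  empty <- tot == 0
  if (any(empty)) d[empty] <- 0
  if (any(empty[lower.tri(empty)])) {
    warn("Empty site pair(s): Sorensen distance set to 0 by convention.",
         class = "betadrivers_empty_sites")
  }
  new_dist_matrix(d, "sorensen")
}

#' Euclidean distance matrix from a predictor block
#'
#' Plain pairwise Euclidean distances over the numeric variables of a
#' predictor block (a tibble with `site_id` followed by numeric columns).
#'
#' @param block Predictor tibble.
#' @return A `dist_matrix` tagged `"euclidean"`.
#' @export
euclidean_matrix <- function(block) {
  m <- block_matrix(block)
  if (nrow(m) < 2) {
    abort("Need at least two sites.", class = "betadrivers_data_error")
  }
  d <- as.matrix(dist(m))
  new_dist_matrix(d, "euclidean")
}

# numeric site-by-variable matrix from a predictor tibble
block_matrix <- function(block, arg = "block") {
  if (!is.data.frame(block) || names(block)[1] != "site_id") {
    abort(sprintf("`%s` must be a tibble whose first column is `site_id`.",
                  arg), class = "betadrivers_data_error")
  }
  if (anyDuplicated(block$site_id)) {
    abort(sprintf("`%s` has duplicated site_ids.", arg),
          class = "betadrivers_data_error")
  }
  m <- as.matrix(block[-1])
  storage.mode(m) <- "double"
  if (ncol(m) && any(!is.finite(m))) {
    abort(sprintf("`%s` contains non-finite values.", arg),
          class = "betadrivers_data_error")
  }
  rownames(m) <- block$site_id
  m
}

#' Standardize predictor variables by their maximum
#'
#' Divides every column by its maximum value, putting variables measured
#' on different scales onto a common 0-to-1-ish range before Euclidean
#' distances (applied to the climate block). Idempotent.
#'
#' @param block Predictor tibble.
#' @return The standardized predictor tibble.
#' @export
max_standardize <- function(block) {
  m <- block_matrix(block)
  mx <- apply(m, 2, max)
  if (any(mx == 0)) {
    abort(sprintf("Column(s) with zero maximum cannot be max-standardized: %s.",
                  paste(colnames(m)[mx == 0], collapse = ", ")),
          class = "betadrivers_data_error")
  }
  out <- sweep(m, 2, mx, "/")
  dplyr::bind_cols(tibble(site_id = block$site_id), as_tibble(out))
}
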