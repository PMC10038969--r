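`%||%` <- function(a, b) if (is.null(a)) b else a

# Fixture builders and independent oracles used across the suite.
# Oracles are written naively (loops, set counts, direct linear solves)
# so they stay independent of the implementation paths they check.

rand_community <- function(n_sites, n_taxa, p = 0.4, seed = 1,
                           prefix = "s") {
  set.seed(seed)
  m <- matrix(rbinom(n_sites * n_taxa, 1, p), n_sites, n_taxa,
              dimnames = list(sprintf("%s%02d", prefix, seq_len(n_sites)),
                              sprintf("tax%03d", seq_len(n_taxa))))
  as_community(m)
}

rand_block <- function(n_sites, n_vars, seed = 1, sites = NULL) {
  set.seed(seed)
  sites <- sites %||% sprintf("s%02d", seq_len(n_sites))
  m <- matrix(rnorm(n_sites * n_vars), n_sites, n_vars,
              dimnames = list(NULL, sprintf("v%02d", seq_len(n_vars))))
  dplyr::bind_cols(tibble::tibble(site_id = sites), tibble::as_tibble(m))
}

# Sorensen by explicit shared/unique set counts, double loop
naive_sorensen <- function(cm) {
  m <- as.matrix(cm[-1])
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      si <- which(m[i, ] == 1)
      sj <- which(m[j, ] == 1)
      a <- length(intersect(si, sj))
      b <- length(setdiff(si, sj))
      cc <- length(setdiff(sj, si))
      d[i, j] <- if (2 * a + b + cc == 0) 0 else (b + cc) / (2 * a + b + cc)
    }
  }
  dimnames(d) <- list(cm$site_id, cm$site_id)
  d
}

# quantitative Bray-Curtis formula applied to the 0/1 matrix
bray_binary <- function(cm) {
  m <- as.matrix(cm[-1])
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      tot <- sum(m[i, ] + m[j, ])
      d[i, j] <- if (tot == 0) 0 else sum(abs(m[i, ] - m[j, ])) / tot
    }
  }
  d
}

naive_euclidean <- function(block) {
  m <- as.matrix(block[-1])
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
    }
  }
  d
}

# classical redundancy analysis R2 of a raw data table on predictors
naive_rda_r2 <- function(y, x) {
  yc <- scale(as.matrix(y), center = TRUE, scale = FALSE)
  xc <- scale(as.matrix(x), center = TRUE, scale = FALSE)
  fit <- qr.fitted(qr(xc), yc)
  sum(fit^2) / sum(yc^2)
}

# exclusive fractions by direct solve of the inclusion-exclusion system:
# adjR2(union S) = sum of regions touching S
varpart_solve_oracle <- function(union_adj_r2, labels) {
  k <- length(labels)
  subsets <- unlist(lapply(seq_len(k), function(s) {
    lapply(seq_len(ncol(utils::combn(k, s))),
           function(j) utils::combn(k, s)[, j])
  }), recursive = FALSE)
  key <- function(ix) paste(sort(labels[ix]), collapse = "+")
  nr <- length(subsets)
  mat <- matrix(0, nr, nr)
  for (si in seq_len(nr)) {
    for (ti in seq_len(nr)) {
      if (length(intersect(subsets[[si]], subsets[[ti]])) > 0) {
        mat[si, ti] <- 1
      }
    }
  }
  rhs <- vapply(subsets, function(s) union_adj_r2[[key(s)]], numeric(1))
  f <- solve(mat, rhs)
  names(f) <- vapply(subsets, function(ix) {
    paste(sort(labels[ix]), collapse = "&")
  }, character(1))
  f
}

# Euclidean distance matrix from planar points as a dist_matrix
points_dist <- function(n, seed = 1) {
  set.seed(seed)
  euclidean_matrix(tibble::tibble(site_id = sprintf("s%02d", seq_len(n)),
                                  x = rnorm(n), y = rnorm(n)))
}

# small trait-table builder
make_traits <- function(taxon_id, order = "Diptera",
                        functional_groups = "herbivore",
                        monophagous = FALSE, host_genus = NA_character_,
                        id_confidence = 0.99) {
  tibble::tibble(taxon_id = taxon_id,
                 order = rep_len(order, length(taxon_id)),
                 functional_groups = rep_len(functional_groups,
                                             length(taxon_id)),
                 monophagous = rep_len(monophagous, length(taxon_id)),
                 host_genus = rep_len(host_genus, length(taxon_id)),
                 id_confidence = rep_len(id_confidence,
                                         length(taxon_id)))
}

quiet <- function(expr) suppressWarnings(expr)
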