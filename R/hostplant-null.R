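#' Plant-unique adjusted R-squared given indicator conditions
#'
#' Two-set variation partitioning of an arthropod dissimilarity matrix on
#' (i) the Sorensen distances of a plant subset (expanded to principal
#' coordinates) and (ii) the Euclidean distances of the Ellenberg
#' indicator profile block (likewise expanded). Returns the unique
#' fraction of the plant subset: adjR2(plants + indicators) minus
#' adjR2(indicators alone).
#'
#' @param arthropod_d `dist_matrix` of arthropod dissimilarities.
#' @param plant_subset Plant community tibble (at least one species
#'   column).
#' @param indicator_block Output of [indicator_frequency_matrix()], or
#'   any predictor tibble describing site conditions.
#' @param max_axes Principal-coordinate cap per predictor set
#'   (default 8).
#' @return The plant-unique adjusted R-squared (may be negative).
#' @export
independent_plant_fraction <- function(arthropod_d, plant_subset,
                                       indicator_block, max_axes = 8) {
  validate_community(plant_subset, "plant_subset")
  if (ncol(plant_subset) < 2) {
    abort("Plant subset has no species columns.",
          class = "betadrivers_data_error")
  }
  vp <- varpart(arthropod_d,
                list(plants = sorensen_matrix(plant_subset),
                     indicators = euclidean_matrix(indicator_block)),
                max_axes = max_axes)
  unname(vp$independent["plants"])
}

#' Host-plant randomization null for the plant-unique fraction
#'
#' Tests whether a focal plant subset (the host plants of monophagous
#' herbivores) explains arthropod composition better than random plant
#' subsets of the same size. Draws `n_reps` subsets of `subset_size`
#' species uniformly without replacement from the full plant pool,
#' computes the plant-unique adjusted R-squared of each (conditioning on
#' the indicator profile both times), and compares the observed value
#' against the null sample with a two-sided one-sample t-test (the null
#' sample tested against the observed value as reference constant); a
#' z-score is reported alongside.
#'
#' @param arthropod_d `dist_matrix` of arthropod dissimilarities.
#' @param plants Full plant community tibble (the sampling pool).
#' @param indicator_block Indicator profile predictor tibble.
#' @param host_plants Focal plant subset community tibble (e.g. from
#'   [host_plant_subset()]); the observed statistic is computed from it.
#' @param subset_size Species per random subset; defaults to the number
#'   of species in `host_plants`.
#' @param n_reps Number of random subsets (default 1000).
#' @param seed Integer seed.
#' @param max_axes Principal-coordinate cap (default 8).
#' @param exclude_hosts If `TRUE`, random subsets are drawn from
#'   non-host species only (default `FALSE`: the full pool).
#' @return A `hostplant_null` object: `observed`, `null_samples`,
#'   `subset_size`, `t_statistic`, `p_value`, `dof`, `z_score`, `seed`.
#' @export
random_subset_null <- function(arthropod_d, plants, indicator_block,
                               host_plants, subset_size = NULL,
                               n_reps = 1000, seed = 1, max_axes = 8,
                               exclude_hosts = FALSE) {
  validate_community(plants, "plants")
  validate_community(host_plants, "host_plants")
  n_reps <- stopifnot_scalar_int(n_reps, "n_reps", min = 2L)
  pool <- names(plants)[-1]
  hosts <- names(host_plants)[-1]
  if (exclude_hosts) pool <- setdiff(pool, hosts)
  subset_size <- subset_size %||% length(hosts)
  subset_size <- stopifnot_scalar_int(subset_size, "subset_size")
  if (subset_size > length(pool)) {
    abort("`subset_size` exceeds the plant pool.",
          class = "betadrivers_config_error")
  }
  # indicator expansion is identical across draws: precompute its axes
  ind_axes <- pcoa_axes(euclidean_matrix(indicator_block),
                        max_axes = max_axes)
  frac <- function(subset_tbl) {
    vp <- varpart(arthropod_d,
                  list(plants = sorensen_matrix(subset_tbl),
                       indicators = ind_axes),
                  max_axes = max_axes)
    unname(vp$independent["plants"])
  }
  observed <- frac(host_plants)
  local_seed(seed)
  null_samples <- vapply(seq_len(n_reps), function(i) {
    frac(plants[c("site_id", sample(pool, subset_size))])
  }, numeric(1))
  if (sd(null_samples) == 0) {
    abort("Null distribution has zero variance.",
          class = "betadrivers_degenerate_error")
  }
  se <- sd(null_samples) / sqrt(n_reps)
  t_stat <- (mean(null_samples) - observed) / se
  dof <- n_reps - 1L
  p_val <- 2 * pt(-abs(t_stat), dof)
  structure(list(observed = observed, null_samples = null_samples,
                 subset_size = subset_size, t_statistic = t_stat,
                 p_value = p_val, dof = dof,
                 z_score = (observed - mean(null_samples)) /
                   sd(null_samples),
                 seed = as.integer(seed)),
            class = "hostplant_null")
}

significance_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else ""
}

#' Summarize a host-plant randomization null
#'
#' One-row summary in the layout of a host-plant results table: observed
#' plant-unique fraction, null mean and SD, t, p, and significance stars
#' (*** p < 0.001, ** p < 0.01, * p < 0.05).
#'
#' @param result A `hostplant_null`.
#' @return A one-row tibble.
#' @export
summarize_null <- function(result) {
  stopifnot(inherits(result, "hostplant_null"))
  tibble(observed = result$observed,
         null_mean = mean(result$null_samples),
         null_sd = sd(result$null_samples),
         subset_size = result$subset_size,
         t_statistic = result$t_statistic,
         p_value = result$p_value,
         dof = result$dof,
         z_score = result$z_score,
         stars = significance_stars(result$p_value))
}

#' @export
print.hostplant_null <- function(x, ...) {
  s <- summarize_null(x)
  cat(sprintf(
    "Host-plant null: observed = %.4f vs null %.4f +/- %.4f (%d reps)\n  t = %.2f, p = %.3g %s\n",
    s$observed, s$null_mean, s$null_sd, length(x$null_samples),
    s$t_statistic, s$p_value, s$stars))
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.hostplant_null <- function(x, ...) {
  tibble(replicate = seq_along(x$null_samples),
         adj_r2 = x$null_samples)
}

#' @rdname tidy
#' @export
glance.hostplant_null <- function(x, ...) summarize_null(x)

#' @rdname plot_hostplant_null
#' @export
autoplot.hostplant_null <- function(object, ...) {
  plot_hostplant_null(object, ...)
}

#' Histogram of a host-plant null distribution
#'
#' Null sample of plant-unique adjusted R-squared values as a histogram
#' with the observed host-plant value as a vertical line.
#'
#' @param object A `hostplant_null`.
#' @param bins Histogram bins (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_hostplant_null <- function(object, bins = 30, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$adj_r2)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70",
                            colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linewidth = 1) +
    ggplot2::labs(x = "plant-unique adjusted R²", y = "count") +
    ggplot2::theme_minimal()
}
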