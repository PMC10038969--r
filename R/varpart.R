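#' Variation partitioning over 2-4 predictor sets
#'
#' Decomposes the adjusted R-squared of a distance-based RDA into the
#' exclusive fractions of every combination of 2-4 named predictor sets.
#' Each set is either a predictor tibble (used as is) or a `dist_matrix`
#' (expanded to its positive principal coordinates first, optionally
#' capped by `max_axes`). For every nonempty subset of the sets one dbRDA
#' is fitted on the concatenated columns; the exclusive fractions are then
#' recovered by Moebius inversion over the subset lattice. Fractions can
#' be negative and are never truncated.
#'
#' @param d A `dist_matrix` response.
#' @param sets Named list of 2-4 predictor sets (tibbles or
#'   `dist_matrix` objects).
#' @param max_axes Cap on principal-coordinate axes per distance-matrix
#'   set (default unlimited).
#' @param rel_tol Relative eigenvalue cutoff for the expansion.
#' @return A `varpart_result` with `union_adj_r2` (named by `+`-joined
#'   subset labels), `fractions` (tibble: one row per exclusive region,
#'   `&`-joined labels, plus the residual), `independent` (named vector of
#'   unique fractions) and `residual`.
#' @examples
#' sim <- simulate_study(synthetic_config(n_sites = 30, seed = 1))
#' vp <- varpart(sorensen_matrix(sim$arthropods),
#'               list(plants = sorensen_matrix(sim$plants),
#'                    climate = climate_block(sim$sites)),
#'               max_axes = 6)
#' tidy(vp)
#' @export
varpart <- function(d, sets, max_axes = Inf, rel_tol = 1e-8) {
  k <- length(sets)
  if (k < 2 || k > 4) {
    abort("`sets` must hold 2 to 4 predictor sets.",
          class = "betadrivers_config_error")
  }
  labels <- names(sets)
  if (is.null(labels) || any(labels == "") || anyDuplicated(labels)) {
    abort("`sets` must have unique, nonempty names.",
          class = "betadrivers_config_error")
  }
  blocks <- lapply(seq_along(sets), function(i) {
    b <- expand_predictor_set(sets[[i]], max_axes = max_axes,
                              rel_tol = rel_tol)
    names(b)[-1] <- paste(labels[i], names(b)[-1], sep = ".")
    b
  })
  sites <- dist_sites(d)
  subsets <- unlist(lapply(seq_len(k), function(s) {
    asplit(utils::combn(k, s), 2)
  }), recursive = FALSE)
  key <- function(ix) paste(sort(labels[ix]), collapse = "+")
  union_adj_r2 <- vapply(subsets, function(ix) {
    x <- Reduce(function(a, b) dplyr::inner_join(a, b, by = "site_id"),
                blocks[ix])
    fit <- tryCatch(dbrda_fit(d, x), betadrivers_df_error = function(e) {
      abort(sprintf("Union '%s' exhausts residual degrees of freedom; lower `max_axes`.",
                    key(ix)), class = "betadrivers_df_error", parent = e)
    })
    fit$adj_r2
  }, numeric(1))
  names(union_adj_r2) <- vapply(subsets, key, character(1))
  full <- union_adj_r2[key(seq_len(k))]

  # B(U) = adjR2(all) - adjR2(all \ U); exclusive region of exactly T:
  # f(T) = sum_{U subset T} (-1)^{|T| - |U|} B(U), B(empty) = 0
  bfun <- function(ix) {
    if (!length(ix)) return(0)
    rest <- setdiff(seq_len(k), ix)
    if (!length(rest)) return(unname(full))
    unname(full - union_adj_r2[key(rest)])
  }
  powerset <- function(ix) {
    n <- length(ix)
    lapply(0:(2^n - 1), function(b) {
      ix[bitwAnd(b, 2^(seq_len(n) - 1)) > 0]
    })
  }
  fractions <- purrr::map_dfr(subsets, function(ix) {
    f <- sum(vapply(powerset(ix), function(u) {
      (-1)^(length(ix) - length(u)) * bfun(u)
    }, numeric(1)))
    tibble(region = paste(sort(labels[ix]), collapse = "&"),
           n_sets = length(ix), adj_r2 = f)
  })
  independent <- fractions$adj_r2[fractions$n_sets == 1]
  names(independent) <- fractions$region[fractions$n_sets == 1]
  independent <- independent[labels]
  residual <- 1 - unname(full)
  structure(list(set_labels = labels, union_adj_r2 = union_adj_r2,
                 fractions = fractions, independent = independent,
                 residual = residual, n = length(sites),
                 max_axes = max_axes),
            class = "varpart_result")
}

# dist_matrix -> positive PCoA axes; tibble -> unchanged
expand_predictor_set <- function(set, max_axes = Inf, rel_tol = 1e-8) {
  if (inherits(set, "dist_matrix")) {
    pcoa_axes(set, rel_tol = rel_tol, max_axes = max_axes)
  } else if (is.data.frame(set)) {
    set
  } else {
    abort("Each predictor set must be a tibble or a dist_matrix.",
          class = "betadrivers_config_error")
  }
}

#' @export
print.varpart_result <- function(x, ...) {
  cat(sprintf("Variation partitioning (%d sets: %s; n = %d sites)\n",
              length(x$set_labels), paste(x$set_labels, collapse = ", "),
              x$n))
  cat(sprintf("  total adjusted R2 = %.4f, residual = %.4f\n",
              1 - x$residual, x$residual))
  cat("  independent fractions:\n")
  for (l in x$set_labels) {
    cat(sprintf("    %-12s %.4f\n", l, x$independent[[l]]))
  }
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.varpart_result <- function(x, ...) {
  dplyr::bind_rows(x$fractions,
                   tibble(region = "residual", n_sets = 0L,
                          adj_r2 = x$residual))
}

#' @rdname tidy
#' @export
glance.varpart_result <- function(x, ...) {
  tibble(total.adj.r.squared = 1 - x$residual, residual = x$residual,
         n = x$n, n.sets = length(x$set_labels))
}

#' @rdname plot_varpart
#' @export
autoplot.varpart_result <- function(object, ...) {
  plot_varpart(object, ...)
}

#' Stacked-bar display of a variation partitioning
#'
#' Shows the exclusive fractions (unique and shared) of a
#' `varpart_result` as a horizontal stacked bar; negative fractions are
#' drawn below zero.
#'
#' @param object A `varpart_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_varpart <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$region != "residual", ]
  df$region <- factor(df$region, levels = rev(df$region))
  ggplot2::ggplot(df, ggplot2::aes(x = "fractions", y = .data$adj_r2,
                                   fill = .data$region)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "adjusted R²", fill = "region") +
    ggplot2::theme_minimal()
}
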