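#' Ellenberg indicator class grids
#'
#' The six indicator systems and their ordinal class grids: light (L),
#' temperature (T), continentality (K), moisture (F), soil reaction (R)
#' and nutrients (N) run 1-9, except moisture which extends to 12
#' (aquatic classes).
#'
#' @return Named list of integer class vectors.
#' @export
indicator_grids <- function() {
  list(L = 1:9, T = 1:9, K = 1:9, F = 1:12, R = 1:9, N = 1:9)
}

validate_plant_attrs <- function(attrs) {
  need <- c("species_id", "genus", "family", names(indicator_grids()))
  miss <- setdiff(need, names(attrs))
  if (length(miss)) {
    abort(sprintf("Plant attribute table is missing columns: %s.",
                  paste(miss, collapse = ", ")),
          class = "betadrivers_data_error")
  }
  if (anyDuplicated(attrs$species_id)) {
    abort("Plant attribute table has duplicated species_ids.",
          class = "betadrivers_data_error")
  }
  for (ind in names(indicator_grids())) {
    v <- attrs[[ind]]
    ok <- is.na(v) | (v == round(v) & v %in% indicator_grids()[[ind]])
    if (any(!ok)) {
      abort(sprintf(
        "Indicator %s has out-of-grid values for species %s.",
        ind, paste(head(attrs$species_id[!ok], 3), collapse = ", ")),
        class = "betadrivers_load_error")
    }
  }
  invisible(attrs)
}

#' Per-site Ellenberg indicator-class frequency profiles
#'
#' Converts floristic presence data into the relative frequency of each
#' indicator class among the species present at a site. For each site and
#' indicator, species lacking a value for that indicator are excluded
#' from that indicator's denominator only; a site where no present
#' species carries a value gets all-zero frequencies for that indicator
#' (with a warning). Columns exist for every grid class (e.g. `T_1` ...
#' `T_9`) even when the class never occurs, so block dimensions do not
#' depend on the data.
#'
#' @param plants Plant community tibble.
#' @param attrs Plant attribute tibble covering all plant taxa.
#' @return Predictor tibble `site_id`, `L_1`, ..., `N_9` with per-site
#'   relative frequencies; the per-indicator fraction of species carrying
#'   values is in attribute `"coverage"`.
#' @examples
#' # a site with temperature values {5, 5, 7} has T_5 = 2/3, T_7 = 1/3
#' @export
indicator_frequency_matrix <- function(plants, attrs) {
  validate_community(plants, "plants")
  validate_plant_attrs(attrs)
  m <- cm_matrix(plants)
  missing_sp <- setdiff(colnames(m), attrs$species_id)
  if (length(missing_sp)) {
    abort(sprintf("Attribute table lacks plant species: %s.",
                  paste(head(missing_sp, 3), collapse = ", ")),
          class = "betadrivers_data_error")
  }
  grids <- indicator_grids()
  row <- match(colnames(m), attrs$species_id)
  blocks <- list(tibble(site_id = rownames(m)))
  warned <- character(0)
  for (ind in names(grids)) {
    vals <- attrs[[ind]][row]             # per plant column
    classes <- grids[[ind]]
    # counts: sites x classes; species with NA contribute nowhere
    memb <- outer(vals, classes, function(v, k) as.numeric(!is.na(v) & v == k))
    counts <- m %*% memb
    denom <- rowSums(counts)
    zero <- denom == 0
    if (any(zero)) warned <- union(warned, ind)
    freq <- counts / ifelse(denom == 0, 1, denom)
    colnames(freq) <- paste(ind, classes, sep = "_")
    blocks[[length(blocks) + 1]] <- as_tibble(freq)
  }
  if (length(warned)) {
    warn(sprintf(
      "Sites with no valued species for indicator(s) %s: frequencies set to 0.",
      paste(warned, collapse = ", ")),
      class = "betadrivers_zero_indicator")
  }
  out <- dplyr::bind_cols(blocks)
  cov <- vapply(names(grids), function(ind) {
    mean(!is.na(attrs[[ind]][row]))
  }, numeric(1))
  attr(out, "coverage") <- cov
  out
}

#' Extract the class columns of one indicator
#'
#' Restricts a full indicator-profile block to a single indicator's
#' classes (e.g. all `T_*` columns), ready for `euclidean_matrix()`.
#'
#' @param profile Output of [indicator_frequency_matrix()].
#' @param indicator One of `"L"`, `"T"`, `"K"`, `"F"`, `"R"`, `"N"`.
#' @return Predictor tibble with that indicator's class columns.
#' @export
single_indicator_block <- function(profile, indicator) {
  grids <- indicator_grids()
  if (!(indicator %in% names(grids))) {
    abort(sprintf("Unknown indicator '%s'.", indicator),
          class = "betadrivers_lookup_error")
  }
  cols <- paste(indicator, grids[[indicator]], sep = "_")
  miss <- setdiff(cols, names(profile))
  if (length(miss)) {
    abort(sprintf("Profile lacks columns: %s.", paste(miss, collapse = ", ")),
          class = "betadrivers_data_error")
  }
  profile[c("site_id", cols)]
}
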