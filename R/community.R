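#' Community tables
#'
#' A community table is a tibble holding a binary site-by-taxon
#' presence-absence matrix: the first column `site_id` identifies sites and
#' every remaining column is one taxon, with entries 0 or 1. All assembly
#' operations in the package consume and return this shape, so calls chain
#' with the pipe.
#'
#' @param x A matrix with row names (sites) and column names (taxa), or a
#'   data frame already in community shape.
#' @return A community tibble.
#' @examples
#' m <- matrix(c(1, 0, 1, 1), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("taxA", "taxB")))
#' as_community(m)
#' @export
as_community <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("Community matrices need site row names and taxon column names.",
            class = "betadrivers_data_error")
    }
    out <- as_tibble(x, rownames = "site_id")
  } else {
    out <- as_tibble(x)
  }
  validate_community(out)
  if (ncol(out) > 1) out[-1] <- lapply(out[-1], as.integer)
  out
}

validate_community <- function(df, arg = "community") {
  if (!is.data.frame(df) || ncol(df) < 1 || names(df)[1] != "site_id") {
    abort(sprintf("`%s` must be a data frame whose first column is `site_id`.",
                  arg), class = "betadrivers_data_error")
  }
  ids <- df$site_id
  if (anyDuplicated(ids)) {
    abort(sprintf("`%s` has duplicated site_ids: %s", arg,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "betadrivers_data_error")
  }
  if (ncol(df) > 1) {
    vals <- as.matrix(df[-1])
    bad <- which(!(vals %in% c(0, 1)))
    if (length(bad)) {
      i <- arrayInd(bad[1], dim(vals))
      abort(sprintf(
        "`%s` must be binary; cell [site %s, taxon %s] is %s.",
        arg, ids[i[1]], colnames(vals)[i[2]], vals[bad[1]]),
        class = "betadrivers_load_error")
    }
    if (anyDuplicated(colnames(vals))) {
      abort(sprintf("`%s` has duplicated taxon columns.", arg),
            class = "betadrivers_data_error")
    }
  }
  invisible(df)
}

# site-by-taxon 0/1 matrix from a community tibble
cm_matrix <- function(df) {
  m <- as.matrix(df[-1])
  storage.mode(m) <- "double"
  rownames(m) <- df$site_id
  m
}

check_same_sites <- function(a, b, what = "tables") {
  if (!setequal(a$site_id, b$site_id)) {
    abort(sprintf("Site sets of the %s differ (%d vs %d sites; e.g. %s).",
                  what, nrow(a), nrow(b),
                  paste(head(c(setdiff(a$site_id, b$site_id),
                               setdiff(b$site_id, a$site_id)), 3),
                        collapse = ", ")),
          class = "betadrivers_alignment_error")
  }
  invisible(TRUE)
}

#' Aggregate sampling-period matrices into one presence-absence table
#'
#' Unions per-site occurrences over a list of period-specific community
#' tables, on the union of their taxon sets. This mirrors pooling the total
#' taxon lists per site across repeated sampling periods. Sites are matched
#' by identifier; a mismatch in site sets is an error, never a silent
#' intersection.
#'
#' @param matrices A list of community tibbles sharing one site set.
#' @return A community tibble with the union taxon set (taxa sorted).
#' @examples
#' p1 <- as_community(matrix(1, 1, 1, dimnames = list("s1", "A")))
#' p2 <- as_community(matrix(1, 1, 1, dimnames = list("s1", "B")))
#' aggregate_periods(list(p1, p2))
#' @export
aggregate_periods <- function(matrices) {
  if (!length(matrices)) {
    abort("Need at least one period matrix.",
          class = "betadrivers_config_error")
  }
  purrr::walk(matrices, validate_community)
  ref <- matrices[[1]]
  purrr::walk(matrices[-1], check_same_sites, a = ref,
              what = "period matrices")
  taxa <- sort(unique(unlist(lapply(matrices, function(m) names(m)[-1]))))
  out <- matrix(0, nrow(ref), length(taxa),
                dimnames = list(ref$site_id, taxa))
  for (m in matrices) {
    mm <- cm_matrix(m)[ref$site_id, , drop = FALSE]
    if (ncol(mm)) out[, colnames(mm)] <- pmax(out[, colnames(mm)], mm)
  }
  as_community(out)
}

#' Combine two vegetation surveys into one presence-absence table
#'
#' Per-site union of the occurrences of a plot-scale survey and a
#' transect-scale survey, over the union of their species sets.
#'
#' @param site_survey,transect_survey Community tibbles with identical
#'   site sets.
#' @return A community tibble.
#' @export
combine_surveys <- function(site_survey, transect_survey) {
  validate_community(site_survey, "site_survey")
  validate_community(transect_survey, "transect_survey")
  check_same_sites(site_survey, transect_survey, "surveys")
  aggregate_periods(list(site_survey, transect_survey))
}

known_functional_groups <- c("herbivore", "pollinator", "predator",
                             "parasitoid", "detritivore")
known_orders <- c("Lepidoptera", "Coleoptera", "Hymenoptera", "Diptera")

# parse the semicolon-separated functional_groups column into a list
split_groups <- function(x) {
  strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE)
}

#' Subset an arthropod community by functional group or taxonomic order
#'
#' Restricts the taxon columns to members of one of the five functional
#' groups (herbivore, pollinator, predator, parasitoid, detritivore) or one
#' of the four large orders (Lepidoptera, Coleoptera, Hymenoptera, Diptera).
#' A taxon can belong to several functional groups (lepidopterans feeding
#' as larvae and nectaring as adults sit in both the herbivore and the
#' pollinator subset); taxa with no functional classification appear in no
#' functional subset but are retained in order subsets.
#'
#' @param arthropods Community tibble of arthropod occurrences.
#' @param traits Arthropod trait tibble with columns `taxon_id`, `order`,
#'   `functional_groups` (semicolon-separated), `monophagous`,
#'   `host_genus`, `id_confidence`.
#' @param group A functional group or order label.
#' @return A community tibble; sites unchanged, columns filtered (possibly
#'   zero taxa).
#' @export
subset_by_group <- function(arthropods, traits, group) {
  validate_community(arthropods, "arthropods")
  validate_traits(traits)
  if (!(group %in% c(known_functional_groups, known_orders))) {
    abort(sprintf("Unknown group '%s'; expected one of: %s.", group,
                  paste(c(known_functional_groups, known_orders),
                        collapse = ", ")),
          class = "betadrivers_lookup_error")
  }
  keep <- if (group %in% known_orders) {
    traits$taxon_id[traits$order == group]
  } else {
    in_group <- vapply(split_groups(traits$functional_groups),
                       function(g) group %in% g, logical(1))
    traits$taxon_id[in_group]
  }
  keep <- intersect(names(arthropods)[-1], keep)
  arthropods[c("site_id", keep)]
}

validate_traits <- function(traits) {
  need <- c("taxon_id", "order", "functional_groups", "monophagous",
            "host_genus", "id_confidence")
  miss <- setdiff(need, names(traits))
  if (length(miss)) {
    abort(sprintf("Trait table is missing columns: %s.",
                  paste(miss, collapse = ", ")),
          class = "betadrivers_data_error")
  }
  if (anyDuplicated(traits$taxon_id)) {
    abort("Trait table has duplicated taxon_ids.",
          class = "betadrivers_data_error")
  }
  bad <- traits$monophagous & (is.na(traits$host_genus) |
                                 traits$host_genus == "")
  if (any(bad)) {
    abort(sprintf("Monophagous taxa without host_genus: %s.",
                  paste(head(traits$taxon_id[bad], 3), collapse = ", ")),
          class = "betadrivers_data_error")
  }
  invisible(traits)
}

#' Taxa identified above a confidence threshold
#'
#' Returns the taxon ids whose identification confidence meets or exceeds
#' the threshold (default 0.97, the conventional barcode-identification
#' cutoff; the boundary is inclusive).
#'
#' @param traits Arthropod trait tibble.
#' @param threshold Confidence cutoff in (0, 1].
#' @return Character vector of taxon ids.
#' @export
filter_confident_taxa <- function(traits, threshold = 0.97) {
  validate_traits(traits)
  if (length(threshold) != 1 || !is.finite(threshold) ||
      threshold <= 0 || threshold > 1) {
    abort("`threshold` must lie in (0, 1].",
          class = "betadrivers_config_error")
  }
  traits$taxon_id[traits$id_confidence >= threshold]
}

#' Host-plant subset of the plant community
#'
#' Restricts the plant columns to species whose genus hosts at least one
#' monophagous, confidently identified herbivore. Matching is exact string
#' equality on the genus field.
#'
#' @param plants Plant community tibble.
#' @param plant_attrs Plant attribute tibble (`species_id`, `genus`,
#'   `family`, indicator columns).
#' @param traits Arthropod trait tibble.
#' @param confidence Identification-confidence cutoff applied to the
#'   monophage list (default 0.97).
#' @return A community tibble restricted to host-genus plant species
#'   (possibly zero columns when there are no monophages).
#' @export
host_plant_subset <- function(plants, plant_attrs, traits,
                              confidence = 0.97) {
  validate_community(plants, "plants")
  validate_traits(traits)
  confident <- filter_confident_taxa(traits, confidence)
  herb <- vapply(split_groups(traits$functional_groups),
                 function(g) "herbivore" %in% g, logical(1))
  mono <- traits$monophagous & herb & traits$taxon_id %in% confident
  hosts <- unique(traits$host_genus[mono])
  genus <- plant_attrs$genus[match(names(plants)[-1],
                                   plant_attrs$species_id)]
  keep <- names(plants)[-1][!is.na(genus) & genus %in% hosts]
  plants[c("site_id", keep)]
}
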