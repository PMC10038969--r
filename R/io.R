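#' Read and write analysis tables
#'
#' All tables travel as UTF-8, comma-delimited CSV with a `site_id` (or
#' `species_id` / `taxon_id`) first column and `.` decimal marks.
#' Community matrices are validated as binary on load, with the offending
#' cell named on failure; indicator columns accept empty cells or the
#' letter `x` as missing.
#'
#' @param path File path.
#' @param x Table to write.
#' @name betadrivers_io
NULL

read_csv_checked <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path),
          class = "betadrivers_load_error")
  }
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8"),
    error = function(e) {
      abort(sprintf("Cannot parse %s: %s", path, conditionMessage(e)),
            class = "betadrivers_load_error", parent = e)
    })
  if (!nrow(df)) {
    abort(sprintf("File %s has no data rows.", path),
          class = "betadrivers_load_error")
  }
  as_tibble(df)
}

#' @rdname betadrivers_io
#' @export
read_community_matrix <- function(path) {
  df <- read_csv_checked(path)
  names(df)[1] <- "site_id"
  df$site_id <- as.character(df$site_id)
  validate_community(df, path)
  df
}

#' @rdname betadrivers_io
#' @export
write_community_matrix <- function(x, path) {
  validate_community(x)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname betadrivers_io
#' @export
read_site_table <- function(path) {
  df <- read_csv_checked(path)
  need <- c("site_id", "longitude", "latitude", "habitat",
            "summer_temperature", "summer_precipitation",
            "annual_temperature_range", "elevation",
            paste0("lc_", landcover_classes))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("Site table %s is missing columns: %s.", path,
                  paste(miss, collapse = ", ")),
          class = "betadrivers_load_error")
  }
  df$site_id <- as.character(df$site_id)
  lc <- as.matrix(df[paste0("lc_", landcover_classes)])
  bad <- abs(rowSums(lc) - 1) > 1e-6
  if (any(bad)) {
    abort(sprintf("Land-cover proportions do not sum to 1 at site(s) %s.",
                  paste(head(df$site_id[bad], 3), collapse = ", ")),
          class = "betadrivers_load_error")
  }
  df
}

#' @rdname betadrivers_io
#' @export
write_site_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname betadrivers_io
#' @export
read_plant_attributes <- function(path) {
  df <- read_csv_checked(path)
  names(df)[1] <- "species_id"
  df$species_id <- as.character(df$species_id)
  for (ind in names(indicator_grids())) {
    if (ind %in% names(df)) {
      v <- df[[ind]]
      v[v %in% c("", "x", "X")] <- NA
      df[[ind]] <- as.numeric(v)
    }
  }
  validate_plant_attrs(df)
  df
}

#' @rdname betadrivers_io
#' @export
write_plant_attributes <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname betadrivers_io
#' @export
read_arthropod_traits <- function(path) {
  df <- read_csv_checked(path)
  df$taxon_id <- as.character(df$taxon_id)
  df$monophagous <- as.logical(df$monophagous)
  df$host_genus <- ifelse(df$host_genus %in% c("", NA), NA_character_,
                          as.character(df$host_genus))
  validate_traits(df)
  df
}

#' @rdname betadrivers_io
#' @export
write_arthropod_traits <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname betadrivers_io
#' @export
read_distance_matrix <- function(path, metric = "euclidean") {
  df <- read_csv_checked(path)
  m <- as.matrix(df[-1])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  new_dist_matrix(m, metric)
}

#' @rdname betadrivers_io
#' @export
write_distance_matrix <- function(x, path) {
  df <- dplyr::bind_cols(tibble(site_id = rownames(x)),
                         as_tibble(unclass(x)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a synthetic study to a directory
#'
#' Serializes every table of a [simulate_study()] result as CSV plus the
#' configuration as YAML and a small run manifest (JSON) recording the
#' seed and an md5 hash of every written file.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    sites = write_site_table(study$sites, file.path(dir, "sites.csv")),
    plants = write_community_matrix(study$plants,
                                    file.path(dir, "plants.csv")),
    plant_attrs = write_plant_attributes(
      study$plant_attrs, file.path(dir, "plant_attributes.csv")),
    arthropods = write_community_matrix(
      study$arthropods, file.path(dir, "arthropods.csv")),
    traits = write_arthropod_traits(study$traits,
                                    file.path(dir, "arthropod_traits.csv")))
  cfg <- study$config
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  write_manifest(file.path(dir, "run_manifest.json"),
                 config = unclass(cfg), files = paths,
                 seed = cfg$seed)
  invisible(file.path(dir, "run_manifest.json"))
}

#' Load a study directory written by [write_study()]
#'
#' @param dir Directory containing the CSV tables.
#' @return List in the [simulate_study()] layout.
#' @export
read_study <- function(dir) {
  list(sites = read_site_table(file.path(dir, "sites.csv")),
       plants = read_community_matrix(file.path(dir, "plants.csv")),
       plant_attrs = read_plant_attributes(
         file.path(dir, "plant_attributes.csv")),
       arthropods = read_community_matrix(file.path(dir,
                                                    "arthropods.csv")),
       traits = read_arthropod_traits(
         file.path(dir, "arthropod_traits.csv")))
}

write_manifest <- function(path, config, files, seed,
                           warnings = character(0)) {
  hashes <- tools::md5sum(unname(unlist(files)))
  names(hashes) <- basename(names(hashes))
  hashes <- as.list(hashes)
  manifest <- list(
    package = "betadrivers",
    version = as.character(utils::packageVersion("betadrivers")),
    seed = seed,
    config = config,
    files = hashes,
    warnings = warnings)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}
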