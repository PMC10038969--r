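#' Configuration for the synthetic community generator
#'
#' Bundles every knob of the synthetic plant-arthropod study generator.
#' The generator emulates a regional survey: sites spread over a planar
#' landscape in four habitat types, climate gradients tied to latitude
#' and elevation, Dirichlet land-cover composition concentrated on each
#' habitat's characteristic classes, niche-structured plant occurrences
#' whose indicator values track the niche optima, and arthropod
#' occurrences assembled from a configurable mixture of drivers (plant
#' composition, land cover, climate, space, noise) per functional group,
#' with optional monophage-host dependencies.
#'
#' @param n_sites Number of sites (>= 8).
#' @param n_plant_species,n_arthropod_taxa Pool sizes.
#' @param habitat_types Habitat labels (default forest, grassland,
#'   arable, settlement).
#' @param driver_weights Either one named nonnegative vector over
#'   `c("plants", "landcover", "climate", "space", "noise")` applied to
#'   every functional group, or a named list of such vectors per group
#'   (missing groups fall back to the `"default"` entry).
#' @param monophage_fraction Fraction of herbivore taxa that are
#'   monophagous, in \[0, 1\].
#' @param host_dependence Probability that a monophage strictly requires
#'   its host genus present, in \[0, 1\].
#' @param niche_breadth Plant niche breadth in indicator-grid units
#'   (`Inf` gives flat niches: occurrence independent of environment).
#' @param missing_indicator_fraction Fraction of species-by-indicator
#'   values left missing (emulating species without published values).
#' @param richness_floor Minimum plant species per site (default 1).
#' @param signal_strength Standard deviation of the arthropod
#'   environmental logit component (default 2).
#' @param n_plant_axes Plant principal coordinates used as the plant
#'   driver signal (default 5).
#' @param seed Integer seed; all generator stages derive their streams
#'   from it, so identical configs give bit-identical output.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_sites = 60,
                             n_plant_species = 150,
                             n_arthropod_taxa = 400,
                             habitat_types = c("forest", "grassland",
                                               "arable", "settlement"),
                             driver_weights = c(plants = 1, landcover = 0.5,
                                                climate = 0.25, space = 0.1,
                                                noise = 1),
                             monophage_fraction = 0.2,
                             host_dependence = 1,
                             niche_breadth = 4,
                             missing_indicator_fraction = 0.35,
                             richness_floor = 1,
                             signal_strength = 2,
                             n_plant_axes = 5,
                             seed = 1) {
  n_sites <- stopifnot_scalar_int(n_sites, "n_sites", min = 8L)
  n_plant_species <- stopifnot_scalar_int(n_plant_species,
                                          "n_plant_species")
  n_arthropod_taxa <- stopifnot_scalar_int(n_arthropod_taxa,
                                           "n_arthropod_taxa")
  seed <- stopifnot_scalar_int(seed, "seed", min = 0L)
  if (monophage_fraction < 0 || monophage_fraction > 1) {
    abort("`monophage_fraction` must lie in [0, 1].",
          class = "betadrivers_config_error")
  }
  if (host_dependence < 0 || host_dependence > 1) {
    abort("`host_dependence` must lie in [0, 1].",
          class = "betadrivers_config_error")
  }
  weights <- normalize_driver_weights(driver_weights)
  structure(list(n_sites = n_sites, n_plant_species = n_plant_species,
                 n_arthropod_taxa = n_arthropod_taxa,
                 habitat_types = habitat_types,
                 driver_weights = weights,
                 monophage_fraction = monophage_fraction,
                 host_dependence = host_dependence,
                 niche_breadth = niche_breadth,
                 missing_indicator_fraction = missing_indicator_fraction,
                 richness_floor = richness_floor,
                 signal_strength = signal_strength,
                 n_plant_axes = n_plant_axes,
                 seed = seed),
            class = "synthetic_config")
}

driver_names <- c("plants", "landcover", "climate", "space", "noise")

normalize_driver_weights <- function(w) {
  check_one <- function(v, label) {
    if (is.null(names(v)) || !all(names(v) %in% driver_names)) {
      abort(sprintf("Driver weights (%s) must be named among: %s.", label,
                    paste(driver_names, collapse = ", ")),
            class = "betadrivers_config_error")
    }
    full <- stats::setNames(numeric(length(driver_names)), driver_names)
    full[names(v)] <- v
    if (any(full < 0) || sum(full) <= 0) {
      abort(sprintf(
        "Driver weights (%s) must be nonnegative with positive sum.", label),
        class = "betadrivers_config_error")
    }
    full
  }
  groups <- c(known_functional_groups, "none")
  if (!is.list(w)) {
    v <- check_one(w, "default")
    return(stats::setNames(rep(list(v), length(groups)), groups))
  }
  default <- if (!is.null(w$default)) check_one(w$default, "default") else
    check_one(c(plants = 1, landcover = 0.5, climate = 0.25, space = 0.1,
                noise = 1), "default")
  out <- lapply(groups, function(g) {
    if (!is.null(w[[g]])) check_one(w[[g]], g) else default
  })
  stats::setNames(out, groups)
}

rescale_range <- function(x, lo, hi) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep((lo + hi) / 2, length(x)))
  lo + (hi - lo) * (x - rng[1]) / diff(rng)
}

landcover_classes <- c("annual_crop", "perennial_crop", "managed_grassland",
                       "succession", "small_woody", "coniferous_forest",
                       "deciduous_forest", "mixed_forest", "wetland",
                       "water", "roads", "settlement")

habitat_concentration <- function(habitat) {
  a <- stats::setNames(rep(0.2, length(landcover_classes)),
                       landcover_classes)
  bump <- switch(habitat,
    forest = c(coniferous_forest = 6, deciduous_forest = 4,
               mixed_forest = 3),
    grassland = c(managed_grassland = 8, succession = 2,
                  small_woody = 1),
    arable = c(annual_crop = 8, perennial_crop = 2),
    settlement = c(settlement = 7, roads = 2),
    c(succession = 4))
  a[names(bump)] <- a[names(bump)] + bump
  a
}

#' Generate synthetic study sites
#'
#' Draws site coordinates on a planar landscape, assigns habitats in a
#' balanced rotation, derives climate variables from latitude/elevation
#' gradients plus noise, and draws the 12 land-cover proportions per site
#' from a Dirichlet distribution concentrated on the habitat's
#' characteristic classes (so the proportions always sum to one).
#'
#' @param config A [synthetic_config()].
#' @return Site tibble: `site_id`, `longitude`, `latitude`, `habitat`,
#'   `summer_temperature` (degrees C), `summer_precipitation` (mm),
#'   `annual_temperature_range` (degrees C), `elevation` (m), and 12
#'   `lc_*` proportions.
#' @export
generate_sites <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  local_seed(derive_seed(config$seed, 101))
  n <- config$n_sites
  longitude <- runif(n, 0, 300)
  latitude <- runif(n, 0, 300)
  habitat <- sample(rep_len(config$habitat_types, n))
  elevation <- pmax(100, 160 + 3.0 * latitude + rnorm(n, 0, 80))
  summer_temperature <- 19 - 0.006 * elevation - 0.008 * latitude +
    rnorm(n, 0, 0.5)
  summer_precipitation <- pmax(150, 380 + 0.55 * elevation + rnorm(n, 0, 60))
  annual_temperature_range <- 16.5 + 0.012 * longitude + rnorm(n, 0, 0.8)
  lc <- t(vapply(habitat, function(h) {
    g <- rgamma(length(landcover_classes), shape = habitat_concentration(h))
    g / sum(g)
  }, numeric(length(landcover_classes))))
  colnames(lc) <- paste0("lc_", landcover_classes)
  dplyr::bind_cols(
    tibble(site_id = sprintf("site_%03d", seq_len(n)),
           longitude = longitude, latitude = latitude, habitat = habitat,
           summer_temperature = summer_temperature,
           summer_precipitation = summer_precipitation,
           annual_temperature_range = annual_temperature_range,
           elevation = elevation),
    as_tibble(lc))
}

#' Climate, land-cover and space predictor blocks of a site table
#'
#' Convenience extractors returning the predictor tibbles used throughout
#' the analysis: four climate variables (summer temperature and
#' precipitation, annual temperature range, elevation), the 12 land-cover
#' proportions, and the planar coordinates.
#'
#' @param sites A site tibble.
#' @return A predictor tibble (`site_id` first).
#' @export
climate_block <- function(sites) {
  sites[c("site_id", "summer_temperature", "summer_precipitation",
          "annual_temperature_range", "elevation")]
}

#' @rdname climate_block
#' @export
landcover_block <- function(sites) {
  sites[c("site_id", paste0("lc_", landcover_classes))]
}

#' @rdname climate_block
#' @export
space_block <- function(sites) {
  sites[c("site_id", "longitude", "latitude")]
}

# latent site environment on the six indicator grids (columns L T K F R N)
site_env_grid <- function(sites) {
  forest <- sites$lc_coniferous_forest + sites$lc_deciduous_forest +
    sites$lc_mixed_forest
  open_fertile <- sites$lc_annual_crop + sites$lc_managed_grassland +
    sites$lc_settlement
  cbind(L = 9 - 8 * forest,
        T = rescale_range(sites$summer_temperature, 1, 9),
        K = rescale_range(sites$annual_temperature_range, 1, 9),
        F = rescale_range(sites$summer_precipitation, 1, 11),
        R = rescale_range(-sites$elevation, 1, 9),
        N = rescale_range(open_fertile, 1, 9))
}

#' Generate a niche-structured plant community with indicator values
#'
#' Each species gets niche optima on the six indicator grids; its
#' occurrence probability at a site is a logistic function of the squared
#' environmental distance between the site's latent conditions and those
#' optima (Gaussian niche on the logit scale). Indicator values are the
#' optima rounded onto the class grid, with a configurable fraction set
#' missing. With `niche_breadth = Inf` the niches are flat and occurrence
#' is independent of the environment.
#'
#' @param sites Site tibble from [generate_sites()].
#' @param config A [synthetic_config()].
#' @return List with `community` (plant community tibble) and `attrs`
#'   (plant attribute tibble: `species_id`, `genus`, `family`, `L` ...
#'   `N`).
#' @export
generate_plants <- function(sites, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!nrow(sites)) {
    abort("`sites` is empty.", class = "betadrivers_config_error")
  }
  local_seed(derive_seed(config$seed, 202))
  n_sp <- config$n_plant_species
  grids <- indicator_grids()
  env <- site_env_grid(sites)
  mu <- vapply(names(grids), function(ind) {
    runif(n_sp, min(grids[[ind]]), max(grids[[ind]]))
  }, numeric(n_sp))
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = n_sp)
  alpha <- qlogis(runif(n_sp, 0.25, 0.75))
  sigma2 <- config$niche_breadth^2
  penalty <- if (is.finite(sigma2)) {
    # sites x species: sum_k (E - mu)^2 / (2 sigma^2)
    e2 <- rowSums(env^2)
    m2 <- rowSums(mu^2)
    (outer(e2, m2, "+") - 2 * env %*% t(mu)) / (2 * sigma2)
  } else {
    matrix(0, nrow(env), n_sp)
  }
  p <- plogis(sweep(-penalty, 2, alpha, "+"))
  occ <- matrix(rbinom(length(p), 1, p), nrow(p), ncol(p))
  species_id <- sprintf("plant_%03d", seq_len(n_sp))
  dimnames(occ) <- list(sites$site_id, species_id)
  if (config$richness_floor >= 1) {
    for (i in which(rowSums(occ) < config$richness_floor)) {
      need <- config$richness_floor - sum(occ[i, ])
      occ[i, order(p[i, ], decreasing = TRUE)[seq_len(need)]] <- 1
    }
  }
  n_gen <- max(1L, ceiling(n_sp / 3))
  genus <- sprintf("Genus_%03d", sample(rep_len(seq_len(n_gen), n_sp)))
  n_fam <- max(1L, ceiling(n_gen / 4))
  fam_of_gen <- sample(rep_len(seq_len(n_fam), n_gen))
  family <- sprintf("Family_%02d",
                    fam_of_gen[as.integer(sub("Genus_", "", genus))])
  values <- round(mu)
  for (j in seq_along(grids)) {
    values[, j] <- pmin(pmax(values[, j], min(grids[[j]])),
                        max(grids[[j]]))
  }
  miss <- matrix(runif(n_sp * length(grids)) <
                   config$missing_indicator_fraction,
                 n_sp, length(grids))
  values[miss] <- NA
  attrs <- dplyr::bind_cols(
    tibble(species_id = species_id, genus = genus, family = family),
    as_tibble(matrix(values, n_sp, length(grids),
                     dimnames = list(NULL, names(grids)))))
  list(community = as_community(occ), attrs = attrs)
}

#' Generate arthropod occurrences with known causal structure
#'
#' Assigns each taxon an order, functional groups (lepidopteran
#' herbivores are also pollinators), monophagy with a host genus, and an
#' identification confidence. The per-taxon occurrence logit is a
#' weighted sum of standardized site scores derived from plant
#' composition (leading principal coordinates of the plant Sorensen
#' matrix), land cover, climate, space and pure noise, with the weights
#' taken from the taxon's functional-group entry in
#' `config$driver_weights`. Monophages that require their host (with
#' probability `host_dependence`) occur only at sites where at least one
#' plant of their host genus occurs.
#'
#' @param sites Site tibble.
#' @param plants Plant community tibble aligned to `sites`.
#' @param plant_attrs Plant attribute tibble.
#' @param config A [synthetic_config()].
#' @return List with `community` (arthropod community tibble) and
#'   `traits` (arthropod trait tibble).
#' @export
generate_arthropods <- function(sites, plants, plant_attrs, config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_community(plants, "plants")
  if (!setequal(sites$site_id, plants$site_id)) {
    abort("`plants` sites do not match `sites`.",
          class = "betadrivers_alignment_error")
  }
  plants <- plants[match(sites$site_id, plants$site_id), ]
  local_seed(derive_seed(config$seed, 303))
  n <- nrow(sites)
  n_t <- config$n_arthropod_taxa

  orders <- sample(c("Lepidoptera", "Coleoptera", "Hymenoptera",
                     "Diptera", "other"), n_t, replace = TRUE,
                   prob = c(0.15, 0.15, 0.25, 0.35, 0.10))
  primary <- sample(c(known_functional_groups, "none"), n_t,
                    replace = TRUE,
                    prob = c(0.42, 0.07, 0.13, 0.18, 0.13, 0.07))
  fg <- lapply(seq_len(n_t), function(i) {
    g <- setdiff(primary[i], "none")
    if (orders[i] == "Lepidoptera" && "herbivore" %in% g) {
      g <- union(g, "pollinator")
    }
    g
  })
  herb <- vapply(fg, function(g) "herbivore" %in% g, logical(1))
  mono <- herb & runif(n_t) < config$monophage_fraction
  genera <- unique(plant_attrs$genus)
  host_genus <- rep(NA_character_, n_t)
  host_genus[mono] <- sample(genera, sum(mono), replace = TRUE)
  requires_host <- mono & runif(n_t) < config$host_dependence
  u <- runif(n_t)
  id_confidence <- ifelse(u < 0.9, runif(n_t, 0.97, 1),
                          runif(n_t, 0.5, 0.97))

  std <- function(m) {
    m <- as.matrix(m)
    keep <- apply(m, 2, sd) > 0
    scale(m[, keep, drop = FALSE])
  }
  pm <- cm_matrix(plants)
  plant_scores <- if (nrow(pm) >= 3 && any(colSums(pm) > 0)) {
    ax <- pcoa_axes(sorensen_matrix(plants),
                    max_axes = config$n_plant_axes)
    std(ax[-1])
  } else {
    matrix(0, n, 0)
  }
  score_sets <- list(
    plants = plant_scores,
    landcover = std(landcover_block(sites)[-1]),
    climate = std(climate_block(sites)[-1]),
    space = std(space_block(sites)[-1]))

  taxon_score <- function(zs, i) {
    w <- config$driver_weights[[if (primary[i] == "none") "none"
                                else primary[i]]]
    latent <- rep(0, n)
    for (dn in names(score_sets)) {
      z <- score_sets[[dn]]
      if (w[dn] > 0 && ncol(z) > 0) {
        beta <- rnorm(ncol(z))
        s <- drop(z %*% beta)
        s_sd <- sd(s)
        if (s_sd > 0) latent <- latent + w[dn] * s / s_sd
      }
    }
    if (w["noise"] > 0) latent <- latent + w["noise"] * rnorm(n)
    l_sd <- sd(latent)
    if (l_sd > 0) latent <- config$signal_strength * latent / l_sd
    latent
  }
  prev <- runif(n_t, 0.15, 0.5)
  occ <- matrix(0, n, n_t)
  for (i in seq_len(n_t)) {
    p <- plogis(qlogis(prev[i]) + taxon_score(NULL, i))
    occ[, i] <- rbinom(n, 1, p)
  }

  # host masking: a monophage that requires its host occurs only with it
  genus_of <- plant_attrs$genus[match(colnames(pm), plant_attrs$species_id)]
  for (i in which(requires_host)) {
    cols <- which(genus_of == host_genus[i])
    present <- if (length(cols)) {
      rowSums(pm[, cols, drop = FALSE]) > 0
    } else {
      rep(FALSE, n)
    }
    occ[, i] <- occ[, i] * as.numeric(present)
  }

  taxon_id <- sprintf("arth_%04d", seq_len(n_t))
  dimnames(occ) <- list(sites$site_id, taxon_id)
  traits <- tibble(
    taxon_id = taxon_id, order = orders,
    functional_groups = vapply(fg, paste, character(1), collapse = ";"),
    monophagous = mono, host_genus = host_genus,
    id_confidence = id_confidence)
  list(community = as_community(occ), traits = traits)
}

#' Simulate a full synthetic study
#'
#' Runs the three generator stages in order and returns every table the
#' downstream analysis needs. Identical configs (including the seed)
#' yield bit-identical output.
#'
#' @param config A [synthetic_config()].
#' @return List: `sites`, `plants`, `plant_attrs`, `arthropods`,
#'   `traits`, `config`.
#' @export
simulate_study <- function(config = synthetic_config()) {
  sites <- generate_sites(config)
  pl <- generate_plants(sites, config)
  ar <- generate_arthropods(sites, pl$community, pl$attrs, config)
  list(sites = sites, plants = pl$community, plant_attrs = pl$attrs,
       arthropods = ar$community, traits = ar$traits, config = config)
}
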