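test_that("the generator is deterministic and structurally valid", {
  cfg <- synthetic_config(n_sites = 20, n_plant_species = 40,
                          n_arthropod_taxa = 60, seed = 5)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$sites, b$sites)
  expect_identical(a$plants, b$plants)
  expect_identical(a$plant_attrs, b$plant_attrs)
  expect_identical(a$arthropods, b$arthropods)
  expect_identical(a$traits, b$traits)

  lc <- as.matrix(a$sites[paste0("lc_",
                                 betadrivers:::landcover_classes)])
  expect_lt(max(abs(rowSums(lc) - 1)), 1e-9)
  expect_false(anyDuplicated(a$sites$site_id) > 0)
  # binary matrices, shared site axis
  expect_true(all(as.matrix(a$plants[-1]) %in% 0:1))
  expect_true(all(as.matrix(a$arthropods[-1]) %in% 0:1))
  expect_identical(a$plants$site_id, a$sites$site_id)
  expect_identical(a$arthropods$site_id, a$sites$site_id)
  # richness floor keeps every site occupied
  expect_true(all(rowSums(a$plants[-1]) >= 1))
  # indicator values on the grid or missing
  for (ind in names(indicator_grids())) {
    v <- a$plant_attrs[[ind]]
    expect_true(all(is.na(v) | v %in% indicator_grids()[[ind]]))
  }
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(n_sites = 4),
               class = "betadrivers_config_error")
  expect_error(synthetic_config(monophage_fraction = 1.2),
               class = "betadrivers_config_error")
  expect_error(synthetic_config(driver_weights = c(plants = -1)),
               class = "betadrivers_config_error")
  expect_error(synthetic_config(driver_weights = c(bogus = 1)),
               class = "betadrivers_config_error")
  # per-group weights with fallback
  cfg <- synthetic_config(driver_weights = list(
    herbivore = c(plants = 1, noise = 0.5),
    default = c(climate = 1, noise = 1)))
  expect_equal(cfg$driver_weights$herbivore[["plants"]], 1)
  expect_equal(cfg$driver_weights$predator[["climate"]], 1)
})

test_that("habitat drives land cover in the configured direction", {
  cfg <- synthetic_config(n_sites = 200, n_plant_species = 10,
                          n_arthropod_taxa = 10, seed = 9)
  sites <- generate_sites(cfg)
  forest_prop <- sites$lc_coniferous_forest + sites$lc_deciduous_forest +
    sites$lc_mixed_forest
  expect_gt(mean(forest_prop[sites$habitat == "forest"]),
            mean(forest_prop[sites$habitat == "arable"]))
  expect_gt(mean(sites$lc_annual_crop[sites$habitat == "arable"]),
            mean(sites$lc_annual_crop[sites$habitat == "forest"]))
})

test_that("flat plant niches erase the plant-climate association", {
  rs <- vapply(1:20, function(s) {
    cfg <- synthetic_config(n_sites = 60, n_plant_species = 80,
                            n_arthropod_taxa = 10,
                            niche_breadth = Inf, seed = s)
    sites <- generate_sites(cfg)
    pl <- generate_plants(sites, cfg)
    dp <- quiet(sorensen_matrix(pl$community))
    dc <- euclidean_matrix(max_standardize(climate_block(sites)))
    cor(dp[lower.tri(dp)], unclass(dc)[lower.tri(dc)])
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("missing-value fraction zero gives a complete attribute table", {
  cfg <- synthetic_config(n_sites = 12, n_plant_species = 30,
                          n_arthropod_taxa = 10,
                          missing_indicator_fraction = 0, seed = 2)
  pl <- generate_plants(generate_sites(cfg), cfg)
  expect_false(anyNA(pl$attrs[names(indicator_grids())]))
})

test_that("full host dependence confines monophages to host-genus sites", {
  cfg <- synthetic_config(n_sites = 30, n_plant_species = 60,
                          n_arthropod_taxa = 120,
                          monophage_fraction = 0.5, host_dependence = 1,
                          seed = 4)
  sim <- simulate_study(cfg)
  pm <- as.matrix(sim$plants[-1])
  am <- as.matrix(sim$arthropods[-1])
  genus <- sim$plant_attrs$genus[match(colnames(pm),
                                       sim$plant_attrs$species_id)]
  for (i in which(sim$traits$monophagous)) {
    host_cols <- genus == sim$traits$host_genus[i]
    host_present <- rowSums(pm[, host_cols, drop = FALSE]) > 0
    occupied <- am[, sim$traits$taxon_id[i]] == 1
    expect_true(all(host_present[occupied]))
  }
  # trait invariants
  expect_true(all(!sim$traits$monophagous |
                    !is.na(sim$traits$host_genus)))
  lep_herb <- grepl("herbivore", sim$traits$functional_groups) &
    sim$traits$order == "Lepidoptera"
  expect_true(all(grepl("pollinator",
                        sim$traits$functional_groups[lep_herb])))
  expect_error(
    generate_arthropods(sim$sites[-1, ], sim$plants, sim$plant_attrs,
                        cfg),
    class = "betadrivers_alignment_error")
})

test_that("a zeroed driver earns a near-zero unique fraction at scale", {
  # climate weight zero for every group: its unique 4-set fraction
  # should vanish on average over seeds at n_sites = 120
  fr <- vapply(1:6, function(s) {
    cfg <- synthetic_config(n_sites = 120, n_plant_species = 100,
                            n_arthropod_taxa = 150,
                            driver_weights = c(plants = 1, landcover = 0.5,
                                               space = 0.1, noise = 1),
                            seed = s)
    sim <- simulate_study(cfg)
    d <- quiet(sorensen_matrix(sim$arthropods))
    vp <- varpart(d, list(
      plants = quiet(sorensen_matrix(sim$plants)),
      landcover = euclidean_matrix(landcover_block(sim$sites)),
      climate = euclidean_matrix(max_standardize(climate_block(sim$sites))),
      space = euclidean_matrix(space_block(sim$sites))),
      max_axes = 8)
    vp$independent[["climate"]]
  }, numeric(1))
  expect_lte(mean(fr), 0.01)
})
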