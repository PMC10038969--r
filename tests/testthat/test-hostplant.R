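make_small_study <- function(seed = 1) {
  cfg <- synthetic_config(n_sites = 30, n_plant_species = 60,
                          n_arthropod_taxa = 90,
                          monophage_fraction = 0.4, seed = seed)
  sim <- simulate_study(cfg)
  herb <- subset_by_group(sim$arthropods, sim$traits, "herbivore")
  list(sim = sim,
       d = quiet(sorensen_matrix(herb)),
       prof = quiet(indicator_frequency_matrix(sim$plants,
                                               sim$plant_attrs)),
       hosts = host_plant_subset(sim$plants, sim$plant_attrs,
                                 sim$traits))
}

test_that("the plant-unique fraction is the two-fit adjusted-R2 difference", {
  st <- make_small_study(3)
  got <- quiet(independent_plant_fraction(st$d, st$hosts, st$prof,
                                          max_axes = 6))
  plant_axes <- pcoa_axes(quiet(sorensen_matrix(st$hosts)), max_axes = 6)
  ind_axes <- pcoa_axes(euclidean_matrix(st$prof), max_axes = 6)
  both <- dplyr::inner_join(plant_axes, ind_axes, by = "site_id",
                            suffix = c(".p", ".i"))
  direct <- dbrda_fit(st$d, both)$adj_r2 - dbrda_fit(st$d, ind_axes)$adj_r2
  expect_equal(got, direct, tolerance = 1e-10)
  expect_error(independent_plant_fraction(st$d, st$sim$plants["site_id"],
                                          st$prof),
               class = "betadrivers_data_error")
})

test_that("random subsets have the right size, stream, and t statistics", {
  st <- make_small_study(5)
  nn <- quiet(random_subset_null(st$d, st$sim$plants, st$prof, st$hosts,
                                 n_reps = 12, seed = 11, max_axes = 6))
  expect_length(nn$null_samples, 12)
  expect_identical(nn$subset_size, ncol(st$hosts) - 1L)
  expect_identical(nn$dof, 11L)
  again <- quiet(random_subset_null(st$d, st$sim$plants, st$prof,
                                    st$hosts, n_reps = 12, seed = 11,
                                    max_axes = 6))
  expect_identical(nn$null_samples, again$null_samples)

  # t and p agree with the standard one-sample test against the observed
  ref <- t.test(nn$null_samples, mu = nn$observed)
  expect_equal(nn$t_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(nn$p_value, ref$p.value, tolerance = 1e-12)
  # direct formula from the spec of the statistic
  expect_equal(nn$t_statistic,
               (mean(nn$null_samples) - nn$observed) /
                 (sd(nn$null_samples) / sqrt(12)), tolerance = 1e-12)
})

test_that("the null summary reproduces moments and significance stars", {
  obj <- structure(list(observed = 0.07,
                        null_samples = c(0.04, 0.05, 0.06, 0.05),
                        subset_size = 10L, t_statistic = -4.9,
                        p_value = 0.009, dof = 3L, z_score = 2.4,
                        seed = 1L),
                   class = "hostplant_null")
  s <- summarize_null(obj)
  expect_equal(s$null_mean, mean(obj$null_samples))
  expect_equal(s$null_sd, sd(obj$null_samples))
  expect_identical(s$stars, "**")
  obj$p_value <- 0.04
  expect_identical(summarize_null(obj)$stars, "*")
  obj$p_value <- 0.0005
  expect_identical(summarize_null(obj)$stars, "***")
  obj$p_value <- 0.2
  expect_identical(summarize_null(obj)$stars, "")
})

test_that("hostplant-null plumbing rejects impossible requests", {
  st <- make_small_study(7)
  expect_error(quiet(random_subset_null(st$d, st$sim$plants, st$prof,
                                        st$hosts, subset_size = 1000,
                                        n_reps = 5)),
               class = "betadrivers_config_error")
  expect_error(quiet(random_subset_null(st$d, st$sim$plants, st$prof,
                                        st$hosts, n_reps = 1)),
               class = "betadrivers_config_error")
})

test_that("a redundant plant subset adds nothing beyond the indicators", {
  # indicators as the sole environmental driver; plants pure noise:
  # the plant-unique fraction should sit near zero
  fr <- vapply(1:8, function(s) {
    cfg <- synthetic_config(n_sites = 40, n_plant_species = 60,
                            n_arthropod_taxa = 80,
                            niche_breadth = Inf,
                            driver_weights = c(climate = 1, noise = 1),
                            seed = 100 + s)
    sim <- simulate_study(cfg)
    d <- quiet(sorensen_matrix(sim$arthropods))
    prof <- quiet(indicator_frequency_matrix(sim$plants,
                                             sim$plant_attrs))
    quiet(independent_plant_fraction(d, sim$plants, prof,
                                     max_axes = 6))
  }, numeric(1))
  expect_lt(abs(mean(fr)), 0.02)
})
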