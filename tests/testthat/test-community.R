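test_that("aggregate_periods unions occurrences over the union taxon set", {
  p1 <- as_community(matrix(1, 1, 1, dimnames = list("s1", "A")))
  p2 <- as_community(matrix(1, 1, 1, dimnames = list("s1", "B")))
  p3 <- as_community(matrix(1, 1, 1, dimnames = list("s1", "A")))
  out <- aggregate_periods(list(p1, p2, p3))
  expect_identical(sort(names(out)[-1]), c("A", "B"))
  expect_true(all(out[-1] == 1))

  one <- rand_community(6, 10, seed = 4)
  expect_identical(aggregate_periods(list(one))[names(one)], one)

  periods <- lapply(1:3, function(s) rand_community(20, 50, seed = s))
  agg <- as.matrix(aggregate_periods(periods)[-1])
  expected <- Reduce(pmax, lapply(periods, function(p) {
    as.matrix(p[-1])[, colnames(agg)]
  }))
  expect_equal(unname(agg), unname(expected))
})

test_that("period aggregation is idempotent, monotone, and id-matched", {
  x <- rand_community(10, 15, seed = 7)
  again <- aggregate_periods(list(x, x))
  expect_equal(as.matrix(again[-1]), as.matrix(x[names(again)[-1]]))
  y <- rand_community(10, 15, seed = 8)
  u <- aggregate_periods(list(x, y))
  expect_true(all(as.matrix(u[-1])[, names(x)[-1]] >= as.matrix(x[-1])))

  shuffled <- y[sample(nrow(y)), ]
  expect_equal(as.matrix(aggregate_periods(list(x, shuffled))[-1]),
               as.matrix(u[-1]))

  z <- rand_community(9, 15, seed = 9)  # different site count
  expect_error(aggregate_periods(list(x, z)),
               class = "betadrivers_alignment_error")
})

test_that("combine_surveys unions species and is commutative", {
  a <- as_community(matrix(c(1, 0, 1, 1), 2, 2,
                           dimnames = list(c("s1", "s2"), c("A", "B"))))
  b <- as_community(matrix(c(1, 1, 0, 1), 2, 2,
                           dimnames = list(c("s1", "s2"), c("B", "C"))))
  out <- combine_surveys(a, b)
  expect_identical(sort(names(out)[-1]), c("A", "B", "C"))

  empty <- a["site_id"]
  expect_equal(as.matrix(combine_surveys(a, empty)[-1]),
               as.matrix(a[-1]))

  for (s in 1:50) {
    x <- rand_community(5, 8, p = 0.5, seed = s)
    y <- rand_community(5, 8, p = 0.5, seed = s + 100)
    names(y)[-1] <- sprintf("oth%02d", 1:8)
    expect_identical(combine_surveys(x, y), combine_surveys(y, x))
  }
})

test_that("group subsets follow trait membership, incl. dual Lepidoptera", {
  cm <- rand_community(6, 4, seed = 2)
  names(cm)[-1] <- c("lep1", "col1", "dip1", "non1")
  traits <- tibble::tibble(
    taxon_id = c("lep1", "col1", "dip1", "non1"),
    order = c("Lepidoptera", "Coleoptera", "Diptera", "Diptera"),
    functional_groups = c("herbivore;pollinator", "predator",
                          "detritivore", ""),
    monophagous = FALSE, host_genus = NA_character_,
    id_confidence = 0.99)
  expect_identical(names(subset_by_group(cm, traits, "herbivore"))[-1],
                   "lep1")
  expect_identical(names(subset_by_group(cm, traits, "pollinator"))[-1],
                   "lep1")
  expect_identical(names(subset_by_group(cm, traits, "Lepidoptera"))[-1],
                   "lep1")
  # unclassified taxa excluded from all functional subsets, kept in orders
  expect_false("non1" %in% unlist(lapply(
    c("herbivore", "pollinator", "predator", "parasitoid", "detritivore"),
    function(g) names(subset_by_group(cm, traits, g)))))
  expect_true("non1" %in% names(subset_by_group(cm, traits, "Diptera")))
  # empty group yields a 0-column matrix; unknown label errors
  expect_identical(ncol(subset_by_group(cm, traits, "parasitoid")), 1L)
  expect_error(subset_by_group(cm, traits, "omnivore"),
               class = "betadrivers_lookup_error")
  expect_identical(subset_by_group(cm, traits, "predator")$site_id,
                   cm$site_id)
})

test_that("order subsets match a direct filter oracle on random traits", {
  set.seed(11)
  cm <- rand_community(8, 40, seed = 11)
  traits <- make_traits(names(cm)[-1],
                        order = sample(c("Lepidoptera", "Coleoptera",
                                         "Hymenoptera", "Diptera", "other"),
                                       40, replace = TRUE))
  all_order_taxa <- character(0)
  for (o in c("Lepidoptera", "Coleoptera", "Hymenoptera", "Diptera")) {
    got <- names(subset_by_group(cm, traits, o))[-1]
    expect_identical(got, traits$taxon_id[traits$order == o])
    all_order_taxa <- c(all_order_taxa, got)
  }
  expect_true(all(all_order_taxa %in% names(cm)[-1]))
})

test_that("confidence filtering is inclusive at the boundary", {
  traits <- make_traits(c("a", "b", "c"),
                        id_confidence = c(0.99, 0.97, 0.90))
  expect_identical(filter_confident_taxa(traits), c("a", "b"))
  expect_error(filter_confident_taxa(traits, 0),
               class = "betadrivers_config_error")
  set.seed(5)
  tr <- make_traits(sprintf("t%02d", 1:30), id_confidence = runif(30))
  thr <- 0.6
  expect_identical(filter_confident_taxa(tr, thr),
                   tr$taxon_id[tr$id_confidence >= thr])
})

test_that("host-plant subset keeps exactly the host-genus species", {
  plants <- rand_community(5, 3, seed = 3)
  names(plants)[-1] <- c("Quercus_robur", "Quercus_petraea",
                         "Fagus_sylvatica")
  attrs <- tibble::tibble(
    species_id = names(plants)[-1],
    genus = c("Quercus", "Quercus", "Fagus"),
    family = "Fagaceae", L = 5, T = 5, K = 5, F = 5, R = 5, N = 5)
  traits <- make_traits("moth1", monophagous = TRUE,
                        host_genus = "Quercus")
  out <- host_plant_subset(plants, attrs, traits)
  expect_identical(sort(names(out)[-1]),
                   c("Quercus_petraea", "Quercus_robur"))
  # no monophages -> zero species columns
  none <- host_plant_subset(plants, attrs,
                            make_traits("fly1", monophagous = FALSE))
  expect_identical(ncol(none), 1L)
  # low-confidence monophages do not define hosts
  lowconf <- make_traits("moth1", monophagous = TRUE,
                         host_genus = "Quercus", id_confidence = 0.5)
  expect_identical(ncol(host_plant_subset(plants, attrs, lowconf)), 1L)
  # monophage without a host genus is a data error
  bad <- make_traits("moth2", monophagous = TRUE)
  expect_error(host_plant_subset(plants, attrs, bad),
               class = "betadrivers_data_error")
})
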