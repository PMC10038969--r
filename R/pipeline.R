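#' Configuration for a full attribution run
#'
#' Collects everything [run_full_analysis()] needs: the synthetic
#' generator configuration (or a directory of input tables written in the
#' package's CSV layout), the arthropod groups to analyze, permutation
#' and replication counts, the principal-coordinate axis policy, and the
#' master seed.
#'
#' @param synthetic A [synthetic_config()]; ignored when `input_dir` is
#'   given.
#' @param input_dir Optional directory readable by [read_study()].
#' @param groups Arthropod groups: functional groups and/or orders
#'   (default all five functional groups and four orders).
#' @param n_perm Mantel permutations (default 199).
#' @param n_reps Host-plant null replicates (default 100; the full-study
#'   convention is 1000 — a scaled-down run is flagged in the manifest).
#' @param max_axes Principal-coordinate cap per distance-matrix predictor
#'   set (default 8).
#' @param seed Master seed; every stochastic stage derives its stream
#'   from it.
#' @return A `run_config` list.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       input_dir = NULL,
                       groups = c(known_functional_groups, known_orders),
                       n_perm = 199, n_reps = 100, max_axes = 8,
                       seed = 1) {
  unknown <- setdiff(groups, c(known_functional_groups, known_orders))
  if (length(unknown)) {
    abort(sprintf("Unknown group label(s): %s.",
                  paste(unknown, collapse = ", ")),
          class = "betadrivers_config_error")
  }
  if (!length(groups)) {
    abort("`groups` must be nonempty.",
          class = "betadrivers_config_error")
  }
  structure(list(synthetic = synthetic, input_dir = input_dir,
                 groups = groups,
                 n_perm = stopifnot_scalar_int(n_perm, "n_perm"),
                 n_reps = stopifnot_scalar_int(n_reps, "n_reps", min = 2L),
                 max_axes = max_axes,
                 seed = stopifnot_scalar_int(seed, "seed", min = 0L)),
            class = "run_config")
}

stage <- function(name, expr, warnings_env) {
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)),
            class = "betadrivers_stage_error", parent = e)
    }),
    warning = function(w) {
      warnings_env$log <- c(warnings_env$log,
                            sprintf("[%s] %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
}

#' Run the full attribution analysis
#'
#' Orchestrates the whole pipeline on synthetic or loaded data: builds
#' the response dissimilarity per arthropod group (Sorensen), the four
#' predictor dissimilarities (plant Sorensen; Euclidean land cover,
#' max-standardized climate, space), the Ellenberg indicator profile and
#' its Euclidean distances, then per group a 4-set variation
#' partitioning (plants, landcover, climate, space), a 2-set partitioning
#' (plants, indicators), Mantel correlations against each single
#' indicator and the full indicator set, and the host-plant randomization
#' null (the host subset defined once, from monophagous confident
#' herbivores, and applied to every group's response). All result tables
#' are written as CSV/JSON plus a manifest with file hashes; runs are
#' deterministic given the seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with all in-memory results and
#'   `manifest_path`.
#' @export
run_full_analysis <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wenv <- new.env()
  wenv$log <- character(0)

  study <- stage("load", {
    if (!is.null(config$input_dir)) {
      read_study(config$input_dir)
    } else {
      cfg <- config$synthetic
      cfg$seed <- derive_seed(config$seed, 11)
      simulate_study(cfg)
    }
  }, wenv)

  preds <- stage("distances", {
    profile <- indicator_frequency_matrix(study$plants,
                                          study$plant_attrs)
    list(profile = profile,
         plants = sorensen_matrix(study$plants),
         landcover = euclidean_matrix(landcover_block(study$sites)),
         climate = euclidean_matrix(
           max_standardize(climate_block(study$sites))),
         space = euclidean_matrix(space_block(study$sites)),
         indicators = euclidean_matrix(profile))
  }, wenv)

  host_plants <- stage("hostplants", {
    host_plant_subset(study$plants, study$plant_attrs, study$traits)
  }, wenv)

  results <- list()
  for (g in config$groups) {
    sub <- stage(paste0("subset:", g), {
      cm <- subset_by_group(study$arthropods, study$traits, g)
      if (ncol(cm) < 3) {
        abort(sprintf("Group '%s' has %d taxa; too few to analyze.",
                      g, ncol(cm) - 1))
      }
      cm
    }, wenv)
    d <- stage(paste0("sorensen:", g), sorensen_matrix(sub), wenv)

    vp4 <- stage(paste0("varpart4:", g), {
      varpart(d, list(plants = preds$plants, landcover = preds$landcover,
                      climate = preds$climate, space = preds$space),
              max_axes = config$max_axes)
    }, wenv)
    vp2 <- stage(paste0("varpart2:", g), {
      varpart(d, list(plants = preds$plants,
                      indicators = preds$indicators),
              max_axes = config$max_axes)
    }, wenv)
    mant <- stage(paste0("mantel:", g), {
      cats <- c(stats::setNames(names(indicator_grids()),
                                names(indicator_grids())),
                all = "all")
      purrr::imap_dfr(cats, function(cat, label) {
        dm <- if (cat == "all") preds$indicators else
          euclidean_matrix(single_indicator_block(preds$profile, cat))
        res <- mantel_test(d, dm, n_perm = config$n_perm,
                           seed = derive_seed(config$seed,
                                              match(label, names(cats))))
        tibble(group = g, indicator = label, estimate = res$r,
               p.value = res$p)
      })
    }, wenv)
    null <- stage(paste0("hostplant-null:", g), {
      random_subset_null(d, study$plants, preds$profile, host_plants,
                         n_reps = config$n_reps,
                         seed = derive_seed(config$seed, 977),
                         max_axes = config$max_axes)
    }, wenv)
    results[[g]] <- list(varpart4 = vp4, varpart2 = vp2, mantel = mant,
                         hostplant_null = null)
  }

  files <- stage("write", {
    write_results(results, preds, config, out_dir)
  }, wenv)
  manifest_path <- write_manifest(
    file.path(out_dir, "run_manifest.json"),
    config = list(groups = config$groups, n_perm = config$n_perm,
                  n_reps = config$n_reps, max_axes = config$max_axes,
                  seed = config$seed,
                  scaled_down_null = config$n_reps < 1000,
                  synthetic = if (is.null(config$input_dir))
                    unclass(config$synthetic) else NULL,
                  input_dir = config$input_dir),
    files = files, seed = config$seed, warnings = wenv$log)
  invisible(list(results = results, study = study, predictors = preds,
                 warnings = wenv$log, manifest_path = manifest_path))
}

varpart_json <- function(vp) {
  list(set_labels = vp$set_labels,
       union_adj_r2 = as.list(vp$union_adj_r2),
       fractions = stats::setNames(as.list(vp$fractions$adj_r2),
                                   vp$fractions$region),
       independent = as.list(vp$independent),
       residual = vp$residual, n = vp$n)
}

write_results <- function(results, preds, config, out_dir) {
  p_vp4 <- file.path(out_dir, "varpart_4set.json")
  jsonlite::write_json(lapply(results, function(r) varpart_json(r$varpart4)),
                       p_vp4, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  p_vp2 <- file.path(out_dir, "varpart_2set.json")
  jsonlite::write_json(lapply(results, function(r) varpart_json(r$varpart2)),
                       p_vp2, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  frac_tbl <- purrr::imap_dfr(results, function(r, g) {
    dplyr::mutate(tidy(r$varpart4), group = g, .before = 1)
  })
  p_frac <- file.path(out_dir, "varpart_fractions.csv")
  utils::write.csv(frac_tbl, p_frac, row.names = FALSE, quote = FALSE)

  mant_tbl <- purrr::map_dfr(results, "mantel")
  mant_wide <- tidyr::pivot_wider(mant_tbl[c("group", "indicator",
                                             "estimate")],
                                  names_from = "indicator",
                                  values_from = "estimate")
  p_mant <- file.path(out_dir, "mantel_indicators.csv")
  utils::write.csv(mant_wide, p_mant, row.names = FALSE, quote = FALSE)

  null_tbl <- purrr::imap_dfr(results, function(r, g) {
    dplyr::mutate(summarize_null(r$hostplant_null),
                  group = g,
                  all_plants_fraction = r$varpart2$independent[["plants"]],
                  .before = 1)
  })
  p_null <- file.path(out_dir, "hostplant_null.csv")
  utils::write.csv(null_tbl, p_null, row.names = FALSE, quote = FALSE)

  cov <- attr(preds$profile, "coverage")
  p_cov <- file.path(out_dir, "indicator_coverage.csv")
  utils::write.csv(tibble(indicator = names(cov), coverage = cov),
                   p_cov, row.names = FALSE, quote = FALSE)

  c(varpart_4set = p_vp4, varpart_2set = p_vp2,
    varpart_fractions = p_frac, mantel_indicators = p_mant,
    hostplant_null = p_null, indicator_coverage = p_cov)
}
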