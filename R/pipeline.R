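#' Run the full functional-spectra pipeline
#'
#' Executes every stage in order: load or simulate the data; per-trait
#' phylogenetic signal and the missingness association test; 40-fold
#' chained-equations PMM imputation with phylogenetic eigenvectors;
#' preprocessing + phylogenetic PCA per imputed dataset and pooling; the TPD
#' functional space with HDR thresholding, quantile contours and hotspot
#' summary; extinction scenarios with randomisation null envelopes; and the
#' binomial risk/threat surfaces. Stage seeds are derived from the master
#' seed by fixed offsets (imputation `+1000`, scenarios `+2000`), so a rerun
#' with the same inputs reproduces every artifact.
#'
#' @param config A [sim_config()] for synthetic data, or `NULL` when `paths`
#'   is given.
#' @param paths Optional list with `tree`, `traits`, `meta` file paths
#'   (exactly one of `config`/`paths` must be supplied).
#' @param output_dir Optional directory; when given, CSV/YAML artifacts and a
#'   manifest are written there.
#' @param n_datasets,maxit,donors,k Imputation settings (see
#'   [impute_traits()]).
#' @param cells_per_dim,pad,q TPD settings (see [build_grid()],
#'   [hdr_threshold()]).
#' @param n_iter Null-model iterations per scenario.
#' @param scenarios Scenario labels to run.
#' @param seed Master seed (default `config$seed`, else 1).
#' @param fit_surfaces Also fit the binomial surfaces (default TRUE).
#' @return A list of class `"fs_pipeline"` with `data`, `lambda`,
#'   `missingness_test`, `imputations`, `ppca`, `space`, `bw`, `grid`, `tpd`,
#'   `contours`, `hotspot`, `scenarios`, `surfaces`, `continents`,
#'   `settings`.
#' @export
run_pipeline <- function(config = NULL, paths = NULL, output_dir = NULL,
                         n_datasets = 40, maxit = 15, donors = 5, k = NULL,
                         cells_per_dim = 200, pad = 3, q = 0.99,
                         n_iter = 999, scenarios = scenario_labels(),
                         seed = NULL, fit_surfaces = TRUE) {
  if (is.null(config) == is.null(paths)) {
    stop("supply exactly one of `config` (synthetic) or `paths` (files)")
  }
  t0 <- Sys.time()
  stage <- function(msg) message(sprintf("[%5.1fs] %s",
                                         as.numeric(Sys.time() - t0, units = "secs"), msg))

  if (!is.null(config)) {
    if (is.null(seed)) seed <- config$seed
    stage("simulating synthetic dataset")
    sim <- simulate_dataset(config)
    tree <- sim$tree; traits <- sim$traits; meta <- sim$meta
  } else {
    if (is.null(seed)) seed <- 1L
    stage("reading input files")
    ds <- read_dataset(paths$tree, paths$traits, paths$meta)
    sim <- NULL; tree <- ds$tree; traits <- ds$traits; meta <- ds$meta
  }
  bad <- setdiff(traits$species, tree$tip.label)
  if (length(bad)) stop("species missing from tree: ", paste(bad, collapse = ", "))
  tree <- ape::keep.tip(tree, traits$species)

  stage("per-trait phylogenetic signal (observed cells)")
  lam_tbl <- trait_lambda(traits, tree)
  n_missing <- rowSums(is.na(traits[focal_traits()]))
  status_group <- dplyr::case_when(
    is.na(meta$iucn) | meta$iucn == "DD" ~ "unknown",
    meta$iucn %in% c("CR", "EN", "VU") ~ "threatened",
    TRUE ~ "non-threatened"
  )
  miss_test <- kruskal_missingness_test(n_missing, status_group)

  stage(paste0("imputation (", n_datasets, " datasets)"))
  iset <- impute_traits(traits, tree, n_datasets = n_datasets, maxit = maxit,
                        donors = donors, k = k, seed = seed + 1000L)

  stage("phylogenetic PCA across imputations")
  ppca <- run_ppca(iset, tree)
  space <- ppca$space

  stage("TPD functional space")
  bw <- select_bandwidth(space)
  grid <- build_grid(space, cells_per_dim, pad, bw)
  tpd_all <- hdr_threshold(tpd_density(space, bw, grid), q)
  contours <- quantile_contours(tpd_all)
  hotspot <- hotspot_summary(tpd_all, space, q = 0.5)

  stage(paste0("extinction scenarios (", n_iter, " nulls each)"))
  scen <- run_scenarios(space, meta, scenarios = scenarios,
                        cells_per_dim = cells_per_dim, pad = pad, q = q,
                        n_iter = n_iter, seed = seed + 2000L,
                        bw = bw, grid = grid)

  surfaces <- NULL
  if (fit_surfaces) {
    stage("binomial risk surfaces")
    assessed <- !is.na(meta$iucn) & meta$iucn != "DD"
    high_risk <- ifelse(assessed, as.integer(meta$iucn %in% c("CR", "EN")), NA)
    surfaces <- list(high_risk = fit_risk_surface(space, high_risk))
    for (th in threat_names()) {
      surfaces[[th]] <- fit_risk_surface(space, meta[[th]])
    }
  }

  continents <- continent_threat_ratios(meta)
  settings <- list(seed = seed, n_datasets = n_datasets, maxit = maxit,
                   donors = donors, cells_per_dim = cells_per_dim, pad = pad,
                   q = q, n_iter = n_iter)
  out <- structure(list(
    data = list(tree = tree, traits = traits, meta = meta, sim = sim),
    lambda = lam_tbl, missingness_test = miss_test, imputations = iset,
    ppca = ppca, space = space, bw = bw, grid = grid, tpd = tpd_all,
    contours = contours, hotspot = hotspot, scenarios = scen,
    surfaces = surfaces, continents = continents, settings = settings
  ), class = "fs_pipeline")
  if (!is.null(output_dir)) write_pipeline(out, output_dir)
  stage("done")
  out
}

#' @export
print.fs_pipeline <- function(x, ...) {
  g <- glance(x$ppca$pooled)
  cat("<fs_pipeline>", nrow(x$space), "species;",
      x$imputations$n_datasets, "imputations\n")
  cat("  PC1", paste0(round(100 * g$pc1_var, 1), "%"),
      "PC2", paste0(round(100 * g$pc2_var, 1), "%"),
      "; pooled lambda", round(g$lambda, 3), "\n")
  cat("  hotspot:", round(100 * x$hotspot$species_fraction, 1),
      "% of species in", round(100 * x$hotspot$area_fraction, 1), "% of spectrum\n")
  iucn <- x$scenarios[x$scenarios$scenario %in% c("-CR", "-EN", "-VU", "-NT"), ]
  for (i in seq_len(nrow(iucn))) {
    cat(sprintf("  %s: loss %.1f%% (null %.1f [%.1f, %.1f])\n",
                iucn$scenario[i], iucn$loss_pct[i], iucn$null_p50[i],
                iucn$null_p5[i], iucn$null_p95[i]))
  }
  invisible(x)
}

#' Write the pipeline artifacts to a directory
#'
#' Writes the functional space, pooled loadings with pooling SEs, per-trait
#' lambda, scenario results, hotspot and continent summaries, the high-risk
#' surface grid, and a YAML manifest of seeds and settings.
#'
#' @param result An [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$space, file.path(dir, "functional_space.csv"))
  readr::write_csv(tidy(result$ppca), file.path(dir, "loadings.csv"))
  readr::write_csv(result$lambda, file.path(dir, "trait_lambda.csv"))
  readr::write_csv(result$scenarios, file.path(dir, "scenarios.csv"))
  readr::write_csv(result$hotspot, file.path(dir, "hotspot.csv"))
  readr::write_csv(result$continents, file.path(dir, "continent_threats.csv"))
  if (!is.null(result$surfaces)) {
    readr::write_csv(predict_surface(result$surfaces$high_risk),
                     file.path(dir, "risk_surface.csv"))
  }
  g <- glance(result$ppca$pooled)
  manifest <- c(result$settings, list(
    n_species = nrow(result$space),
    pooled_lambda = g$lambda,
    pc1_var = g$pc1_var, pc2_var = g$pc2_var,
    written = format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  ))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
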