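#' Configuration for the synthetic chelonian/crocodilian world
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the statistical structure of the real study system: 259 species, traits
#' evolved under Brownian motion with strong phylogenetic signal, allometric
#' dependence on body mass, 38% missingness in the imputable traits (higher
#' for threatened species), IUCN category counts 46/36/49/25/51 (CR/EN/VU/NT/
#' LC) plus 7 DD and 45 unassessed species, 8 species with unknown threats,
#' and per-continent sample sizes with fixed threatened fractions.
#'
#' @param n_species Number of extant tips to simulate (>= 4).
#' @param birth_rate,death_rate Birth-death rates per unit time
#'   (`death_rate < birth_rate`).
#' @param lambda_true Pagel's lambda used to generate traits, in `[0, 1]`.
#' @param sigma2 Named per-trait Brownian rate (variance accrued over one unit
#'   of tree height; trees are rescaled to unit height).
#' @param allometry_slopes Named per-trait slope on centred log body mass
#'   (transformed scale).
#' @param trait_loadings Trait x 2 matrix of loadings on two latent Brownian
#'   factors (a fast-slow "pace" factor and a clutch-frequency vs clutch-size
#'   trade-off), inducing cross-trait correlation beyond allometry while
#'   keeping each trait's marginal covariance exactly `sigma2 * C(lambda)`.
#' @param trait_means Named per-trait mean on the transformed scale
#'   (log, or logit for the survival probabilities).
#' @param missing_rate Baseline fraction of maskable trait cells set missing.
#' @param missing_bias Additive log-odds of missingness for threatened species.
#' @param status_coefs Length-3 coefficients (intercept, PC1, PC2) of the
#'   latent logistic risk score that orders species into IUCN categories.
#' @param threat_coefs 6 x 3 matrix of per-threat logistic coefficients
#'   (intercept, PC1, PC2); rows named by threat.
#' @param iucn_counts Named category quota (CR, EN, VU, NT, LC, DD); scaled
#'   proportionally when `n_species` differs from the default total.
#' @param unassessed_n Number of species without an IUCN category (scaled
#'   with `n_species` like the quotas).
#' @param threat_unknown_n Number of species with unknown threat flags
#'   (scaled likewise).
#' @param continent_unknown_n Number of species with unknown continent
#'   (scaled likewise).
#' @param continent_table Data frame with `continent`, `n`,
#'   `threatened_frac` (the per-continent share of threatened species), or
#'   `NULL` for a uniform continent label.
#' @param seed Integer master seed; each generator stage uses a fixed offset.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_species = 259,
                       birth_rate = 1,
                       death_rate = 0.3,
                       lambda_true = 0.85,
                       sigma2 = NULL,
                       allometry_slopes = NULL,
                       trait_loadings = NULL,
                       trait_means = NULL,
                       missing_rate = 0.38,
                       missing_bias = 0.3,
                       status_coefs = c(0, 0.8, -0.4),
                       threat_coefs = NULL,
                       iucn_counts = c(CR = 46, EN = 36, VU = 49,
                                       NT = 25, LC = 51, DD = 7),
                       unassessed_n = 45,
                       threat_unknown_n = 8,
                       continent_unknown_n = 14,
                       continent_table = default_continent_table(),
                       seed = 1L) {
  if (!is.numeric(n_species) || n_species < 4) stop("`n_species` must be >= 4")
  if (birth_rate < 0 || death_rate < 0) stop("rates must be non-negative")
  if (death_rate >= birth_rate) stop("`death_rate` must be < `birth_rate`")
  if (missing_rate < 0 || missing_rate >= 1) stop("`missing_rate` must be in [0, 1)")
  if (lambda_true < 0 || lambda_true > 1) stop("`lambda_true` must be in [0, 1]")
  if (length(status_coefs) != 3) stop("`status_coefs` must have length 3 (intercept, PC1, PC2)")

  defaults <- default_trait_params()
  sigma2 <- override_named(defaults$sigma2, sigma2)
  allometry_slopes <- override_named(defaults$slopes, allometry_slopes)
  trait_means <- override_named(defaults$means, trait_means)
  if (is.null(trait_loadings)) trait_loadings <- defaults$loadings
  if (any(rowSums(trait_loadings^2) > 1)) {
    stop("rows of `trait_loadings` must have squared norm <= 1")
  }
  if (is.null(threat_coefs)) threat_coefs <- default_threat_coefs()
  if (ncol(threat_coefs) != 3) stop("`threat_coefs` must have 3 columns")

  structure(list(
    n_species = as.integer(n_species), birth_rate = birth_rate,
    death_rate = death_rate, lambda_true = lambda_true, sigma2 = sigma2,
    allometry_slopes = allometry_slopes, trait_loadings = trait_loadings,
    trait_means = trait_means,
    missing_rate = missing_rate, missing_bias = missing_bias,
    status_coefs = status_coefs, threat_coefs = threat_coefs,
    iucn_counts = iucn_counts, unassessed_n = as.integer(unassessed_n),
    threat_unknown_n = as.integer(threat_unknown_n),
    continent_unknown_n = as.integer(continent_unknown_n),
    continent_table = continent_table, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_species, "species, lambda =", x$lambda_true,
      ", missing rate =", x$missing_rate, ", seed =", x$seed, "\n")
  invisible(x)
}

# Transformed-scale generator parameters. Means/scales are in the range
# reported for chelonians and crocodilians (survival as yearly probabilities,
# lifespan and maturity in years, clutch size in eggs, mass in grams).
default_trait_params <- function() {
  traits <- imputation_traits()
  means <- c(Sa = stats::qlogis(0.93), Sj = stats::qlogis(0.70),
             ML = log(40), La = log(12), CN = log(1.5), CS = log(12),
             mass = log(3000), size = log(30), incubation = log(80))
  sigma2 <- c(Sa = 1.0, Sj = 1.0, ML = 0.45, La = 0.45, CN = 0.30,
              CS = 0.80, mass = 3.0, size = 0.30, incubation = 0.20)
  slopes <- c(Sa = 0.15, Sj = 0.10, ML = 0.20, La = 0.25, CN = -0.05,
              CS = 0.45, mass = 0, size = 0.33, incubation = 0.10)
  # latent-factor loadings: column 1 = pace (fast-slow), column 2 =
  # clutch-frequency vs clutch-size trade-off
  loadings <- rbind(
    Sa = c(0.65, 0), Sj = c(0.55, 0), ML = c(0.70, 0.15), La = c(0.60, 0),
    CN = c(-0.20, -0.60), CS = c(0.15, 0.65), mass = c(0, 0),
    size = c(0, 0), incubation = c(0.30, 0)
  )[traits, , drop = FALSE]
  list(means = means[traits], sigma2 = sigma2[traits],
       slopes = slopes[traits], loadings = loadings)
}

#' The six threat categories
#' @return Character vector of threat flag names.
#' @export
threat_names <- function() {
  c("habitat_degradation", "local_consumption", "global_trade",
    "climate_change", "invasive_disease", "pollution")
}

# Intercepts match typical prevalences; only local consumption, invasive
# species/disease and pollution depend on trait-space position (the other
# three threats hit species independently of strategy).
default_threat_coefs <- function() {
  m <- rbind(
    habitat_degradation = c(stats::qlogis(0.60), 0, 0),
    local_consumption   = c(stats::qlogis(0.35), 0.3, -0.5),
    global_trade        = c(stats::qlogis(0.30), 0, 0),
    climate_change      = c(stats::qlogis(0.15), 0, 0),
    invasive_disease    = c(stats::qlogis(0.20), 0.5, 0),
    pollution           = c(stats::qlogis(0.20), 0, -0.5)
  )
  colnames(m) <- c("intercept", "pc1", "pc2")
  m
}

#' Default per-continent composition of the synthetic metadata
#' @return Tibble with `continent`, `n`, `threatened_frac`.
#' @export
default_continent_table <- function() {
  tibble::tibble(
    continent = c("North America", "Europe", "Asia", "South America",
                  "Africa", "Oceania"),
    n = c(65L, 4L, 66L, 57L, 39L, 14L),
    threatened_frac = c(0.34, 0, 0.83, 0.44, 0.41, 0.36)
  )
}

override_named <- function(base, user) {
  if (is.null(user)) return(base)
  if (is.null(names(user)) || !all(names(user) %in% names(base))) {
    stop("named overrides must use trait names: ",
         paste(names(base), collapse = ", "))
  }
  base[names(user)] <- user
  base
}

# Largest-remainder apportionment of quota counts to a new total.
scale_counts <- function(counts, total) {
  if (total <= 0) return(stats::setNames(integer(length(counts)), names(counts)))
  q <- counts / sum(counts) * total
  out <- floor(q)
  rem <- total - sum(out)
  if (rem > 0) {
    add <- order(q - out, decreasing = TRUE)[seq_len(rem)]
    out[add] <- out[add] + 1
  }
  stats::setNames(as.integer(out), names(counts))
}

#' Simulate a birth-death species tree
#'
#' Simulates a reconstructed birth-death phylogeny conditioned on the number
#' of extant tips (via [ape::rphylo()]) and rescales it to unit height so that
#' the Brownian rates in [sim_config()] are interpretable as tip-level trait
#' variances. Reproducible given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A rooted binary `phylo` with `n_species` tips labelled `sp_1` ...
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- ape::rphylo(config$n_species, config$birth_rate, config$death_rate)
  depth <- max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- paste0("sp_", seq_len(ape::Ntip(tree)))
  tree
}

#' Simulate life-history traits on a tree
#'
#' Draws each trait (on log scale; logit for the survival probabilities) from
#' a multivariate normal with covariance `sigma2 * C(lambda_true)`, where `C`
#' is the Brownian covariance of the tree. Body mass is generated first and
#' every other trait receives `allometry_slopes * centred log mass` on the
#' transformed scale, reproducing the allometric structure of real
#' life-history data. Values are back-transformed to the natural scale; no
#' cell is missing at this stage.
#'
#' @param tree A `phylo` (from [simulate_tree()] or read from file).
#' @param config A [sim_config()].
#' @return Tibble: `species`, `Sa`, `Sj`, `ML`, `La`, `CN`, `CS`, `mass`,
#'   `size`, `incubation`.
#' @export
simulate_traits <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- ape::Ntip(tree)
  C <- phylo_vcv(tree)
  Cl <- lambda_transform(C, config$lambda_true)
  R <- chol_safe(Cl)
  bm_draw <- function() drop(crossprod(R, stats::rnorm(n)))

  mu <- config$trait_means
  s2 <- config$sigma2
  sl <- config$allometry_slopes
  L <- config$trait_loadings

  log_mass <- mu[["mass"]] + sqrt(s2[["mass"]]) * bm_draw()
  mass_c <- log_mass - mu[["mass"]]
  u1 <- bm_draw()  # pace factor
  u2 <- bm_draw()  # reproduction trade-off factor

  out <- tibble::tibble(species = tree$tip.label)
  for (tr in imputation_traits()) {
    if (tr == "mass") {
      val <- log_mass
    } else {
      resid_sd <- sqrt(1 - sum(L[tr, ]^2))
      dev <- L[tr, 1] * u1 + L[tr, 2] * u2 + resid_sd * bm_draw()
      val <- mu[[tr]] + sl[[tr]] * mass_c + sqrt(s2[[tr]]) * dev
    }
    out[[tr]] <- unname(back_transform_trait(val, tr))
  }
  out
}

#' Mask trait cells at random, optionally biased by threat status
#'
#' Each maskable cell (all imputation traits except body mass and size, which
#' are always observed) is set missing independently with probability
#' `logistic(logit(missing_rate) + missing_bias * is_threatened)`, a
#' missing-at-random mechanism given threat status only.
#'
#' @param traits Complete trait tibble from [simulate_traits()].
#' @param config A [sim_config()].
#' @param threatened Optional logical vector (per species); when `NULL` the
#'   bias term is not applied.
#' @return The trait tibble with `NA` in masked cells.
#' @seealso [missingness_mask()]
#' @export
apply_missingness <- function(traits, config, threatened = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  if (config$missing_rate == 0) return(traits)
  n <- nrow(traits)
  if (is.null(threatened)) threatened <- rep(FALSE, n)
  threatened[is.na(threatened)] <- FALSE
  p <- stats::plogis(stats::qlogis(config$missing_rate) +
                       config$missing_bias * threatened)
  for (tr in setdiff(imputation_traits(), c("mass", "size"))) {
    traits[[tr]][stats::runif(n) < p] <- NA_real_
  }
  traits
}

#' Missingness mask of a trait table
#' @param traits Trait tibble.
#' @return Logical tibble (TRUE = missing) over the imputation trait columns.
#' @export
missingness_mask <- function(traits) {
  tibble::as_tibble(lapply(traits[imputation_traits()], is.na))
}

#' Assign IUCN categories, threat flags and continents from trait-space position
#'
#' Species are ordered by a latent logistic risk score
#' `status_coefs %*% (1, PC1, PC2) + logistic noise` and the IUCN categories
#' are filled by quota from worst (CR) to best (LC); DD species and unassessed
#' species are drawn uniformly beforehand. This is an ordinal logistic model
#' calibrated to fixed category margins, so higher-risk categories
#' preferentially collect species whose trait-space position carries a higher
#' linear predictor. The six threat flags are independent Bernoulli draws from
#' per-threat logistic models; a fixed number of species get unknown (NA)
#' flags. Continents are filled by quota from `continent_table`, matching each
#' continent's size and threatened fraction.
#'
#' @param scores Tibble with `species`, `pc1`, `pc2` (the functional space).
#' @param config A [sim_config()].
#' @return Tibble: `species`, `iucn`, the six threat flags (logical),
#'   `continent`.
#' @export
assign_status <- function(scores, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  n <- nrow(scores)
  # scale category + unassessed quotas jointly to the world size
  full <- c(config$iucn_counts, unassessed = config$unassessed_n)
  full <- scale_counts(full, n)
  counts <- full[names(config$iucn_counts)]
  n_assessed <- n - full[["unassessed"]]

  iucn <- rep(NA_character_, n)
  assessed <- sample.int(n, n_assessed)
  dd <- assessed[seq_len(counts[["DD"]])]
  iucn[dd] <- "DD"
  ranked_pool <- setdiff(assessed, dd)

  eta <- config$status_coefs[1] +
    config$status_coefs[2] * scores$pc1[ranked_pool] +
    config$status_coefs[3] * scores$pc2[ranked_pool]
  latent <- eta + stats::rlogis(length(ranked_pool))
  ranked <- ranked_pool[order(latent, decreasing = TRUE)]
  cats <- c("CR", "EN", "VU", "NT", "LC")
  idx <- 0
  for (cat in cats) {
    take <- counts[[cat]]
    if (take > 0) iucn[ranked[idx + seq_len(take)]] <- cat
    idx <- idx + take
  }

  meta <- tibble::tibble(species = scores$species, iucn = iucn)
  tc <- config$threat_coefs
  for (j in seq_len(nrow(tc))) {
    p <- stats::plogis(tc[j, 1] + tc[j, 2] * scores$pc1 + tc[j, 3] * scores$pc2)
    meta[[rownames(tc)[j]]] <- stats::runif(n) < p
  }
  n_ref <- sum(full)
  n_unk <- round(config$threat_unknown_n * n / max(n_ref, 1))
  if (n_unk > 0) {
    unk <- sample.int(n, min(n, n_unk))
    for (nm in rownames(tc)) meta[[nm]][unk] <- NA
  }

  meta$continent <- assign_continents(meta, config$continent_table,
                                      config$continent_unknown_n)
  meta
}

# continent is only recorded for threat-known species (as in the source data,
# where the per-continent ratios are computed on threat-known species)

# Quota continent assignment: each continent receives its target number of
# threatened (CR/EN/VU) and non-threatened species (quotas scaled to the
# world size); leftovers get NA (continent unknown).
assign_continents <- function(meta, ct, unknown_n = 0) {
  n <- nrow(meta)
  if (is.null(ct)) {
    return(sample(default_continent_table()$continent, n, replace = TRUE))
  }
  target_known <- round(n * sum(ct$n) / (sum(ct$n) + unknown_n))
  ct$n <- scale_counts(stats::setNames(ct$n, ct$continent), target_known)
  continent <- rep(NA_character_, n)
  threat_known <- stats::complete.cases(meta[threat_names()])
  thr <- which(threat_known & !is.na(meta$iucn) & meta$iucn %in% c("CR", "EN", "VU"))
  non <- setdiff(which(threat_known), thr)
  thr <- sample(thr); non <- sample(non)
  for (i in seq_len(nrow(ct))) {
    n_thr <- min(round(ct$n[i] * ct$threatened_frac[i]), length(thr))
    n_non <- min(ct$n[i] - n_thr, length(non))
    continent[thr[seq_len(n_thr)]] <- ct$continent[i]
    continent[non[seq_len(n_non)]] <- ct$continent[i]
    if (n_thr > 0) thr <- thr[-seq_len(n_thr)]
    if (n_non > 0) non <- non[-seq_len(n_non)]
  }
  continent
}

#' Simulate a complete synthetic study system
#'
#' Runs the whole generator: tree, complete traits, a provisional 2-D trait
#' space (ordinary PCA of the transformed focal traits, scaled to unit
#' variance, used only to place status and threat labels), species metadata,
#' and the masked trait table. All stages derive their seeds from
#' `config$seed`, so the output is fully reproducible.
#'
#' @param config A [sim_config()].
#' @return A list of class `"fs_simulation"`: `tree`, `traits` (with gaps),
#'   `traits_complete`, `meta`, `scores_true`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  tree <- simulate_tree(config)
  traits <- simulate_traits(tree, config)
  X <- sapply(focal_traits(), function(tr) transform_trait(traits[[tr]], tr))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  scores <- tibble::tibble(
    species = traits$species,
    pc1 = pc$x[, 1] / stats::sd(pc$x[, 1]),
    pc2 = pc$x[, 2] / stats::sd(pc$x[, 2])
  )
  # orient: long lifespan to the right, large clutches upward
  if (stats::cor(scores$pc1, log(traits$ML)) < 0) scores$pc1 <- -scores$pc1
  if (stats::cor(scores$pc2, log(traits$CS)) < 0) scores$pc2 <- -scores$pc2
  meta <- assign_status(scores, config)
  masked <- apply_missingness(traits, config,
                              threatened = meta$iucn %in% c("CR", "EN", "VU"))
  structure(list(tree = tree, traits = masked, traits_complete = traits,
                 meta = meta, scores_true = scores, config = config),
            class = "fs_simulation")
}

#' @export
print.fs_simulation <- function(x, ...) {
  cat("<fs_simulation>", ape::Ntip(x$tree), "species;",
      sum(is.na(x$traits[focal_traits()])), "missing focal cells;",
      sum(x$meta$iucn %in% c("CR", "EN", "VU")), "threatened\n")
  invisible(x)
}

#' Write a simulated dataset to standard files
#'
#' Writes the tree as Newick, traits and metadata as CSV (empty string =
#' missing; threat flags as 0/1), and the configuration as a YAML sidecar.
#'
#' @param sim An `fs_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  readr::write_csv(sim$traits, file.path(dir, "traits.csv"), na = "")
  meta <- sim$meta
  for (nm in threat_names()) meta[[nm]] <- as.integer(meta[[nm]])
  readr::write_csv(meta, file.path(dir, "meta.csv"), na = "")
  cfg <- sim$config
  cfg$continent_table <- as.list(cfg$continent_table)
  cfg$threat_coefs <- as.vector(cfg$threat_coefs)
  yaml::write_yaml(lapply(unclass(cfg), unname), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a dataset written by [write_dataset()] (or assembled by hand)
#'
#' @param tree_path Newick file.
#' @param traits_path Trait CSV (empty cells = missing).
#' @param meta_path Metadata CSV (IUCN category, 0/1 threat flags, continent).
#' @return A list with `tree`, `traits`, `meta`; species labels are checked
#'   against the tree after underscore/space normalisation.
#' @export
read_dataset <- function(tree_path, traits_path, meta_path) {
  tree <- ape::read.tree(tree_path)
  traits <- readr::read_csv(traits_path, show_col_types = FALSE)
  meta <- readr::read_csv(meta_path, show_col_types = FALSE)
  for (nm in intersect(threat_names(), names(meta))) {
    meta[[nm]] <- as.logical(meta[[nm]])
  }
  norm <- function(x) gsub(" ", "_", trimws(x))
  tree$tip.label <- norm(tree$tip.label)
  traits$species <- norm(traits$species)
  meta$species <- norm(meta$species)
  bad <- setdiff(traits$species, tree$tip.label)
  if (length(bad)) {
    stop("species absent from tree: ", paste(utils::head(bad, 10), collapse = ", "))
  }
  list(tree = tree, traits = traits, meta = meta)
}
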