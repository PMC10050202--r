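test_that("simulated trees have the requested shape and are seed-deterministic", {
  cfg <- sim_config(n_species = 4, seed = 1)
  tr <- simulate_tree(cfg)
  expect_equal(ape::Ntip(tr), 4)
  expect_equal(tr$Nnode, 3)
  expect_true(ape::is.binary(tr))
  expect_true(all(tr$edge.length > 0))

  yule <- simulate_tree(sim_config(n_species = 259, death_rate = 0, seed = 2))
  expect_equal(ape::Ntip(yule), 259)
  expect_equal(yule$Nnode, 258)

  a <- ape::write.tree(simulate_tree(sim_config(n_species = 50, seed = 7)))
  b <- ape::write.tree(simulate_tree(sim_config(n_species = 50, seed = 7)))
  expect_identical(a, b)

  expect_error(sim_config(n_species = 50, birth_rate = 0.5, death_rate = 0.5),
               "death_rate")
  expect_error(sim_config(n_species = 2), "n_species")
})

test_that("trait generation honours lambda: independent tips when lambda = 0", {
  cfg0 <- sim_config(n_species = 40, lambda_true = 0, seed = 5)
  tr <- simulate_tree(cfg0)
  # with lambda = 0 the generating covariance is diagonal: across many
  # replicate draws, cross-species covariance of a log trait is ~0
  reps <- sapply(1:300, function(i) {
    cfg <- sim_config(n_species = 40, lambda_true = 0, seed = 5000 + i,
                      allometry_slopes = stats::setNames(rep(0, 9), imputation_traits()),
                      trait_loadings = matrix(0, 9, 2,
                                              dimnames = list(imputation_traits(), NULL)))
    log(simulate_traits(tr, cfg)$ML)
  })
  emp <- stats::cov(t(reps))
  off <- emp[upper.tri(emp)]
  expect_lt(mean(abs(off)), 0.1 * mean(diag(emp)))
})

test_that("across-replicate covariance of a log trait converges to sigma2 * C(lambda)", {
  cfg <- sim_config(n_species = 12, lambda_true = 0.7, seed = 3)
  tr <- simulate_tree(cfg)
  zero9 <- stats::setNames(rep(0, 9), imputation_traits())
  reps <- sapply(1:2000, function(i) {
    ci <- sim_config(n_species = 12, lambda_true = 0.7, seed = 10000 + i,
                     allometry_slopes = zero9,
                     trait_loadings = matrix(0, 9, 2,
                                             dimnames = list(imputation_traits(), NULL)))
    log(simulate_traits(tr, ci)$ML)
  })
  emp <- stats::cov(t(reps))
  expected <- sim_config(n_species = 12)$sigma2[["ML"]] *
    lambda_transform(phylo_vcv(tr), 0.7)
  # element-wise agreement within Monte-Carlo error at 2000 replicates
  expect_lt(max(abs(emp - expected)), 4 * max(diag(expected)) / sqrt(2000) * 3)
  expect_equal(mean(diag(emp)), mean(diag(expected)), tolerance = 0.15)
})

test_that("parameter recovery: ML lambda estimates track lambda_true", {
  cfg <- sim_config(n_species = 300, lambda_true = 0.7, seed = 77)
  tr <- simulate_tree(cfg)
  C <- phylo_vcv(tr)
  est <- sapply(1:20, function(i) {
    ci <- sim_config(n_species = 300, lambda_true = 0.7, seed = 600 + i)
    y <- stats::setNames(log(simulate_traits(tr, ci)$ML), tr$tip.label)
    fit_lambda(y, C)$lambda
  })
  expect_gte(stats::median(est), 0.6)
  expect_lte(stats::median(est), 0.8)
})

test_that("missingness respects rate, bias, and always-observed anchors", {
  cfg <- sim_config(n_species = 259, missing_rate = 0, seed = 4)
  tr <- simulate_tree(cfg)
  traits <- simulate_traits(tr, cfg)
  expect_false(anyNA(apply_missingness(traits, cfg)))

  cfg38 <- sim_config(n_species = 259, missing_rate = 0.38, missing_bias = 0,
                      seed = 4)
  masked <- apply_missingness(traits, cfg38)
  mask <- missingness_mask(masked)
  expect_false(any(mask$mass))
  expect_false(any(mask$size))
  frac <- mean(as.matrix(mask[focal_traits()]))
  n_cells <- 259 * 6
  expect_lt(abs(frac - 0.38), 3 * sqrt(0.38 * 0.62 / n_cells))

  # positive bias raises missingness among threatened species
  thr <- rep(c(TRUE, FALSE), length.out = 259)
  cfgb <- sim_config(n_species = 259, missing_rate = 0.3, missing_bias = 1.5,
                     seed = 9)
  mb <- missingness_mask(apply_missingness(traits, cfgb, threatened = thr))
  per_sp <- rowSums(as.matrix(mb[focal_traits()]))
  expect_gt(mean(per_sp[thr]), mean(per_sp[!thr]))
})

test_that("status assignment reproduces category quotas and trait-risk association", {
  w <- fixture_world()
  counts <- table(w$meta$iucn)
  full <- c(sim_config()$iucn_counts, unassessed = 45)
  expected <- funspectra:::scale_counts(full, 100)
  for (cat in c("CR", "EN", "VU", "NT", "LC", "DD")) {
    expect_equal(unname(counts[cat]), unname(expected[cat]), ignore_attr = TRUE)
  }
  # positive PC1 coefficient => threatened species sit at higher PC1
  thr <- w$meta$iucn %in% c("CR", "EN", "VU")
  expect_gt(mean(w$scores_true$pc1[thr]), mean(w$scores_true$pc1[!thr]))
})

test_that("generating status coefficients are recoverable by logistic regression", {
  cfg <- sim_config(n_species = 1000, seed = 31, unassessed_n = 0,
                    iucn_counts = c(CR = 150, EN = 150, VU = 100, NT = 100,
                                    LC = 500, DD = 0))
  set.seed(31)
  scores <- tibble::tibble(species = paste0("sp_", 1:1000),
                           pc1 = rnorm(1000), pc2 = rnorm(1000))
  meta <- assign_status(scores, cfg)
  y <- as.integer(meta$iucn %in% c("CR", "EN", "VU"))
  fit <- stats::glm(y ~ scores$pc1 + scores$pc2, family = stats::binomial())
  expect_gt(stats::coef(fit)[2], 0)   # generating pc1 coef = +0.8
  expect_lt(stats::coef(fit)[3], 0)   # generating pc2 coef = -0.4
})

test_that("the full simulation is byte-deterministic and round-trips through files", {
  a <- simulate_dataset(sim_config(n_species = 30, seed = 12))
  b <- simulate_dataset(sim_config(n_species = 30, seed = 12))
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$traits, b$traits)
  expect_identical(a$meta, b$meta)

  dir <- withr::local_tempdir()
  write_dataset(a, dir)
  ds <- read_dataset(file.path(dir, "tree.nwk"), file.path(dir, "traits.csv"),
                     file.path(dir, "meta.csv"))
  expect_equal(sort(ds$tree$tip.label), sort(a$tree$tip.label))
  expect_equal(ds$traits$ML, a$traits$ML, tolerance = 1e-9)
  expect_identical(ds$meta$iucn, a$meta$iucn)
})
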