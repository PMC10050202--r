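test_that("preprocessing yields standardised, mass-corrected trait columns", {
  w <- fixture_world()
  X <- preprocess_traits(w$traits_complete, w$tree)
  expect_equal(dim(X), c(100, 6))
  expect_equal(unname(colMeans(X)), rep(0, 6), tolerance = 1e-8)
  expect_equal(unname(apply(X, 2, sd)), rep(1, 6), tolerance = 1e-8)
  # allometry reduced (under the phylogenetic GLS fit the ordinary sample
  # correlation need not vanish exactly, but must shrink)
  lm_raw <- abs(cor(log(w$traits_complete$ML), log(w$traits_complete$mass)))
  lm_res <- abs(cor(X[, "ML"], log(w$traits_complete$mass)))
  expect_gt(lm_raw, lm_res)
  expect_error(preprocess_traits(w$traits, w$tree), "complete")

  # on a star phylogeny the GLS is ordinary least squares, so residuals are
  # exactly orthogonal to log mass
  st <- star_tree(100)
  st$tip.label <- w$traits_complete$species
  Xs <- preprocess_traits(w$traits_complete, st)
  for (tr in focal_traits()) {
    expect_lt(abs(cor(Xs[, tr], log(w$traits_complete$mass))), 1e-8)
  }
})

test_that("pPCA on a star phylogeny equals ordinary correlation PCA", {
  set.seed(4)
  st <- star_tree(40)
  X <- matrix(rnorm(40 * 5), 40, 5,
              dimnames = list(st$tip.label, c("ML", "CS", "t3", "t4", "t5")))
  f <- ppca_fit(X, st)
  e <- eigen(cor(X))
  expect_equal(f$eigenvalues, e$values, tolerance = 1e-8)
  V <- e$vectors
  for (j in 1:5) if (sum(V[, j] * f$vectors[, j]) < 0) V[, j] <- -V[, j]
  expect_equal(unname(f$vectors), V, tolerance = 1e-8, ignore_attr = TRUE)
  # eigenvalues on the correlation scale sum to the number of traits
  expect_equal(sum(f$eigenvalues), 5, tolerance = 1e-6)
  # two perfectly correlated traits load equally on the leading component
  X2 <- cbind(a = rnorm(40), b = rnorm(40))
  X2 <- cbind(X2, c = X2[, "a"])
  rownames(X2) <- st$tip.label
  f2 <- ppca_fit(X2, st)
  expect_equal(abs(f2$vectors["a", 1]), abs(f2$vectors["c", 1]),
               tolerance = 1e-8)
})

test_that("pPCA agrees with an independent implementation on a non-star tree", {
  skip_if_not_installed("phytools")
  set.seed(14)
  tr <- ape::rphylo(50, 1, 0.2)
  C <- phylo_vcv(tr)
  X <- matrix(rnorm(50 * 4), 50, 4,
              dimnames = list(tr$tip.label, c("ML", "CS", "t3", "t4")))
  X <- X + bm_trait(tr, lambda = 1, seed = 6)  # shared phylogenetic signal
  mine <- ppca_fit(X, tr)
  ref <- phytools::phyl.pca(tr, X, method = "lambda", mode = "corr")
  expect_equal(mine$lambda, ref$lambda, tolerance = 1e-3)
  expect_equal(mine$eigenvalues, unname(diag(ref$Eval)), tolerance = 1e-4)
  expect_equal(abs(unclass(mine$loadings)), abs(unclass(ref$L)),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("Kaiser retention and varimax behave as defined", {
  set.seed(19)
  st <- star_tree(80)
  # build traits with two strong factors: eigenvalues > 1 for 2 components
  f1 <- rnorm(80); f2 <- rnorm(80)
  X <- cbind(ML = f1 + 0.3 * rnorm(80), La = f1 + 0.3 * rnorm(80),
             CS = f2 + 0.3 * rnorm(80), CN = -f2 + 0.3 * rnorm(80),
             Sa = rnorm(80), Sj = rnorm(80))
  rownames(X) <- st$tip.label
  fit <- varimax_kaiser(ppca_fit(scale(X), st))
  expect_equal(fit$n_retained, sum(fit$eigenvalues > 1))
  expect_gte(fit$n_retained, 2)
  # varimax never decreases the varimax criterion
  L <- fit$loadings[, seq_len(fit$n_retained)]
  expect_gte(funspectra:::varimax_criterion(fit$rotation$loadings),
             funspectra:::varimax_criterion(L) - 1e-10)
})

test_that("pooling aligns axes, averages, and is robust to sign flips", {
  set.seed(23)
  st <- star_tree(30)
  X <- matrix(rnorm(30 * 4), 30, 4,
              dimnames = list(st$tip.label, c("ML", "CS", "t3", "t4")))
  f <- ppca_fit(X, st)
  pooled_same <- pool_ppca(list(f, f, f))
  expect_equal(pooled_same$pooled$scores, f$scores, tolerance = 1e-12)
  expect_equal(max(abs(pooled_same$score_se)), 0, tolerance = 1e-12)

  flipped <- f
  flipped$loadings[, 1] <- -flipped$loadings[, 1]
  flipped$vectors[, 1] <- -flipped$vectors[, 1]
  flipped$scores[, 1] <- -flipped$scores[, 1]
  pooled_flip <- pool_ppca(list(f, flipped))
  expect_equal(pooled_flip$pooled$scores, f$scores, tolerance = 1e-12)

  # scores invariant to species reordering (up to the same permutation)
  perm <- sample(30)
  Xp <- X[perm, ]
  fp <- ppca_fit(Xp, st)
  expect_equal(fp$scores[st$tip.label, ], f$scores[st$tip.label, ],
               tolerance = 1e-8)
})

test_that("pooled scores on low-missingness data track the complete-data ordination", {
  cfg <- sim_config(n_species = 80, missing_rate = 0.08, seed = 99)
  sim <- simulate_dataset(cfg)
  iset <- impute_traits(sim$traits, sim$tree, n_datasets = 5, maxit = 5,
                        seed = 17)
  pooled <- run_ppca(iset, sim$tree)
  Xc <- preprocess_traits(sim$traits_complete, sim$tree)
  complete_fit <- ppca_fit(Xc, sim$tree)
  ss <- procrustes_ss(pooled$pooled$scores[, 1:2], complete_fit$scores[, 1:2])
  expect_lt(ss, 0.1)
})
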