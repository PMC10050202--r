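#' Phylogenetic eigenvector covariates
#'
#' Top-k eigenvectors of the double-centred phylogenetic covariance matrix,
#' the standard way to inject phylogenetic structure into a regression-based
#' imputation model: closely related species share similar eigenvector
#' loadings, so the imputation borrows strength from relatives.
#'
#' @param C Phylogenetic covariance matrix (from [phylo_vcv()]).
#' @param k Number of eigenvectors (`0 < k < n`).
#' @return n x k matrix of unit-norm eigenvectors, ordered by eigenvalue,
#'   rownames preserved.
#' @export
phylo_eigenvectors <- function(C, k) {
  n <- nrow(C)
  if (k <= 0) stop("`k` must be positive")
  if (k >= n) stop("`k` must be smaller than the number of species")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% C %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  rownames(V) <- rownames(C)
  colnames(V) <- paste0("phy_ev", seq_len(k))
  V
}

# Bayesian linear regression parameter draw (the classic "norm.draw"):
# ridge-stabilised least squares, sigma^2 from its scaled inverse-chi-square
# posterior, beta from its normal posterior.
bayes_lm_draw <- function(X, y, ridge = 1e-5) {
  p <- ncol(X)
  xtx <- crossprod(X)
  pen <- diag(ridge * mean(diag(xtx)), p)
  V <- solve(xtx + pen)
  beta_hat <- V %*% crossprod(X, y)
  res <- y - X %*% beta_hat
  df <- max(length(y) - p, 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  Rv <- chol((V + t(V)) / 2)
  beta_dot <- beta_hat + sqrt(sigma2) * crossprod(Rv, stats::rnorm(p))
  list(beta_hat = beta_hat, beta_dot = beta_dot)
}

#' Predictive-mean-matching imputation of a trait table
#'
#' One chained-equations (FCS) run: traits are moved to their modelling scale
#' (log; logit for survivals) and z-scaled; missing cells are initialised by
#' random draws from the observed values; then for `maxit` sweeps each
#' incomplete variable (visited in order of increasing missingness) is
#' regressed on all other traits plus the phylogenetic eigenvector covariates
#' with a Bayesian parameter draw, and each missing cell is filled with the
#' observed value of one of the `donors` nearest neighbours in
#' predicted-mean space (type-1 matching: donor means from the least-squares
#' fit, recipient means from the parameter draw). Every imputed value is an
#' actually observed value of that trait, so ranges are preserved by
#' construction; observed cells are never modified.
#'
#' @param data Trait tibble with `species` and the imputation trait columns.
#' @param covariates Numeric matrix of extra covariates (typically from
#'   [phylo_eigenvectors()]), rows aligned to `data$species`.
#' @param maxit Number of FCS sweeps (default 15).
#' @param donors Donor pool size (default 5).
#' @param seed Integer seed for this chain (optional).
#' @return The completed trait tibble.
#' @export
pmm_impute <- function(data, covariates = NULL, maxit = 15, donors = 5,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  traits <- intersect(imputation_traits(), names(data))
  n <- nrow(data)
  miss <- vapply(data[traits], function(x) sum(is.na(x)), integer(1))
  zero_obs <- names(miss)[miss == n]
  if (length(zero_obs)) {
    stop("variable(s) with no observed values: ", paste(zero_obs, collapse = ", "))
  }
  if (all(miss == 0)) return(data)

  # modelling scale + z-scaling (moments from observed cells)
  Z <- matrix(NA_real_, n, length(traits), dimnames = list(data$species, traits))
  centers <- scales <- stats::setNames(numeric(length(traits)), traits)
  raw_obs <- list()
  for (tr in traits) {
    z <- transform_trait(data[[tr]], tr)
    centers[tr] <- mean(z, na.rm = TRUE)
    scales[tr] <- stats::sd(z, na.rm = TRUE)
    if (!is.finite(scales[tr]) || scales[tr] == 0) scales[tr] <- 1
    Z[, tr] <- (z - centers[tr]) / scales[tr]
    raw_obs[[tr]] <- data[[tr]][!is.na(data[[tr]])]
  }
  mask <- is.na(Z)

  # initialise gaps from the observed marginal
  for (tr in traits[miss > 0]) {
    obs <- Z[!mask[, tr], tr]
    Z[mask[, tr], tr] <- sample(obs, sum(mask[, tr]), replace = TRUE)
  }

  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  visit <- traits[miss > 0][order(miss[miss > 0])]
  filled <- data

  for (sweep in seq_len(maxit)) {
    for (tr in visit) {
      m_rows <- mask[, tr]
      others <- setdiff(traits, tr)
      X <- cbind(1, Z[, others, drop = FALSE], covariates)
      draw <- bayes_lm_draw(X[!m_rows, , drop = FALSE], Z[!m_rows, tr])
      yhat_obs <- drop(X[!m_rows, , drop = FALSE] %*% draw$beta_hat)
      yhat_mis <- drop(X[m_rows, , drop = FALSE] %*% draw$beta_dot)
      obs_z <- Z[!m_rows, tr]
      obs_raw <- data[[tr]][!m_rows]
      pick <- vapply(yhat_mis, function(v) {
        nb <- order(abs(yhat_obs - v))[seq_len(min(donors, length(yhat_obs)))]
        nb[sample.int(length(nb), 1)]
      }, integer(1))
      Z[m_rows, tr] <- obs_z[pick]
      filled[[tr]][m_rows] <- obs_raw[pick]
    }
  }
  filled
}

#' Build a set of independently imputed datasets
#'
#' Runs [pmm_impute()] `n_datasets` times (default 40) with seeds
#' `seed + 1 ... seed + n_datasets`, each a single-imputation chain of
#' `maxit` sweeps, quantifying imputation uncertainty by between-dataset
#' variation. Phylogenetic eigenvectors are computed once from the tree.
#'
#' @param data Trait tibble with gaps.
#' @param tree A `phylo` whose tips cover `data$species`.
#' @param n_datasets Number of completed datasets (default 40).
#' @param maxit FCS sweeps per chain (default 15).
#' @param donors PMM donor pool size (default 5).
#' @param k Number of phylogenetic eigenvectors; default
#'   `min(15, floor(n / 10))`.
#' @param seed Master seed.
#' @return An object of class `"imputation_set"`: list with `datasets` (list
#'   of tibbles), `seeds`, and the settings.
#' @export
impute_traits <- function(data, tree, n_datasets = 40, maxit = 15, donors = 5,
                          k = NULL, seed = 1L) {
  n <- nrow(data)
  if (is.null(k)) k <- max(1, min(15, floor(n / 10)))
  C <- phylo_vcv(tree)[data$species, data$species]
  EV <- phylo_eigenvectors(C, k)
  seeds <- seed + seq_len(n_datasets)
  datasets <- lapply(seeds, function(s) {
    pmm_impute(data, covariates = EV, maxit = maxit, donors = donors, seed = s)
  })
  structure(list(datasets = datasets, seeds = seeds, n_datasets = n_datasets,
                 m = 1L, maxit = maxit, donors = donors, k = k),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("<imputation_set>", x$n_datasets, "datasets (m = 1, maxit =", x$maxit,
      ", donors =", x$donors, ",", x$k, "phylogenetic eigenvectors)\n")
  invisible(x)
}

# Overlap coefficient of two kernel densities on a shared grid.
density_overlap <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  rng <- range(c(a, b))
  da <- stats::density(a, from = rng[1], to = rng[2], n = 512)
  db <- stats::density(b, from = rng[1], to = rng[2], n = 512)
  dx <- diff(da$x[1:2])
  sum(pmin(da$y, db$y)) * dx
}

#' Imputation-quality diagnostics
#'
#' Per trait, the overlap coefficient between the kernel density of observed
#' values and that of imputed values (pooled across the imputation set);
#' values near 1 mean the imputations are distributionally indistinguishable
#' from the data. Optionally, a symmetric Procrustes statistic between two
#' score configurations (e.g. pPCA scores of the fully imputed data vs. a
#' low-imputation subset), which is 0 for configurations identical up to
#' rotation, translation and scale.
#'
#' @param iset An [impute_traits()] result.
#' @param original The pre-imputation trait tibble (with gaps).
#' @param scores_full,scores_subset Optional matrices/data frames of matching
#'   2-D configurations for the Procrustes check.
#' @return A list with `overlap` (tibble: trait, n_imputed, overlap) and
#'   `procrustes_ss` (or `NA` when scores are not supplied).
#' @export
imputation_diagnostics <- function(iset, original,
                                   scores_full = NULL, scores_subset = NULL) {
  traits <- intersect(imputation_traits(), names(original))
  overlap <- purrr::map_dfr(traits, function(tr) {
    m <- is.na(original[[tr]])
    obs <- transform_trait(original[[tr]][!m], tr)
    imp <- unlist(lapply(iset$datasets, function(d) {
      transform_trait(d[[tr]][m], tr)
    }))
    tibble::tibble(trait = tr, n_imputed = sum(m),
                   overlap = if (sum(m) == 0) 1 else density_overlap(obs, imp))
  })
  ss <- NA_real_
  if (!is.null(scores_full) && !is.null(scores_subset)) {
    ss <- procrustes_ss(scores_full, scores_subset)
  }
  list(overlap = overlap, procrustes_ss = ss)
}

#' Write an imputation set to numbered CSV files with a manifest
#'
#' One CSV per completed dataset (`imputed_01.csv`, ...) plus
#' `manifest.yaml` recording the seeds and chain settings.
#'
#' @param iset An [impute_traits()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_imputation_set <- function(iset, dir) {
  stopifnot(inherits(iset, "imputation_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(iset$datasets)) {
    readr::write_csv(iset$datasets[[i]],
                     file.path(dir, sprintf("imputed_%02d.csv", i)), na = "")
  }
  yaml::write_yaml(list(n_datasets = iset$n_datasets, m = iset$m,
                        maxit = iset$maxit, donors = iset$donors, k = iset$k,
                        seeds = iset$seeds),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Symmetric Procrustes sum-of-squares between two configurations
#'
#' @param a,b Matrices (or data frames) with matching rows.
#' @return The symmetric Procrustes statistic (0 = identical up to rotation,
#'   translation and scale).
#' @export
procrustes_ss <- function(a, b) {
  pr <- vegan::procrustes(as.matrix(a), as.matrix(b), symmetric = TRUE)
  pr$ss
}
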