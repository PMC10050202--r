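#' Transform and body-mass-correct the focal traits
#'
#' For each of the six focal life-history traits: move to the modelling scale
#' (log, or logit for the survival probabilities), estimate that trait's
#' Pagel's lambda by ML, take the residuals of a phylogenetic regression on
#' log body mass with the error structure `C(lambda_hat)`, and z-transform to
#' mean 0, SD 1. This removes the dominant allometric signal so the
#' ordination reflects life-history strategy rather than size.
#'
#' @param data Complete (post-imputation) trait tibble with `species` and
#'   `mass` columns.
#' @param tree A `phylo` covering `data$species`.
#' @param traits Trait columns to process (default the six focal traits).
#' @return Numeric species x trait matrix of standardised residuals, with a
#'   `"lambda"` attribute holding the per-trait ML estimates. Columns whose
#'   residual variance collapses (trait proportional to mass) raise an error
#'   naming the trait.
#' @export
preprocess_traits <- function(data, tree, traits = focal_traits()) {
  stopifnot(is.data.frame(data), "species" %in% names(data), "mass" %in% names(data))
  if (anyNA(data[traits]) || anyNA(data$mass)) {
    stop("trait table must be complete; impute first")
  }
  C <- phylo_vcv(tree)[data$species, data$species]
  log_mass <- log(data$mass)
  lambdas <- stats::setNames(numeric(length(traits)), traits)
  out <- matrix(NA_real_, nrow(data), length(traits),
                dimnames = list(data$species, traits))
  for (tr in traits) {
    y <- transform_trait(data[[tr]], tr)
    fit <- fit_lambda(stats::setNames(y, data$species), C)
    lam <- if (isTRUE(fit$degenerate) || is.na(fit$lambda)) 1 else fit$lambda
    lambdas[tr] <- lam
    res <- pgls_residuals(y, log_mass, C, lam)
    s <- stats::sd(res)
    if (!is.finite(s) || s < 1e-12) {
      stop("trait ", tr, " is degenerate after body-mass correction")
    }
    out[, tr] <- (res - mean(res)) / s
  }
  attr(out, "lambda") <- lambdas
  out
}

# Matrix-normal profile log-likelihood over lambda: rows ~ C(lambda), columns
# ~ E estimated by GLS plug-in at each lambda.
ppca_profile_loglik <- function(lambda, X, C) {
  n <- nrow(X); m <- ncol(X)
  Cl <- lambda_transform(C, lambda)
  R <- chol_safe(Cl)
  Xw <- forwardsolve(t(R), X)
  w <- forwardsolve(t(R), rep(1, n))
  a <- drop(crossprod(w, Xw)) / sum(w * w)
  Rw <- Xw - tcrossprod(w, a)
  E_ml <- crossprod(Rw) / n
  # clamped eigenvalues make the log-determinant finite for rank-deficient
  # trait sets (e.g. duplicated traits); the optimum in lambda is unaffected
  ev <- eigen(E_ml, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 1e-12 * max(ev, 1e-300))
  ll <- -0.5 * (n * m * log(2 * pi) + m * 2 * sum(log(diag(R))) +
                  n * sum(log(ev)) + n * m)
  list(loglik = ll, a = a, Rw = Rw)
}

#' Phylogenetically informed principal component analysis
#'
#' Jointly estimates Pagel's lambda by maximising the matrix-normal
#' likelihood of the trait matrix with row covariance `C(lambda)`, computes
#' the evolutionary covariance
#' `E = (X - 1 a')' C(lambda)^-1 (X - 1 a') / (n - 1)` around the GLS
#' phylogenetic mean `a`, converts it to a correlation matrix, and
#' eigendecomposes. Scores are the mean-centred, E-standardised traits
#' projected on the eigenvectors. Signs are fixed so that `ML` loads
#' positively on PC1 (the fast-slow continuum points towards long lifespans)
#' and `CS` loads positively on PC2 (the reproductive-strategy axis points
#' towards large clutches); other components are signed by their largest
#' loading.
#'
#' @param X Complete species x trait matrix (from [preprocess_traits()]),
#'   rownames = species.
#' @param tree A `phylo`, or a phylogenetic covariance matrix.
#' @return An object of class `"fs_ppca"`: `loadings` (trait correlations
#'   with components), `vectors`, `scores`, `eigenvalues`, `var_explained`,
#'   `lambda`, `loglik`, `n_retained` (filled by [varimax_kaiser()]).
#' @export
ppca_fit <- function(X, tree) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (n < m + 1) stop("need more species than traits")
  if (anyNA(X)) stop("`X` must be complete")
  C <- if (inherits(tree, "phylo")) phylo_vcv(tree) else as.matrix(tree)
  if (!is.null(rownames(X))) C <- C[rownames(X), rownames(X)]

  opt <- stats::optimize(function(l) ppca_profile_loglik(l, X, C)$loglik,
                         c(0, 1), maximum = TRUE, tol = 1e-6)
  lam <- opt$maximum
  for (b in c(0, 1)) {
    if (abs(lam - b) < 1e-4 &&
        ppca_profile_loglik(b, X, C)$loglik >= opt$objective) lam <- b
  }
  fit <- ppca_profile_loglik(lam, X, C)
  E <- crossprod(fit$Rw) / (n - 1)
  if (any(diag(E) <= 0)) {
    stop("evolutionary covariance is singular: a trait column is constant")
  }
  V <- stats::cov2cor(E)
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  vec <- e$vectors
  rownames(vec) <- colnames(X)
  colnames(vec) <- paste0("PC", seq_len(m))

  # deterministic sign convention
  for (j in seq_len(m)) {
    anchor <- if (j == 1 && "ML" %in% rownames(vec)) {
      vec["ML", j]
    } else if (j == 2 && "CS" %in% rownames(vec)) {
      vec["CS", j]
    } else {
      vec[which.max(abs(vec[, j])), j]
    }
    if (anchor < 0) vec[, j] <- -vec[, j]
  }

  Xc <- sweep(X, 2, fit$a)
  Xs <- sweep(Xc, 2, sqrt(diag(E)), "/")
  scores <- Xs %*% vec
  loadings <- vec %*% diag(sqrt(pmax(e$values, 0)), m)
  dimnames(loadings) <- dimnames(vec)

  structure(list(
    loadings = loadings, vectors = vec, scores = scores,
    eigenvalues = e$values, var_explained = e$values / sum(e$values),
    lambda = lam, loglik = fit$loglik, mean = fit$a,
    n_retained = NULL, rotation = NULL
  ), class = "fs_ppca")
}

#' @export
print.fs_ppca <- function(x, ...) {
  cat("<fs_ppca>", ncol(x$scores), "components,", nrow(x$scores), "species\n")
  cat("  lambda =", round(x$lambda, 3),
      "; var explained:", paste0(round(100 * x$var_explained, 1), "%", collapse = ", "), "\n")
  invisible(x)
}

# varimax criterion: sum over columns of the variance of squared loadings
varimax_criterion <- function(L) {
  sum(apply(L^2, 2, function(z) mean(z^2) - mean(z)^2))
}

#' Kaiser retention and varimax rotation
#'
#' Counts the components with eigenvalue > 1 (Kaiser criterion on the
#' correlation scale), applies a varimax rotation to their loadings, and
#' stores the rotated loadings/scores on the fit. The unrotated leading two
#' components remain the coordinates used for the TPD functional space.
#'
#' @param fit An [ppca_fit()] result.
#' @return The fit with `n_retained` and a `rotation` list (`loadings`,
#'   `scores`, `rotmat`).
#' @export
varimax_kaiser <- function(fit) {
  stopifnot(inherits(fit, "fs_ppca"))
  nr <- sum(fit$eigenvalues > 1)
  if (nr == 0) stop("no component has eigenvalue > 1; nothing to retain")
  L <- fit$loadings[, seq_len(nr), drop = FALSE]
  if (nr == 1) {
    rot <- list(loadings = L, scores = fit$scores[, 1, drop = FALSE],
                rotmat = matrix(1, 1, 1))
  } else {
    vm <- stats::varimax(L, normalize = FALSE)
    rot <- list(loadings = L %*% vm$rotmat,
                scores = fit$scores[, seq_len(nr), drop = FALSE] %*% vm$rotmat,
                rotmat = vm$rotmat)
  }
  fit$n_retained <- nr
  fit$rotation <- rot
  fit
}

# Greedy axis matching by maximal absolute loading correlation; deterministic
# tie-break by original column order.
match_axes <- function(ref, L) {
  m <- ncol(ref)
  cc <- abs(stats::cor(ref, L))
  perm <- integer(m); used <- logical(m)
  for (j in seq_len(m)) {
    cand <- cc[j, ]
    cand[used] <- -Inf
    perm[j] <- which.max(cand)  # which.max takes the first on ties
    used[perm[j]] <- TRUE
  }
  signs <- vapply(seq_len(m), function(j) {
    s <- sum(ref[, j] * L[, perm[j]])
    if (s < 0) -1 else 1
  }, numeric(1))
  list(perm = perm, signs = signs)
}

#' Pool phylogenetic PCAs across imputed datasets
#'
#' Aligns every fit's axes to the first fit (matching components by maximal
#' absolute loading correlation and flipping signs where needed), then pools
#' loadings, scores, eigenvalues and variance fractions by element-wise mean,
#' with element-wise SD/sqrt(m) as the pooling uncertainty.
#'
#' @param fits List of [ppca_fit()] results sharing species and traits.
#' @return A list of class `"fs_ppca_pooled"`: `pooled` (an `fs_ppca`),
#'   `space` (tibble: species, pc1, pc2, pc1_se, pc2_se), `score_se`,
#'   `loading_se`, `n_fits`.
#' @export
pool_ppca <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1), "fs_ppca")))
  ref <- fits[[1]]
  aligned <- lapply(fits, function(f) {
    mt <- match_axes(ref$loadings, f$loadings)
    f$loadings <- sweep(f$loadings[, mt$perm, drop = FALSE], 2, mt$signs, "*")
    f$vectors <- sweep(f$vectors[, mt$perm, drop = FALSE], 2, mt$signs, "*")
    f$scores <- sweep(f$scores[, mt$perm, drop = FALSE], 2, mt$signs, "*")
    f$eigenvalues <- f$eigenvalues[mt$perm]
    f$var_explained <- f$var_explained[mt$perm]
    f
  })
  mean_arr <- function(get) Reduce(`+`, lapply(aligned, get)) / length(aligned)
  se_arr <- function(get, mu) {
    if (length(aligned) == 1) return(mu * 0)
    v <- Reduce(`+`, lapply(aligned, function(f) (get(f) - mu)^2)) /
      (length(aligned) - 1)
    sqrt(v) / sqrt(length(aligned))
  }
  pooled <- ref
  pooled$loadings <- mean_arr(function(f) f$loadings)
  pooled$vectors <- mean_arr(function(f) f$vectors)
  pooled$scores <- mean_arr(function(f) f$scores)
  pooled$eigenvalues <- mean_arr(function(f) f$eigenvalues)
  pooled$var_explained <- mean_arr(function(f) f$var_explained)
  pooled$lambda <- mean(vapply(aligned, function(f) f$lambda, numeric(1)))
  score_se <- se_arr(function(f) f$scores, pooled$scores)
  loading_se <- se_arr(function(f) f$loadings, pooled$loadings)
  space <- tibble::tibble(
    species = rownames(pooled$scores),
    pc1 = pooled$scores[, 1], pc2 = pooled$scores[, 2],
    pc1_se = score_se[, 1], pc2_se = score_se[, 2]
  )
  structure(list(pooled = pooled, space = space, score_se = score_se,
                 loading_se = loading_se, n_fits = length(fits)),
            class = "fs_ppca_pooled")
}

#' @export
print.fs_ppca_pooled <- function(x, ...) {
  cat("<fs_ppca_pooled> pooled over", x$n_fits, "imputations\n")
  print(x$pooled)
  invisible(x)
}

#' Run the full ordination over an imputation set
#'
#' Preprocesses (log/logit, body-mass PGLS residuals, z-transform) and fits
#' the phylogenetic PCA on every imputed dataset, applies Kaiser/varimax to
#' each, and pools.
#'
#' @param iset An [impute_traits()] result.
#' @param tree A `phylo` covering the species.
#' @return An `"fs_ppca_pooled"` object (see [pool_ppca()]).
#' @export
run_ppca <- function(iset, tree) {
  fits <- lapply(iset$datasets, function(d) {
    X <- preprocess_traits(d, tree)
    varimax_kaiser(ppca_fit(X, tree))
  })
  pool_ppca(fits)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.fs_ppca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "trait") |>
    tidyr::pivot_longer(-"trait", names_to = "component", values_to = "loading")
}

#' @export
glance.fs_ppca <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, loglik = x$loglik,
    pc1_var = x$var_explained[1], pc2_var = x$var_explained[2],
    n_retained = if (is.null(x$n_retained)) NA_integer_ else x$n_retained,
    n_species = nrow(x$scores)
  )
}

#' @export
tidy.fs_ppca_pooled <- function(x, ...) {
  tidy(x$pooled) |>
    dplyr::left_join(
      tibble::as_tibble(x$loading_se, rownames = "trait") |>
        tidyr::pivot_longer(-"trait", names_to = "component",
                            values_to = "loading_se"),
      by = c("trait", "component")
    )
}

#' @export
glance.fs_ppca_pooled <- function(x, ...) {
  dplyr::mutate(glance(x$pooled), n_imputations = x$n_fits)
}
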