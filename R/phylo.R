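#' Phylogenetic covariance matrix under Brownian motion
#'
#' Builds the expected trait covariance matrix implied by a rooted phylogeny
#' under Brownian motion: `C[i, j]` is the depth (root-to-node distance) of the
#' most recent common ancestor of tips `i` and `j`, and `C[i, i]` is the
#' root-to-tip distance of tip `i`. Non-ultrametric trees are allowed, in which
#' case the diagonal varies across tips. Optionally applies Pagel's lambda
#' transform (see [lambda_transform()]).
#'
#' @param tree A rooted `ape::phylo` tree with branch lengths.
#' @param lambda Pagel's lambda in `[0, 1]`; the off-diagonal multiplier.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames and attribute `"lambda"`.
#' @examples
#' tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' phylo_vcv(tree)
#' @export
phylo_vcv <- function(tree, lambda = 1) {
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape 'phylo' object")
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    stop("tree branch lengths must be finite")
  }
  if (any(tree$edge.length < 0)) stop("tree branch lengths must be non-negative")
  C <- ape::vcv.phylo(tree)
  lambda_transform(C, lambda)
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries of `C` by `lambda`, leaving the diagonal
#' untouched. `lambda = 1` returns `C` unchanged (full Brownian expectation);
#' `lambda = 0` removes all phylogenetic covariance.
#'
#' @param C A phylogenetic covariance matrix (from [phylo_vcv()]).
#' @param lambda Signal strength in `[0, 1]`.
#' @return The transformed matrix, with attribute `"lambda"` updated.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("`lambda` must be a single value in [0, 1]")
  }
  d <- diag(C)
  out <- C * lambda
  diag(out) <- d
  attr(out, "lambda") <- lambda
  out
}

# Cholesky with a small jitter fallback for near-singular covariances
# (e.g. near-duplicate tips). Jitter is relative to the mean diagonal.
chol_safe <- function(C, jitter = 1e-10) {
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R)) {
    message("covariance not positive definite; adding jitter ", jitter)
    R <- chol(C + diag(jitter * mean(diag(C)), nrow(C)))
  }
  R
}

# Profile log-likelihood of Pagel's lambda for a single trait:
# y ~ N(mu * 1, sigma2 * C(lambda)), with mu and sigma2 profiled out by GLS.
lambda_profile_loglik <- function(lambda, y, C) {
  n <- length(y)
  Cl <- lambda_transform(C, lambda)
  R <- chol_safe(Cl)
  # whiten: t(R) %*% z = y
  z <- forwardsolve(t(R), y)
  w <- forwardsolve(t(R), rep(1, n))
  mu <- sum(w * z) / sum(w * w)
  r <- z - mu * w
  sigma2 <- sum(r^2) / n
  logdet <- 2 * sum(log(diag(R)))
  list(
    loglik = -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdet + n),
    mu = mu, sigma2 = sigma2
  )
}

#' Maximum-likelihood estimate of Pagel's lambda for one trait
#'
#' Profiles the mean and rate out of the multivariate-normal likelihood
#' `y ~ N(mu 1, sigma2 C(lambda))` and maximises over `lambda` on `[0, 1]`
#' with Brent's method (tolerance 1e-6). The standard error comes from the
#' curvature of the profile log-likelihood at the optimum; it is `NA` when the
#' optimum sits on a boundary with non-negative curvature.
#'
#' @param y Named numeric vector of (complete) trait values, one per tip.
#' @param C Phylogenetic covariance matrix from [phylo_vcv()] (lambda = 1).
#' @return A list with `lambda`, `loglik`, `se`, `sigma2`, `mu`, and
#'   `degenerate` (`TRUE` when `y` is constant, in which case `lambda` is `NA`).
#' @seealso [trait_lambda()] for a data-frame interface over several traits.
#' @export
fit_lambda <- function(y, C) {
  if (length(y) < 4) stop("need at least 4 taxa to estimate lambda")
  if (anyNA(y)) stop("`y` must be complete; impute first")
  if (!is.null(names(y))) {
    if (!all(names(y) %in% rownames(C))) stop("names of `y` must match rownames of `C`")
    C <- C[names(y), names(y)]
  }
  if (stats::var(y) == 0) {
    return(list(lambda = NA_real_, loglik = NA_real_, se = NA_real_,
                sigma2 = 0, mu = y[[1]], degenerate = TRUE))
  }
  f <- function(l) lambda_profile_loglik(l, y, C)$loglik
  opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = 1e-6)
  lam <- opt$maximum
  # snap to boundary when the optimiser stops just inside it
  if (lam < 1e-4 && f(0) >= opt$objective) lam <- 0
  if (lam > 1 - 1e-4 && f(1) >= opt$objective) lam <- 1
  fit <- lambda_profile_loglik(lam, y, C)
  h <- 1e-3
  lo <- max(0, lam - h); hi <- min(1, lam + h)
  d2 <- (f(hi) - 2 * f(lam) + f(lo)) / ((hi - lam) * (lam - lo) + .Machine$double.eps)
  se <- if (is.finite(d2) && d2 < 0) 1 / sqrt(-d2) else NA_real_
  list(lambda = lam, loglik = fit$loglik, se = se,
       sigma2 = fit$sigma2, mu = fit$mu, degenerate = FALSE)
}

#' Phylogenetic signal for several traits of a trait table
#'
#' Data-frame interface to [fit_lambda()]: estimates Pagel's lambda per trait
#' column (on its modelling scale: log for positive traits, logit for
#' survival probabilities) using complete cells only.
#'
#' @param data A trait table with a `species` column matching tree tips.
#' @param tree A rooted `ape::phylo` tree.
#' @param traits Character vector of trait columns to test.
#' @param transform Apply the standard log/logit transform first (default TRUE).
#' @return A tibble with one row per trait: `trait`, `n`, `lambda`, `se`,
#'   `loglik`.
#' @export
trait_lambda <- function(data, tree, traits = focal_traits(), transform = TRUE) {
  stopifnot(is.data.frame(data), "species" %in% names(data))
  C <- phylo_vcv(tree)
  purrr::map_dfr(traits, function(tr) {
    y <- data[[tr]]
    names(y) <- data$species
    y <- y[!is.na(y)]
    if (transform) y <- transform_trait(y, tr)
    fit <- fit_lambda(y, C[names(y), names(y)])
    tibble::tibble(trait = tr, n = length(y), lambda = fit$lambda,
                   se = fit$se, loglik = fit$loglik)
  })
}

#' Residuals of a phylogenetic generalized least squares regression
#'
#' Fits `y ~ 1 + x` by GLS with error covariance `C(lambda)` and returns the
#' raw residuals `y - X beta_hat`. Used to remove the allometric effect of
#' body mass from each life-history trait before ordination.
#'
#' @param y Response vector (complete).
#' @param x Covariate vector (e.g. log body mass).
#' @param C Phylogenetic covariance matrix (lambda = 1 scale).
#' @param lambda Pagel's lambda used to weight the error structure.
#' @return Numeric vector of residuals, named as `y`.
#' @export
pgls_residuals <- function(y, x, C, lambda = 1) {
  if (length(y) != length(x)) stop("`y` and `x` must have equal length")
  if (anyNA(y) || anyNA(x)) stop("inputs must be complete")
  if (stats::var(x) == 0) stop("covariate `x` is constant; design is singular")
  Cl <- lambda_transform(C, lambda)
  R <- chol_safe(Cl)
  X <- cbind(1, x)
  Xw <- forwardsolve(t(R), X)
  yw <- forwardsolve(t(R), y)
  qrX <- qr(Xw)
  if (qrX$rank < ncol(X)) stop("singular design in PGLS for covariate `x`")
  beta <- qr.coef(qrX, yw)
  res <- y - drop(X %*% beta)
  names(res) <- names(y)
  attr(res, "beta") <- beta
  res
}

#' Kruskal-Wallis test for trait missingness across threat-status groups
#'
#' Tests whether the number of missing trait values per species differs among
#' threat-status groups (e.g. threatened / non-threatened / unknown), the
#' standard check that missingness is associated with conservation status.
#'
#' @param missing_counts Integer vector: number of missing trait cells per
#'   species.
#' @param groups Factor (or coercible) of group labels, same length.
#' @return A tibble with `H` (the rank statistic, tie-corrected), `df`, and
#'   `p_value`.
#' @export
kruskal_missingness_test <- function(missing_counts, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  kt <- stats::kruskal.test(missing_counts, groups)
  tibble::tibble(H = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value)
}

#' The six focal life-history traits
#'
#' Adult survival (`Sa`, 1/yr), juvenile survival (`Sj`, 1/yr), maximum
#' lifespan (`ML`, yr), age at sexual maturity (`La`, yr), clutches per year
#' (`CN`), and clutch size (`CS`, eggs).
#'
#' @return Character vector of column names.
#' @export
focal_traits <- function() c("Sa", "Sj", "ML", "La", "CN", "CS")

# Traits used in the imputation model (focal + auxiliary).
imputation_traits <- function() c(focal_traits(), "mass", "size", "incubation")

# Modelling-scale transform: survivals are probabilities -> logit; everything
# else is positive -> log.
transform_trait <- function(y, trait) {
  if (trait %in% c("Sa", "Sj")) {
    if (any(y <= 0 | y >= 1, na.rm = TRUE)) {
      stop("survival trait ", trait, " must lie strictly in (0, 1)")
    }
    stats::qlogis(y)
  } else {
    if (any(y <= 0, na.rm = TRUE)) {
      bad <- which(y <= 0)
      stop("trait ", trait, " must be positive; offending rows: ",
           paste(utils::head(bad, 10), collapse = ", "))
    }
    log(y)
  }
}

back_transform_trait <- function(y, trait) {
  if (trait %in% c("Sa", "Sj")) stats::plogis(y) else exp(y)
}
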