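#' Binomial smooth surface of risk over the functional space
#'
#' Fits a generalized additive model `label ~ s(pc1, pc2)` with a binomial
#' (logit) family: a thin-plate penalized regression spline over the 2-D
#' functional space, with the smoothing parameter chosen by REML. Used both
#' for extinction risk (1 = high-risk, i.e. CR or EN; 0 = other assessed,
#' DD excluded) and for per-threat affliction (1 = affected).
#'
#' @param space Functional-space tibble (`species`, `pc1`, `pc2`).
#' @param labels 0/1 (or logical) vector aligned to `space$species`; `NA`
#'   rows are dropped.
#' @param k Basis dimension of the 2-D smooth (default 30).
#' @param method Smoothing-parameter criterion passed to [mgcv::gam()]
#'   (default `"REML"`).
#' @return An object of class `"fs_surface"` wrapping the `gam` fit, with the
#'   data kept for prediction.
#' @export
fit_risk_surface <- function(space, labels, k = 30, method = "REML") {
  labels <- as.integer(labels)
  keep <- !is.na(labels)
  d <- tibble::tibble(pc1 = space$pc1[keep], pc2 = space$pc2[keep],
                      y = labels[keep])
  if (length(unique(d$y)) < 2) {
    stop("labels contain a single class; cannot fit a risk surface")
  }
  k <- min(k, nrow(d) - 2)
  fit <- mgcv::gam(y ~ s(pc1, pc2, k = k), family = stats::binomial(),
                   data = d, method = method)
  if (max(abs(stats::coef(fit))) > 1e3) {
    warning("possible separation: very large smooth coefficients")
  }
  structure(list(gam = fit, data = d, mean_prob = mean(d$y), k = k,
                 method = method), class = "fs_surface")
}

#' @export
print.fs_surface <- function(x, ...) {
  st <- smooth_term_test(x)
  cat("<fs_surface> binomial smooth on", nrow(x$data), "species; edf =",
      round(st$edf, 2), ", chi2 =", round(st$chi2, 2),
      ", p =", signif(st$p_value, 3), "\n")
  invisible(x)
}

#' Significance test of the smooth term
#'
#' Wald-type test of the fitted 2-D smooth against the constant model, as
#' reported by the GAM machinery (test statistic on the chi-square scale with
#' the smooth's reference degrees of freedom). A smooth shrunk to (near)
#' nothing yields a statistic near 0 and p near 1.
#'
#' @param model An [fit_risk_surface()] result.
#' @return Tibble with `chi2`, `edf`, `ref_df`, `p_value`.
#' @export
smooth_term_test <- function(model) {
  stopifnot(inherits(model, "fs_surface"))
  st <- summary(model$gam)$s.table
  tibble::tibble(chi2 = st[1, "Chi.sq"], edf = st[1, "edf"],
                 ref_df = st[1, "Ref.df"], p_value = st[1, "p-value"])
}

#' Predicted probability surface with confidence bands
#'
#' Predicts the fitted probability over a rectangular grid spanning the data,
#' with pointwise 95% confidence bands computed on the link scale and mapped
#' through the inverse logit (so bands always contain the point estimate and
#' stay inside (0, 1)). Cells outside the convex hull of the data are flagged
#' as extrapolated.
#'
#' @param model An [fit_risk_surface()] result.
#' @param grid Optional `tpd_grid_spec`/`tpd_grid` supplying cell centres;
#'   default a `cells_per_dim^2` grid over the data range.
#' @param cells_per_dim Grid resolution when `grid` is `NULL` (default 100).
#' @return Tibble: `pc1`, `pc2`, `prob`, `lo`, `hi`, `extrapolated`; the
#'   attribute `"mean_prob"` holds the average observed probability (the
#'   red-contour level of the maps).
#' @export
predict_surface <- function(model, grid = NULL, cells_per_dim = 100) {
  stopifnot(inherits(model, "fs_surface"))
  d <- model$data
  if (is.null(grid)) {
    xs <- seq(min(d$pc1), max(d$pc1), length.out = cells_per_dim)
    ys <- seq(min(d$pc2), max(d$pc2), length.out = cells_per_dim)
  } else {
    xs <- grid$x_mid
    ys <- grid$y_mid
  }
  nd <- expand.grid(pc1 = xs, pc2 = ys, KEEP.OUT.ATTRS = FALSE)
  pr <- mgcv::predict.gam(model$gam, newdata = nd, type = "link", se.fit = TRUE)
  hull <- grDevices::chull(d$pc1, d$pc2)
  inside <- mgcv::in.out(
    as.matrix(d[c(hull, hull[1]), c("pc1", "pc2")]),
    as.matrix(nd)
  )
  out <- tibble::as_tibble(nd)
  eta <- as.numeric(pr$fit)
  se <- as.numeric(pr$se.fit)
  out$prob <- stats::plogis(eta)
  out$lo <- stats::plogis(eta - 1.96 * se)
  out$hi <- stats::plogis(eta + 1.96 * se)
  out$extrapolated <- !inside
  attr(out, "mean_prob") <- model$mean_prob
  out
}

#' @export
tidy.fs_surface <- function(x, ...) smooth_term_test(x)

#' @export
glance.fs_surface <- function(x, ...) {
  st <- smooth_term_test(x)
  tibble::tibble(
    n = nrow(x$data), mean_prob = x$mean_prob, edf = st$edf,
    chi2 = st$chi2, p_value = st$p_value,
    deviance = stats::deviance(x$gam), aic = stats::AIC(x$gam)
  )
}
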