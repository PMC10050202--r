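#' Unconstrained plug-in bandwidth for a 2-D kernel density
#'
#' Two-dimensional plug-in selector in the Wand-Jones tradition: the data are
#' pre-sphered, the fourth-order integrated density-derivative functionals
#' `psi_r` are estimated with a normal-scale pilot, the asymptotic MISE of a
#' full (unconstrained) Gaussian bandwidth matrix is minimised numerically,
#' and the result is conjugated back to the data scale. The full matrix
#' permits correlated, anisotropic kernels. Collinear point clouds fall back
#' to a diagonal normal-reference (Silverman-type) rule with a warning.
#'
#' @param points Matrix/data frame with 2 columns (or a functional-space
#'   tibble with `pc1`, `pc2`).
#' @return A 2 x 2 symmetric positive-definite bandwidth matrix `H`
#'   (squared-PC units).
#' @export
select_bandwidth <- function(points) {
  P <- as_points(points)
  n <- nrow(P)
  if (n < 10) stop("need at least 10 points to select a bandwidth")
  S <- stats::cov(P)
  sds <- sqrt(diag(S))
  if (any(sds == 0)) stop("degenerate scatter: a coordinate is constant")
  det_ok <- det(S) / prod(diag(S)) > 1e-10
  if (!det_ok) {
    warning("points are (near-)collinear; falling back to a diagonal normal-reference bandwidth")
    return(diag((sds * n^(-1 / 6))^2))
  }
  es <- eigen(S, symmetric = TRUE)
  A <- es$vectors %*% diag(sqrt(es$values)) %*% t(es$vectors)     # S^(1/2)
  Ai <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  Z <- P %*% Ai

  psi <- psi_functionals(Z, g = n^(-1 / 8))
  amise <- function(par) {
    h11 <- exp(par[1]); h22 <- exp(par[2])
    h12 <- tanh(par[3]) * sqrt(h11 * h22)
    detH <- h11 * h22 - h12^2
    if (detH <= 0) return(Inf)
    bias <- h11^2 * psi["40"] + h22^2 * psi["04"] +
      (4 * h12^2 + 2 * h11 * h22) * psi["22"] +
      4 * h11 * h12 * psi["31"] + 4 * h12 * h22 * psi["13"]
    1 / (4 * pi * n * sqrt(detH)) + 0.25 * bias
  }
  start <- c(log(n^(-1 / 3)), log(n^(-1 / 3)), 0)
  opt <- stats::optim(start, amise, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-10))
  h11 <- exp(opt$par[1]); h22 <- exp(opt$par[2])
  h12 <- tanh(opt$par[3]) * sqrt(h11 * h22)
  Hs <- matrix(c(h11, h12, h12, h22), 2, 2)
  if (!is.finite(opt$value) || any(!is.finite(Hs)) || det(Hs) <= 0) {
    Hs <- diag(2) * n^(-1 / 3)  # normal reference on the sphered scale
  }
  H <- A %*% Hs %*% t(A)
  (H + t(H)) / 2
}

# Estimate the five fourth-order functionals psi_r = int D^r f * f on sphered
# data with an isotropic Gaussian pilot of SD g: psi_r is the average over all
# point pairs of the r-th derivative of the pilot kernel at their difference.
psi_functionals <- function(Z, g) {
  n <- nrow(Z)
  d1 <- outer(Z[, 1], Z[, 1], "-") / g
  d2 <- outer(Z[, 2], Z[, 2], "-") / g
  phi1 <- stats::dnorm(d1) / g
  phi2 <- stats::dnorm(d2) / g
  he <- function(x, k) {
    switch(as.character(k),
           "0" = 1, "1" = x, "2" = x^2 - 1, "3" = x^3 - 3 * x,
           "4" = x^4 - 6 * x^2 + 3)
  }
  deriv1 <- function(x, phi, k) (-1)^k * g^(-k) * he(x, k) * phi
  est <- function(k1, k2) {
    mean(deriv1(d1, phi1, k1) * deriv1(d2, phi2, k2))
  }
  c("40" = est(4, 0), "04" = est(0, 4), "22" = est(2, 2),
    "31" = est(3, 1), "13" = est(1, 3))
}

as_points <- function(points) {
  if (is.data.frame(points) && all(c("pc1", "pc2") %in% names(points))) {
    P <- cbind(points$pc1, points$pc2)
  } else {
    P <- as.matrix(points)
  }
  if (ncol(P) != 2) stop("points must be 2-dimensional")
  if (any(!is.finite(P))) stop("points must be finite")
  storage.mode(P) <- "double"
  P
}

#' Build the shared evaluation grid of the functional space
#'
#' Equal-width cells spanning the data range expanded on each side by
#' `pad * sqrt(max eigenvalue of H)` (the kernel SD along its widest axis),
#' so kernel mass is not clipped. The grid is built once from the full
#' species set and reused for every extinction-scenario subset, which makes
#' "cells becoming empty" well defined.
#'
#' @param points Points (see [select_bandwidth()]).
#' @param cells_per_dim Cells per axis (default 200, i.e. 40,000 cells).
#' @param pad Padding in kernel-SD units (default 3; 0 = exact data range).
#' @param bw Bandwidth matrix; required when `pad > 0`.
#' @return A list of class `"tpd_grid_spec"`: `x_edges`, `y_edges` (length
#'   `cells_per_dim + 1`), `x_mid`, `y_mid`, `cell_area`, `cells_per_dim`.
#' @export
build_grid <- function(points, cells_per_dim = 200, pad = 3, bw = NULL) {
  if (cells_per_dim < 2) stop("`cells_per_dim` must be at least 2")
  P <- as_points(points)
  expand <- 0
  if (pad > 0) {
    if (is.null(bw)) stop("`bw` is required when `pad` > 0")
    expand <- pad * sqrt(max(eigen(bw, symmetric = TRUE,
                                   only.values = TRUE)$values))
  }
  rx <- range(P[, 1]) + c(-expand, expand)
  ry <- range(P[, 2]) + c(-expand, expand)
  if (diff(rx) == 0 || diff(ry) == 0) stop("degenerate range: points are identical along an axis")
  x_edges <- seq(rx[1], rx[2], length.out = cells_per_dim + 1)
  y_edges <- seq(ry[1], ry[2], length.out = cells_per_dim + 1)
  structure(list(
    x_edges = x_edges, y_edges = y_edges,
    x_mid = (x_edges[-1] + x_edges[-length(x_edges)]) / 2,
    y_mid = (y_edges[-1] + y_edges[-length(y_edges)]) / 2,
    cell_area = diff(x_edges[1:2]) * diff(y_edges[1:2]),
    cells_per_dim = cells_per_dim
  ), class = "tpd_grid_spec")
}

# Per-species Gaussian kernel values at all cell centres: S x (cells^2)
# matrix, row s = N(cell; point_s, H) in column-major (x fastest) cell order.
species_kernel_matrix <- function(points, bw, grid) {
  P <- as_points(points)
  Hi <- solve(bw)
  dH <- det(bw)
  if (dH <= 0) stop("bandwidth matrix must be positive definite")
  norm_const <- 1 / (2 * pi * sqrt(dH))
  nx <- length(grid$x_mid); ny <- length(grid$y_mid)
  K <- matrix(NA_real_, nrow(P), nx * ny)
  for (s in seq_len(nrow(P))) {
    dx <- grid$x_mid - P[s, 1]
    dy <- grid$y_mid - P[s, 2]
    Q <- outer(Hi[1, 1] * dx^2, rep(1, ny)) +
      2 * Hi[1, 2] * outer(dx, dy) +
      outer(rep(1, nx), Hi[2, 2] * dy^2)
    K[s, ] <- norm_const * exp(-0.5 * as.vector(Q))
  }
  K
}

#' Trait probability density on the grid
#'
#' Evaluates the TPD at every cell centre as the equal-weight mixture of
#' per-species Gaussian kernels `(1/S) sum_s N(cell; point_s, H)` (midpoint
#' rule), then renormalises so the density integrates to exactly 1 over the
#' grid, compensating the truncation of kernel tails.
#'
#' @param points Species coordinates in the functional space.
#' @param bw 2 x 2 bandwidth matrix from [select_bandwidth()].
#' @param grid Grid from [build_grid()].
#' @return An object of class `"tpd_grid"`: the grid fields plus `density`
#'   (cells x cells matrix, x indexing rows), `n_species`, `occupancy`
#'   (`NULL` until [hdr_threshold()]), `threshold_q`.
#' @export
tpd_density <- function(points, bw, grid) {
  P <- as_points(points)
  if (nrow(P) < 1) stop("need at least one point")
  K <- species_kernel_matrix(P, bw, grid)
  dens <- colSums(K) / nrow(P)
  dens <- dens / (sum(dens) * grid$cell_area)
  new_tpd_grid(dens, grid, n_species = nrow(P))
}

new_tpd_grid <- function(dens_vec, grid, n_species,
                         occupancy = NULL, threshold_q = NULL) {
  nx <- length(grid$x_mid)
  structure(list(
    x_edges = grid$x_edges, y_edges = grid$y_edges,
    x_mid = grid$x_mid, y_mid = grid$y_mid,
    cell_area = grid$cell_area, cells_per_dim = grid$cells_per_dim,
    density = matrix(dens_vec, nx), n_species = n_species,
    occupancy = occupancy, threshold_q = threshold_q
  ), class = "tpd_grid")
}

#' @export
print.tpd_grid <- function(x, ...) {
  cat("<tpd_grid>", x$cells_per_dim, "x", x$cells_per_dim, "cells,",
      x$n_species, "species")
  if (!is.null(x$threshold_q)) {
    cat("; thresholded at q =", x$threshold_q,
        "(", sum(x$occupancy), "occupied cells )")
  }
  cat("\n")
  invisible(x)
}

# Occupancy of the smallest set of highest-density cells reaching mass q.
# Ties in density are broken by cell index (row-major over the vectorised
# density) for determinism.
occupancy_from_density <- function(dens_vec, cell_area, q) {
  if (q >= 1) return(dens_vec > 0)
  ord <- order(dens_vec, seq_along(dens_vec), decreasing = c(TRUE, FALSE),
               method = "radix")
  mass <- cumsum(dens_vec[ord]) * cell_area
  total <- mass[length(mass)]
  k <- which(mass >= min(q, total) - 1e-12)[1]
  occ <- logical(length(dens_vec))
  occ[ord[seq_len(k)]] <- dens_vec[ord[seq_len(k)]] > 0
  occ
}

#' Highest-density-region thresholding
#'
#' Keeps the smallest set of highest-density cells whose cumulative mass
#' reaches `q` (default 99%, trimming outlier tails), zeroes the density
#' outside it, and renormalises the retained mass to 1.
#'
#' @param grid A [tpd_density()] result.
#' @param q Quantile threshold in `(0, 1]`.
#' @return The `tpd_grid` with `occupancy` filled and density renormalised.
#' @export
hdr_threshold <- function(grid, q = 0.99) {
  stopifnot(inherits(grid, "tpd_grid"))
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q > 1) {
    stop("`q` must be in (0, 1]")
  }
  v <- as.vector(grid$density)
  occ <- occupancy_from_density(v, grid$cell_area, q)
  v[!occ] <- 0
  v <- v / (sum(v) * grid$cell_area)
  grid$density <- matrix(v, nrow(grid$density))
  grid$occupancy <- matrix(occ, nrow(grid$density))
  grid$threshold_q <- q
  grid
}

#' Nested quantile contours of a TPD
#'
#' Occupancy masks of the highest-density regions containing each requested
#' fraction of total density; masks are nested by construction.
#'
#' @param grid A [tpd_density()] result (thresholded or not; the raw density
#'   is used).
#' @param qs Quantiles, default `c(0.5, 0.6, 0.7, 0.8, 0.9, 0.99)`.
#' @return Named list of logical cell matrices.
#' @export
quantile_contours <- function(grid, qs = c(0.5, 0.6, 0.7, 0.8, 0.9, 0.99)) {
  stopifnot(inherits(grid, "tpd_grid"))
  v <- as.vector(grid$density)
  out <- lapply(qs, function(q) {
    matrix(occupancy_from_density(v, grid$cell_area, q), nrow(grid$density))
  })
  names(out) <- paste0("q", qs)
  out
}

#' Functional richness of a thresholded TPD
#'
#' The area of the occupied region: occupied-cell count times cell area.
#'
#' @param grid A thresholded `tpd_grid`.
#' @return Occupied area (squared PC units).
#' @export
tpd_richness <- function(grid) {
  stopifnot(inherits(grid, "tpd_grid"))
  if (is.null(grid$occupancy)) {
    stop("grid is not thresholded; call hdr_threshold() first")
  }
  sum(grid$occupancy) * grid$cell_area
}

#' Hotspot summary of the functional space
#'
#' Fraction of species falling inside the `q` highest-density region, and the
#' area of that region as a fraction of the 99% region (the "total
#' spectrum").
#'
#' @param grid A `tpd_grid` (raw density is used).
#' @param points Species coordinates.
#' @param q Hotspot quantile (default 0.5).
#' @return Tibble with `species_fraction`, `area_fraction`, `n_inside`.
#' @export
hotspot_summary <- function(grid, points, q = 0.5) {
  stopifnot(inherits(grid, "tpd_grid"))
  P <- as_points(points)
  v <- as.vector(grid$density)
  mask_q <- occupancy_from_density(v, grid$cell_area, q)
  mask_99 <- occupancy_from_density(v, grid$cell_area, 0.99)
  nx <- length(grid$x_mid)
  ix <- findInterval(P[, 1], grid$x_edges, rightmost.closed = TRUE)
  iy <- findInterval(P[, 2], grid$y_edges, rightmost.closed = TRUE)
  inside_grid <- ix >= 1 & ix <= nx & iy >= 1 & iy <= nx
  cell <- (iy - 1) * nx + ix
  n_in <- sum(mask_q[cell[inside_grid]])
  tibble::tibble(
    species_fraction = n_in / nrow(P),
    area_fraction = sum(mask_q) / sum(mask_99),
    n_inside = n_in
  )
}

#' Write a TPD grid and its quantile contours to plain-text files
#'
#' Writes the cell table (`tpd_cells.csv`: coordinates, density, occupancy),
#' the grid metadata (`tpd_meta.yaml`: edges, threshold, bandwidth), and one
#' CSV of occupied cell indices per requested contour quantile.
#'
#' @param grid A `tpd_grid`.
#' @param dir Output directory (created if needed).
#' @param bw Optional bandwidth matrix to record in the metadata.
#' @param qs Contour quantiles to export (default none).
#' @return `dir`, invisibly.
#' @export
write_tpd <- function(grid, dir, bw = NULL, qs = NULL) {
  stopifnot(inherits(grid, "tpd_grid"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tidy(grid), file.path(dir, "tpd_cells.csv"))
  meta <- list(cells_per_dim = grid$cells_per_dim, cell_area = grid$cell_area,
               x_edges = range(grid$x_edges), y_edges = range(grid$y_edges),
               threshold_q = grid$threshold_q, n_species = grid$n_species)
  if (!is.null(bw)) meta$bandwidth <- as.vector(bw)
  yaml::write_yaml(meta, file.path(dir, "tpd_meta.yaml"))
  if (!is.null(qs)) {
    masks <- quantile_contours(grid, qs)
    for (nm in names(masks)) {
      idx <- which(masks[[nm]], arr.ind = TRUE)
      readr::write_csv(tibble::tibble(x_cell = idx[, 1], y_cell = idx[, 2]),
                       file.path(dir, paste0("contour_", nm, ".csv")))
    }
  }
  invisible(dir)
}

#' Tidy the cells of a TPD grid
#' @param x A `tpd_grid`.
#' @param ... Unused.
#' @return Tibble with `pc1`, `pc2`, `density`, `occupied`.
#' @export
tidy.tpd_grid <- function(x, ...) {
  occ <- if (is.null(x$occupancy)) x$density > 0 else x$occupancy
  tibble::tibble(
    pc1 = rep(x$x_mid, times = length(x$y_mid)),
    pc2 = rep(x$y_mid, each = length(x$x_mid)),
    density = as.vector(x$density),
    occupied = as.vector(occ)
  )
}
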