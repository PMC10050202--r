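test_that("plug-in bandwidth has the right scale on isotropic normal data", {
  P <- normal_points(1000, seed = 1)
  H <- select_bandwidth(P)
  # near-isotropic
  expect_lt(abs(H[1, 2]) / sqrt(H[1, 1] * H[2, 2]), 0.2)
  # per-axis SD within 25% of the n^(-1/6) reference scaling
  href <- 1000^(-1 / 6)
  expect_lt(abs(sqrt(H[1, 1]) - href) / href, 0.25)
  expect_lt(abs(sqrt(H[2, 2]) - href) / href, 0.25)
})

test_that("bandwidth is scale- and rotation-equivariant and falls back when collinear", {
  set.seed(9)
  P <- matrix(rnorm(600), 300, 2) %*% matrix(c(1, 0.5, 0, 0.8), 2)
  H <- select_bandwidth(P)
  expect_equal(select_bandwidth(3 * P), 9 * H, tolerance = 1e-6)
  th <- 0.7
  Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(select_bandwidth(P %*% t(Q)), Q %*% H %*% t(Q),
               tolerance = 1e-3, ignore_attr = TRUE)
  line <- cbind(1:50, 2 * (1:50))
  expect_warning(Hl <- select_bandwidth(line), "collinear")
  expect_true(all(diag(Hl) > 0) && Hl[1, 2] == 0)
  expect_error(select_bandwidth(P[1:5, ]), "at least 10")
})

test_that("the grid has the requested geometry", {
  P <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  g0 <- build_grid(P, cells_per_dim = 10, pad = 0)
  expect_equal(range(g0$x_edges), c(0, 1))
  expect_equal(range(g0$y_edges), c(0, 1))
  expect_length(g0$x_edges, 11)

  g200 <- build_grid(P, cells_per_dim = 200, pad = 0)
  expect_equal(length(g200$x_mid) * length(g200$y_mid), 40000)

  expect_error(build_grid(P, cells_per_dim = 1, pad = 0), "at least 2")
  expect_error(build_grid(matrix(1, 5, 2), pad = 0), "degenerate")
})

test_that("TPD density equals the direct Gaussian-mixture oracle and integrates to 1", {
  set.seed(3)
  P <- matrix(rnorm(100), 50, 2)
  H <- matrix(c(0.09, 0.02, 0.02, 0.06), 2)
  grid <- build_grid(P, cells_per_dim = 40, pad = 3, bw = H)
  tp <- tpd_density(P, H, grid)
  expect_equal(sum(tp$density) * tp$cell_area, 1, tolerance = 1e-9)

  oracle <- direct_mixture_density(P, H, grid$x_mid, grid$y_mid)
  oracle_norm <- oracle / (sum(oracle) * tp$cell_area)
  expect_equal(max(abs(tp$density - oracle_norm)) / max(oracle_norm), 0,
               tolerance = 1e-10)

  # symmetry: two species mirrored through the origin
  P2 <- rbind(c(1, 0.5), c(-1, -0.5))
  g2 <- build_grid(rbind(c(-2, -2), c(2, 2)), cells_per_dim = 81, pad = 0)
  d2 <- tpd_density(P2, diag(0.2, 2), g2)$density
  expect_equal(d2, d2[rev(seq_len(81)), rev(seq_len(81))], tolerance = 1e-10)

  # species-order permutation invariance
  tp_perm <- tpd_density(P[sample(50), ], H, grid)
  expect_equal(tp$density, tp_perm$density, tolerance = 1e-12)
})

test_that("HDR thresholding keeps the smallest top set reaching q and renormalises", {
  set.seed(6)
  P <- matrix(rnorm(80), 40, 2)
  H <- select_bandwidth(P)
  grid <- build_grid(P, cells_per_dim = 60, pad = 3, bw = H)
  tp <- tpd_density(P, H, grid)

  th <- hdr_threshold(tp, 0.99)
  expect_equal(sum(th$density) * th$cell_area, 1, tolerance = 1e-9)
  expect_true(all(!th$occupancy | tp$density > 0))

  # greedy optimality: mass inside >= q, and removing the last cell drops below
  v <- as.vector(tp$density)
  occ <- as.vector(th$occupancy)
  inside <- sum(v[occ]) * tp$cell_area
  expect_gte(inside, 0.99 - 1e-9)
  smallest_kept <- min(v[occ])
  expect_lt(inside - smallest_kept * tp$cell_area, 0.99)

  # q = 1 keeps every positive cell
  t1 <- hdr_threshold(tp, 1)
  expect_equal(sum(t1$occupancy), sum(tp$density > 0))
  expect_error(hdr_threshold(tp, 0), "\\(0, 1\\]")

  # uniform density over k cells at q = 0.5 keeps ceiling(k/2), tie-break by index
  ug <- tp
  k <- 10
  vv <- rep(0, length(v)); vv[1:k] <- 1
  ug$density <- matrix(vv / (sum(vv) * tp$cell_area), nrow(tp$density))
  uth <- hdr_threshold(ug, 0.5)
  expect_equal(sum(uth$occupancy), ceiling(k / 2))
  expect_true(all(which(as.vector(uth$occupancy)) == 1:ceiling(k / 2)))
})

test_that("quantile contours are nested and concentric for a unimodal density", {
  set.seed(10)
  P <- matrix(rnorm(400), 200, 2)
  H <- select_bandwidth(P)
  grid <- build_grid(P, cells_per_dim = 80, pad = 3, bw = H)
  tp <- tpd_density(P, H, grid)
  masks <- quantile_contours(tp)
  qs <- c(0.5, 0.6, 0.7, 0.8, 0.9, 0.99)
  for (i in seq_len(length(masks) - 1)) {
    expect_true(all(masks[[i + 1]][masks[[i]]]))  # nestedness
  }
  # radial ordering: every cell of the 50% mask is denser than any outside
  # the 90% mask
  expect_gt(min(tp$density[masks[[1]]]), max(tp$density[!masks[[5]]]))
})

test_that("richness and hotspot summaries behave at the extremes", {
  set.seed(12)
  P <- matrix(rnorm(300), 150, 2)
  H <- select_bandwidth(P)
  grid <- build_grid(P, cells_per_dim = 60, pad = 3, bw = H)
  tp <- tpd_density(P, H, grid)
  expect_error(tpd_richness(tp), "threshold")
  th <- hdr_threshold(tp, 0.99)
  expect_equal(tpd_richness(th), sum(th$occupancy) * th$cell_area)

  hs <- hotspot_summary(th, P, q = 0.999999)
  expect_gt(hs$species_fraction, 0.97)

  # two well-separated equal clusters: the 50% HDR splits its area evenly
  # between the clusters and captures at least half the species (kernel
  # smoothing concentrates the mass, so the fraction exceeds 0.5)
  set.seed(13)
  Pc <- rbind(matrix(rnorm(400, 0, 0.5), 200, 2),
              matrix(rnorm(400, 12, 0.5), 200, 2))
  Hc <- select_bandwidth(Pc)
  gc_ <- build_grid(Pc, cells_per_dim = 100, pad = 3, bw = Hc)
  tc <- hdr_threshold(tpd_density(Pc, Hc, gc_), 0.99)
  hc <- hotspot_summary(tc, Pc, q = 0.5)
  expect_gte(hc$species_fraction, 0.5)
  mask <- funspectra:::occupancy_from_density(as.vector(tc$density),
                                              tc$cell_area, 0.5)
  cells <- tidy(tc)
  left <- sum(mask & cells$pc1 < 6)
  right <- sum(mask & cells$pc1 > 6)
  expect_equal(left, right, tolerance = 0.2)

  # richness is stable under grid refinement for a smooth density
  g2 <- build_grid(P, cells_per_dim = 120, pad = 3, bw = H)
  th2 <- hdr_threshold(tpd_density(P, H, g2), 0.99)
  expect_lt(abs(tpd_richness(th2) - tpd_richness(th)) / tpd_richness(th), 0.05)
})
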