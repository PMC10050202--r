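# Shared fixtures, built once per test run.

# small deterministic three-tip tree: ((A:1,B:1):1,C:2);
tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

star_tree <- function(n, depth = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(depth, nrow(tr$edge))
  tr
}

# a BM trait on a tree, drawn under lambda
bm_trait <- function(tree, lambda = 1, sigma2 = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- phylo_vcv(tree)
  Cl <- lambda_transform(C, lambda)
  y <- drop(crossprod(chol(Cl + diag(1e-12, nrow(Cl))),
                      stats::rnorm(nrow(Cl)))) * sqrt(sigma2)
  stats::setNames(y, tree$tip.label)
}

# medium synthetic world reused across test files
fixture_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(sim_config(n_species = 100, seed = 2024))
    }
    cache
  }
})

# simple isotropic-normal point cloud
normal_points <- function(n, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(2 * n), n, 2)
}

# direct Gaussian-mixture density oracle (no grid tricks)
direct_mixture_density <- function(points, H, xs, ys) {
  Hi <- solve(H)
  nc <- 1 / (2 * pi * sqrt(det(H)))
  out <- matrix(0, length(xs), length(ys))
  for (s in seq_len(nrow(points))) {
    for (i in seq_along(xs)) {
      for (j in seq_along(ys)) {
        d <- c(xs[i] - points[s, 1], ys[j] - points[s, 2])
        out[i, j] <- out[i, j] + nc * exp(-0.5 * drop(t(d) %*% Hi %*% d))
      }
    }
  }
  out / nrow(points)
}
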