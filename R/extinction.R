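#' Valid extinction-scenario labels
#'
#' Cumulative IUCN scenarios (`-CR`, `-EN`, `-VU`, `-NT`) and per-threat
#' scenarios in two variants: `<threat>_all` removes every species carrying
#' the threat flag, `<threat>_threatened` removes only the threatened
#' (CR/EN/VU) species carrying it.
#'
#' @return Character vector of labels.
#' @export
scenario_labels <- function() {
  c("-CR", "-EN", "-VU", "-NT",
    paste0(rep(threat_names(), each = 2), c("_all", "_threatened")))
}

#' Species removed under an extinction scenario
#'
#' IUCN scenarios are cumulative: `-CR` removes CR; `-EN` removes CR and EN;
#' `-VU` removes CR, EN and VU; `-NT` additionally removes NT. Data Deficient
#' and unassessed species are never removed by IUCN scenarios. Threat
#' scenarios remove the species whose flag is `TRUE` (variant `_all`) or the
#' intersection of that set with the threatened categories (variant
#' `_threatened`); species with unknown (NA) flags are never removed.
#'
#' @param meta Species metadata tibble (`species`, `iucn`, threat flags).
#' @param scenario A label from [scenario_labels()].
#' @return Character vector of species to remove.
#' @export
scenario_species <- function(meta, scenario) {
  if (!scenario %in% scenario_labels()) {
    stop("unknown scenario '", scenario, "'; valid labels: ",
         paste(scenario_labels(), collapse = ", "))
  }
  if (startsWith(scenario, "-")) {
    cats <- switch(scenario,
                   "-CR" = "CR",
                   "-EN" = c("CR", "EN"),
                   "-VU" = c("CR", "EN", "VU"),
                   "-NT" = c("CR", "EN", "VU", "NT"))
    return(meta$species[!is.na(meta$iucn) & meta$iucn %in% cats])
  }
  threatened_only <- endsWith(scenario, "_threatened")
  threat <- sub("_(all|threatened)$", "", scenario)
  flag <- !is.na(meta[[threat]]) & meta[[threat]]
  if (threatened_only) {
    flag <- flag & !is.na(meta$iucn) & meta$iucn %in% c("CR", "EN", "VU")
  }
  meta$species[flag]
}

# Loss of occupied cells relative to a baseline occupancy, computed from a
# precomputed kernel matrix; keep_idx indexes rows of K.
loss_from_kernels <- function(K, keep_idx, baseline_occ, cell_area, q) {
  n_base <- sum(baseline_occ)
  if (length(keep_idx) == 0) return(100)
  dens <- colSums(K[keep_idx, , drop = FALSE]) / length(keep_idx)
  dens <- dens / (sum(dens) * cell_area)
  occ <- occupancy_from_density(dens, cell_area, q)
  100 * sum(baseline_occ & !occ) / n_base
}

#' Percentage of functional diversity lost after removing species
#'
#' Rebuilds the TPD for the reduced species set on the shared grid and
#' bandwidth, thresholds it, and reports the percentage of baseline-occupied
#' cells that became empty.
#'
#' @param baseline A thresholded `tpd_grid` for the full pool.
#' @param reduced_points Coordinates of the surviving species.
#' @param bw Shared bandwidth matrix.
#' @param grid Shared grid specification ([build_grid()]).
#' @param q Threshold quantile (default the baseline's).
#' @return Loss percentage in `[0, 100]`.
#' @export
diversity_loss <- function(baseline, reduced_points, bw, grid,
                           q = baseline$threshold_q) {
  stopifnot(inherits(baseline, "tpd_grid"))
  if (is.null(baseline$occupancy)) stop("baseline must be thresholded")
  if (is.null(q)) q <- 0.99
  base_occ <- as.vector(baseline$occupancy)
  P <- tryCatch(as_points(reduced_points), error = function(e) NULL)
  if (is.null(P) || nrow(P) == 0) {
    message("empty reduced set: loss is 100%")
    return(100)
  }
  K <- species_kernel_matrix(P, bw, grid)
  loss_from_kernels(K, seq_len(nrow(P)), base_occ, grid$cell_area, q)
}

#' Null envelope of functional-diversity loss under random extinctions
#'
#' Removes `n_removed` species uniformly at random (without replacement) from
#' the pool `n_iter` times (default 999), recomputes the loss each time, and
#' returns the 5th, 50th and 95th percentiles (linear interpolation).
#'
#' @param points Coordinates of the pool species.
#' @param n_removed Number of species to remove per iteration.
#' @param bw,grid Shared bandwidth and grid.
#' @param baseline Thresholded baseline `tpd_grid` for the pool.
#' @param n_iter Number of randomisations (default 999).
#' @param seed Integer seed.
#' @param q Threshold quantile.
#' @return Tibble with `p5`, `p50`, `p95` and the vector of losses as the
#'   attribute `"losses"`.
#' @export
null_envelope <- function(points, n_removed, bw, grid, baseline,
                          n_iter = 999, seed = 1L, q = baseline$threshold_q) {
  if (n_iter < 1) stop("`n_iter` must be at least 1")
  P <- as_points(points)
  if (n_removed > nrow(P)) stop("`n_removed` exceeds the pool size")
  K <- species_kernel_matrix(P, bw, grid)
  env <- null_envelope_kernels(K, n_removed, as.vector(baseline$occupancy),
                               grid$cell_area, if (is.null(q)) 0.99 else q,
                               n_iter, seed)
  env
}

null_envelope_kernels <- function(K, n_removed, base_occ, cell_area, q,
                                  n_iter, seed, chunk = 64L) {
  set.seed(seed)
  n <- nrow(K)
  if (n_removed == 0) {
    losses <- rep(0, n_iter)
  } else if (n_removed == n) {
    losses <- rep(100, n_iter)
  } else {
    # batched: each chunk of iterations is one 0/1 keep-indicator matrix
    # multiplied against the kernel matrix (BLAS), then thresholded per row
    n_base <- sum(base_occ)
    losses <- numeric(n_iter)
    done <- 0L
    while (done < n_iter) {
      b <- min(chunk, n_iter - done)
      M <- matrix(0, b, n)
      for (i in seq_len(b)) M[i, sample.int(n, n - n_removed)] <- 1
      D <- M %*% K
      for (i in seq_len(b)) {
        dens <- D[i, ] / (sum(D[i, ]) * cell_area)
        occ <- occupancy_from_density(dens, cell_area, q)
        losses[done + i] <- 100 * sum(base_occ & !occ) / n_base
      }
      done <- done + b
    }
  }
  qs <- stats::quantile(losses, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  out <- tibble::tibble(p5 = qs[1], p50 = qs[2], p95 = qs[3])
  attr(out, "losses") <- losses
  out
}

#' Run every extinction scenario with its null envelope
#'
#' IUCN scenarios run on the IUCN-assessed pool (species with a category,
#' including DD, which are never removed); threat scenarios run on the pool
#' of species with known threat flags. Bandwidth and grid are estimated once
#' from the full species set and shared across all subsets, so occupancy
#' masks are comparable cell by cell.
#'
#' @param space Functional-space tibble (`species`, `pc1`, `pc2`).
#' @param meta Species metadata tibble.
#' @param scenarios Labels to run (default all 16).
#' @param cells_per_dim,pad,q TPD settings (defaults 200, 3, 0.99).
#' @param n_iter Null-model iterations per scenario (default 999).
#' @param seed Master seed; scenario `i` uses `seed + i`.
#' @param bw,grid Optional precomputed bandwidth/grid (otherwise from the
#'   full space).
#' @return Tibble of class `"fs_scenarios"`: `scenario`, `pool`, `pool_size`,
#'   `n_removed`, `loss_pct`, `null_p5`, `null_p50`, `null_p95`,
#'   `exceeds_null`.
#' @export
run_scenarios <- function(space, meta, scenarios = scenario_labels(),
                          cells_per_dim = 200, pad = 3, q = 0.99,
                          n_iter = 999, seed = 1L, bw = NULL, grid = NULL) {
  stopifnot(all(space$species %in% meta$species))
  meta <- meta[match(space$species, meta$species), ]
  if (is.null(bw)) bw <- select_bandwidth(space)
  if (is.null(grid)) grid <- build_grid(space, cells_per_dim, pad, bw)

  known_threats <- stats::complete.cases(meta[threat_names()])
  pools <- list(
    iucn = space$species[!is.na(meta$iucn)],
    threat = space$species[known_threats]
  )
  # per-pool kernels and thresholded baselines, computed once
  pool_data <- lapply(pools, function(sp) {
    idx <- match(sp, space$species)
    K <- species_kernel_matrix(space[idx, ], bw, grid)
    dens <- colSums(K) / length(idx)
    dens <- dens / (sum(dens) * grid$cell_area)
    occ <- occupancy_from_density(dens, grid$cell_area, q)
    list(species = sp, K = K, occ = occ)
  })

  rows <- purrr::imap_dfr(scenarios, function(sc, i) {
    pool <- if (startsWith(sc, "-")) "iucn" else "threat"
    pd <- pool_data[[pool]]
    removed <- intersect(scenario_species(meta, sc), pd$species)
    keep <- which(!pd$species %in% removed)
    loss <- loss_from_kernels(pd$K, keep, pd$occ, grid$cell_area, q)
    env <- null_envelope_kernels(pd$K, length(removed), pd$occ,
                                 grid$cell_area, q, n_iter, seed + i)
    tibble::tibble(
      scenario = sc, pool = pool, pool_size = length(pd$species),
      n_removed = length(removed), loss_pct = loss,
      null_p5 = env$p5, null_p50 = env$p50, null_p95 = env$p95,
      exceeds_null = loss > env$p95
    )
  })
  class(rows) <- c("fs_scenarios", class(rows))
  rows
}

#' Per-continent threat composition
#'
#' For each continent (species with unknown continent are dropped): the
#' number of species with known threat flags, the fraction that is threatened
#' (CR/EN/VU), and the fraction affected by each threat.
#'
#' @param meta Species metadata tibble.
#' @return Tibble with one row per continent.
#' @export
continent_threat_ratios <- function(meta) {
  known <- stats::complete.cases(meta[threat_names()])
  df <- meta[known & !is.na(meta$continent), ]
  df |>
    dplyr::group_by(.data$continent) |>
    dplyr::summarise(
      n = dplyr::n(),
      frac_threatened = mean(.data$iucn %in% c("CR", "EN", "VU"), na.rm = FALSE),
      dplyr::across(dplyr::all_of(threat_names()), ~ mean(.x),
                    .names = "frac_{.col}"),
      .groups = "drop"
    )
}
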