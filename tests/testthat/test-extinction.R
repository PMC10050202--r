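test_that("scenario removal sets follow the cumulative IUCN definitions", {
  meta <- tibble::tibble(
    species = paste0("s", 1:12),
    iucn = c("CR", "CR", "EN", "EN", "EN", "VU", "VU", "VU", "VU",
             "NT", "LC", "DD")
  )
  for (nm in threat_names()) meta[[nm]] <- FALSE
  meta$habitat_degradation <- c(rep(TRUE, 6), rep(FALSE, 6))

  expect_length(scenario_species(meta, "-CR"), 2)
  expect_length(scenario_species(meta, "-EN"), 5)
  expect_length(scenario_species(meta, "-VU"), 9)
  expect_length(scenario_species(meta, "-NT"), 10)
  # DD never removed
  expect_false("s12" %in% scenario_species(meta, "-NT"))
  # nesting
  expect_true(all(scenario_species(meta, "-CR") %in% scenario_species(meta, "-EN")))
  expect_true(all(scenario_species(meta, "-EN") %in% scenario_species(meta, "-VU")))
  expect_true(all(scenario_species(meta, "-VU") %in% scenario_species(meta, "-NT")))

  expect_length(scenario_species(meta, "habitat_degradation_all"), 6)
  expect_length(scenario_species(meta, "habitat_degradation_threatened"), 6)
  meta$habitat_degradation[1:3] <- FALSE
  expect_length(scenario_species(meta, "habitat_degradation_threatened"), 3)
  expect_length(scenario_species(meta, "pollution_all"), 0)
  expect_error(scenario_species(meta, "nope"), "valid labels")
})

test_that("diversity loss is 0 for no removal and 100 for total removal", {
  set.seed(2)
  P <- matrix(rnorm(160), 80, 2)
  H <- select_bandwidth(P)
  grid <- build_grid(P, cells_per_dim = 50, pad = 3, bw = H)
  base <- hdr_threshold(tpd_density(P, H, grid), 0.99)
  expect_equal(diversity_loss(base, P, H, grid), 0)
  expect_message(l100 <- diversity_loss(base, P[0, , drop = FALSE], H, grid),
                 "100")
  expect_equal(l100, 100)
  # removing a few central species loses little
  few <- P[-(1:3), ]
  expect_lt(diversity_loss(base, few, H, grid), 15)
})

test_that("null envelopes are ordered, reproducible, and degenerate at n_removed = 0", {
  set.seed(4)
  P <- matrix(rnorm(120), 60, 2)
  H <- select_bandwidth(P)
  grid <- build_grid(P, cells_per_dim = 40, pad = 3, bw = H)
  base <- hdr_threshold(tpd_density(P, H, grid), 0.99)
  e0 <- null_envelope(P, 0, H, grid, base, n_iter = 50, seed = 1)
  expect_equal(c(e0$p5, e0$p50, e0$p95), c(0, 0, 0))
  e <- null_envelope(P, 15, H, grid, base, n_iter = 99, seed = 1)
  expect_lte(e$p5, e$p50)
  expect_lte(e$p50, e$p95)
  e2 <- null_envelope(P, 15, H, grid, base, n_iter = 99, seed = 1)
  expect_identical(e, e2)
  expect_error(null_envelope(P, 61, H, grid, base), "pool")
  expect_error(null_envelope(P, 5, H, grid, base, n_iter = 0), "n_iter")

  # removing more species loses more functional space, in median
  e_big <- null_envelope(P, 40, H, grid, base, n_iter = 99, seed = 2)
  expect_gt(e_big$p50, e$p50)
})

test_that("run_scenarios produces the full 16-scenario table with sane pools", {
  w <- fixture_world()
  scen <- run_scenarios(w$scores_true, w$meta, cells_per_dim = 60,
                        n_iter = 49, seed = 3)
  expect_equal(nrow(scen), 16)
  expect_setequal(scen$scenario, scenario_labels())
  expect_true(all(scen$loss_pct >= 0 & scen$loss_pct <= 100))
  expect_true(all(scen$null_p5 <= scen$null_p50 + 1e-12))
  expect_true(all(scen$null_p50 <= scen$null_p95 + 1e-12))
  # pools: IUCN scenarios use assessed species, threat scenarios threat-known
  n_assessed <- sum(!is.na(w$meta$iucn))
  n_known <- sum(stats::complete.cases(w$meta[threat_names()]))
  expect_equal(unique(scen$pool_size[startsWith(scen$scenario, "-")]), n_assessed)
  expect_equal(unique(scen$pool_size[!startsWith(scen$scenario, "-")]), n_known)
  # cumulative scenarios remove nested, growing sets
  iucn <- scen[match(c("-CR", "-EN", "-VU", "-NT"), scen$scenario), ]
  expect_true(all(diff(iucn$n_removed) >= 0))
})

test_that("trait-independent risk keeps observed losses inside the null envelope", {
  # calibration: when status is unrelated to trait-space position, the
  # observed loss behaves like one more draw from the null
  inside <- logical(30)
  for (i in seq_len(30)) {
    set.seed(100 + i)
    P <- matrix(rnorm(140), 70, 2)
    lab <- sample(c(rep(TRUE, 14), rep(FALSE, 56)))
    H <- select_bandwidth(P)
    grid <- build_grid(P, cells_per_dim = 40, pad = 3, bw = H)
    base <- hdr_threshold(tpd_density(P, H, grid), 0.99)
    loss <- diversity_loss(base, P[!lab, ], H, grid)
    e <- null_envelope(P, 14, H, grid, base, n_iter = 99, seed = 200 + i)
    inside[i] <- loss >= e$p5 & loss <= e$p95
  }
  expect_gte(mean(inside), 0.7)  # ~90% coverage, binomial noise at 30 worlds
})

test_that("peripheral high-risk species produce losses beyond the null envelope", {
  set.seed(41)
  core <- matrix(rnorm(300, 0, 0.6), 150, 2)
  ring_angle <- runif(25, 0, 2 * pi)
  periph <- cbind(3.5 * cos(ring_angle), 3.5 * sin(ring_angle)) +
    matrix(rnorm(50, 0, 0.15), 25, 2)
  P <- rbind(core, periph)
  H <- select_bandwidth(P)
  grid <- build_grid(P, cells_per_dim = 60, pad = 3, bw = H)
  base <- hdr_threshold(tpd_density(P, H, grid), 0.99)
  loss <- diversity_loss(base, core, H, grid)  # remove the peripheral 25
  e <- null_envelope(P, 25, H, grid, base, n_iter = 99, seed = 5)
  expect_gt(loss, e$p95)
})

test_that("continent ratios count threat-known species and bounded fractions", {
  w <- fixture_world()
  ct <- continent_threat_ratios(w$meta)
  expect_true(all(ct$frac_threatened >= 0 & ct$frac_threatened <= 1))
  known <- stats::complete.cases(w$meta[threat_names()])
  expect_equal(sum(ct$n), sum(known & !is.na(w$meta$continent)))
  one <- tibble::tibble(species = c("a", "b"), iucn = c("CR", "EN"),
                        continent = "Asia")
  for (nm in threat_names()) one[[nm]] <- TRUE
  ct1 <- continent_threat_ratios(one)
  expect_equal(ct1$frac_threatened, 1)
})
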