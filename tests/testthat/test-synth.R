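test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(fine_grid_shape = c(0, 10)), "zero-area")
  expect_error(synthetic_config(fine_grid_shape = c(10, 10),
                                coarsen_factor = 3), "divide")
  expect_error(synthetic_config(ar1_coefficient = 1), "< 1")
  expect_error(synthetic_config(noise_sd_space = -1), "non-negative")
  expect_error(synthetic_config(n_plots = 2, n_habitats = 8), "n_plots")
})

test_that("generator outputs are deterministic under a fixed seed", {
  cfg <- tiny_config()
  d1 <- generate_synthetic_dataset(cfg)
  d2 <- generate_synthetic_dataset(cfg)
  expect_identical(d1$land, d2$land)
  expect_identical(d1$plots, d2$plots)
  expect_identical(d1$climate$ref$energy$ts, d2$climate$ref$energy$ts)
  expect_identical(d1$climate$truth, d2$climate$truth)
  # a different seed changes the maps
  d3 <- generate_synthetic_dataset(tiny_config(seed = 43L))
  expect_false(identical(d1$land$ls_ref, d3$land$ls_ref))
})

test_that("scenario maps differ on approximately the configured fraction", {
  cfg <- synthetic_config(fine_grid_shape = c(100L, 100L),
                          coarsen_factor = 2L,
                          scenario_change_fraction = 0.3, seed = 9L)
  land <- generate_land_systems(cfg)
  n_diff <- sum(land$ls_ref != land$ls_scen)
  # direct cell-wise comparison against binomial sampling bounds
  expect_gt(n_diff, qbinom(0.0005, 1e4, 0.3))
  expect_lt(n_diff, qbinom(0.9995, 1e4, 0.3))
  # zero change fraction gives identical maps
  land0 <- generate_land_systems(tiny_config(scenario_change_fraction = 0))
  expect_identical(land0$ls_ref, land0$ls_scen)
})

test_that("crosswalk covers every mapped code; suitability is valid", {
  land <- generate_land_systems(tiny_config())
  present <- unique(c(as.vector(land$ls_ref), as.vector(land$ls_scen)))
  expect_true(all(present %in% land$crosswalk$land_system))
  expect_true(all(is.finite(land$suitability)))
  expect_true(all(land$suitability >= 0))
  expect_setequal(unique(land$habitat_tags$tag), c("cropland", "natural"))
})

test_that("plot archive covers every habitat with valid assignments", {
  cfg <- tiny_config()
  land <- generate_land_systems(cfg)
  pl <- generate_plot_table(cfg, land$habitat_tags)
  expect_setequal(unique(pl$plots$habitat), land$habitat_tags$habitat)
  expect_true(all(pl$plots$cover > 0))
  expect_true(all(pl$plots$species %in% pl$species_pft$species))
  expect_equal(anyDuplicated(pl$species_pft$species), 0L)
  # every species maps to a vegetated slot
  sch <- pft_schema()
  expect_true(all(sch$layer[pl$species_pft$pft_slot] != "bare"))
  # single-species degenerate composition: one plot, 100% cover, C3 grass
  comp <- habitat_composition_from_plots(
    data.frame(plot_id = 1L, habitat = 7L, species = "x", cover = 100),
    data.frame(species = "x", pft_slot = 14L))
  adj <- layer_adjust(comp$cover["7", ])
  expect_equal(adj[14], 1)
})

test_that("energy balance closes exactly in both generated runs", {
  d <- generate_synthetic_dataset(tiny_config())
  expect_lt(max(abs(balance_residual(d$climate$ref$energy))), 1e-9)
  expect_lt(max(abs(balance_residual(d$climate$scen$energy))), 1e-9)
})

test_that("null configuration produces identical mean temperature fields", {
  zero_sens <- default_sensitivities() * 0
  cfg <- tiny_config(true_sensitivities = zero_sens, nonlocal_offset = 0,
                     noise_sd_space = 0)
  d <- generate_synthetic_dataset(cfg)
  expect_equal(d$climate$scen$energy$ts, d$climate$ref$energy$ts)
  expect_equal(d$climate$scen$t2m, d$climate$ref$t2m)
})

test_that("mean response equals the linear transition model exactly", {
  cfg <- tiny_config()
  d <- generate_synthetic_dataset(cfg)
  dts <- apply(d$climate$scen$energy$ts - d$climate$ref$energy$ts,
               c(1, 2), mean)
  beta <- d$climate$truth$sensitivities
  beta[is.na(beta)] <- 0
  flux <- d$climate$transitions$flux
  ny <- dim(flux)[1]; nx <- dim(flux)[2]
  manual <- matrix(0, ny, nx)
  for (a in 1:7) for (b in 1:7)
    manual <- manual + flux[, , a, b] * beta[a, b]
  manual <- manual + cfg$nonlocal_offset + d$climate$truth$spatial_noise
  expect_equal(dts, manual, tolerance = 1e-10)
})

test_that("a single transition with known sensitivity gives the expected response", {
  # one coarse cell, one transition of 0.5 at beta = +1 degC/fraction
  cats <- lc_categories()
  ref <- array(0, c(1, 1, 7), dimnames = list(NULL, NULL, cats))
  ref[1, 1, "grass"] <- 0.8; ref[1, 1, "bare"] <- 0.2
  scen <- ref
  scen[1, 1, "grass"] <- 0.3; scen[1, 1, "bare"] <- 0.7
  field <- greedy_net_transitions(ref, scen)
  expect_equal(field$flux[1, 1, "grass", "bare"], 0.5)
  sens <- c("grass->bare" = 1.0)
  # expected mean response: 0.5 * 1.0 = +0.5 degC
  beta <- pftclim:::sensitivity_matrix(sens)
  expect_equal(beta["grass", "bare"], 1.0, ignore_attr = TRUE)
  expect_equal(beta["bare", "grass"], -1.0, ignore_attr = TRUE)
  expect_equal(sum(field$flux[1, 1, , ] * beta, na.rm = TRUE), 0.5)
})

test_that("transitions without configured sensitivities are named in errors", {
  cfg <- tiny_config(true_sensitivities = c("grass->bare" = 1.0))
  land <- generate_land_systems(cfg)
  pl <- generate_plot_table(cfg, land$habitat_tags)
  comp <- habitat_composition_from_plots(pl$plots, pl$species_pft)
  g1 <- translate_land_systems(land$ls_ref, land$crosswalk,
                               land$suitability, land$habitat_tags, comp,
                               cfg$coarsen_factor)
  g2 <- translate_land_systems(land$ls_scen, land$crosswalk,
                               land$suitability, land$habitat_tags, comp,
                               cfg$coarsen_factor)
  expect_error(generate_climate_fields(cfg, g1, g2),
               "no sensitivity configured")
})

test_that("interannual anomalies follow the configured AR(1) process", {
  cfg <- synthetic_config(fine_grid_shape = c(8L, 8L), coarsen_factor = 2L,
                          n_years = 250L, n_days_per_year = 2L,
                          ar1_coefficient = 0.5, seed = 12L, n_plots = 24L)
  d <- generate_synthetic_dataset(cfg)
  ts <- d$climate$ref$energy$ts
  # pool lag-1 autocorrelation of per-cell anomaly series
  rhos <- apply(ts, c(1, 2), function(v) {
    a <- v - mean(v)
    sum(a[-1] * a[-length(a)]) / sum(a^2)
  })
  expect_lt(abs(mean(rhos) - 0.5), 0.1)
})

test_that("daily maxima exceed the annual means they fluctuate around", {
  d <- generate_synthetic_dataset(tiny_config())
  tx <- txx(d$climate$ref$t2m_daily_max)
  expect_true(all(tx > d$climate$ref$t2m))
  # scenario daily stream carries the same mean response
  tx_s <- txx(d$climate$scen$t2m_daily_max)
  dts <- apply(d$climate$scen$energy$ts - d$climate$ref$energy$ts,
               c(1, 2), mean)
  expect_equal(tx_s - tx, array(dts, dim(tx)), tolerance = 1e-9)
})

test_that("auxiliary fields carry the configured scenario offsets", {
  cfg <- tiny_config()
  d <- generate_synthetic_dataset(cfg)
  off <- cfg$scenario_offsets
  expect_equal(d$climate$scen$pr - d$climate$ref$pr,
               array(off[["pr"]], dim(d$climate$ref$pr)))
  expect_equal(d$climate$scen$gpp - d$climate$ref$gpp,
               array(off[["gpp"]], dim(d$climate$ref$gpp)))
})
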