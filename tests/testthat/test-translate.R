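test_that("habitat assignment picks the most suitable candidate", {
  # single candidate is forced; two candidates resolve by argmax
  cw <- data.frame(land_system = c(1L, 2L, 2L), habitat = c(1L, 1L, 2L))
  ls <- matrix(c(1L, 2L), 1, 2)
  suit <- array(0, c(1, 2, 2))
  suit[1, 2, ] <- c(0.2, 0.7)
  hab <- land_system_to_habitat(ls, cw, suit)
  expect_equal(hab[1, 1], 1L)   # forced choice
  expect_equal(hab[1, 2], 2L)   # argmax of (0.2, 0.7)
})

test_that("habitat assignment equals brute-force per-cell argmax", {
  set.seed(11)
  n_ls <- 4L; n_hab <- 6L
  cw <- do.call(rbind, lapply(seq_len(n_ls), function(code)
    data.frame(land_system = code,
               habitat = sort(sample(n_hab, sample(1:3, 1))))))
  ls <- matrix(sample(n_ls, 50 * 50, TRUE), 50, 50)
  suit <- array(runif(50 * 50 * n_hab), c(50, 50, n_hab))
  hab <- land_system_to_habitat(ls, cw, suit)
  for (cell in sample(50 * 50, 200)) {
    i <- (cell - 1) %% 50 + 1; j <- (cell - 1) %/% 50 + 1
    cand <- sort(cw$habitat[cw$land_system == ls[i, j]])
    expect_equal(hab[i, j], cand[which.max(suit[i, j, cand])])
  }
})

test_that("habitat assignment ties resolve to the lowest habitat code", {
  cw <- data.frame(land_system = 1L, habitat = c(3L, 5L))
  ls <- matrix(1L, 2, 2)
  suit <- array(0.5, c(2, 2, 5))
  expect_true(all(land_system_to_habitat(ls, cw, suit) == 3L))
})

test_that("missing crosswalk entries are reported by code", {
  cw <- data.frame(land_system = 1L, habitat = 1L)
  ls <- matrix(c(1L, 7L), 1, 2)
  expect_error(land_system_to_habitat(ls, cw, array(1, c(1, 2, 1))), "7")
})

test_that("plot averaging matches hand-worked and brute-force results", {
  sch <- pft_schema()
  # one plot, two species both C3 grass -> 100% C3 grass raw cover
  plots <- data.frame(plot_id = 1L, habitat = 1L,
                      species = c("a", "b"), cover = c(60, 40))
  sp <- data.frame(species = c("a", "b"), pft_slot = c(14L, 14L))
  comp <- habitat_composition_from_plots(plots, sp)
  expect_equal(unname(comp$cover["1", 14]), 100)
  expect_equal(sum(comp$cover["1", -14]), 0)

  # two plots with C3 grass covers 100 and 0 -> mean 50
  plots2 <- data.frame(plot_id = c(1L, 2L), habitat = 1L,
                       species = c("a", "c"), cover = c(100, 30))
  sp2 <- data.frame(species = c("a", "c"), pft_slot = c(14L, 8L))
  comp2 <- habitat_composition_from_plots(plots2, sp2)
  expect_equal(unname(comp2$cover["1", 14]), 50)

  # 20 random plots vs an explicit loop
  set.seed(5)
  n_sp <- 12L
  sp3 <- data.frame(species = sprintf("s%02d", 1:n_sp),
                    pft_slot = sample(c(2:4, 6, 8:17), n_sp, TRUE))
  rows <- do.call(rbind, lapply(1:20, function(p) {
    k <- sample(1:4, 1)
    data.frame(plot_id = p, habitat = sample(1:3, 1),
               species = sample(sp3$species, k), cover = runif(k, 5, 90))
  }))
  comp3 <- habitat_composition_from_plots(rows, sp3)
  for (h in unique(rows$habitat)) {
    ids <- unique(rows$plot_id[rows$habitat == h])
    manual <- rep(0, 17)
    for (p in ids) {
      v <- rep(0, 17)
      sub <- rows[rows$plot_id == p, ]
      for (r in seq_len(nrow(sub))) {
        slot <- sp3$pft_slot[sp3$species == sub$species[r]]
        v[slot] <- v[slot] + sub$cover[r]
      }
      manual <- manual + v / length(ids)
    }
    expect_equal(unname(comp3$cover[as.character(h), ]), manual)
    expect_equal(unname(comp3$n_plots[as.character(h)]), length(ids))
  }
})

test_that("unassigned species are listed in the error", {
  plots <- data.frame(plot_id = 1L, habitat = 1L, species = "mystery",
                      cover = 10)
  sp <- data.frame(species = "other", pft_slot = 14L)
  expect_error(habitat_composition_from_plots(plots, sp), "mystery")
})

test_that("layer adjustment applies top-down occlusion with proportional caps", {
  sch <- pft_schema()
  # tree 60 + grass 70: tree keeps 60, grass squeezed to 40, no bare
  x <- numeric(17); x[8] <- 60; x[14] <- 70
  out <- layer_adjust(x, sch)
  expect_equal(out[8], 0.60)
  expect_equal(out[14], 0.40)
  expect_equal(out[1], 0)
  expect_equal(sum(out), 1)

  # grass 30 alone: 0.30 grass + 0.70 bare
  y <- numeric(17); y[14] <- 30
  out_y <- layer_adjust(y, sch)
  expect_equal(out_y[14], 0.30)
  expect_equal(out_y[1], 0.70)

  # two trees 80 + 40 exceed 100: capped and split 2:1
  z <- numeric(17); z[2] <- 80; z[8] <- 40
  out_z <- layer_adjust(z, sch)
  expect_equal(out_z[2], 2 / 3)
  expect_equal(out_z[8], 1 / 3)

  # all-zero input is all bare, not an error
  expect_equal(layer_adjust(numeric(17), sch)[1], 1)
})

test_that("land-unit split tags cells and rejects untagged habitats", {
  tags <- data.frame(habitat = 1:3,
                     tag = c("cropland", "natural", "urban"))
  hm <- matrix(c(1L, 1L, 2L, 3L), 2, 2)
  um <- split_land_units(hm, tags)
  expect_equal(um, matrix(c("crop", "crop", "natural", "urban"), 2, 2))
  expect_error(split_land_units(matrix(9L, 1, 1), tags), "9")
})

test_that("coarse aggregation equals nested-loop block means and conserves area", {
  sch <- pft_schema()
  set.seed(21)
  nyf <- 12L; nxf <- 8L; f <- 4L
  # random per-cell fraction vectors summing to 1
  raw <- array(runif(nyf * nxf * 17), c(nyf, nxf, 17))
  tot <- apply(raw, c(1, 2), sum)
  fine <- sweep(raw, c(1, 2), tot, "/")
  unit_map <- matrix(sample(c("natural", "crop"), nyf * nxf, TRUE,
                            prob = c(0.7, 0.3)), nyf, nxf)
  grid <- aggregate_to_coarse(fine, unit_map, f, sch)

  for (bi in seq_len(nyf / f)) {
    for (bj in seq_len(nxf / f)) {
      rows <- ((bi - 1) * f + 1):(bi * f)
      cols <- ((bj - 1) * f + 1):(bj * f)
      sel <- unit_map[rows, cols] == "crop"
      expect_equal(grid$unit_frac$crop[bi, bj], mean(sel))
      if (any(sel)) {
        manual <- rep(0, 17)
        for (k in 1:17) {
          blk <- fine[rows, cols, k]
          manual[k] <- mean(blk[sel])
        }
        expect_equal(grid$frac$crop[bi, bj, ], manual)
      }
    }
  }
  # per-land-unit sums are 1 at every coarse cell
  for (u in c("natural", "crop")) {
    s <- apply(grid$frac[[u]], c(1, 2), sum)
    expect_true(max(abs(s - 1)) < 1e-9)
  }
  # unit fractions partition the cell
  us <- grid$unit_frac$natural + grid$unit_frac$crop +
    grid$unit_frac$ice + grid$unit_frac$urban
  expect_true(max(abs(us - 1)) < 1e-12)
  # total fractions sum to 1
  ts <- apply(total_pft_fractions(grid), c(1, 2), sum)
  expect_true(max(abs(ts - 1)) < 1e-9)
})

test_that("aggregation rejects non-divisible factors and keeps constants", {
  sch <- pft_schema()
  fine <- array(0, c(4, 4, 17)); fine[, , 14] <- 1
  um <- matrix("natural", 4, 4)
  expect_error(aggregate_to_coarse(fine, um, 3L, sch), "divide")
  g <- aggregate_to_coarse(fine, um, 2L, sch)
  expect_true(all(g$frac$natural[, , 14] == 1))
})

test_that("translation is a pure function and zero change propagates", {
  cfg <- tiny_config()
  land <- generate_land_systems(cfg)
  pl <- generate_plot_table(cfg, land$habitat_tags)
  comp <- habitat_composition_from_plots(pl$plots, pl$species_pft)
  g1 <- translate_land_systems(land$ls_ref, land$crosswalk,
                               land$suitability, land$habitat_tags, comp,
                               cfg$coarsen_factor)
  g2 <- translate_land_systems(land$ls_ref, land$crosswalk,
                               land$suitability, land$habitat_tags, comp,
                               cfg$coarsen_factor)
  expect_identical(g1, g2)
  # identical maps -> identically zero transition field
  field <- greedy_net_transitions(aggregate_categories(g1),
                                  aggregate_categories(g2))
  expect_true(all(field$flux == 0))
})
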