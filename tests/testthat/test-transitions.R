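test_that("category aggregation sums member slots across land units", {
  sch <- pft_schema()
  # one cell, natural unit only: C3 arctic 0.1 + C3 0.2 + C4 0.1 -> grass 0.4
  fine <- array(0, c(1, 1, 17))
  fine[1, 1, 13] <- 0.1; fine[1, 1, 14] <- 0.2; fine[1, 1, 15] <- 0.1
  fine[1, 1, 1] <- 0.6
  grid <- aggregate_to_coarse(fine, matrix("natural", 1, 1), 1L, sch)
  cat <- aggregate_categories(grid)
  expect_equal(unname(cat[1, 1, "grass"]), 0.4)
  expect_equal(unname(cat[1, 1, "bare"]), 0.6)

  # all-bare cell
  fine2 <- array(0, c(1, 1, 17)); fine2[1, 1, 1] <- 1
  cat2 <- aggregate_categories(
    aggregate_to_coarse(fine2, matrix("natural", 1, 1), 1L, sch))
  expect_equal(unname(cat2[1, 1, "bare"]), 1)
  expect_equal(sum(cat2[1, 1, ]), 1)
})

test_that("category aggregation matches brute-force re-summation", {
  set.seed(31)
  sch <- pft_schema()
  raw <- array(runif(6 * 6 * 17), c(6, 6, 17))
  fine <- sweep(raw, c(1, 2), apply(raw, c(1, 2), sum), "/")
  um <- matrix(sample(c("natural", "crop"), 36, TRUE), 6, 6)
  grid <- aggregate_to_coarse(fine, um, 2L, sch)
  cat <- aggregate_categories(grid)
  tot <- total_pft_fractions(grid)
  for (j in seq_along(lc_categories())) {
    manual <- apply(tot[, , sch$category == lc_categories()[j], drop = FALSE],
                    c(1, 2), sum)
    expect_equal(cat[, , j], manual, ignore_attr = TRUE)
  }
  expect_true(max(abs(apply(cat, c(1, 2), sum) - 1)) < 1e-9)
})

test_that("greedy matching reproduces the hand-traced example", {
  # grass +0.10, crop rainfed -0.06, tree needleleaf -0.04
  delta <- c(tree_needleleaf = -0.04, tree_broadleaf = 0, shrub = 0,
             grass = 0.10, crop_rainfed = -0.06, crop_irrigated = 0,
             bare = 0)
  g <- delta_to_grids(unname(delta))
  field <- greedy_net_transitions(g$ref, g$scen)
  expect_equal(field$flux[1, 1, "crop_rainfed", "grass"], 0.06)
  expect_equal(field$flux[1, 1, "tree_needleleaf", "grass"], 0.04)
  expect_equal(sum(field$flux), 0.10)
})

test_that("zero change gives an empty transition set", {
  g <- delta_to_grids(rep(0, 7))
  expect_true(all(greedy_net_transitions(g$ref, g$scen)$flux == 0))
})

test_that("greedy transitions conserve per-category change and total area", {
  set.seed(77)
  for (rep in 1:300) {
    delta <- random_balanced_delta() * 0.05
    g <- delta_to_grids(delta)
    field <- greedy_net_transitions(g$ref, g$scen)
    recon <- transition_net_change(field)[1, 1, ]
    expect_true(max(abs(recon - delta)) < 1e-12)
    expect_equal(sum(field$flux), sum(abs(delta)) / 2, tolerance = 1e-12)
    # each iteration zeroes a category: at most 6 recorded transitions
    expect_lte(sum(field$flux[1, 1, , ] > 0), 6L)
  }
})

test_that("swapping scenario and reference negates the signed transitions", {
  set.seed(13)
  delta <- random_balanced_delta() * 0.05
  g <- delta_to_grids(delta)
  f1 <- greedy_net_transitions(g$ref, g$scen)
  f2 <- greedy_net_transitions(g$scen, g$ref)
  # the swapped run records every transition in the opposite direction
  expect_equal(f2$flux[1, 1, , ], t(f1$flux[1, 1, , ]))
  # relative to a fixed orientation, each signed x therefore flips sign:
  # the swapped run's dominant direction is the reverse pair, same magnitude
  o1 <- orient_by_dominant_direction(f1)
  o2 <- orient_by_dominant_direction(f2)
  for (r in seq_len(nrow(o1$inventory))) {
    rev_nm <- paste(lc_category_label(o1$inventory$to[r]), "to",
                    lc_category_label(o1$inventory$from[r]))
    expect_true(rev_nm %in% o2$inventory$name)
    expect_equal(unname(o2$design[, rev_nm]),
                 unname(o1$design[, o1$inventory$name[r]]))
  }
})

test_that("unbalanced inputs are rejected", {
  ref <- array(rep(1 / 7, 7), c(1, 1, 7))
  scen <- array(rep(1 / 7, 7), c(1, 1, 7))
  scen[1, 1, 1] <- scen[1, 1, 1] + 0.01
  expect_error(greedy_net_transitions(ref, scen), "not conserved")
})

test_that("orientation follows the dominant direction and signs cells", {
  # two cells: crop->grass 0.8 total vs grass->crop 0.2 total
  cats <- lc_categories()
  ref <- array(0, c(1, 2, 7), dimnames = list(NULL, NULL, cats))
  scen <- ref
  base <- rep(1 / 7, 7)
  ref[1, 1, ] <- base; scen[1, 1, ] <- base
  ref[1, 1, 5] <- base[5] + 0.08; scen[1, 1, 5] <- base[5] - 0.00
  scen[1, 1, 4] <- base[4] + 0.08; ref[1, 1, 4] <- base[4] + 0.00
  ref[1, 2, ] <- base; scen[1, 2, ] <- base
  ref[1, 2, 4] <- base[4] + 0.02; scen[1, 2, 4] <- base[4] - 0.00
  scen[1, 2, 5] <- base[5] + 0.02; ref[1, 2, 5] <- base[5] + 0.00
  field <- greedy_net_transitions(ref, scen)
  o <- orient_by_dominant_direction(field)
  expect_equal(o$inventory$name, "crop rainfed to grass")
  expect_equal(as.vector(o$design), c(0.08, -0.02))
})

test_that("single-direction fields give non-negative x", {
  fx <- simulate_attribution_fixture(6, recovery_pairs(), noise_sd = 0,
                                     seed = 2)
  expect_true(all(fx$oriented$design >= 0))
})

test_that("inventory covers 20 types when rainfed-irrigated is absent", {
  cats <- lc_categories()
  pairs <- t(combn(7, 2))
  keep <- !(cats[pairs[, 1]] == "crop_rainfed" &
              cats[pairs[, 2]] == "crop_irrigated")
  pairs <- pairs[keep, ]
  n <- nrow(pairs)
  ref <- array(0, c(1, n, 7), dimnames = list(NULL, NULL, cats))
  scen <- ref
  base <- rep(1 / 7, 7)
  for (k in seq_len(n)) {
    ref[1, k, ] <- base; scen[1, k, ] <- base
    ref[1, k, pairs[k, 1]] <- base[1] + 0.05
    scen[1, k, pairs[k, 1]] <- base[1] - 0.05
    ref[1, k, pairs[k, 2]] <- base[2] - 0.03
    scen[1, k, pairs[k, 2]] <- base[2] + 0.07
  }
  field <- greedy_net_transitions(ref, scen)
  o <- orient_by_dominant_direction(field)
  expect_equal(nrow(o$inventory), 20L)
  expect_false(any(o$inventory$from == "crop_rainfed" &
                     o$inventory$to == "crop_irrigated"))
  expect_false(any(o$inventory$from == "crop_irrigated" &
                     o$inventory$to == "crop_rainfed"))
})

test_that("exact direction ties orient by canonical category order", {
  cats <- lc_categories()
  ref <- array(0, c(1, 2, 7), dimnames = list(NULL, NULL, cats))
  scen <- ref
  base <- rep(1 / 7, 7)
  # cell 1: grass -> bare 0.05; cell 2: bare -> grass 0.05 (tie)
  ref[1, 1, ] <- base; scen[1, 1, ] <- base
  ref[1, 1, 4] <- base[4] + 0.05; scen[1, 1, 7] <- base[7] + 0.05
  scen[1, 1, 4] <- base[4]; ref[1, 1, 7] <- base[7]
  ref[1, 2, ] <- base; scen[1, 2, ] <- base
  ref[1, 2, 7] <- base[7] + 0.05; scen[1, 2, 4] <- base[4] + 0.05
  scen[1, 2, 7] <- base[7]; ref[1, 2, 4] <- base[4]
  o <- orient_by_dominant_direction(greedy_net_transitions(ref, scen))
  # grass precedes bare in canonical order
  expect_equal(o$inventory$name, "grass to bare")
})
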