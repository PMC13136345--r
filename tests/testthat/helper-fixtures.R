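# Shared fixtures, built in code at test time.

tiny_config <- function(..., seed = 42L) {
  synthetic_config(fine_grid_shape = c(20L, 20L), coarsen_factor = 2L,
                   n_years = 5L, n_days_per_year = 8L, n_plots = 24L,
                   n_habitats = 8L, n_land_systems = 6L, n_species = 40L,
                   seed = seed, ...)
}

# A closed single-value energy state.
scalar_state <- function(alpha = 0.2, sw_down = 500, lw_down = 300,
                         ts = 290, lh = 100, sh = 80) {
  close_balance(energy_state(alpha = alpha, sw_down = sw_down,
                             lw_down = lw_down, ts = ts, lh = lh, sh = sh))
}

# Random balanced category-change vector (sums to zero).
random_balanced_delta <- function(n_cat = 7L) {
  d <- stats::rnorm(n_cat)
  d - mean(d)
}

# Category grids holding a single prescribed per-cell delta.
delta_to_grids <- function(delta) {
  n_cat <- length(delta)
  base <- rep(1 / n_cat, n_cat)
  ref <- array(base, c(1, 1, n_cat))
  scen <- array(base + delta, c(1, 1, n_cat))
  list(ref = ref, scen = scen)
}

# Standard 5-transition recovery fixture.
recovery_pairs <- function() {
  data.frame(
    from = c("tree_broadleaf", "crop_rainfed", "tree_needleleaf",
             "shrub", "grass"),
    to = c("grass", "grass", "crop_rainfed", "bare", "bare"),
    beta = c(1.5, 0.8, -0.4, 1.2, 1.0),
    stringsAsFactors = FALSE)
}
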