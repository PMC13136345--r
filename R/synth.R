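#' Default true transition sensitivities for the synthetic generator
#'
#' One value per unordered category pair, given in a canonical direction
#' (earlier category in \code{\link{lc_categories}} order first) and extended
#' antisymmetrically: the reverse transition has the negated sensitivity.
#' Units: degC per unit cell fraction transitioned. Signs follow the
#' qualitative pattern seen in mid-latitude land-cover studies (loss of
#' broadleaf trees or crops to grass warms locally; conversion to irrigated
#' crops cools; bare ground is warmest).
#'
#' @return Named numeric vector; names are "from->to" category ids.
#' @export
default_sensitivities <- function() {
  c("tree_needleleaf->tree_broadleaf" = -0.3,
    "tree_needleleaf->shrub"          =  0.5,
    "tree_needleleaf->grass"          =  0.8,
    "tree_needleleaf->crop_rainfed"   = -0.4,
    "tree_needleleaf->crop_irrigated" = -1.0,
    "tree_needleleaf->bare"           =  2.0,
    "tree_broadleaf->shrub"           =  1.0,
    "tree_broadleaf->grass"           =  1.5,
    "tree_broadleaf->crop_rainfed"    =  0.6,
    "tree_broadleaf->crop_irrigated"  = -0.5,
    "tree_broadleaf->bare"            =  2.5,
    "shrub->grass"                    =  0.4,
    "shrub->crop_rainfed"             = -0.6,
    "shrub->crop_irrigated"           = -1.2,
    "shrub->bare"                     =  1.2,
    "grass->crop_rainfed"             = -0.8,
    "grass->crop_irrigated"           = -1.5,
    "grass->bare"                     =  1.0,
    "crop_rainfed->crop_irrigated"    = -0.7,
    "crop_rainfed->bare"              =  1.5,
    "crop_irrigated->bare"            =  2.8)
}

#' Configuration of the synthetic Earth-system-output generator
#'
#' Defines the study conditions emulated by the generator: a fine
#' land-system grid coarsened to the model analysis grid, a 15-year analysis
#' period of paired reference/scenario runs sharing interannual variability,
#' a prescribed linear transition-response model for the mean skin
#' temperature difference (plus a spatially uniform non-local offset and
#' spatial noise), AR(1) interannual anomalies, and a closed surface energy
#' balance in both runs.
#'
#' @param fine_grid_shape Fine grid \code{c(ny, nx)}; both divisible by
#'   \code{coarsen_factor}.
#' @param coarsen_factor Fine cells per coarse cell per axis.
#' @param n_years Analysis years (default 15).
#' @param n_days_per_year Days per year carried in the daily-maximum
#'   temperature stream (default 91, a summer season).
#' @param scenario_change_fraction Fraction of fine cells whose land system
#'   differs between scenario and reference.
#' @param true_sensitivities Named vector of transition sensitivities
#'   ("from->to" -> degC per unit fraction); extended antisymmetrically.
#' @param nonlocal_offset Spatially uniform temperature offset (degC)
#'   emulating non-local effects; absorbed by the regression intercept.
#' @param noise_sd_space Spatial noise sd on the mean response (degC).
#' @param ar1_coefficient AR(1) coefficient of interannual anomalies
#'   (|rho| < 1).
#' @param noise_sd_year Innovation sd of interannual anomalies (degC).
#' @param seed Root seed; all randomness flows from it via named substreams.
#' @param n_land_systems,n_habitats,n_species,n_plots Sizes of the
#'   categorical inputs. The defaults provide enough thematic diversity
#'   that all transition types are linearly identifiable from the resulting
#'   maps (a register that is too coarse makes transition predictors
#'   exactly collinear).
#' @param flux_weights How the required flux perturbation is allocated across
#'   -dLH, -dSH, -SWdown dAlpha, (1-alpha) dSWdown, dLWdown; must be
#'   non-negative and sum to 1.
#' @param gumbel_location,gumbel_scale Location (degC above the seasonal
#'   mean) and scale of the Gumbel daily excursions used for the daily
#'   maximum stream.
#' @param scenario_offsets Scenario-minus-reference offsets for the
#'   uncoupled auxiliary fields (precipitation mm/day, soil moisture
#'   fraction, wind m/s, gross primary production gC m-2 day-1).
#' @return Object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(fine_grid_shape = c(80L, 80L),
                             coarsen_factor = 2L,
                             n_years = 15L,
                             n_days_per_year = 91L,
                             scenario_change_fraction = 0.3,
                             true_sensitivities = default_sensitivities(),
                             nonlocal_offset = 0.1,
                             noise_sd_space = 0.1,
                             ar1_coefficient = 0.5,
                             noise_sd_year = 0.5,
                             seed = 1L,
                             n_land_systems = 12L,
                             n_habitats = 16L,
                             n_species = 60L,
                             n_plots = 120L,
                             flux_weights = c(lh = 0.35, sh = 0.25,
                                              albedo = 0.15, sw_down = 0.15,
                                              lw_down = 0.10),
                             gumbel_location = 8,
                             gumbel_scale = 2,
                             scenario_offsets = c(pr = -0.05, sm = -0.005,
                                                  wind = 0.05, gpp = -0.1)) {
  if (any(fine_grid_shape < 1L)) stop("zero-area grid")
  if (any(fine_grid_shape %% coarsen_factor != 0L))
    stop("coarsen_factor must divide fine_grid_shape")
  if (noise_sd_space < 0 || noise_sd_year < 0)
    stop("noise scales must be non-negative")
  if (abs(ar1_coefficient) >= 1) stop("|ar1_coefficient| must be < 1")
  if (scenario_change_fraction < 0 || scenario_change_fraction > 1)
    stop("scenario_change_fraction must be in [0, 1]")
  if (n_plots < n_habitats) stop("n_plots must be >= n_habitats")
  stopifnot(all(c("lh", "sh", "albedo", "sw_down", "lw_down") %in%
                  names(flux_weights)))
  if (any(flux_weights < 0) || abs(sum(flux_weights) - 1) > 1e-9)
    stop("flux_weights must be non-negative and sum to 1")
  structure(list(
    fine_grid_shape = as.integer(fine_grid_shape),
    coarsen_factor = as.integer(coarsen_factor),
    n_years = as.integer(n_years),
    n_days_per_year = as.integer(n_days_per_year),
    scenario_change_fraction = scenario_change_fraction,
    true_sensitivities = true_sensitivities,
    nonlocal_offset = nonlocal_offset,
    noise_sd_space = noise_sd_space,
    ar1_coefficient = ar1_coefficient,
    noise_sd_year = noise_sd_year,
    seed = as.integer(seed),
    n_land_systems = as.integer(n_land_systems),
    n_habitats = as.integer(n_habitats),
    n_species = as.integer(n_species),
    n_plots = as.integer(n_plots),
    flux_weights = flux_weights,
    gumbel_location = gumbel_location,
    gumbel_scale = gumbel_scale,
    scenario_offsets = scenario_offsets
  ), class = "synthetic_config")
}

# Deterministic per-output substream seed derived from the root seed.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Generate land-system maps, crosswalk, and suitability grids
#'
#' Reference and scenario categorical land-system maps on the fine grid
#' (each cell one code; a configurable fraction of cells differ), a
#' crosswalk giving every land-system code at least one candidate habitat
#' (cropland systems map to cropland habitats, natural systems to natural
#' habitats), a habitat tag register, and finite non-negative suitability
#' score grids per habitat.
#'
#' @param config A \code{synthetic_config}.
#' @return List: \code{ls_ref}, \code{ls_scen} (integer matrices),
#'   \code{crosswalk} (data frame \code{land_system}, \code{habitat}),
#'   \code{habitat_tags} (data frame \code{habitat}, \code{tag}),
#'   \code{suitability} (array \code{[ny, nx, n_habitats]}).
#' @export
generate_land_systems <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(substream_seed(config$seed, "land_systems"))
  ny <- config$fine_grid_shape[1]; nx <- config$fine_grid_shape[2]
  n_ls <- config$n_land_systems
  n_hab <- config$n_habitats
  stopifnot(n_ls >= 2L, n_hab >= 2L)

  n_crop_ls <- max(1L, n_ls %/% 3L)
  crop_ls <- seq_len(n_crop_ls)
  natural_ls <- setdiff(seq_len(n_ls), crop_ls)
  n_crop_hab <- max(1L, n_hab %/% 4L)
  crop_hab <- seq_len(n_crop_hab)
  natural_hab <- setdiff(seq_len(n_hab), crop_hab)

  habitat_tags <- data.frame(
    habitat = seq_len(n_hab),
    tag = c(rep("cropland", n_crop_hab),
            rep("natural", n_hab - n_crop_hab)),
    stringsAsFactors = FALSE)

  cw <- lapply(seq_len(n_ls), function(code) {
    pool <- if (code %in% crop_ls) crop_hab else natural_hab
    k <- sample(seq_len(min(3L, length(pool))), 1L)
    data.frame(land_system = code,
               habitat = sort(sample(pool, k)))
  })
  crosswalk <- do.call(rbind, cw)

  ls_ref <- matrix(sample(seq_len(n_ls), ny * nx, replace = TRUE), ny, nx)
  changed <- stats::runif(ny * nx) < config$scenario_change_fraction
  ls_scen <- ls_ref
  if (any(changed)) {
    old <- ls_ref[changed]
    shift <- sample(n_ls - 1L, sum(changed), replace = TRUE)
    ls_scen[changed] <- (old - 1L + shift) %% n_ls + 1L
  }

  suitability <- array(stats::runif(ny * nx * n_hab), c(ny, nx, n_hab))

  list(ls_ref = ls_ref, ls_scen = ls_scen, crosswalk = crosswalk,
       habitat_tags = habitat_tags, suitability = suitability)
}

#' Generate a toy vegetation-plot archive and species-to-PFT assignment
#'
#' Emulates a plot archive at toy scale: each habitat has at least one plot;
#' each plot lists species with positive percent cover; each species maps to
#' exactly one vegetated PFT slot. Cropland habitats carry crop species,
#' natural habitats draw species from a habitat-specific set of 2-4 dominant
#' extratropical slots, so habitats have distinct PFT compositions. Tropical
#' tree slots receive no species (identically zero over this domain).
#'
#' @param config A \code{synthetic_config}.
#' @param habitat_tags Habitat tag register from
#'   \code{\link{generate_land_systems}}.
#' @return List: \code{plots} (data frame \code{plot_id}, \code{habitat},
#'   \code{species}, \code{cover}) and \code{species_pft} (data frame
#'   \code{species}, \code{pft_slot}).
#' @export
generate_plot_table <- function(config, habitat_tags) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(substream_seed(config$seed, "plots"))
  schema <- pft_schema()
  n_hab <- nrow(habitat_tags)
  if (config$n_plots < n_hab) stop("n_plots must be >= number of habitats")

  tropical <- grep("tropical", schema$name)
  crop_slots <- which(schema$category %in% c("crop_rainfed",
                                             "crop_irrigated"))
  natural_slots <- setdiff(which(schema$layer != "bare"),
                           c(tropical, crop_slots))

  # species pool: round-robin over usable slots so every slot has species
  usable <- c(natural_slots, crop_slots)
  species_pft <- data.frame(
    species = sprintf("sp%03d", seq_len(config$n_species)),
    pft_slot = rep_len(usable, config$n_species),
    stringsAsFactors = FALSE)

  # habitat community profiles: cropland habitats on crop slots, natural
  # habitats on 2-4 dominant natural slots
  profiles <- lapply(seq_len(n_hab), function(h) {
    pool <- if (habitat_tags$tag[h] == "cropland") crop_slots else
      sort(sample(natural_slots, sample(2:4, 1L)))
    w <- stats::runif(length(pool), 0.2, 1)
    list(slots = pool, weights = w / sum(w))
  })

  hab_of_plot <- c(seq_len(n_hab),
                   sample(seq_len(n_hab), config$n_plots - n_hab,
                          replace = TRUE))
  rows <- lapply(seq_len(config$n_plots), function(p) {
    h <- hab_of_plot[p]
    prof <- profiles[[h]]
    n_sp <- sample(1:5, 1L)
    slots <- sample(prof$slots, n_sp, replace = TRUE, prob = prof$weights)
    sp <- vapply(slots, function(s) {
      cand <- species_pft$species[species_pft$pft_slot == s]
      cand[sample.int(length(cand), 1L)]
    }, character(1))
    data.frame(plot_id = p, habitat = h, species = sp,
               cover = stats::runif(n_sp, 5, 80),
               stringsAsFactors = FALSE)
  })
  plots <- do.call(rbind, rows)
  # collapse duplicate species within a plot
  key <- paste(plots$plot_id, plots$species)
  plots <- stats::aggregate(cover ~ plot_id + habitat + species, plots, sum)
  plots <- plots[order(plots$plot_id, plots$species), ]
  rownames(plots) <- NULL
  list(plots = plots, species_pft = species_pft)
}

# Parse "from->to" sensitivity names into a full antisymmetric 7x7 matrix.
sensitivity_matrix <- function(true_sensitivities) {
  cats <- lc_categories()
  beta <- matrix(NA_real_, length(cats), length(cats),
                 dimnames = list(cats, cats))
  diag(beta) <- 0
  parts <- strsplit(names(true_sensitivities), "->", fixed = TRUE)
  for (k in seq_along(true_sensitivities)) {
    p <- parts[[k]]
    if (length(p) != 2L || !all(p %in% cats))
      stop("malformed sensitivity name: ", names(true_sensitivities)[k])
    v <- unname(true_sensitivities[k])
    if (!is.na(beta[p[1], p[2]]) && beta[p[1], p[2]] != v)
      stop("conflicting sensitivities for ", names(true_sensitivities)[k])
    beta[p[1], p[2]] <- v
    beta[p[2], p[1]] <- -v
  }
  beta
}

# Replicate a [ny, nx] matrix along a third (year) dimension.
bcast_years <- function(mat, n_years) {
  array(mat, c(dim(mat), n_years))
}

#' Generate multi-year gridded climate fields for a scenario pair
#'
#' Works backwards from the prescribed response: the 15-year-mean skin
#' temperature difference per coarse cell is drawn from the linear
#' transition model (sensitivities times the cell's net transition fractions
#' from the greedy matching, plus the uniform non-local offset and spatial
#' noise). The flux perturbation required by the linearised decomposition,
#' Delta Ts / lambda, is then allocated across latent heat, sensible heat,
#' albedo, and downwelling short-/longwave radiation by the configured
#' weights, and ground heat flux closes the balance exactly in both runs.
#' Interannual anomalies follow an AR(1) process shared by both runs
#' (paired boundary conditions), so the mean difference carries no
#' interannual sampling error. A daily maximum temperature stream with
#' Gumbel excursions supports the TXx index, and uncoupled auxiliary fields
#' (precipitation, soil moisture, wind, gross primary production) carry
#' configurable scenario offsets.
#'
#' @param config A \code{synthetic_config}.
#' @param grid_ref,grid_scen Coarse \code{pft_grid}s for reference and
#'   scenario.
#' @return Object of class \code{synthetic_climate}: list with \code{ref}
#'   and \code{scen} (each: \code{energy} closed \code{energy_state} of
#'   arrays \code{[ny, nx, nyear]}, \code{t2m}, \code{t2m_daily_max}
#'   \code{[ny, nx, nyear, nday]}, \code{pr}, \code{sm}, \code{wind},
#'   \code{gpp}), \code{transitions} (the \code{transition_field} used),
#'   and \code{truth} (sensitivity matrix, realised offset, spatial noise
#'   field, and the target mean response; for recovery tests only, never an
#'   analysis input).
#' @export
generate_climate_fields <- function(config, grid_ref, grid_scen) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(grid_ref, "pft_grid"), inherits(grid_scen, "pft_grid"))
  cat_ref <- aggregate_categories(grid_ref)
  cat_scen <- aggregate_categories(grid_scen)
  field <- greedy_net_transitions(cat_ref, cat_scen)
  ny <- dim(cat_ref)[1]; nx <- dim(cat_ref)[2]
  n_cat <- dim(cat_ref)[3]
  nyr <- config$n_years

  beta <- sensitivity_matrix(config$true_sensitivities)
  observed <- apply(field$flux, c(3, 4), sum) > 0
  missing <- which(observed & is.na(beta), arr.ind = TRUE)
  if (nrow(missing) > 0L) {
    nm <- paste(rownames(beta)[missing[, 1]], "->",
                colnames(beta)[missing[, 2]], sep = "")
    stop("no sensitivity configured for transition type(s): ",
         paste(unique(nm), collapse = ", "))
  }
  beta0 <- beta
  beta0[is.na(beta0)] <- 0

  # mean response: sum over directed transitions + offset + spatial noise
  flux_flat <- matrix(field$flux, nrow = ny * nx)
  set.seed(substream_seed(config$seed, "space_noise"))
  space_noise <- matrix(stats::rnorm(ny * nx, 0, config$noise_sd_space),
                        ny, nx)
  dts_mean <- matrix(flux_flat %*% as.vector(beta0), ny, nx) +
    config$nonlocal_offset + space_noise

  # reference climatology on the coarse grid
  lat_grad <- matrix((seq_len(ny) - 0.5) / ny, ny, nx)
  ts0 <- 285 + 8 * lat_grad
  veg_frac <- 1 - total_pft_fractions(grid_ref)[, , 1]
  cat_albedo <- c(tree_needleleaf = 0.10, tree_broadleaf = 0.12,
                  shrub = 0.15, grass = 0.18, crop_rainfed = 0.17,
                  crop_irrigated = 0.16, bare = 0.30)
  alpha_ref2 <- matrix(matrix(cat_ref, ncol = n_cat) %*%
                         cat_albedo[lc_categories()], ny, nx)
  sw0 <- 240 + 40 * lat_grad
  lw0 <- matrix(330, ny, nx)
  lh0 <- 60 + 40 * veg_frac
  sh0 <- matrix(55, ny, nx)

  # shared AR(1) interannual anomalies
  set.seed(substream_seed(config$seed, "interannual"))
  eta <- matrix(0, ny * nx, nyr)
  if (config$noise_sd_year > 0) {
    rho <- config$ar1_coefficient
    eta[, 1] <- stats::rnorm(ny * nx, 0,
                             config$noise_sd_year / sqrt(1 - rho^2))
    if (nyr > 1L) for (t in 2:nyr)
      eta[, t] <- rho * eta[, t - 1] +
        stats::rnorm(ny * nx, 0, config$noise_sd_year)
  }
  eta_arr <- array(eta, c(ny, nx, nyr))

  ts_ref <- bcast_years(ts0, nyr) + eta_arr
  state_ref <- close_balance(energy_state(
    alpha = bcast_years(alpha_ref2, nyr),
    sw_down = bcast_years(sw0, nyr),
    lw_down = bcast_years(lw0, nyr),
    ts = ts_ref,
    lh = bcast_years(lh0, nyr),
    sh = bcast_years(sh0, nyr)))

  # scenario: prescribed time-invariant mean response; flux perturbations
  # allocated so the linearised decomposition reproduces it
  dts_arr <- bcast_years(dts_mean, nyr)
  lam <- temperature_sensitivity(ts_ref)
  f_req <- dts_arr / lam
  w <- config$flux_weights
  d_lh <- -w[["lh"]] * f_req
  d_sh <- -w[["sh"]] * f_req
  d_alpha <- -w[["albedo"]] * f_req / state_ref$sw_down
  d_sw <- w[["sw_down"]] * f_req / (1 - state_ref$alpha)
  d_lw <- w[["lw_down"]] * f_req
  alpha_scen <- state_ref$alpha + d_alpha
  if (any(alpha_scen < 0 | alpha_scen > 1))
    stop("scenario albedo left [0, 1]; response too large for the ",
         "configured flux weights")
  state_scen <- close_balance(energy_state(
    alpha = alpha_scen,
    sw_down = state_ref$sw_down + d_sw,
    lw_down = state_ref$lw_down + d_lw,
    ts = ts_ref + dts_arr,
    lh = state_ref$lh + d_lh,
    sh = state_ref$sh + d_sh))

  # 2 m air temperature: annual means and daily maxima (degC)
  t2m_ref <- bcast_years(ts0 - 273.15 - 1.5, nyr) + eta_arr
  t2m_scen <- t2m_ref + dts_arr
  nday <- config$n_days_per_year
  set.seed(substream_seed(config$seed, "daily"))
  gum <- -config$gumbel_scale *
    log(-log(stats::runif(ny * nx * nyr * nday)))
  daily_ref <- array(ts0 - 273.15 + config$gumbel_location,
                     c(ny, nx, nyr, nday)) +
    array(eta_arr, c(ny, nx, nyr, nday)) +
    array(gum, c(ny, nx, nyr, nday))
  daily_scen <- daily_ref + array(dts_arr, c(ny, nx, nyr, nday))

  # uncoupled auxiliary fields with scenario offsets
  set.seed(substream_seed(config$seed, "aux"))
  aux_noise <- function(sd) array(stats::rnorm(ny * nx * nyr, 0, sd),
                                  c(ny, nx, nyr))
  off <- config$scenario_offsets
  pr_ref <- 2 + 0.5 * bcast_years(lat_grad, nyr) + aux_noise(0.2)
  sm_ref <- 0.25 + aux_noise(0.02)
  wind_ref <- 4 + aux_noise(0.3)
  gpp_ref <- 4 + 2 * bcast_years(veg_frac, nyr) + aux_noise(0.3)

  run <- function(state, t2m, daily, pr, sm, wind, gpp)
    list(energy = state, t2m = t2m, t2m_daily_max = daily, pr = pr,
         sm = sm, wind = wind, gpp = gpp)
  structure(list(
    ref = run(state_ref, t2m_ref, daily_ref, pr_ref, sm_ref, wind_ref,
              gpp_ref),
    scen = run(state_scen, t2m_scen, daily_scen, pr_ref + off[["pr"]],
               sm_ref + off[["sm"]], wind_ref + off[["wind"]],
               gpp_ref + off[["gpp"]]),
    transitions = field,
    truth = list(sensitivities = beta, realized_offset =
                   config$nonlocal_offset, spatial_noise = space_noise,
                 delta_ts_mean = dts_mean)
  ), class = "synthetic_climate")
}

#' Generate a complete synthetic dataset with known ground truth
#'
#' Runs the full generator: land-system maps, crosswalk and suitability,
#' vegetation plots and species assignments, translation of both maps to
#' coarse PFT grids, and paired multi-year climate fields. Identical seed
#' and configuration give bit-identical outputs.
#'
#' @param config A \code{synthetic_config}.
#' @return List: \code{config}, \code{land} (see
#'   \code{\link{generate_land_systems}}), \code{plots} (see
#'   \code{\link{generate_plot_table}}), \code{composition},
#'   \code{grid_ref}, \code{grid_scen}, \code{climate} (see
#'   \code{\link{generate_climate_fields}}).
#' @export
generate_synthetic_dataset <- function(config = synthetic_config()) {
  land <- generate_land_systems(config)
  plots <- generate_plot_table(config, land$habitat_tags)
  composition <- habitat_composition_from_plots(plots$plots,
                                                plots$species_pft)
  grid_ref <- translate_land_systems(land$ls_ref, land$crosswalk,
                                     land$suitability, land$habitat_tags,
                                     composition, config$coarsen_factor)
  grid_scen <- translate_land_systems(land$ls_scen, land$crosswalk,
                                      land$suitability, land$habitat_tags,
                                      composition, config$coarsen_factor)
  climate <- generate_climate_fields(config, grid_ref, grid_scen)
  list(config = config, land = land, plots = plots,
       composition = composition, grid_ref = grid_ref,
       grid_scen = grid_scen, climate = climate)
}

#' Targeted fixture for attribution recovery experiments
#'
#' Builds category grids in which every cell undergoes exactly one net
#' transition drawn from a small set of active pairs, with uniform random
#' magnitude, and a temperature response that follows the linear model
#' exactly up to iid noise. Useful for parameter-recovery and
#' permutation-null experiments where an analytic expectation is needed.
#'
#' @param n_side Coarse grid side length (cells).
#' @param pairs Data frame with columns \code{from}, \code{to} (category
#'   ids) and \code{beta} (degC per unit fraction) listing the active
#'   transitions.
#' @param intercept Uniform offset added to the response (degC).
#' @param noise_sd iid noise sd on the response (degC).
#' @param max_magnitude Upper bound of the uniform transition magnitude.
#' @param seed Seed.
#' @return List: \code{cat_ref}, \code{cat_scen}, \code{oriented}
#'   (from \code{\link{orient_by_dominant_direction}}), \code{delta_t}
#'   (response matrix), \code{beta} (named by the oriented transition-type
#'   names), \code{intercept}.
#' @export
simulate_attribution_fixture <- function(n_side = 40L, pairs,
                                         intercept = 0.1, noise_sd = 0.1,
                                         max_magnitude = 0.5, seed = 1L) {
  cats <- lc_categories()
  stopifnot(all(pairs$from %in% cats), all(pairs$to %in% cats),
            all(pairs$from != pairs$to), max_magnitude <= 0.5)
  set.seed(seed)
  n <- n_side * n_side
  which_pair <- sample(nrow(pairs), n, replace = TRUE)
  mag <- stats::runif(n, 0, max_magnitude)

  n_cat <- length(cats)
  cat_ref <- array(0, c(n_side, n_side, n_cat),
                   dimnames = list(NULL, NULL, cats))
  cat_scen <- cat_ref
  base <- rep(0.4 / (n_cat - 2), n_cat)  # spread over uninvolved categories
  for (cell in seq_len(n)) {
    i <- (cell - 1L) %% n_side + 1L
    j <- (cell - 1L) %/% n_side + 1L
    p <- which_pair[cell]
    fi <- match(pairs$from[p], cats); ti <- match(pairs$to[p], cats)
    v <- base; v[fi] <- 0.5; v[ti] <- 0.1
    v <- v / sum(v)
    cat_ref[i, j, ] <- v
    v2 <- v; v2[fi] <- v[fi] - mag[cell]; v2[ti] <- v[ti] + mag[cell]
    cat_scen[i, j, ] <- v2
  }
  field <- greedy_net_transitions(cat_ref, cat_scen)
  oriented <- orient_by_dominant_direction(field)

  name_of <- paste(lc_category_label(pairs$from), "to",
                   lc_category_label(pairs$to))
  beta <- pairs$beta
  names(beta) <- name_of
  if (!setequal(colnames(oriented$design), name_of))
    stop("oriented transition types do not match the requested pairs")
  beta <- beta[colnames(oriented$design)]
  dt_vec <- as.vector(oriented$design %*% beta) + intercept +
    stats::rnorm(n, 0, noise_sd)
  delta_t <- matrix(NA_real_, n_side, n_side)
  delta_t[oriented$cell_index] <- dt_vec
  list(cat_ref = cat_ref, cat_scen = cat_scen, oriented = oriented,
       delta_t = delta_t, beta = beta, intercept = intercept)
}
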