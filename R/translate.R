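#' Assign one habitat per fine-grid cell from land systems and suitability
#'
#' Each fine cell holds exactly one land-system code. The crosswalk restricts
#' the candidate habitats for that code, and the cell's habitat is the
#' candidate with maximal suitability at that cell. Ties are resolved
#' deterministically by the lowest habitat code.
#'
#' @param ls_map Integer matrix of land-system codes (fine grid).
#' @param crosswalk Data frame with columns \code{land_system} and
#'   \code{habitat}; every code present in \code{ls_map} must appear with at
#'   least one candidate habitat.
#' @param suitability Numeric array \code{[nrow, ncol, n_habitats]} of finite,
#'   non-negative suitability scores; the third dimension is indexed by
#'   habitat code.
#' @return Integer matrix of habitat codes, same shape as \code{ls_map}.
#' @export
land_system_to_habitat <- function(ls_map, crosswalk, suitability) {
  stopifnot(is.matrix(ls_map), length(dim(suitability)) == 3L)
  if (any(dim(ls_map) != dim(suitability)[1:2]))
    stop("suitability grid does not match the land-system map shape")
  if (any(!is.finite(suitability)) || any(suitability < 0))
    stop("suitability scores must be finite and non-negative")

  codes <- sort(unique(as.vector(ls_map)))
  missing <- setdiff(codes, unique(crosswalk$land_system))
  if (length(missing) > 0L)
    stop("no crosswalk entry for land-system code(s): ",
         paste(missing, collapse = ", "))

  n_hab <- dim(suitability)[3]
  hab <- matrix(NA_integer_, nrow(ls_map), ncol(ls_map))
  suit_flat <- matrix(suitability, ncol = n_hab)  # cells x habitats
  for (code in codes) {
    cand <- sort(crosswalk$habitat[crosswalk$land_system == code])
    if (any(cand > n_hab))
      stop("crosswalk habitat code exceeds suitability grid depth")
    idx <- which(ls_map == code)
    if (length(cand) == 1L) {
      hab[idx] <- cand
    } else {
      s <- suit_flat[idx, cand, drop = FALSE]
      # max.col with "first" tie-break; candidates sorted so ties pick the
      # lowest habitat code
      hab[idx] <- cand[max.col(s, ties.method = "first")]
    }
  }
  hab
}

#' Mean PFT cover per habitat from vegetation plots
#'
#' Emulates the derivation of habitat-level PFT composition from a
#' vegetation-plot archive: each species' percent cover is assigned to its PFT
#' slot, covers are summed within a plot, and plot totals are averaged (plots
#' equally weighted) within each habitat.
#'
#' @param plot_table Data frame with columns \code{plot_id}, \code{habitat},
#'   \code{species}, \code{cover} (percent ground cover, positive).
#' @param species_to_pft Data frame with columns \code{species} and
#'   \code{pft_slot} (1-based index into the schema); every species occurring
#'   in \code{plot_table} must be assigned to exactly one vegetated slot.
#' @param schema PFT schema, see \code{\link{pft_schema}}.
#' @return Object of class \code{habitat_composition}: list with \code{cover}
#'   (matrix habitats x 17 slots of mean raw percent cover, rownames are
#'   habitat codes) and \code{n_plots} (named integer vector).
#' @export
habitat_composition_from_plots <- function(plot_table, species_to_pft,
                                           schema = pft_schema()) {
  stopifnot(all(c("plot_id", "habitat", "species", "cover") %in%
                  names(plot_table)))
  if (any(plot_table$cover <= 0))
    stop("species covers must be positive")
  unassigned <- setdiff(unique(plot_table$species), species_to_pft$species)
  if (length(unassigned) > 0L)
    stop("species without a PFT assignment: ",
         paste(unassigned, collapse = ", "))
  if (anyDuplicated(species_to_pft$species))
    stop("species assigned to more than one PFT")
  if (any(species_to_pft$pft_slot < 1 | species_to_pft$pft_slot > nrow(schema)))
    stop("pft_slot out of range")

  slot_of <- species_to_pft$pft_slot[
    match(plot_table$species, species_to_pft$species)]
  # per-plot summed cover per slot
  plot_slot <- tapply(plot_table$cover,
                      list(plot = plot_table$plot_id, slot = factor(slot_of, levels = 1:nrow(schema))),
                      sum, default = 0)
  plot_hab <- plot_table$habitat[match(rownames(plot_slot),
                                       as.character(plot_table$plot_id))]
  habs <- sort(unique(plot_hab))
  cover <- t(sapply(habs, function(h) {
    colMeans(plot_slot[plot_hab == h, , drop = FALSE])
  }))
  colnames(cover) <- schema$name
  rownames(cover) <- habs
  n_plots <- vapply(habs, function(h) sum(plot_hab == h), integer(1))
  names(n_plots) <- habs
  structure(list(cover = cover, n_plots = n_plots),
            class = "habitat_composition")
}

#' Vertical-layer adjustment of raw PFT covers
#'
#' Plot-derived covers can sum to more or less than 100\% because vegetation
#' layers overlap vertically, but only the highest layer is seen by the
#' land model's flux calculations. Layers occlude top-down in the order tree >
#' shrub > herb: the tree layer claims \code{min(sum tree covers, 100)}\%,
#' distributed among tree slots proportionally to their raw covers; the
#' residual area is offered to shrubs likewise, then herbs; any remaining area
#' becomes bare ground. The output is a proper fraction vector summing to 1.
#'
#' @param raw_cover Numeric vector of length 17 (percent raw cover per slot,
#'   non-negative). Raw cover on the bare slot is ignored; bare arises as the
#'   unclaimed remainder.
#' @param schema PFT schema.
#' @return Numeric vector of length 17 of fractions in [0, 1] summing to 1.
#' @examples
#' sch <- pft_schema()
#' x <- numeric(17); x[14] <- 70; x[8] <- 60  # C3 grass 70%, broadleaf tree 60%
#' layer_adjust(x, sch)  # tree 0.60, grass 0.40, bare 0
#' @export
layer_adjust <- function(raw_cover, schema = pft_schema()) {
  stopifnot(length(raw_cover) == nrow(schema))
  if (any(!is.finite(raw_cover)) || any(raw_cover < 0))
    stop("raw covers must be finite and non-negative")
  out <- numeric(nrow(schema))
  remaining <- 100
  for (lay in c("tree", "shrub", "herb")) {
    idx <- which(schema$layer == lay)
    tot <- sum(raw_cover[idx])
    if (tot > 0 && remaining > 0) {
      claim <- min(tot, remaining)
      out[idx] <- raw_cover[idx] / tot * claim
      remaining <- remaining - claim
    }
  }
  out[schema$layer == "bare"] <- remaining
  out / 100
}

#' Tag fine cells as crop / natural / ice / urban land units
#'
#' Habitats are tagged once in the crosswalk's habitat register; cropland
#' habitats populate the crop land unit, all other vegetated habitats the
#' natural-vegetation unit, and ice/urban cells pass through unchanged.
#'
#' @param habitat_map Integer matrix of habitat codes.
#' @param habitat_tags Data frame with columns \code{habitat} and \code{tag}
#'   (one of \code{"cropland"}, \code{"natural"}, \code{"ice"},
#'   \code{"urban"}).
#' @return Character matrix of unit tags, same shape as \code{habitat_map}.
#' @export
split_land_units <- function(habitat_map, habitat_tags) {
  codes <- sort(unique(as.vector(habitat_map)))
  missing <- setdiff(codes, habitat_tags$habitat)
  if (length(missing) > 0L)
    stop("habitat code(s) without a land-unit tag: ",
         paste(missing, collapse = ", "))
  bad <- setdiff(unique(habitat_tags$tag),
                 c("cropland", "natural", "ice", "urban"))
  if (length(bad) > 0L)
    stop("unknown land-unit tag(s): ", paste(bad, collapse = ", "))
  tag <- habitat_tags$tag[match(as.vector(habitat_map), habitat_tags$habitat)]
  tag <- c(cropland = "crop", natural = "natural",
           ice = "ice", urban = "urban")[tag]
  matrix(unname(tag), nrow(habitat_map), ncol(habitat_map))
}

#' Aggregate fine-grid PFT fractions to the coarse model grid
#'
#' Fine cells are equal-area, so block aggregation is the arithmetic mean.
#' Fine cells are grouped per land unit (crop vs natural vegetation): the
#' coarse land-unit area fraction is the share of fine cells carrying that
#' tag, and the land-unit PFT composition is the mean of the member cells'
#' fraction vectors (each summing to 1, hence so does the mean). Ice and
#' urban cells pass through as area fractions only.
#'
#' @param fine_frac Numeric array \code{[ny_fine, nx_fine, 17]} of per-cell
#'   PFT fraction vectors (each cell sums to 1).
#' @param unit_map Character matrix of unit tags from
#'   \code{\link{split_land_units}}.
#' @param factor Integer coarsening factor; must divide both fine dimensions.
#' @param schema PFT schema.
#' @return Object of class \code{pft_grid}: list with \code{frac} (list of
#'   arrays \code{natural}, \code{crop}, each \code{[ny, nx, 17]} summing to 1
#'   over slots), \code{unit_frac} (list of matrices \code{natural},
#'   \code{crop}, \code{ice}, \code{urban} summing to 1 per cell), and
#'   \code{schema}. Land units absent from a coarse cell get a placeholder
#'   all-bare composition (their area fraction is 0).
#' @export
aggregate_to_coarse <- function(fine_frac, unit_map, factor,
                                schema = pft_schema()) {
  dims <- dim(fine_frac)
  stopifnot(length(dims) == 3L, dims[3] == nrow(schema))
  if (dims[1] %% factor != 0L || dims[2] %% factor != 0L)
    stop("coarsening factor does not divide the fine grid shape")
  ny <- dims[1] %/% factor
  nx <- dims[2] %/% factor
  n_slot <- dims[3]

  block_row <- (seq_len(dims[1]) - 1L) %/% factor + 1L
  block_col <- (seq_len(dims[2]) - 1L) %/% factor + 1L
  block_id <- outer(block_row, block_col, function(r, c) (c - 1L) * ny + r)

  units <- c("natural", "crop", "ice", "urban")
  unit_frac <- lapply(units, function(u) {
    m <- tapply(as.vector(unit_map == u), as.vector(block_id), mean)
    matrix(as.numeric(m), ny, nx)
  })
  names(unit_frac) <- units

  frac <- list()
  for (u in c("natural", "crop")) {
    arr <- array(0, c(ny, nx, n_slot))
    sel <- unit_map == u
    cnt <- tapply(as.vector(sel), as.vector(block_id), sum)
    for (k in seq_len(n_slot)) {
      v <- fine_frac[, , k]
      v[!sel] <- 0
      s <- tapply(as.vector(v), as.vector(block_id), sum)
      arr[, , k] <- matrix(ifelse(cnt > 0, s / cnt, 0), ny, nx)
    }
    # empty land units get a valid placeholder composition (all bare)
    bare_slot <- which(schema$layer == "bare")
    empty <- matrix(cnt == 0, ny, nx)
    arr[, , bare_slot][empty] <- 1
    frac[[u]] <- arr
  }

  structure(list(frac = frac, unit_frac = unit_frac, schema = schema),
            class = "pft_grid")
}

#' Per-cell total PFT fractions of a coarse grid
#'
#' Combines land units: total fraction of slot k = sum over land units of
#' (unit area fraction x within-unit fraction). Ice and urban area is
#' reported on the bare slot so that totals sum to 1 per cell.
#'
#' @param grid A \code{pft_grid}.
#' @return Numeric array \code{[ny, nx, 17]}.
#' @export
total_pft_fractions <- function(grid) {
  stopifnot(inherits(grid, "pft_grid"))
  dims <- dim(grid$frac$natural)
  out <- array(0, dims)
  for (u in c("natural", "crop")) {
    w <- grid$unit_frac[[u]]
    for (k in seq_len(dims[3])) {
      out[, , k] <- out[, , k] + w * grid$frac[[u]][, , k]
    }
  }
  bare_slot <- which(grid$schema$layer == "bare")
  out[, , bare_slot] <- out[, , bare_slot] +
    grid$unit_frac$ice + grid$unit_frac$urban
  out
}

#' Translate a land-system map into a coarse fractional PFT grid
#'
#' End-to-end translation: habitat assignment by suitability-constrained
#' crosswalk, habitat-level PFT composition from plot averages, vertical-layer
#' adjustment, land-unit splitting, and block aggregation to the coarse grid.
#' A pure function: identical inputs give identical grids.
#'
#' @param ls_map Integer matrix of land-system codes (fine grid).
#' @param crosswalk Data frame (\code{land_system}, \code{habitat}).
#' @param suitability Suitability array, see
#'   \code{\link{land_system_to_habitat}}.
#' @param habitat_tags Data frame (\code{habitat}, \code{tag}).
#' @param composition \code{habitat_composition} from
#'   \code{\link{habitat_composition_from_plots}}.
#' @param factor Coarsening factor.
#' @param schema PFT schema.
#' @return A \code{pft_grid}.
#' @export
translate_land_systems <- function(ls_map, crosswalk, suitability,
                                   habitat_tags, composition,
                                   factor, schema = pft_schema()) {
  stopifnot(inherits(composition, "habitat_composition"))
  habitat_map <- land_system_to_habitat(ls_map, crosswalk, suitability)
  habs_used <- sort(unique(as.vector(habitat_map)))
  missing <- setdiff(habs_used, as.integer(rownames(composition$cover)))
  if (length(missing) > 0L)
    stop("habitat(s) without plot-derived composition: ",
         paste(missing, collapse = ", "))

  # adjusted fraction vector per habitat (computed once, looked up per cell)
  adj <- t(vapply(habs_used, function(h) {
    layer_adjust(composition$cover[as.character(h), ], schema)
  }, numeric(nrow(schema))))
  rownames(adj) <- habs_used

  idx <- match(as.vector(habitat_map), habs_used)
  fine_frac <- array(adj[idx, ], c(dim(habitat_map), nrow(schema)))

  unit_map <- split_land_units(habitat_map, habitat_tags)
  aggregate_to_coarse(fine_frac, unit_map, factor, schema)
}
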