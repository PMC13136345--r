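#' Aggregate the 17 PFT slots into 7 land-cover categories
#'
#' Category fraction = sum of member-slot fractions across both land units
#' (so crop/natural conversions appear later as category transitions). Ice
#' and urban area counts as bare. Per-cell category fractions sum to 1.
#'
#' @param grid A \code{pft_grid}.
#' @return Numeric array \code{[ny, nx, 7]}, third dimension named by
#'   \code{\link{lc_categories}}.
#' @export
aggregate_categories <- function(grid) {
  stopifnot(inherits(grid, "pft_grid"))
  total <- total_pft_fractions(grid)
  cats <- lc_categories()
  dims <- dim(total)
  out <- array(0, c(dims[1], dims[2], length(cats)),
               dimnames = list(NULL, NULL, cats))
  for (j in seq_along(cats)) {
    member <- which(grid$schema$category == cats[j])
    for (k in member) out[, , j] <- out[, , j] + total[, , k]
  }
  out
}

# Greedy matching of one cell's balanced category-change vector.
# Returns a 7x7 from->to matrix of transitioned fractions.
greedy_match_cell <- function(delta, tol = 1e-12) {
  n <- length(delta)
  flux <- matrix(0, n, n)
  res <- delta
  # at most n-1 iterations: each zeroes at least one residual
  for (iter in seq_len(n)) {
    if (max(abs(res)) < tol) break
    to <- which.max(res)     # largest remaining increase (first-index tie-break
    from <- which.min(res)   # follows canonical category order)
    amount <- min(res[to], -res[from])
    if (amount < tol) break
    flux[from, to] <- flux[from, to] + amount
    res[to] <- res[to] - amount
    res[from] <- res[from] + amount
  }
  flux
}

#' Per-cell net land-cover transitions by greedy matching
#'
#' In fractional PFT maps, category changes do not identify which cover
#' replaced which. Net transitions are resolved per grid cell by a greedy
#' algorithm: in each iteration the most increased and the most decreased
#' categories are matched, a transition of the smaller magnitude is recorded
#' from the decreased to the increased category, and residuals are updated
#' until all change is captured. Ties in "most increased/decreased" break by
#' the canonical category order.
#'
#' @param cat_ref,cat_scen Numeric arrays \code{[ny, nx, 7]} of category
#'   fractions (reference and scenario); per-cell sums must agree within
#'   \code{tol_balance}.
#' @param tol Residual-exhaustion tolerance (absolute fraction).
#' @param tol_balance Tolerance on per-cell conservation of total fraction.
#' @return Object of class \code{transition_field}: list with \code{flux}
#'   (array \code{[ny, nx, 7, 7]}, \code{flux[i,j,a,b]} = fraction of cell
#'   area transitioned from category a to category b) and \code{categories}.
#' @export
greedy_net_transitions <- function(cat_ref, cat_scen, tol = 1e-12,
                                   tol_balance = 1e-9) {
  stopifnot(identical(dim(cat_ref), dim(cat_scen)),
            dim(cat_ref)[3] == length(lc_categories()))
  ny <- dim(cat_ref)[1]; nx <- dim(cat_ref)[2]; nc <- dim(cat_ref)[3]
  sum_ref <- apply(cat_ref, c(1, 2), sum)
  sum_scen <- apply(cat_scen, c(1, 2), sum)
  if (max(abs(sum_ref - sum_scen)) > tol_balance)
    stop("category fractions are not conserved between scenario and ",
         "reference (per-cell sums differ by more than ", tol_balance, ")")

  flux <- array(0, c(ny, nx, nc, nc),
                dimnames = list(NULL, NULL, lc_categories(), lc_categories()))
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      delta <- cat_scen[i, j, ] - cat_ref[i, j, ]
      if (max(abs(delta)) >= tol)
        flux[i, j, , ] <- greedy_match_cell(delta, tol)
    }
  }
  structure(list(flux = flux, categories = lc_categories()),
            class = "transition_field")
}

#' Orient transition pairs by their dominant direction
#'
#' For each unordered category pair, the total transitioned area in each
#' direction is summed over the region; the direction with the larger total
#' defines the positive orientation and the pair's name (e.g. if crop-to-grass
#' area exceeds grass-to-crop, the net transition type is named "crop rainfed
#' to grass"). The signed per-cell predictor is x = (fraction in the dominant
#' direction) - (fraction in the opposite direction). Pairs with zero total
#' area in both directions are absent from the inventory; with all 7
#' categories active and the rainfed/irrigated-crop pair empty the inventory
#' has 20 transition types. Exact area ties orient by canonical category
#' order (earlier category is the "from" side).
#'
#' @param field A \code{transition_field}.
#' @param region_mask Optional logical matrix selecting the cells used both
#'   for direction totals and in the design matrix (default: all cells).
#' @param tol Areas at or below this total are treated as absent.
#' @return Object of class \code{oriented_transitions}: list with
#'   \code{inventory} (data frame: \code{from}, \code{to}, \code{name},
#'   \code{area_dominant}, \code{area_opposite}, \code{area_pct} — gross
#'   transitioned area as percent of regional area —, \code{occupancy_pct} —
#'   percent of region cells with nonzero x), \code{design} (matrix cells x
#'   types of signed fractions, columns named by transition type),
#'   \code{cell_index} (indices of region cells into the flattened grid), and
#'   \code{grid_shape}.
#' @export
orient_by_dominant_direction <- function(field, region_mask = NULL,
                                         tol = 0) {
  stopifnot(inherits(field, "transition_field"))
  dims <- dim(field$flux)
  ny <- dims[1]; nx <- dims[2]; nc <- dims[3]
  cats <- field$categories
  if (is.null(region_mask)) region_mask <- matrix(TRUE, ny, nx)
  stopifnot(identical(dim(region_mask), c(ny, nx)))
  cell_index <- which(region_mask)
  n_cells <- length(cell_index)
  if (n_cells == 0L) stop("empty region mask")

  flux_flat <- matrix(field$flux, nrow = ny * nx)  # cells x (from,to) pairs
  flux_flat <- flux_flat[cell_index, , drop = FALSE]
  pair_col <- function(a, b) (b - 1L) * nc + a  # column of from=a, to=b

  inv <- list()
  design_cols <- list()
  for (a in seq_len(nc - 1L)) {
    for (b in (a + 1L):nc) {
      fab <- flux_flat[, pair_col(a, b)]
      fba <- flux_flat[, pair_col(b, a)]
      area_ab <- sum(fab)
      area_ba <- sum(fba)
      if (area_ab + area_ba <= tol) next
      if (area_ab >= area_ba) {        # ties keep canonical order a -> b
        from <- a; to <- b; x <- fab - fba
        area_dom <- area_ab; area_opp <- area_ba
      } else {
        from <- b; to <- a; x <- fba - fab
        area_dom <- area_ba; area_opp <- area_ab
      }
      name <- paste(lc_category_label(cats[from]), "to",
                    lc_category_label(cats[to]))
      inv[[length(inv) + 1L]] <- data.frame(
        from = cats[from], to = cats[to], name = name,
        area_dominant = area_dom, area_opposite = area_opp,
        area_pct = (area_dom + area_opp) / n_cells * 100,
        occupancy_pct = mean(x != 0) * 100,
        stringsAsFactors = FALSE)
      design_cols[[name]] <- x
    }
  }
  inventory <- if (length(inv) > 0L) do.call(rbind, inv) else
    data.frame(from = character(), to = character(), name = character(),
               area_dominant = numeric(), area_opposite = numeric(),
               area_pct = numeric(), occupancy_pct = numeric())
  design <- if (length(design_cols) > 0L)
    do.call(cbind, design_cols) else matrix(0, n_cells, 0)
  structure(list(inventory = inventory, design = design,
                 cell_index = cell_index, grid_shape = c(ny, nx)),
            class = "oriented_transitions")
}

#' Reconstruct per-category net change from a transition field
#'
#' For each category, inflow minus outflow summed over recorded transitions.
#' Used to verify that greedy matching exactly accounts for the input change.
#'
#' @param field A \code{transition_field}.
#' @return Numeric array \code{[ny, nx, 7]} of reconstructed net changes.
#' @export
transition_net_change <- function(field) {
  stopifnot(inherits(field, "transition_field"))
  dims <- dim(field$flux)
  inflow <- apply(field$flux, c(1, 2, 4), sum)
  outflow <- apply(field$flux, c(1, 2, 3), sum)
  out <- inflow - outflow
  dimnames(out) <- list(NULL, NULL, field$categories)
  out
}
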