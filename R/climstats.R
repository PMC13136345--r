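#' Annual maximum of daily maximum temperature (TXx)
#'
#' @param daily_tmax Numeric array \code{[ny, nx, nyear, nday]} of daily 2 m
#'   maximum temperatures; missing days may be \code{NA}.
#' @return Numeric array \code{[ny, nx, nyear]} of annual maxima. If any days
#'   were missing the result carries attribute \code{incomplete = TRUE} and
#'   maxima are computed over the available days.
#' @export
txx <- function(daily_tmax) {
  stopifnot(length(dim(daily_tmax)) == 4L)
  if (dim(daily_tmax)[4] < 1L) stop("at least one day per year required")
  has_na <- anyNA(daily_tmax)
  out <- apply(daily_tmax, c(1, 2, 3), max, na.rm = TRUE)
  if (has_na) attr(out, "incomplete") <- TRUE
  out
}

# Two-sided signed-rank p on paired differences. All-tied input has no
# defined p (returns 1, not significant); a single-signed configuration is
# the distribution's extreme, whose exact p is 2^(1-n) irrespective of
# magnitude ties.
signed_rank_p <- function(d, exact = TRUE) {
  if (all(d == 0)) return(1)
  if (exact && (all(d > 0) || all(d < 0))) return(min(1, 2^(1 - length(d))))
  suppressWarnings(stats::wilcox.test(d, exact = exact)$p.value)
}

#' Paired per-cell scenario-vs-reference significance test
#'
#' Two-sided Wilcoxon signed-rank test on the paired yearly values of each
#' grid cell. Pairing on years removes year-to-year variation as a
#' confounder when both runs share boundary conditions. Cells whose yearly
#' pairs are all tied have no defined p-value and are flagged not significant
#' (p = 1). When every difference has the same sign the exact two-sided
#' p-value is \code{2^(1-n)} whatever the magnitudes (the extreme of the
#' signed-rank distribution does not depend on magnitude ties), so that case
#' is computed directly.
#'
#' @param field_scen,field_ref Numeric arrays \code{[ny, nx, nyear]} with the
#'   same years in both runs.
#' @param exact Use the exact signed-rank distribution where possible
#'   (default TRUE; falls back to the normal approximation on ties).
#' @return Matrix \code{[ny, nx]} of two-sided p-values.
#' @export
paired_scenario_test <- function(field_scen, field_ref, exact = TRUE) {
  stopifnot(identical(dim(field_scen), dim(field_ref)),
            length(dim(field_scen)) == 3L)
  ny <- dim(field_scen)[1]; nx <- dim(field_scen)[2]
  p <- matrix(1, ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      d <- field_scen[i, j, ] - field_ref[i, j, ]
      p[i, j] <- signed_rank_p(d, exact)
    }
  }
  p
}

#' Unpaired per-cell change test between two periods
#'
#' Two-sided Mann-Whitney U (rank-sum) test per cell, for comparisons
#' without a meaningful year pairing (e.g. a future run against recent
#' climate).
#'
#' @param field_a,field_b Numeric arrays \code{[ny, nx, nyear]}; the year
#'   counts may differ but each needs at least 2 years.
#' @param exact Use the exact rank-sum distribution where possible.
#' @return Matrix \code{[ny, nx]} of two-sided p-values.
#' @export
unpaired_change_test <- function(field_a, field_b, exact = TRUE) {
  stopifnot(length(dim(field_a)) == 3L, length(dim(field_b)) == 3L,
            identical(dim(field_a)[1:2], dim(field_b)[1:2]))
  if (dim(field_a)[3] < 2L || dim(field_b)[3] < 2L)
    stop("at least 2 years per sample required")
  ny <- dim(field_a)[1]; nx <- dim(field_a)[2]
  p <- matrix(1, ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      a <- field_a[i, j, ]; b <- field_b[i, j, ]
      if (all(a == b)) next
      p[i, j] <- suppressWarnings(
        stats::wilcox.test(a, b, exact = exact)$p.value)
    }
  }
  p
}

#' Benjamini-Hochberg false-discovery-rate adjustment of a p-value grid
#'
#' Step-up adjustment over all tested cells within one family (one family
#' per variable x season x scenario). Adjusted p-values are monotone in the
#' raw p-values and never smaller than them.
#'
#' @param p_grid Numeric matrix (or vector) of finite p-values in [0, 1].
#' @return Adjusted p-values, same shape.
#' @export
adjust_fdr <- function(p_grid) {
  if (any(!is.finite(p_grid)))
    stop("p-values must be finite for the FDR adjustment")
  adj <- stats::p.adjust(as.vector(p_grid), method = "BH")
  if (is.matrix(p_grid)) matrix(adj, nrow(p_grid), ncol(p_grid)) else adj
}

#' Top-fraction mask of a gridded score
#'
#' Selects the \code{ceiling(frac * n)} highest-scoring cells; ties break by
#' cell index (column-major order), making the mask deterministic.
#'
#' @param score Numeric matrix.
#' @param frac Fraction of cells to select (default 0.01).
#' @return Logical matrix with exactly \code{ceiling(frac * n)} TRUE cells.
#' @export
top_fraction_mask <- function(score, frac = 0.01) {
  stopifnot(is.matrix(score), frac > 0, frac <= 1)
  n <- length(score)
  k <- ceiling(frac * n)
  ord <- order(-as.vector(score), seq_len(n))
  mask <- matrix(FALSE, nrow(score), ncol(score))
  mask[ord[seq_len(k)]] <- TRUE
  mask
}

#' Per-cell PFT change fraction between two grids
#'
#' Fraction of the cell area whose PFT composition changes:
#' sum over slots of |Delta fraction| / 2 (gains and losses balance, so half
#' the L1 difference is the turned-over area).
#'
#' @param grid_ref,grid_scen \code{pft_grid}s on the same coarse grid.
#' @return Numeric matrix \code{[ny, nx]} of change fractions in [0, 1].
#' @export
pft_change_fraction <- function(grid_ref, grid_scen) {
  tr <- total_pft_fractions(grid_ref)
  ts <- total_pft_fractions(grid_scen)
  apply(abs(ts - tr), c(1, 2), sum) / 2
}

#' Analysis masks and perturbation bins
#'
#' Builds the standard analysis masks: the 1\% most affected cells (by PFT
#' change fraction), optionally the 1\% most extreme cells of a reference
#' field and the 1\% most changing cells of a reference-minus-recent change
#' field; plus perturbation bins grouping cells by the proportion of the cell
#' area with changed PFTs (0-10, 10-30, 30-50, 50-100\%; intervals right-open
#' except the last). The bins partition all cells.
#'
#' @param change_fraction Matrix of per-cell PFT change fractions in [0, 1].
#' @param reference_field Optional matrix (e.g. mean reference temperature)
#'   for the most-extreme-in-reference mask.
#' @param recent_change Optional matrix (reference minus recent climate) for
#'   the most-changing mask.
#' @param frac Mask fraction (default 0.01).
#' @return Object of class \code{mask_set}: list with logical matrices
#'   \code{most_affected}, \code{most_extreme} (or NULL),
#'   \code{most_changing} (or NULL), and \code{bins} (integer matrix with
#'   levels 1-4 and a \code{labels} attribute).
#' @export
masks_and_bins <- function(change_fraction, reference_field = NULL,
                           recent_change = NULL, frac = 0.01) {
  stopifnot(is.matrix(change_fraction))
  if (any(change_fraction < 0 | change_fraction > 1))
    stop("change fractions must lie in [0, 1]")
  breaks <- c(0, 0.1, 0.3, 0.5, 1)
  labels <- c("0-10%", "10-30%", "30-50%", "50-100%")
  bins <- matrix(findInterval(as.vector(change_fraction), breaks,
                              rightmost.closed = TRUE),
                 nrow(change_fraction), ncol(change_fraction))
  attr(bins, "labels") <- labels
  structure(list(
    most_affected = top_fraction_mask(change_fraction, frac),
    most_extreme = if (!is.null(reference_field))
      top_fraction_mask(reference_field, frac),
    most_changing = if (!is.null(recent_change))
      top_fraction_mask(recent_change, frac),
    bins = bins
  ), class = "mask_set")
}

#' Area share of significant cells in a region
#'
#' Area-weighted percentage of region cells whose adjusted p-value falls
#' below the significance level.
#'
#' @param adjusted_p Matrix of adjusted p-values.
#' @param alpha Significance level (default 0.05).
#' @param region_mask Optional logical matrix (default: all cells).
#' @param weights Optional non-negative area weights (default: equal).
#' @return Percent of regional area significant (scalar in [0, 100]).
#' @export
significant_area_share <- function(adjusted_p, alpha = 0.05,
                                   region_mask = NULL, weights = NULL) {
  stopifnot(is.matrix(adjusted_p))
  if (is.null(region_mask)) region_mask <- matrix(TRUE, nrow(adjusted_p),
                                                  ncol(adjusted_p))
  if (is.null(weights)) weights <- matrix(1, nrow(adjusted_p),
                                          ncol(adjusted_p))
  w <- weights[region_mask]
  sig <- adjusted_p[region_mask] < alpha
  sum(w * sig) / sum(w) * 100
}

#' Regional mean response with interannual spread
#'
#' Climatological summary of a scenario-minus-reference response: the
#' multi-year regional mean plus or minus one standard deviation across
#' years, with a paired signed-rank significance test on the yearly regional
#' means and its place in a caller-managed FDR family.
#'
#' @param field_scen,field_ref Arrays \code{[ny, nx, nyear]}.
#' @param region_mask Logical matrix.
#' @param weights Optional area weights.
#' @return List: \code{mean} (regional multi-year mean response), \code{sd}
#'   (standard deviation of yearly regional mean responses), \code{p_value}
#'   (two-sided signed-rank on the yearly pairs).
#' @export
regional_response <- function(field_scen, field_ref, region_mask,
                              weights = NULL) {
  stopifnot(identical(dim(field_scen), dim(field_ref)))
  dims <- dim(field_scen)
  if (is.null(weights)) weights <- matrix(1, dims[1], dims[2])
  w <- weights[region_mask]; w <- w / sum(w)
  yearly <- vapply(seq_len(dims[3]), function(t) {
    sum((field_scen[, , t] - field_ref[, , t])[region_mask] * w)
  }, numeric(1))
  list(mean = mean(yearly), sd = stats::sd(yearly),
       p_value = signed_rank_p(yearly))
}
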