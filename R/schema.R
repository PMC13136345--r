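#' Plant functional type schema
#'
#' The 17 PFT slots used by the land model configuration this package targets:
#' bare ground plus 16 vegetated types (tree, shrub, and herbaceous variants,
#' including the two managed crop types). Each slot carries a vertical-layer
#' tag (\code{bare}, \code{tree}, \code{shrub}, \code{herb}) used by
#' \code{\link{layer_adjust}}, and a land-cover category tag used by
#' \code{\link{aggregate_categories}}. The two tropical tree slots are part of
#' the schema but are typically identically zero over extratropical domains.
#'
#' @return A data frame with one row per slot and columns \code{slot}
#'   (1-based index), \code{name}, \code{layer}, and \code{category}.
#' @examples
#' sch <- pft_schema()
#' nrow(sch)            # 17
#' sum(sch$layer == "bare")
#' @export
pft_schema <- function() {
  data.frame(
    slot = 1:17,
    name = c(
      "bare ground",
      "needleleaf evergreen temperate tree",
      "needleleaf evergreen boreal tree",
      "needleleaf deciduous boreal tree",
      "broadleaf evergreen tropical tree",
      "broadleaf evergreen temperate tree",
      "broadleaf deciduous tropical tree",
      "broadleaf deciduous temperate tree",
      "broadleaf deciduous boreal tree",
      "broadleaf evergreen temperate shrub",
      "broadleaf deciduous temperate shrub",
      "broadleaf deciduous boreal shrub",
      "C3 arctic grass",
      "C3 grass",
      "C4 grass",
      "rainfed crop",
      "irrigated crop"
    ),
    layer = c(
      "bare",
      rep("tree", 8L),
      rep("shrub", 3L),
      rep("herb", 5L)
    ),
    category = c(
      "bare",
      "tree_needleleaf", "tree_needleleaf", "tree_needleleaf",
      "tree_broadleaf", "tree_broadleaf", "tree_broadleaf",
      "tree_broadleaf", "tree_broadleaf",
      "shrub", "shrub", "shrub",
      "grass", "grass", "grass",
      "crop_rainfed",
      "crop_irrigated"
    ),
    stringsAsFactors = FALSE
  )
}

#' Land-cover categories
#'
#' The seven aggregated land-cover categories used for net-transition analysis:
#' needleleaf tree (evergreen temperate, evergreen boreal, deciduous boreal),
#' broadleaf tree, shrub, grass (herbs excluding annual crops: C3 arctic, C3,
#' C4), rainfed crop, irrigated crop, and bare ground. The order is fixed and
#' is the deterministic tie-break order used throughout.
#'
#' @return Character vector of the 7 category identifiers, in canonical order.
#' @export
lc_categories <- function() {
  c("tree_needleleaf", "tree_broadleaf", "shrub", "grass",
    "crop_rainfed", "crop_irrigated", "bare")
}

#' Human-readable category labels
#'
#' @param categories Character vector of category identifiers.
#' @return Character vector of display labels (e.g. "crop rainfed").
#' @export
lc_category_label <- function(categories = lc_categories()) {
  labels <- c(
    tree_needleleaf = "tree needleleaf",
    tree_broadleaf  = "tree broadleaf",
    shrub           = "shrub",
    grass           = "grass",
    crop_rainfed    = "crop rainfed",
    crop_irrigated  = "crop irrigated",
    bare            = "bare"
  )
  unknown <- setdiff(categories, names(labels))
  if (length(unknown) > 0L)
    stop("unknown land-cover categories: ", paste(unknown, collapse = ", "))
  unname(labels[categories])
}

# Membership matrix (17 x 7) mapping PFT slots onto categories.
category_membership <- function(schema = pft_schema()) {
  cats <- lc_categories()
  m <- sapply(cats, function(cc) as.numeric(schema$category == cc))
  dimnames(m) <- list(schema$name, cats)
  m
}
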