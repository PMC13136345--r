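#' Write a gridded field as a flattened CSV table
#'
#' Plain-text interchange for gridded fields: one row per cell (and per
#' index along any extra dimensions), with columns \code{y}, \code{x},
#' optional extra dimension columns, and \code{value}. Deterministic row
#' order (column-major), so identical fields give byte-identical files.
#'
#' @param field Numeric matrix or array (2-4 dimensions; the first two are
#'   y and x).
#' @param path Output CSV path.
#' @param dim_names Names for dimensions beyond the first two (e.g.
#'   \code{c("year")}).
#' @export
write_grid_csv <- function(field, path, dim_names = NULL) {
  d <- dim(field)
  if (is.null(d) || length(d) < 2L || length(d) > 4L)
    stop("field must have 2 to 4 dimensions")
  extra <- d[-(1:2)]
  if (is.null(dim_names))
    dim_names <- if (length(extra) > 0L)
      paste0("dim", seq_along(extra)) else character(0)
  if (length(dim_names) != length(extra))
    stop("dim_names must name every dimension beyond y and x")
  idx <- do.call(expand.grid, c(list(y = seq_len(d[1]), x = seq_len(d[2])),
                                stats::setNames(lapply(extra, seq_len),
                                                dim_names)))
  df <- cbind(idx, value = as.vector(field))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a gridded field written by \code{\link{write_grid_csv}}
#'
#' @param path CSV path.
#' @return Numeric array with dimensions recovered from the index columns.
#' @export
read_grid_csv <- function(path) {
  df <- utils::read.csv(path)
  dims <- vapply(df[seq_len(ncol(df) - 1L)], max, numeric(1))
  array(df$value, unname(dims))
}

#' Write a categorical map as CSV
#' @param map Integer matrix.
#' @param path Output path.
#' @export
write_map_csv <- function(map, path) {
  write_grid_csv(map, path)
}

#' Read a categorical map written by \code{\link{write_map_csv}}
#' @param path CSV path.
#' @return Integer matrix.
#' @export
read_map_csv <- function(path) {
  m <- read_grid_csv(path)
  storage.mode(m) <- "integer"
  m
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override the defaults of \code{\link{synthetic_config}}
#' and \code{\link{attribution_spec}}; the \code{sensitivities} block (map
#' "from->to" -> value) overrides the default true sensitivities.
#'
#' @param path YAML file path.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  synth_args <- y$synth %||% list()
  if (!is.null(y$sensitivities))
    synth_args$true_sensitivities <- unlist(y$sensitivities)
  attr_args <- y$attribution %||% list()
  pipeline_config(
    synth = do.call(synthetic_config, synth_args),
    attribution = do.call(attribution_spec, attr_args),
    reference = y$reference %||% "reference",
    scenario = y$scenario %||% "scenario",
    alpha = y$alpha %||% 0.05,
    response = y$response %||% "t2m",
    seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical config hash: md5 of the sorted-key JSON serialisation.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip)
    else if (is.numeric(x)) signif(unclass(x), 12)
    else x
  }
  plain <- strip(config)
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       sort_keys = TRUE)
  unname(tools::md5sum(tmp))
}
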