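#' Specification of the transition-attribution regression
#'
#' The local temperature response is modelled as
#' \code{dT_i = b0 + sum_p b_p x_ip + e_i} across grid cells, where x_ip are
#' signed net-transition fractions and b_p the temperature sensitivities in
#' degC per unit cell fraction. Multicollinearity among transitions is
#' handled by ridge regression; the penalty is chosen per fit from a
#' log-spaced grid by grouped cross-validation over spatial blocks, and
#' uncertainty comes from repeated block-wise train/test resampling.
#'
#' @param penalty_grid Strictly positive, increasing penalty values; default
#'   25 log-spaced points on [0.1, 2000].
#' @param n_iterations Number of split-fit-evaluate iterations (default 200).
#' @param block_size Side length of square spatial blocks, in cells.
#' @param train_fraction Fraction of blocks used for training (default 0.75).
#' @param n_folds Folds of the internal grouped CV over training blocks.
#' @return Object of class \code{attribution_spec}.
#' @export
attribution_spec <- function(penalty_grid = 10^seq(log10(0.1), log10(2000),
                                                   length.out = 25),
                             n_iterations = 200L,
                             block_size = 5L,
                             train_fraction = 0.75,
                             n_folds = 5L) {
  if (any(penalty_grid <= 0) || is.unsorted(penalty_grid, strictly = TRUE))
    stop("penalty grid must be strictly positive and increasing")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train fraction must be in (0, 1)")
  stopifnot(block_size >= 1L, n_iterations >= 1L, n_folds >= 2L)
  structure(list(penalty_grid = penalty_grid,
                 n_iterations = as.integer(n_iterations),
                 block_size = as.integer(block_size),
                 train_fraction = train_fraction,
                 n_folds = as.integer(n_folds)),
            class = "attribution_spec")
}

#' Tile a grid into contiguous square blocks
#'
#' Blocks tile the grid row/column-wise; edge blocks may be smaller. A block
#' larger than the grid yields a single block with a warning.
#'
#' @param grid_shape Integer vector \code{c(ny, nx)}.
#' @param block_size Cells per block side.
#' @return Integer matrix \code{[ny, nx]} of block ids (1-based, contiguous).
#' @export
make_blocks <- function(grid_shape, block_size) {
  stopifnot(length(grid_shape) == 2L, block_size >= 1L)
  ny <- grid_shape[1]; nx <- grid_shape[2]
  if (block_size > max(ny, nx))
    warning("block size exceeds grid extent; using a single block")
  br <- (seq_len(ny) - 1L) %/% block_size
  bc <- (seq_len(nx) - 1L) %/% block_size
  nbr <- max(br) + 1L
  outer(br, bc, function(r, c) c * nbr + r + 1L)
}

# Closed-form ridge on train-standardised predictors with an unpenalised
# intercept. Returns coefficients on the original predictor scale.
ridge_fit <- function(x_train, y_train, lambda) {
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2, stats::sd)
  keep <- which(sdv > 0)
  b <- numeric(ncol(x_train))
  if (length(keep) > 0L) {
    xs <- sweep(sweep(x_train[, keep, drop = FALSE], 2, mu[keep]), 2,
                sdv[keep], "/")
    xtx <- crossprod(xs)
    xty <- crossprod(xs, y_train - mean(y_train))
    bs <- solve(xtx + diag(lambda, length(keep)), xty)
    b[keep] <- bs / sdv[keep]
  }
  b0 <- mean(y_train) - sum(b * mu)
  list(intercept = b0, coef = b, dropped = setdiff(seq_len(ncol(x_train)),
                                                   keep))
}

# Grouped k-fold CV over training blocks to choose the penalty.
# Standardisation is refit inside every fold (no leakage); fold-wise
# cross-products are reused across the penalty grid. Ties in CV error pick
# the smaller penalty.
choose_penalty <- function(x, y, block_of, spec) {
  blocks <- unique(block_of)
  k <- min(spec$n_folds, length(blocks))
  if (k < 2L) return(spec$penalty_grid[1])
  fold_of_block <- rep_len(seq_len(k), length(blocks))[sample.int(length(blocks))]
  fold <- fold_of_block[match(block_of, blocks)]
  cv_err <- numeric(length(spec$penalty_grid))
  for (f in seq_len(k)) {
    tr <- fold != f
    if (sum(tr) < 2L || all(!tr)) next
    x_tr <- x[tr, , drop = FALSE]; y_tr <- y[tr]
    mu <- colMeans(x_tr)
    sdv <- apply(x_tr, 2, stats::sd)
    keep <- which(sdv > 0)
    ybar <- mean(y_tr)
    x_te <- x[!tr, , drop = FALSE]; y_te <- y[!tr]
    if (length(keep) == 0L) {
      cv_err <- cv_err + sum((y_te - ybar)^2)
      next
    }
    xs <- sweep(sweep(x_tr[, keep, drop = FALSE], 2, mu[keep]), 2,
                sdv[keep], "/")
    xtx <- crossprod(xs)
    xty <- crossprod(xs, y_tr - ybar)
    x_te_k <- x_te[, keep, drop = FALSE]
    for (li in seq_along(spec$penalty_grid)) {
      bs <- solve(xtx + diag(spec$penalty_grid[li], length(keep)), xty)
      b <- bs / sdv[keep]
      pred <- ybar - sum(b * mu[keep]) + x_te_k %*% b
      cv_err[li] <- cv_err[li] + sum((y_te - pred)^2)
    }
  }
  spec$penalty_grid[which.min(cv_err)]
}

#' One attribution fit on a block-wise train/test split
#'
#' Standardises predictors on training cells only (constant predictors are
#' dropped from the fit and reported), selects the ridge penalty by grouped
#' cross-validation over training blocks, fits with an unpenalised intercept,
#' back-transforms coefficients to degC per unit fraction, and evaluates mean
#' absolute error and R-squared on the held-out blocks.
#'
#' @param delta_t Numeric response vector (degC per cell).
#' @param x Design matrix (cells x transition types, signed fractions).
#' @param block_of Integer vector assigning each cell to a spatial block.
#' @param spec An \code{attribution_spec}.
#' @param train_blocks Block ids forming the training set; duplicated ids
#'   (as drawn by a block bootstrap) contribute their cells with
#'   multiplicity. Cells of blocks not listed form the test set.
#' @return List: \code{intercept}, \code{coef} (named), \code{penalty},
#'   \code{mae}, \code{r2}, \code{dropped} (indices of constant predictors).
#' @export
fit_once <- function(delta_t, x, block_of, spec, train_blocks) {
  stopifnot(inherits(spec, "attribution_spec"),
            length(delta_t) == nrow(x), length(block_of) == nrow(x))
  if (length(unique(train_blocks)) < 2L)
    stop("at least 2 training blocks required")
  tr_idx <- unlist(lapply(train_blocks, function(b) which(block_of == b)))
  te <- !(block_of %in% train_blocks)
  if (!any(te)) stop("empty test set")
  lambda <- choose_penalty(x[tr_idx, , drop = FALSE], delta_t[tr_idx],
                           block_of[tr_idx], spec)
  fit <- ridge_fit(x[tr_idx, , drop = FALSE], delta_t[tr_idx], lambda)
  names(fit$coef) <- colnames(x)
  pred <- fit$intercept + x[te, , drop = FALSE] %*% fit$coef
  resid <- delta_t[te] - pred
  sst <- sum((delta_t[te] - mean(delta_t[te]))^2)
  list(intercept = fit$intercept, coef = fit$coef, penalty = lambda,
       mae = mean(abs(resid)),
       r2 = if (sst > 0) 1 - sum(resid^2) / sst else NA_real_,
       dropped = fit$dropped)
}

#' Bootstrap attribution of temperature response to land-cover transitions
#'
#' Runs \code{n_iterations} independent iterations of the full pipeline —
#' spatial block bootstrap (75\% of blocks drawn with replacement for
#' training, the never-drawn blocks held out for testing), training-set
#' standardisation, penalty selection by grouped CV, ridge fit, held-out
#' evaluation — and summarises each coefficient by its mean and
#' 2.5th/97.5th percentiles over iterations. Contributions are mean
#' sensitivity times the regional signed percentage change of the
#' transition. A spatially uniform non-local offset in the response is
#' absorbed by the intercept.
#'
#' @param delta_t Response vector or matrix \code{[ny, nx]} (degC).
#' @param oriented An \code{oriented_transitions} (provides the signed design
#'   matrix and the transition inventory), or a plain design matrix.
#' @param spec An \code{attribution_spec}.
#' @param seed Integer seed controlling all splits.
#' @return Object of class \code{attribution_result}: list with \code{table}
#'   (data frame per transition type: \code{name}, \code{mean}, \code{lower},
#'   \code{upper}, \code{pct_change}, \code{contribution}, \code{area_pct},
#'   \code{occupancy_pct}), \code{intercept} (mean, lower, upper),
#'   \code{samples} (iterations x coefficients), \code{test_error}
#'   (mean MAE and R2), and \code{n_failed}.
#' @export
bootstrap_attribution <- function(delta_t, oriented, spec = attribution_spec(),
                                  seed = 1L) {
  if (inherits(oriented, "oriented_transitions")) {
    x <- oriented$design
    inventory <- oriented$inventory
    grid_shape <- oriented$grid_shape
    if (is.matrix(delta_t)) delta_t <- delta_t[oriented$cell_index]
  } else {
    x <- as.matrix(oriented)
    inventory <- NULL
    grid_shape <- c(nrow(x), 1L)
  }
  stopifnot(length(delta_t) == nrow(x))
  if (ncol(x) == 0L) stop("no transition types in the design")

  block_mat <- make_blocks(grid_shape, spec$block_size)
  block_of <- if (inherits(oriented, "oriented_transitions"))
    block_mat[oriented$cell_index] else block_mat[seq_len(nrow(x))]
  blocks <- unique(block_of)
  n_train <- max(1L, min(length(blocks) - 1L,
                         round(spec$train_fraction * length(blocks))))

  set.seed(seed)
  samples <- matrix(NA_real_, spec$n_iterations, ncol(x) + 1L,
                    dimnames = list(NULL, c("(intercept)", colnames(x))))
  mae <- r2 <- rep(NA_real_, spec$n_iterations)
  n_failed <- 0L
  failures <- character()
  for (it in seq_len(spec$n_iterations)) {
    res <- tryCatch({
      train_blocks <- sample(blocks, n_train, replace = TRUE)
      fit_once(delta_t, x, block_of, spec, train_blocks)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      failures <- c(failures, conditionMessage(res))
      next
    }
    samples[it, ] <- c(res$intercept, res$coef)
    mae[it] <- res$mae
    r2[it] <- res$r2
  }
  if (n_failed > 0.1 * spec$n_iterations)
    stop("more than 10% of attribution iterations failed; first error: ",
         failures[1])

  qs <- apply(samples, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  means <- colMeans(samples, na.rm = TRUE)

  coef_names <- colnames(x)
  if (!is.null(inventory)) {
    pct_change <- colMeans(x) * 100
    area_pct <- inventory$area_pct[match(coef_names, inventory$name)]
    occupancy_pct <- inventory$occupancy_pct[match(coef_names,
                                                   inventory$name)]
  } else {
    pct_change <- colMeans(x) * 100
    area_pct <- colMeans(abs(x)) * 100
    occupancy_pct <- colMeans(x != 0) * 100
  }
  tab <- data.frame(
    name = coef_names,
    mean = means[-1],
    lower = qs[1, -1],
    upper = qs[2, -1],
    pct_change = pct_change,
    contribution = means[-1] * pct_change / 100,
    area_pct = area_pct,
    occupancy_pct = occupancy_pct,
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(
    table = tab,
    intercept = c(mean = unname(means[1]), lower = qs[1, 1], upper = qs[2, 1]),
    samples = samples,
    test_error = c(mae = mean(mae, na.rm = TRUE), r2 = mean(r2, na.rm = TRUE)),
    n_failed = n_failed
  ), class = "attribution_result")
}

#' Filter attribution results to robustly sampled transitions
#'
#' Only transition types occurring on more than \code{area_threshold} percent
#' of the regional area and in more than \code{occupancy_threshold} percent of
#' grid cells are retained for reporting; the full result is kept unchanged.
#'
#' @param result An \code{attribution_result}.
#' @param area_threshold Gross-area threshold in percent (default 0.2).
#' @param occupancy_threshold Cell-occupancy threshold in percent (default 20).
#' @return The filtered reporting table (data frame).
#' @export
filter_reported_transitions <- function(result, area_threshold = 0.2,
                                        occupancy_threshold = 20) {
  stopifnot(inherits(result, "attribution_result"))
  tab <- result$table
  keep <- tab$area_pct > area_threshold &
    tab$occupancy_pct > occupancy_threshold
  tab[keep, , drop = FALSE]
}
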