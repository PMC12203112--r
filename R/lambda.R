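#' Select the balancing factor by sensitivity analysis
#'
#' Solves the community LP at every grid value of lambda (averaging the
#' objective over samples when several are supplied), min-max normalizes both
#' the grid and the objective curve to `[0, 1]`, and returns the grid point
#' maximizing the discrete second difference (curvature) of the normalized
#' curve - the transition (inflection) point where growth maximization and
#' relaxation penalty balance. Ties go to the smallest lambda. The objective
#' is piecewise linear, convex and non-increasing in lambda; a violation of
#' monotonicity beyond tolerance raises a warning, and a flat curve returns
#' the smallest grid value with a warning.
#'
#' @param model A `community_model` in irreversible form.
#' @param factors Correction factors ([correction_factors()]); may contain
#'   several samples.
#' @param config An [imic_config()]; `config$lambda_grid` (>= 3 points) is the
#'   grid scanned.
#' @return A `lambda_scan`: list with `path` (tibble: `lambda`, `z`, `sum_mu`,
#'   `sum_beta`, `curvature`, `selected`), `selected` (the chosen lambda) and
#'   `method = "sensitivity"`.
#' @export
select_lambda_sensitivity <- function(model, factors, config = imic_config()) {
  grid <- config$lambda_grid
  if (length(grid) < 3L) stop("need at least 3 grid points", call. = FALSE)
  samples <- unique(factors$sample_id)

  rec <- purrr::map(grid, function(l) {
    fits <- purrr::map(samples, function(s) {
      solve_imic(model, factors[factors$sample_id == s, ], l, config)
    })
    tibble::tibble(lambda = l,
                   z = mean(purrr::map_dbl(fits, "z")),
                   sum_mu = mean(purrr::map_dbl(fits, "sum_mu")),
                   sum_beta = mean(purrr::map_dbl(fits, "sum_beta")))
  })
  path <- dplyr::bind_rows(rec)

  tol <- config$tol * max(1, max(abs(path$z)))
  if (any(diff(path$z) > tol)) {
    warning("objective is not non-increasing along the lambda grid; ",
            "check solver tolerances")
  }

  kink <- select_kink(grid, path$z, tol = config$tol)
  if (kink$flat) {
    warning("objective curve is flat over the lambda grid; ",
            "returning the smallest grid value")
  }
  selected <- kink$selected
  path$curvature <- kink$curvature
  path$selected <- path$lambda == selected
  structure(list(path = path, selected = selected, method = "sensitivity"),
            class = "lambda_scan")
}

# Transition-point detector: min-max normalize both axes and take the grid
# point with the largest discrete second difference (curvature) of the
# normalized curve; ties break toward the smaller lambda. A flat curve (range
# below tolerance) selects the smallest grid value.
select_kink <- function(grid, z, tol = 1e-9) {
  rng <- max(z) - min(z)
  if (rng <= max(tol, 1e-7 * max(1, abs(max(z))))) {
    return(list(selected = grid[1], curvature = rep(NA_real_, length(grid)),
                flat = TRUE))
  }
  ln <- (grid - min(grid)) / (max(grid) - min(grid))
  zn <- (z - min(z)) / rng
  curv <- rep(NA_real_, length(grid))
  for (k in 2:(length(grid) - 1L)) {
    curv[k] <- (zn[k + 1] - zn[k]) / (ln[k + 1] - ln[k]) -
               (zn[k] - zn[k - 1]) / (ln[k] - ln[k - 1])
  }
  list(selected = grid[which.max(curv)], curvature = curv, flat = FALSE)
}

#' Select the balancing factor by cross-validation against abundances
#'
#' Samples are randomly partitioned into `k` folds. For every fold and every
#' grid lambda, the mean Spearman correlation between the predicted member
#' growth rates and the members' relative abundance is evaluated on the
#' fold's held-out samples; the fold's best lambda is the correlation argmax
#' (ties toward the smaller value). The returned lambda is the average of the
#' per-fold bests. Samples with a constant abundance vector (correlation
#' undefined) are excluded with a warning.
#'
#' @inheritParams select_lambda_sensitivity
#' @param abundance Tibble with `sample_id`, `member_id`, `abundance`
#'   (relative abundance per sample).
#' @param k Number of folds (`k <=` number of usable samples).
#' @param seed Integer seed for the fold assignment (mandatory - the partition
#'   is the only stochastic step).
#' @return A `lambda_scan` with `path` (tibble: `lambda`, `mean_cor`),
#'   `fold_best` (per-fold best lambda), `selected` and
#'   `method = "cross_validation"`.
#' @export
select_lambda_cv <- function(model, factors, abundance, k, seed,
                             config = imic_config()) {
  if (missing(seed)) stop("a seed is required for the fold partition", call. = FALSE)
  grid <- config$lambda_grid
  stopifnot(all(c("sample_id", "member_id", "abundance") %in% names(abundance)))
  samples <- intersect(unique(factors$sample_id), unique(abundance$sample_id))

  usable <- character(0)
  for (s in samples) {
    ab <- abundance[abundance$sample_id == s, ]
    if (length(unique(ab$abundance)) < 2L) {
      warning("sample ", s, " has a constant abundance vector; excluded")
    } else usable <- c(usable, s)
  }
  if (k > length(usable)) {
    stop("k (", k, ") exceeds the number of usable samples (", length(usable), ")",
         call. = FALSE)
  }

  # correlation needs no training: precompute it per (sample, lambda)
  cors <- matrix(NA_real_, length(usable), length(grid),
                 dimnames = list(usable, NULL))
  for (s in usable) {
    ab <- abundance[abundance$sample_id == s, ]
    for (g in seq_along(grid)) {
      fit <- solve_imic(model, factors[factors$sample_id == s, ], grid[g], config)
      mu <- fit$growth$mu[match(ab$member_id, fit$growth$member)]
      cors[s, g] <- suppressWarnings(stats::cor(mu, ab$abundance, method = "spearman"))
    }
  }

  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = length(usable)))
  fold_best <- numeric(k)
  for (f in seq_len(k)) {
    test <- usable[fold == f]
    m <- colMeans(cors[test, , drop = FALSE], na.rm = TRUE)
    fold_best[f] <- grid[which.max(m)]
  }
  selected <- mean(fold_best)
  structure(list(
    path = tibble::tibble(lambda = grid, mean_cor = colMeans(cors, na.rm = TRUE)),
    fold_best = fold_best,
    selected = selected,
    method = "cross_validation"
  ), class = "lambda_scan")
}

#' @export
print.lambda_scan <- function(x, ...) {
  cat("<lambda_scan> method = ", x$method, ", selected lambda = ",
      format(x$selected), "\n", sep = "")
  invisible(x)
}
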