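#' Solver configuration
#'
#' @param lambda_grid Ordered grid of balancing-factor values for the
#'   sensitivity / cross-validation scans; default [default_lambda_grid()].
#' @param beta_box Box bound on each relaxation variable (default 1000).
#' @param tol Numerical tolerance used in feasibility checks and flat-curve
#'   detection.
#' @param use_beta_minus Keep the tightening relaxations beta-minus in the
#'   program (they are provably redundant at the optimum; disabling them
#'   halves the relaxation variables).
#' @param refine After the optimum z* is found, re-solve with z fixed and the
#'   total relaxation minimized, so the reported fluxes and growth rates are a
#'   deterministic, least-relaxed representative of the optimal face. z*
#'   itself always comes from the first stage.
#' @return An `imic_config` list.
#' @export
imic_config <- function(lambda_grid = default_lambda_grid(), beta_box = 1000,
                        tol = 1e-9, use_beta_minus = TRUE, refine = TRUE) {
  stopifnot(length(lambda_grid) >= 1L, all(diff(lambda_grid) > 0), all(lambda_grid > 0))
  stopifnot(beta_box > 0)
  structure(list(lambda_grid = lambda_grid, beta_box = beta_box, tol = tol,
                 use_beta_minus = use_beta_minus, refine = refine),
            class = "imic_config")
}

#' Default balancing-factor grid
#'
#' `0.1, 0.5, 1, 2, 3, ..., 50`: dense unit steps after 1, with two sub-unit
#' points to resolve the weak-penalty end of the path.
#'
#' @return Numeric vector of 52 grid values.
#' @export
default_lambda_grid <- function() c(0.1, 0.5, seq(1, 50, by = 1))

# Assemble the community LP for one sample.
#
# Variables x = [v (one per reaction column); beta_plus; beta_minus], all >= 0.
# Constraints: S v = 0; for every GPR column i of reaction r:
#   v_i - vmax_i (bp_r - bm_r) <= vmax_i * s_r        (expression-scaled bound)
#   bp_r - bm_r <= 1 - s_r;  bm_r - bp_r <= s_r       (factor box [0, 1])
# plus v <= vmax, beta <= beta_box, and v_i >= lb_i for warned forced-flux
# reactions. Objective coefficients for max sum(mu) - lambda * sum(beta) are
# returned separately so callers can swap objectives over the same polytope.
build_imic_lp <- function(model, factors, lambda, config = imic_config()) {
  stopifnot(inherits(model, "community_model"))
  if (!isTRUE(model$irreversible)) {
    stop("model must be in irreversible form; call to_irreversible()", call. = FALSE)
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop("lambda must be a single positive number", call. = FALSE)
  }
  if (length(unique(factors$sample_id)) > 1L) {
    stop("factors contain more than one sample; filter to one sample_id", call. = FALSE)
  }
  keys <- names(model$gpr)
  miss <- setdiff(keys, factors$gpr_key)
  if (length(miss)) {
    stop("correction factors missing for GPR reaction(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  s <- stats::setNames(factors$f_scaled, factors$gpr_key)[keys]
  if (any(s < -1e-12 | s > 1 + 1e-12)) stop("scaled factors outside [0, 1]", call. = FALSE)
  s <- pmin(pmax(s, 0), 1)

  n <- nrow(model$rxns)
  nb <- length(keys)
  nv <- n + 2L * nb
  vmax <- ifelse(is.finite(model$rxns$ub), model$rxns$ub, 1000)

  A_eq <- cbind(as.matrix(model$S), matrix(0, nrow(model$S), 2L * nb))
  b_eq <- rep(0, nrow(A_eq))

  gcols <- which(!is.na(model$rxns$gpr_key))
  tidx <- match(model$rxns$gpr_key[gcols], keys)
  n_le <- length(gcols) + 2L * nb
  A_le <- matrix(0, n_le, nv)
  b_le <- numeric(n_le)
  for (q in seq_along(gcols)) {
    j <- gcols[q]; t <- tidx[q]
    A_le[q, j] <- 1
    A_le[q, n + t] <- -vmax[j]
    A_le[q, n + nb + t] <- vmax[j]
    b_le[q] <- vmax[j] * s[t]
  }
  for (t in seq_len(nb)) {
    r1 <- length(gcols) + 2L * (t - 1L) + 1L
    A_le[r1, n + t] <- 1; A_le[r1, n + nb + t] <- -1; b_le[r1] <- 1 - s[t]
    A_le[r1 + 1L, n + nb + t] <- 1; A_le[r1 + 1L, n + t] <- -1; b_le[r1 + 1L] <- s[t]
  }
  forced <- which(model$rxns$lb > 0)
  if (length(forced)) {
    Fm <- matrix(0, length(forced), nv)
    Fm[cbind(seq_along(forced), forced)] <- -1
    A_le <- rbind(A_le, Fm)
    b_le <- c(b_le, -model$rxns$lb[forced])
  }

  ub <- c(vmax, rep(config$beta_box, nb),
          rep(if (config$use_beta_minus) config$beta_box else 0, nb))

  obj <- numeric(nv)
  bcols <- match(model$biomass, model$rxns$col)
  obj[bcols] <- 1
  obj[(n + 1L):nv] <- -lambda

  list(obj = obj, A_eq = A_eq, b_eq = b_eq, A_le = A_le, b_le = b_le, ub = ub,
       n = n, nb = nb, keys = keys, s = s, bcols = bcols)
}

#' Solve the community growth-relaxation linear program
#'
#' Maximizes the sum of member growth rates minus `lambda` times the total
#' relaxation of the expression-derived flux bounds:
#' `max sum_j mu_j - lambda * sum(beta+ + beta-)` subject to steady state
#' `S v = 0`, `0 <= v_i <= vmax_i (f_i/M + beta+_i - beta-_i)` for GPR-bearing
#' reactions, the factor box `0 <= f/M + beta+ - beta- <= 1`, plain bounds
#' `0 <= v <= vmax`, and `0 <= beta <= beta_box`. Forward/reverse columns of a
#' split reversible reaction share one pair of relaxation variables. With
#' `config$refine = TRUE` (default) a second stage re-solves with the optimum
#' fixed and total relaxation minimized, making the reported solution a
#' deterministic least-relaxed point of the optimal face.
#'
#' @param model A `community_model` in irreversible form.
#' @param factors One sample of correction factors from
#'   [correction_factors()].
#' @param lambda Balancing factor (> 0) trading growth against relaxation.
#' @param config An [imic_config()].
#' @return An `imic_fit`: list with `sample_id`, `lambda`, objective `z`,
#'   `status`, `growth` (tibble: `member`, `mu`), `fluxes` (tibble per column
#'   with `flux`), `net` (tibble of net fluxes per original reaction), `beta`
#'   (tibble per GPR reaction: `beta_plus`, `beta_minus`), `sum_mu`,
#'   `sum_beta`.
#' @seealso [growth_variability()], [select_lambda_sensitivity()]
#' @export
solve_imic <- function(model, factors, lambda, config = imic_config()) {
  lp <- build_imic_lp(model, factors, lambda, config)
  st1 <- lp_solve(lp$obj, lp$A_eq, lp$b_eq, lp$A_le, lp$b_le, lp$ub, maximize = TRUE)
  if (st1$status != "optimal") {
    stop("IMIC LP did not solve to optimality (status: ", st1$status,
         if (!is.null(st1$message)) paste0("; ", st1$message) else "", ")", call. = FALSE)
  }
  z <- st1$value
  x <- st1$x

  if (isTRUE(config$refine)) {
    eps <- 1e-9 * max(1, abs(z))
    zrow <- matrix(lp$obj, 1)
    A_le2 <- rbind(lp$A_le, zrow, -zrow)
    b_le2 <- c(lp$b_le, z + eps, -(z - eps))
    obj2 <- c(rep(0, lp$n), rep(1, 2L * lp$nb))
    st2 <- lp_solve(obj2, lp$A_eq, lp$b_eq, A_le2, b_le2, lp$ub, maximize = FALSE)
    if (st2$status == "optimal") x <- st2$x
  }

  v <- stats::setNames(x[seq_len(lp$n)], model$rxns$col)
  bp <- x[lp$n + seq_len(lp$nb)]
  bm <- x[lp$n + lp$nb + seq_len(lp$nb)]
  fit <- structure(list(
    sample_id = if (nrow(factors)) factors$sample_id[1] else NA_character_,
    lambda = lambda,
    z = z,
    status = "optimal",
    growth = tibble::tibble(member = names(model$biomass),
                            mu = as.numeric(v[model$biomass])),
    fluxes = dplyr::mutate(model$rxns[, c("col", "member", "orig_id", "direction")],
                           flux = as.numeric(v)),
    net = net_fluxes(model, v),
    beta = tibble::tibble(gpr_key = lp$keys,
                          member_id = sub("::.*$", "", lp$keys),
                          reaction_id = sub("^[^:]*::", "", lp$keys),
                          beta_plus = bp, beta_minus = bm),
    sum_mu = sum(as.numeric(v[model$biomass])),
    sum_beta = sum(bp) + sum(bm)
  ), class = "imic_fit")
  fit
}

#' @export
print.imic_fit <- function(x, ...) {
  cat("<imic_fit> sample ", x$sample_id, ", lambda = ", format(x$lambda),
      ", z* = ", format(x$z, digits = 6), "\n", sep = "")
  cat("  growth rates (1/h):\n")
  print(x$growth, n = 10)
  invisible(x)
}

#' Growth-rate variability at the fixed community optimum
#'
#' For each member, maximizes and minimizes its growth rate over the IMIC
#' constraint set with the objective pinned to the previously computed optimum
#' (`z* - eps <= sum(mu) - lambda sum(beta) <= z*`, relative
#' `eps = 1e-6 * max(1, |z*|)`; an exact equality is numerically brittle).
#' The relative variability `(mu_max - mu_min) / mu_max` (0 when `mu_max` is
#' 0) measures how precisely the optimum determines each growth rate.
#'
#' @inheritParams solve_imic
#' @param z Objective value from a prior [solve_imic()] with the same
#'   `factors` and `lambda`.
#' @return Tibble with `member`, `mu_min`, `mu_max`, `rel_var`.
#' @export
growth_variability <- function(model, factors, lambda, z, config = imic_config()) {
  lp <- build_imic_lp(model, factors, lambda, config)
  eps <- 1e-6 * max(1, abs(z))
  zrow <- matrix(lp$obj, 1)
  A_le <- rbind(lp$A_le, zrow, -zrow)
  b_le <- c(lp$b_le, z, -(z - eps))

  out <- vector("list", length(lp$bcols))
  for (q in seq_along(lp$bcols)) {
    obj <- numeric(length(lp$obj)); obj[lp$bcols[q]] <- 1
    hi <- lp_solve(obj, lp$A_eq, lp$b_eq, A_le, b_le, lp$ub, maximize = TRUE)
    lo <- lp_solve(obj, lp$A_eq, lp$b_eq, A_le, b_le, lp$ub, maximize = FALSE)
    if (hi$status != "optimal" || lo$status != "optimal") {
      stop("variability LP not optimal (status ", hi$status, "/", lo$status,
           "); the fixed objective may be stale - re-run solve_imic()", call. = FALSE)
    }
    mu_max <- hi$value; mu_min <- lo$value
    out[[q]] <- tibble::tibble(
      member = names(model$biomass)[q],
      mu_min = mu_min, mu_max = mu_max,
      rel_var = if (mu_max <= config$tol) 0 else (mu_max - mu_min) / mu_max
    )
  }
  dplyr::bind_rows(out)
}
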