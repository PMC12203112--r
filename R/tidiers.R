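#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a community LP solution
#'
#' @param x An `imic_fit` from [solve_imic()].
#' @param ... Unused.
#' @return Tibble with one row per member: `sample_id`, `member`, `mu`.
#' @method tidy imic_fit
#' @export
tidy.imic_fit <- function(x, ...) {
  dplyr::mutate(x$growth, sample_id = x$sample_id, .before = 1)
}

#' One-row summary of a community LP solution
#'
#' @param x An `imic_fit`.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `lambda`, `z`, `sum_mu`, `sum_beta`,
#'   `n_members`, `status`.
#' @method glance imic_fit
#' @export
glance.imic_fit <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_id, lambda = x$lambda, z = x$z,
                 sum_mu = x$sum_mu, sum_beta = x$sum_beta,
                 n_members = nrow(x$growth), status = x$status)
}

#' @rdname tidy.imic_fit
#' @param x A `lambda_scan`.
#' @method tidy lambda_scan
#' @export
tidy.lambda_scan <- function(x, ...) x$path

#' @rdname glance.imic_fit
#' @method glance lambda_scan
#' @export
glance.lambda_scan <- function(x, ...) {
  tibble::tibble(method = x$method, selected = x$selected,
                 n_grid = nrow(x$path))
}

#' Growth-rate table across samples
#'
#' Convenience assembler: runs [solve_imic()] (and optionally
#' [growth_variability()]) per sample and binds the tidy results.
#'
#' @inheritParams solve_imic
#' @param variability Also compute per-member growth-rate ranges.
#' @return Tibble with `sample_id`, `member`, `mu` and, when requested,
#'   `mu_min`, `mu_max`, `rel_var`.
#' @export
growth_table <- function(model, factors, lambda, variability = FALSE,
                         config = imic_config()) {
  out <- list()
  for (s in unique(factors$sample_id)) {
    fs <- factors[factors$sample_id == s, ]
    fit <- solve_imic(model, fs, lambda, config)
    g <- tidy(fit)
    if (variability) {
      vv <- growth_variability(model, fs, lambda, fit$z, config)
      g <- dplyr::left_join(g, vv, by = "member")
    }
    out[[s]] <- g
  }
  dplyr::bind_rows(out)
}

#' Net-flux table across samples
#'
#' @inheritParams growth_table
#' @param reactions Optional subset of original reaction ids to keep.
#' @return Tibble with `sample_id`, `member_id`, `reaction_id`, `net_flux`.
#' @export
flux_table <- function(model, factors, lambda, reactions = NULL,
                       config = imic_config()) {
  out <- list()
  for (s in unique(factors$sample_id)) {
    fit <- solve_imic(model, factors[factors$sample_id == s, ], lambda, config)
    net <- dplyr::rename(fit$net, member_id = "member", reaction_id = "orig_id")
    net$sample_id <- s
    out[[s]] <- net[, c("sample_id", "member_id", "reaction_id", "net_flux")]
  }
  res <- dplyr::bind_rows(out)
  if (!is.null(reactions)) res <- res[res$reaction_id %in% reactions, ]
  res
}
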