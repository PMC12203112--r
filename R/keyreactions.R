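#' Reactions common to all community members
#'
#' @param model A `community_model`.
#' @param require_gpr Keep only reactions carrying a GPR rule in every member.
#' @return Sorted character vector of original reaction ids present in every
#'   member (community-level exchange reactions are not member reactions and
#'   are excluded).
#' @export
common_reactions <- function(model, require_gpr = FALSE) {
  stopifnot(inherits(model, "community_model"))
  rx <- model$rxns[!model$rxns$member %in% "community", ]
  rx <- rx[!duplicated(paste(rx$member, rx$orig_id)), ]
  tab <- dplyr::summarise(dplyr::group_by(rx, .data$orig_id),
                          n = dplyr::n_distinct(.data$member),
                          all_gpr = all(!is.na(.data$gpr_key)),
                          .groups = "drop")
  keep <- tab$n == length(model$members) & (!require_gpr | tab$all_gpr)
  sort(tab$orig_id[keep])
}

#' Identify key reactions by flux-abundance correlation
#'
#' For each common reaction and each sample, computes the Spearman correlation
#' across members between the reaction's net flux and the members' relative
#' abundance, corrects p-values per sample with the Benjamini-Hochberg
#' procedure, and flags a reaction as key when it passes both cutoffs
#' (`rho > rho_min` and adjusted p `< alpha`) in more than
#' `min_sample_fraction` of the samples in which it was testable.
#'
#' @param flux_table Tibble with `sample_id`, `member_id`, `reaction_id`,
#'   `net_flux` (e.g. assembled from `imic_fit$net` over samples).
#' @param abundance_table Tibble with `sample_id`, `member_id`, `abundance`;
#'   abundances should sum to 1 within each sample.
#' @param rho_min Correlation cutoff (default 0.7).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param min_sample_fraction A reaction is key when the fraction of samples
#'   passing exceeds this value (default 0.5, a strict majority).
#' @return Tibble with one row per (sample, reaction): `sample_id`,
#'   `reaction_id`, `rho`, `p`, `p_adj`, `pass`, plus the per-reaction `key`
#'   flag (constant across samples). Reactions with a constant flux vector in
#'   a sample are skipped for that sample with a note in the `note` column.
#' @export
key_reactions <- function(flux_table, abundance_table, rho_min = 0.7,
                          alpha = 0.05, min_sample_fraction = 0.5) {
  stopifnot(all(c("sample_id", "member_id", "reaction_id", "net_flux") %in% names(flux_table)))
  stopifnot(all(c("sample_id", "member_id", "abundance") %in% names(abundance_table)))
  sums <- tapply(abundance_table$abundance, abundance_table$sample_id, sum)
  if (any(abs(sums - 1) > 1e-6)) {
    warning("abundances do not sum to 1 in sample(s): ",
            paste(names(sums)[abs(sums - 1) > 1e-6], collapse = ", "))
  }

  joined <- dplyr::inner_join(flux_table, abundance_table,
                              by = c("sample_id", "member_id"))
  out <- list()
  for (s in unique(joined$sample_id)) {
    ds <- joined[joined$sample_id == s, ]
    rows <- list()
    for (r in unique(ds$reaction_id)) {
      dr <- ds[ds$reaction_id == r, ]
      n <- nrow(dr)
      if (n < 4L) {
        warning("reaction ", r, " in sample ", s, " has only ", n,
                " members; skipped (Spearman p-values are degenerate below 4)")
        rows[[r]] <- tibble::tibble(sample_id = s, reaction_id = r,
                                    rho = NA_real_, p = NA_real_,
                                    note = "too_few_members")
        next
      }
      if (length(unique(dr$net_flux)) < 2L || length(unique(dr$abundance)) < 2L) {
        rows[[r]] <- tibble::tibble(sample_id = s, reaction_id = r,
                                    rho = NA_real_, p = NA_real_,
                                    note = "constant_values")
        next
      }
      ct <- suppressWarnings(stats::cor.test(dr$net_flux, dr$abundance,
                                             method = "spearman"))
      rows[[r]] <- tibble::tibble(sample_id = s, reaction_id = r,
                                  rho = unname(ct$estimate), p = ct$p.value,
                                  note = NA_character_)
    }
    d <- dplyr::bind_rows(rows)
    d$p_adj <- NA_real_
    ok <- !is.na(d$p)
    d$p_adj[ok] <- stats::p.adjust(d$p[ok], method = "BH")
    out[[s]] <- d
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble::tibble(sample_id = character(0), reaction_id = character(0),
                          rho = numeric(0), p = numeric(0), p_adj = numeric(0),
                          pass = logical(0), key = logical(0),
                          note = character(0)))
  }
  res$pass <- !is.na(res$rho) & res$rho > rho_min & !is.na(res$p_adj) & res$p_adj < alpha
  keyflag <- dplyr::summarise(dplyr::group_by(res, .data$reaction_id),
    key = {
      tested <- sum(is.na(.data$note))
      tested > 0L && sum(.data$pass) / tested > min_sample_fraction
    }, .groups = "drop")
  res <- dplyr::left_join(res, keyflag, by = "reaction_id")
  res[, c("sample_id", "reaction_id", "rho", "p", "p_adj", "pass", "key", "note")]
}

#' Re-evaluate community growth after single-reaction knockouts
#'
#' For each reaction id, sets the upper bound of every matching column
#' (forward and reverse, in every member) to zero, re-solves the community LP
#' at the same lambda and records the knockout objective and community growth.
#' The model itself is never mutated, so the baseline is identical between
#' knockouts.
#'
#' @inheritParams solve_imic
#' @param reaction_ids Original reaction ids to knock out (key reactions are
#'   by construction common to all members, so knockouts are community-wide).
#' @return Tibble with `reaction_id`, `z_ko`, `sum_mu_ko`, `delta_sum_mu`
#'   (knockout minus baseline community growth) and `status`; unknown ids get
#'   `status = "unknown_reaction"` and the scan continues.
#' @export
knockout_scan <- function(model, reaction_ids, factors, lambda,
                          config = imic_config()) {
  base <- solve_imic(model, factors, lambda, config)
  out <- vector("list", length(reaction_ids))
  for (q in seq_along(reaction_ids)) {
    rid <- reaction_ids[q]
    hit <- which(model$rxns$orig_id == rid)
    if (length(hit) == 0L) {
      out[[q]] <- tibble::tibble(reaction_id = rid, z_ko = NA_real_,
                                 sum_mu_ko = NA_real_, delta_sum_mu = NA_real_,
                                 status = "unknown_reaction")
      next
    }
    ko <- model
    ko$rxns$ub[hit] <- 0
    ko$rxns$lb[hit] <- 0
    fit <- solve_imic(ko, factors, lambda, config)
    out[[q]] <- tibble::tibble(reaction_id = rid, z_ko = fit$z,
                               sum_mu_ko = fit$sum_mu,
                               delta_sum_mu = fit$sum_mu - base$sum_mu,
                               status = "ok")
  }
  dplyr::bind_rows(out)
}
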