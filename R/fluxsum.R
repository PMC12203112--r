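#' Minimum flux sum of a metabolite at the community optimum
#'
#' The flux sum of metabolite m, `Phi_m = 0.5 * sum_i |S_mi| v_i`, is the
#' total turnover (production equals consumption at steady state) and serves
#' as a proxy for the metabolite's availability. This function minimizes
#' Phi_m over the IMIC-feasible set with the objective held near its optimum
#' (`sum(mu) - lambda sum(beta) >= z - eps`, relative
#' `eps = 1e-6 * max(1, |z|)`). In the irreversible model all fluxes are
#' nonnegative, so the objective is linear.
#'
#' @inheritParams growth_variability
#' @param metabolite Row identifier of the metabolite in the community model
#'   (for extracellular species, the original id; for intracellular ones,
#'   `member::id`).
#' @return Minimum flux sum (mmol/gDW/h), a single nonnegative number.
#' @export
min_flux_sum <- function(model, factors, lambda, z, metabolite,
                         config = imic_config()) {
  stopifnot(inherits(model, "community_model"))
  row <- match(metabolite, model$mets$row)
  if (is.na(row)) stop("unknown metabolite: ", metabolite, call. = FALSE)
  w <- abs(as.numeric(model$S[row, ]))
  if (all(w == 0)) {
    warning("metabolite ", metabolite, " has no incident reactions; flux sum is 0")
    return(0)
  }
  lp <- build_imic_lp(model, factors, lambda, config)
  eps <- 1e-6 * max(1, abs(z))
  A_le <- rbind(lp$A_le, -matrix(lp$obj, 1))
  b_le <- c(lp$b_le, -(z - eps))
  obj <- c(0.5 * w, rep(0, 2L * lp$nb))
  res <- lp_solve(obj, lp$A_eq, lp$b_eq, A_le, b_le, lp$ub, maximize = FALSE)
  if (res$status != "optimal") {
    stop("flux-sum LP not optimal (status ", res$status, ")", call. = FALSE)
  }
  max(res$value, 0)
}

#' Essential imported metabolites across samples
#'
#' For each candidate metabolite and each sample, solves the community LP,
#' computes the minimum flux sum at the optimum and flags the metabolite
#' essential when it exceeds `threshold` (default 1e-5): community growth at
#' the optimum is then impossible without turnover of that metabolite. Across
#' samples each metabolite is classified `time_independent` (essential in
#' every sample), `time_dependent` (essential in at least one but not all) or
#' `never_essential`.
#'
#' @inheritParams solve_imic
#' @param factors Correction factors for one or more samples.
#' @param threshold Flux-sum essentiality threshold.
#' @param candidates Either `"common_imports"` - extracellular species
#'   consumed by an import reaction (extracellular -> member compartment)
#'   whose original id is shared by every member - or `"extracellular"` - all
#'   extracellular species.
#' @return Tibble with `sample_id`, `metabolite`, `phi_min`, `essential`,
#'   `class`, ranked by `phi_min` (descending) within sample so top-k
#'   selections read off the head.
#' @export
essential_imports <- function(model, factors, lambda, threshold = 1e-5,
                              candidates = c("common_imports", "extracellular"),
                              config = imic_config()) {
  candidates <- match.arg(candidates)
  mets <- candidate_import_metabolites(model, candidates)
  if (length(mets) == 0L) {
    warning("no candidate metabolites (no common import reactions)")
    return(tibble::tibble(sample_id = character(0), metabolite = character(0),
                          phi_min = numeric(0), essential = logical(0),
                          class = character(0)))
  }
  out <- list()
  for (s in unique(factors$sample_id)) {
    fs <- factors[factors$sample_id == s, ]
    fit <- solve_imic(model, fs, lambda, config)
    phi <- vapply(mets, function(m) {
      min_flux_sum(model, fs, lambda, fit$z, m, config)
    }, numeric(1))
    out[[s]] <- tibble::tibble(sample_id = s, metabolite = mets, phi_min = phi,
                               essential = phi > threshold)
  }
  res <- dplyr::bind_rows(out)
  cls <- dplyr::summarise(dplyr::group_by(res, .data$metabolite),
    class = if (all(.data$essential)) "time_independent"
            else if (any(.data$essential)) "time_dependent"
            else "never_essential",
    .groups = "drop")
  res <- dplyr::left_join(res, cls, by = "metabolite")
  dplyr::arrange(res, .data$sample_id, dplyr::desc(.data$phi_min))
}

# Extracellular species consumed by member transport reactions; with
# scope = "common_imports", only those whose importing reaction id is common
# to all members.
candidate_import_metabolites <- function(model, scope) {
  ext_rows <- which(model$mets$scope == "extracellular")
  if (scope == "extracellular") return(model$mets$row[ext_rows])
  member_cols <- which(!model$rxns$member %in% "community")
  imports <- list()
  for (j in member_cols) {
    colv <- model$S[, j]
    consumed <- intersect(which(colv < 0), ext_rows)
    produced_inside <- any(colv > 0 & model$mets$scope != "extracellular")
    if (length(consumed) && produced_inside) {
      imports[[length(imports) + 1L]] <- tibble::tibble(
        member = model$rxns$member[j],
        orig_id = model$rxns$orig_id[j],
        metabolite = model$mets$row[consumed])
    }
  }
  if (length(imports) == 0L) return(character(0))
  imp <- dplyr::bind_rows(imports)
  common <- dplyr::summarise(dplyr::group_by(imp, .data$orig_id),
                             n_members = dplyr::n_distinct(.data$member),
                             .groups = "drop")
  common <- common$orig_id[common$n_members == length(model$members)]
  unique(imp$metabolite[imp$orig_id %in% common])
}
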