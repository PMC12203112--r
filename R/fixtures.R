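#' Specification of a synthetic toy community
#'
#' Defines a deterministic cross-feeding community with known ground truth.
#' Every member runs a linear pathway - substrate import, `pathway_depth`
#' conversion steps, biomass - in which each reaction carries a unique gene.
#' Conversion step 1 additionally secretes a byproduct (yield 0.5) that the
#' next member must import (0.1 per unit biomass); member 1 analogously
#' requires an externally supplied cofactor, so every member's pathway has the
#' same number of GPR-bearing reactions. GPR-bearing reactions share one
#' upper bound `vmax_gpr`; exchanges supply substrate and cofactor generously
#' so growth is limited by expression-scaled bounds, not by the medium.
#'
#' @param n_members Number of members (>= 1).
#' @param designed_activity Positive per-member growth propensity; gene
#'   expression scales with it (default `1:n_members`).
#' @param n_shared_metabolites Shared medium species: substrate, cofactor and
#'   `n_shared_metabolites - 2` unused components (default 3).
#' @param pathway_depth Conversion steps per member (default 3).
#' @param expression_sparsity Fraction of gene entries zeroed in generated
#'   expression (default 0.2).
#' @param noise_sd Standard deviation of multiplicative lognormal expression
#'   noise (default 0.1).
#' @param seed Integer seed; the same seed reproduces fixtures bit for bit.
#' @param vmax_gpr Upper bound of GPR-bearing reactions (default 40).
#' @param uptake Medium supply bound on substrate/cofactor exchanges
#'   (default 1000).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_members = 4, designed_activity = seq_len(n_members),
                         n_shared_metabolites = 3, pathway_depth = 3,
                         expression_sparsity = 0.2, noise_sd = 0.1, seed = 1,
                         vmax_gpr = 40, uptake = 1000) {
  stopifnot(n_members >= 1, length(designed_activity) == n_members,
            all(designed_activity > 0), pathway_depth >= 1,
            expression_sparsity >= 0, expression_sparsity < 1,
            noise_sd >= 0, n_shared_metabolites >= 2, vmax_gpr > 0, uptake > 0)
  structure(list(n_members = n_members, designed_activity = designed_activity,
                 n_shared_metabolites = n_shared_metabolites,
                 pathway_depth = pathway_depth,
                 expression_sparsity = expression_sparsity,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 vmax_gpr = vmax_gpr, uptake = uptake),
            class = "fixture_spec")
}

#' Build the toy cross-feeding community
#'
#' @param spec A [fixture_spec()].
#' @return List with `model` (irreversible `community_model`), `members`
#'   (list of `member_model`, usable for SBML round trips), `genes` (tibble:
#'   `member_id`, `gene_id`, `reaction_id`, `weight` - the pathway-position
#'   weight used by [make_expression()]), `truth` (tibble: `member`,
#'   `activity`, `iso_max_growth` - the analytic maximum growth of the member
#'   alone in the medium) and `spec`.
#' @export
make_toy_community <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_members; d <- spec$pathway_depth
  vg <- spec$vmax_gpr; up <- spec$uptake
  members <- vector("list", n)
  genes <- list()

  for (j in seq_len(n)) {
    mid <- paste0("m", j)
    aux_ext <- if (j == 1) "cof_e" else paste0("byp", j - 1, "_e")
    mets <- tibble::tibble(
      id = c("sub_e", aux_ext, paste0("byp", j, "_e"),
             paste0("A", 0:d), "B"),
      compartment = c("e", "e", "e", rep("c", d + 2))
    )
    if (j == 1 && spec$n_shared_metabolites > 2) {
      extra <- paste0("med", seq_len(spec$n_shared_metabolites - 2), "_e")
      mets <- dplyr::bind_rows(mets, tibble::tibble(id = extra, compartment = "e"))
    }

    rid <- character(0); lb <- ub <- numeric(0); st <- list(); gp <- list()
    add <- function(id, coef, lo, hi, gene = NULL) {
      rid <<- c(rid, id); lb <<- c(lb, lo); ub <<- c(ub, hi)
      st[[id]] <<- coef
      if (!is.null(gene)) gp[[id]] <<- gpr_gene(gene)
    }
    gT <- paste0("gT_", mid); gAux <- paste0("gB_", mid)
    gC <- paste0("gC", seq_len(d), "_", mid)
    add("TS", c(sub_e = -1, A0 = 1), 0, vg, gT)
    c1 <- c(A0 = -1, A1 = 1, 0.5); names(c1)[3] <- paste0("byp", j, "_e")
    add("C1", c1, 0, vg, gC[1])
    if (d >= 2) for (k in 2:d) {
      coef <- c(-1, 1); names(coef) <- paste0("A", c(k - 1, k))
      add(paste0("C", k), coef, 0, vg, gC[k])
    }
    aux_coef <- c(-1, 1); names(aux_coef) <- c(aux_ext, "B")
    add("TAUX", aux_coef, 0, vg, gAux)
    bio <- c(-1, -0.1); names(bio) <- c(paste0("A", d), "B")
    add("biomass", bio, 0, 1000)
    add("EX_sub", c(sub_e = -1), -up, 0)
    if (j == 1) add("EX_cof", c(cof_e = -1), -up, 0)
    ex_byp <- -1; names(ex_byp) <- paste0("byp", j, "_e")
    add(paste0("EX_byp", j), ex_byp, 0, 1000)
    if (j == 1 && spec$n_shared_metabolites > 2) {
      for (e in paste0("med", seq_len(spec$n_shared_metabolites - 2), "_e")) {
        coef <- -1; names(coef) <- e
        add(paste0("EX_", sub("_e$", "", e)), coef, -up, 0)
      }
    }

    S <- Matrix::sparseMatrix(
      i = match(unlist(lapply(st, names), use.names = FALSE), mets$id),
      j = rep(seq_along(rid), lengths(st)),
      x = unlist(st, use.names = FALSE),
      dims = c(nrow(mets), length(rid)), dimnames = list(mets$id, rid))
    members[[j]] <- structure(list(
      member_id = mid, mets = mets,
      rxns = tibble::tibble(id = rid, lb = lb, ub = ub,
                            gpr = vapply(rid, function(r) {
                              if (is.null(gp[[r]])) NA_character_ else deparse_gpr(gp[[r]])
                            }, character(1))),
      S = S, gpr = gp, biomass_reaction_id = "biomass"
    ), class = "member_model")

    genes[[j]] <- tibble::tibble(
      member_id = mid,
      gene_id = c(gT, gC, gAux),
      reaction_id = c("TS", paste0("C", seq_len(d)), "TAUX"),
      weight = c(1, 0.85^seq_len(d), 0.9)
    )
  }

  model <- to_irreversible(build_community(members, extracellular = "e"))
  truth <- tibble::tibble(
    member = paste0("m", seq_len(n)),
    activity = spec$designed_activity,
    iso_max_growth = c(min(vg, up), rep(0, n - 1))
  )
  list(model = model, members = members,
       genes = dplyr::bind_rows(genes), truth = truth, spec = spec)
}

#' Generate expression profiles for a toy community
#'
#' Gene TPM is `activity(member) * weight(gene) * lognormal(0, noise_sd)`;
#' a fraction `expression_sparsity` of gene entries (rounded) is then set to
#' exactly zero, and the sample is renormalized to sum to 1e6. Each sample
#' draws fresh noise and sparsity; activities can vary across samples through
#' `activity_schedule` (emulating time points).
#'
#' @param fixture Result of [make_toy_community()].
#' @param n_samples Number of samples to generate.
#' @param activity_schedule Optional numeric matrix (`n_samples` x
#'   `n_members`) of per-sample activities; defaults to the designed
#'   activities in every sample.
#' @param seed Seed; defaults to the fixture spec's seed.
#' @return Tibble with `sample_id`, `member_id`, `gene_id`, `tpm`.
#' @export
make_expression <- function(fixture, n_samples = 1, activity_schedule = NULL,
                            seed = fixture$spec$seed) {
  spec <- fixture$spec
  genes <- fixture$genes
  if (is.null(activity_schedule)) {
    activity_schedule <- matrix(spec$designed_activity, n_samples,
                                spec$n_members, byrow = TRUE)
  }
  stopifnot(nrow(activity_schedule) == n_samples,
            ncol(activity_schedule) == spec$n_members)
  set.seed(seed)
  out <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    act <- stats::setNames(activity_schedule[s, ], paste0("m", seq_len(spec$n_members)))
    tpm <- act[genes$member_id] * genes$weight *
      exp(stats::rnorm(nrow(genes), 0, spec$noise_sd))
    nzero <- round(spec$expression_sparsity * length(tpm))
    if (nzero > 0) tpm[sample(length(tpm), nzero)] <- 0
    tot <- sum(tpm)
    if (tot > 0) tpm <- 1e6 * tpm / tot
    out[[s]] <- tibble::tibble(sample_id = paste0("s", s),
                               member_id = genes$member_id,
                               gene_id = genes$gene_id, tpm = as.numeric(tpm))
  }
  dplyr::bind_rows(out)
}

#' Plain flux balance analysis of the community
#'
#' Maximizes total community growth `sum_j mu_j` under steady state and the
#' model's flux bounds only (no expression constraints); the reference point
#' for the weak-penalty limit of the community LP.
#'
#' @param model A `community_model` in irreversible form.
#' @return List with `z` (optimal total growth) and `growth` tibble.
#' @export
community_fba <- function(model) {
  stopifnot(inherits(model, "community_model"), isTRUE(model$irreversible))
  n <- nrow(model$rxns)
  obj <- numeric(n)
  obj[match(model$biomass, model$rxns$col)] <- 1
  ub <- ifelse(is.finite(model$rxns$ub), model$rxns$ub, 1000)
  A_le <- NULL; b_le <- NULL
  forced <- which(model$rxns$lb > 0)
  if (length(forced)) {
    A_le <- matrix(0, length(forced), n)
    A_le[cbind(seq_along(forced), forced)] <- -1
    b_le <- -model$rxns$lb[forced]
  }
  res <- lp_solve(obj, as.matrix(model$S), rep(0, nrow(model$S)), A_le, b_le,
                  ub, maximize = TRUE)
  if (res$status != "optimal") stop("FBA LP not optimal: ", res$status, call. = FALSE)
  v <- stats::setNames(res$x, model$rxns$col)
  list(z = res$value,
       growth = tibble::tibble(member = names(model$biomass),
                               mu = as.numeric(v[model$biomass])))
}
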