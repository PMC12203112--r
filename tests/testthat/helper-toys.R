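# Shared toy builders for the test suite. Everything is constructed in code;
# no stored fixtures.

# A member_model built directly from parts.
new_member <- function(member_id, mets, rxns, stoich, gpr = list(),
                       biomass = "biomass") {
  S <- Matrix::sparseMatrix(
    i = match(unlist(lapply(stoich, names), use.names = FALSE), mets$id),
    j = rep(seq_along(stoich), lengths(stoich)),
    x = unlist(stoich, use.names = FALSE),
    dims = c(nrow(mets), length(stoich)),
    dimnames = list(mets$id, names(stoich)))
  structure(list(
    member_id = member_id, mets = mets,
    rxns = tibble::tibble(id = names(stoich), lb = rxns$lb, ub = rxns$ub,
                          gpr = vapply(names(stoich), function(r) {
                            if (is.null(gpr[[r]])) NA_character_
                            else imicr::deparse_gpr(gpr[[r]])
                          }, character(1))),
    S = S, gpr = gpr, biomass_reaction_id = biomass
  ), class = "member_model")
}

# Single member, single GPR reaction: uptake EX_a (10), R1 a -> b (vmax 10,
# gene g), biomass b -> 0. With f/M = 0.5 the value function has its kink at
# lambda = vmax = 10: z = 10 - lambda/2 below, 5 above.
toy_single_path <- function() {
  m <- new_member(
    "t",
    mets = tibble::tibble(id = c("a_e", "b"), compartment = c("e", "c")),
    rxns = list(lb = c(0, 0, -10), ub = c(10, 1000, 0)),
    stoich = list(R1 = c(a_e = -1, b = 1),
                  biomass = c(b = -1),
                  EX_a = c(a_e = -1)),
    gpr = list(R1 = imicr::parse_gpr("g")))
  model <- to_irreversible(build_community(list(m), "e"))
  factors <- tibble::tibble(sample_id = "s1", member_id = "t",
                            reaction_id = "R1", gpr_key = "t::R1",
                            f_raw = 1, M = 2, f_scaled = 0.5)
  list(model = model, factors = factors)
}

# Branching toy for flux-sum checks: R1 a -> b feeds both biomass and a waste
# route; at large lambda the optimum forces R1 = biomass = 5, waste = 0.
toy_branch <- function() {
  m <- new_member(
    "t",
    mets = tibble::tibble(id = c("a_e", "b", "w_e"),
                          compartment = c("e", "c", "e")),
    rxns = list(lb = c(0, 0, 0, -10, 0), ub = c(10, 1000, 10, 0, 1000)),
    stoich = list(R1 = c(a_e = -1, b = 1),
                  biomass = c(b = -1),
                  RW = c(b = -1, w_e = 1),
                  EX_a = c(a_e = -1),
                  EX_w = c(w_e = -1)),
    gpr = list(R1 = imicr::parse_gpr("g1"), RW = imicr::parse_gpr("g2")))
  model <- to_irreversible(build_community(list(m), "e"))
  factors <- tibble::tibble(sample_id = "s1", member_id = "t",
                            reaction_id = c("R1", "RW"),
                            gpr_key = c("t::R1", "t::RW"),
                            f_raw = c(1, 2), M = 2, f_scaled = c(0.5, 1))
  list(model = model, factors = factors)
}

# Uniform factors (f/M = 1) for every GPR reaction of a model.
unit_factors <- function(model, sample_id = "s1") {
  keys <- names(model$gpr)
  tibble::tibble(sample_id = sample_id,
                 member_id = sub("::.*$", "", keys),
                 reaction_id = sub("^[^:]*::", "", keys),
                 gpr_key = keys, f_raw = 1, M = 1, f_scaled = 1)
}

# Random small community (<= 8 reactions) with random bounds, GPR rules and
# factors; used by the LP-oracle equivalence checks.
random_toy <- function(seed) {
  set.seed(seed)
  n_members <- sample(1:2, 1)
  members <- lapply(seq_len(n_members), function(j) {
    mid <- paste0("r", j)
    ub_t <- round(runif(1, 4, 15), 2)
    ub_c <- round(runif(1, 4, 15), 2)
    depth2 <- runif(1) < 0.5
    mets <- tibble::tibble(id = c("s_e", "x", if (depth2) "y"),
                           compartment = c("e", "c", if (depth2) "c"))
    gpr_t <- if (runif(1) < 0.5) imicr::parse_gpr(paste0("gA_", mid, " and gB_", mid))
             else imicr::parse_gpr(paste0("gA_", mid, " or gB_", mid))
    stoich <- list(T = c(s_e = -1, x = 1))
    lb <- 0; ub <- ub_t
    gpr <- list(T = gpr_t)
    if (depth2) {
      # occasionally reversible, to exercise the fwd/rev shared relaxation
      rev <- runif(1) < 0.4
      stoich$C <- c(x = -1, y = 1)
      lb <- c(lb, if (rev) -round(runif(1, 1, 6), 2) else 0)
      ub <- c(ub, ub_c)
      gpr$C <- imicr::parse_gpr(paste0("gC_", mid))
      stoich$biomass <- c(y = -1)
    } else {
      stoich$biomass <- c(x = -1)
    }
    lb <- c(lb, 0); ub <- c(ub, 1000)
    stoich$EX_s <- c(s_e = -1)
    lb <- c(lb, -15); ub <- c(ub, 0)
    new_member(mid, mets, list(lb = lb, ub = ub), stoich, gpr)
  })
  model <- to_irreversible(build_community(members, "e"))
  keys <- names(model$gpr)
  f_raw <- round(runif(length(keys), 0.1, 4), 3)
  M <- max(f_raw)
  factors <- tibble::tibble(sample_id = "s1",
                            member_id = sub("::.*$", "", keys),
                            reaction_id = sub("^[^:]*::", "", keys),
                            gpr_key = keys, f_raw = f_raw, M = M,
                            f_scaled = f_raw / M)
  list(model = model, factors = factors)
}

quiet_factors <- function(model, expr) {
  suppressMessages(imicr::correction_factors(model, expr))
}
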