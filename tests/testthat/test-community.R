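# two members sharing three extracellular species, each declaring the same
# three exchange reactions; intracellular reaction counts 5 and 7
two_member_toy <- function() {
  mk <- function(mid, n_intra) {
    depth <- n_intra - 3           # conversion steps beyond the transporter
    ext <- c("e1_e", "e2_e", "e3_e")
    intra <- paste0("x", seq_len(depth + 1))
    mets <- tibble::tibble(id = c(ext, intra),
                           compartment = c(rep("e", 3), rep("c", depth + 1)))
    stoich <- list(T1 = c(e1_e = -1, x1 = 1))
    for (k in seq_len(depth)) {
      coef <- c(-1, 1); names(coef) <- paste0("x", c(k, k + 1))
      stoich[[paste0("C", k + 1)]] <- coef
    }
    sec <- c(-1, 1); names(sec) <- c("x1", "e2_e")
    stoich$SEC <- sec
    bio <- -1; names(bio) <- paste0("x", depth + 1)
    stoich$biomass <- bio
    stopifnot(length(stoich) == n_intra)  # n_intra member reactions
    stoich$EX_e1 <- c(e1_e = -1)
    stoich$EX_e2 <- c(e2_e = -1)
    stoich$EX_e3 <- c(e3_e = -1)
    new_member(mid, mets,
               list(lb = c(rep(0, n_intra), -10, 0, -10),
                    ub = rep(10, n_intra + 3)),
               stoich)
  }
  list(mk("A", 5), mk("B", 7))
}

test_that("community assembly counts and merges as specified", {
  members <- two_member_toy()
  cm <- build_community(members, "e")
  # 5 + 7 member reactions plus 3 deduplicated exchanges
  expect_equal(nrow(cm$rxns), 15)
  expect_equal(sum(cm$rxns$member == "community"), 3)
  # shared extracellular species collapse to single rows
  expect_equal(sum(cm$mets$orig_id == "e1_e"), 1)
  r <- match("e1_e", cm$mets$row)
  transporters <- cm$rxns$col[which(cm$S[r, ] != 0 & cm$rxns$member != "community")]
  expect_setequal(sub("::.*", "", transporters), c("A", "B"))
})

test_that("a single-member community is the member model up to namespacing", {
  m <- two_member_toy()[[1]]
  cm <- build_community(list(m), "e")
  expect_equal(nrow(cm$rxns), nrow(m$rxns))
  expect_equal(sort(cm$rxns$orig_id), sort(m$rxns$id))
  expect_equal(unname(Matrix::colSums(abs(cm$S))[order(cm$rxns$orig_id)]),
               unname(Matrix::colSums(abs(m$S))[order(m$rxns$id)]))
})

test_that("duplicate member ids are fatal", {
  m <- two_member_toy()[[1]]
  expect_error(build_community(list(m, m), "e"), "duplicate member_id")
})

test_that("assembly is invariant to member order up to permutation", {
  members <- two_member_toy()
  c1 <- build_community(members, "e")
  c2 <- build_community(rev(members), "e")
  expect_setequal(colnames(c1$S), colnames(c2$S))
  expect_setequal(rownames(c1$S), rownames(c2$S))
  expect_equal(as.matrix(c2$S)[rownames(c1$S), colnames(c1$S)],
               as.matrix(c1$S))
})

test_that("irreversible conversion splits reversible reactions", {
  m <- new_member(
    "t",
    mets = tibble::tibble(id = c("a_e", "b"), compartment = c("e", "c")),
    rxns = list(lb = c(-10, 0, 0, -8), ub = c(10, 1000, 1000, 0)),
    stoich = list(R1 = c(a_e = -1, b = 1), R2 = c(b = -1),
                  biomass = c(b = -1), EX_a = c(a_e = -1)),
    gpr = list(R1 = parse_gpr("g")))
  cm <- build_community(list(m), "e")
  ir <- to_irreversible(cm)
  # columns grow by one per reversible reaction
  expect_equal(nrow(ir$rxns), nrow(cm$rxns) + sum(cm$rxns$lb < 0 & cm$rxns$ub > 0))
  expect_true(all(ir$rxns$lb >= 0))
  r1 <- ir$rxns[ir$rxns$orig_id == "R1", ]
  expect_setequal(r1$direction, c("fwd", "rev"))
  expect_equal(sort(r1$ub), c(10, 10))
  # both split columns share the GPR
  expect_equal(unique(r1$gpr_key), "t::R1")
  # an already irreversible reaction is untouched
  expect_equal(nrow(ir$rxns[ir$rxns$orig_id == "R2", ]), 1)
  # pure-uptake exchange becomes a single reverse column
  exa <- ir$rxns[ir$rxns$orig_id == "EX_a", ]
  expect_equal(exa$direction, "rev")
  expect_equal(exa$ub, 8)
})

test_that("net fluxes reconstruct and stay feasible in the original model", {
  m <- new_member(
    "t",
    mets = tibble::tibble(id = c("a_e", "b"), compartment = c("e", "c")),
    rxns = list(lb = c(-10, 0, -8), ub = c(10, 1000, 0)),
    stoich = list(R1 = c(a_e = -1, b = 1), biomass = c(b = -1),
                  EX_a = c(a_e = -1)))
  cm <- build_community(list(m), "e")
  ir <- to_irreversible(cm)
  v <- stats::setNames(c(3, 1, 2, 0, 2), ir$rxns$col)  # fwd=3, rev=1
  net <- net_fluxes(ir, v)
  expect_equal(net$net_flux[net$orig_id == "R1"], 2)

  # random feasible points of the irreversible model map to feasible points
  # of the reversible one
  set.seed(9)
  lpu <- ifelse(is.finite(ir$rxns$ub), ir$rxns$ub, 1000)
  for (i in 1:10) {
    # sample a feasible flux by solving with a random objective
    obj <- runif(nrow(ir$rxns), -1, 1)
    sol <- imicr:::lp_solve(obj, as.matrix(ir$S), rep(0, nrow(ir$S)),
                            ub = lpu, maximize = TRUE)
    expect_equal(sol$status, "optimal")
    net <- net_fluxes(ir, stats::setNames(sol$x, ir$rxns$col))
    key <- paste(cm$rxns$member, cm$rxns$orig_id)
    vnet <- net$net_flux[match(key, paste(net$member, net$orig_id))]
    expect_true(all(vnet >= cm$rxns$lb - 1e-8))
    expect_true(all(vnet <= cm$rxns$ub + 1e-8))
    resid <- as.numeric(cm$S %*% vnet)
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("bound pathologies are handled as contracted", {
  m <- new_member(
    "t",
    mets = tibble::tibble(id = c("a_e", "b"), compartment = c("e", "c")),
    rxns = list(lb = c(2, 0, -10), ub = c(10, 1000, 0)),
    stoich = list(R1 = c(a_e = -1, b = 1), biomass = c(b = -1),
                  EX_a = c(a_e = -1)))
  cm <- build_community(list(m), "e")
  expect_warning(to_irreversible(cm), "forced-flux")

  cm2 <- cm
  cm2$rxns$lb[1] <- 20   # lb > ub
  expect_error(to_irreversible(cm2), "lower bound > upper bound")
})

test_that("medium overrides change exchange uptake bounds", {
  fx <- make_toy_community(fixture_spec(n_members = 2, seed = 1))
  med <- tibble::tibble(exchange_reaction_id = "EX_sub", max_uptake = 3)
  m2 <- apply_medium(fx$model, med)
  j <- which(m2$rxns$orig_id == "EX_sub" & m2$rxns$direction == "rev")
  expect_equal(m2$rxns$ub[j], 3)
  expect_warning(apply_medium(fx$model,
    tibble::tibble(exchange_reaction_id = "EX_nope", max_uptake = 1)),
    "no reverse")
})
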