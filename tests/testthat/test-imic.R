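test_that("the single-pathway toy solves to its hand-computed optima", {
  toy <- toy_single_path()
  # strong penalty: the expression bound holds, mu = vmax * f/M = 5
  f50 <- solve_imic(toy$model, toy$factors, lambda = 50)
  expect_equal(f50$z, 5, tolerance = 1e-8)
  expect_equal(f50$growth$mu, 5, tolerance = 1e-6)
  expect_equal(f50$sum_beta, 0, tolerance = 1e-9)

  # weak penalty: beta+ = 0.5 lifts the factor to 1, mu = 10
  f001 <- solve_imic(toy$model, toy$factors, lambda = 0.01)
  expect_equal(f001$z, 10 - 0.01 * 0.5, tolerance = 1e-8)
  expect_equal(f001$growth$mu, 10, tolerance = 1e-6)
  expect_equal(sum(f001$beta$beta_plus), 0.5, tolerance = 1e-6)
  expect_equal(sum(f001$beta$beta_minus), 0, tolerance = 1e-6)
})

test_that("solutions satisfy every constraint of the program", {
  fx <- make_toy_community(fixture_spec(seed = 4))
  cf <- quiet_factors(fx$model, make_expression(fx))
  for (lambda in c(0.5, 10, 35)) {
    fit <- solve_imic(fx$model, cf, lambda)
    v <- stats::setNames(fit$fluxes$flux, fit$fluxes$col)
    # steady state
    expect_lt(max(abs(as.numeric(fx$model$S %*% v))), 1e-6)
    # objective identity z = sum(mu) - lambda * sum(beta)
    expect_equal(fit$z, fit$sum_mu - lambda * fit$sum_beta, tolerance = 1e-6)
    # GPR-scaled bounds and factor box
    s <- stats::setNames(cf$f_scaled, cf$gpr_key)
    bp <- stats::setNames(fit$beta$beta_plus, fit$beta$gpr_key)
    bm <- stats::setNames(fit$beta$beta_minus, fit$beta$gpr_key)
    for (j in seq_len(nrow(fx$model$rxns))) {
      k <- fx$model$rxns$gpr_key[j]
      expect_gte(v[j], -1e-9)
      if (!is.na(k)) {
        eff <- s[k] + bp[k] - bm[k]
        expect_gte(eff, -1e-6); expect_lte(eff, 1 + 1e-6)
        expect_lte(v[j], fx$model$rxns$ub[j] * eff + 1e-6)
      } else {
        expect_lte(v[j], fx$model$rxns$ub[j] + 1e-9)
      }
    }
    expect_true(all(fit$beta$beta_plus >= -1e-9 & fit$beta$beta_plus <= 1000 + 1e-9))
    expect_true(all(fit$beta$beta_minus >= -1e-9 & fit$beta$beta_minus <= 1000 + 1e-9))
  }
})

test_that("uniform factors reduce the program to plain FBA", {
  fx <- make_toy_community(fixture_spec(n_members = 3, seed = 6))
  uf <- unit_factors(fx$model)
  fit <- solve_imic(fx$model, uf, lambda = 7)
  fba <- community_fba(fx$model)
  expect_equal(fit$z, fba$z, tolerance = 1e-6)
  expect_equal(fit$sum_beta, 0, tolerance = 1e-9)
})

test_that("the optimum matches the independently assembled oracle", {
  for (seed in 1:12) {
    toy <- random_toy(seed)
    for (lambda in c(0.5, 5)) {
      fit <- solve_imic(toy$model, toy$factors, lambda)
      orc <- oracle_imic(toy$model, toy$factors, lambda)
      expect_equal(fit$z, orc$z, tolerance = 1e-6,
                   label = paste("seed", seed, "lambda", lambda))
    }
  }
})

test_that("tightening relaxations are redundant at the optimum", {
  for (seed in c(2, 9)) {
    toy <- random_toy(seed)
    z_full <- solve_imic(toy$model, toy$factors, 3)$z
    z_nobm <- solve_imic(toy$model, toy$factors, 3,
                         imic_config(use_beta_minus = FALSE))$z
    expect_equal(z_full, z_nobm, tolerance = 1e-6)
  }
})

test_that("weak- and strong-penalty limits recover FBA and hard E-flux bounds", {
  fx <- make_toy_community(fixture_spec(n_members = 2, pathway_depth = 2, seed = 3))
  cf <- quiet_factors(fx$model, make_expression(fx))
  # lambda -> 0: relaxation is free, every GPR bound lifts to vmax
  z0 <- solve_imic(fx$model, cf, 1e-9)$z
  expect_equal(z0, community_fba(fx$model)$z, tolerance = 1e-6)
  # lambda huge: no relaxation; equals FBA with hard expression bounds
  fit_inf <- solve_imic(fx$model, cf, 1e6)
  expect_equal(fit_inf$sum_beta, 0, tolerance = 1e-9)
  hard <- fx$model
  gj <- which(!is.na(hard$rxns$gpr_key))
  s <- stats::setNames(cf$f_scaled, cf$gpr_key)
  hard$rxns$ub[gj] <- hard$rxns$ub[gj] * s[hard$rxns$gpr_key[gj]]
  expect_equal(fit_inf$z, community_fba(hard)$z, tolerance = 1e-6)
})

test_that("the regularization path is monotone and convex", {
  grid <- c(0.5, 2, 5, 8, 11, 20, 35, 50)
  fx <- make_toy_community(fixture_spec(n_members = 2, pathway_depth = 1, seed = 10))
  cf <- quiet_factors(fx$model, make_expression(fx))
  fits <- lapply(grid, function(l) solve_imic(fx$model, cf, l))
  z <- vapply(fits, `[[`, numeric(1), "z")
  smu <- vapply(fits, `[[`, numeric(1), "sum_mu")
  sbe <- vapply(fits, `[[`, numeric(1), "sum_beta")
  expect_true(all(diff(z) <= 1e-7))
  expect_true(all(diff(smu) <= 1e-6))
  expect_true(all(diff(sbe) <= 1e-6))
  # midpoint convexity of the piecewise-linear value function
  for (k in 2:(length(grid) - 1)) {
    w <- (grid[k + 1] - grid[k]) / (grid[k + 1] - grid[k - 1])
    expect_lte(z[k], w * z[k - 1] + (1 - w) * z[k + 1] + 1e-7)
  }
})

test_that("configuration and input contracts are enforced", {
  toy <- toy_single_path()
  expect_error(solve_imic(toy$model, toy$factors, -1), "positive")
  expect_error(solve_imic(toy$model, toy$factors, 0), "positive")
  two <- dplyr::bind_rows(toy$factors,
                          dplyr::mutate(toy$factors, sample_id = "s2"))
  expect_error(solve_imic(toy$model, two, 1), "more than one sample")
  rev_model <- build_community(list(new_member(
    "t", tibble::tibble(id = c("a_e", "b"), compartment = c("e", "c")),
    list(lb = c(0, 0, -10), ub = c(10, 1000, 0)),
    list(R1 = c(a_e = -1, b = 1), biomass = c(b = -1), EX_a = c(a_e = -1)),
    gpr = list(R1 = parse_gpr("g")))), "e")
  expect_error(solve_imic(rev_model, toy$factors, 1), "irreversible")
  expect_error(build_imic_lp <- imicr:::build_imic_lp(toy$model,
    dplyr::mutate(toy$factors, gpr_key = "t::other"), 1), "missing")
})

test_that("tidy and glance expose the fit as tables", {
  toy <- toy_single_path()
  fit <- solve_imic(toy$model, toy$factors, 50)
  td <- tidy(fit)
  expect_named(td, c("sample_id", "member", "mu"))
  gl <- glance(fit)
  expect_equal(gl$z, 5, tolerance = 1e-9)
  expect_equal(gl$n_members, 1)
})
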