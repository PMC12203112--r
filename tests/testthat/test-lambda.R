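test_that("sensitivity analysis finds the analytic kink of the value function", {
  # z(lambda) = 10 - lambda/2 below lambda = vmax = 10, constant 5 above
  toy <- toy_single_path()
  scan <- select_lambda_sensitivity(toy$model, toy$factors)
  expect_equal(scan$selected, 10)
  expect_equal(scan$method, "sensitivity")
  path <- scan$path
  below <- path$lambda < 10
  expect_equal(path$z[below], 10 - path$lambda[below] / 2, tolerance = 1e-7)
  expect_equal(path$z[path$lambda > 10], rep(5, sum(path$lambda > 10)),
               tolerance = 1e-7)
  expect_true(path$selected[path$lambda == 10])
})

test_that("a flat objective curve falls back to the smallest grid value", {
  fx <- make_toy_community(fixture_spec(n_members = 2, pathway_depth = 1, seed = 2))
  uf <- unit_factors(fx$model)
  cfg <- imic_config(lambda_grid = c(0.1, 1, 5, 20))
  expect_warning(scan <- select_lambda_sensitivity(fx$model, uf, cfg), "flat")
  expect_equal(scan$selected, 0.1)
})

test_that("the kink detector picks the curvature maximum on constructed curves", {
  # three-segment piecewise-linear curve: steep, shallow, flat
  grid <- seq(1, 13)
  z <- c(20 - 4 * (0:4), 4 - 1 * (1:4), rep(0, 4))
  k <- imicr:::select_kink(grid, z)
  expect_equal(k$selected, 5)   # largest slope change: -4 -> -1
  # equal slope changes at grid points 5 and 9: ties break to the smaller
  z2 <- c(20, 18, 16, 14, 12, 11, 10, 9, 8, 8, 8, 8, 8)
  k2 <- imicr:::select_kink(grid, z2)
  expect_equal(k2$selected, 5)
  expect_false(k2$flat)
})

test_that("a grid with fewer than three points is rejected", {
  toy <- toy_single_path()
  expect_error(select_lambda_sensitivity(toy$model, toy$factors,
                                         imic_config(lambda_grid = c(1, 2))),
               "at least 3")
})

# Cross-validation fixture where the best lambda is known by construction:
# each member has an informative reaction (factor proportional to abundance)
# and an anti-informative one (factor anti-proportional). The binding bound is
# the minimum, i.e. the anti-informative one; for vmax/2 < lambda < vmax the
# relaxation lifts exactly the binding reaction up to the informative level
# (correlation +1), while for lambda > vmax no lift happens and predictions
# anti-correlate with abundance.
cv_toy <- function(n_samples = 4) {
  members <- lapply(1:4, function(j) {
    mid <- paste0("m", j)
    new_member(mid,
      mets = tibble::tibble(id = c("s_e", "x", "y"),
                            compartment = c("e", "c", "c")),
      rxns = list(lb = c(0, 0, 0, -1000), ub = c(40, 40, 1000, 0)),
      stoich = list(RA = c(s_e = -1, x = 1), RB = c(x = -1, y = 1),
                    biomass = c(y = -1), EX_s = c(s_e = -1)),
      gpr = list(RA = parse_gpr(paste0("gA_", mid)),
                 RB = parse_gpr(paste0("gB_", mid))))
  })
  model <- to_irreversible(build_community(members, "e"))
  keys <- names(model$gpr)
  inf_s <- c(m1 = 0.4, m2 = 0.6, m3 = 0.8, m4 = 1.0)    # ~ abundance
  anti_s <- c(m1 = 0.35, m2 = 0.3, m3 = 0.25, m4 = 0.2) # anti-ordered, binding
  factors <- dplyr::bind_rows(lapply(seq_len(n_samples), function(s) {
    tibble::tibble(sample_id = paste0("s", s),
                   member_id = rep(paste0("m", 1:4), each = 2),
                   reaction_id = rep(c("RA", "RB"), 4),
                   gpr_key = paste0(rep(paste0("m", 1:4), each = 2), "::",
                                    rep(c("RA", "RB"), 4)),
                   f_raw = NA_real_, M = 1,
                   f_scaled = as.numeric(rbind(inf_s, anti_s)))
  }))
  abundance <- dplyr::bind_rows(lapply(seq_len(n_samples), function(s) {
    tibble::tibble(sample_id = paste0("s", s),
                   member_id = paste0("m", 1:4),
                   abundance = c(0.1, 0.2, 0.3, 0.4))
  }))
  list(model = model, factors = factors, abundance = abundance)
}

test_that("cross-validation selects the lambda that predicts abundance", {
  toy <- cv_toy(4)
  cfg <- imic_config(lambda_grid = c(25, 45))
  scan <- select_lambda_cv(toy$model, toy$factors, toy$abundance,
                           k = 2, seed = 17, config = cfg)
  expect_equal(scan$fold_best, c(25, 25))
  expect_equal(scan$selected, 25)
  expect_equal(scan$method, "cross_validation")
  # held-out correlation really separates the two grid points
  expect_equal(scan$path$mean_cor, c(1, -1), tolerance = 1e-9)
})

test_that("cross-validation procedure contracts hold", {
  toy <- cv_toy(5)
  # a one-point grid is returned regardless of folds
  one <- imic_config(lambda_grid = 7)
  scan <- select_lambda_cv(toy$model, toy$factors, toy$abundance,
                           k = 2, seed = 1, config = one)
  expect_equal(scan$selected, 7)

  # leave-one-out: one fold best per sample
  loo <- select_lambda_cv(toy$model, toy$factors, toy$abundance,
                          k = 5, seed = 3, config = imic_config(lambda_grid = c(25, 45)))
  expect_length(loo$fold_best, 5)

  # seed is mandatory, k is bounded by the sample count
  expect_error(select_lambda_cv(toy$model, toy$factors, toy$abundance, k = 2),
               "seed")
  expect_error(select_lambda_cv(toy$model, toy$factors, toy$abundance,
                                k = 9, seed = 1), "exceeds")

  # constant abundance vectors are excluded with a warning
  ab <- toy$abundance
  ab$abundance[ab$sample_id == "s1"] <- 0.25
  expect_warning(select_lambda_cv(toy$model, toy$factors, ab, k = 2, seed = 1,
                                  config = imic_config(lambda_grid = 7)),
                 "constant abundance")
})

test_that("fold assignment is reproducible given the seed", {
  toy <- cv_toy(4)
  cfg <- imic_config(lambda_grid = c(25, 45))
  s1 <- select_lambda_cv(toy$model, toy$factors, toy$abundance, k = 2,
                         seed = 42, config = cfg)
  s2 <- select_lambda_cv(toy$model, toy$factors, toy$abundance, k = 2,
                         seed = 42, config = cfg)
  expect_identical(s1$fold_best, s2$fold_best)
})
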