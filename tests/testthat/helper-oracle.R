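# Independent brute-force LP oracle for the community program, assembled
# equation by equation from the mathematical statement (objective
# max sum(mu) - lambda sum(beta+ + beta-); S v = 0; GPR-scaled bounds; factor
# box; beta box), deliberately sharing no assembly code with the package's
# build_imic_lp(). Variables are ordered [v | beta+ | beta-] with one beta
# pair per GPR-bearing reaction.
oracle_imic <- function(model, factors, lambda, beta_box = 1000,
                        fix_beta_minus = FALSE) {
  rx <- model$rxns
  n <- nrow(rx)
  keys <- sort(names(model$gpr))
  nb <- length(keys)
  sc <- stats::setNames(factors$f_scaled, factors$gpr_key)
  vmax <- ifelse(is.finite(rx$ub), rx$ub, 1000)

  nvar <- n + 2 * nb
  rows <- list(); rhs <- numeric(0); dir <- character(0)
  push <- function(coef, d, b) {
    rows[[length(rows) + 1L]] <<- coef
    dir <<- c(dir, d); rhs <<- c(rhs, b)
  }

  # steady state, one equation per metabolite
  for (i in seq_len(nrow(model$S))) {
    coef <- numeric(nvar)
    coef[seq_len(n)] <- as.numeric(model$S[i, ])
    push(coef, "=", 0)
  }
  # expression-scaled upper bounds for GPR reactions
  for (j in seq_len(n)) {
    if (is.na(rx$gpr_key[j])) next
    t <- match(rx$gpr_key[j], keys)
    coef <- numeric(nvar)
    coef[j] <- 1
    coef[n + t] <- -vmax[j]
    coef[n + nb + t] <- vmax[j]
    push(coef, "<=", vmax[j] * sc[rx$gpr_key[j]])
  }
  # factor box 0 <= f/M + beta+ - beta- <= 1
  for (t in seq_len(nb)) {
    coef <- numeric(nvar); coef[n + t] <- 1; coef[n + nb + t] <- -1
    push(coef, "<=", 1 - sc[keys[t]])
    coef <- numeric(nvar); coef[n + t] <- -1; coef[n + nb + t] <- 1
    push(coef, "<=", sc[keys[t]])
  }
  # plain bounds v <= vmax and beta boxes
  for (j in seq_len(n)) {
    coef <- numeric(nvar); coef[j] <- 1
    push(coef, "<=", vmax[j])
  }
  for (t in seq_len(2 * nb)) {
    coef <- numeric(nvar); coef[n + t] <- 1
    push(coef, "<=", if (fix_beta_minus && t > nb) 0 else beta_box)
  }

  obj <- numeric(nvar)
  obj[match(model$biomass, rx$col)] <- -1   # minimize the negated objective
  obj[n + seq_len(2 * nb)] <- lambda

  A <- do.call(rbind, rows)
  res <- imicr:::simplex_core(obj, A, rhs, dir)
  stopifnot(res$status == "optimal")
  list(z = -res$value,
       mu = stats::setNames(res$x[match(model$biomass, rx$col)],
                            names(model$biomass)),
       beta = res$x[n + seq_len(2 * nb)])
}

# Textbook Benjamini-Hochberg step-up, written independently of p.adjust():
# order the p-values, compute p_(i) * m / i, and enforce monotonicity from the
# largest rank downwards.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
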