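# Dense two-phase primal simplex.
#
# Solves  min c'x  s.t.  A x (<=|>=|=) b,  x >= 0,  with b >= 0 after row
# normalization. Written for the heavily degenerate LPs that arise from
# stoichiometric models (most right-hand sides are exactly zero): Dantzig
# pricing with an automatic switch to Bland's rule after a run of degenerate
# pivots, explicit driving-out of basic artificials after phase 1, and
# redundant-row elimination. All arithmetic is vectorized full-tableau
# Gauss-Jordan.
#
# Arguments: cc objective (min), A dense matrix, b rhs, dir character vector
# of "<=", ">=", "=" per row. Returns list(status, value, x).
simplex_core <- function(cc, A, b, dir,
                         tol = 1e-9, max_iter = 20000L) {
  M <- nrow(A); N <- ncol(A)
  stopifnot(length(b) == M, length(dir) == M, length(cc) == N)

  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    dir[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[neg]]
  }

  n_le <- sum(dir == "<="); n_ge <- sum(dir == ">=")
  # columns: x (N), slacks (one per <=), surpluses (one per >=), artificials
  art_rows <- which(dir != "<=")
  n_art <- length(art_rows)
  Ntot <- N + n_le + n_ge + n_art

  Afull <- matrix(0, M, Ntot)
  Afull[, seq_len(N)] <- A
  j <- N
  slack_col <- integer(M)
  for (i in which(dir == "<=")) { j <- j + 1L; Afull[i, j] <- 1; slack_col[i] <- j }
  for (i in which(dir == ">=")) { j <- j + 1L; Afull[i, j] <- -1 }
  art_col <- integer(M)
  for (i in art_rows) { j <- j + 1L; Afull[i, j] <- 1; art_col[i] <- j }

  basis <- integer(M)
  basis[dir == "<="] <- slack_col[dir == "<="]
  basis[art_rows] <- art_col[art_rows]

  # tableau: M constraint rows [A | b], cost row appended per phase
  tab <- cbind(Afull, b)

  run_phase <- function(tab, basis, cost, live_cols) {
    M <- nrow(tab); W <- ncol(tab)
    # reduced-cost row for the given cost vector under the current basis
    crow <- c(cost, 0)
    for (i in seq_len(M)) {
      cb <- crow[basis[i]]
      if (cb != 0) crow <- crow - cb * tab[i, ]
    }
    degen <- 0L; bland <- FALSE
    for (it in seq_len(max_iter)) {
      cand <- live_cols[crow[live_cols] < -tol]
      if (length(cand) == 0L) {
        return(list(tab = tab, basis = basis, crow = crow, status = "optimal"))
      }
      pc <- if (bland) cand[1L] else cand[which.min(crow[cand])]
      col <- tab[, pc]
      pos <- which(col > tol)
      if (length(pos) == 0L) {
        return(list(tab = tab, basis = basis, crow = crow, status = "unbounded"))
      }
      ratio <- tab[pos, W] / col[pos]
      rmin <- min(ratio)
      ties <- pos[ratio <= rmin + tol * max(1, rmin)]
      pr <- ties[which.min(basis[ties])]   # smallest basis index on ties
      if (rmin <= tol) {
        degen <- degen + 1L
        if (degen > 2L * M && !bland) bland <- TRUE
      } else degen <- 0L
      # Gauss-Jordan pivot on (pr, pc)
      piv <- tab[pr, pc]
      tab[pr, ] <- tab[pr, ] / piv
      fac <- tab[, pc]; fac[pr] <- 0
      tab <- tab - outer(fac, tab[pr, ])
      crow <- crow - crow[pc] * tab[pr, ]
      basis[pr] <- pc
    }
    list(tab = tab, basis = basis, crow = crow, status = "iteration_limit")
  }

  x_cols <- seq_len(N + n_le + n_ge)
  if (n_art > 0L) {
    cost1 <- c(rep(0, N + n_le + n_ge), rep(1, n_art))
    ph1 <- run_phase(tab, basis, cost1, seq_len(Ntot))
    if (ph1$status != "optimal") return(list(status = ph1$status, value = NA_real_, x = NULL))
    val1 <- sum(ph1$tab[ph1$basis > N + n_le + n_ge, ncol(ph1$tab)])
    if (val1 > 1e-7 * max(1, max(abs(b)))) {
      return(list(status = "infeasible", value = NA_real_, x = NULL))
    }
    tab <- ph1$tab; basis <- ph1$basis
    # drive remaining (degenerate) basic artificials out of the basis
    drop_rows <- integer(0)
    for (i in which(basis > N + n_le + n_ge)) {
      entry <- which(abs(tab[i, x_cols]) > tol)
      if (length(entry) == 0L) { drop_rows <- c(drop_rows, i); next }
      pc <- entry[1L]
      piv <- tab[i, pc]
      tab[i, ] <- tab[i, ] / piv
      fac <- tab[, pc]; fac[i] <- 0
      tab <- tab - outer(fac, tab[i, ])
      basis[i] <- pc
    }
    if (length(drop_rows)) {
      tab <- tab[-drop_rows, , drop = FALSE]
      basis <- basis[-drop_rows]
    }
  }

  cost2 <- c(cc, rep(0, n_le + n_ge), rep(0, n_art))
  ph2 <- run_phase(tab, basis, cost2, x_cols)
  if (ph2$status != "optimal") return(list(status = ph2$status, value = NA_real_, x = NULL))

  W <- ncol(ph2$tab)
  x <- numeric(Ntot)
  x[ph2$basis] <- ph2$tab[, W]
  xx <- x[seq_len(N)]
  list(status = "optimal", value = sum(cc * xx), x = xx)
}
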