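# Internal linear-programming interface.
#
# Solves  max/min  obj' x   s.t.  A_eq x = b_eq,  A_le x <= b_le,  0 <= x <= ub
# with the package's two-phase simplex (simplex_core). Finite upper bounds
# become <= rows; variables with a zero upper bound are eliminated before the
# solve and re-inserted as zeros afterwards, which keeps knocked-out reactions
# from bloating the tableau.
lp_solve <- function(obj, A_eq = NULL, b_eq = NULL, A_le = NULL, b_le = NULL,
                     ub = NULL, maximize = TRUE) {
  n <- length(obj)
  if (is.null(ub)) ub <- rep(Inf, n)
  keep <- ub > 1e-12
  nk <- sum(keep)
  if (nk == 0L) {
    ok <- (is.null(b_eq) || all(abs(b_eq) < 1e-9)) &&
          (is.null(b_le) || all(b_le > -1e-9))
    return(list(status = if (ok) "optimal" else "infeasible",
                value = if (ok) 0 else NA_real_, x = rep(0, n), message = NULL))
  }

  sub <- function(A) if (is.null(A) || nrow(A) == 0L) NULL else as.matrix(A)[, keep, drop = FALSE]
  A_eq <- sub(A_eq); A_le <- sub(A_le)
  objk <- obj[keep]; ubk <- ub[keep]

  A <- NULL; b <- numeric(0); dir <- character(0)
  drop_null <- function(A, b, eq) {
    nz <- rowSums(A != 0) > 0L
    bad <- if (eq) abs(b[!nz]) > 1e-9 else b[!nz] < -1e-9
    list(A = A[nz, , drop = FALSE], b = b[nz], infeasible = any(bad))
  }
  if (!is.null(A_le)) {
    d <- drop_null(A_le, b_le, eq = FALSE)
    if (d$infeasible) {
      return(list(status = "infeasible", value = NA_real_,
                  x = rep(NA_real_, n), message = "constant row violated"))
    }
    A <- rbind(A, d$A); b <- c(b, d$b); dir <- c(dir, rep("<=", length(d$b)))
  }
  fin <- which(is.finite(ubk))
  if (length(fin)) {
    U <- matrix(0, length(fin), nk)
    U[cbind(seq_along(fin), fin)] <- 1
    A <- rbind(A, U); b <- c(b, ubk[fin]); dir <- c(dir, rep("<=", length(fin)))
  }
  if (!is.null(A_eq)) {
    d <- drop_null(A_eq, b_eq, eq = TRUE)
    if (d$infeasible) {
      return(list(status = "infeasible", value = NA_real_,
                  x = rep(NA_real_, n), message = "constant equality violated"))
    }
    A <- rbind(A, d$A); b <- c(b, d$b); dir <- c(dir, rep("=", length(d$b)))
  }

  res <- simplex_core(if (maximize) -objk else objk, A, b, dir)
  if (res$status != "optimal") {
    return(list(status = res$status, value = NA_real_, x = rep(NA_real_, n),
                message = NULL))
  }
  x <- rep(0, n)
  x[keep] <- res$x
  list(status = "optimal",
       value = if (maximize) -res$value else res$value,
       x = x, message = NULL)
}
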