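# Internal dense linear-programming engine.
#
# The constraint-based calculations in this package (growth maximisation,
# flux-consistency checks, least-absolute-deviation fitting, stoichiometric
# consistency) all reduce to small dense LPs over networks of a few dozen
# reactions. They are solved with a two-phase primal simplex using Bland's
# rule, which terminates on the degenerate, massively redundant systems that
# steady-state stoichiometry produces. The optimal basis is re-solved against
# the original constraint matrix so returned solutions are accurate to
# near machine precision.

# Solve: min/max obj'x  s.t.  Aeq x = beq, lb <= x <= ub (finite bounds).
# Returns list(status, x, objval). status: "optimal" | "infeasible".
solveLP <- function(obj, Aeq, beq, lb, ub, maximize = FALSE, tol = 1e-9) {
  n <- length(obj)
  Aeq <- as.matrix(Aeq)
  stopifnot(ncol(Aeq) == n, nrow(Aeq) == length(beq),
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solveLP requires finite bounds")
  if (any(lb > ub + tol)) return(list(status = "infeasible", x = NULL, objval = NA_real_))
  cc <- if (maximize) -obj else obj

  # shift x = y + lb, y in [0, u]
  u <- ub - lb
  b1 <- beq - as.vector(Aeq %*% lb)
  m1 <- nrow(Aeq)

  # standard form: [Aeq 0; I I] (y, s) = (b1, u), y,s >= 0
  ncols <- 2L * n
  M <- matrix(0, m1 + n, ncols)
  M[seq_len(m1), seq_len(n)] <- Aeq
  M[m1 + seq_len(n), seq_len(n)] <- diag(n)
  M[m1 + seq_len(n), n + seq_len(n)] <- diag(n)
  rhs <- c(b1, u)
  neg <- rhs < 0
  if (any(neg)) { M[neg, ] <- -M[neg, , drop = FALSE]; rhs[neg] <- -rhs[neg] }

  res <- .simplexTwoPhase(c(cc, numeric(n)), M, rhs, tol = tol)
  if (res$status != "optimal") return(list(status = res$status, x = NULL, objval = NA_real_))
  x <- res$x[seq_len(n)] + lb
  objval <- sum(obj * x)
  list(status = "optimal", x = x, objval = objval)
}

# Two-phase simplex for min c'z s.t. M z = rhs (rhs >= 0), z >= 0.
# Dense tableau, Bland's rule (anti-cycling). Basis re-solved at the end.
.simplexTwoPhase <- function(cc, M, rhs, tol = 1e-9, maxit = 50000L) {
  m <- nrow(M); nv <- ncol(M)
  # tableau with artificial columns appended
  Tm <- cbind(M, diag(m), rhs)
  art <- nv + seq_len(m)
  basis <- art
  rhscol <- nv + m + 1L

  # phase-1 objective row: minimize sum of artificials
  zrow <- -colSums(Tm)          # reduced costs for phase 1 (artificials price to 0)
  zrow[art] <- 0

  piv <- function(r, j) {
    Tm[r, ] <<- Tm[r, ] / Tm[r, j]
    upd <- which(abs(Tm[, j]) > 1e-13); upd <- upd[upd != r]
    if (length(upd)) Tm[upd, ] <<- Tm[upd, ] - outer(Tm[upd, j], Tm[r, ])
    f <- zrow[j]
    if (abs(f) > 1e-13) zrow <<- zrow - f * Tm[r, ]
    basis[r] <<- j
  }

  runSimplex <- function(allowed) {
    for (it in seq_len(maxit)) {
      j <- which(allowed & zrow[seq_len(nv + m)] < -tol)
      if (!length(j)) return(TRUE)
      j <- j[1L]                               # Bland: smallest index
      pos <- which(Tm[, j] > tol)
      if (!length(pos)) return(NA)             # unbounded
      ratio <- Tm[pos, rhscol] / Tm[pos, j]
      best <- pos[ratio <= min(ratio) + 1e-12]
      r <- best[which.min(basis[best])]        # Bland tie-break
      piv(r, j)
    }
    stop("simplex iteration limit reached")
  }

  allowed <- c(rep(TRUE, nv), rep(FALSE, m))
  ok <- runSimplex(allowed)
  if (is.na(ok)) return(list(status = "infeasible"))
  p1 <- -sum(ifelse(basis %in% art, Tm[, rhscol], 0))
  if (sum(Tm[basis %in% art, rhscol]) > 1e-7) return(list(status = "infeasible"))

  # drive remaining artificials out of the basis (degenerate rows)
  for (r in which(basis %in% art)) {
    cand <- which(abs(Tm[r, seq_len(nv)]) > tol)
    if (length(cand)) piv(r, cand[1L]) else Tm[r, ] <- 0   # redundant row
  }

  # phase-2 reduced costs
  zrow <- c(cc, rep(0, m), 0)
  for (r in seq_len(m)) {
    j <- basis[r]
    if (j <= nv && abs(cc[j]) > 1e-13) zrow <- zrow - cc[j] * Tm[r, ]
  }
  zrow[art] <- Inf                              # never re-enter
  ok <- runSimplex(allowed)
  if (is.na(ok)) return(list(status = "unbounded"))

  # recover x, then polish by re-solving the basis system exactly
  x <- numeric(nv)
  inb <- basis <= nv
  x[basis[inb]] <- Tm[inb, rhscol]
  live <- which(apply(abs(Tm[, seq_len(nv), drop = FALSE]) > 1e-13, 1L, any) |
                  Tm[, rhscol] != 0 | inb)
  bcols <- basis[inb]
  if (length(bcols)) {
    B <- M[, bcols, drop = FALSE]
    xb <- tryCatch(qr.solve(B, rhs, tol = 1e-12), error = function(e) NULL)
    if (!is.null(xb) && max(abs(B %*% xb - rhs)) < 1e-6) {
      x <- numeric(nv); x[bcols] <- xb
    }
  }
  x[abs(x) < 1e-11] <- 0
  list(status = "optimal", x = x, objval = sum(cc * x))
}
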