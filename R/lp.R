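# Dense two-phase bounded-variable primal simplex.
#
# Solves  max/min c'x  s.t.  A x = b,  lb <= x <= ub.
#
# Purpose-built for flux balance problems: the constraint matrix is a (small,
# possibly rank-deficient) stoichiometric matrix, b is zero or nearly so, and
# bounds may be infinite on either side. Phase 1 introduces one artificial
# variable per row (signed so the start is feasible) and minimises their sum;
# rank-deficient rows simply keep their artificial basic at zero, which is
# then locked to [0,0] for phase 2. Pivoting is deterministic (largest
# reduced cost, lowest index on ties, Bland's rule after a stall budget) so
# repeated solves return the identical vertex.

simplexLP <- function(obj, A, b, lb, ub, maximize = TRUE,
                      tol = 1e-9, ftol = 1e-7, maxit = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n, length(b) == m)
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  sense <- if (maximize) 1 else -1
  cvec <- sense * obj

  # initial point: each structural variable at its finite bound nearest zero
  x <- numeric(n)
  stat <- character(n)                      # "lb", "ub", "free" (nonbasic state)
  for (j in seq_len(n)) {
    if (is.finite(lb[j]) && is.finite(ub[j])) {
      if (abs(lb[j]) <= abs(ub[j])) { x[j] <- lb[j]; stat[j] <- "lb" }
      else { x[j] <- ub[j]; stat[j] <- "ub" }
    } else if (is.finite(lb[j])) { x[j] <- lb[j]; stat[j] <- "lb" }
    else if (is.finite(ub[j])) { x[j] <- ub[j]; stat[j] <- "ub" }
    else { x[j] <- 0; stat[j] <- "free" }
  }

  r <- b - as.vector(A %*% x)
  asign <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(asign, nrow = m, ncol = m))
  N <- n + m
  lbe <- c(lb, rep(0, m)); ube <- c(ub, rep(Inf, m))
  xe <- c(x, abs(r))
  state <- c(stat, rep("basic", m))
  basis <- n + seq_len(m)

  c1 <- c(rep(0, n), rep(-1, m))            # phase 1: maximise -sum(artificials)
  c2 <- c(cvec, rep(0, m))

  run_phase <- function(cc, xe, state, basis, lbe, ube) {
    it <- 0L; stall <- 0L
    repeat {
      it <- it + 1L
      if (it > maxit) stop("simplex iteration limit reached")
      B <- Aext[, basis, drop = FALSE]
      Blu <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(Blu)) stop("singular basis encountered")
      # recompute basic values exactly each iteration (drift-free)
      nonb <- setdiff(seq_len(N), basis)
      rhs <- b - if (length(nonb)) as.vector(Aext[, nonb, drop = FALSE] %*% xe[nonb]) else 0
      xe[basis] <- as.vector(Blu %*% rhs)
      y <- as.vector(crossprod(Blu, cc[basis]))
      d <- cc[nonb] - as.vector(crossprod(Aext[, nonb, drop = FALSE], y))
      # eligible entering moves
      up <- (state[nonb] %in% c("lb", "free")) & d > tol
      dn <- (state[nonb] == "ub" | state[nonb] == "free") & d < -tol
      elig <- which(up | dn)
      if (!length(elig)) return(list(x = xe, state = state, basis = basis,
                                     obj = sum(cc * xe), status = "optimal"))
      use_bland <- stall > 2L * N
      pick <- if (use_bland) elig[which.min(nonb[elig])] else elig[which.max(abs(d[elig]))]
      q <- nonb[pick]
      dirn <- if (d[pick] > 0) 1 else -1     # entering variable moves up/down
      w <- as.vector(Blu %*% Aext[, q])      # basic response: x_B -= dirn * theta * w
      # ratio test
      theta <- ube[q] - lbe[q]               # bound-to-bound flip distance
      leave <- 0L; leave_to <- ""
      chg <- dirn * w
      for (k in seq_len(m)) {
        bi <- basis[k]
        if (chg[k] > tol) {                  # basic variable decreases
          if (is.finite(lbe[bi])) {
            t_k <- (xe[bi] - lbe[bi]) / chg[k]
            if (t_k < theta - tol) { theta <- t_k; leave <- k; leave_to <- "lb" }
            else if (t_k < theta + tol && leave > 0L && basis[k] < basis[leave]) {
              theta <- min(theta, t_k); leave <- k; leave_to <- "lb"
            }
          }
        } else if (chg[k] < -tol) {          # basic variable increases
          if (is.finite(ube[bi])) {
            t_k <- (ube[bi] - xe[bi]) / (-chg[k])
            if (t_k < theta - tol) { theta <- t_k; leave <- k; leave_to <- "ub" }
            else if (t_k < theta + tol && leave > 0L && basis[k] < basis[leave]) {
              theta <- min(theta, t_k); leave <- k; leave_to <- "ub"
            }
          }
        }
      }
      if (!is.finite(theta))
        return(list(x = xe, state = state, basis = basis, obj = Inf,
                    status = "unbounded"))
      theta <- max(theta, 0)
      stall <- if (theta <= tol) stall + 1L else 0L
      xe[q] <- xe[q] + dirn * theta
      xe[basis] <- xe[basis] - theta * chg
      if (leave == 0L) {                     # entering variable flipped bounds
        state[q] <- if (dirn > 0) "ub" else "lb"
      } else {
        lv <- basis[leave]
        state[lv] <- leave_to
        xe[lv] <- if (leave_to == "lb") lbe[lv] else ube[lv]
        state[q] <- "basic"
        basis[leave] <- q
      }
    }
  }

  ph1 <- run_phase(c1, xe, state, basis, lbe, ube)
  if (-ph1$obj > ftol)
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  ube[n + seq_len(m)] <- 0                  # lock artificials for phase 2
  xe <- ph1$x; xe[n + seq_len(m)] <- pmin(xe[n + seq_len(m)], 0)
  xe[n + seq_len(m)] <- pmax(xe[n + seq_len(m)], 0)
  state <- ph1$state
  state[n + seq_len(m)][state[n + seq_len(m)] != "basic"] <- "lb"
  ph2 <- run_phase(c2, xe, state, ph1$basis, lbe, ube)
  if (ph2$status == "unbounded")
    return(list(status = "unbounded", objective = Inf * sense, x = NULL))
  xs <- ph2$x[seq_len(n)]
  xs <- pmin(pmax(xs, lb), ub)              # clip solver noise onto the box
  list(status = "optimal", objective = sum(obj * xs), x = xs)
}
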