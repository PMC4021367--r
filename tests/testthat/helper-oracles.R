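# Independent oracles used to cross-check the package's own algorithms.
# These deliberately take different computational routes than the
# implementation (exhaustive enumeration instead of simplex pivoting,
# closed-set intersection instead of fixpoint propagation, model rebuilding
# instead of bound zeroing).

# Exhaustive vertex enumeration for max c'x s.t. Ax = 0, lb <= x <= ub with
# finite bounds. Every optimum of a bounded LP is attained at a basic
# feasible solution: n - rank(A) variables sit at a bound. Enumerate all
# such fixings, solve the remaining square-ish system by least squares, and
# keep the best feasible point.
vertexEnumOptimum <- function(obj, A, lb, ub, tol = 1e-7) {
  A <- as.matrix(A)
  n <- ncol(A)
  r <- qr(A)$rank
  f <- n - r
  best <- -Inf
  fix_sets <- utils::combn(n, f, simplify = FALSE)
  for (J in fix_sets) {
    K <- setdiff(seq_len(n), J)
    grid <- expand.grid(rep(list(c(1, 2)), length(J)))
    for (g in seq_len(nrow(grid))) {
      x <- numeric(n)
      x[J] <- ifelse(unlist(grid[g, ]) == 1, lb[J], ub[J])
      rhs <- -A[, J, drop = FALSE] %*% x[J]
      sol <- tryCatch(qr.solve(A[, K, drop = FALSE], rhs, tol = 1e-10),
                      error = function(e) NULL)
      if (is.null(sol)) next
      x[K] <- sol
      if (max(abs(A %*% x)) > tol) next
      if (any(x < lb - tol) || any(x > ub + tol)) next
      val <- sum(obj * x)
      if (val > best) best <- val
    }
  }
  best
}

# Dead-end oracle: the producible (consumable) set is the least set closed
# under "all substrates (products) present => add products (substrates)".
# For monotone rules the least fixpoint equals the intersection of all
# closed subsets, which we find by exhaustive subset enumeration.
bruteForceDeadEnds <- function(model) {
  mets <- metabolites(model)$id
  n <- length(mets)
  stopifnot(n <= 20)
  dirs <- list()
  r <- reactions(model)
  S <- as.matrix(stoichiometricMatrix(model))
  for (j in seq_len(nrow(r))) {
    s <- S[, j]
    sub <- mets[s < 0]; prod <- mets[s > 0]
    if (r$upper[j] > 0) dirs[[length(dirs) + 1L]] <- list(sub = sub, prod = prod)
    if (r$lower[j] < 0) dirs[[length(dirs) + 1L]] <- list(sub = prod, prod = sub)
  }
  closedUnder <- function(set, from, to) {
    for (d in dirs) if (all(d[[from]] %in% set) && !all(d[[to]] %in% set))
      return(FALSE)
    TRUE
  }
  leastClosed <- function(from, to) {
    inter <- mets
    for (mask in 0:(2^n - 1)) {
      set <- mets[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
      if (closedUnder(set, from, to)) inter <- intersect(inter, set)
    }
    inter
  }
  producible <- leastClosed("sub", "prod")
  consumable <- leastClosed("prod", "sub")
  list(no_production = setdiff(mets, producible),
       no_consumption = setdiff(mets, consumable))
}

# Knockout oracle: rebuild the model from scratch with the disabled
# reactions physically removed (instead of bound-zeroed) and re-solve.
bruteForceKnockoutGrowth <- function(model, gene, medium, ngam = 0) {
  r <- reactions(model)
  keep <- vapply(seq_len(nrow(r)), function(j)
    evaluateGpr(parseGpr(r$gpr[j]), deleted = gene), logical(1))
  tab <- data.frame(id = r$id, name = r$name, stringsAsFactors = FALSE)
  S <- stoichiometricMatrix(model)
  tab$equation <- vapply(seq_len(nrow(r)), function(j) {
    col <- S[, j]; col <- col[col != 0]
    thermoflux:::stoichToString(stats::setNames(as.numeric(col), names(col)),
                                r$reversible[j])
  }, character(1))
  tab$gpr <- r$gpr; tab$subsystem <- r$subsystem
  tab$lower <- r$lower; tab$upper <- r$upper; tab$objective <- r$objective
  tab <- tab[keep, , drop = FALSE]
  m2 <- metabolicModel(tab)
  med2 <- mediumSpec(medium@name,
                     medium@bounds[medium@bounds$id %in% tab$id, , drop = FALSE],
                     intersect(medium@unconstrained, tab$id))
  sol <- solveFBA(applyMedium(m2, med2, ngam = ngam))
  if (solutionStatus(sol) == "optimal") max(objectiveValue(sol), 0) else 0
}

# Random bounded test LP in FBA form (A x = 0, finite box) with a seeded,
# reproducible structure; always feasible because x = 0 is interior.
randomBoundedFbaLike <- function(seed, nMet = 8, nRxn = 10) {
  set.seed(seed)
  A <- matrix(0, nMet, nRxn)
  for (j in seq_len(nRxn)) {
    k <- sample(1:3, 1)
    rows <- sample(nMet, k)
    A[rows, j] <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
  }
  lb <- -sample(0:5, nRxn, replace = TRUE)
  ub <- sample(1:5, nRxn, replace = TRUE)
  obj <- round(stats::rnorm(nRxn), 2)
  list(A = A, lb = lb, ub = ub, obj = obj)
}
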