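# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: brute-force enumeration and dense root
# scanning stand in for the assignment solver and the closed-form cubic.

# Exhaustive one-to-one matching: maximize the number of matches within
# `radius`, then minimize the total matched distance. Recursion over the
# points of the first set; feasible for <= ~8 points.
bruteMatchOracle <- function(p1, p2, radius) {
  p1 <- as.matrix(p1); p2 <- as.matrix(p2)
  n1 <- nrow(p1); n2 <- nrow(p2)
  if (n1 == 0L || n2 == 0L) return(list(count = 0L, cost = 0))
  d <- as.matrix(dist(rbind(p1, p2)))[seq_len(n1), n1 + seq_len(n2),
                                      drop = FALSE]
  best <- list(count = -1L, cost = Inf)
  rec <- function(i, used, count, cost) {
    if (i > n1) {
      if (count > best$count ||
          (count == best$count && cost < best$cost - 1e-12))
        best <<- list(count = count, cost = cost)
      return(invisible())
    }
    rec(i + 1L, used, count, cost)              # leave point i unmatched
    for (j in seq_len(n2)) {
      if (!used[j] && d[i, j] <= radius) {
        used[j] <- TRUE
        rec(i + 1L, used, count + 1L, cost + d[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, n2), 0L, 0)
  best
}

# Exhaustive minimum-cost full assignment over all column permutations
# (square matrices, n <= 6), for checking lapMinAssign.
bruteAssignOracle <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (k in seq_along(v))
      out <- c(out, lapply(perms(v[-k]), function(p) c(v[k], p)))
    out
  }
  best <- Inf; bestP <- NULL
  for (p in perms(seq_len(n))) {
    s <- sum(cost[cbind(seq_len(n), p)])
    if (s < best) { best <- s; bestP <- p }
  }
  list(cost = best, perm = bestP)
}

# Dense scan + bisection root of f*(f^2 - f0^2) = alpha*v on [f0, hi],
# independent of the closed-form solver.
bruteRootScan <- function(v, alpha, f0) {
  g <- function(f) f * (f^2 - f0^2) - alpha * v
  if (v == 0) return(f0)
  hi <- f0 + (alpha * v)^(1 / 3) + 1
  grid <- seq(f0, hi, length.out = 4001)
  gv <- g(grid)
  k <- which(gv[-1] >= 0 & gv[-length(gv)] <= 0)[1]
  lo <- grid[k]; up <- grid[k + 1]
  for (i in 1:200) {
    mid <- (lo + up) / 2
    if (g(mid) <= 0) lo <- mid else up <- mid
  }
  (lo + up) / 2
}

# Shared toy protocol: short, fast versions of the default acquisition
shortProtocol <- function(nCycles = 2, frameRate = 100)
  genFieldProtocol(nCycles = nCycles, frameRate = frameRate)
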