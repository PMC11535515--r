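#' Minimum-cost assignment (shortest augmenting path)
#'
#' Solves the rectangular linear assignment problem by the
#' Jonker-Volgenant shortest augmenting path algorithm (O(n^2 m)).
#' Entries of `Inf` mark forbidden pairings.
#'
#' @param cost numeric cost matrix (rows are assigned to columns; if
#'   there are more rows than columns the problem is transposed
#'   internally).
#' @return An integer vector `a` of length `nrow(cost)`: `a[i]` is the
#'   column assigned to row `i` (`NA` for rows left out when
#'   `nrow > ncol`), or `NULL` when no feasible assignment exists.
#' @examples
#' lapMinAssign(rbind(c(1, 2), c(2, 1)))  # 1, 2
#' @export
lapMinAssign <- function(cost) {
  cost <- as.matrix(cost)
  if (any(is.na(cost))) stop("cost matrix must not contain NA")
  transposed <- FALSE
  if (nrow(cost) > ncol(cost)) {
    cost <- t(cost)
    transposed <- TRUE
  }
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L)
    return(if (transposed) rep(NA_integer_, m) else integer(0))
  u <- numeric(n); v <- numeric(m)
  col4row <- rep(NA_integer_, n)
  row4col <- rep(NA_integer_, m)
  for (curRow in seq_len(n)) {
    shortest <- rep(Inf, m)
    pred <- rep(NA_integer_, m)
    done <- rep(FALSE, m)
    i <- curRow
    minVal <- 0
    sink <- NA_integer_
    while (is.na(sink)) {
      idx <- which(!done)
      r <- minVal + cost[i, idx] - u[i] - v[idx]
      upd <- which(r < shortest[idx])
      shortest[idx[upd]] <- r[upd]
      pred[idx[upd]] <- i
      jrel <- which.min(shortest[idx])
      j <- idx[jrel]
      minVal <- shortest[j]
      if (!is.finite(minVal)) return(NULL)
      done[j] <- TRUE
      if (is.na(row4col[j])) sink <- j else i <- row4col[j]
    }
    for (j in which(done)) {
      v[j] <- v[j] + shortest[j] - minVal
      i2 <- row4col[j]
      if (!is.na(i2)) u[i2] <- u[i2] + minVal - shortest[j]
    }
    u[curRow] <- u[curRow] + minVal
    j <- sink
    repeat {
      i2 <- pred[j]
      row4col[j] <- i2
      k <- col4row[i2]
      col4row[i2] <- j
      if (i2 == curRow) break
      j <- k
    }
  }
  if (transposed) row4col else col4row
}

#' One-to-one point matching within a radius
#'
#' Matches two point sets one-to-one so that (i) no match exceeds
#' `radius`, (ii) the number of matches is maximal, and (iii) among
#' maximal matchings the total matched distance is minimal. Solved
#' exactly by padding the distance matrix with per-point "unmatched"
#' dummies of cost `radius` and running [lapMinAssign()].
#'
#' @param p1,p2 matrices (or data.frames) of point coordinates, one row
#'   per point, same number of columns.
#' @param radius maximum matching distance (same units as coordinates).
#' @return list with `pairs` (data.frame `i`, `j`, `dist`),
#'   `unmatched1` and `unmatched2` (integer indices).
#' @export
matchPoints <- function(p1, p2, radius) {
  stopIfNot(radius > 0, "radius must be > 0")
  p1 <- as.matrix(p1); p2 <- as.matrix(p2)
  n1 <- nrow(p1); n2 <- nrow(p2)
  empty <- list(pairs = data.frame(i = integer(), j = integer(), dist = numeric()),
                unmatched1 = seq_len(n1), unmatched2 = seq_len(n2))
  if (n1 == 0L || n2 == 0L) return(empty)
  d2 <- outer(rowSums(p1^2), rowSums(p2^2), "+") - 2 * p1 %*% t(p2)
  d2[d2 < 0] <- 0  # numerical underflow
  d <- sqrt(d2)
  n <- n1 + n2
  cost <- matrix(Inf, n, n)
  cost[seq_len(n1), seq_len(n2)] <- ifelse(d <= radius, d, Inf)
  cost[cbind(seq_len(n1), n2 + seq_len(n1))] <- radius
  cost[cbind(n1 + seq_len(n2), seq_len(n2))] <- radius
  cost[n1 + seq_len(n2), n2 + seq_len(n1)] <- 0
  a <- lapMinAssign(cost)
  i <- seq_len(n1)
  j <- a[i]
  real <- j <= n2
  pairs <- data.frame(i = i[real], j = j[real])
  pairs$dist <- d[cbind(pairs$i, pairs$j)]
  list(pairs = pairs,
       unmatched1 = i[!real],
       unmatched2 = setdiff(seq_len(n2), pairs$j))
}
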