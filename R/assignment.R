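# Linear assignment problem, Jonker-Volgenant style shortest augmenting
# path with potentials, O(n^2 m). Rows must not outnumber columns.
# Returns, for each row, the index of its assigned column.
lap_solve <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stop("lap_solve needs nrow <= ncol")
  if (n == 0L) return(integer(0))
  u <- numeric(n)
  v <- numeric(m + 1)        # v[j + 1]; j = 0 is the virtual column
  p <- integer(m + 1)        # p[j + 1] = row occupying column j (0 = free)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    way <- integer(m)
    used <- logical(m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      free <- which(!used[-1])
      cur <- cost[i0, free] - u[i0] - v[free + 1]
      better <- cur < minv[free]
      if (any(better)) {
        bi <- free[better]
        minv[bi] <- cur[better]
        way[bi] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedcols <- which(used)          # 1-based positions = j + 1
      rows <- p[usedcols]
      u[rows] <- u[rows] + delta
      v[usedcols] <- v[usedcols] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0L) ans[p[j + 1]] <- j
  ans
}
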