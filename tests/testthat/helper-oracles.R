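# Brute-force 2-D grid search over (monomer, K) for the truncated
# isodesmic system: minimizes the summed relative residuals of protomer
# conservation and the number-average mass constraint.
grid_search_kd <- function(ctot, m1, mavg, N,
                           m_grid = seq(1, ctot - 1, by = 0.5),
                           k_grid = exp(seq(log(10), log(5000),
                                            length.out = 4000))) {
  best <- c(res = Inf, m = NA, k = NA)
  n <- seq_len(N)
  for (m in m_grid) {
    x <- m / k_grid                       # vector over k_grid
    # concentrations c_n = m * x^(n-1); accumulate sums over n
    s_c <- rep(0, length(x)); s_nc <- rep(0, length(x))
    p <- rep(1, length(x))
    for (j in n) {
      cj <- m * p
      s_c <- s_c + cj
      s_nc <- s_nc + j * cj
      p <- p * x
    }
    res <- abs(s_nc - ctot) / ctot + abs(m1 * s_nc / s_c - mavg) / mavg
    j <- which.min(res)
    if (res[j] < best["res"]) best <- c(res = res[j], m = m, k = k_grid[j])
  }
  best
}

# Exhaustive minimal-total-squared-displacement matching of two point
# sets (used to validate the assignment step on small cases). Returns,
# per point in (px, py), the matched index in (cx, cy) or NA, where any
# pair farther than the gate stays unmatched.
brute_force_match <- function(px, py, cx, cy, gate) {
  np <- length(px); nc <- length(cx)
  d2 <- outer(px, cx, "-")^2 + outer(py, cy, "-")^2
  gate2 <- gate^2
  best_cost <- Inf; best <- rep(NA_integer_, np)
  # enumerate all partial injective matchings
  assign_rec <- function(i, used, cur, cost) {
    if (i > np) {
      if (cost < best_cost) { best_cost <<- cost; best <<- cur }
      return(invisible())
    }
    # leaving i unmatched also leaves one detection unmatched relative
    # to a fuller matching, so it pays the death + birth cost (the
    # difference from the augmented-matrix total is then a constant)
    assign_rec(i + 1, used, cur, cost + 2 * gate2 * 1.0001)
    for (j in seq_len(nc)) {
      if (!used[j] && d2[i, j] <= gate2) {
        cur[i] <- j; used[j] <- TRUE
        assign_rec(i + 1, used, cur, cost + d2[i, j])
        cur[i] <- NA; used[j] <- FALSE
      }
    }
  }
  assign_rec(1L, logical(nc), rep(NA_integer_, np), 0)
  best
}

# exact two-sided Mann-Whitney p by enumeration of all label assignments
perm_rank_sum_p <- function(a, b) {
  n <- length(a); m <- length(b)
  pool <- c(a, b)
  u_stat <- function(ia) {
    aa <- pool[ia]; bb <- pool[-ia]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  }
  u_obs <- u_stat(seq_len(n))
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, u_stat)
  mu <- n * m / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# brute-force grayscale opening with a disc structuring element
brute_opening <- function(mat, diameter) {
  r <- diameter / 2
  ri <- floor(r)
  offs <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  offs <- offs[sqrt(offs$dy^2 + offs$dx^2) <= r + 1e-9, ]
  nr <- nrow(mat); nc <- ncol(mat)
  ero <- matrix(Inf, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ys <- i + offs$dy; xs <- j + offs$dx
    ok <- ys >= 1 & ys <= nr & xs >= 1 & xs <= nc
    ero[i, j] <- min(mat[cbind(ys[ok], xs[ok])])
  }
  dil <- matrix(-Inf, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ys <- i + offs$dy; xs <- j + offs$dx
    ok <- ys >= 1 & ys <= nr & xs >= 1 & xs <= nc
    dil[i, j] <- max(ero[cbind(ys[ok], xs[ok])])
  }
  dil
}

# render a pixel-integrated Gaussian spot into a frame (0-based centre
# coordinates), used to build detection fixtures with known truth
add_spot <- function(frame, x0, y0, flux, sigma) {
  nr <- nrow(frame); nc <- ncol(frame)
  rows <- max(0, round(y0) - 8):min(nr - 1, round(y0) + 8)
  cols <- max(0, round(x0) - 8):min(nc - 1, round(x0) + 8)
  fx <- pnorm(cols + 0.5, x0, sigma) - pnorm(cols - 0.5, x0, sigma)
  fy <- pnorm(rows + 0.5, y0, sigma) - pnorm(rows - 0.5, y0, sigma)
  frame[rows + 1, cols + 1] <- frame[rows + 1, cols + 1] +
    flux * outer(fy, fx)
  frame
}
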