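mkdet <- function(frame, x, y, amplitude = 10) {
  n <- length(frame)
  data.frame(frame = frame, x = x, y = y,
             amplitude = rep_len(amplitude, n), sigma = rep_len(1, n))
}

test_that("a persistent static spot gives one full-length trajectory", {
  det <- mkdet(1:20, rep(10, 20), rep(12, 20))
  trs <- link_trajectories(det, max_gap = 4, max_disp_px = 2)
  expect_length(trs, 1)
  expect_equal(nrow(trs[[1]]), 20)
  expect_true(all(diff(trs[[1]]$frame) > 0))
})

test_that("gap closing respects the max_gap boundary exactly", {
  # present frames 1..10 and 15..20: 4 missing frames -> closed
  det4 <- mkdet(c(1:10, 15:20), rep(5, 16), rep(5, 16))
  trs4 <- link_trajectories(det4, max_gap = 4, max_disp_px = 2)
  expect_length(trs4, 1)
  expect_equal(nrow(trs4[[1]]), 16)
  # 5 missing frames -> two trajectories
  det5 <- mkdet(c(1:10, 16:20), rep(5, 15), rep(5, 15))
  trs5 <- link_trajectories(det5, max_gap = 4, max_disp_px = 2)
  expect_length(trs5, 2)
})

test_that("empty input yields empty output", {
  expect_equal(link_trajectories(mkdet(integer(0), numeric(0), numeric(0))),
               list())
})

test_that("frame-to-frame assignment is the brute-force optimum", {
  # two crossing constant-velocity spots plus one wanderer
  set.seed(21)
  frames <- 1:8
  xa <- 2 + 0.8 * (frames - 1); ya <- rep(5, 8)
  xb <- 8 - 0.8 * (frames - 1); yb <- rep(5.4, 8)
  xc <- rep(12, 8); yc <- 2 + 0.3 * (frames - 1)
  for (f in 2:8) {
    prev <- f - 1
    got <- oligocount:::match_frame(
      c(xa[prev], xb[prev], xc[prev]), c(ya[prev], yb[prev], yc[prev]),
      c(xa[f], xb[f], xc[f]), c(ya[f], yb[f], yc[f]), gate2 = 4)
    want <- brute_force_match(
      c(xa[prev], xb[prev], xc[prev]), c(ya[prev], yb[prev], yc[prev]),
      c(xa[f], xb[f], xc[f]), c(ya[f], yb[f], yc[f]), gate = 2)
    expect_equal(got, want)
  }
  # randomized small cases
  for (rep in 1:20) {
    np <- sample(1:4, 1); nc <- sample(1:4, 1)
    px <- runif(np, 0, 6); py <- runif(np, 0, 6)
    cx <- runif(nc, 0, 6); cy <- runif(nc, 0, 6)
    got <- oligocount:::match_frame(px, py, cx, cy, gate2 = 4)
    want <- brute_force_match(px, py, cx, cy, gate = 2)
    # both must be optimal; compare total costs (ties can differ in
    # assignment but not in cost)
    cost <- function(asg) {
      s <- 0
      for (i in seq_along(asg)) {
        if (is.na(asg[i])) s <- s + 2 * 4 * 1.0001
        else s <- s + (px[i] - cx[asg[i]])^2 + (py[i] - cy[asg[i]])^2
      }
      s
    }
    expect_equal(cost(got), cost(want), tolerance = 1e-9)
  }
})

test_that("trajectory selection keeps the boundary length", {
  trs <- list(mkdet(1:9, rep(1, 9), rep(1, 9)),
              mkdet(1:10, rep(2, 10), rep(2, 10)),
              mkdet(1:40, rep(3, 40), rep(3, 40)))
  trs <- lapply(trs, function(tr) { class(tr) <- c("trajectory", class(tr)); tr })
  kept <- select_trajectories(trs, 10)
  expect_length(kept, 2)
  expect_equal(vapply(kept, nrow, integer(1)), c(10, 40))
  expect_length(select_trajectories(list(), 10), 0)
})

test_that("start intensities are the integrated Gaussian volume", {
  tr <- mkdet(1:12, rep(1, 12), rep(1, 12), amplitude = c(7, rep(3, 11)))
  s <- start_intensities(list(tr))
  expect_equal(s, 2 * pi * 1^2 * 7)
  trs <- list(tr, mkdet(1:10, rep(2, 10), rep(2, 10), amplitude = 2))
  expect_length(start_intensities(trs), 2)
})
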