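#' Link per-frame detections into trajectories
#'
#' Frame-to-frame linking by optimal bipartite assignment minimizing
#' total squared displacement (gated at `max_disp_px`), followed by gap
#' closing: a track that ends at frame e is joined to a track that
#' starts at frame s when the number of missing frames s - e - 1 is
#' between 1 and `max_gap` and the displacement is within the diffusive
#' budget `max_disp_px * sqrt(gap + 1)`. Gap closing is greedy by
#' ascending displacement. The assignment is solved exactly: the gated
#' candidate graph is split into connected components and each component
#' is solved with the standard augmented cost matrix in which leaving a
#' track or a detection unmatched costs just over the gate, so any
#' within-gate match is preferred and the total squared displacement is
#' minimal.
#'
#' @param detections data.frame with columns `frame`, `x`, `y` (plus any
#'   others, carried along), sortable by frame.
#' @param max_gap maximum number of consecutive missing frames to close
#'   (default 4).
#' @param max_disp_px frame-to-frame displacement gate in pixels
#'   (default 2; the search radius for slowly moving spots).
#' @return A list of trajectories; each is a data.frame of the linked
#'   detection rows (class `trajectory`, frame strictly increasing).
#' @export
link_trajectories <- function(detections, max_gap = 4, max_disp_px = 2) {
  if (is.null(detections) || nrow(detections) == 0) return(list())
  stopifnot(all(c("frame", "x", "y") %in% names(detections)))
  if (max_gap < 0) stop("max_gap must be >= 0")
  if (max_disp_px <= 0) stop("max_disp_px must be > 0")
  det <- detections[order(detections$frame), , drop = FALSE]
  frames <- sort(unique(det$frame))
  gate2 <- max_disp_px^2

  tracks <- list()        # integer row indices into det, per track
  active <- integer(0)    # track ids whose last frame is prev_f
  prev_f <- NULL
  for (f in frames) {
    rows <- which(det$frame == f)
    if (is.null(prev_f) || f != prev_f + 1 || length(active) == 0) {
      new_ids <- length(tracks) + seq_along(rows)
      for (k in seq_along(rows)) tracks[[new_ids[k]]] <- rows[k]
      active <- new_ids
      prev_f <- f
      next
    }
    last_rows <- vapply(active, function(t) tracks[[t]][length(tracks[[t]])],
                        integer(1))
    res <- match_frame(det$x[last_rows], det$y[last_rows],
                       det$x[rows], det$y[rows], gate2)
    next_active <- integer(0)
    for (ti in seq_along(active)) {
      j <- res[ti]
      if (!is.na(j)) {
        tracks[[active[ti]]] <- c(tracks[[active[ti]]], rows[j])
        next_active <- c(next_active, active[ti])
      }
    }
    unmatched <- setdiff(seq_along(rows), res[!is.na(res)])
    for (j in unmatched) {
      tracks[[length(tracks) + 1]] <- rows[j]
      next_active <- c(next_active, length(tracks))
    }
    active <- next_active
    prev_f <- f
  }

  tracks <- close_gaps(tracks, det, max_gap, max_disp_px)

  lapply(tracks, function(r) {
    tr <- det[r, , drop = FALSE]
    rownames(tr) <- NULL
    class(tr) <- c("trajectory", class(tr))
    tr
  })
}

# optimal gated matching of previous positions (px, py) to current
# (cx, cy); returns, per previous point, the matched current index or NA
match_frame <- function(px, py, cx, cy, gate2) {
  np <- length(px); nc <- length(cx)
  d2 <- outer(px, cx, "-")^2 + outer(py, cy, "-")^2
  ok <- d2 <= gate2
  res <- rep(NA_integer_, np)
  if (!any(ok)) return(res)
  # connected components of the candidate bipartite graph
  comp_p <- rep(0L, np); comp_c <- rep(0L, nc)
  ncomp <- 0L
  for (i in seq_len(np)) {
    if (comp_p[i] > 0L || !any(ok[i, ])) next
    ncomp <- ncomp + 1L
    qp <- i
    while (length(qp) > 0) {
      comp_p[qp] <- ncomp
      qc <- which(colSums(ok[qp, , drop = FALSE]) > 0 & comp_c == 0L)
      if (length(qc) == 0) break
      comp_c[qc] <- ncomp
      qp <- which(rowSums(ok[, qc, drop = FALSE]) > 0 & comp_p == 0L)
    }
  }
  big <- 1e12
  for (cc in seq_len(ncomp)) {
    ip <- which(comp_p == cc); ic <- which(comp_c == cc)
    nt <- length(ip); nd <- length(ic)
    if (nt == 1L && nd == 1L) { res[ip] <- ic; next }
    sub <- d2[ip, ic, drop = FALSE]
    sub[sub > gate2] <- big
    sz <- nt + nd
    cm <- matrix(big, sz, sz)
    cm[seq_len(nt), seq_len(nd)] <- sub
    cm[cbind(seq_len(nt), nd + seq_len(nt))] <- gate2 * 1.0001
    cm[cbind(nt + seq_len(nd), seq_len(nd))] <- gate2 * 1.0001
    cm[nt + seq_len(nd), nd + seq_len(nt)] <- 0
    asg <- lap_solve(cm)
    for (t in seq_len(nt)) {
      j <- asg[t]
      if (j <= nd && sub[t, j] < big) res[ip[t]] <- ic[j]
    }
  }
  res
}

# greedy gap closing, ascending displacement; diffusive budget
close_gaps <- function(tracks, det, max_gap, max_disp_px) {
  n_tr <- length(tracks)
  if (n_tr < 2 || max_gap < 1) return(tracks)
  end_row <- vapply(tracks, function(r) r[length(r)], integer(1))
  start_row <- vapply(tracks, function(r) r[1], integer(1))
  ends_f <- det$frame[end_row]
  starts_f <- det$frame[start_row]
  ex <- det$x[end_row]; ey <- det$y[end_row]
  sx <- det$x[start_row]; sy <- det$y[start_row]
  ord_s <- order(starts_f)
  cand <- vector("list", n_tr)
  for (a in seq_len(n_tr)) {
    gaps <- starts_f - ends_f[a] - 1
    ok <- which(gaps >= 1 & gaps <= max_gap)
    ok <- ok[ok != a]
    if (length(ok) == 0) next
    disp <- sqrt((sx[ok] - ex[a])^2 + (sy[ok] - ey[a])^2)
    pass <- disp <= max_disp_px * sqrt(gaps[ok] + 1)
    if (any(pass))
      cand[[a]] <- data.frame(from = a, to = ok[pass], disp = disp[pass])
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0) return(tracks)
  cand <- cand[order(cand$disp), , drop = FALSE]
  root <- seq_len(n_tr)          # head track of the chain containing i
  find_root <- function(i) { while (root[i] != i) i <- root[i]; i }
  tail_of <- seq_len(n_tr)       # tail track of the chain headed at i
  used_to <- logical(n_tr)
  closed_from <- logical(n_tr)
  for (k in seq_len(nrow(cand))) {
    a <- cand$from[k]; b <- cand$to[k]
    if (used_to[b] || closed_from[a]) next
    ra <- find_root(a)
    if (ra == find_root(b)) next           # cycle
    if (tail_of[ra] != a) next             # chain already extended past a
    tracks[[ra]] <- c(tracks[[ra]], tracks[[b]])
    root[b] <- ra
    tail_of[ra] <- tail_of[b]
    used_to[b] <- TRUE
    closed_from[a] <- TRUE
  }
  tracks[root == seq_len(n_tr)]
}

#' Keep trajectories with at least `min_length` detected frames
#'
#' Length counts frames with detections; closed gaps do not count.
#'
#' @param trajectories list of trajectories from [link_trajectories()].
#' @param min_length inclusive minimum number of detected frames
#'   (default 10).
#' @return The filtered list.
#' @export
select_trajectories <- function(trajectories, min_length = 10) {
  Filter(function(tr) nrow(tr) >= min_length, trajectories)
}

#' Integrated spot intensities at trajectory start
#'
#' One sample per trajectory: the integrated Gaussian volume
#' 2 pi sigma^2 A of the fitted spot at the trajectory's first detected
#' frame, in counts.
#'
#' @param trajectories list of trajectories with `amplitude` and `sigma`
#'   columns.
#' @return Numeric vector of intensity samples.
#' @export
start_intensities <- function(trajectories) {
  vapply(trajectories, function(tr) {
    if (!all(c("amplitude", "sigma") %in% names(tr)))
      stop("trajectories must carry fitted amplitude and sigma")
    2 * pi * tr$sigma[1]^2 * tr$amplitude[1]
  }, numeric(1))
}
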