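# Shared fixtures and independent oracles.

# Random long-form detection trace: mixture of empty frames, single- and
# multi-box frames, with nondecreasing timestamps.
make_random_trace <- function(n = 20, seed = 1, p_empty = 0.2,
                              frame_rate = 15) {
  set.seed(seed)
  rows <- lapply(seq_len(n) - 1L, function(f) {
    t <- f / frame_rate
    if (stats::runif(1) < p_empty) {
      return(data.frame(frame = f, t = t, label = NA_character_,
                        cx = NA_real_, cy = NA_real_, w = NA_real_,
                        h = NA_real_, conf = NA_real_))
    }
    k <- sample(1:2, 1)
    data.frame(frame = f, t = t,
               label = sample(c("head", "trunk"), k),
               cx = stats::runif(k, 0, 640), cy = stats::runif(k, 0, 360),
               w = stats::runif(k, 10, 80), h = stats::runif(k, 10, 120),
               conf = stats::runif(k, 0.5, 1))
  })
  detection_trace(do.call(rbind, rows), frame_rate = frame_rate)
}

# Frame-by-frame reference for classify_trace: literal carry of the last
# observed position through classify_status.
oracle_classify <- function(positions, p0, epsilon) {
  last <- NULL
  vapply(positions, function(cur) {
    s <- classify_status(last, cur, p0, epsilon)
    if (!is.null(cur)) last <<- cur
    s
  }, integer(1))
}

# Brute-force list-slicing reference for the SCQ: keep every status since
# the last flush, slice the last M, count per queue. Returns per-step
# occupancies and events.
oracle_scq <- function(status, M, L) {
  qmap <- c(`1` = 1L, `0` = 2L, `-1` = 3L, `-2` = 4L)
  q <- unname(qmap[as.character(status)])
  n <- length(q)
  occ <- matrix(0L, n, 4L)
  ev <- integer(n)
  buf <- integer(0)
  for (i in seq_len(n)) {
    buf <- c(buf, q[i])
    win <- buf[max(1L, length(buf) - M + 1L):length(buf)]
    sizes <- tabulate(win, 4L)
    if (sizes[q[i]] == L[q[i]]) {
      ev[i] <- q[i]
      buf <- integer(0)
      sizes <- integer(4L)
    }
    occ[i, ] <- sizes
  }
  list(occupancy = occ, event_queue = ev)
}

# Uniform status stream helper
status_stream <- function(status, frame_rate = 15) {
  n <- length(status)
  data.frame(frame = seq_len(n) - 1L, t = (seq_len(n) - 1L) / frame_rate,
             status = as.integer(status))
}
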