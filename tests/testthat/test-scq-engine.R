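test_that("configuration arithmetic and constraints", {
  cfg <- scq_config(R = 15, T = 1, L = c(15, 15, 15, 15))
  expect_identical(cfg$M, 15L)
  expect_identical(scq_config(R = 30, T = 0.5, L = c(15, 15, 15, 15))$M, 15L)
  # window larger than total capacity
  expect_error(scq_config(R = 15, T = 2, L = c(5, 5, 5, 5)),
               "total queue capacity")
  # a queue longer than the window could never fill
  expect_error(scq_config(R = 15, T = 1, L = c(20, 5, 5, 5)),
               "longest queue")
  expect_error(scq_config(R = 0, T = 1), "positive")
  expect_error(scq_config(L = c(15, 15, 15, 0)), "at least 1")
})

test_that("single steps enqueue, recognize and flush", {
  cfg <- scq_config(R = 15, T = 1, L = c(15, 15, 15, 15))
  st <- scq_state(cfg)
  # one missing-box status: queue 4 holds it, no event
  out <- scq_step(st, list(frame = 0L, t = 0, status = -2L), cfg)
  expect_null(out$event)
  expect_equal(scq_queue_sizes(out$state), c(0L, 0L, 0L, 1L))
  expect_error(scq_step(st, list(frame = 0L, t = 0, status = 7L), cfg),
               "unknown status")

  # 15 consecutive +1: off_bed exactly at the 15th sample, then empty
  st <- scq_state(cfg)
  for (i in 0:14) {
    out <- scq_step(st, list(frame = i, t = i / 15, status = 1L), cfg)
    st <- out$state
    if (i < 14) expect_null(out$event)
  }
  expect_equal(out$event$behavior, "off_bed")
  expect_equal(out$event$frame, 14L)
  expect_equal(scq_queue_sizes(st), c(0L, 0L, 0L, 0L))
})

test_that("run_scq equals the fold of scq_step", {
  cfg <- scq_config(R = 15, T = 1, L = c(15, 15, 15, 15))
  set.seed(7)
  status <- sample(c(1L, 0L, -1L, -2L), 200, replace = TRUE,
                   prob = c(0.3, 0.4, 0.2, 0.1))
  stream <- status_stream(status)
  events <- run_scq(stream, cfg)
  st <- scq_state(cfg)
  folded <- list()
  for (i in seq_len(nrow(stream))) {
    out <- scq_step(st, stream[i, ], cfg)
    st <- out$state
    if (!is.null(out$event)) folded[[length(folded) + 1L]] <- out$event
  }
  folded <- if (length(folded)) do.call(rbind, folded) else events[0, ]
  expect_equal(events$behavior, folded$behavior)
  expect_equal(events$frame, folded$frame)
})

test_that("queue occupancies match the sliding-window oracle", {
  set.seed(11)
  for (rep in 1:300) {
    L <- sample(3:8, 4, replace = TRUE)
    M <- sample(max(L):min(sum(L), max(L) + 5L), 1)
    cfg <- scq_config(R = M, T = 1, L = L)
    status <- sample(c(1L, 0L, -1L, -2L), sample(20:60, 1), replace = TRUE)
    events <- run_scq(status_stream(status), cfg, record_occupancy = TRUE)
    ref <- oracle_scq(status, M, L)
    expect_identical(attr(events, "occupancy"), ref$occupancy)
    expect_identical(events$frame, which(ref$event_queue > 0L) - 1L)
    expect_identical(events$behavior, scq_behaviors()[ref$event_queue[ref$event_queue > 0L]])
  }
})

test_that("known streams recognize at the documented frames", {
  cfg <- scq_config(R = 15, T = 1, L = c(15, 15, 15, 15))
  # 15 neutral then 15 away
  ev <- run_scq(status_stream(c(rep(0L, 15), rep(1L, 15))), cfg)
  expect_equal(ev$behavior, c("on_bed", "off_bed"))
  expect_equal(ev$frame, c(14L, 29L))
  # all missing
  ev2 <- run_scq(status_stream(rep(-2L, 15)), cfg)
  expect_equal(ev2$behavior, "nobody")
  expect_equal(ev2$frame, 14L)
  # alternating +1/0 never fills any length-15 queue under a 15-window
  ev3 <- run_scq(status_stream(rep(c(1L, 0L), 30)), cfg)
  expect_equal(nrow(ev3), 0L)
  # empty stream
  expect_equal(nrow(run_scq(status_stream(integer(0)), cfg)), 0L)
})

test_that("pure-window recognition satisfies the per-behavior sum forms", {
  # with M = L_j the queue fills iff the last M statuses are uniform, which
  # makes the corresponding sum identity hold exactly
  cfg <- scq_config(R = 15, T = 1, L = c(15, 15, 15, 15))
  set.seed(3)
  for (rep in 1:50) {
    status <- sample(c(1L, 0L, -1L, -2L), 120, replace = TRUE,
                     prob = c(0.35, 0.35, 0.15, 0.15))
    # splice uniform runs in so events actually occur
    run_at <- sample(1:90, 2)
    for (r in run_at)
      status[r:(r + 15)] <- sample(c(1L, 0L, -1L, -2L), 1)
    ev <- run_scq(status_stream(status), cfg)
    # reconstruct flush boundaries to extract each event's window
    last_flush <- 0L
    for (k in seq_len(nrow(ev))) {
      i <- ev$frame[k] + 1L
      since <- status[(last_flush + 1L):i]
      win <- since[max(1L, length(since) - cfg$M + 1L):length(since)]
      expect_equal(length(win), 15L)
      ok <- switch(ev$behavior[k],
                   off_bed = sum(win) == cfg$L[1],
                   on_bed = sum(1 - win) == cfg$L[2],
                   return = sum(-win) == cfg$L[3],
                   nobody = sum(-win / 2) == cfg$L[4])
      expect_true(ok)
      last_flush <- i
    }
  }
})

test_that("uniform streams have minimum latency L_j and re-emit thereafter", {
  cfg <- scq_config(R = 15, T = 1, L = c(15, 10, 15, 15))
  ev <- run_scq(status_stream(rep(0L, 45)), cfg)
  expect_equal(ev$frame, c(9L, 19L, 29L, 39L))   # every L_2 = 10 statuses
  expect_true(all(ev$behavior == "on_bed"))
  # never earlier than L_j from an empty queue system
  for (j in 1:4) {
    s <- c(1L, 0L, -1L, -2L)[j]
    ev_j <- run_scq(status_stream(rep(s, cfg$L[j])), cfg)
    expect_equal(nrow(ev_j), 1L)
    expect_equal(ev_j$frame, cfg$L[j] - 1L)
    short <- run_scq(status_stream(rep(s, cfg$L[j] - 1L)), cfg)
    expect_equal(nrow(short), 0L)
  }
})

test_that("behavior index trace is the documented step function", {
  ev <- data.frame(behavior = "off_bed", frame = 10L, t = 10 / 15)
  idx <- behavior_index_trace(ev, n_frames = 20)
  expect_equal(idx$index, c(rep(0L, 10), rep(1L, 10)))
  expect_equal(behavior_index_trace(ev[0, ], n_frames = 5)$index, rep(0L, 5))
  ev3 <- data.frame(behavior = c("off_bed", "return", "on_bed"),
                    frame = c(10L, 15L, 18L), t = c(10, 15, 18) / 15)
  idx3 <- behavior_index_trace(ev3, n_frames = 22)
  expect_equal(idx3$index,
               c(rep(0L, 10), rep(1L, 5), rep(-1L, 3), rep(0L, 4)))
  expect_error(behavior_index_trace(ev, n_frames = 10), "beyond")
  expect_equal(behavior_index(c("on_bed", "off_bed", "return", "nobody")),
               c(0L, 1L, -1L, 2L))
})
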