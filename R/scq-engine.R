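# Stage 3: Status Classification Queueing (SCQ).
#
# Four output queues buffer the per-frame statuses: queue 1 collects +1
# (moving away -> "off bed"), queue 2 collects 0 (neutral -> "on bed"),
# queue 3 collects -1 (moving toward -> "return"), queue 4 collects -2
# (missing box -> "nobody"). At most M statuses are buffered in total;
# when a new status arrives with the buffer full, the controller drops the
# globally oldest buffered status from the head of its queue, so the buffer
# is always the sliding window of the last min(M, received-since-flush)
# statuses. The moment a queue reaches its configured length L_j, the
# behavior mapped to it is recognized and every queue is emptied.
#
# Because each queue holds a single status value, the full SCQ state is the
# arrival-ordered sequence of queue ids; per-queue occupancy is derived
# from it. scq_step() exposes the single-status transition; run_scq() is
# the (equivalent, loop-inlined) fold over a stream.

.status_queue <- function(status) {
  q <- integer(length(status))
  q[status == 1L] <- 1L
  q[status == 0L] <- 2L
  q[status == -1L] <- 3L
  q[status == -2L] <- 4L
  if (any(q == 0L))
    stop("unknown status value(s): ",
         paste(unique(status[q == 0L]), collapse = ", "),
         " (expected 1, 0, -1 or -2)", call. = FALSE)
  q
}

#' SCQ configuration
#'
#' Builds and validates the queueing parameters. The buffered-status window
#' is \code{M = round(R * T)} and must satisfy both
#' \code{M <= L1 + L2 + L3 + L4} (the queues can hold a full window) and
#' \code{M >= max(L)} (every queue can fill inside one window).
#'
#' @param R Frame rate in fps (one status arrives per frame).
#' @param T Status-window time slot in seconds.
#' @param L Integer vector of the four queue lengths, in queue order
#'   \code{(off_bed, on_bed, return, nobody)}. A queue's length is its
#'   recognition sensitivity: behavior j is declared after L_j supporting
#'   statuses within the window, so smaller L_j means earlier notification.
#' @return Object of class \code{"scq_config"} with fields
#'   \code{R, T, M, L}.
#' @export
#' @examples
#' scq_config(R = 15, T = 1, L = c(15, 15, 15, 15))  # M = 15
scq_config <- function(R = 15, T = 1, L = c(15L, 15L, 15L, 15L)) {
  if (!is.numeric(R) || length(R) != 1L || R <= 0)
    stop("R must be a positive frame rate", call. = FALSE)
  if (!is.numeric(T) || length(T) != 1L || T <= 0)
    stop("T must be a positive time slot in seconds", call. = FALSE)
  if (length(L) != 4L || any(!is.finite(L)) || any(L < 1))
    stop("L must give four queue lengths, each at least 1", call. = FALSE)
  L <- as.integer(round(L))
  M <- max(1L, as.integer(round(R * T)))
  if (M > sum(L))
    stop(sprintf("window M = %d exceeds total queue capacity sum(L) = %d",
                 M, sum(L)), call. = FALSE)
  if (M < max(L))
    stop(sprintf("window M = %d is smaller than the longest queue max(L) = %d (that queue could never fill)",
                 M, max(L)), call. = FALSE)
  structure(list(R = R, T = T, M = M, L = L), class = "scq_config")
}

#' @export
print.scq_config <- function(x, ...) {
  cat(sprintf("SCQ config: R = %g fps, T = %g s, window M = %d\n", x$R, x$T, x$M))
  cat(sprintf("  queue lengths: off_bed %d, on_bed %d, return %d, nobody %d\n",
              x$L[1], x$L[2], x$L[3], x$L[4]))
  invisible(x)
}

#' Empty SCQ state
#'
#' @param config An \code{\link{scq_config}} (kept for interface symmetry;
#'   the empty state does not depend on it).
#' @return Object of class \code{"scq_state"}: arrival-ordered queue ids of
#'   the buffered statuses plus a since-last-flush counter.
#' @export
scq_state <- function(config = scq_config()) {
  structure(list(order = integer(0), since_flush = 0L), class = "scq_state")
}

#' Queue occupancies of an SCQ state
#' @param state An \code{scq_state}.
#' @return Integer vector of length 4 (sizes of queues 1..4).
#' @export
scq_queue_sizes <- function(state) tabulate(state$order, nbins = 4L)

#' Advance the SCQ by one status
#'
#' One controller step: if the buffer already holds M statuses, the globally
#' oldest one is dropped from the head of its queue; the incoming status is
#' enqueued at the tail of its queue; if that queue now holds L_j statuses,
#' the behavior mapped to it is recognized, stamped with the completing
#' sample's frame and time, and all queues are flushed.
#'
#' @param state An \code{\link{scq_state}}.
#' @param sample List or one-row data frame with fields
#'   \code{frame}, \code{t}, \code{status}.
#' @param config An \code{\link{scq_config}}.
#' @return List with elements \code{state} (the new state) and \code{event}
#'   (\code{NULL}, or a one-row data frame \code{behavior, frame, t}).
#' @export
scq_step <- function(state, sample, config) {
  stopifnot(inherits(state, "scq_state"), inherits(config, "scq_config"))
  q <- .status_queue(as.integer(sample$status))
  ord <- state$order
  if (length(ord) == config$M) ord <- ord[-1L]  # evict globally oldest
  ord <- c(ord, q)
  event <- NULL
  if (sum(ord == q) == config$L[q]) {
    event <- data.frame(behavior = scq_behaviors()[q],
                        frame = as.integer(sample$frame),
                        t = as.numeric(sample$t),
                        stringsAsFactors = FALSE)
    ord <- integer(0)
    since <- 0L
  } else {
    since <- state$since_flush + 1L
  }
  list(state = structure(list(order = ord, since_flush = since),
                         class = "scq_state"),
       event = event)
}

#' Run the SCQ over a status stream
#'
#' Folds \code{\link{scq_step}} from the empty state over an ordered status
#' stream. Events carry the frame/time of the sample that completed its
#' queue; a sustained uniform stream re-emits its behavior every L_j
#' statuses (there is no refractory period; see the \code{debounce}
#' argument of \code{\link{detect_behaviors}} to suppress consecutive
#' duplicates).
#'
#' @param statuses Data frame with columns \code{frame, t, status} as
#'   produced by \code{\link{classify_trace}}.
#' @param config An \code{\link{scq_config}}.
#' @param record_occupancy If \code{TRUE}, attach an \code{"occupancy"}
#'   attribute: an n x 4 integer matrix of post-step queue sizes, used for
#'   diagnostics and window-equivalence checks.
#' @return Data frame of events with columns \code{behavior, frame, t}
#'   (zero rows when nothing is recognized).
#' @export
run_scq <- function(statuses, config = scq_config(), record_occupancy = FALSE) {
  stopifnot(inherits(config, "scq_config"))
  n <- nrow(statuses)
  q <- if (n) .status_queue(as.integer(statuses$status)) else integer(0)
  M <- config$M
  L <- config$L
  buf <- integer(M)        # arrival-ordered queue ids
  len <- 0L
  sizes <- c(0L, 0L, 0L, 0L)
  ev_behavior <- integer(n)  # queue id per event, 0 = none
  occ <- if (record_occupancy) matrix(0L, n, 4L) else NULL
  for (i in seq_len(n)) {
    if (len == M) {                      # evict globally oldest
      h <- buf[1L]
      sizes[h] <- sizes[h] - 1L
      buf[seq_len(len - 1L)] <- buf[2L:len]
      len <- len - 1L
    }
    qi <- q[i]
    len <- len + 1L
    buf[len] <- qi
    sizes[qi] <- sizes[qi] + 1L
    if (sizes[qi] == L[qi]) {            # recognize and flush
      ev_behavior[i] <- qi
      len <- 0L
      sizes <- c(0L, 0L, 0L, 0L)
    }
    if (record_occupancy) occ[i, ] <- sizes
  }
  hit <- which(ev_behavior > 0L)
  events <- data.frame(behavior = scq_behaviors()[ev_behavior[hit]],
                       frame = as.integer(statuses$frame[hit]),
                       t = as.numeric(statuses$t[hit]),
                       stringsAsFactors = FALSE)
  if (record_occupancy) attr(events, "occupancy") <- occ
  events
}

#' Behavior index codes
#'
#' Plotting/encoding convention for recognized behaviors:
#' on bed = 0, off bed = 1, return = -1, nobody = 2.
#'
#' @param behavior Character vector of behavior names.
#' @return Integer vector of indices.
#' @export
behavior_index <- function(behavior) {
  codes <- c(off_bed = 1L, on_bed = 0L, return = -1L, nobody = 2L)
  bad <- setdiff(behavior, names(codes))
  if (length(bad))
    stop("unknown behavior(s): ", paste(bad, collapse = ", "), call. = FALSE)
  unname(codes[behavior])
}

#' Per-frame behavior-index trace
#'
#' Expands an event sequence into a step function over frames: each frame
#' carries the index of the most recently recognized behavior; frames before
#' the first event carry \code{initial_index} (default 0 = on bed, the
#' resting state of a monitored patient).
#'
#' @param events Event data frame (\code{behavior, frame, t}), ordered by
#'   frame.
#' @param n_frames Number of frames to cover.
#' @param frame_rate Frame rate used to derive timestamps.
#' @param initial_index Index assigned before the first event.
#' @return Data frame with columns \code{frame, t, index}.
#' @export
behavior_index_trace <- function(events, n_frames, frame_rate = 15,
                                 initial_index = 0L) {
  n_frames <- as.integer(n_frames)
  if (nrow(events) && any(events$frame >= n_frames))
    stop("event frame beyond the requested trace length", call. = FALSE)
  idx <- rep(as.integer(initial_index), n_frames)
  if (nrow(events)) {
    ev <- events[order(events$frame), , drop = FALSE]
    code <- behavior_index(ev$behavior)
    for (k in seq_len(nrow(ev)))
      idx[(ev$frame[k] + 1L):n_frames] <- code[k]
  }
  data.frame(frame = seq_len(n_frames) - 1L,
             t = (seq_len(n_frames) - 1L) / frame_rate,
             index = idx)
}
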