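# Seeded simulator of narrow-field-of-view detection traces.
#
# Real bedside footage with a narrow field of view shows four phenomena the
# downstream stages must survive: bed-anchored jitter while the patient lies
# still (including larger turning-over excursions), roughly monotone
# transits when exiting or returning, runs of frames with no detection at
# all (dropouts), and frames where the box flickers in and out. The
# generator scripts a sequence of behavior segments and renders a detection
# trace with exactly these features, plus the matching ground-truth clip
# file, so the whole pipeline is testable without a camera.

#' Script a simulation scenario
#'
#' @param segments Data frame with columns \code{behavior} (one of
#'   \code{off_bed, on_bed, return, nobody}) and \code{duration_s} (seconds,
#'   positive).
#' @param R Frame rate in fps.
#' @param image_size \code{c(width, height)} of the simulated image in
#'   pixels; all positions are clamped inside it.
#' @param bed_anchor Pixel position of the tracked body part while on the
#'   bed; transits start or end here.
#' @param exit_anchor Pixel position the body moves toward when exiting.
#' @param jitter_sigma Standard deviation (pixels) of the Gaussian jitter
#'   added to every detected center.
#' @param speed Transit speed in pixels per second for exit and return
#'   segments; progress along the bed--exit line is clamped at the anchors.
#' @param dropouts Data frame (\code{start_frame, length_frames}) of windows
#'   in which detections are blanked (only inside non-nobody segments).
#' @param flickers Data frame (\code{start_frame, length_frames}) of windows
#'   in which detections alternate present/absent frame by frame.
#' @param turning_bursts If \code{TRUE}, each on-bed segment gets one short
#'   window of amplified jitter emulating the patient turning over; the
#'   excursion is capped at \code{burst_cap} pixels so it stays below the
#'   default movement threshold.
#' @param burst_cap Maximum turning-burst excursion in pixels.
#' @param clip_breaks Integer frame positions at which the ground-truth clip
#'   file inserts an extra boundary without a behavior change (used to split
#'   a long segment into several evaluation clips).
#' @param seed Integer seed; generation is fully deterministic given the
#'   scenario.
#' @return Object of class \code{"scq_scenario"}.
#' @export
scenario <- function(segments,
                     R = 15,
                     image_size = c(640, 360),
                     bed_anchor = c(160, 240),
                     exit_anchor = c(600, 60),
                     jitter_sigma = 1,
                     speed = 200,
                     dropouts = NULL,
                     flickers = NULL,
                     turning_bursts = TRUE,
                     burst_cap = 4,
                     clip_breaks = integer(0),
                     seed = 1L) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  stopifnot(all(c("behavior", "duration_s") %in% names(segments)))
  bad <- setdiff(segments$behavior, scq_behaviors())
  if (length(bad))
    stop("unknown behavior(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(segments$duration_s <= 0))
    stop("segment durations must be positive", call. = FALSE)
  if (R <= 0) stop("R must be positive", call. = FALSE)
  if (speed <= 0) stop("speed must be positive", call. = FALSE)
  if (jitter_sigma < 0) stop("jitter_sigma must be nonnegative", call. = FALSE)
  inside <- function(p) all(p >= 0) && p[1] <= image_size[1] && p[2] <= image_size[2]
  if (!inside(bed_anchor) || !inside(exit_anchor))
    stop("anchors must lie inside the image", call. = FALSE)
  norm_win <- function(w) {
    if (is.null(w) || NROW(w) == 0L)
      return(data.frame(start_frame = integer(0), length_frames = integer(0)))
    w <- as.data.frame(w)
    stopifnot(all(c("start_frame", "length_frames") %in% names(w)))
    w$start_frame <- as.integer(w$start_frame)
    w$length_frames <- as.integer(w$length_frames)
    if (any(w$start_frame < 0L) || any(w$length_frames < 1L))
      stop("failure windows need start_frame >= 0 and length_frames >= 1",
           call. = FALSE)
    w
  }
  sc <- structure(list(segments = segments[c("behavior", "duration_s")],
                       R = R, image_size = as.numeric(image_size),
                       bed_anchor = as.numeric(bed_anchor),
                       exit_anchor = as.numeric(exit_anchor),
                       jitter_sigma = jitter_sigma, speed = speed,
                       dropouts = norm_win(dropouts),
                       flickers = norm_win(flickers),
                       turning_bursts = isTRUE(turning_bursts),
                       burst_cap = burst_cap,
                       clip_breaks = as.integer(clip_breaks),
                       seed = as.integer(seed)),
                  class = "scq_scenario")
  nf <- sum(.segment_frames(sc))
  w <- rbind(sc$dropouts, sc$flickers)
  if (nrow(w) && any(w$start_frame + w$length_frames > nf))
    stop("failure windows must lie within the trace", call. = FALSE)
  if (length(sc$clip_breaks) &&
      (any(sc$clip_breaks <= 0L) || any(sc$clip_breaks >= nf)))
    stop("clip_breaks must be strictly inside the trace", call. = FALSE)
  sc
}

.segment_frames <- function(sc) {
  vapply(sc$segments$duration_s,
         function(d) window_frame_count(d, sc$R), integer(1))
}

#' @export
print.scq_scenario <- function(x, ...) {
  nf <- sum(.segment_frames(x))
  cat(sprintf("Scenario: %d segments, %.1f s (%d frames) at %g fps, seed %d\n",
              nrow(x$segments), sum(x$segments$duration_s), nf, x$R, x$seed))
  cat(sprintf("  %d dropout window(s), %d flicker window(s)\n",
              nrow(x$dropouts), nrow(x$flickers)))
  invisible(x)
}

# run expr with a private, seeded RNG stream; global state is untouched
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a detection trace and ground truth from a scenario
#'
#' Renders each scripted segment: \code{on_bed} frames jitter around the bed
#' anchor with label \code{"head"}; \code{off_bed} frames move from the bed
#' anchor toward the exit anchor at the scenario speed, the label switching
#' from \code{"head"} to \code{"trunk"} at the segment midpoint (the
#' detector sees the head while the patient sits up, then the trunk while
#' walking); \code{return} is the reverse transit; \code{nobody} frames are
#' empty. Dropout windows blank detections inside non-nobody segments and
#' flicker windows remove every other frame. Head boxes are 40x40 px, trunk
#' boxes 80x120 px; confidences are Uniform(0.6, 0.99). Deterministic for a
#' fixed scenario (seed included).
#'
#' @param sc An \code{\link{scenario}}.
#' @return Object of class \code{"generated_case"}: list with elements
#'   \code{trace} (a \code{\link{detection_trace}}), \code{truth}
#'   (\code{\link{behavior_segments}} tiling the frame range) and
#'   \code{scenario}.
#' @export
generate <- function(sc) {
  stopifnot(inherits(sc, "scq_scenario"))
  nseg <- .segment_frames(sc)
  nf <- sum(nseg)
  seg_end <- cumsum(nseg)
  seg_start <- seg_end - nseg            # 0-based segment starts
  .with_seed(sc$seed, {
    cx <- rep(NA_real_, nf); cy <- rep(NA_real_, nf)
    label <- rep(NA_character_, nf)
    present <- logical(nf)
    dir <- sc$exit_anchor - sc$bed_anchor
    path_len <- sqrt(sum(dir^2))
    u <- dir / path_len
    for (s in seq_len(nrow(sc$segments))) {
      beh <- sc$segments$behavior[s]
      k <- nseg[s]
      if (k == 0L) next
      i <- seg_start[s] + seq_len(k)     # 1-based row indices
      tloc <- (seq_len(k) - 0.5) / sc$R  # seconds into the segment
      if (beh == "nobody") next
      present[i] <- TRUE
      if (beh == "on_bed") {
        base_x <- rep(sc$bed_anchor[1], k)
        base_y <- rep(sc$bed_anchor[2], k)
        label[i] <- "head"
        jx <- stats::rnorm(k, 0, sc$jitter_sigma)
        jy <- stats::rnorm(k, 0, sc$jitter_sigma)
        if (sc$turning_bursts && k >= 8L) {
          # one short turning-over burst per on-bed segment, bounded excursion
          blen <- min(k, sample(5:8, 1L))
          bstart <- sample(seq_len(k - blen + 1L), 1L)
          bi <- bstart:(bstart + blen - 1L)
          jx[bi] <- pmax(pmin(3 * jx[bi], sc$burst_cap), -sc$burst_cap)
          jy[bi] <- pmax(pmin(3 * jy[bi], sc$burst_cap), -sc$burst_cap)
        }
        cx[i] <- base_x + jx
        cy[i] <- base_y + jy
      } else {
        prog <- pmin(sc$speed * tloc, path_len)
        if (beh == "return") prog <- path_len - prog
        jx <- stats::rnorm(k, 0, sc$jitter_sigma)
        jy <- stats::rnorm(k, 0, sc$jitter_sigma)
        cx[i] <- sc$bed_anchor[1] + prog * u[1] + jx
        cy[i] <- sc$bed_anchor[2] + prog * u[2] + jy
        half <- ceiling(k / 2)
        # exiting: head first then trunk; returning: the mirror image
        if (beh == "off_bed")
          label[i] <- c(rep("head", half), rep("trunk", k - half))
        else
          label[i] <- c(rep("trunk", half), rep("head", k - half))
      }
    }
    # detection failures
    drop_frame <- function(w) {
      if (!nrow(w)) return(integer(0))
      unlist(lapply(seq_len(nrow(w)), function(j)
        w$start_frame[j] + seq_len(w$length_frames[j]) - 1L))
    }
    gone <- drop_frame(sc$dropouts)
    fl <- sc$flickers
    if (nrow(fl))
      gone <- c(gone, unlist(lapply(seq_len(nrow(fl)), function(j) {
        win <- fl$start_frame[j] + seq_len(fl$length_frames[j]) - 1L
        win[seq_along(win) %% 2L == 1L]   # every other frame vanishes
      })))
    if (length(gone)) present[gone + 1L] <- FALSE
    present[is.na(cx)] <- FALSE          # nobody segments stay empty
    cx[!present] <- NA_real_; cy[!present] <- NA_real_
    label[!present] <- NA_character_
    cx <- pmin(pmax(cx, 0), sc$image_size[1])
    cy <- pmin(pmax(cy, 0), sc$image_size[2])
    conf <- stats::runif(nf, 0.6, 0.99)

    w <- ifelse(label == "head", 40, 80)
    h <- ifelse(label == "head", 40, 120)
    frames <- data.frame(frame = seq_len(nf) - 1L,
                         t = (seq_len(nf) - 1L) / sc$R,
                         label = label, cx = cx, cy = cy, w = w, h = h,
                         conf = ifelse(present, conf, NA_real_),
                         stringsAsFactors = FALSE)
    trace <- detection_trace(frames, frame_rate = sc$R)

    truth <- data.frame(behavior = sc$segments$behavior,
                        start_frame = as.integer(seg_start),
                        end_frame = as.integer(seg_end - 1L),
                        stringsAsFactors = FALSE)
    for (b in sort(sc$clip_breaks)) {
      j <- which(truth$start_frame < b & truth$end_frame >= b)
      truth <- rbind(truth[seq_len(j - 1L), ],
                     data.frame(behavior = truth$behavior[j],
                                start_frame = truth$start_frame[j],
                                end_frame = b - 1L),
                     data.frame(behavior = truth$behavior[j],
                                start_frame = b,
                                end_frame = truth$end_frame[j]),
                     truth[-seq_len(j), ])
    }
    structure(list(trace = trace, truth = behavior_segments(truth),
                   scenario = sc),
              class = "generated_case")
  })
}

#' @export
print.generated_case <- function(x, ...) {
  cat("Generated case\n  ")
  print(x$trace)
  cat(sprintf("  truth: %d clips (%s)\n", nrow(x$truth),
              paste(sprintf("%s x%d", names(table(x$truth$behavior)),
                            as.integer(table(x$truth$behavior))),
                    collapse = ", ")))
  invisible(x)
}

#' Reference ward scenario
#'
#' The scripted sequence used throughout the package's evaluation: the
#' patient lies on the bed, exits, is absent, returns -- twice -- and ends
#' lying on the bed, i.e. nine behavior segments
#' \code{on_bed, off_bed, nobody, return} (x2) \code{, on_bed}. The long
#' initial on-bed period is divided into two ground-truth clips, so one
#' sequence contributes 4 on-bed, 2 off-bed, 2 return and 2 nobody clips to
#' clip-based evaluation. The \code{horizontal} camera profile uses the full
#' across-the-image transit and, unless \code{clean}, dropout windows inside
#' the on-bed segments; the \code{vertical} profile has a shorter transit
#' (narrower view) and additionally flicker windows, emulating the abrupt
#' appear/disappear events such footage shows.
#'
#' @param profile \code{"horizontal"} or \code{"vertical"} camera angle
#'   profile.
#' @param seed Integer seed (drives jitter and failure-window placement).
#' @param clean If \code{TRUE}, no dropout or flicker windows are injected.
#' @return An \code{\link{scenario}}.
#' @export
ward_scenario <- function(profile = c("horizontal", "vertical"), seed = 1L,
                          clean = FALSE) {
  profile <- match.arg(profile)
  R <- 15
  behaviors <- c("on_bed", "off_bed", "nobody", "return",
                 "on_bed", "off_bed", "nobody", "return", "on_bed")
  durations <- if (profile == "horizontal")
    c(6, 3, 2, 3, 4, 3, 2, 3, 4) else c(6, 2, 2, 2, 4, 2, 2, 2, 5)
  exit_anchor <- if (profile == "horizontal") c(600, 60) else c(400, 80)
  segs <- data.frame(behavior = behaviors, duration_s = durations)
  nseg <- round(durations * R)
  seg_start <- cumsum(nseg) - nseg
  on_bed_segs <- which(behaviors == "on_bed")
  dropouts <- NULL
  flickers <- NULL
  if (!clean) {
    fail <- .with_seed(seed + 1000L, {
      # one dropout per on-bed segment, in its middle third so every clip
      # keeps an uninterrupted stretch long enough to recognize
      d <- do.call(rbind, lapply(on_bed_segs, function(s) {
        len <- sample(5:10, 1L)
        third <- nseg[s] %/% 3L
        start <- seg_start[s] + third + sample.int(max(1L, third - len), 1L) - 1L
        data.frame(start_frame = start, length_frames = len)
      }))
      f <- if (profile == "vertical") {
        # extra flicker windows in the later on-bed segments
        do.call(rbind, lapply(on_bed_segs[-1L], function(s) {
          len <- sample(6:8, 1L)
          start <- seg_start[s] + (2L * nseg[s]) %/% 3L +
            sample.int(max(1L, nseg[s] %/% 3L - len), 1L) - 1L
          data.frame(start_frame = start, length_frames = len)
        }))
      }
      list(dropouts = d, flickers = f)
    })
    dropouts <- fail$dropouts
    flickers <- fail$flickers
  }
  scenario(segs, R = R, exit_anchor = exit_anchor,
           dropouts = dropouts, flickers = flickers,
           clip_breaks = seg_start[2L] %/% 2L,  # split initial on-bed in two
           seed = seed)
}

#' Classifier configuration matched to a scenario
#'
#' Convenience wrapper: a classifier whose reference position P0 is the
#' scenario's bed anchor, so distance to P0 is distance from the bed and a
#' transit changes it by the full per-frame step.
#'
#' @param sc An \code{\link{scenario}}.
#' @param epsilon Movement threshold in pixels.
#' @return A \code{\link{classifier_config}}.
#' @export
scenario_classifier <- function(sc, epsilon = 5) {
  classifier_config(epsilon = epsilon, p0_mode = "fixed",
                    p0_fixed = sc$bed_anchor)
}

#' Write / read a scenario record
#'
#' Scenario records are YAML and reproduce the generated case exactly
#' (the seed is part of the record).
#'
#' @param sc An \code{\link{scenario}}.
#' @param path File path.
#' @return \code{write_scenario} returns \code{path} invisibly;
#'   \code{read_scenario} returns the \code{\link{scenario}}.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "scq_scenario"))
  x <- unclass(sc)
  x$segments <- as.list(as.data.frame(x$segments))
  x$dropouts <- as.list(as.data.frame(x$dropouts))
  x$flickers <- as.list(as.data.frame(x$flickers))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  win <- function(w) if (length(w$start_frame) == 0L) NULL else as.data.frame(w)
  scenario(as.data.frame(x$segments), R = x$R, image_size = x$image_size,
           bed_anchor = x$bed_anchor, exit_anchor = x$exit_anchor,
           jitter_sigma = x$jitter_sigma, speed = x$speed,
           dropouts = win(x$dropouts), flickers = win(x$flickers),
           turning_bursts = x$turning_bursts, burst_cap = x$burst_cap,
           clip_breaks = if (length(x$clip_breaks)) x$clip_breaks else integer(0),
           seed = x$seed)
}
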