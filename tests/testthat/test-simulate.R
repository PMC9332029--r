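test_that("scripted segments render with the documented geometry", {
  # nobody-only: all frames empty
  sc <- scenario(data.frame(behavior = "nobody", duration_s = 2), seed = 5)
  case <- generate(sc)
  expect_equal(n_frames(case$trace), 30L)
  expect_true(all(is.na(case$trace$frames$label)))

  # zero-jitter on-bed: every center sits exactly on the bed anchor
  sc2 <- scenario(data.frame(behavior = "on_bed", duration_s = 2),
                  jitter_sigma = 0, turning_bursts = FALSE, seed = 5)
  fr <- generate(sc2)$trace$frames
  expect_true(all(fr$cx == 160 & fr$cy == 240))
  expect_true(all(fr$label == "head"))
})

test_that("generation is deterministic in the scenario seed", {
  a <- generate(ward_scenario("horizontal", seed = 3))
  b <- generate(ward_scenario("horizontal", seed = 3))
  c <- generate(ward_scenario("horizontal", seed = 4))
  expect_identical(a$trace$frames, b$trace$frames)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$trace$frames, c$trace$frames))
  # same script, different noise placement
  expect_identical(a$scenario$segments, c$scenario$segments)
})

test_that("truth clips exactly tile the frame range", {
  for (profile in c("horizontal", "vertical")) for (seed in 1:3) {
    case <- generate(ward_scenario(profile, seed = seed))
    tr <- case$truth
    expect_equal(tr$start_frame[1], 0L)
    expect_equal(tr$end_frame[nrow(tr)], n_frames(case$trace) - 1L)
    if (nrow(tr) > 1L)
      expect_equal(tr$start_frame[-1L], tr$end_frame[-nrow(tr)] + 1L)
  }
})

test_that("the ward script has nine segments in the on/off/nobody/return cycle", {
  sc <- ward_scenario("horizontal", seed = 1)
  beh <- sc$segments$behavior
  expect_equal(length(beh), 9L)
  expect_equal(beh[1], "on_bed")
  expect_equal(beh[9], "on_bed")
  expect_equal(beh, c("on_bed", "off_bed", "nobody", "return",
                      "on_bed", "off_bed", "nobody", "return", "on_bed"))
  # clip division: 4 on-bed, 2 off-bed, 2 return, 2 nobody per sequence
  truth <- generate(sc)$truth
  expect_equal(as.integer(table(factor(truth$behavior,
                                       levels = scq_behaviors()))),
               c(2L, 4L, 2L, 2L))
  # vertical profile carries flicker windows, horizontal does not
  expect_gt(nrow(ward_scenario("vertical", seed = 1)$flickers), 0L)
  expect_equal(nrow(ward_scenario("horizontal", seed = 1)$flickers), 0L)
  expect_equal(nrow(ward_scenario("vertical", seed = 1, clean = TRUE)$dropouts), 0L)
})

test_that("zero-noise transits classify exactly", {
  # durations sized so the transit spans each segment with step >= epsilon
  sc <- scenario(data.frame(behavior = c("on_bed", "off_bed", "nobody", "return"),
                            duration_s = c(2, 2, 1, 2)),
                 jitter_sigma = 0, turning_bursts = FALSE,
                 speed = 200, seed = 1)
  st <- classify_trace(generate(sc)$trace, scenario_classifier(sc, epsilon = 5))
  seg <- rep(c("on_bed", "off_bed", "nobody", "return"), c(30, 30, 15, 30))
  expect_true(all(st$status[seg == "on_bed"] == 0L))
  expect_true(all(st$status[seg == "nobody"] == -2L))
  # transit step = 200/15 = 13.3 px >= epsilon; neither 2 s transit reaches
  # the far anchor, so every off-bed frame moves away and every return
  # frame after the first moves toward the bed
  off <- st$status[seg == "off_bed"]
  expect_true(all(off == 1L))
  ret <- st$status[seg == "return"]
  expect_true(all(ret[-1] == -1L))
})

test_that("a transit segment yields mostly +1 statuses despite jitter", {
  sc <- scenario(data.frame(behavior = c("on_bed", "off_bed"),
                            duration_s = c(2, 2)),
                 jitter_sigma = 1, seed = 8, speed = 200)
  st <- classify_trace(generate(sc)$trace, scenario_classifier(sc, epsilon = 5))
  off <- st$status[31:60]
  expect_gte(mean(off == 1L), 0.9)
})

test_that("dropouts shorter than the nobody queue never alarm as nobody", {
  for (seed in 1:20) {
    set.seed(seed)
    sc <- scenario(data.frame(behavior = "on_bed", duration_s = 6),
                   dropouts = data.frame(start_frame = sample(0:80, 1),
                                         length_frames = sample(2:10, 1)),
                   seed = seed)
    case <- generate(sc)
    fit <- detect_behaviors(case$trace,
                            classifier = scenario_classifier(sc))
    expect_false(any(fit$events$behavior == "nobody"))
  }
})

test_that("scenario records round-trip through YAML", {
  for (clean in c(TRUE, FALSE)) {
    sc <- ward_scenario("vertical", seed = 6, clean = clean)
    p <- tempfile(fileext = ".yaml")
    write_scenario(sc, p)
    back <- read_scenario(p)
    expect_equal(unclass(back), unclass(sc))
    expect_identical(generate(back)$trace$frames, generate(sc)$trace$frames)
    unlink(p)
  }
})

test_that("scenario validation catches bad scripts", {
  expect_error(scenario(data.frame(behavior = "on_bed", duration_s = -1)),
               "positive")
  expect_error(scenario(data.frame(behavior = "flying", duration_s = 1)),
               "unknown behavior")
  expect_error(scenario(data.frame(behavior = "on_bed", duration_s = 1),
                        dropouts = data.frame(start_frame = 10,
                                              length_frames = 20)),
               "within the trace")
  expect_error(scenario(data.frame(behavior = "on_bed", duration_s = 1),
                        bed_anchor = c(-5, 10)), "inside the image")
})
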