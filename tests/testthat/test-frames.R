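test_that("build_schedule expands block specs into contiguous frames", {
  sch <- full_schedule()
  expect_equal(sch$J, 62L)
  expect_equal(sum(sch$duration_s), 65 * 60)
  expect_equal(sch$start_s[1], 0)
  # contiguity
  expect_equal(sch$start_s[-1], (sch$start_s + sch$duration_s)[-sch$J])

  one <- frame_schedule(list(c(1, 60)))
  expect_equal(one$J, 1L)
  expect_equal(one$duration_s, 60)

  three <- frame_schedule(list(c(3, 10)))
  expect_equal(three$start_s, c(0, 10, 20))
  expect_equal(three$mid_s, c(5, 15, 25))

  expect_error(frame_schedule(list()), "empty")
  expect_error(frame_schedule(list(c(2, -1))), "positive")
})

test_that("fit_weights follows duration x decay and normalises", {
  # no decay, equal durations -> equal weights
  sch <- frame_schedule(list(c(2, 30)), isotope_halflife_min = 1e12)
  expect_equal(fit_weights(sch), c(0.5, 0.5))

  # duration proportionality: frames of 10 s and 300 s, no decay
  sd2 <- frame_schedule(list(c(1, 10), c(1, 300)), isotope_halflife_min = 1e12)
  wd <- fit_weights(sd2)
  expect_equal(wd[2] / wd[1], 30)

  # closed-form decay ratio: mids at 5 s and 3600 s with 18F half-life;
  # frozen value 1.460 computed from the weight formula by hand
  sch2 <- frame_schedule(list(c(1, 10), c(1, 7180)))
  expect_equal(sch2$mid_s, c(5, 3600))
  w2 <- fit_weights(sch2)
  decay_ratio <- (w2[1] / w2[2]) * (7180 / 10)   # strip the duration part
  expect_equal(round(decay_ratio, 3), 1.460)

  # scale invariance: multiplying durations by a constant leaves weights
  # unchanged once mid-times match (no decay)
  sA <- frame_schedule(list(c(3, 10)), isotope_halflife_min = 1e12)
  sB <- frame_schedule(list(c(3, 70)), isotope_halflife_min = 1e12)
  expect_equal(fit_weights(sA), fit_weights(sB))

  # the two conventions are reciprocal in the decay factor
  sch3 <- full_schedule()
  wi <- fit_weights(sch3, "inverse")
  wp <- fit_weights(sch3, "product")
  lam_s <- log(2) / (109.77 * 60)
  expect_equal(wi / sum(wi),
               (sch3$duration_s * exp(-lam_s * sch3$mid_s)) /
                 sum(sch3$duration_s * exp(-lam_s * sch3$mid_s)))
  expect_true(all(abs(wi - wp) > 0))      # conventions genuinely differ
})

test_that("input functions evaluate, shift and round-trip", {
  aif <- input_function(c(10, 20, 30), c(0, 4, 2))
  expect_equal(eval_input(aif, c(5, 10, 15, 25, 40)), c(0, 0, 2, 3, 2))

  sh <- shift_input(aif, 10)
  t <- seq(0, 50, by = 2.5)
  expect_equal(eval_input(sh, t), eval_input(aif, t - 10))

  # delta-like peak translation
  peak <- input_function(c(29, 30, 31), c(0, 10, 0))
  sh10 <- shift_input(peak, 10)
  tt <- seq(0, 60, 0.5)
  expect_equal(tt[which.max(eval_input(sh10, tt))], 40)

  # round trip -5 then +5
  rt <- shift_input(shift_input(aif, -5), 5)
  expect_equal(eval_input(rt, t), eval_input(aif, t))

  expect_error(input_function(c(1, 1), c(0, 0)), "increasing")
  expect_error(input_function(c(1, 2), c(-1, 0)), "non-negative")
})

test_that("frame_average integrates curves over frames", {
  sch <- frame_schedule(list(c(3, 10)))
  expect_equal(frame_average(function(t) rep(7, length(t)), sch), rep(7, 3))
  expect_equal(frame_average(function(t) t, sch), c(5, 15, 25))

  # analytic mean of exp(-t_min) over the first minute
  sch2 <- frame_schedule(list(c(1, 60)))
  got <- frame_average(function(t) exp(-t / 60), sch2, fine_dt_s = 0.1)
  expect_equal(got, 1 - exp(-1), tolerance = 1e-4)

  # frame-wise constant curve is reproduced exactly
  schc <- short_schedule()
  vals <- seq_len(schc$J)
  stepf <- function(t) vals[findInterval(t, schc$start_s)]
  expect_equal(frame_average(stepf, schc), vals)

  expect_error(frame_average(function(t) t, short_schedule(), fine_dt_s = 50),
               "coarser")
})

test_that("schedule and AIF CSV round-trips preserve values", {
  sch <- short_schedule()
  f <- tempfile(fileext = ".csv")
  write_schedule(sch, f)
  sch2 <- read_schedule(f)
  expect_equal(sch2$start_s, sch$start_s)
  expect_equal(sch2$duration_s, sch$duration_s)

  aif <- test_aif()
  g <- tempfile(fileext = ".csv")
  write_aif(aif, g)
  aif2 <- read_aif(g)
  expect_equal(aif2$activity, aif$activity)
  unlink(c(f, g))
})
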