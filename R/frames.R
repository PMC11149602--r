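#' Frame schedules, fit weights and arterial input functions
#'
#' Dynamic PET acquisitions are binned into contiguous time frames.  A
#' \code{frame_schedule} records the start and duration of every frame in
#' seconds, the derived mid-frame times, and the isotope half-life used for
#' decay-related fit weighting (default 109.77 min, 18F).
#'
#' @name frames
NULL

#' Build a frame schedule from a block specification
#'
#' Expands a compact description such as "2 frames of 10 s, then 30 frames of
#' 2 s, ..." into a contiguous schedule starting at time 0.
#'
#' @param blocks list (or 2-column matrix) of \code{c(count, duration_s)}
#'   pairs.
#' @param isotope_halflife_min isotope half-life in minutes; default 109.77
#'   (18F).
#' @return object of class \code{frame_schedule} with fields
#'   \code{start_s}, \code{duration_s}, \code{mid_s}, \code{J},
#'   \code{isotope_halflife_min}.
#' @examples
#' sch <- frame_schedule(list(c(2, 10), c(30, 2), c(4, 10), c(8, 30),
#'                            c(4, 60), c(5, 120), c(9, 300)))
#' sch$J            # 62
#' sum(sch$duration_s) / 60   # 65 minutes
#' @export
frame_schedule <- function(blocks, isotope_halflife_min = 109.77) {
  if (is.matrix(blocks)) blocks <- lapply(seq_len(nrow(blocks)), function(i) blocks[i, ])
  if (length(blocks) == 0L) stop("empty block specification")
  durs <- unlist(lapply(blocks, function(b) {
    count <- b[[1]]; dur <- b[[2]]
    if (count < 1 || count != round(count)) stop("block counts must be positive integers")
    if (dur <= 0) stop("block durations must be positive")
    rep(dur, count)
  }))
  starts <- cumsum(c(0, durs[-length(durs)]))
  new_frame_schedule(starts, durs, isotope_halflife_min)
}

new_frame_schedule <- function(start_s, duration_s, isotope_halflife_min = 109.77) {
  J <- length(start_s)
  stopifnot(J == length(duration_s), all(duration_s > 0))
  if (J > 1L && any(abs(start_s[-1] - (start_s[-J] + duration_s[-J])) > 1e-9))
    stop("frames must be contiguous and non-overlapping")
  structure(list(start_s = as.numeric(start_s),
                 duration_s = as.numeric(duration_s),
                 mid_s = as.numeric(start_s) + as.numeric(duration_s) / 2,
                 end_s = as.numeric(start_s) + as.numeric(duration_s),
                 J = J,
                 isotope_halflife_min = isotope_halflife_min),
            class = "frame_schedule")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("frame_schedule: %d frames, %.1f to %.1f s (total %.1f min)\n",
              x$J, x$start_s[1], x$end_s[x$J], sum(x$duration_s) / 60))
  invisible(x)
}

#' Frame weights for weighted least-squares fitting
#'
#' Weights are proportional to the frame duration combined with the decay
#' correction at the frame mid-time, then normalised to sum to one.  With
#' \code{convention = "inverse"} (default) the weight is
#' \code{duration * exp(-lambda * mid)}: decay-corrected late frames carry
#' fewer raw counts, hence larger variance and smaller weight.  The literal
#' duration-times-correction-multiplier reading
#' (\code{duration * exp(+lambda * mid)}) is available as
#' \code{convention = "product"}.
#'
#' @param schedule a \code{frame_schedule}.
#' @param convention \code{"inverse"} or \code{"product"}, see Details.
#' @return numeric vector of length \code{schedule$J}, non-negative, summing
#'   to 1.
#' @export
fit_weights <- function(schedule, convention = c("inverse", "product")) {
  convention <- match.arg(convention)
  lam <- log(2) / (schedule$isotope_halflife_min * 60)  # per second
  dc <- exp(if (convention == "inverse") -lam * schedule$mid_s else lam * schedule$mid_s)
  w <- schedule$duration_s * dc
  w / sum(w)
}

#' Arterial input function
#'
#' A sampled whole-blood tracer concentration curve.  Evaluation is
#' piecewise linear, returns 0 before the first sample, and holds the last
#' value after the last sample.
#'
#' @param time_s strictly increasing sample times, seconds.
#' @param activity tracer activity, kBq/mL, non-negative.
#' @return object of class \code{input_function}.
#' @export
input_function <- function(time_s, activity) {
  stopifnot(length(time_s) == length(activity), length(time_s) >= 1)
  if (any(diff(time_s) <= 0)) stop("AIF sample times must be strictly increasing")
  if (any(activity < 0)) stop("AIF activity must be non-negative")
  structure(list(time_s = as.numeric(time_s), activity = as.numeric(activity),
                 delay_s = 0), class = "input_function")
}

#' Evaluate an input function at arbitrary times
#'
#' @param aif an \code{input_function}.
#' @param t times in seconds (any numeric vector).
#' @return activity values, kBq/mL.
#' @export
eval_input <- function(aif, t) {
  tt <- t - aif$delay_s
  y <- stats::approx(aif$time_s, aif$activity, xout = tt,
                     yleft = 0, yright = aif$activity[length(aif$activity)])$y
  y[tt < aif$time_s[1]] <- 0
  y
}

#' Shift an input function in time
#'
#' \code{eval_input(shift_input(aif, d), t)} equals
#' \code{eval_input(aif, t - d)}.
#'
#' @param aif an \code{input_function}.
#' @param delay_s shift in seconds (positive = later arrival).
#' @export
shift_input <- function(aif, delay_s) {
  aif$delay_s <- aif$delay_s + delay_s
  aif
}

#' Average a continuous curve over the frames of a schedule
#'
#' @param curve either a function of time (seconds) or a list with fields
#'   \code{t} and \code{y} giving the curve on a fine grid.
#' @param schedule a \code{frame_schedule}.
#' @param fine_dt_s evaluation grid step, seconds; must not exceed the
#'   shortest frame duration.
#' @return numeric vector of per-frame means.
#' @export
frame_average <- function(curve, schedule, fine_dt_s = 1) {
  if (fine_dt_s > min(schedule$duration_s))
    stop("fine_dt_s coarser than the shortest frame")
  vapply(seq_len(schedule$J), function(j) {
    tg <- seq(schedule$start_s[j], schedule$end_s[j] - fine_dt_s / 2, by = fine_dt_s)
    tg <- tg + fine_dt_s / 2  # midpoint rule within the frame
    vals <- if (is.function(curve)) curve(tg)
            else stats::approx(curve$t, curve$y, xout = tg, yleft = 0,
                               yright = curve$y[length(curve$y)])$y
    mean(vals)
  }, numeric(1))
}

# Frame-average a curve sampled on the regular fine grid fg (fine_grid object)
# using precomputed frame bin indices; used heavily by the basis/fit code.
frame_average_indexed <- function(y_fine, bins) {
  as.numeric(vapply(bins, function(idx) mean(y_fine[idx]), numeric(1)))
}

# Regular fine grid covering [t0, t1] with step dt; t0 may be negative to
# accommodate delay shifts.  Curve samples live at cell CENTRES (t), so
# frame means are midpoint-rule averages; convolution kernels are sampled
# at integer offsets (s) so that centre - offset is again a centre.
fine_grid <- function(schedule, dt = 1, pad_before_s = 0, pad_after_s = 0) {
  t0 <- -pad_before_s
  t1 <- schedule$end_s[schedule$J] + pad_after_s
  t <- seq(t0 + dt / 2, t1, by = dt)
  s <- seq(0, t1 - t0, by = dt)
  bins <- lapply(seq_len(schedule$J), function(j) {
    which(t > schedule$start_s[j] & t < schedule$end_s[j])
  })
  list(t = t, s = s, dt = dt, bins = bins)
}

#' Read / write frame schedules as CSV
#'
#' CSV columns: \code{frame,start_s,duration_s}.
#'
#' @param path file path.
#' @rdname schedule_io
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("start_s", "duration_s") %in% names(df)))
  new_frame_schedule(df$start_s, df$duration_s)
}

#' @param schedule a \code{frame_schedule}.
#' @rdname schedule_io
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(data.frame(frame = seq_len(schedule$J),
                              start_s = schedule$start_s,
                              duration_s = schedule$duration_s),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write arterial input functions as CSV
#'
#' CSV columns: \code{time_s,activity_kBq_ml}.
#'
#' @param path file path.
#' @rdname aif_io
#' @export
read_aif <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "activity_kBq_ml") %in% names(df)))
  input_function(df$time_s, df$activity_kBq_ml)
}

#' @param aif an \code{input_function}.
#' @rdname aif_io
#' @export
write_aif <- function(aif, path) {
  utils::write.csv(data.frame(time_s = aif$time_s + aif$delay_s,
                              activity_kBq_ml = aif$activity),
                   path, row.names = FALSE)
  invisible(path)
}
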