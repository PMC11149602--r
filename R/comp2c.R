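#' Huang-Sokoloff two-tissue-compartment model
#'
#' The classical FDG compartmental description: rate constants K1 (mL/min/g)
#' and k2, k3, k4 (1/min), a fractional blood volume term Vb_frac applied to
#' the whole-blood input curve, and an input delay.  Its impulse response is
#' h(t) = K1 [ (k3 + k4 - a1) e^(-a1 t) + (a2 - k3 - k4) e^(-a2 t) ] /
#' (a2 - a1), with a1, a2 the roots of the two-tissue system; the tissue
#' curve is Vb_frac Cb(t - delay) + (h * Cp)(t - delay), frame-averaged.
#'
#' @name comp2c
NULL

#' Two-compartment parameter container
#'
#' @param K1 delivery rate, mL/min/g.
#' @param k2,k3,k4 rate constants, 1/min.
#' @param Vb_frac fractional blood volume, mL/mL.
#' @param delay_s input delay, seconds.
#' @export
twoc_params <- function(K1, k2, k3 = 0, k4 = 0, Vb_frac = 0, delay_s = 0) {
  stopifnot(K1 >= 0, k2 >= 0, k3 >= 0, k4 >= 0, Vb_frac >= 0)
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, Vb_frac = Vb_frac,
                 delay_s = delay_s), class = "twoc_params")
}

# impulse response h(t), t in minutes, value in mL/min/g
twoc_impulse <- function(p, t_min) {
  s <- p$k2 + p$k3 + p$k4
  disc <- s^2 - 4 * p$k2 * p$k4
  disc <- max(disc, 0)
  a1 <- (s - sqrt(disc)) / 2
  a2 <- (s + sqrt(disc)) / 2
  if (a2 - a1 < 1e-10 * max(a2, 1)) {
    # repeated root: h = K1 e^(-a t) (1 + (k3 + k4 - a) t)
    a <- (a1 + a2) / 2
    p$K1 * exp(-a * t_min) * (1 + (p$k3 + p$k4 - a) * t_min)
  } else {
    p$K1 * ((p$k3 + p$k4 - a1) * exp(-a1 * t_min) +
            (a2 - p$k3 - p$k4) * exp(-a2 * t_min)) / (a2 - a1)
  }
}

# convolution of cp with an exponential kernel exp(-a t) on a regular grid,
# via a first-order recursive filter (trapezoid rule); a in 1/min, dt in s
.exp_conv <- function(cp, a_per_min, dt_s) {
  k <- exp(-a_per_min * dt_s / 60)
  n <- length(cp)
  x <- (dt_s / 60) * (cp + k * c(0, cp[-n])) / 2
  as.numeric(stats::filter(x, k, method = "recursive"))
}

# two-compartment model curve on the fine grid (cp already evaluated there)
.twoc_fine_curve <- function(p, cp, dt_s, t_pos_idx = NULL) {
  s <- p$k2 + p$k3 + p$k4
  disc <- max(s^2 - 4 * p$k2 * p$k4, 0)
  a1 <- (s - sqrt(disc)) / 2
  a2 <- (s + sqrt(disc)) / 2
  if (a2 - a1 < 1e-8 * max(a2, 1)) {
    a2 <- a1 + max(1e-8, 1e-8 * a1)   # nudge off the repeated root
  }
  c1 <- (p$k3 + p$k4 - a1) / (a2 - a1)
  c2 <- (a2 - p$k3 - p$k4) / (a2 - a1)
  p$K1 * (c1 * .exp_conv(cp, a1, dt_s) + c2 * .exp_conv(cp, a2, dt_s)) +
    p$Vb_frac * cp
}

# precomputed index tables for frame means of index-shifted fine-grid
# curves (cumulative-sum trick); ns_vec: integer shifts in fine-grid steps,
# positive = later arrival.
.shift_index <- function(fg, ns_vec) {
  nfg <- length(fg$t)
  lo <- vapply(fg$bins, min, numeric(1))
  hi <- vapply(fg$bins, max, numeric(1))
  H <- pmin(pmax(outer(hi, ns_vec, "-"), 0), nfg) + 1L   # into c(0, cumsum)
  L <- pmin(pmax(outer(lo - 1, ns_vec, "-"), 0), nfg) + 1L
  list(H = H, L = L, nb = hi - lo + 1, J = length(fg$bins),
       D = length(ns_vec))
}

# J x D matrix of frame means of U shifted by each ns in the index table
.shift_means <- function(U, si) {
  cs0 <- c(0, cumsum(U))
  matrix(cs0[si$H] - cs0[si$L], si$J, si$D) / si$nb
}

# convenience wrapper (kept for callers that shift once)
shifted_frame_means <- function(U, fg, ns_vec) {
  .shift_means(U, .shift_index(fg, ns_vec))
}

#' Frame-averaged two-compartment model curve
#'
#' @param p a \code{twoc_params}.
#' @param aif an \code{input_function} (whole blood; also used for the
#'   vascular term).
#' @param schedule a \code{frame_schedule}.
#' @param fine_dt_s fine grid step, seconds.
#' @return per-frame tissue activity, kBq/mL.
#' @export
model_2c_curve <- function(p, aif, schedule, fine_dt_s = 1) {
  fg <- fine_grid(schedule, dt = fine_dt_s)
  cp <- eval_input(aif, fg$t - p$delay_s)
  U <- .twoc_fine_curve(p, cp, fg$dt)
  frame_average_indexed(U, fg$bins)
}

#' Fit the two-compartment model to a time course
#'
#' Weighted least squares minimised by BFGS (\code{stats::optim}) in a
#' log/softplus parameterisation enforcing non-negativity, with multistart
#' over jittered log-uniform ranges and the input delay profiled on a grid.
#'
#' @param tac per-frame values, length J.
#' @param aif,schedule,weights as elsewhere.
#' @param n_starts multistart count (default 10).
#' @param delay_range_s half-width of the profiled delay grid, seconds
#'   (default 300 = +/- 5 min).
#' @param delay_step_s delay grid step, seconds.
#' @param seed RNG seed for the start jitter (deterministic fits).
#' @param fine_dt_s fine grid step.
#' @return list of class \code{twoc_fit}: \code{params}
#'   (\code{twoc_params} incl. fitted delay), \code{wrss}, \code{fitted},
#'   \code{converged}, \code{n_starts}.
#' @export
fit_2c <- function(tac, aif, schedule, weights = fit_weights(schedule),
                   n_starts = 10, delay_range_s = 300, delay_step_s = 10,
                   seed = 1, fine_dt_s = 1) {
  J <- schedule$J
  stopifnot(length(tac) == J)
  if (all(abs(tac) < 1e-12)) {
    p <- twoc_params(0, 0.01)
    return(structure(list(params = p, wrss = 0,
                          fitted = rep(0, J), converged = TRUE,
                          n_starts = 0), class = "twoc_fit"))
  }
  pad <- delay_range_s
  fg <- fine_grid(schedule, dt = fine_dt_s, pad_after_s = pad)
  cp <- eval_input(aif, fg$t)
  ns_grid <- as.integer(round(seq(-delay_range_s, delay_range_s,
                                  by = delay_step_s) / fine_dt_s))
  delay_grid <- ns_grid * fine_dt_s

  softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
  inv_softplus <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-12))))
  unpack <- function(th) twoc_params(exp(th[1]), exp(th[2]),
                                     softplus(th[3]), softplus(th[4]),
                                     softplus(th[5]))
  si <- .shift_index(fg, ns_grid)
  obj_env <- new.env()
  objective <- function(th) {
    p <- unpack(th)
    U <- .twoc_fine_curve(p, cp, fg$dt)
    Fm <- .shift_means(U, si)
    wr <- colSums(weights * (tac - Fm)^2)
    d <- which.min(wr)
    obj_env$last_delay <- delay_grid[d]
    wr[d]
  }

  set.seed(seed)
  lo <- c(0.01, 0.01, 1e-4, 1e-4, 1e-4)
  hi <- c(1, 1, 0.2, 0.05, 0.3)
  starts <- lapply(seq_len(n_starts), function(i) {
    v <- exp(stats::runif(5, log(lo), log(hi)))
    c(log(v[1]), log(v[2]), inv_softplus(v[3]), inv_softplus(v[4]),
      inv_softplus(v[5]))
  })
  best <- NULL
  any_conv <- FALSE
  for (th0 in starts) {
    o <- tryCatch(stats::optim(th0, objective, method = "BFGS",
                               control = list(maxit = 500, reltol = 1e-12)),
                  error = function(e) NULL)
    if (is.null(o)) next
    if (o$convergence == 0) any_conv <- TRUE
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("all 2C starts failed")
  objective(best$par)                      # refresh profiled delay
  p <- unpack(best$par)
  p$delay_s <- obj_env$last_delay
  # zero-out numerically inactive softplus parameters
  for (nm in c("k3", "k4", "Vb_frac")) if (p[[nm]] < 1e-8) p[[nm]] <- 0
  fitted <- model_2c_curve(p, aif, schedule, fine_dt_s)
  structure(list(params = p, wrss = best$value, fitted = fitted,
                 converged = any_conv, n_starts = n_starts),
            class = "twoc_fit")
}

#' Extended Meier-Zierler residue of a two-compartment fit
#'
#' The exponential impulse response is augmented with a sharp vascular
#' element: a triangle of height 2 Vb_frac / t* dropping to zero at t*
#' (area Vb_frac, mean transit t*/2, consistent with the central volume
#' blood-flow convention), or a rectangle of the same area with
#' \code{shape = "rectangle"}.
#'
#' @param p a \code{twoc_params}.
#' @param t_star_s vascular transit threshold, seconds.
#' @param T_end_s residue support end, seconds.
#' @param shape vascular element shape.
#' @param n_knots knots for the exponential part.
#' @return a \code{residue}.
#' @export
residue_2c <- function(p, t_star_s = 15, T_end_s, shape = c("triangle", "rectangle"),
                       n_knots = 60) {
  shape <- match.arg(shape)
  g <- sort(unique(c(seq(0, t_star_s, length.out = 16),
                     exp(seq(log(max(t_star_s, 1)), log(T_end_s),
                             length.out = n_knots)),
                     T_end_s)))
  ts_min <- t_star_s / 60
  vb_flow <- if (shape == "triangle") {
    h0 <- 2 * p$Vb_frac / ts_min
    h0 * pmax(1 - g / t_star_s, 0)
  } else {
    (p$Vb_frac / ts_min) * as.numeric(g < t_star_s)
  }
  vals <- vb_flow + twoc_impulse(p, g / 60)
  residue(g, vals, tol = 1e-6)
}
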