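#' Meier-Zierler tissue residue functions
#'
#' The residue R(t) is the flow-weighted fraction of tracer atoms still
#' resident in a tissue region a time t after arterial arrival.  It is
#' non-negative and non-increasing, carries flow units (mL/min/g), and is the
#' convolution kernel linking the arterial input to the tissue time course.
#' Kinetic parameters are read off a three-way decomposition of R into a
#' fast vascular component (transit < t*), an in-distribution component, and
#' a flat extracted component.
#'
#' @name residue
NULL

#' Construct a residue function
#'
#' Stored as a piecewise-linear function on a strictly increasing time grid
#' starting at 0.  Admissibility (non-negative, non-increasing) is enforced
#' at construction: violations larger than \code{tol} raise an error, smaller
#' ones are clipped.
#'
#' @param grid_s time grid in seconds, starting at 0, strictly increasing.
#' @param values residue heights, mL/min/g.
#' @param tol admissibility tolerance relative to the maximum height.
#' @return object of class \code{residue}.
#' @export
residue <- function(grid_s, values, tol = 1e-8) {
  stopifnot(length(grid_s) == length(values), length(grid_s) >= 2)
  if (grid_s[1] != 0) stop("residue grid must start at 0")
  if (any(diff(grid_s) <= 0)) stop("residue grid must be strictly increasing")
  scale <- max(abs(values), 1e-300)
  if (min(values) < -tol * scale) stop("residue has negative values beyond tolerance")
  values <- pmax(values, 0)
  inc <- diff(values)
  if (max(inc) > tol * scale) stop("residue increases along the grid beyond tolerance")
  values <- rev(cummax(rev(values)))  # clip tiny increases
  structure(list(grid_s = as.numeric(grid_s), values = as.numeric(values)),
            class = "residue")
}

#' Evaluate a residue at arbitrary times
#'
#' Piecewise linear within the grid; constant extrapolation of the end
#' values outside it (t < 0 maps to R(0)).
#'
#' @param r a \code{residue}.
#' @param t times, seconds.
#' @export
eval_residue <- function(r, t) {
  stats::approx(r$grid_s, r$values, xout = t, yleft = r$values[1],
                yright = r$values[length(r$values)])$y
}

#' @export
print.residue <- function(x, ...) {
  cat(sprintf("residue on [0, %.0f] s: R(0) = %.4g, R(end) = %.4g mL/min/g\n",
              max(x$grid_s), x$values[1], x$values[length(x$values)]))
  invisible(x)
}

# trapezoidal integral of a piecewise-linear curve, x in seconds -> minutes
trapz_min <- function(x_s, y) sum(diff(x_s) * (y[-1] + y[-length(y)]) / 2) / 60

# refine a residue grid so that t_star and T_end are knots
.with_knots <- function(r, knots) {
  g <- sort(unique(c(r$grid_s, knots)))
  g <- g[g >= 0 & g <= max(r$grid_s, knots)]
  list(grid_s = g, values = eval_residue(r, g))
}

#' Decompose a residue into vascular, in-distribution and extracted parts
#'
#' \code{R_b(t) = (R(t) - R(t_star)) 1\{t < t_star\}} is the fast vascular
#' component, \code{R_e(t) = R(T_end)} the flat extracted (trapped)
#' component, and \code{R_d = R - R_b - R_e} the in-distribution component.
#' The three parts sum to R pointwise by construction.
#'
#' @param r a \code{residue} defined through \code{T_end_s}.
#' @param t_star_s vascular transit threshold, seconds (default 15).
#' @param T_end_s end of acquisition, seconds; default end of the residue
#'   grid.
#' @return list of class \code{residue_decomposition} with residues
#'   \code{R_b}, \code{R_d}, \code{R_e} on a common grid, plus
#'   \code{t_star_s} and \code{T_end_s}.
#' @export
decompose_residue <- function(r, t_star_s = 15, T_end_s = max(r$grid_s)) {
  if (t_star_s >= T_end_s) stop("t_star must precede T_end")
  if (T_end_s > max(r$grid_s) + 1e-9) stop("residue not defined through T_end")
  rr <- .with_knots(r, c(t_star_s, T_end_s))
  keep <- rr$grid_s <= T_end_s + 1e-12
  g <- rr$grid_s[keep]; v <- rr$values[keep]
  R_ts <- eval_residue(r, t_star_s)
  R_T <- eval_residue(r, T_end_s)
  Rb <- ifelse(g < t_star_s, v - R_ts, 0)
  Re <- rep(R_T, length(g))
  Rd <- v - Rb - Re
  structure(list(
    grid_s = g, R = v,
    R_b = pmax(Rb, 0), R_d = pmax(Rd, 0), R_e = Re,
    t_star_s = t_star_s, T_end_s = T_end_s),
    class = "residue_decomposition")
}

#' Kinetic parameters from a residue decomposition
#'
#' Areas under the components give the vascular blood volume
#' \code{V_b = int R_b dt} and distribution volume \code{V_d = int R_d dt}
#' (mL/g; time in minutes).  The flux \code{K_i} is the residue height at the
#' end of acquisition, the distribution flow \code{K_d} the initial height of
#' the in-distribution component.  Ratios give the mean transit time
#' \code{MTT = V_d / K_d} (minutes) and extraction fraction
#' \code{Ext = K_i / (K_d + K_i)} (or \code{K_i / K_d} with
#' \code{ext_convention = "flow"}).
#'
#' @param dec a \code{residue_decomposition}.
#' @param ext_convention \code{"delivery"} for K_i/(K_d+K_i) (default) or
#'   \code{"flow"} for K_i/K_d.
#' @param eps flow floor under which ratio parameters are reported missing.
#' @return named list: V_b, V_d, K_d, K_i (flow/volume units), MTT (min,
#'   NA when K_d ~ 0), Ext (fraction), plus wrss/delay slots left NA for
#'   callers to fill.
#' @export
kinetic_params <- function(dec, ext_convention = c("delivery", "flow"),
                           eps = 1e-9) {
  ext_convention <- match.arg(ext_convention)
  g <- dec$grid_s
  V_b <- trapz_min(g, dec$R_b)
  V_d <- trapz_min(g, dec$R_d)
  K_i <- dec$R_e[1]
  K_d <- dec$R_d[1]
  MTT <- if (K_d < eps) NA_real_ else V_d / K_d
  Ext <- if (ext_convention == "delivery") {
    if (K_d + K_i < eps) NA_real_ else K_i / (K_d + K_i)
  } else {
    if (K_d < eps) NA_real_ else K_i / K_d
  }
  list(V_b = V_b, V_d = V_d, K_d = K_d, K_i = K_i, MTT = MTT, Ext = Ext,
       delay_s = NA_real_)
}

#' Derived clinical variables
#'
#' \code{MR_FDG = mu_glc * K_i} converted to micromol/100 g/min,
#' \code{DV = V_d}, and blood flow via the central volume theorem
#' \code{BF = V_b / (t_star / 2)} with the vascular mean transit time taken
#' as half the transit threshold (7.5 s for the default t* = 15 s).
#'
#' @param params output of \code{\link{kinetic_params}}.
#' @param mu_glc plasma glucose concentration, mmol/L; must be positive.
#' @param t_star_s vascular transit threshold, seconds.
#' @return named list MR_FDG (micromol/100 g/min), DV (mL/g),
#'   BF (mL/min/g), mu_glc.
#' @export
derived_vars <- function(params, mu_glc, t_star_s = 15) {
  if (mu_glc <= 0) stop("plasma glucose must be positive")
  # mmol/L * mL/min/g = micromol/mL * mL/min/g / 1000 ... per 100 g:
  # mu_glc [mmol/L = umol/mL] * K_i [mL/min/g] -> umol/min/g; x100 -> /100g
  MR_FDG <- mu_glc * params$K_i * 100
  BF <- params$V_b / (t_star_s / 2 / 60)
  list(MR_FDG = MR_FDG, DV = params$V_d, BF = BF, mu_glc = mu_glc)
}
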