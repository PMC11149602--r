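#' Voxelwise non-negative least-squares kinetic fitting
#'
#' Every voxel time course z(t_j) is approximated as
#' sum_k alpha_k mu_k(t_j - delta) with alpha >= 0, by weighted non-negative
#' least squares (quadratic programming) over the tissue basis, with the
#' voxel delay delta optimised by a crude grid search.  The fitted voxel
#' residue sum_k alpha_k R_k is then decomposed to give the kinetic maps.
#'
#' @name nprm_fit
NULL

#' Default voxel and VOI delay grids (seconds)
#'
#' Voxels use a narrow grid (-10..30 s, step 2); VOI mean time courses allow
#' a wide +/- 5 min range.
#'
#' @rdname delay_grids
#' @export
voxel_delay_grid <- function() seq(-10, 30, by = 2)

#' @rdname delay_grids
#' @export
voi_delay_grid <- function(range_s = 300, step_s = 2) seq(-range_s, range_s, by = step_s)

#' Fit one time course over the basis
#'
#' @param tac per-frame values, length J.
#' @param basis a \code{tissue_basis}.
#' @param weights frame weights.
#' @param delta_grid_s candidate voxel delays, seconds.
#' @return list of class \code{voxel_fit}: \code{alpha}, \code{delay_s},
#'   \code{fitted}, \code{wrss}, \code{residue} (combined voxel residue),
#'   \code{flag}.
#' @export
fit_voxel <- function(tac, basis, weights = fit_weights(basis$schedule),
                      delta_grid_s = voxel_delay_grid()) {
  J <- basis$schedule$J
  stopifnot(length(tac) == J)
  M <- basis_design(basis, delta_grid_s)
  if (all(abs(M) < 1e-300)) {
    return(structure(list(alpha = rep(0, basis$K), delay_s = 0,
                          fitted = rep(0, J), wrss = sum(weights * tac^2),
                          residue = NULL, flag = "degenerate-basis"),
                     class = "voxel_fit"))
  }
  f <- fit_tacs_cpp(matrix(tac, ncol = 1), M, basis$K, length(delta_grid_s),
                    weights, want_fitted = TRUE)
  alpha <- as.numeric(f$alpha)
  structure(list(alpha = alpha, delay_s = delta_grid_s[f$delta_index[1]],
                 fitted = as.numeric(f$fitted), wrss = f$wrss[1],
                 residue = combine_residues(basis, alpha), flag = "ok"),
            class = "voxel_fit")
}

#' Fit a VOI mean time course (wide delay range)
#'
#' Identical machinery to \code{\link{fit_voxel}} with the +/- 5 min VOI
#' delay grid.
#'
#' @inheritParams fit_voxel
#' @param delta_range_s half-width of the delay search, seconds.
#' @export
fit_voi_tac <- function(tac, basis, weights = fit_weights(basis$schedule),
                        delta_range_s = 300) {
  fit_voxel(tac, basis, weights,
            delta_grid_s = voi_delay_grid(delta_range_s))
}

#' Combined voxel residue from basis amplitudes
#'
#' @param basis a \code{tissue_basis}.
#' @param alpha non-negative amplitudes, length K.
#' @export
combine_residues <- function(basis, alpha) {
  vals <- rep(0, length(basis$knots))
  for (k in seq_len(basis$K))
    vals <- vals + alpha[k] * basis$residues[[k]]$values
  residue(basis$knots, vals, tol = 1e-6)
}

#' Fit a whole dynamic image and produce kinetic maps
#'
#' Masked voxels with total weighted signal below \code{signal_floor} times
#' the image maximum are skipped (maps set NA, flagged).  Parameter maps are
#' derived from the per-element kinetic loadings, which are linear in the
#' amplitudes.
#'
#' @param image a \code{dynamic_image}.
#' @param basis a \code{tissue_basis} built on the same schedule.
#' @param weights frame weights.
#' @param delta_grid_s voxel delay grid.
#' @param t_star_s vascular transit threshold, seconds.
#' @param signal_floor relative skip threshold (default 1e-3).
#' @param want_fitted keep the fitted J x N matrix (needed for the
#'   bootstrap DGP).
#' @return list of class \code{nprm_fit}: \code{maps} (named 3D arrays:
#'   V_b, V_d, K_d, K_i, MTT, Ext, delay_s, wrss), \code{alpha} (K x N),
#'   \code{delay_s}, \code{wrss}, \code{fitted} (optional), \code{skipped},
#'   \code{image}, \code{basis}, \code{param_loadings}.
#' @export
fit_image <- function(image, basis, weights = fit_weights(image$schedule),
                      delta_grid_s = voxel_delay_grid(), t_star_s = 15,
                      signal_floor = 1e-3, want_fitted = FALSE) {
  if (!isTRUE(all.equal(image$schedule$start_s, basis$schedule$start_s)) ||
      image$schedule$J != basis$schedule$J)
    stop("image and basis schedules differ")
  Z <- image_tac_matrix(image)
  fit <- fit_tac_matrix(Z, basis, weights, delta_grid_s, t_star_s,
                        signal_floor, want_fitted)
  fit$maps <- lapply(fit$params, map_from_vector, image = image)
  fit$maps$delay_s <- map_from_vector(fit$delay_s, image)
  fit$maps$wrss <- map_from_vector(fit$wrss, image)
  fit$image <- image
  structure(fit, class = "nprm_fit")
}

# shared TAC-matrix fitter (columns = voxels); returns per-voxel parameter
# vectors rather than maps so it can be reused by the bootstrap.
fit_tac_matrix <- function(Z, basis, weights, delta_grid_s, t_star_s = 15,
                           signal_floor = 1e-3, want_fitted = FALSE) {
  J <- nrow(Z); N <- ncol(Z)
  M <- basis_design(basis, delta_grid_s)
  sig <- as.numeric(crossprod(abs(Z), weights))
  floor_abs <- signal_floor * max(sig, 0)
  active <- sig > floor_abs & sig > 0
  alpha <- matrix(0, basis$K, N)
  delay <- rep(NA_real_, N)
  wrss <- rep(NA_real_, N)
  fitted <- if (want_fitted) matrix(0, J, N) else NULL
  if (any(active)) {
    f <- fit_tacs_cpp(Z[, active, drop = FALSE], M, basis$K,
                      length(delta_grid_s), weights, want_fitted = want_fitted)
    alpha[, active] <- f$alpha
    delay[active] <- delta_grid_s[f$delta_index]
    wrss[active] <- f$wrss
    if (want_fitted) fitted[, active] <- f$fitted
  }
  P <- basis_param_matrix(basis, t_star_s)    # K x 4
  lin <- t(alpha) %*% P                        # N x 4: V_b V_d K_d K_i
  K_d <- lin[, 3]; K_i <- lin[, 4]
  MTT <- ifelse(K_d < 1e-9, NA_real_, lin[, 2] / K_d)
  Ext <- ifelse(K_d + K_i < 1e-9, NA_real_, K_i / (K_d + K_i))
  params <- list(V_b = lin[, 1], V_d = lin[, 2], K_d = K_d, K_i = K_i,
                 MTT = MTT, Ext = Ext)
  params <- lapply(params, function(v) { v[!active] <- NA_real_; v })
  list(params = params, alpha = alpha, delay_s = delay, wrss = wrss,
       fitted = fitted, skipped = !active, basis = basis,
       weights = weights, delta_grid_s = delta_grid_s, t_star_s = t_star_s,
       param_loadings = P)
}
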