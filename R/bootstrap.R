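#' Image-domain bootstrap
#'
#' Residuals from the voxel-level fit are factored into an overall error
#' scale sigma_e, a per-voxel relative scale psi_i, and a per-frame relative
#' scale phi_j, leaving a pool of normalised residuals.  Replicate images
#' are generated as
#' z*_i(t_j) = zhat_i(t_j) + sigma_e psi_i phi_j eps*_i(t_j), with eps*
#' resampled framewise with replacement from donor voxels in the same
#' stratum (preserving per-frame marginals, including skewness; see
#' \code{\link{generate_replicate}} for why whole-vector resampling is not
#' the default).  Refitting replicates yields SD-based standard-error maps.
#'
#' @name bootstrap
NULL

# weighted RMS helper (weights sum to 1 over frames)
.wrms <- function(E, w) sqrt(mean(colMeans(w * E^2) / mean(w)) )

#' Build the data-generation process from fit residuals
#'
#' Scales are estimated by alternating robust (winsorized-RMS) passes over
#' voxels and frames, renormalised each pass (weighted mean psi^2 = 1 over
#' voxels, weighted mean phi^2 = 1 over frames with the fit weights);
#' sigma_e is the overall weighted RMS of the factored residuals.  Optional
#' refinements (on by default) standardise residuals for fit leverage and
#' moderate the per-voxel scales within strata.
#'
#' @param image the original \code{dynamic_image}.
#' @param fit an \code{nprm_fit} obtained with \code{want_fitted = TRUE}.
#' @param weights frame weights used in the fit.
#' @param n_signal_strata,n_axial_strata resampling strata: quantile bins of
#'   fitted time-integrated signal crossed with axial bands.
#' @param tol convergence tolerance of the alternating scale passes.
#' @param df_correction standardise residuals for the degrees of freedom
#'   absorbed by the fit: each frame's residuals are divided by
#'   sqrt(1 - h_j), with h_j the per-frame leverage of the weighted basis
#'   design (computed at delay 0 with the full basis).  Fitting deflates
#'   residual variance most in the high-weight late frames that drive the
#'   flux, so a global inflation is not enough.  TRUE by default; only
#'   applies when the fit carries a basis.
#' @param psi_shrink moderate the per-voxel scales by empirical-Bayes
#'   shrinkage of log(psi) toward the stratum mean (limma-style variance
#'   moderation; TRUE by default).  The sampling noise of a J-frame scale
#'   estimate (~1/sqrt(2J)) otherwise transfers directly into the SE maps.
#' @return object of class \code{dgp_model}: sigma_e, psi (per active
#'   voxel), phi (per frame), eps (J x N normalised residuals), strata,
#'   fitted, plus bookkeeping (active set, geometry).
#' @export
build_dgp <- function(image, fit, weights = fit$weights,
                      n_signal_strata = 5, n_axial_strata = 3, tol = 1e-6,
                      df_correction = TRUE, psi_shrink = TRUE) {
  if (is.null(fit$fitted)) stop("fit must be run with want_fitted = TRUE")
  Z <- image_tac_matrix(image)
  active <- !fit$skipped
  E <- Z[, active, drop = FALSE] - fit$fitted[, active, drop = FALSE]
  J <- nrow(E); N <- ncol(E)
  w <- weights / sum(weights)

  if (df_correction && !is.null(fit$basis)) {
    M <- basis_design(fit$basis, 0)
    Sinv <- tryCatch(solve(crossprod(M, w * M)), error = function(e) NULL)
    if (!is.null(Sinv)) {
      h <- pmin(w * rowSums((M %*% Sinv) * M), 0.9)
      E <- E / sqrt(1 - h)
    }
  }

  # strata: fitted time-integral quantile bins x axial bands; collapsed so
  # every stratum keeps >= 40 donor voxels (tiny strata bias the replicate
  # SD downward by the (n-1)/n resampling factor)
  min_stratum <- 40L
  n_ax <- max(1L, min(n_axial_strata, N %/% min_stratum))
  n_sig <- max(1L, min(n_signal_strata, N %/% (min_stratum * n_ax)))
  dur <- image$schedule$duration_s
  integ <- as.numeric(crossprod(fit$fitted[, active, drop = FALSE], dur))
  qs <- unique(stats::quantile(integ, probs = seq(0, 1, length.out = n_sig + 1)))
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  sig_bin <- if (length(qs) > 2) cut(integ, qs, labels = FALSE) else rep(1L, N)
  zidx <- arrayInd(which(image$mask), image$dim)[, 3][active]
  ax_breaks <- seq(0.5, image$dim[3] + 0.5, length.out = n_ax + 1)
  ax_bin <- cut(zidx, ax_breaks, labels = FALSE)
  strata <- (sig_bin - 1L) * n_ax + ax_bin
  # merge any residual small stratum into its signal-bin neighbours
  tab <- table(strata)
  small <- as.integer(names(tab)[tab < pmin(min_stratum, N)])
  if (length(small) > 0 && length(tab) > 1) {
    for (s in small) {
      keep <- setdiff(unique(strata), s)
      strata[strata == s] <- keep[which.min(abs(keep - s))]
    }
  }

  if (max(abs(E)) < 1e-300) {
    psi <- rep(1, N); phi <- rep(1, J); sigma_e <- 0
    eps <- E
  } else {
    # winsorized RMS scale: clip standardised residuals at 6 before the
    # quadratic mean.  A plain MAD is robust but its ~1.6/sqrt(J) sampling
    # noise on the per-voxel scale (J ~ 62 frames) propagates directly
    # into every bootstrap SE and breaks SE calibration; winsorizing keeps
    # the tail robustness at near-RMS efficiency.
    wrms_scale <- function(x) {
      s0 <- stats::median(abs(x)) * 1.4826          # scale-equivariant pivot
      if (s0 <= 0) return(sqrt(mean(x^2)))
      sqrt(mean(pmin(x^2, (6 * s0)^2)))
    }
    psi <- rep(1, N); phi <- rep(1, J)
    for (pass in seq_len(100)) {
      Eps <- sweep(sweep(E, 2, psi, "/"), 1, phi, "/")
      s_i <- apply(Eps, 2, wrms_scale)
      s_i <- pmax(s_i, 1e-8 * max(s_i))
      psi_new <- psi * s_i
      psi_new <- psi_new / sqrt(mean(psi_new^2))
      Eps <- sweep(sweep(E, 2, psi_new, "/"), 1, phi, "/")
      s_j <- apply(Eps, 1, wrms_scale)
      s_j <- pmax(s_j, 1e-8 * max(s_j))
      phi_new <- phi * s_j
      phi_new <- phi_new / sqrt(sum(w * phi_new^2))
      delta <- max(abs(psi_new - psi) / pmax(psi, 1e-12),
                   abs(phi_new - phi) / pmax(phi, 1e-12))
      psi <- psi_new; phi <- phi_new
      if (delta < tol) break
    }
    if (psi_shrink) {
      # moderate the per-voxel scales: a scale estimated from J frames
      # carries ~1/sqrt(2J) log-scale sampling noise that would propagate
      # verbatim into every bootstrap SE, so shrink log psi toward its
      # stratum mean by the usual empirical-Bayes factor
      s2 <- 1 / (2 * J)
      lp <- log(pmax(psi, 1e-12))
      for (st in unique(strata)) {
        idx <- which(strata == st)
        if (length(idx) < 3) next
        m_s <- mean(lp[idx])
        tau2 <- max(stats::var(lp[idx]) - s2, 0)
        lp[idx] <- m_s + (lp[idx] - m_s) * tau2 / (tau2 + s2)
      }
      psi <- exp(lp)
      psi <- psi / sqrt(mean(psi^2))
    }
    Eps <- sweep(sweep(E, 2, psi, "/"), 1, phi, "/")
    sigma_e <- sqrt(mean(colSums(w * Eps^2)))
    eps <- if (sigma_e > 0) Eps / sigma_e else Eps
  }

  structure(list(sigma_e = sigma_e, psi = psi, phi = phi, eps = eps,
                 strata = strata, fitted = fit$fitted, active = active,
                 image = image, weights = w, z_index = zidx),
            class = "dgp_model")
}

#' @export
print.dgp_model <- function(x, ...) {
  cat(sprintf("dgp_model: sigma_e = %.4g, %d voxels x %d frames, %d strata\n",
              x$sigma_e, ncol(x$eps), nrow(x$eps), length(unique(x$strata))))
  invisible(x)
}

# replicate TAC matrix over the active voxels only (J x N_active).
#
# Default resampling is frame-wise within strata: each replicate entry
# draws its normalised residual from a random donor voxel of the same
# stratum at the SAME frame, preserving per-frame marginals (including
# skewness) while producing noise with full rank over the basis span.
# Whole-vector resampling ("vector") preserves intra-voxel temporal
# correlation but is *invalid* for SEs of fitted parameters here: fit
# residual vectors are weighted-orthogonal to the basis curves, so a
# refit of fitted + resampled-vector noise barely moves the amplitudes
# and the bootstrap SEs collapse (observed ~5x too small).
replicate_tacs <- function(dgp, seed, resample = c("frame", "vector")) {
  resample <- match.arg(resample)
  set.seed(seed)
  J <- nrow(dgp$eps)
  N <- ncol(dgp$eps)
  Estar <- matrix(0, J, N)
  for (s in unique(dgp$strata)) {
    idx <- which(dgp$strata == s)
    n_s <- length(idx)
    if (resample == "vector") {
      donor <- idx[sample.int(n_s, n_s, replace = TRUE)]
      Estar[, idx] <- dgp$eps[, donor, drop = FALSE]
    } else {
      donors <- idx[sample.int(n_s, J * n_s, replace = TRUE)]
      Estar[, idx] <- matrix(dgp$eps[cbind(rep(seq_len(J), n_s), donors)],
                             J, n_s)
    }
  }
  Fit <- dgp$fitted[, dgp$active, drop = FALSE]
  Fit + dgp$sigma_e * sweep(sweep(Estar, 2, dgp$psi, "*"), 1, dgp$phi, "*")
}

#' Generate one bootstrap replicate image
#'
#' Bit-reproducible given \code{(dgp, seed)}.  Skipped (below-floor) voxels
#' keep their original data.
#'
#' @param dgp a \code{dgp_model}.
#' @param seed integer seed.
#' @param resample \code{"frame"} (default) or \code{"vector"}; see
#'   \code{\link{build_dgp}} and the methods vignette.
#' @return a \code{dynamic_image}.
#' @export
generate_replicate <- function(dgp, seed, resample = "frame") {
  Zstar <- replicate_tacs(dgp, seed, resample)
  img <- dgp$image
  flat <- matrix(img$data, prod(img$dim), img$schedule$J)
  vox <- which(as.vector(img$mask))[dgp$active]
  flat[vox, ] <- t(Zstar)
  img$data <- array(flat, c(img$dim, img$schedule$J))
  img
}

#' Bootstrap kinetic-parameter standard-error maps
#'
#' Each replicate is refitted with the same basis, weights and delay grid;
#' per voxel and parameter the SE is the SD across replicates (denominator
#' N_B - 1).
#'
#' @param image original \code{dynamic_image}.
#' @param basis \code{tissue_basis} used for the point fit.
#' @param weights frame weights.
#' @param dgp a \code{dgp_model}.
#' @param N_B number of bootstrap replicates (default 25).
#' @param seed base seed; replicate b uses seed + b.
#' @param delta_grid_s voxel delay grid.
#' @param t_star_s vascular transit threshold.
#' @return list of class \code{bootstrap_ensemble}: \code{se_maps} (named
#'   3D arrays), \code{replicate_params} (list over replicates of per-voxel
#'   parameter lists), \code{seeds}, \code{N_B}, \code{failed}.
#' @export
bootstrap_maps <- function(image, basis, weights, dgp, N_B = 25, seed = 1,
                           delta_grid_s = voxel_delay_grid(), t_star_s = 15,
                           resample = "frame") {
  if (N_B < 2) stop("N_B must be at least 2")
  seeds <- seed + seq_len(N_B)
  reps <- vector("list", N_B)
  failed <- logical(N_B)
  for (b in seq_len(N_B)) {
    Zstar <- replicate_tacs(dgp, seeds[b], resample)
    f <- tryCatch(fit_tac_matrix(Zstar, basis, weights, delta_grid_s,
                                 t_star_s, signal_floor = 0),
                  error = function(e) NULL)
    if (is.null(f)) { failed[b] <- TRUE; next }
    reps[[b]] <- f$params
  }
  ok <- which(!failed)
  if (length(ok) < 2) stop("fewer than 2 successful bootstrap replicates")
  pnames <- names(reps[[ok[1]]])
  se_active <- lapply(pnames, function(pn) {
    mat <- vapply(ok, function(b) reps[[b]][[pn]], reps[[ok[1]]][[pn]])
    apply(matrix(mat, ncol = length(ok)), 1, stats::sd, na.rm = TRUE)
  })
  names(se_active) <- pnames
  se_maps <- lapply(se_active, function(v) {
    full <- rep(NA_real_, sum(dgp$image$mask))
    full[dgp$active] <- v
    map_from_vector(full, dgp$image)
  })
  structure(list(se_maps = se_maps, replicate_params = reps[ok],
                 seeds = seeds, N_B = N_B, failed = sum(failed),
                 image = dgp$image, active = dgp$active),
            class = "bootstrap_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximum-intensity projections and their bootstrap SEs
#'
#' The point MIP is the max of the point-estimate map along an axis; its SE
#' is the SD across replicates of each replicate's own MIP (not the MIP of
#' the SE map: the maximum is a nonlinear statistic).
#'
#' @param ensemble a \code{bootstrap_ensemble}.
#' @param point_map 3D point-estimate array for one parameter.
#' @param param parameter name within the ensemble replicates.
#' @param axis projection axis (1, 2 or 3).
#' @return list: \code{mip} (2D), \code{mip_se} (2D).
#' @export
mip_and_se <- function(ensemble, point_map, param = "K_i", axis = 3) {
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3")
  proj <- function(a) {
    m <- suppressWarnings(apply(a, setdiff(1:3, axis), max, na.rm = TRUE))
    m[!is.finite(m)] <- NA_real_
    m
  }
  mips <- lapply(ensemble$replicate_params, function(p) {
    full <- rep(NA_real_, sum(ensemble$image$mask))
    full[ensemble$active] <- p[[param]]
    proj(map_from_vector(full, ensemble$image))
  })
  arr <- simplify2array(mips)
  mip_se <- apply(arr, 1:2, stats::sd, na.rm = TRUE)
  list(mip = proj(point_map), mip_se = mip_se)
}

# directional autocorrelation of a 3D field at integer lags; NA-aware
.axis_acf <- function(field, axis, max_lag) {
  acf <- numeric(max_lag + 1)
  acf[1] <- 1
  d <- dim(field)
  for (L in seq_len(max_lag)) {
    idx1 <- lapply(1:3, function(a) seq_len(d[a]))
    idx2 <- idx1
    idx1[[axis]] <- seq_len(d[axis] - L)
    idx2[[axis]] <- seq_len(d[axis] - L) + L
    x <- do.call(`[`, c(list(field), idx1))
    y <- do.call(`[`, c(list(field), idx2))
    keep <- is.finite(x) & is.finite(y)
    acf[L + 1] <- if (sum(keep) > 10)
      stats::cor(as.numeric(x[keep]), as.numeric(y[keep])) else NA_real_
  }
  acf
}

# FWHM (in voxels) of an ACF: twice the interpolated half-height crossing
.acf_fwhm <- function(acf) {
  below <- which(acf < 0.5)
  if (length(below) == 0) return(NA_real_)
  i <- below[1]
  if (i == 1) return(1)
  lag_half <- (i - 2) + (acf[i - 1] - 0.5) / (acf[i - 1] - acf[i])
  2 * lag_half
}

#' DGP diagnostics
#'
#' Axial profile of the voxel scale, the normalised-residual histogram with
#' a standard-gaussian reference, coordinatewise autocorrelation of the
#' normalised residual field with per-axis FWHM, and (given a multi-study
#' table) the linear correlation between sigma_e and dose.
#'
#' @param dgp a \code{dgp_model}.
#' @param per_study_table optional data.frame with columns \code{study},
#'   \code{dose}, \code{sigma_e}.
#' @param n_frames number of (highest-weight) frames entering the ACF.
#' @param max_lag maximum ACF lag, voxels.
#' @return list: \code{axial_profile} (data.frame slice, mean_psi),
#'   \code{residual_hist} (data.frame mid, density, gaussian),
#'   \code{acf} (data.frame axis, lag, acf), \code{fwhm_voxels} (length 3),
#'   \code{dose_correlation} (number or NA with attribute "flag").
#' @export
dgp_diagnostics <- function(dgp, per_study_table = NULL, n_frames = 5,
                            max_lag = 8) {
  prof <- stats::aggregate(psi ~ slice,
                           data = data.frame(psi = dgp$psi, slice = dgp$z_index),
                           FUN = mean)
  names(prof) <- c("slice", "mean_psi")

  pool <- as.numeric(dgp$eps)
  if (length(pool) > 2e5) pool <- pool[seq(1, length(pool), length.out = 2e5)]
  h <- graphics::hist(pool, breaks = 60, plot = FALSE)
  hist_df <- data.frame(mid = h$mids, density = h$density,
                        gaussian = stats::dnorm(h$mids))

  img <- dgp$image
  frames <- order(dgp$weights, decreasing = TRUE)[seq_len(min(n_frames, nrow(dgp$eps)))]
  vox <- which(as.vector(img$mask))[dgp$active]
  acfs <- array(NA_real_, c(3, max_lag + 1, length(frames)))
  for (fi in seq_along(frames)) {
    field <- array(NA_real_, img$dim)
    field[vox] <- dgp$eps[frames[fi], ]
    for (ax in 1:3)
      acfs[ax, , fi] <- .axis_acf(field, ax, max_lag)
  }
  acf_mean <- apply(acfs, 1:2, mean, na.rm = TRUE)
  acf_df <- data.frame(axis = rep(1:3, each = max_lag + 1),
                       lag = rep(0:max_lag, 3),
                       acf = as.numeric(t(acf_mean)))
  fwhm <- vapply(1:3, function(ax) .acf_fwhm(acf_mean[ax, ]), numeric(1))

  dose_cor <- NA_real_
  if (!is.null(per_study_table) && nrow(per_study_table) >= 3) {
    dose_cor <- stats::cor(per_study_table$dose, per_study_table$sigma_e)
  } else {
    attr(dose_cor, "flag") <- "dose correlation needs >= 3 studies"
  }
  list(axial_profile = prof, residual_hist = hist_df, acf = acf_df,
       fwhm_voxels = fwhm, dose_correlation = dose_cor)
}
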