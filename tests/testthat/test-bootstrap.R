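wfit_small <- function(sim, sch, basis = NULL) {
  w <- fit_weights(sch)
  if (is.null(basis)) {
    spec <- attr(sim, "spec")
    basis <- tissue_basis(lapply(spec$organs, `[[`, "residue"),
                          vapply(spec$organs, `[[`, numeric(1), "delay_s"),
                          sim$aif, sch)
  }
  fit <- fit_image(sim$image, basis, w, want_fitted = TRUE)
  list(fit = fit, w = w, basis = basis)
}

sim_small <- function(sch, sigma_e = 0.4, seed = 1, dim = c(8, 8, 12)) {
  spec <- standard_phantoms("twocomp", dim = dim, T_end_s = sch$end_s[sch$J])
  sim <- simulate_image(spec, sch, sigma_e = sigma_e, seed = seed)
  attr(sim, "spec") <- spec
  sim
}

test_that("DGP on a perfect fit is degenerate and replicates exactly", {
  sch <- short_schedule()
  sim <- sim_small(sch, sigma_e = 0)
  fw <- wfit_small(sim, sch)
  dgp <- build_dgp(sim$image, fw$fit, fw$w)
  expect_equal(dgp$sigma_e, 0, tolerance = 1e-10)
  rep1 <- generate_replicate(dgp, 42)
  expect_equal(rep1$data, sim$image$data, tolerance = 1e-10)

  ens <- bootstrap_maps(sim$image, fw$basis, fw$w, dgp, N_B = 3, seed = 1)
  for (pn in c("V_b", "K_i"))
    expect_equal(max(ens$se_maps[[pn]], na.rm = TRUE), 0, tolerance = 1e-10)
})

test_that("planted factor structure is recovered", {
  # residuals e_ij = 2 a_i b_j eta with unit-RMS eta: psi ~ a, phi ~ b,
  # sigma_e ~ 2 after the module's own normalisation
  sch <- frame_schedule(list(c(60, 5)))       # J = 60 for scale stability
  J <- sch$J; N <- 3000
  set.seed(17)
  img <- dynamic_image(array(rnorm(4 * 5 * 150 * J), c(4, 5, 150, J)), sch)
  a <- exp(rnorm(N, 0, 0.3)); b <- exp(rnorm(J, 0, 0.4))
  E <- 2 * outer(b, a) * matrix(rnorm(J * N), J, N)
  fake_fit <- list(fitted = image_tac_matrix(img) - E,
                   skipped = rep(FALSE, N),
                   weights = fit_weights(sch))
  # raw factorisation (no scale moderation): the planted-factor oracle
  dgp <- build_dgp(img, fake_fit, fit_weights(sch), psi_shrink = FALSE)
  w <- fit_weights(sch); w <- w / sum(w)
  a_n <- a / sqrt(mean(a^2)); b_n <- b / sqrt(sum(w * b^2))
  expect_equal(dgp$sigma_e, 2 * sqrt(mean(a^2)) * sqrt(sum(w * b^2)),
               tolerance = 0.05)
  # per-voxel scales carry ~1.6/sqrt(J) sampling noise; compare the pattern
  # by correlation and by decile means
  expect_gt(stats::cor(dgp$psi, a_n), 0.85)
  dec <- cut(a_n, stats::quantile(a_n, 0:10 / 10), include.lowest = TRUE)
  expect_lt(max(abs(tapply(dgp$psi, dec, mean) / tapply(a_n, dec, mean) - 1)),
            0.03)
  expect_equal(dgp$phi, b_n, tolerance = 0.1)
  # phi elementwise within a few percent (3000 voxels per frame)
  expect_lt(stats::median(abs(dgp$phi / b_n - 1)), 0.03)

  # scale equivariance: doubling residuals doubles sigma_e only
  fake2 <- fake_fit; fake2$fitted <- image_tac_matrix(img) - 2 * E
  dgp2 <- build_dgp(img, fake2, fit_weights(sch), psi_shrink = FALSE)
  expect_equal(dgp2$sigma_e, 2 * dgp$sigma_e, tolerance = 1e-6)
  expect_equal(dgp2$psi, dgp$psi, tolerance = 1e-8)
  expect_equal(dgp2$phi, dgp$phi, tolerance = 1e-8)

  # normalisation invariants
  expect_equal(mean(dgp$psi^2), 1, tolerance = 1e-6)
  expect_equal(sum(w * dgp$phi^2), 1, tolerance = 1e-6)
  expect_equal(sqrt(mean(colSums(w * dgp$eps^2))), 1, tolerance = 1e-6)
})

test_that("replicates are reproducible and match DGP moments", {
  sch <- short_schedule()
  sim <- sim_small(sch, sigma_e = 0.5, seed = 3)
  fw <- wfit_small(sim, sch)
  dgp <- build_dgp(sim$image, fw$fit, fw$w)
  r1 <- generate_replicate(dgp, 7)
  r2 <- generate_replicate(dgp, 7)
  expect_identical(r1$data, r2$data)
  r3 <- generate_replicate(dgp, 8)
  expect_false(identical(r1$data, r3$data))

  # across replicates, per-voxel-frame SD approx sigma_e psi_i phi_j
  reps <- vapply(1:150, function(s) nprm:::replicate_tacs(dgp, s),
                 matrix(0, sch$J, ncol(dgp$eps)))
  sd_emp <- apply(reps, 1:2, stats::sd)
  sd_mod <- dgp$sigma_e * outer(dgp$phi, dgp$psi)
  expect_equal(mean(sd_emp / sd_mod), 1, tolerance = 0.08)

  # resampling preserves the skewness of the pool
  pool_skew <- mean(dgp$eps^3) / stats::sd(dgp$eps)^3
  rep_err <- (reps[, , 1] - dgp$fitted[, dgp$active]) /
    (dgp$sigma_e * outer(dgp$phi, dgp$psi))
  rep_skew <- mean(rep_err^3) / stats::sd(rep_err)^3
  expect_equal(rep_skew, pool_skew, tolerance = 0.25)
})

test_that("MIP SE is the SD of replicate MIPs, not the MIP of SEs", {
  sch <- short_schedule()
  sim <- sim_small(sch, sigma_e = 0.5, seed = 5, dim = c(6, 6, 9))
  fw <- wfit_small(sim, sch)
  dgp <- build_dgp(sim$image, fw$fit, fw$w)
  ens <- bootstrap_maps(sim$image, fw$basis, fw$w, dgp, N_B = 8, seed = 2)
  m <- mip_and_se(ens, fw$fit$maps$K_i, "K_i", axis = 3)
  expect_equal(dim(m$mip), c(6, 6))
  # direct recomputation of the definition
  mips <- vapply(ens$replicate_params, function(p) {
    full <- rep(NA_real_, sum(ens$image$mask))
    full[ens$active] <- p$K_i
    arr <- map_from_vector(full, ens$image)
    suppressWarnings(apply(arr, 1:2, max, na.rm = TRUE))
  }, matrix(0, 6, 6))
  expect_equal(m$mip_se, apply(mips, 1:2, stats::sd), tolerance = 1e-12)
  expect_error(mip_and_se(ens, fw$fit$maps$K_i, "K_i", axis = 9), "axis")

  # order-statistic toy: two voxels anti-correlated across replicates can
  # give a MIP SE exceeding each voxel's own SD
  reps <- list(c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  mip_vals <- vapply(reps, max, numeric(1))      # always 1
  expect_equal(stats::sd(mip_vals), 0)
  reps2 <- list(c(1, 0.9), c(0.9, 1.2), c(1.1, 0.8), c(0.7, 1.3))
  per_vox_sd <- apply(do.call(rbind, reps2), 2, stats::sd)
  mip_sd <- stats::sd(vapply(reps2, max, numeric(1)))
  expect_true(mip_sd > 0)                         # nonlinear statistic
})

test_that("DGP diagnostics measure axial profile, skewness and resolution", {
  sch <- short_schedule()
  sim <- sim_small(sch, sigma_e = 0.5, seed = 11, dim = c(10, 10, 18))
  fw <- wfit_small(sim, sch)
  dgp <- build_dgp(sim$image, fw$fit, fw$w)
  di <- dgp_diagnostics(dgp)
  # white-noise residual field: ACF FWHM about one voxel
  expect_true(all(di$fwhm_voxels < 1.5, na.rm = TRUE))
  expect_true(is.data.frame(di$axial_profile))
  expect_true(all(c("mid", "density", "gaussian") %in% names(di$residual_hist)))
  expect_true(!is.null(attr(di$dose_correlation, "flag")))

  # planted dose relation across synthetic studies
  set.seed(2)
  dose <- runif(12, 1, 4)
  tab <- data.frame(study = 1:12, dose = dose,
                    sigma_e = 0.3 * dose + rnorm(12, 0, 0.05))
  di2 <- dgp_diagnostics(dgp, per_study_table = tab)
  expect_gt(di2$dose_correlation, 0.85)

  # smoothed field raises the FWHM toward the kernel width
  img <- sim$image
  E <- dgp$eps
  field_dim <- img$dim
  # replace residual pool with a field smoothed along x by a boxcar(3)
  vox <- which(as.vector(img$mask))[dgp$active]
  eps_s <- E
  for (j in 1:nrow(E)) {
    f3 <- array(NA_real_, field_dim)
    f3[vox] <- E[j, ]
    fs <- f3
    fs[2:(field_dim[1] - 1), , ] <-
      (f3[1:(field_dim[1] - 2), , ] + f3[2:(field_dim[1] - 1), , ] +
       f3[3:field_dim[1], , ]) / 3
    eps_s[j, ] <- fs[vox]
  }
  dgp_s <- dgp; dgp_s$eps <- eps_s
  di3 <- dgp_diagnostics(dgp_s)
  expect_gt(di3$fwhm_voxels[1], di$fwhm_voxels[1] * 1.5)
})

test_that("bootstrap SE of a VOI mean is below the mean voxel SE", {
  sch <- short_schedule()
  sim <- sim_small(sch, sigma_e = 0.5, seed = 13, dim = c(8, 8, 12))
  fw <- wfit_small(sim, sch)
  dgp <- build_dgp(sim$image, fw$fit, fw$w)
  ens <- bootstrap_maps(sim$image, fw$basis, fw$w, dgp, N_B = 20, seed = 3)
  lab <- sim$organ_labels[sim$image$mask][dgp$active]
  for (voi in 1:2) {
    m <- lab == voi
    voi_means <- vapply(ens$replicate_params, function(p) mean(p$K_i[m]),
                        numeric(1))
    se_voi <- stats::sd(voi_means)
    mean_vox_se <- mean(ens$se_maps$K_i[sim$organ_labels == voi], na.rm = TRUE)
    expect_lt(se_voi, mean_vox_se)
  }
})
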