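test_that("segmentation recovers homogeneous organs and handles edge cases", {
  sch <- short_schedule()
  aif <- test_aif(sch)
  fx <- two_organ_tacs(sch, aif, N_per = 60, noise = 0.25, seed = 3)
  seg <- segment_tacs(fx$Z, sch, S = 2, seed = 1)
  # adjusted agreement with ground-truth labels (label-permutation safe)
  tab <- table(seg$labels, fx$labels)
  agree <- max(sum(diag(tab)), sum(diag(tab[2:1, ]))) / length(fx$labels)
  expect_gt(agree, 0.95)

  # S = 1: single segment, mean TAC = global mean
  s1 <- segment_tacs(fx$Z, sch, S = 1)
  expect_equal(as.numeric(s1$mean_tacs), rowMeans(fx$Z))

  # duplicated voxels always share a label
  Zdup <- cbind(fx$Z, fx$Z[, 1])
  sd2 <- segment_tacs(Zdup, sch, S = 2, seed = 4)
  expect_equal(sd2$labels[ncol(Zdup)], sd2$labels[1])

  expect_error(segment_tacs(fx$Z[, 1:3], sch, S = 10), "more segments")
})

test_that("shape-constrained residue fitting recovers known residues", {
  sch <- full_schedule()
  aif <- test_aif(sch)
  w <- fit_weights(sch)
  spec <- standard_phantoms("twocomp", dim = c(8, 8, 9),
                            T_end_s = sch$end_s[sch$J])
  # truth representable on the fitting knot grid (tests the fitter, not
  # the interpolation error of an off-grid shape)
  knots <- nprm:::residue_knots(sch$end_s[sch$J])
  r_true <- residue(knots, eval_residue(spec$organs[[1]]$residue, knots),
                    tol = 1e-6)
  tb <- tissue_basis(list(r_true), 0, aif, sch)
  tac <- as.numeric(tb$mu)

  f <- fit_segment_residue(tac, aif, sch, w, delay_grid_s = seq(-6, 6, 2))
  expect_equal(f$delay_s, 0)
  rms <- sqrt(mean((eval_residue(f$residue, knots) -
                    eval_residue(r_true, knots))^2)) / max(r_true$values)
  expect_lt(rms, 0.02)

  # zero TAC is flagged
  z <- fit_segment_residue(rep(0, sch$J), aif, sch, w)
  expect_equal(z$flag, "zero-signal")
  expect_equal(z$wrss, 0)
  expect_equal(max(z$residue$values), 0)

  # known delay is recovered on the grid
  tb6 <- tissue_basis(list(r_true), 6, aif, sch)
  f6 <- fit_segment_residue(as.numeric(tb6$mu), aif, sch, w,
                            delay_grid_s = seq(-10, 10, 2))
  expect_equal(f6$delay_s, 6)
})

test_that("basis tissue curves are admissible model curves", {
  sch <- short_schedule()
  tb <- tissue_basis(list(step_residue(sch$end_s[sch$J])), 0, test_aif(sch), sch)
  expect_true(all(tb$mu >= -1e-12))
  # pre-injection frames carry essentially no signal (bolus at 15 s)
  expect_lt(tb$mu[1, 1], 0.01 * max(tb$mu))
})

test_that("select_basis identifies a one-dimensional truth and is seeded", {
  sch <- short_schedule()
  aif <- test_aif(sch)
  w <- fit_weights(sch)
  spec <- standard_phantoms("twocomp", dim = c(8, 8, 9),
                            T_end_s = sch$end_s[sch$J])
  r <- spec$organs[[3]]$residue
  tb1 <- tissue_basis(list(r), 0, aif, sch)
  set.seed(20)
  Z <- matrix(tb1$mu, sch$J, 80) %*% diag(rgamma(80, 4, 4)) +
    0.15 * matrix(rnorm(sch$J * 80), sch$J)
  seg <- segment_tacs(Z, sch, S = 6, seed = 2)
  sel <- select_basis(seg, aif, sch, w, K_grid = 1:4, cv_folds = 4, seed = 2,
                      delay_grid_s = seq(-4, 4, 2))
  expect_equal(attr(sel, "K_selected"), 1L)

  # deterministic given the seed
  sel2 <- select_basis(seg, aif, sch, w, K_grid = 1:4, cv_folds = 4, seed = 2,
                       delay_grid_s = seq(-4, 4, 2))
  expect_equal(attr(sel2, "cv"), attr(sel, "cv"))
  expect_equal(sel2$delays_s, sel$delays_s)

  expect_error(select_basis(seg, aif, sch, w, K_grid = integer(0)), "empty")
})

test_that("cross-validated WRSS decreases sharply up to the true dimension", {
  sch <- short_schedule()
  aif <- test_aif(sch)
  w <- fit_weights(sch)
  fx <- two_organ_tacs(sch, aif, N_per = 60, noise = 0.25, seed = 8)
  seg <- segment_tacs(fx$Z, sch, S = 8, seed = 3)
  sel <- select_basis(seg, aif, sch, w, K_grid = 1:4, cv_folds = 4, seed = 3,
                      delay_grid_s = seq(-4, 4, 2))
  cv <- attr(sel, "cv")
  # sharp drop up to the true dimension, then flat or rising (U-shape):
  # the tail spread is small relative to the initial drop
  drop1 <- cv$cv_wrss[1] - cv$cv_wrss[2]
  tail_spread <- max(cv$cv_wrss[2:4]) - min(cv$cv_wrss[2:4])
  expect_gt(cv$cv_wrss[1], cv$cv_wrss[2] * 1.5)
  expect_lt(tail_spread, 0.25 * drop1)
  expect_lte(attr(sel, "K_selected"), 3L)
})

test_that("selected K concentrates on the true basis dimension", {
  # three organs with distinct residues at realistic noise: the
  # cross-validated choice (one-SE rule) lands on K = 3
  sch <- full_schedule()
  w <- fit_weights(sch)
  spec <- standard_phantoms("twocomp", dim = c(10, 10, 12))
  sel <- integer(2)
  for (rep in 1:2) {
    sim <- simulate_image(spec, sch, seed = rep)
    seg <- segment_tacs(sim$image, sch, S = 12, seed = rep)
    tb <- select_basis(seg, sim$aif, sch, w, K_grid = 1:6, cv_folds = 5,
                       seed = rep)
    sel[rep] <- attr(tb, "K_selected")
  }
  expect_true(all(sel == 3L))
})

test_that("basis JSON round-trip reproduces curves", {
  sch <- short_schedule()
  tb <- tissue_basis(list(step_residue(sch$end_s[sch$J]),
                          .flat <- residue(c(0, sch$end_s[sch$J]), c(0.05, 0.05))),
                     c(0, 4), test_aif(sch), sch)
  f <- tempfile(fileext = ".json")
  save_basis(tb, f)
  tb2 <- load_basis(f)
  expect_equal(tb2$K, tb$K)
  expect_equal(tb2$delays_s, tb$delays_s)
  expect_equal(tb2$mu, tb$mu, tolerance = 1e-10)
  unlink(f)
})
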