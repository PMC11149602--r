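test_that("paired Wilcoxon matches exact enumeration", {
  # n = 6, all differences positive: two-sided p = 2/64
  r <- paired_wilcoxon(c(1, 2, 3, 4, 5, 6) + 10, rep(10, 6))
  expect_equal(r$statistic, 21)
  expect_equal(r$p_value, 2 / 64)

  # exhaustive check against enumeration of all sign patterns, n <= 10
  enum_p <- function(d) {
    n <- length(d); r <- rank(abs(d))
    V <- sum(r[d > 0])
    Vs <- vapply(0:(2^n - 1), function(m) {
      s <- as.integer(intToBits(m))[1:n]
      sum(r[s == 1])
    }, numeric(1))
    p_lo <- mean(Vs <= V); p_hi <- mean(Vs >= V)
    min(1, 2 * min(p_lo, p_hi))
  }
  set.seed(12)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    d <- round(rnorm(n), 2)
    d <- d[d != 0]
    if (any(duplicated(abs(d))) || length(d) < 5) next
    got <- paired_wilcoxon(d, rep(0, length(d)))
    expect_equal(got$p_value, enum_p(d), tolerance = 1e-12)
  }

  # symmetry under swapping
  x <- c(3, 1, 4, 1, 5, 9, 2, 6); y <- c(2, 7, 1, 8, 2, 8, 1, 8)
  a <- paired_wilcoxon(x, y); b <- paired_wilcoxon(y, x)
  expect_equal(a$p_value, b$p_value)

  # identical vectors
  same <- paired_wilcoxon(1:8, 1:8)
  expect_equal(same$p_value, 1)
  expect_equal(same$flag, "all differences zero")

  # large-n normal path agrees with stats::wilcox.test
  set.seed(3)
  x <- rnorm(40); y <- rnorm(40, 0.4)
  got <- paired_wilcoxon(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("WRSS comparison computes percent deviations with exclusions", {
  tab <- data.frame(
    study_id = rep("s1", 6),
    voi_label = rep(1:3, 2),
    method = rep(c("voxel-NP", "VOI-2C"), each = 3),
    wrss = c(0.02, 0.05, 0, 0.09, 0.05, 0.3))
  out <- wrss_compare(tab)
  twoc <- out[out$method == "VOI-2C", ]
  expect_equal(twoc$n_excluded, 1)             # the zero-reference VOI
  expect_equal(twoc$mean_pct_dev, mean(c(350, 0)))
  ref <- out[out$method == "voxel-NP", ]
  expect_equal(ref$mean_pct_dev, 0)
  expect_error(wrss_compare(tab, reference = "nope"), "not present")
})

test_that("log-linear SE regression recovers a planted model", {
  set.seed(21)
  n <- 120
  voi_type <- sample(c("gm", "liver", "tumor"), n, replace = TRUE)
  wrms <- rexp(n, 2) + 0.05
  value <- rgamma(n, 2, 10)
  beta <- c(gm = 0, liver = 0.7, tumor = -0.4)
  log_se <- -2 + beta[voi_type] + 0.8 * log(wrms) + 0.5 * log(abs(value) + 1e-6)
  tab <- data.frame(voi_type = voi_type, se = exp(log_se), wrms = wrms,
                    value = value)
  f <- se_loglinear(tab)
  expect_gt(f$cor_log, 0.999)
  expect_equal(unname(f$coefficients["log_wrms"]), 0.8, tolerance = 1e-6)
  expect_equal(unname(f$coefficients["log_val"]), 0.5, tolerance = 1e-6)
  expect_false(f$rank_deficient)

  # scale equivariance: multiplying SEs shifts only the intercept
  tab2 <- tab; tab2$se <- tab$se * 10
  f2 <- se_loglinear(tab2)
  expect_equal(unname(f2$coefficients[-1]), unname(f$coefficients[-1]),
               tolerance = 1e-8)
  expect_equal(unname(f2$coefficients[1] - f$coefficients[1]), log(10),
               tolerance = 1e-8)

  # constant SEs: slope coefficients ~ 0
  tab3 <- tab; tab3$se <- 0.123
  f3 <- se_loglinear(tab3)
  expect_lt(max(abs(f3$coefficients[-1])), 1e-8)
  expect_error(se_loglinear(data.frame(voi_type = "a", se = 1, wrms = 1,
                                       value = 1)), "2 VOI types")
})

test_that("VOI aggregation and delay maps behave as defined", {
  sch <- short_schedule()
  aif <- test_aif(sch)
  spec <- standard_phantoms("twocomp", dim = c(6, 6, 9),
                            T_end_s = sch$end_s[sch$J])
  sim <- simulate_image(spec, sch, sigma_e = 0, seed = 1)
  tb <- tissue_basis(lapply(spec$organs, `[[`, "residue"),
                     vapply(spec$organs, `[[`, numeric(1), "delay_s"),
                     sim$aif, sch)
  fit <- fit_image(sim$image, tb, fit_weights(sch), want_fitted = TRUE)
  agg <- voi_aggregate(fit, sim$organ_labels)
  # homogeneous VOIs: mean equals any member voxel value
  ki_voi1 <- agg$table$value[agg$table$voi_label == 1 &
                             agg$table$parameter == "K_i"]
  vox_vals <- fit$maps$K_i[sim$organ_labels == 1]
  expect_equal(ki_voi1, vox_vals[1], tolerance = 1e-9)
  # invariance to voxel order is inherited from mean(); check sub-VOI
  # recombination with voxel-count weights
  m <- sim$organ_labels == 1
  half <- which(m)[seq_len(floor(sum(m) / 2))]
  labs2 <- sim$organ_labels
  labs2[half] <- 9L
  agg2 <- voi_aggregate(fit, labs2)
  t2 <- agg2$table[agg2$table$parameter == "K_i", ]
  va <- t2$value[t2$voi_label == 1]; na <- t2$voxel_count[t2$voi_label == 1]
  vb <- t2$value[t2$voi_label == 9]; nb <- t2$voxel_count[t2$voi_label == 9]
  expect_equal((va * na + vb * nb) / (na + nb), ki_voi1, tolerance = 1e-9)

  # delay map: single active element with Delta, plus centering
  dm <- delay_map(fit)
  # organ 1 voxels: only elements with its residue active; delay = delta + Delta
  d1 <- dm[sim$organ_labels == 1][1]
  expect_equal(d1, fit$delay_s[1] +
                 sum(fit$alpha[, 1] * tb$delays_s) / sum(fit$alpha[, 1]))
  ref <- sim$organ_labels == 2
  dmc <- delay_map(fit, reference_mask = ref)
  expect_equal(mean(dmc[ref & sim$image$mask], na.rm = TRUE), 0,
               tolerance = 1e-10)
})

test_that("two-voxel mean of basis members fits with averaged amplitudes", {
  sch <- short_schedule()
  tb <- tissue_basis(list(step_residue(sch$end_s[sch$J]),
                          residue(c(0, sch$end_s[sch$J]), c(0.05, 0.05))),
                     c(0, 0), test_aif(sch), sch)
  w <- fit_weights(sch)
  mean_tac <- rowMeans(cbind(tb$mu[, 1], tb$mu[, 2]))
  f <- fit_voi_tac(mean_tac, tb, w)
  expect_equal(f$alpha, c(0.5, 0.5), tolerance = 1e-6)
})
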