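# shared fixtures: all built in code, no stored data

# the printed whole-body binning scheme: 62 frames over 65 min
full_schedule <- function() {
  frame_schedule(list(c(2, 10), c(30, 2), c(4, 10), c(8, 30),
                      c(4, 60), c(5, 120), c(9, 300)))
}

# compact schedule for fast unit tests: 16 frames over 530 s
short_schedule <- function() {
  frame_schedule(list(c(2, 10), c(6, 5), c(4, 30), c(2, 60), c(2, 120)))
}

test_aif <- function(schedule = short_schedule()) make_aif(schedule)

# the closed-form reference residue: 1.0 on [0, 15 s), then
# 0.1 + 0.2 exp(-(t - t*) in minutes); knots dense at the t* step so the
# piecewise-linear representation matches the closed form
step_residue <- function(T_end_s = 3600) {
  g <- c(seq(0, 15, by = 0.5), 15 - 1e-6,
         seq(15, min(600, T_end_s), by = 2.5))
  if (T_end_s > 600) g <- c(g, seq(600, T_end_s, by = 30))
  g <- sort(unique(c(g, T_end_s)))
  g <- g[g <= T_end_s]
  v <- ifelse(g < 15, 1.0, 0.1 + 0.2 * exp(-(g - 15) / 60))
  residue(g, v, tol = 1e-5)
}

# random admissible residue on a given grid (seeded by caller)
random_residue <- function(T_end_s = 600, n_knots = 12) {
  g <- c(0, sort(runif(n_knots - 2, 0, T_end_s)), T_end_s)
  inc <- rgamma(n_knots, 1, 4)          # increments of a nonincreasing fn
  v <- rev(cumsum(rev(inc)))
  residue(g, v)
}

# brute-force non-negative weighted LS by active-set enumeration:
# the independent oracle for the QP solver
nnls_enum <- function(A, b, w = rep(1, length(b))) {
  K <- ncol(A)
  Aw <- A * sqrt(w); bw <- b * sqrt(w)
  best <- NULL
  for (mask in 0:(2^K - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(K) - 1)) > 0)
    x <- rep(0, K)
    if (length(idx) > 0) {
      As <- Aw[, idx, drop = FALSE]
      xi <- tryCatch(solve(crossprod(As), crossprod(As, bw)),
                     error = function(e) NULL)
      if (is.null(xi) || any(xi < 0)) next
      x[idx] <- xi
    }
    r <- sum((bw - Aw %*% x)^2)
    if (is.null(best) || r < best$wrss - 1e-12) best <- list(x = x, wrss = r)
  }
  best
}

# small two-organ phantom TAC matrix with known labels
two_organ_tacs <- function(schedule, aif, N_per = 40, noise = 0.3, seed = 1) {
  spec <- standard_phantoms("twocomp", dim = c(8, 8, 9),
                            T_end_s = schedule$end_s[schedule$J])
  res <- lapply(spec$organs[1:2], `[[`, "residue")
  tb <- tissue_basis(res, c(0, 0), aif, schedule)
  set.seed(seed)
  Z0 <- cbind(matrix(tb$mu[, 1], schedule$J, N_per),
              matrix(tb$mu[, 2], schedule$J, N_per))
  Z <- Z0 + noise * matrix(rnorm(length(Z0)), nrow(Z0))
  list(Z = Z, labels = rep(1:2, each = N_per), residues = res, mu = tb$mu)
}
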