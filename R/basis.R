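#' Tissue basis construction
#'
#' Voxel time courses are modelled as non-negative combinations of K basis
#' tissue curves mu_k(t) = int_0^t R_k(t - s) Cp(s - Delta_k) ds, where R_k
#' is a data-derived admissible residue and Delta_k its delay.  Candidate
#' residues are fitted to segment mean time courses under shape constraints
#' (non-negative, non-increasing) via a quadratic program over residue
#' increments; cross-validation over voxels selects the number of elements.
#'
#' @name basis
NULL

# Geometric residue knot grid, seconds: dense early (vascular transit),
# sparse late.  0 is always a knot.
residue_knots <- function(T_end_s, n = 30) {
  c(0, exp(seq(log(1), log(T_end_s), length.out = n)))
}

# Elementary non-increasing residue shapes on a knot grid, evaluated on a
# fine time vector (0 outside [0, max knot]).  Column 1 is the constant
# element; column m+1 drops linearly from 1 at knots[m] to 0 at knots[m+1].
# Any admissible piecewise-linear residue on the knots is a non-negative
# combination of these.
elementary_residues <- function(knots, t) {
  M <- length(knots) - 1L
  B <- matrix(0, length(t), M + 1L)
  inside <- t >= 0 & t <= knots[M + 1L]
  B[inside, 1L] <- 1
  for (m in seq_len(M)) {
    g0 <- knots[m]; g1 <- knots[m + 1L]
    v <- ifelse(t <= g0, 1, ifelse(t >= g1, 0, (g1 - t) / (g1 - g0)))
    v[t < 0] <- 0
    B[, m + 1L] <- v
  }
  B
}

# causal convolution of y (sampled on a grid starting at time y_t0, step dt)
# with r (sampled on 0, dt, 2dt, ...): returns the convolution on the same
# grid as y (first length(y) points), rectangle rule.
conv_causal <- function(r, y, dt) {
  n <- length(y)
  z <- stats::convolve(y, rev(r), type = "open")[seq_len(n)]
  z * dt
}

#' Construct a tissue basis set
#'
#' Bundles K residues with their delays and precomputes the frame-averaged
#' tissue curves on the study schedule.  All residues are resampled onto a
#' common knot grid.
#'
#' @param residues list of \code{\link{residue}} objects.
#' @param delays_s per-element delay Delta_k, seconds.
#' @param aif an \code{input_function}.
#' @param schedule a \code{frame_schedule}.
#' @param fine_dt_s fine evaluation grid step, seconds.
#' @param pad_after_s padding beyond the last frame so negative voxel delays
#'   can be evaluated.
#' @return object of class \code{tissue_basis}: fields K, residues,
#'   delays_s, mu (J x K frame-averaged curves at voxel delay 0), plus the
#'   internal fine-grid convolutions used by the fitters.
#' @export
tissue_basis <- function(residues, delays_s, aif, schedule, fine_dt_s = 1,
                         pad_after_s = 60) {
  stopifnot(length(residues) == length(delays_s), length(residues) >= 1)
  K <- length(residues)
  knots <- sort(unique(unlist(lapply(residues, function(r) r$grid_s))))
  residues <- lapply(residues, function(r)
    residue(knots, eval_residue(r, knots), tol = 1e-6))
  fg <- fine_grid(schedule, dt = fine_dt_s, pad_after_s = pad_after_s)
  tpos <- fg$s
  cp <- eval_input(aif, fg$t)
  # base convolutions U_k(t) = (R_k * Cp)(t) on the fine grid; element delay
  # applied as an index shift of Cp
  U <- matrix(0, length(fg$t), K)
  for (k in seq_len(K)) {
    rfine <- eval_residue(residues[[k]], tpos) / 60  # flow per second
    cpk <- eval_input(aif, fg$t - delays_s[k])
    U[, k] <- conv_causal(rfine, cpk, fg$dt)
  }
  mu <- vapply(seq_len(K), function(k)
    frame_average_indexed(U[, k], fg$bins), numeric(schedule$J))
  mu <- matrix(mu, nrow = schedule$J)
  structure(list(K = K, residues = residues, delays_s = as.numeric(delays_s),
                 knots = knots, mu = mu, U = U, fg = fg,
                 schedule = schedule, aif = aif, fine_dt_s = fine_dt_s),
            class = "tissue_basis")
}

#' @export
print.tissue_basis <- function(x, ...) {
  cat(sprintf("tissue_basis: K = %d elements, delays %s s\n", x$K,
              paste(format(x$delays_s), collapse = ", ")))
  invisible(x)
}

# J x (K*D) design of frame-averaged basis curves over a voxel delay grid,
# delay-major column order (matches fit_tacs_cpp).
basis_design <- function(basis, delta_grid_s) {
  fg <- basis$fg
  J <- basis$schedule$J
  K <- basis$K
  D <- length(delta_grid_s)
  M <- matrix(0, J, K * D)
  nfg <- length(fg$t)
  for (d in seq_len(D)) {
    nshift <- delta_grid_s[d] / fg$dt
    for (k in seq_len(K)) {
      if (abs(nshift - round(nshift)) < 1e-9) {
        ns <- as.integer(round(nshift))
        shifted <- numeric(nfg)
        if (ns >= 0) {
          if (ns < nfg) shifted[(ns + 1L):nfg] <- basis$U[seq_len(nfg - ns), k]
        } else {
          shifted[seq_len(nfg + ns)] <- basis$U[(-ns + 1L):nfg, k]
        }
      } else {
        shifted <- stats::approx(fg$t + delta_grid_s[d], basis$U[, k],
                                 xout = fg$t, yleft = 0,
                                 yright = basis$U[nfg, k])$y
      }
      M[, (d - 1L) * K + k] <- frame_average_indexed(shifted, fg$bins)
    }
  }
  M
}

# per-element kinetic parameter loadings: K x 4 matrix (V_b, V_d, K_d, K_i);
# voxel parameters are alpha' %*% loadings since the decomposition is linear
# in the residue.
basis_param_matrix <- function(basis, t_star_s = 15,
                               T_end_s = basis$schedule$end_s[basis$schedule$J]) {
  out <- t(vapply(basis$residues, function(r) {
    p <- kinetic_params(decompose_residue(r, t_star_s, min(T_end_s, max(r$grid_s))))
    c(V_b = p$V_b, V_d = p$V_d, K_d = p$K_d, K_i = p$K_i)
  }, numeric(4)))
  out
}

#' Segment voxel time courses by k-means on normalised TACs
#'
#' Each masked voxel TAC is normalised by its time integral (frames weighted
#' by duration) and clustered with k-means.  Deterministic given
#' \code{seed}.
#'
#' @param tacs J x N matrix of voxel time courses (columns = voxels), or a
#'   \code{dynamic_image} (masked voxels are extracted).
#' @param schedule a \code{frame_schedule}.
#' @param S number of segments, >= 1.
#' @param seed RNG seed.
#' @param max_voxels voxels subsampled for the k-means step (labels for the
#'   rest by nearest centre).
#' @return list of class \code{tac_segmentation}: \code{labels} (per
#'   voxel/column), \code{mean_tacs} (J x S), \code{sizes}, \code{tacs}.
#' @export
segment_tacs <- function(tacs, schedule, S, seed = 1, max_voxels = 50000) {
  if (inherits(tacs, "dynamic_image")) tacs <- image_tac_matrix(tacs)
  Z <- tacs
  stopifnot(nrow(Z) == schedule$J, S >= 1)
  N <- ncol(Z)
  if (S > N) stop("more segments than voxels")
  integ <- as.numeric(crossprod(Z, schedule$duration_s))
  integ[integ <= 0] <- 1
  Znorm <- sweep(Z, 2, integ, "/")
  if (S == 1L) {
    labels <- rep(1L, N)
  } else {
    set.seed(seed)
    idx <- if (N > max_voxels) sort(sample.int(N, max_voxels)) else seq_len(N)
    km <- tryCatch(
      stats::kmeans(t(Znorm[, idx, drop = FALSE]), centers = S,
                    nstart = 5, iter.max = 100),
      error = function(e) {
        # fewer distinct time courses than requested segments (e.g. a
        # noiseless phantom): fall back to the distinct count
        nd <- nrow(unique(round(t(Znorm[, idx, drop = FALSE]), 10)))
        if (nd >= S) stop(e)
        S <<- nd
        stats::kmeans(t(Znorm[, idx, drop = FALSE]), centers = nd,
                      nstart = 5, iter.max = 100)
      })
    labels <- integer(N)
    labels[idx] <- km$cluster
    if (length(idx) < N) {
      rest <- setdiff(seq_len(N), idx)
      d2 <- t(km$centers %*% Znorm[, rest, drop = FALSE])  # N_rest x S inner prods
      cn2 <- rowSums(km$centers^2)
      zn2 <- colSums(Znorm[, rest, drop = FALSE]^2)
      dist2 <- outer(zn2, cn2, "+") - 2 * d2
      labels[rest] <- max.col(-dist2)
    }
  }
  mean_tacs <- vapply(seq_len(S), function(s) {
    m <- labels == s
    if (!any(m)) rep(0, schedule$J) else rowMeans(Z[, m, drop = FALSE])
  }, numeric(schedule$J))
  structure(list(labels = labels, mean_tacs = matrix(mean_tacs, nrow = schedule$J),
                 sizes = tabulate(labels, S), S = S, tacs = Z),
            class = "tac_segmentation")
}

#' Fit a shape-constrained residue (plus delay) to one time course
#'
#' The residue is piecewise linear on a fixed knot grid, non-negative and
#' non-increasing by construction: it is expressed as a non-negative
#' combination of elementary non-increasing shapes, and the weighted
#' least-squares fit of the frame-averaged convolution model is solved as a
#' quadratic program.  The delay is optimised by grid search.
#'
#' @param tac per-frame time course, length J.
#' @param aif an \code{input_function}.
#' @param schedule a \code{frame_schedule}.
#' @param weights frame weights (default \code{\link{fit_weights}}).
#' @param delay_grid_s candidate delays, seconds.
#' @param knots residue knot grid, seconds (default geometric, 30 knots).
#' @param fine_dt_s fine grid step.
#' @return list: \code{residue}, \code{delay_s}, \code{wrss},
#'   \code{fitted}, \code{flag} ("ok" or "zero-signal").
#' @export
fit_segment_residue <- function(tac, aif, schedule, weights = fit_weights(schedule),
                                delay_grid_s = seq(-20, 60, by = 2),
                                knots = residue_knots(schedule$end_s[schedule$J]),
                                fine_dt_s = 1) {
  J <- schedule$J
  stopifnot(length(tac) == J)
  T_end <- schedule$end_s[J]
  if (all(abs(tac) < 1e-12)) {
    r0 <- residue(knots, rep(0, length(knots)))
    return(list(residue = r0, delay_s = 0, wrss = 0,
                fitted = rep(0, J), flag = "zero-signal"))
  }
  pad <- max(0, -min(delay_grid_s))
  fg <- fine_grid(schedule, dt = fine_dt_s, pad_after_s = pad)
  tpos <- fg$s
  B <- elementary_residues(knots, tpos) / 60   # flow per second
  cp <- eval_input(aif, fg$t)
  # conv with a delayed input equals a time-shift of the base convolution,
  # so convolve each elementary shape once and shift per candidate delay
  U0 <- apply(B, 2, function(b) conv_causal(b, cp, fg$dt))
  ns_grid <- as.integer(round(delay_grid_s / fg$dt))
  si <- .shift_index(fg, ns_grid)
  # frame means for every (delay, elementary shape) pair at once
  FmArr <- array(0, c(schedule$J, length(ns_grid), ncol(U0)))
  for (m in seq_len(ncol(U0))) FmArr[, , m] <- .shift_means(U0[, m], si)
  best <- NULL
  zW <- weights * tac
  zWz <- sum(weights * tac^2)
  for (d in seq_along(delay_grid_s)) {
    A <- matrix(FmArr[, d, ], nrow = schedule$J)
    AtA <- crossprod(A, weights * A)
    Atb <- as.numeric(crossprod(A, zW))
    beta <- as.numeric(nnls_solve_cpp(AtA, Atb))
    wrss <- max(0, zWz - 2 * sum(beta * Atb) +
                  as.numeric(t(beta) %*% AtA %*% beta))
    if (is.null(best) || wrss < best$wrss) {
      best <- list(beta = beta, delta = delay_grid_s[d], wrss = wrss, A = A)
    }
  }
  # beta multiplies the per-second elementary shapes B/60, so the fitted
  # residue in per-minute flow units is simply B %*% beta
  Bk <- elementary_residues(knots, knots)
  rvals <- as.numeric(Bk %*% best$beta)
  r <- residue(knots, rvals, tol = 1e-6)
  list(residue = r, delay_s = best$delta, wrss = best$wrss,
       fitted = as.numeric(best$A %*% best$beta), flag = "ok")
}

#' Select a tissue basis by cross-validation over voxels
#'
#' One candidate residue is fitted per segment mean time course.  For each
#' candidate basis size K, elements are chosen greedily (seeded by segment
#' signal ranking) to minimise training WRSS; K is chosen to minimise
#' cross-validated prediction WRSS on held-out voxel TACs, ties broken
#' toward smaller K.
#'
#' @param segments a \code{tac_segmentation}.
#' @param aif,schedule,weights as elsewhere.
#' @param K_grid candidate basis sizes.
#' @param cv_folds folds over voxels (default 10).
#' @param seed RNG seed (fold assignment).
#' @param delay_grid_s candidate element delays.
#' @param max_cv_voxels voxels subsampled for the CV computation.
#' @param fine_dt_s fine grid step.
#' @param one_se use the one-standard-error rule (smallest K whose CV score
#'   is within one fold-SE of the minimum; default TRUE).  With
#'   \code{FALSE} the plain minimiser is used, which for nested
#'   non-negative bases tends to drift to the largest K because unused
#'   elements carry almost no variance penalty.
#' @return a \code{tissue_basis} with attributes \code{cv} (per-K CV WRSS
#'   and fold-SE) and \code{K_selected}.
#' @export
select_basis <- function(segments, aif, schedule, weights = fit_weights(schedule),
                         K_grid = 1:6, cv_folds = 10, seed = 1,
                         delay_grid_s = seq(-20, 60, by = 2),
                         max_cv_voxels = 2000, fine_dt_s = 1, one_se = TRUE) {
  if (length(K_grid) == 0L) stop("empty K_grid")
  S <- segments$S
  K_grid <- sort(unique(pmin(K_grid, S)))
  knots <- residue_knots(schedule$end_s[schedule$J])
  cand <- lapply(seq_len(S), function(s)
    fit_segment_residue(segments$mean_tacs[, s], aif, schedule, weights,
                        delay_grid_s, knots, fine_dt_s))
  ok <- vapply(cand, function(cf) cf$flag == "ok", logical(1))
  signal <- segments$sizes * as.numeric(crossprod(segments$mean_tacs,
                                                  schedule$duration_s))
  ord <- order(!ok, -signal)   # zero-signal candidates last

  full <- tissue_basis(lapply(cand, `[[`, "residue"),
                       vapply(cand, `[[`, numeric(1), "delay_s"),
                       aif, schedule, fine_dt_s = fine_dt_s)
  mu_all <- full$mu            # J x S, voxel delay 0 (selection uses delta = 0)

  Z <- segments$tacs
  N <- ncol(Z)
  set.seed(seed)
  sub <- if (N > max_cv_voxels) sort(sample.int(N, max_cv_voxels)) else seq_len(N)
  Zs <- Z[, sub, drop = FALSE]
  fold <- sample(rep_len(seq_len(cv_folds), length(sub)))

  greedy_path <- function(cols_avail, Ztrain, Kmax) {
    chosen <- integer(0)
    # seed with the highest-signal candidate, then greedy WRSS descent
    for (step in seq_len(Kmax)) {
      rem <- setdiff(cols_avail, chosen)
      if (length(rem) == 0L) break
      sc <- vapply(rem, function(cidx) {
        Mtry <- mu_all[, c(chosen, cidx), drop = FALSE]
        f <- fit_tacs_cpp(Ztrain, Mtry, ncol(Mtry), 1L, weights)
        sum(f$wrss)
      }, numeric(1))
      chosen <- c(chosen, rem[which.min(sc)])
    }
    chosen
  }

  avail <- ord[ok[ord]]
  if (length(avail) == 0L) stop("all segment candidates have zero signal")
  Kmax <- min(max(K_grid), length(avail))
  K_grid <- K_grid[K_grid <= Kmax]

  # held-out voxels are scored by genuine prediction: amplitudes fitted on
  # the odd frames only, WRSS evaluated on the even frames (refitting the
  # held-out TAC on all frames is monotone in K for nested bases and
  # cannot show overfitting)
  odd <- seq_len(schedule$J) %% 2 == 1
  w_fit <- weights * odd
  w_eval <- weights * !odd
  cv_fold <- matrix(NA_real_, cv_folds, length(K_grid))
  for (f in seq_len(cv_folds)) {
    tr <- Zs[, fold != f, drop = FALSE]
    ho <- Zs[, fold == f, drop = FALSE]
    if (ncol(tr) == 0L || ncol(ho) == 0L) next
    path <- greedy_path(avail, tr, Kmax)
    for (ki in seq_along(K_grid)) {
      cols <- path[seq_len(K_grid[ki])]
      Mtry <- mu_all[, cols, drop = FALSE]
      fit <- fit_tacs_cpp(ho, Mtry, length(cols), 1L, w_fit)
      pred <- Mtry %*% fit$alpha
      cv_fold[f, ki] <- sum(w_eval * (ho - pred)^2) / ncol(ho)
    }
  }
  cv_mean <- colMeans(cv_fold, na.rm = TRUE)
  nf_ok <- colSums(!is.na(cv_fold))
  cv_se <- apply(cv_fold, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(nf_ok, 1))
  kmin <- which.min(cv_mean)
  K_sel <- if (one_se) {
    K_grid[which(cv_mean <= cv_mean[kmin] + cv_se[kmin])[1]]
  } else {
    K_grid[kmin]   # which.min takes the first (smallest K) tie
  }

  path <- greedy_path(avail, Zs, Kmax)
  cols <- path[seq_len(K_sel)]
  out <- tissue_basis(lapply(cand[cols], `[[`, "residue"),
                      vapply(cand[cols], `[[`, numeric(1), "delay_s"),
                      aif, schedule, fine_dt_s = fine_dt_s)
  attr(out, "cv") <- data.frame(K = K_grid, cv_wrss = cv_mean, cv_se = cv_se)
  attr(out, "K_selected") <- K_sel
  attr(out, "candidates") <- cols
  out
}

#' Save / load a tissue basis as a JSON bundle
#'
#' Stores the knot grid, residue values, delays and schedule so fits are
#' reproducible; the AIF samples are embedded.
#'
#' @param basis a \code{tissue_basis}.
#' @param path output file (.json).
#' @rdname basis_io
#' @export
save_basis <- function(basis, path) {
  obj <- list(
    knots = basis$knots,
    residues = lapply(basis$residues, function(r) r$values),
    delays_s = basis$delays_s,
    fine_dt_s = basis$fine_dt_s,
    schedule = list(start_s = basis$schedule$start_s,
                    duration_s = basis$schedule$duration_s,
                    halflife_min = basis$schedule$isotope_halflife_min),
    aif = list(time_s = basis$aif$time_s + basis$aif$delay_s,
               activity = basis$aif$activity))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname basis_io
#' @export
load_basis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sch <- new_frame_schedule(obj$schedule$start_s, obj$schedule$duration_s,
                            obj$schedule$halflife_min)
  aif <- input_function(obj$aif$time_s, obj$aif$activity)
  K <- length(obj$delays_s)
  res <- lapply(seq_len(K), function(k) {
    v <- if (is.list(obj$residues)) obj$residues[[k]]
         else if (is.matrix(obj$residues)) obj$residues[k, ]
         else obj$residues
    residue(obj$knots, v)
  })
  tissue_basis(res, obj$delays_s, aif, sch, fine_dt_s = obj$fine_dt_s)
}
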