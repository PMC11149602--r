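#' VOI aggregation and cross-method comparisons
#'
#' @name summaries
NULL

#' Aggregate voxel kinetics over labelled VOIs
#'
#' Produces one row per (VOI, parameter) with the unweighted mean of voxel
#' parameter values, plus the VOI mean measured and fitted time courses.
#'
#' @param fit an \code{nprm_fit} (from \code{\link{fit_image}}).
#' @param voi_labels 3D integer array of VOI labels (0 = outside all VOIs),
#'   matching the image geometry.
#' @param method method tag recorded in the table (default "voxel-NP").
#' @param study_id study identifier recorded in the table.
#' @return list: \code{table} (data.frame study_id, voi_label, method,
#'   parameter, value, voxel_count), \code{mean_tacs} and
#'   \code{mean_fitted} (J x n_voi matrices, fitted only if available).
#' @export
voi_aggregate <- function(fit, voi_labels, method = "voxel-NP", study_id = "study1") {
  image <- fit$image
  if (!identical(dim(voi_labels), image$dim))
    stop("VOI label geometry does not match the image")
  lab_masked <- voi_labels[image$mask]
  labs <- sort(unique(lab_masked[lab_masked > 0]))
  if (length(labs) == 0) stop("no non-empty VOI labels inside the mask")
  Z <- image_tac_matrix(image)
  pnames <- names(fit$params)
  rows <- list()
  mean_tacs <- matrix(0, image$schedule$J, length(labs),
                      dimnames = list(NULL, paste0("voi", labs)))
  mean_fitted <- if (!is.null(fit$fitted)) mean_tacs else NULL
  for (li in seq_along(labs)) {
    m <- lab_masked == labs[li]
    mean_tacs[, li] <- rowMeans(Z[, m, drop = FALSE])
    if (!is.null(mean_fitted))
      mean_fitted[, li] <- rowMeans(fit$fitted[, m, drop = FALSE])
    for (pn in pnames) {
      rows[[length(rows) + 1L]] <- data.frame(
        study_id = study_id, voi_label = labs[li], method = method,
        parameter = pn, value = mean(fit$params[[pn]][m], na.rm = TRUE),
        wrss = mean(fit$wrss[m], na.rm = TRUE),
        voxel_count = sum(m))
    }
  }
  list(table = do.call(rbind, rows), mean_tacs = mean_tacs,
       mean_fitted = mean_fitted, voi_labels = labs)
}

#' Compare WRSS between methods over matched VOIs
#'
#' For each pair of methods the percent deviation
#' 100 (WRSS_B - WRSS_A) / WRSS_A is computed per (study, VOI), with A the
#' reference method; zero-denominator pairs are excluded and counted.
#'
#' @param wrss_table data.frame with columns study_id, voi_label, method,
#'   wrss (one row per combination).
#' @param reference reference method A (default "voxel-NP").
#' @return data.frame: method, mean_wrss, sd_wrss, mean_pct_dev,
#'   sd_pct_dev, n, n_excluded.
#' @export
wrss_compare <- function(wrss_table, reference = "voxel-NP") {
  methods <- unique(wrss_table$method)
  if (!reference %in% methods) stop("reference method not present")
  key <- function(d) paste(d$study_id, d$voi_label)
  ref <- wrss_table[wrss_table$method == reference, ]
  out <- lapply(methods, function(m) {
    dm <- wrss_table[wrss_table$method == m, ]
    idx <- match(key(dm), key(ref))
    a <- ref$wrss[idx]; b <- dm$wrss
    ok <- !is.na(a) & a > 0
    pct <- 100 * (b[ok] - a[ok]) / a[ok]
    data.frame(method = m,
               mean_wrss = mean(b, na.rm = TRUE),
               sd_wrss = stats::sd(b, na.rm = TRUE),
               mean_pct_dev = if (m == reference) 0 else mean(pct),
               sd_pct_dev = if (m == reference) 0 else stats::sd(pct),
               n = sum(ok), n_excluded = sum(!ok))
  })
  do.call(rbind, out)
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped; ties get midranks.  The exact null
#' distribution is used for n <= 25 (no ties), otherwise a normal
#' approximation with continuity and tie corrections.  Two-sided p-value.
#'
#' @param x,y paired samples of equal length.
#' @return list: \code{statistic} (V, sum of positive-difference ranks),
#'   \code{p_value}, \code{n} (non-zero pairs), \code{flag}.
#' @export
paired_wilcoxon <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p_value = 1, n = 0,
                flag = "all differences zero"))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    p_lo <- stats::psignrank(V, n)
    p_hi <- stats::psignrank(V - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = V, p_value = p, n = n,
       flag = if (n < 5) "n < 5 after dropping zeros" else "ok")
}

#' Log-linear regression of bootstrap SEs on fit summaries
#'
#' log(SE) is regressed on VOI-type indicators, log weighted-RMS residual of
#' the VOI fit, and the log kinetic magnitude (entered as
#' \code{log(|value| + 1e-6)}).
#'
#' @param se_table data.frame with columns voi_type, se (> 0), wrms (> 0),
#'   value.
#' @return list: \code{fit} (lm), \code{coefficients},
#'   \code{predicted_se} (raw scale), \code{cor_log}, \code{cor_raw},
#'   \code{rank_deficient}.
#' @export
se_loglinear <- function(se_table) {
  stopifnot(all(c("voi_type", "se", "wrms", "value") %in% names(se_table)))
  if (any(se_table$se <= 0)) stop("SEs must be positive")
  if (length(unique(se_table$voi_type)) < 2)
    stop("need at least 2 VOI types")
  df <- data.frame(log_se = log(se_table$se),
                   voi_type = factor(se_table$voi_type),
                   log_wrms = log(se_table$wrms),
                   log_val = log(abs(se_table$value) + 1e-6))
  fit <- stats::lm(log_se ~ voi_type + log_wrms + log_val, data = df)
  pred_log <- stats::fitted(fit)
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  list(fit = fit, coefficients = stats::coef(fit),
       predicted_se = exp(pred_log),
       cor_log = safe_cor(df$log_se, pred_log),
       cor_raw = safe_cor(se_table$se, exp(pred_log)),
       rank_deficient = fit$rank < length(stats::coef(fit)))
}

#' Amplitude-weighted delay map
#'
#' Per voxel d = delta + sum_k alpha_k Delta_k / sum_k alpha_k (missing
#' where all amplitudes are zero), optionally centred so a reference VOI has
#' mean delay 0.
#'
#' @param fit an \code{nprm_fit}.
#' @param reference_mask optional 3D logical array (e.g. a descending-aorta
#'   VOI) whose mean delay is subtracted.
#' @return 3D array of delays, seconds.
#' @export
delay_map <- function(fit, reference_mask = NULL) {
  alpha <- fit$alpha
  basis <- fit$basis
  tot <- colSums(alpha)
  wdel <- as.numeric(crossprod(alpha, basis$delays_s))
  d <- ifelse(tot > 0, fit$delay_s + wdel / tot, NA_real_)
  m <- map_from_vector(d, fit$image)
  if (!is.null(reference_mask)) {
    ref <- m[reference_mask & fit$image$mask]
    ref <- ref[is.finite(ref)]
    if (length(ref) == 0) stop("reference VOI empty (or all flagged)")
    m <- m - mean(ref)
  }
  m
}
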